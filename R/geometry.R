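# Electrode geometry: planar disk microelectrodes on an array plane.

#' Planar disk electrode geometry
#'
#' Describes a single disk stimulating electrode by its diameter and position
#' on the array plane. Charge capacities in this package are referenced to
#' the geometric (not electrochemically effective) disk area.
#'
#' @param diameter_um Disk diameter in micrometres (> 0). Typical values for
#'   high-acuity subretinal arrays are 10, 20 and 30 um.
#' @param center_um Numeric length-2, electrode centre on the array plane (um).
#' @param label Optional identifier.
#' @return An object of class `electrode_geometry`.
#' @examples
#' geom <- electrode_geometry(10)
#' disk_area(geom) # 7.854e-7 cm^2
#' @export
electrode_geometry <- function(diameter_um, center_um = c(0, 0), label = NULL) {
  if (!is.numeric(diameter_um) || length(diameter_um) != 1L ||
      !is.finite(diameter_um) || diameter_um <= 0) {
    stop_stim("electrode diameter must be a single positive number (um)",
              "invalid_geometry")
  }
  structure(
    list(diameter_um = diameter_um, center_um = center_um,
         label = label %||% sprintf("d%gum", diameter_um)),
    class = "electrode_geometry"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.electrode_geometry <- function(x, ...) {
  cat(sprintf("<electrode_geometry> %s: disk d = %g um, area = %.4g cm^2\n",
              x$label, x$diameter_um, disk_area(x)))
  invisible(x)
}

#' Geometric disk area
#'
#' @param geometry An [electrode_geometry()].
#' @return Area pi d^2 / 4 in cm^2.
#' @export
disk_area <- function(geometry) {
  stopifnot(inherits(geometry, "electrode_geometry"))
  d_cm <- geometry$diameter_um * 1e-4
  pi * d_cm^2 / 4
}

#' Maximum injectable charge per pulse phase
#'
#' The safe charge per stimulation phase scales with geometric area at a
#' fixed charge-injection-capacity density, so it grows as diameter squared.
#'
#' @param geometry An [electrode_geometry()].
#' @param cic_mC_cm2 Charge injection capacity density (mC/cm^2, >= 0).
#' @param signif Optional number of significant figures for presentation
#'   rounding (reports in the field typically quote 2); `NULL` (default)
#'   returns the exact product.
#' @return Charge in nC.
#' @examples
#' max_injectable_charge(electrode_geometry(10), 3.3) # 2.59 nC
#' max_injectable_charge(electrode_geometry(20), 3.3) # 10.37 nC
#' @export
max_injectable_charge <- function(geometry, cic_mC_cm2, signif = NULL) {
  if (!is.numeric(cic_mC_cm2) || length(cic_mC_cm2) != 1L || cic_mC_cm2 < 0) {
    stop_stim("CIC density must be a single non-negative number (mC/cm^2)",
              "invalid_parameter")
  }
  q_nC <- cic_mC_cm2 * 1e-3 * disk_area(geometry) * 1e9
  if (!is.null(signif)) q_nC <- base::signif(q_nC, signif)
  q_nC
}
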