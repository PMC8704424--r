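# Electrochemical characterisation of stimulation microelectrodes:
# charge storage capacity (CSC) from slow cyclic voltammetry, and charge
# injection capacity (CIC) from biphasic-pulse voltage transients.
#
# Conventions: anodic current positive; potentials vs the reference
# electrode; densities reported per geometric area in mC/cm^2; SI units
# internally.

#' Electrochemical safety limits (water window)
#'
#' The water window is the potential range within which electrode reactions
#' stay reversible; for sputtered iridium oxide it spans -0.6 V (cathodal)
#' to +0.8 V (anodal). Electrode polarization is sampled a short delay after
#' each current phase ends, once the ohmic access-voltage step has vanished.
#'
#' @param anodic_limit_V Upper polarization limit (V), default +0.8.
#' @param cathodic_limit_V Lower polarization limit (V), default -0.6.
#' @param sample_delay_s Delay after a phase end at which polarization is
#'   read (s), default 10 us.
#' @return Object of class `electrochem_limits`.
#' @export
electrochem_limits <- function(anodic_limit_V = 0.8, cathodic_limit_V = -0.6,
                               sample_delay_s = 10e-6) {
  if (!(cathodic_limit_V < 0 && 0 < anodic_limit_V)) {
    stop_stim("water window must straddle 0 V (cathodic < 0 < anodic)",
              "invalid_parameter")
  }
  if (sample_delay_s <= 0) stop_stim("sample_delay_s must be > 0", "invalid_parameter")
  structure(list(anodic_limit_V = anodic_limit_V,
                 cathodic_limit_V = cathodic_limit_V,
                 sample_delay_s = sample_delay_s),
            class = "electrochem_limits")
}

#' Cyclic voltammetry scan record
#'
#' @param time_s Sample times (s), strictly increasing.
#' @param potential_V Working-electrode potential vs reference (V).
#' @param current_A Measured current (A), anodic positive.
#' @param scan_rate_V_per_s Nominal sweep rate (V/s), e.g. 0.2.
#' @param vertex_low_V,vertex_high_V Sweep vertices (V).
#' @return Object of class `cv_scan`.
#' @export
cv_scan <- function(time_s, potential_V, current_A, scan_rate_V_per_s,
                    vertex_low_V, vertex_high_V) {
  n <- length(time_s)
  if (length(potential_V) != n || length(current_A) != n) {
    stop_stim("time, potential and current must have equal length", "format")
  }
  if (n < 2L || any(diff(time_s) <= 0)) {
    stop_stim("CV scan time base must be strictly increasing", "format")
  }
  if (vertex_low_V >= vertex_high_V) stop_stim("vertex_low_V must be < vertex_high_V", "format")
  tol <- 1e-9 + 1e-6 * (vertex_high_V - vertex_low_V)
  if (any(potential_V < vertex_low_V - tol | potential_V > vertex_high_V + tol)) {
    stop_stim("potential leaves the [vertex_low, vertex_high] range", "format")
  }
  structure(list(time_s = time_s, potential_V = potential_V, current_A = current_A,
                 scan_rate_V_per_s = scan_rate_V_per_s,
                 vertex_low_V = vertex_low_V, vertex_high_V = vertex_high_V),
            class = "cv_scan")
}

#' Charge storage capacity from a CV scan
#'
#' Integrates the anodic (i > 0) and cathodic (i < 0) current magnitudes over
#' time, restricted to samples whose potential lies inside the water window,
#' and normalises by geometric area. When the scan covers two or more full
#' cycles the first (conditioning) cycle is discarded and the remainder
#' averaged per cycle; a scan shorter than one full cycle is integrated as a
#' single segment with a warning. Trapezoidal quadrature.
#'
#' @param scan A [cv_scan()].
#' @param geometry An [electrode_geometry()].
#' @param limits An [electrochem_limits()].
#' @return List with `csc_anodic_mC_cm2` and `csc_cathodic_mC_cm2`.
#' @export
compute_csc <- function(scan, geometry, limits = electrochem_limits()) {
  stopifnot(inherits(scan, "cv_scan"))
  t <- scan$time_s; v <- scan$potential_V; i <- scan$current_A
  area <- disk_area(geometry)

  cycle_s <- 2 * (scan$vertex_high_V - scan$vertex_low_V) / scan$scan_rate_V_per_s
  span <- t[length(t)] - t[1L]
  n_complete <- floor(span / cycle_s + 1e-9)
  if (n_complete < 1L) {
    warn_stim("CV scan shorter than one full cycle; integrating single segment",
              "incomplete_cycle")
    window <- rep(TRUE, length(t))
    n_used <- 1L
  } else if (n_complete >= 2L) {
    t0 <- t[1L] + cycle_s                 # drop the conditioning cycle
    t1 <- t[1L] + n_complete * cycle_s
    window <- t >= t0 - 1e-12 & t <= t1 + 1e-12
    n_used <- n_complete - 1L
  } else {
    window <- t <= t[1L] + cycle_s + 1e-12
    n_used <- 1L
  }

  in_win <- v >= limits$cathodic_limit_V - 1e-12 & v <= limits$anodic_limit_V + 1e-12
  # Per-interval integration with the anodic/cathodic attribution taken from
  # the sweep direction: |i| is continuous across the vertices while the
  # sampled current sign flips there, so direction-based attribution keeps
  # the quadrature error at O(dt^2) instead of O(dt) per vertex.
  ok <- (window & in_win)[-length(t)] & (window & in_win)[-1L]
  up <- diff(v) > 0
  seg <- diff(t) * (abs(i)[-length(i)] + abs(i)[-1L]) / 2
  q_an <- sum(seg[ok & up])
  q_ca <- sum(seg[ok & !up])

  list(csc_anodic_mC_cm2   = 1e3 * q_an / (n_used * area),
       csc_cathodic_mC_cm2 = 1e3 * q_ca / (n_used * area))
}

#' Charge-balanced biphasic stimulus pulse
#'
#' Anodic-first rectangular current pulse; the two phases carry equal and
#' opposite charge Q = I * phase_width. An interphase gap at zero current
#' separates the phases so post-phase polarization can be sampled without
#' the ohmic access-voltage contribution.
#'
#' @param amplitude_A Phase current magnitude (A, > 0 for a real pulse).
#' @param phase_width_s Duration of each phase (s); 1 or 5 ms typical.
#' @param interphase_gap_s Zero-current gap between phases (s), default 100 us.
#' @param n_pulses,freq_hz Train structure: number of pulses and rate
#'   (20 pulses at 500 Hz for train protocols; defaults describe a single pulse).
#' @return Object of class `stimulus_pulse` with derived `charge_nC`
#'   (per-phase charge).
#' @export
stimulus_pulse <- function(amplitude_A, phase_width_s,
                           interphase_gap_s = 100e-6,
                           n_pulses = 1L, freq_hz = NA_real_) {
  if (amplitude_A < 0) stop_stim("pulse amplitude must be >= 0", "invalid_parameter")
  if (phase_width_s <= 0) stop_stim("phase width must be > 0", "invalid_parameter")
  if (n_pulses > 1L && (!is.finite(freq_hz) || freq_hz <= 0)) {
    stop_stim("pulse trains need a positive freq_hz", "invalid_parameter")
  }
  structure(list(amplitude_A = amplitude_A, phase_width_s = phase_width_s,
                 interphase_gap_s = interphase_gap_s,
                 n_pulses = as.integer(n_pulses), freq_hz = freq_hz,
                 polarity = "anodic_first",
                 charge_nC = amplitude_A * phase_width_s * 1e9),
            class = "stimulus_pulse")
}

#' Voltage transient record for a biphasic current pulse
#'
#' @param time_s Uniform, strictly increasing sample times (s).
#' @param command_current_A Commanded current waveform (A, anodic positive).
#' @param measured_potential_V Working-vs-reference potential (V).
#' @param pulse Optional [stimulus_pulse()] metadata.
#' @return Object of class `voltage_transient`.
#' @export
voltage_transient <- function(time_s, command_current_A, measured_potential_V,
                              pulse = NULL) {
  n <- length(time_s)
  if (length(command_current_A) != n || length(measured_potential_V) != n) {
    stop_stim("transient vectors must have equal length", "format")
  }
  dt <- diff(time_s)
  if (n < 3L || any(dt <= 0)) stop_stim("transient time base must be strictly increasing", "format")
  if (max(dt) - min(dt) > 1e-6 * stats::median(dt)) {
    stop_stim("transient sampling must be uniform", "format")
  }
  structure(list(time_s = time_s, command_current_A = command_current_A,
                 measured_potential_V = measured_potential_V, pulse = pulse),
            class = "voltage_transient")
}

#' Access voltage and post-phase polarization from a voltage transient
#'
#' The access voltage V_a is the near-instantaneous ohmic step across the
#' electrolyte at each current edge; it is measured as the potential step
#' across the single sample interval straddling the edge, scaled to the full
#' pulse amplitude and averaged over all edges. The anodic and cathodic
#' polarizations E_ma / E_mc are the potentials (relative to the pre-pulse
#' baseline, mean of the 1 ms before onset) read `sample_delay_s` after the
#' end of the respective phase, i.e. E_m = dV - V_a in the classic transient
#' decomposition.
#'
#' @param transient A [voltage_transient()].
#' @param limits An [electrochem_limits()] (supplies the sample delay).
#' @return List of class `polarization_measurement`: `V_a_V`, `E_ma_V`,
#'   `E_mc_V`, `status` ("ok" or "no_pulse" for an all-zero command trace).
#' @export
measure_polarization <- function(transient, limits = electrochem_limits()) {
  stopifnot(inherits(transient, "voltage_transient"))
  t <- transient$time_s; ic <- transient$command_current_A
  v <- transient$measured_potential_V
  dt <- t[2L] - t[1L]

  if (all(ic == 0)) {
    return(structure(list(V_a_V = 0, E_ma_V = 0, E_mc_V = 0, status = "no_pulse"),
                     class = "polarization_measurement"))
  }
  if (dt > limits$sample_delay_s * (1 + 1e-9)) {
    stop_stim(sprintf(
      "sampling interval (%.3g s) too coarse to resolve the %.3g s sample delay",
      dt, limits$sample_delay_s), "resolution")
  }
  edges <- which(diff(ic) != 0)           # step between sample k and k+1
  if (length(edges) == 0L) stop_stim("no current pulse found in command trace", "protocol")

  i_amp <- max(abs(ic))
  # Potential step across the edge interval, with the polarization ramp
  # removed by extrapolating the pre-edge slope across the interval (the
  # step is ohmic and instantaneous; the ramp is the capacitive drift).
  step_of <- function(k) {
    drift <- if (k >= 2L && ic[k - 1L] == ic[k]) v[k] - v[k - 1L] else 0
    v[k + 1L] - (v[k] + drift)
  }
  v_a <- mean(vapply(edges, function(k) {
    abs(step_of(k)) * i_amp / abs(ic[k + 1L] - ic[k])
  }, numeric(1)))

  onset <- t[edges[1L] + 1L]
  pre <- t < onset & t >= onset - 1e-3
  if (!any(pre)) pre <- t < onset
  baseline <- if (any(pre)) mean(v[pre]) else 0

  read_after <- function(phase_mask) {
    if (!any(phase_mask)) return(NA_real_)
    t_end <- t[max(which(phase_mask)) + 1L]   # first sample past the phase
    stats::approx(t, v, xout = t_end + limits$sample_delay_s, rule = 2)$y - baseline
  }
  e_ma <- read_after(ic > 0)
  e_mc <- read_after(ic < 0)

  structure(list(V_a_V = v_a, E_ma_V = e_ma, E_mc_V = e_mc, status = "ok"),
            class = "polarization_measurement")
}

#' Charge injection capacity from a family of voltage transients
#'
#' Measures the post-phase polarizations for an ordered family of transients
#' at strictly increasing per-phase charge, finds the largest pulse whose
#' polarizations stay inside the water window, and refines the limit by
#' linear interpolation (in charge) of the binding polarization between the
#' last passing and first failing pulse. Returns the limit as a density over
#' geometric area.
#'
#' @param transients List of [voltage_transient()] objects, each carrying a
#'   `pulse`, ordered by increasing per-phase charge.
#' @param geometry An [electrode_geometry()].
#' @param limits An [electrochem_limits()].
#' @return List of class `cic_result`: `cic_mC_cm2`, `status` ("ok" when the
#'   limit is bracketed; "unbounded" when even the largest pulse passes, in
#'   which case the value is a lower bound), `binding` ("anodic"/"cathodic"),
#'   and the per-transient table `polarizations`.
#' @export
compute_cic <- function(transients, geometry, limits = electrochem_limits()) {
  if (length(transients) < 2L) stop_stim("need >= 2 transients", "invalid_parameter")
  q_C <- vapply(transients, function(tr) {
    if (!is.null(tr$pulse)) {
      tr$pulse$amplitude_A * tr$pulse$phase_width_s
    } else {
      # fall back to integrating the anodic half of the command waveform
      trapz_masked(tr$time_s, pmax(tr$command_current_A, 0),
                   rep(TRUE, length(tr$time_s)))
    }
  }, numeric(1))
  if (any(diff(q_C) <= 0)) {
    stop_stim("per-phase charge must be strictly increasing across the family",
              "invalid_parameter")
  }

  pol <- lapply(transients, measure_polarization, limits = limits)
  e_ma <- vapply(pol, `[[`, numeric(1), "E_ma_V")
  e_mc <- vapply(pol, `[[`, numeric(1), "E_mc_V")
  pass <- e_ma <= limits$anodic_limit_V & e_mc >= limits$cathodic_limit_V
  tab <- data.frame(charge_nC = q_C * 1e9, E_ma_V = e_ma, E_mc_V = e_mc, pass = pass)
  area <- disk_area(geometry)

  if (!any(pass)) {
    stop_stim("even the smallest pulse polarizes past the water window; reduce charge",
              "below_resolution")
  }
  if (all(pass)) {
    return(structure(list(cic_mC_cm2 = 1e3 * q_C[length(q_C)] / area,
                          status = "unbounded", binding = NA_character_,
                          polarizations = tab), class = "cic_result"))
  }

  j <- min(which(!pass))                  # first failing pulse
  k <- j - 1L                             # last passing pulse before it
  q_cross <- Inf; binding <- NA_character_
  if (e_ma[j] > limits$anodic_limit_V) {
    qa <- q_C[k] + (limits$anodic_limit_V - e_ma[k]) / (e_ma[j] - e_ma[k]) * (q_C[j] - q_C[k])
    if (qa < q_cross) { q_cross <- qa; binding <- "anodic" }
  }
  if (e_mc[j] < limits$cathodic_limit_V) {
    qc <- q_C[k] + (limits$cathodic_limit_V - e_mc[k]) / (e_mc[j] - e_mc[k]) * (q_C[j] - q_C[k])
    if (qc < q_cross) { q_cross <- qc; binding <- "cathodic" }
  }

  structure(list(cic_mC_cm2 = 1e3 * q_cross / area, status = "ok",
                 binding = binding, polarizations = tab),
            class = "cic_result")
}
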