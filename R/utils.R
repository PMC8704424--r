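# Internal helpers shared across modules.

#' Signal a classed error
#'
#' All package errors carry a subclass (e.g. "stimlimit_invalid_geometry")
#' so callers and tests can discriminate failure modes.
#' @noRd
stop_stim <- function(msg, class, call. = FALSE) {
  cond <- structure(
    class = c(paste0("stimlimit_", class), "stimlimit_error", "error", "condition"),
    list(message = msg, call = if (call.) sys.call(-1) else NULL)
  )
  stop(cond)
}

warn_stim <- function(msg, class) {
  cond <- structure(
    class = c(paste0("stimlimit_", class), "stimlimit_warning", "warning", "condition"),
    list(message = msg, call = NULL)
  )
  warning(cond)
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards, so generators with an explicit
#' `seed` argument do not perturb the global random stream. `seed = NULL`
#' uses the current stream.
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1) # initialise the stream so it can be saved
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

#' Derive a per-stage seed from a top-level seed
#'
#' All randomness in a pipeline run flows from a single top-level seed
#' through named per-stage substreams: stages stay individually
#' reproducible and mutually independent. The result stays below 2^31 so
#' it is a valid R integer seed.
#'
#' @param seed Top-level integer seed.
#' @param stage Stage name (any string).
#' @return An integer seed.
#' @export
substream_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h) %% .Machine$integer.max)
}

#' Trapezoidal integral of y over t restricted to a logical mask
#'
#' An interval contributes only when both endpoints are inside the mask, so
#' partial edge intervals are dropped (error O(dt) at mask edges, O(dt^2)
#' inside).
#' @noRd
trapz_masked <- function(t, y, mask) {
  if (length(t) < 2L) return(0)
  keep <- mask[-length(mask)] & mask[-1L]
  dt <- diff(t)[keep]
  ym <- (y[-length(y)] + y[-1L])[keep] / 2
  sum(dt * ym)
}

#' Linear interpolation of the first upward crossing of `target`
#'
#' Scans adjacent pairs (x_i, y_i), (x_{i+1}, y_{i+1}) for y_i < target <=
#' y_{i+1} and interpolates x at the crossing. Returns NA when no crossing
#' exists. Used for charge thresholds and half-max ("lowest crossing" rule).
#' @noRd
lowest_crossing <- function(x, y, target) {
  for (i in seq_len(length(x) - 1L)) {
    if (y[i] < target && y[i + 1L] >= target) {
      return(x[i] + (target - y[i]) / (y[i + 1L] - y[i]) * (x[i + 1L] - x[i]))
    }
  }
  NA_real_
}
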