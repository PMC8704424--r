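# Reduction of per-trial spike recordings to evoked-response metrics:
# PSTHs, spontaneous-corrected spike counts, interpolated charge thresholds,
# half-max and dynamic range within charge-injection limits.

#' Per-trial spike response
#'
#' Spike times are relative to stimulus onset; negative times are the
#' pre-stimulus baseline. The analysis assumes a baseline span of at least
#' 2 s for spontaneous-rate correction.
#'
#' @param spike_times_s Sorted spike times (s) relative to stimulus onset.
#' @param trial Trial index.
#' @param charge_nC Per-phase stimulus charge of this trial (nC).
#' @param protocol Optional [stimulus_pulse()] / protocol metadata.
#' @param baseline_span_s Recorded pre-stimulus span (s), default 2.
#' @return Object of class `trial_response`.
#' @export
trial_response <- function(spike_times_s, trial = 1L, charge_nC = NA_real_,
                           protocol = NULL, baseline_span_s = 2) {
  if (is.unsorted(spike_times_s)) spike_times_s <- sort(spike_times_s)
  structure(list(spike_times_s = as.numeric(spike_times_s),
                 trial = as.integer(trial), charge_nC = charge_nC,
                 protocol = protocol, baseline_span_s = baseline_span_s),
            class = "trial_response")
}

#' Spontaneous-corrected evoked spike count
#'
#' Counts spikes in the evoked window and subtracts the expected spontaneous
#' count, estimated from the firing rate over the 2 s before the stimulus.
#' The result may be negative (suppression) and is deliberately not clipped.
#'
#' @param trial A [trial_response()].
#' @param window Evoked window (s), default 0 to 0.5.
#' @param baseline_window Baseline window (s), default -2 to 0.
#' @return Evoked spike count (numeric, possibly negative).
#' @export
count_evoked <- function(trial, window = c(0, 0.5), baseline_window = c(-2, 0)) {
  stopifnot(inherits(trial, "trial_response"))
  span <- baseline_window[2] - baseline_window[1]
  if (trial$baseline_span_s < span - 1e-9) {
    stop_stim("trial baseline span shorter than the baseline window", "baseline")
  }
  st <- trial$spike_times_s
  n_post <- sum(st >= window[1] & st < window[2])
  n_base <- sum(st >= baseline_window[1] & st < baseline_window[2])
  rate <- n_base / span
  n_post - rate * (window[2] - window[1])
}

#' Peristimulus time histogram
#'
#' Trial-averaged spike rate in fixed bins aligned to stimulus onset. By
#' construction the rate integrates back to the mean spike count: the sum of
#' rate x bin width over post-stimulus bins equals the mean post-stimulus
#' count per trial.
#'
#' @param trials List of [trial_response()] objects (>= 1).
#' @param bin_width_s Bin width (s), default 10 ms.
#' @param range_s Histogram range (s), default -50 ms to +500 ms.
#' @param normalize Optional scalar maximum rate to normalise against (the
#'   usual display convention is rate / max rate over a dataset).
#' @return Object of class `psth`: `bin_edges_s`, `rate_hz` (or normalised),
#'   `n_trials`, `normalized`.
#' @export
build_psth <- function(trials, bin_width_s = 0.01, range_s = c(-0.05, 0.5),
                       normalize = NULL) {
  if (length(trials) == 0L) stop_stim("need at least one trial", "input")
  edges <- seq(range_s[1], range_s[2], by = bin_width_s)
  if (abs(edges[length(edges)] - range_s[2]) > 1e-12) edges <- c(edges, range_s[2])
  counts <- numeric(length(edges) - 1L)
  for (tr in trials) {
    st <- tr$spike_times_s
    st <- st[st >= range_s[1] & st < range_s[2]]
    if (length(st)) {
      counts <- counts + tabulate(findInterval(st, edges), nbins = length(counts))
    }
  }
  rate <- counts / (length(trials) * diff(edges))
  normalized <- FALSE
  if (!is.null(normalize) && normalize > 0) { rate <- rate / normalize; normalized <- TRUE }
  structure(list(bin_edges_s = edges, rate_hz = rate,
                 n_trials = length(trials), normalized = normalized),
            class = "psth")
}

#' Stimulus-response curve for one cell
#'
#' Groups a cell's trials by per-phase charge and computes, per level, the
#' response probability (fraction of trials with at least one spike in the
#' evoked window, after stimulus-artifact blanking) and the mean and SD of
#' the spontaneous-corrected evoked count. Response probability is a per-
#' trial boolean and is not spontaneous-corrected (a boolean cannot be
#' rate-corrected); the correction applies to counts only. Levels above the
#' charge-injection limit are retained but flagged and excluded from
#' threshold / dynamic-range computations.
#'
#' @param trials List of [trial_response()] objects carrying `charge_nC`.
#' @param cic_limit_nC Charge-injection limit for this electrode (nC).
#' @param evoked_window Evoked window (s), default 0 to 0.5.
#' @param blank_s Artifact blanking: spikes in `[0, blank_s)` are ignored
#'   for the response boolean. `NULL` derives pulse span + 0.5 ms from the
#'   trial protocol when present, else 0.
#' @param cell_id,diameter_um Metadata carried on the curve.
#' @return Object of class `response_curve`: a data.frame with columns
#'   `charge_nC`, `p_response`, `mean_evoked`, `sd_evoked`, `n_trials`,
#'   `within_cic`, plus attributes `cic_limit_nC`, `cell_id`, `diameter_um`.
#' @export
response_curve <- function(trials, cic_limit_nC, evoked_window = c(0, 0.5),
                           blank_s = NULL, cell_id = NA, diameter_um = NA) {
  q <- vapply(trials, `[[`, numeric(1), "charge_nC")
  if (anyNA(q)) stop_stim("every trial needs a charge_nC", "input")
  levels <- sort(unique(q))
  if (length(levels) < 2L) stop_stim("need >= 2 charge levels", "input")

  blank_of <- function(tr) {
    if (!is.null(blank_s)) return(blank_s)
    p <- tr$protocol
    if (is.null(p)) return(0)
    span <- if (!is.null(p$n_pulses) && p$n_pulses > 1L && is.finite(p$freq_hz)) {
      p$n_pulses / p$freq_hz
    } else {
      2 * p$phase_width_s + (p$interphase_gap_s %||% 0)
    }
    span + 5e-4
  }

  rows <- lapply(levels, function(Q) {
    sel <- trials[q == Q]
    resp <- vapply(sel, function(tr) {
      b <- blank_of(tr)
      any(tr$spike_times_s >= b & tr$spike_times_s < evoked_window[2])
    }, logical(1))
    cnt <- vapply(sel, count_evoked, numeric(1), window = evoked_window)
    data.frame(charge_nC = Q, p_response = mean(resp),
               mean_evoked = mean(cnt),
               sd_evoked = if (length(cnt) > 1L) stats::sd(cnt) else NA_real_,
               n_trials = length(sel))
  })
  out <- do.call(rbind, rows)
  out$within_cic <- out$charge_nC <= cic_limit_nC + 1e-9
  structure(out, cic_limit_nC = cic_limit_nC, cell_id = cell_id,
            diameter_um = diameter_um,
            class = c("response_curve", "data.frame"))
}

#' Charge threshold by lowest-crossing linear interpolation
#'
#' The charge at which the response probability first reaches 0.5, obtained
#' by linear interpolation between the first adjacent pair of tested levels
#' that brackets 0.5 (the "lowest crossing"). If even the lowest tested
#' level responds on at least half the trials the estimate is that level,
#' flagged left-censored. Levels above the CIC limit are ignored.
#'
#' @param curve A [response_curve()].
#' @return List: `threshold_nC`, `status` ("ok", "left_censored",
#'   "no_threshold").
#' @export
estimate_threshold <- function(curve) {
  stopifnot(inherits(curve, "response_curve"))
  cc <- curve[curve$within_cic, , drop = FALSE]
  if (nrow(cc) == 0L || max(cc$p_response) < 0.5) {
    return(list(threshold_nC = NA_real_, status = "no_threshold"))
  }
  if (cc$p_response[1L] >= 0.5) {
    return(list(threshold_nC = cc$charge_nC[1L], status = "left_censored"))
  }
  thr <- lowest_crossing(cc$charge_nC, cc$p_response, 0.5)
  if (is.na(thr)) return(list(threshold_nC = NA_real_, status = "no_threshold"))
  list(threshold_nC = thr, status = "ok")
}

#' Half-max charge of the evoked-count curve
#'
#' Charge at which the mean evoked count first reaches half its within-CIC
#' maximum, by the same lowest-crossing interpolation as the threshold.
#'
#' @param curve A [response_curve()].
#' @return List: `half_max_nC`, `status` ("ok" or "undefined").
#' @export
estimate_half_max <- function(curve) {
  stopifnot(inherits(curve, "response_curve"))
  cc <- curve[curve$within_cic, , drop = FALSE]
  if (nrow(cc) < 2L || max(cc$mean_evoked) <= 0) {
    return(list(half_max_nC = NA_real_, status = "undefined"))
  }
  target <- max(cc$mean_evoked) / 2
  if (cc$mean_evoked[1L] >= target) {
    return(list(half_max_nC = cc$charge_nC[1L], status = "ok"))
  }
  hm <- lowest_crossing(cc$charge_nC, cc$mean_evoked, target)
  if (is.na(hm)) return(list(half_max_nC = NA_real_, status = "undefined"))
  list(half_max_nC = hm, status = "ok")
}

#' Dynamic range of evoked spiking within the charge-injection limit
#'
#' 10 log10 of the ratio between the maximal mean evoked count within the
#' CIC limit and the count evoked at the threshold charge. The power-style
#' 10 log10 convention is used (counts are magnitude-like quantities);
#' multiply by 2 for the 20 log10 amplitude convention. The threshold count
#' is obtained by linear interpolation of the count curve at the threshold
#' charge (`mode = "interpolated"`, default) or read at the nearest tested
#' level (`mode = "nearest"`).
#'
#' @param curve A [response_curve()].
#' @param mode Threshold-count convention, see above.
#' @return List: `dynamic_range_dB`, `threshold_nC`, `count_at_threshold`,
#'   `max_count`, `status` ("ok" or "undefined").
#' @export
dynamic_range <- function(curve, mode = c("interpolated", "nearest")) {
  mode <- match.arg(mode)
  thr <- estimate_threshold(curve)
  undefined <- list(dynamic_range_dB = NA_real_, threshold_nC = thr$threshold_nC,
                    count_at_threshold = NA_real_, max_count = NA_real_,
                    status = "undefined")
  if (thr$status == "no_threshold") return(undefined)
  cc <- curve[curve$within_cic, , drop = FALSE]
  max_count <- max(cc$mean_evoked)
  c_thr <- if (mode == "interpolated") {
    stats::approx(cc$charge_nC, cc$mean_evoked, xout = thr$threshold_nC, rule = 2)$y
  } else {
    cc$mean_evoked[which.min(abs(cc$charge_nC - thr$threshold_nC))]
  }
  if (!is.finite(c_thr) || c_thr <= 0 || max_count <= 0) return(undefined)
  list(dynamic_range_dB = 10 * log10(max_count / c_thr),
       threshold_nC = thr$threshold_nC, count_at_threshold = c_thr,
       max_count = max_count, status = "ok")
}

#' Population summary of per-cell stimulation metrics
#'
#' Per diameter and protocol: mean, median, quartiles (25-75%) and 9-91%
#' whisker range of charge thresholds and dynamic ranges; the responsive
#' fraction (cells with a threshold / cells tested); and charge-density
#' thresholds (threshold / geometric disk area).
#'
#' @param cells data.frame with columns `cell_id`, `diameter_um`,
#'   `protocol_id`, `threshold_nC`, `threshold_status`, `dynamic_range_dB`
#'   (NA where undefined).
#' @return data.frame, one row per (diameter, protocol) group.
#' @export
population_summary <- function(cells) {
  if (nrow(cells) == 0L) stop_stim("need at least one cell", "input")
  groups <- split(cells, interaction(cells$diameter_um, cells$protocol_id, drop = TRUE))
  qs <- function(x) stats::quantile(x, c(0.09, 0.25, 0.5, 0.75, 0.91), na.rm = TRUE,
                                    names = FALSE)
  rows <- lapply(groups, function(g) {
    resp <- !is.na(g$threshold_nC)
    if (!any(resp)) {
      warn_stim(sprintf("group d=%g/%s has no responsive cells; omitted",
                        g$diameter_um[1], g$protocol_id[1]), "empty_group")
      return(NULL)
    }
    thr <- g$threshold_nC[resp]
    dr <- g$dynamic_range_dB[!is.na(g$dynamic_range_dB)]
    area <- disk_area(electrode_geometry(g$diameter_um[1]))
    tq <- qs(thr)
    dq <- if (length(dr)) qs(dr) else rep(NA_real_, 5)
    data.frame(
      diameter_um = g$diameter_um[1], protocol_id = g$protocol_id[1],
      n_tested = nrow(g), n_responsive = sum(resp),
      responsive_fraction = mean(resp),
      threshold_mean_nC = mean(thr), threshold_median_nC = tq[3],
      threshold_q25_nC = tq[2], threshold_q75_nC = tq[4],
      threshold_q09_nC = tq[1], threshold_q91_nC = tq[5],
      density_threshold_median_mC_cm2 = tq[3] * 1e-6 / area,
      dr_mean_dB = if (length(dr)) mean(dr) else NA_real_,
      dr_median_dB = dq[3], dr_q25_dB = dq[2], dr_q75_dB = dq[4],
      dr_q09_dB = dq[1], dr_q91_dB = dq[5],
      row.names = NULL)
  })
  out <- do.call(rbind, rows)
  out[order(out$protocol_id, out$diameter_um), , drop = FALSE]
}

#' Analyse one cell's trials end to end
#'
#' Convenience wrapper: response curve, threshold, half-max and dynamic
#' range for a single cell. Before a threshold is accepted, the cell must
#' pass a responsiveness screen: at least one within-CIC level's response
#' count has to exceed what the cell's own spontaneous rate predicts for
#' the evoked window (one-sided binomial test at `alpha`, Bonferroni-
#' corrected over levels). Without the screen, cells firing spontaneously
#' can reach a 50% any-spike rate by chance at some level and acquire a
#' spurious threshold, inflating the responsive fraction.
#'
#' @inheritParams response_curve
#' @param alpha Significance level of the responsiveness screen; `NULL`
#'   disables the screen.
#' @return List with `curve`, `threshold_nC`, `threshold_status`,
#'   `half_max_nC`, `dynamic_range_dB`, `dr_status`.
#' @export
analyze_cell <- function(trials, cic_limit_nC, evoked_window = c(0, 0.5),
                         blank_s = NULL, cell_id = NA, diameter_um = NA,
                         alpha = 0.05) {
  curve <- response_curve(trials, cic_limit_nC, evoked_window, blank_s,
                          cell_id, diameter_um)
  thr <- estimate_threshold(curve)

  if (!is.null(alpha) && thr$status != "no_threshold") {
    n_base <- sum(vapply(trials, function(tr)
      sum(tr$spike_times_s >= -2 & tr$spike_times_s < 0), numeric(1)))
    lam <- n_base / (2 * length(trials))
    p0 <- min(1 - exp(-lam * (evoked_window[2] - evoked_window[1])), 1 - 1e-12)
    cc <- curve[curve$within_cic, , drop = FALSE]
    pvals <- stats::pbinom(round(cc$p_response * cc$n_trials) - 1L,
                           cc$n_trials, p0, lower.tail = FALSE)
    if (min(pvals) > alpha / nrow(cc)) {
      thr <- list(threshold_nC = NA_real_, status = "no_threshold")
    }
  }

  hm <- estimate_half_max(curve)
  dr <- if (thr$status == "no_threshold") {
    list(dynamic_range_dB = NA_real_, status = "undefined")
  } else {
    dynamic_range(curve)
  }
  list(curve = curve, threshold_nC = thr$threshold_nC,
       threshold_status = thr$status, half_max_nC = hm$half_max_nC,
       dynamic_range_dB = dr$dynamic_range_dB, dr_status = dr$status)
}

#' Latency split of evoked spikes
#'
#' Descriptive short/long latency fractions of post-stimulus spikes. The
#' default split at 100 ms follows the usual short-latency convention for
#' subretinal stimulation PSTHs; a 10 ms cut is sometimes used to describe
#' putative direct activation and is available via `split_s`. No functional
#' attribution is made.
#'
#' @param trials List of [trial_response()].
#' @param split_s Latency cut (s), default 0.1.
#' @param window Post-stimulus window (s).
#' @return List: `n_short`, `n_long`, `frac_short`.
#' @export
latency_split <- function(trials, split_s = 0.1, window = c(0, 0.5)) {
  st <- unlist(lapply(trials, function(tr) {
    s <- tr$spike_times_s
    s[s >= window[1] & s < window[2]]
  }))
  n_short <- sum(st < split_s)
  n_long <- length(st) - n_short
  list(n_short = n_short, n_long = n_long,
       frac_short = if (length(st)) n_short / length(st) else NA_real_)
}

#' Spike detection on a filtered extracellular trace
#'
#' Band-pass filters the trace, estimates baseline noise by the median
#' absolute deviation of a baseline segment, detects threshold crossings at
#' `k` x MAD, merges events closer than the refractory window, and blanks
#' stimulus-artifact windows.
#'
#' @param trace Numeric sampled signal.
#' @param fs_hz Sampling rate (Hz, >= 10 kHz).
#' @param band_hz Band-pass corner frequencies (Hz), default 100-4000.
#' @param k MAD multiplier for the detection threshold, default 5.
#' @param refractory_s Minimum inter-event interval (s), default 1 ms.
#' @param baseline_idx Indices of a spike-free baseline segment used for the
#'   noise estimate; default the first 10% of samples.
#' @param blank_windows Optional list of `c(t0, t1)` windows (s) excluded
#'   from detection (stimulus span + 0.5 ms is the usual choice).
#' @return Spike times (s).
#' @export
detect_spikes <- function(trace, fs_hz, band_hz = c(100, 4000), k = 5,
                          refractory_s = 1e-3, baseline_idx = NULL,
                          blank_windows = NULL) {
  if (fs_hz < 1e4) stop_stim("sampling below 10 kHz cannot resolve spikes", "resolution")
  amp <- max(abs(trace))
  if (amp > 0 && sum(abs(trace) >= 0.999 * amp) > 0.01 * length(trace)) {
    warn_stim("trace appears saturated/clipped", "quality")
  }
  ny <- fs_hz / 2
  bf <- signal::butter(2, pmin(band_hz / ny, 0.99), type = "pass")
  y <- signal::filtfilt(bf, trace)
  if (is.null(baseline_idx)) baseline_idx <- seq_len(max(10L, floor(length(y) * 0.1)))
  noise <- stats::mad(y[baseline_idx])
  if (noise == 0) noise <- stats::sd(y[baseline_idx])
  if (!is.finite(noise) || noise == 0) return(numeric(0))
  thr <- k * noise
  above <- abs(y) > thr
  if (!is.null(blank_windows)) {
    t <- (seq_along(y) - 1L) / fs_hz
    for (w in blank_windows) above[t >= w[1] & t < w[2]] <- FALSE
  }
  if (!any(above)) return(numeric(0))
  # event = run of supra-threshold samples; time at the peak of |y|
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  ev <- which(runs$values)
  peaks <- vapply(ev, function(e) {
    seg <- starts[e]:ends[e]
    seg[which.max(abs(y[seg]))]
  }, integer(1))
  tt <- (peaks - 1L) / fs_hz
  # refractory merge: keep the first event of any cluster
  keep <- c(TRUE, diff(tt) > refractory_s)
  tt[keep]
}
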