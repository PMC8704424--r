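# Synthetic electrochemistry records and retinal ganglion cell (RGC)
# population recordings with the statistical structure the analysis assumes.
# Every generator takes an explicit seed and restores the caller's RNG
# state; identical (parameters, seed) give bit-identical output.

#' Equivalent-circuit parameters of a synthetic electrode
#'
#' The pulse transient is modelled as an access resistance in series with a
#' polarization capacitance (specific, per cm^2). The slow CV response is a
#' potential-dependent pseudocapacitance profile, separate per sweep
#' direction: a baseline plus Gaussian redox peaks, emulating the broad
#' faradaic peaks of oxide electrodes.
#'
#' @param access_resistance_ohm Electrolyte access resistance (Ohm).
#' @param c_specific_F_cm2 Polarization capacitance per area (F/cm^2, > 0).
#' @param cv_anodic,cv_cathodic Pseudocapacitance profiles, each a list
#'   `list(baseline_F_cm2 =, peaks = data.frame(center_V, width_V,
#'   height_F_cm2))`; `peaks` may be empty.
#' @param noise_sd_V Additive Gaussian noise on measured potentials (V) and,
#'   scaled by the capacitive current, on CV current.
#' @return Object of class `electrode_circuit`.
#' @export
electrode_circuit <- function(access_resistance_ohm = 1e5,
                              c_specific_F_cm2 = 4.125e-3,
                              cv_anodic = list(baseline_F_cm2 = 8.571e-3,
                                               peaks = NULL),
                              cv_cathodic = list(baseline_F_cm2 = 12.143e-3,
                                                 peaks = NULL),
                              noise_sd_V = 0) {
  if (c_specific_F_cm2 <= 0) stop_stim("polarization capacitance must be > 0",
                                       "invalid_parameter")
  if (noise_sd_V < 0) stop_stim("noise sd must be >= 0", "invalid_parameter")
  for (p in list(cv_anodic, cv_cathodic)) {
    if (p$baseline_F_cm2 < 0) stop_stim("CV baseline capacitance must be >= 0",
                                        "invalid_parameter")
  }
  structure(list(access_resistance_ohm = access_resistance_ohm,
                 c_specific_F_cm2 = c_specific_F_cm2,
                 cv_anodic = cv_anodic, cv_cathodic = cv_cathodic,
                 noise_sd_V = noise_sd_V),
            class = "electrode_circuit")
}

# pseudocapacitance c(V) in F/cm^2 for one sweep direction
.cv_profile <- function(profile, v) {
  c_v <- rep(profile$baseline_F_cm2, length(v))
  pk <- profile$peaks
  if (!is.null(pk) && nrow(pk)) {
    for (r in seq_len(nrow(pk))) {
      c_v <- c_v + pk$height_F_cm2[r] *
        exp(-(v - pk$center_V[r])^2 / (2 * pk$width_V[r]^2))
    }
  }
  c_v
}

#' Reference sputtered-iridium-oxide-like circuit preset
#'
#' Calibrated so the designed charge capacities match typical SIROF values:
#' anodic / cathodic CSC of 12 and 17 mC/cm^2 over the -0.6..0.8 V water
#' window, and a polarization capacitance of 4.125 mF/cm^2, which puts the
#' anodic-limit-bound charge injection capacity at 0.8 V x 4.125 mF/cm^2 =
#' 3.3 mC/cm^2. Peak heights are solved in closed form from the target
#' window integrals.
#'
#' @param noise_sd_V Measurement noise (V), default 0.
#' @return An [electrode_circuit()].
#' @export
sirof_circuit_preset <- function(noise_sd_V = 0) {
  window <- c(-0.6, 0.8); dv <- diff(window)
  solve_height <- function(target_C_cm2, baseline, center, width) {
    cov <- stats::pnorm(window[2], center, width) - stats::pnorm(window[1], center, width)
    (target_C_cm2 - baseline * dv) / (width * sqrt(2 * pi) * cov)
  }
  an_base <- 5e-3
  an_peak <- data.frame(center_V = 0.2, width_V = 0.15,
                        height_F_cm2 = solve_height(12e-3, an_base, 0.2, 0.15))
  ca_base <- 7e-3
  ca_peak <- data.frame(center_V = -0.1, width_V = 0.18,
                        height_F_cm2 = solve_height(17e-3, ca_base, -0.1, 0.18))
  electrode_circuit(
    access_resistance_ohm = 1e5,
    c_specific_F_cm2 = 4.125e-3,
    cv_anodic = list(baseline_F_cm2 = an_base, peaks = an_peak),
    cv_cathodic = list(baseline_F_cm2 = ca_base, peaks = ca_peak),
    noise_sd_V = noise_sd_V)
}

#' Designed charge storage capacity of a synthetic circuit
#'
#' Ground truth for the CV generator: the window integral of the
#' pseudocapacitance profile, evaluated by adaptive quadrature
#' (independent of the trapezoidal path used by the analyzer).
#'
#' @param circuit An [electrode_circuit()].
#' @param limits An [electrochem_limits()].
#' @return List `csc_anodic_mC_cm2`, `csc_cathodic_mC_cm2`.
#' @export
designed_csc <- function(circuit, limits = electrochem_limits()) {
  f <- function(profile) stats::integrate(
    function(v) .cv_profile(profile, v),
    limits$cathodic_limit_V, limits$anodic_limit_V, rel.tol = 1e-10)$value
  list(csc_anodic_mC_cm2 = 1e3 * f(circuit$cv_anodic),
       csc_cathodic_mC_cm2 = 1e3 * f(circuit$cv_cathodic))
}

#' Designed charge injection capacity of a synthetic circuit
#'
#' For the series-RC transient model the anodic polarization is Q / (c A),
#' so the anodic water-window limit binds at Q/A = anodic limit x specific
#' capacitance.
#'
#' @inheritParams designed_csc
#' @return CIC density in mC/cm^2.
#' @export
designed_cic <- function(circuit, limits = electrochem_limits()) {
  1e3 * limits$anodic_limit_V * circuit$c_specific_F_cm2
}

#' Generate a cyclic voltammetry trace
#'
#' Triangle potential sweep between the vertices at constant scan rate,
#' sampled every `dv_V`; the current is the capacitive response
#' i = sign(dV/dt) x rate x area x c(V) with the direction-specific
#' pseudocapacitance profile, plus Gaussian noise.
#'
#' @param circuit An [electrode_circuit()].
#' @param geometry An [electrode_geometry()].
#' @param scan_rate_V_per_s Sweep rate (V/s), default 0.2.
#' @param vertices Sweep vertices (V), default c(-0.6, 0.8).
#' @param n_cycles Number of full cycles, default 3.
#' @param dv_V Potential increment per sample (V), default 10 mV.
#' @param seed RNG seed (NULL = use current stream).
#' @return A [cv_scan()].
#' @export
gen_cv_trace <- function(circuit, geometry, scan_rate_V_per_s = 0.2,
                         vertices = c(-0.6, 0.8), n_cycles = 3, dv_V = 0.01,
                         seed = NULL) {
  if (scan_rate_V_per_s <= 0) stop_stim("scan rate must be > 0", "invalid_parameter")
  wl <- electrochem_limits()
  if (vertices[1] < wl$cathodic_limit_V - 1e-9 || vertices[2] > wl$anodic_limit_V + 1e-9) {
    warn_stim("sweep vertices extend beyond the water window", "protocol")
  }
  vl <- vertices[1]; vh <- vertices[2]
  up <- seq(vl, vh - dv_V, by = dv_V)
  down <- seq(vh, vl + dv_V, by = -dv_V)
  v <- c(rep(c(up, down), n_cycles), vl)
  # per-sample sweep direction = direction of arrival (first sample ascending)
  arr <- c(TRUE, diff(v) > 0)
  dt <- dv_V / scan_rate_V_per_s
  t <- (seq_along(v) - 1) * dt
  area <- disk_area(geometry)
  c_v <- ifelse(arr, .cv_profile(circuit$cv_anodic, v),
                .cv_profile(circuit$cv_cathodic, v))
  i <- ifelse(arr, 1, -1) * scan_rate_V_per_s * area * c_v
  if (circuit$noise_sd_V > 0) {
    i_scale <- scan_rate_V_per_s * area * circuit$cv_anodic$baseline_F_cm2
    i <- i + with_seed(seed, stats::rnorm(length(i), 0, circuit$noise_sd_V * i_scale))
  }
  cv_scan(t, v, i, scan_rate_V_per_s, vl, vh)
}

#' Generate a biphasic-pulse voltage transient
#'
#' Series-RC response to an anodic-first charge-balanced current pulse:
#' V(t) = I(t) R_access + Q(t) / (c_specific x area) + noise, with exact
#' (not cumulated) phase charge so step edges land on samples.
#'
#' @param circuit An [electrode_circuit()].
#' @param geometry An [electrode_geometry()].
#' @param pulse A [stimulus_pulse()].
#' @param fs_hz Sampling rate (Hz), default 100 kHz so the 10 us
#'   polarization sample delay is resolvable.
#' @param pre_s,post_s Padding before/after the pulse (s).
#' @param seed RNG seed.
#' @return A [voltage_transient()].
#' @export
gen_voltage_transient <- function(circuit, geometry, pulse, fs_hz = 1e5,
                                  pre_s = 2e-3, post_s = 2e-3, seed = NULL) {
  stopifnot(inherits(pulse, "stimulus_pulse"))
  dt <- 1 / fs_hz
  pw <- pulse$phase_width_s; gap <- pulse$interphase_gap_s; I <- pulse$amplitude_A
  t_on <- pre_s; t_ca <- t_on + pw + gap
  total <- t_ca + pw + post_s
  t <- seq(0, total, by = dt)
  cmd <- I * (t >= t_on & t < t_on + pw) - I * (t >= t_ca & t < t_ca + pw)
  overlap <- function(x, a, b) pmin(pmax(x - a, 0), b - a)
  q <- I * overlap(t, t_on, t_on + pw) - I * overlap(t, t_ca, t_ca + pw)
  cap <- circuit$c_specific_F_cm2 * disk_area(geometry)
  v <- cmd * circuit$access_resistance_ohm + q / cap
  if (circuit$noise_sd_V > 0) {
    v <- v + with_seed(seed, stats::rnorm(length(v), 0, circuit$noise_sd_V))
  }
  voltage_transient(t, cmd, v, pulse)
}

#' Generate an increasing-charge family of voltage transients
#'
#' @param circuit,geometry,fs_hz,seed See [gen_voltage_transient()].
#' @param currents_A Strictly increasing phase currents (A).
#' @param phase_width_s Phase width (s), default 1 ms.
#' @return List of [voltage_transient()] objects.
#' @export
gen_transient_family <- function(circuit, geometry, currents_A,
                                 phase_width_s = 1e-3, fs_hz = 1e5, seed = NULL) {
  lapply(seq_along(currents_A), function(k) {
    gen_voltage_transient(circuit, geometry,
                          stimulus_pulse(currents_A[k], phase_width_s),
                          fs_hz = fs_hz,
                          seed = if (is.null(seed)) NULL else seed + k)
  })
}

#' Generative parameters for a heterogeneous RGC population
#'
#' One object per electrode diameter. Cells draw a charge-threshold midpoint
#' from a log-normal distribution; per-trial spiking is Bernoulli with a
#' logistic probability in charge around the midpoint; the evoked count is
#' (at least one spike, plus Poisson) with a saturating-linear mean
#' m(Q) = min(g (Q - Q_b), m_sat), where the count onset Q_b sits a fixed
#' fraction below the midpoint. Pulse trains scale the midpoint down by the
#' train threshold factor, steepen the count slope and saturate at a higher
#' count. A cell is responsive with probability `p_resp`; non-responsive
#' cells only fire spontaneously (homogeneous Poisson).
#'
#' @param diameter_um Electrode diameter the population is recorded on.
#' @param cic_limit_nC Per-phase charge limit for this diameter (nC).
#' @param p_resp Probability a cell is responsive, in `[0, 1]`.
#' @param threshold_median_nC Median of the log-normal midpoint distribution
#'   (single pulses), nC.
#' @param threshold_sdlog Log-scale dispersion of midpoints, default 0.35.
#' @param slope_rel Logistic scale as a fraction of the cell midpoint,
#'   default 0.12.
#' @param count_onset_frac Fraction delta in Q_b = (1 - delta) x midpoint,
#'   in (0, 1].
#' @param count_at_cic_single Designed mean evoked count at the CIC limit,
#'   single pulses (sets the count slope g).
#' @param count_sat_train Saturation count for 20-pulse trains.
#' @param train_threshold_factor Multiplies the midpoint for trains, (0, 1].
#' @param train_slope_gain Multiplies the count slope for trains, default 3.
#' @param count_sdlog Per-cell log-normal dispersion of count amplitudes.
#' @param spont_shape,spont_mean_hz Gamma distribution of spontaneous rates.
#' @param latency Latency mixture: short Gamma (mean, shape) and long
#'   Uniform (range), with short-component weight.
#' @return Object of class `population_params`.
#' @export
population_params <- function(diameter_um, cic_limit_nC,
                              p_resp = 1,
                              threshold_median_nC,
                              threshold_sdlog = 0.35,
                              slope_rel = 0.12,
                              count_onset_frac = 0.8,
                              count_at_cic_single = 15,
                              count_sat_train = 30,
                              train_threshold_factor = 1,
                              train_slope_gain = 3,
                              count_sdlog = 0.25,
                              spont_shape = 2, spont_mean_hz = 0.2,
                              latency = list(short_mean_s = 0.01,
                                             short_shape = 2,
                                             long_range_s = c(0.1, 0.4),
                                             w_short = 0.6)) {
  if (p_resp < 0 || p_resp > 1) stop_stim("p_resp must be in [0,1]", "invalid_parameter")
  if (threshold_median_nC <= 0) stop_stim("threshold median must be > 0", "invalid_parameter")
  if (train_threshold_factor <= 0 || train_threshold_factor > 1) {
    stop_stim("train threshold factor must be in (0,1]", "invalid_parameter")
  }
  if (count_onset_frac <= 0 || count_onset_frac > 1) {
    stop_stim("count_onset_frac must be in (0,1]", "invalid_parameter")
  }
  structure(as.list(environment()), class = "population_params")
}

#' Population presets per electrode diameter
#'
#' Calibration targets: single-pulse threshold medians 0.83 / 1.8 / 3.6 nC
#' and train medians 0.46 / 1.6 / 2.4 nC at 10 / 20 / 30 um; responsive
#' fractions 0.47 / 1.0 / 1.0; and designed population dynamic ranges of
#' 8.0 / 10.4 / 12.8 dB (single) and 9.0 / 10.5 / 11.7 dB (trains), i.e.
#' the 30 um dynamic range is 1.6x (single) and 1.3x (trains) the 10 um
#' value on the decibel scale. The count-curve parameters below were solved
#' in closed form from those designed values (see the methods vignette).
#' CIC limits are 3.3 mC/cm^2 x geometric area.
#'
#' @param diameter_um One of 10, 20, 30.
#' @return A [population_params()].
#' @export
rgc_population_preset <- function(diameter_um = c(10, 20, 30)) {
  diameter_um <- match.arg(as.character(diameter_um[1]), c("10", "20", "30"))
  qcic <- max_injectable_charge(electrode_geometry(as.numeric(diameter_um)), 3.3)
  tab <- list(
    "10" = list(p = 0.47, thr = 0.83, tf = 0.46 / 0.83, delta = 0.963,
                m_cic = 10, m_sat_t = 20.6),
    "20" = list(p = 1.00, thr = 1.80, tf = 1.6 / 1.8, delta = 1.0,
                m_cic = 13, m_sat_t = 33.8),
    "30" = list(p = 1.00, thr = 3.60, tf = 2.4 / 3.6, delta = 0.599,
                m_cic = 20, m_sat_t = 29.3))[[diameter_um]]
  population_params(
    diameter_um = as.numeric(diameter_um), cic_limit_nC = qcic,
    p_resp = tab$p, threshold_median_nC = tab$thr,
    count_onset_frac = tab$delta, count_at_cic_single = tab$m_cic,
    count_sat_train = tab$m_sat_t, train_threshold_factor = tab$tf)
}

#' Draw a synthetic RGC population
#'
#' @param params A [population_params()].
#' @param n_cells Number of cells (>= 1).
#' @param seed RNG seed.
#' @return List of `synthetic_cell` objects, reproducible from
#'   (params, seed, index).
#' @export
gen_cell_population <- function(params, n_cells, seed = NULL) {
  stopifnot(inherits(params, "population_params"))
  if (n_cells < 1L) stop_stim("n_cells must be >= 1", "invalid_parameter")
  with_seed(seed, {
    lapply(seq_len(n_cells), function(k) {
      q0 <- stats::rlnorm(1, log(params$threshold_median_nC), params$threshold_sdlog)
      m_amp <- stats::rlnorm(1, 0, params$count_sdlog)
      qb <- (1 - params$count_onset_frac) * q0
      structure(list(
        cell_id = sprintf("d%s_c%03d", params$diameter_um, k),
        diameter_um = params$diameter_um,
        responsive = stats::runif(1) < params$p_resp,
        q0_nC = q0,
        logistic_scale_nC = params$slope_rel * q0,
        qb_nC = qb,
        count_slope_per_nC = params$count_at_cic_single * m_amp /
          (params$cic_limit_nC - qb),
        m_sat_single = params$count_at_cic_single * m_amp,
        m_sat_train = params$count_sat_train * m_amp,
        train_threshold_factor = params$train_threshold_factor,
        train_slope_gain = params$train_slope_gain,
        spont_hz = stats::rgamma(1, shape = params$spont_shape,
                                 scale = params$spont_mean_hz / params$spont_shape),
        distance_um = stats::runif(1, 0, 25),
        latency = params$latency,
        cic_limit_nC = params$cic_limit_nC),
        class = "synthetic_cell")
    })
  })
}

# mean evoked count of a cell at per-phase charge Q for a protocol
.mean_count <- function(cell, q_nC, train = FALSE) {
  g <- cell$count_slope_per_nC * (if (train) cell$train_slope_gain else 1)
  m_sat <- if (train) cell$m_sat_train else cell$m_sat_single
  pmin(g * pmax(q_nC - cell$qb_nC, 0), m_sat)
}

# per-trial response probability
.p_response <- function(cell, q_nC, train = FALSE) {
  q0 <- cell$q0_nC * (if (train) cell$train_threshold_factor else 1)
  stats::plogis((q_nC - q0) / cell$logistic_scale_nC)
}

#' Simulate loose-patch trials for one cell
#'
#' Per trial: spontaneous spikes as a homogeneous Poisson process over
#' [-2 s, +0.5 s]; if the cell is responsive, the trial responds with the
#' logistic probability at that charge, in which case the evoked count is
#' at least one spike plus Poisson around the saturating-linear mean, with
#' latencies drawn from the short-Gamma / long-Uniform mixture. Pulse
#' trains (protocol `n_pulses > 1`) use the train midpoint, slope and
#' saturation.
#'
#' @param cell A `synthetic_cell` from [gen_cell_population()].
#' @param protocol A [stimulus_pulse()]; `n_pulses > 1` marks a train.
#' @param charge_levels_nC Per-phase charge levels to test (nC, > 0).
#' @param n_repeats Repeats per level, default 5.
#' @param seed RNG seed.
#' @return List of [trial_response()] objects (levels x repeats).
#' @export
gen_recording <- function(cell, protocol, charge_levels_nC, n_repeats = 5,
                          seed = NULL) {
  stopifnot(inherits(cell, "synthetic_cell"))
  if (any(charge_levels_nC <= 0)) stop_stim("charge levels must be > 0", "invalid_parameter")
  train <- protocol$n_pulses > 1L
  lat <- cell$latency
  with_seed(seed, {
    out <- list()
    trial_i <- 0L
    for (q in charge_levels_nC) {
      p_q <- if (cell$responsive) .p_response(cell, q, train) else 0
      m_q <- .mean_count(cell, q, train)
      for (rep_k in seq_len(n_repeats)) {
        trial_i <- trial_i + 1L
        n_spont <- stats::rpois(1, cell$spont_hz * 2.5)
        spk <- stats::runif(n_spont, -2, 0.5)
        if (p_q > 0 && stats::runif(1) < p_q) {
          n_ev <- max(1L, stats::rpois(1, m_q))
          short <- stats::runif(n_ev) < lat$w_short
          latc <- ifelse(short,
                         stats::rgamma(n_ev, shape = lat$short_shape,
                                       scale = lat$short_mean_s / lat$short_shape),
                         stats::runif(n_ev, lat$long_range_s[1], lat$long_range_s[2]))
          spk <- c(spk, latc)
        }
        out[[trial_i]] <- trial_response(sort(spk), trial = trial_i,
                                         charge_nC = q, protocol = protocol)
      }
    }
    out
  })
}

#' Default charge-level ladder up to the CIC limit
#'
#' Eight log-spaced per-phase charge levels from CIC/20 to the CIC limit.
#'
#' @param cic_limit_nC Charge limit (nC).
#' @param n Number of levels, default 8.
#' @export
charge_levels <- function(cic_limit_nC, n = 8) {
  exp(seq(log(cic_limit_nC / 20), log(cic_limit_nC), length.out = n))
}

#' Simulate and analyse a population study arm
#'
#' Draws a population, simulates 5-repeat recordings over the default
#' charge ladder for the given protocol, and reduces every cell with
#' [analyze_cell()].
#'
#' @param params A [population_params()].
#' @param n_cells Cells to simulate.
#' @param protocol `"single"` or `"train"` (20 pulses at 500 Hz).
#' @param pulse_width_s Phase width (s), default 1 ms.
#' @param seed RNG seed (stage substreams derived internally).
#' @param n_levels,n_repeats Charge ladder size and repeats.
#' @return List: `cells` (per-cell results data.frame with threshold,
#'   half-max and dynamic range), `population` (the drawn cells),
#'   `trials_by_cell`.
#' @export
simulate_population_study <- function(params, n_cells,
                                      protocol = c("single", "train"),
                                      pulse_width_s = 1e-3, seed = NULL,
                                      n_levels = 8, n_repeats = 5) {
  protocol <- match.arg(protocol)
  cells <- gen_cell_population(params, n_cells,
                               seed = if (is.null(seed)) NULL
                               else substream_seed(seed, "population"))
  levels <- charge_levels(params$cic_limit_nC, n_levels)
  proto <- if (protocol == "train") {
    stimulus_pulse(1e-6, pulse_width_s, n_pulses = 20L, freq_hz = 500)
  } else {
    stimulus_pulse(1e-6, pulse_width_s)
  }
  trials_by_cell <- lapply(seq_along(cells), function(k) {
    gen_recording(cells[[k]], proto, levels, n_repeats = n_repeats,
                  seed = if (is.null(seed)) NULL
                  else substream_seed(seed, paste0("rec", k)))
  })
  rows <- lapply(seq_along(cells), function(k) {
    res <- analyze_cell(trials_by_cell[[k]], params$cic_limit_nC,
                        cell_id = cells[[k]]$cell_id,
                        diameter_um = params$diameter_um)
    data.frame(cell_id = cells[[k]]$cell_id,
               diameter_um = params$diameter_um,
               protocol_id = protocol,
               threshold_nC = res$threshold_nC,
               threshold_status = res$threshold_status,
               half_max_nC = res$half_max_nC,
               dynamic_range_dB = res$dynamic_range_dB,
               dr_status = res$dr_status,
               true_midpoint_nC = cells[[k]]$q0_nC *
                 (if (protocol == "train") cells[[k]]$train_threshold_factor else 1),
               responsive_truth = cells[[k]]$responsive)
  })
  list(cells = do.call(rbind, rows), population = cells,
       trials_by_cell = trials_by_cell)
}
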