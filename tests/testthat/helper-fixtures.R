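# Shared fixtures, all built in code.

# A response_curve object from raw per-level values (bypasses trials).
make_curve <- function(charge_nC, p_response, mean_evoked, cic_limit_nC = Inf) {
  df <- data.frame(charge_nC = charge_nC, p_response = p_response,
                   mean_evoked = mean_evoked, sd_evoked = NA_real_,
                   n_trials = 5L,
                   within_cic = charge_nC <= cic_limit_nC + 1e-9)
  structure(df, cic_limit_nC = cic_limit_nC, cell_id = "fix", diameter_um = NA,
            class = c("response_curve", "data.frame"))
}

# Trials with given spike times per trial at a common charge level.
trials_from_times <- function(times_by_trial, charge_nC = 1) {
  lapply(seq_along(times_by_trial), function(k) {
    trial_response(times_by_trial[[k]], trial = k, charge_nC = charge_nC)
  })
}

# Purely capacitive synthetic electrode with the reference polarization
# capacitance (anodic water-window limit binds at 3.3 mC/cm^2).
capacitive_circuit <- function(c_specific_F_cm2 = 4.125e-3,
                               access_resistance_ohm = 1e5) {
  electrode_circuit(access_resistance_ohm = access_resistance_ohm,
                    c_specific_F_cm2 = c_specific_F_cm2)
}

# Ideal-capacitor CV circuit: constant pseudocapacitance both directions.
flat_cv_circuit <- function(c_F_cm2 = 10e-3) {
  electrode_circuit(cv_anodic = list(baseline_F_cm2 = c_F_cm2, peaks = NULL),
                    cv_cathodic = list(baseline_F_cm2 = c_F_cm2, peaks = NULL))
}

# Extracellular trace with biphasic spike templates injected at known times.
spike_trace <- function(spike_times_s, fs_hz = 2e4, dur_s = 1, snr = 10,
                        seed = 7) {
  n <- round(dur_s * fs_hz)
  tpl_t <- seq(0, 1.5e-3, by = 1 / fs_hz)
  tpl <- -exp(-((tpl_t - 3e-4) / 1.5e-4)^2) + 0.45 * exp(-((tpl_t - 8e-4) / 3e-4)^2)
  noise_sd <- max(abs(tpl)) / snr
  tr <- with_seed_test(seed, stats::rnorm(n, 0, noise_sd))
  for (t0 in spike_times_s) {
    i0 <- round((t0 - 3e-4) * fs_hz) + 1L   # dominant trough lands at t0
    idx <- i0:(i0 + length(tpl) - 1L)
    tr[idx] <- tr[idx] + tpl
  }
  tr
}

with_seed_test <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  expr
}
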