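# Evoked-response reduction: counts, PSTHs, thresholds, dynamic range.

test_that("evoked count subtracts the baseline rate and preserves suppression", {
  tr <- trial_response(c(-1.9, -1.2, -0.7, -0.1, 0.01, 0.05, 0.1, 0.2, 0.3, 0.4, 0.45))
  # 7 post spikes, 4 baseline spikes in 2 s (2 Hz) -> 7 - 1 = 6
  expect_equal(count_evoked(tr), 6)
  expect_equal(count_evoked(trial_response(numeric(0))), 0)
  # suppression: 0 post, 8 baseline in 2 s -> -2, not clipped
  sup <- trial_response(seq(-1.95, -0.2, length.out = 8))
  expect_equal(count_evoked(sup), -2)
})

test_that("PSTH bins rates correctly and conserves the mean spike count", {
  trials <- trials_from_times(rep(list(0.010), 5))
  p <- build_psth(trials, bin_width_s = 0.01)
  hot <- which(p$rate_hz > 0)
  expect_length(hot, 1L)
  expect_equal(p$rate_hz[hot], 100)   # 1 spike / 10 ms bin
  expect_true(all(build_psth(trials_from_times(list(numeric(0))))$rate_hz == 0))
  expect_error(build_psth(list()), class = "stimlimit_input")

  # conservation on arbitrary rasters
  raster <- with_seed_test(11, lapply(1:7, function(k) sort(runif(rpois(1, 12), -0.05, 0.5))))
  p <- build_psth(trials_from_times(raster))
  post <- p$bin_edges_s[-length(p$bin_edges_s)] >= 0
  lhs <- sum(p$rate_hz[post] * diff(p$bin_edges_s)[post])
  rhs <- mean(vapply(raster, function(s) sum(s >= 0 & s < 0.5), numeric(1)))
  expect_equal(lhs, rhs, tolerance = 1e-12)
})

test_that("response curves report per-level probabilities and flag over-CIC levels", {
  trials <- c(
    trials_from_times(list(0.02, 0.03, numeric(0), numeric(0), 0.1), charge_nC = 1),
    trials_from_times(rep(list(0.02), 5), charge_nC = 2),
    trials_from_times(rep(list(0.02), 5), charge_nC = 5))
  cv <- response_curve(trials, cic_limit_nC = 3)
  expect_equal(cv$p_response, c(0.6, 1, 1))
  expect_equal(cv$within_cic, c(TRUE, TRUE, FALSE))
  expect_equal(cv$charge_nC, c(1, 2, 5))
})

test_that("threshold interpolation uses the lowest crossing", {
  expect_equal(estimate_threshold(make_curve(c(1, 2), c(0.2, 0.8), c(1, 2)))$threshold_nC,
               1.5)
  # a level at exactly 0.5 is itself the threshold
  expect_equal(estimate_threshold(make_curve(c(1, 2, 3), c(0.1, 0.5, 0.9),
                                             c(0, 1, 2)))$threshold_nC, 2)
  # lowest crossing wins for non-monotone curves
  expect_equal(estimate_threshold(make_curve(c(1, 2, 3, 4), c(0.2, 0.6, 0.4, 0.9),
                                             c(0, 1, 1, 2)))$threshold_nC, 1.75)
  # censoring and absence
  lc <- estimate_threshold(make_curve(c(1, 2), c(0.7, 0.9), c(1, 2)))
  expect_identical(lc$status, "left_censored")
  expect_equal(lc$threshold_nC, 1)
  expect_identical(estimate_threshold(make_curve(c(1, 2), c(0, 0.1), c(0, 0)))$status,
                   "no_threshold")
  # levels above the CIC limit cannot provide the crossing
  over <- make_curve(c(1, 2, 5), c(0.1, 0.3, 1), c(0, 1, 3), cic_limit_nC = 3)
  expect_identical(estimate_threshold(over)$status, "no_threshold")
})

test_that("threshold is invariant to levels added above the crossing", {
  base <- make_curve(c(1, 2, 3), c(0.2, 0.8, 0.9), c(1, 2, 3))
  ext <- make_curve(c(1, 2, 3, 4, 6), c(0.2, 0.8, 0.9, 1, 1), c(1, 2, 3, 4, 4))
  expect_equal(estimate_threshold(base)$threshold_nC,
               estimate_threshold(ext)$threshold_nC)
})

test_that("half-max finds 50% of the within-CIC maximum count", {
  expect_equal(estimate_half_max(make_curve(c(1, 2, 3), c(0, 0.5, 1),
                                            c(0, 4, 8)))$half_max_nC, 2)
  # flat nonzero curve: first level
  expect_equal(estimate_half_max(make_curve(c(1, 2, 3), c(1, 1, 1),
                                            c(3, 3, 3)))$half_max_nC, 1)
  # a single within-CIC level is not enough
  one <- make_curve(c(1, 5), c(0.5, 1), c(2, 9), cic_limit_nC = 2)
  expect_identical(estimate_half_max(one)$status, "undefined")
  expect_identical(estimate_half_max(make_curve(c(1, 2), c(0, 0), c(0, 0)))$status,
                   "undefined")
})

test_that("dynamic range is 10 log10 of the max/threshold count ratio", {
  # max equals threshold count -> 0 dB exactly
  flat <- make_curve(c(1, 2, 3), c(0.2, 0.8, 1), c(2, 2, 2))
  expect_equal(dynamic_range(flat)$dynamic_range_dB, 0)
  # 10x the threshold count -> 10 dB
  cv <- make_curve(c(1, 2, 3), c(0.2, 0.8, 1), c(1, 1, 10))
  expect_equal(dynamic_range(cv)$dynamic_range_dB, 10)
  # scale invariance: scaling all counts leaves DR unchanged
  cv2 <- make_curve(c(1, 2, 3), c(0.2, 0.8, 1), 7.3 * c(1, 1, 10))
  expect_equal(dynamic_range(cv2)$dynamic_range_dB,
               dynamic_range(cv)$dynamic_range_dB)
  # nearest-level mode reads the tested level instead of interpolating
  cv3 <- make_curve(c(1, 2), c(0.2, 0.6), c(1, 3))   # threshold at 1.75
  expect_equal(dynamic_range(cv3, mode = "nearest")$dynamic_range_dB,
               10 * log10(3 / 3))
  expect_equal(dynamic_range(cv3)$dynamic_range_dB, 10 * log10(3 / 2.5))
  # undefined when the interpolated threshold count is non-positive
  z <- make_curve(c(1, 2, 3), c(0.2, 0.8, 1), c(-1, 0, 5))
  expect_identical(dynamic_range(z)$status, "undefined")
})

test_that("population summary reports order statistics and responsive fraction", {
  cells <- data.frame(cell_id = sprintf("c%d", 1:6), diameter_um = 10,
                      protocol_id = "single",
                      threshold_nC = c(1, 2, 3, 4, 5, NA),
                      threshold_status = c(rep("ok", 5), "no_threshold"),
                      dynamic_range_dB = c(3, 4, 5, 6, 7, NA))
  s <- population_summary(cells)
  expect_equal(s$threshold_median_nC, 3)
  expect_equal(s$threshold_q25_nC, 2)
  expect_equal(s$threshold_q75_nC, 4)
  expect_equal(s$responsive_fraction, 5 / 6)
  expect_equal(s$n_tested, 6)
  # single-cell group: mean = median = the cell
  one <- population_summary(cells[1, ])
  expect_equal(one$threshold_mean_nC, one$threshold_median_nC)
  # density threshold = median / area, in mC/cm^2
  expect_equal(s$density_threshold_median_mC_cm2,
               3e-6 / disk_area(electrode_geometry(10)), tolerance = 1e-9)
})

test_that("latency split counts short and long latency spikes", {
  trials <- trials_from_times(list(c(0.005, 0.02, 0.25), c(0.01, 0.3)))
  ls <- latency_split(trials)
  expect_equal(ls$n_short, 3)
  expect_equal(ls$n_long, 2)
  ls5 <- latency_split(trials, split_s = 0.01)
  expect_equal(ls5$n_short, 1)
})

test_that("spike detection recovers injected templates and merges refractory pairs", {
  truth <- c(0.2, 0.45, 0.7)
  tr <- spike_trace(truth, snr = 10)
  det <- detect_spikes(tr, 2e4)
  expect_length(det, 3L)
  expect_true(all(abs(det - truth) < 2e-4))
  # two templates 0.5 ms apart collapse to one event
  tr2 <- spike_trace(c(0.3, 0.3005), snr = 50)
  expect_length(detect_spikes(tr2, 2e4), 1L)
  # flat trace: nothing
  expect_length(detect_spikes(rep(0, 2e4), 2e4), 0L)
  expect_error(detect_spikes(rnorm(100), 5e3), class = "stimlimit_resolution")
  # artifact blanking removes events inside the blank window
  det_b <- detect_spikes(tr, 2e4, blank_windows = list(c(0.195, 0.21)))
  expect_length(det_b, 2L)
})
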