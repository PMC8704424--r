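# Generators: determinism, designed ground truths, generative laws.

test_that("generators are bit-identical for identical seeds", {
  circ <- sirof_circuit_preset(noise_sd_V = 0.01)
  g <- electrode_geometry(10)
  s1 <- gen_cv_trace(circ, g, seed = 5)
  s2 <- gen_cv_trace(circ, g, seed = 5)
  expect_identical(s1, s2)
  expect_false(identical(s1$current_A, gen_cv_trace(circ, g, seed = 6)$current_A))

  pp <- rgc_population_preset(10)
  expect_identical(gen_cell_population(pp, 5, seed = 3),
                   gen_cell_population(pp, 5, seed = 3))
  cell <- gen_cell_population(pp, 1, seed = 3)[[1]]
  p <- stimulus_pulse(1e-6, 1e-3)
  expect_identical(gen_recording(cell, p, c(1, 2), seed = 9),
                   gen_recording(cell, p, c(1, 2), seed = 9))
})

test_that("generator seeds do not disturb the caller's RNG stream", {
  set.seed(123); a <- runif(1)
  set.seed(123)
  invisible(gen_cv_trace(sirof_circuit_preset(0.01), electrode_geometry(10), seed = 4))
  expect_identical(runif(1), a)
})

test_that("zero pseudocapacitance gives a zero CV current", {
  scan <- gen_cv_trace(flat_cv_circuit(0), electrode_geometry(10))
  expect_true(all(scan$current_A == 0))
})

test_that("zero-amplitude pulse gives a flat transient", {
  tr <- gen_voltage_transient(capacitive_circuit(), electrode_geometry(10),
                              stimulus_pulse(0, 1e-3))
  expect_true(all(tr$measured_potential_V == 0))
  expect_true(all(tr$command_current_A == 0))
})

test_that("population draws respect the designed distributions", {
  pp <- rgc_population_preset(20)
  cells <- gen_cell_population(pp, 1000, seed = 12)
  q0 <- vapply(cells, `[[`, numeric(1), "q0_nC")
  expect_equal(median(q0), 1.8, tolerance = 0.05)     # lognormal median
  expect_true(all(vapply(cells, `[[`, logical(1), "responsive")))  # p_resp = 1
  d <- vapply(cells, `[[`, numeric(1), "distance_um")
  expect_true(all(d >= 0 & d <= 25))

  none <- gen_cell_population(population_params(10, 2.6, p_resp = 0,
                                                threshold_median_nC = 1),
                              50, seed = 1)
  expect_false(any(vapply(none, `[[`, logical(1), "responsive")))
})

test_that("recordings follow the generative law at charge extremes", {
  pp <- rgc_population_preset(10)
  cell <- gen_cell_population(pp, 1, seed = 21)[[1]]
  p <- stimulus_pulse(1e-6, 1e-3)

  # far below the midpoint: only spontaneous spikes, rate within Poisson CI
  cell_lo <- cell; cell_lo$spont_hz <- 2
  far_lo <- cell$q0_nC / 20
  trials <- gen_recording(cell_lo, p, rep(far_lo, 50), n_repeats = 2, seed = 8)
  n_sp <- sum(vapply(trials, function(tr) length(tr$spike_times_s), numeric(1)))
  lam <- 2 * 2.5 * 100                     # rate x span x trials
  expect_lt(abs(n_sp - lam) / sqrt(lam), 4)

  # far above the midpoint with no spontaneous firing: every trial responds
  cell_hi <- cell; cell_hi$spont_hz <- 0; cell_hi$responsive <- TRUE
  hi <- gen_recording(cell_hi, p, rep(cell$q0_nC * 3, 20), n_repeats = 1, seed = 9)
  expect_true(all(vapply(hi, function(tr) length(tr$spike_times_s) > 0, logical(1))))
  # and all spikes are post-stimulus evoked latencies inside the window
  st <- unlist(lapply(hi, `[[`, "spike_times_s"))
  expect_true(all(st > 0 & st < 0.5))
})

test_that("estimated threshold is monotone in the generator midpoint", {
  pp_lo <- population_params(20, 10.4, threshold_median_nC = 1.2, threshold_sdlog = 0.2)
  pp_hi <- population_params(20, 10.4, threshold_median_nC = 3.0, threshold_sdlog = 0.2)
  thr <- function(pp) {
    arm <- simulate_population_study(pp, 25, protocol = "single", seed = 77)
    median(arm$cells$threshold_nC, na.rm = TRUE)
  }
  expect_lt(thr(pp_lo), thr(pp_hi))
})

test_that("threshold estimator recovers logistic midpoints within 15% median error", {
  arm <- simulate_population_study(rgc_population_preset(20), 500,
                                   protocol = "single", seed = 1234)
  cc <- arm$cells[!is.na(arm$cells$threshold_nC), ]
  rel_err <- abs(cc$threshold_nC - cc$true_midpoint_nC) / cc$true_midpoint_nC
  expect_lt(median(rel_err), 0.15)
})

test_that("charge-density thresholds decrease with diameter at calibrated medians", {
  # threshold medians 0.83 / 1.8 / 3.6 nC over areas scaling as d^2
  dens <- vapply(c(10, 20, 30), function(d) {
    thr <- c("10" = 0.83, "20" = 1.8, "30" = 3.6)[[as.character(d)]]
    thr * 1e-6 / disk_area(electrode_geometry(d))
  }, numeric(1))
  expect_true(all(diff(dens) < 0))
})
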