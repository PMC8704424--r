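# Charge storage and injection capacity extraction.

test_that("disk area follows pi d^2 / 4 in cm^2 and rejects bad geometry", {
  expect_equal(disk_area(electrode_geometry(10)), 7.854e-7, tolerance = 1e-4)
  expect_equal(disk_area(electrode_geometry(20)), 3.1416e-6, tolerance = 1e-4)
  expect_equal(disk_area(electrode_geometry(1e-6)), pi / 4 * 1e-20)
  expect_error(electrode_geometry(0), class = "stimlimit_invalid_geometry")
  expect_error(electrode_geometry(-5), class = "stimlimit_invalid_geometry")
})

test_that("max injectable charge is density x area, scales as d^2", {
  expect_equal(max_injectable_charge(electrode_geometry(10), 3.3), 2.592,
               tolerance = 1e-3)
  expect_equal(max_injectable_charge(electrode_geometry(20), 3.3), 10.367,
               tolerance = 1e-3)
  expect_equal(max_injectable_charge(electrode_geometry(10), 0), 0)
  q <- vapply(c(10, 20, 30), function(d)
    max_injectable_charge(electrode_geometry(d), 3.3), numeric(1))
  expect_equal(q / q[1], c(1, 4, 9), tolerance = 1e-12)
  expect_equal(max_injectable_charge(electrode_geometry(20), 3.3, signif = 2), 10)
  expect_error(max_injectable_charge(electrode_geometry(10), -1),
               class = "stimlimit_invalid_parameter")
})

test_that("CSC of an ideal capacitor CV equals c x window width", {
  g <- electrode_geometry(10)
  scan <- gen_cv_trace(flat_cv_circuit(10e-3), g)
  csc <- compute_csc(scan, g)
  # closed form: 10 mF/cm^2 x 1.4 V = 14 mC/cm^2; trapezoid is exact here
  expect_equal(csc$csc_anodic_mC_cm2, 14, tolerance = 1e-6)
  expect_equal(csc$csc_cathodic_mC_cm2, 14, tolerance = 1e-6)
})

test_that("CSC of an all-zero current trace is zero and short scans warn", {
  g <- electrode_geometry(10)
  scan <- gen_cv_trace(flat_cv_circuit(0), g)
  expect_equal(unlist(compute_csc(scan, g)), c(csc_anodic_mC_cm2 = 0,
                                               csc_cathodic_mC_cm2 = 0))
  # half a cycle only
  v <- seq(-0.6, 0.8, by = 0.01)
  t <- seq_along(v) * 0.05
  short <- cv_scan(t, v, rep(1e-9, length(v)), 0.2, -0.6, 0.8)
  expect_warning(compute_csc(short, g), class = "stimlimit_incomplete_cycle")
})

test_that("CSC recovers the designed SIROF-like values per diameter", {
  circ <- sirof_circuit_preset()
  truth <- designed_csc(circ)
  expect_equal(truth$csc_anodic_mC_cm2, 12, tolerance = 1e-6)
  expect_equal(truth$csc_cathodic_mC_cm2, 17, tolerance = 1e-6)
  for (d in c(10, 20, 30)) {
    g <- electrode_geometry(d)
    csc <- compute_csc(gen_cv_trace(circ, g), g)
    expect_equal(csc$csc_anodic_mC_cm2, truth$csc_anodic_mC_cm2, tolerance = 0.01)
    expect_equal(csc$csc_cathodic_mC_cm2, truth$csc_cathodic_mC_cm2, tolerance = 0.01)
  }
})

test_that("cv_scan rejects non-monotone time and out-of-range potentials", {
  expect_error(cv_scan(c(0, 2, 1), c(0, 0.1, 0.2), rep(0, 3), 0.2, -0.6, 0.8),
               class = "stimlimit_format")
  expect_error(cv_scan(0:2, c(0, 0.9, 0.2), rep(0, 3), 0.2, -0.6, 0.8),
               class = "stimlimit_format")
})

test_that("polarization measurement matches the series-RC closed form", {
  g <- electrode_geometry(10)
  # R_a = 100 kOhm, C = 25 nF, I = 1 uA, 1 ms phase: V_a = I R = 0.1 V,
  # E_ma = Q/C = 1 nC / 25 nF = 0.04 V; balanced pulse leaves E_mc = 0.
  circ <- electrode_circuit(access_resistance_ohm = 1e5,
                            c_specific_F_cm2 = 25e-9 / disk_area(g))
  tr <- gen_voltage_transient(circ, g, stimulus_pulse(1e-6, 1e-3))
  p <- measure_polarization(tr)
  expect_equal(p$V_a_V, 0.100, tolerance = 1e-9)
  expect_equal(p$E_ma_V, 0.040, tolerance = 1e-9)
  expect_equal(p$E_mc_V, 0, tolerance = 1e-9)

  # linearity of the circuit: doubling I doubles V_a and E_ma exactly
  p2 <- measure_polarization(gen_voltage_transient(circ, g, stimulus_pulse(2e-6, 1e-3)))
  expect_equal(p2$V_a_V, 2 * p$V_a_V, tolerance = 1e-9)
  expect_equal(p2$E_ma_V, 2 * p$E_ma_V, tolerance = 1e-9)
})

test_that("zero-current transient yields zero polarization, coarse sampling errors", {
  g <- electrode_geometry(10)
  circ <- capacitive_circuit()
  tr0 <- gen_voltage_transient(circ, g, stimulus_pulse(0, 1e-3))
  p0 <- measure_polarization(tr0)
  expect_equal(c(p0$V_a_V, p0$E_ma_V, p0$E_mc_V), c(0, 0, 0))
  expect_identical(p0$status, "no_pulse")

  tr <- gen_voltage_transient(circ, g, stimulus_pulse(1e-6, 1e-3), fs_hz = 2e4)
  expect_error(measure_polarization(tr), class = "stimlimit_resolution")
})

test_that("CIC on the purely capacitive electrode hits the anodic-limit closed form", {
  for (d in c(10, 20, 30)) {  # densities invariant to diameter
    g <- electrode_geometry(d)
    q_lim <- max_injectable_charge(g, 3.3) * 1e-9    # C at the designed CIC
    fam <- gen_transient_family(capacitive_circuit(), g,
                                currents_A = seq(0.3, 1.6, by = 0.1) * q_lim / 1e-3)
    cic <- compute_cic(fam, g)
    expect_equal(cic$cic_mC_cm2, 3.3, tolerance = 1e-9)
    expect_identical(cic$binding, "anodic")
    expect_identical(cic$status, "ok")
  }
})

test_that("CIC scales linearly with polarization capacitance", {
  g <- electrode_geometry(20)
  grid <- seq(0.3, 3, by = 0.15)
  q_lim <- max_injectable_charge(g, 3.3) * 1e-9
  cic1 <- compute_cic(gen_transient_family(capacitive_circuit(4.125e-3), g,
                                           currents_A = grid * q_lim / 1e-3), g)
  cic2 <- compute_cic(gen_transient_family(capacitive_circuit(8.25e-3), g,
                                           currents_A = grid * q_lim / 1e-3), g)
  expect_equal(cic2$cic_mC_cm2, 2 * cic1$cic_mC_cm2, tolerance = 1e-9)
})

test_that("CIC flags families entirely past or entirely inside the window", {
  g <- electrode_geometry(10)
  q_lim <- max_injectable_charge(g, 3.3) * 1e-9
  too_big <- gen_transient_family(capacitive_circuit(), g,
                                  currents_A = c(2, 4) * q_lim / 1e-3)
  expect_error(compute_cic(too_big, g), class = "stimlimit_below_resolution")
  all_small <- gen_transient_family(capacitive_circuit(), g,
                                    currents_A = c(0.2, 0.4) * q_lim / 1e-3)
  res <- compute_cic(all_small, g)
  expect_identical(res$status, "unbounded")
  expect_lt(res$cic_mC_cm2, 3.3)
})
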