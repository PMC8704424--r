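# Volume-conductor disk-electrode field model.

fullspace_model <- function(d_um = 10, sigma = 0.2) {
  volume_conductor(electrode_geometry(d_um), sigma_S_per_m = sigma,
                   domain = "fullspace", domain_diameter_mm = 10)
}

test_that("far-field potential matches the point monopole", {
  m <- fullspace_model()
  # I/(4 pi sigma r) at r = 1 mm, I = 2.5 uA, sigma = 0.2: 0.9947 mV
  v <- analytic_disk_field(m, 2.5e-6, z_um = 1000)$V_V
  expect_equal(v, 2.5e-6 / (4 * pi * 0.2 * 1e-3), tolerance = 1e-4)
  expect_equal(v, 0.9947e-3, tolerance = 1e-3)
})

test_that("zero current gives an identically zero field", {
  m <- fullspace_model()
  f <- analytic_disk_field(m, 0, z_um = c(1, 10, 100))
  expect_true(all(f$V_V == 0) && all(f$E_mag_V_per_m == 0))
  sol <- solve_field(m, 0, field_grid(m, extent_mm = 1))
  expect_true(all(sol$V_V == 0))
})

test_that("on-axis field crosses 1000 V/m at the closed-form depth", {
  m <- fullspace_model()
  e <- analytic_disk_field(m, 2.5e-6, z_um = 31.2)$E_mag_V_per_m
  expect_equal(e, 1000, tolerance = 3e-3)
  # inversion agrees with independent root finding on the forward field
  z_root <- uniroot(function(z) analytic_disk_field(m, 2.5e-6, z)$E_mag_V_per_m - 1000,
                    c(1, 200), tol = 1e-10)$root
  ad <- activation_depth(m, 2.5e-6)
  expect_equal(ad$depth_um, z_root, tolerance = 1e-6)
  expect_equal(ad$depth_um, 31.24, tolerance = 1e-3)
})

test_that("finite-volume solution matches the closed form on axis", {
  m <- fullspace_model()
  errs <- vapply(1:2, function(rf) {
    sol <- solve_field(m, 2.5e-6, field_grid(m, refine = rf))
    prof <- on_axis_profile(sol)
    sel <- prof$z_um >= 2 & prof$z_um <= 50
    an <- analytic_disk_field(m, 2.5e-6, prof$z_um[sel])
    max(abs(prof$E_mag_V_per_m[sel] / an$E_mag_V_per_m - 1),
        abs(prof$V_V[sel] / an$V_V - 1))
  }, numeric(1))
  expect_lt(errs[1], 0.02)
  expect_lt(errs[2], 0.02)
  expect_lt(errs[2], errs[1])   # converging under refinement
})

test_that("finite-volume solution matches the monopole beyond 10 radii", {
  m <- fullspace_model()
  sol <- solve_field(m, 2.5e-6, field_grid(m))
  prof <- on_axis_profile(sol)
  sel <- prof$z_um >= 50 & prof$z_um <= 500
  mono <- 2.5e-6 / (4 * pi * 0.2 * prof$z_um[sel] * 1e-6)
  expect_lt(max(abs(prof$V_V[sel] / mono - 1)), 0.01)
})

test_that("solutions are linear in current to machine precision", {
  m <- fullspace_model()
  g <- field_grid(m, extent_mm = 2)
  s1 <- solve_field(m, 2.5e-6, g)
  s2 <- solve_field(m, 5.0e-6, g)
  expect_equal(s2$V_V, 2 * s1$V_V, tolerance = 1e-12)
  expect_equal(s2$E_mag_V_per_m, 2 * s1$E_mag_V_per_m, tolerance = 1e-12)
})

test_that("the field is axisymmetric in the radial offset", {
  m <- fullspace_model()
  f1 <- analytic_disk_field(m, 2.5e-6, z_um = 10, r_um = 8)
  f2 <- analytic_disk_field(m, 2.5e-6, z_um = 10, r_um = -8)
  expect_equal(f1$E_mag_V_per_m, f2$E_mag_V_per_m)
  expect_equal(f1$V_V, f2$V_V)
})

test_that("half-space solution doubles the full-space one", {
  mh <- volume_conductor(electrode_geometry(10), domain = "halfspace",
                         domain_diameter_mm = 10)
  mf <- fullspace_model()
  zz <- c(5, 20, 60)
  expect_equal(analytic_disk_field(mh, 1e-6, zz)$V_V,
               2 * analytic_disk_field(mf, 1e-6, zz)$V_V)
})

test_that("activation depth handles subthreshold input and scaling", {
  m <- fullspace_model()
  expect_identical(activation_depth(m, 2.5e-6,
                                    activation_criterion(1e12))$status,
                   "subthreshold")
  expect_equal(activation_depth(m, 2.5e-6, activation_criterion(1e12))$depth_um, 0)
  # far-field monopole scaling: quadrupling I roughly doubles the depth
  d1 <- activation_depth(m, 1e-5)$depth_um
  d4 <- activation_depth(m, 4e-5)$depth_um
  expect_gt(d1, 5 * 5)             # depth beyond 5 radii so far field applies
  expect_equal(d4 / d1, 2, tolerance = 0.03)
})

test_that("required current inverts activation depth", {
  m <- fullspace_model()
  # closed-form spot value at z = 50 um
  expect_equal(required_current(50, m) * 1e6, 6.330, tolerance = 1e-3)
  for (I in c(1e-6, 2.5e-6, 1e-5)) {
    z <- activation_depth(m, I)$depth_um
    expect_equal(required_current(z, m), I, tolerance = 1e-3)
  }
  # finite limit as z -> 0: E(0) = I/(2 pi sigma a^2)
  I0 <- required_current(1e-6, m)
  expect_equal(I0, 1000 * 2 * pi * 0.2 * (5e-6)^2, tolerance = 1e-3)
})

test_that("required-current curve truncates at the CIC-limited current", {
  m <- fullspace_model()
  cur <- required_current_curve(m, z_um = seq(5, 100, by = 5))
  expect_true(all(diff(cur$I_uA) > 0))
  i_max <- max_injectable_charge(electrode_geometry(10), 3.3) * 1e-9 / 1e-3
  expect_true(all(cur$I_uA[cur$within_cic] <= i_max * 1e6 + 1e-9))
  expect_true(any(!cur$within_cic))
})

test_that("equipotential-disk variant agrees with uniform-J in the far field", {
  me <- volume_conductor(electrode_geometry(10), domain = "fullspace",
                         domain_diameter_mm = 10, bc = "equipotential")
  mu <- fullspace_model()
  z <- c(200, 500)
  expect_equal(analytic_disk_field(me, 1e-6, z)$V_V,
               analytic_disk_field(mu, 1e-6, z)$V_V, tolerance = 1e-3)
  # and differs near the disk (edge current crowding)
  vn_e <- analytic_disk_field(me, 1e-6, 1)$V_V
  vn_u <- analytic_disk_field(mu, 1e-6, 1)$V_V
  expect_gt(abs(vn_e / vn_u - 1), 0.02)
})
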