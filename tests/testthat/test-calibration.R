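test_that("conversion factor is sigma_ref / G_buffer per frequency", {
  buf <- flat_buffer(sigma_ref = 0.25, g = 0.05)
  curve <- build_calibration(buf)
  expect_equal(curve$k, rep(5, 16))
  # self-consistency identity holds by construction at every point
  expect_equal(curve$k * conductance(buf$spectrum), rep(0.25, 16),
               tolerance = 1e-15)
  expect_error(reference_buffer("bad", 0, buf$spectrum), "positive")
})

test_that("buffer calibrated against itself is flat at sigma_ref to machine precision", {
  set.seed(31)
  grid <- default_frequency_grid()
  # a deliberately non-flat measured buffer spectrum (instrument distortion)
  z <- apply_parasitics(buffer_impedance(0.13, probe_geometry(), grid),
                        parasitic_model())
  buf <- reference_buffer("Reference #2", 0.13, z)
  sig <- apply_calibration(build_calibration(buf), z)
  expect_equal(sig$sigma, rep(0.13, 256), tolerance = 1e-14)
})

test_that("identity curve leaves conductance unchanged and grids must align", {
  grid <- log_frequency_grid(16)
  ident <- reference_buffer("unit", 0.25,
    impedance_spectrum(grid, rep(4, 16), rep(0, 16)))  # G = 0.25 -> k = 1
  curve <- build_calibration(ident)
  expect_equal(curve$k, rep(1, 16))
  tissue <- random_spectrum(16, seed = 3)
  tissue <- impedance_spectrum(grid, tissue$resistance, tissue$reactance)
  sig <- apply_calibration(curve, tissue)
  expect_equal(sig$sigma, conductance(tissue), tolerance = 1e-15)

  other <- impedance_spectrum(log_frequency_grid(17), rep(10, 17), rep(0, 17))
  expect_error(apply_calibration(curve, other), "grid mismatch")
})

test_that("calibration is linear: scaling tissue impedance by a scales sigma by 1/a", {
  buf <- flat_buffer()
  curve <- build_calibration(buf)
  grid <- buf$spectrum$frequency
  set.seed(32)
  z <- impedance_spectrum(grid, runif(16, 10, 300), runif(16, -100, 100))
  a <- 3.7
  za <- impedance_spectrum(grid, a * z$resistance, a * z$reactance)
  expect_equal(apply_calibration(curve, za)$sigma,
               apply_calibration(curve, z)$sigma / a, tolerance = 1e-12)
})

test_that("cohort calibration drops unusable records and logs reasons", {
  grid <- log_frequency_grid(16)
  buf <- reference_buffer("Reference #3", 0.25,
    impedance_spectrum(grid, rep(5, 16), rep(0, 16)))
  good <- lapply(1:19, function(i)
    measurement_record(paste0("P", i), "normal", "in_vivo", "none",
      impedance_spectrum(grid, rep(100 + i, 16), rep(-5, 16))))
  # record with a singular point: R = X = 0 at one frequency
  bad <- measurement_record("P20", "tumor", "in_vivo", "HCC",
    impedance_spectrum(grid, c(0, rep(50, 15)), c(0, rep(-5, 15))))
  cal <- calibrate_cohort(as_cohort(c(good, list(bad))), buf)
  expect_length(cal, 19)
  excl <- attr(cal, "exclusions")
  expect_equal(nrow(excl), 1)
  expect_equal(excl$patient_id, "P20")
  expect_match(excl$reason, "singular")
  # metadata untouched, spectra replaced
  expect_equal(cal[[1]]$patient_id, "P1")
  expect_s3_class(cal[[1]]$spectrum, "conductivity_spectrum")
  expect_error(calibrate_cohort(list(), buf), "empty")
})

test_that("purely multiplicative common-mode distortion cancels exactly", {
  grid <- log_frequency_grid(64)
  p <- cole_parameters(r0 = 150, r_inf = 40, fc = 3e4, alpha = 0.9)
  tissue <- cole_impedance(p, grid)
  kappa <- 25
  sigma_true <- kappa * conductance(tissue)
  m <- 1 + 0.5 * (grid / 1e6)^2   # instrument gain error, common to both
  distort <- function(z) impedance_spectrum(grid, z$resistance / m, z$reactance / m)
  buf <- reference_buffer("Reference #3", 0.25,
                          distort(buffer_impedance(0.25, probe_geometry(), grid)))
  sig <- apply_calibration(build_calibration(buf), distort(tissue))
  expect_equal(sig$sigma, sigma_true, tolerance = 1e-12)
})

test_that("recovery error at 1 MHz shrinks monotonically as parasitics shrink", {
  grid <- default_frequency_grid()
  geom <- probe_geometry()
  p <- cole_parameters(r0 = 190, r_inf = 35, fc = 5e4, alpha = 0.9)
  ideal <- cole_impedance(p, grid)
  sigma_true_1mhz <- geom$cell_constant_per_m * conductance(ideal)[256]
  err <- vapply(c(1, 0.5, 0.25, 0.1, 0), function(s) {
    par <- parasitic_model(s * 0.5e-6, s * 0.2e-9)
    buf <- reference_buffer("Reference #3", 0.25,
      apply_parasitics(buffer_impedance(0.25, geom, grid), par))
    sig <- apply_calibration(build_calibration(buf), apply_parasitics(ideal, par))
    abs(sig$sigma[256] / sigma_true_1mhz - 1)
  }, numeric(1))
  expect_false(is.unsorted(rev(err)))   # non-increasing toward the ideal instrument
  expect_equal(err[5], 0, tolerance = 1e-12)
})

test_that("buffer choice is irrelevant without parasitics and matters with them", {
  grid <- default_frequency_grid()
  geom <- probe_geometry()
  p <- cole_parameters(r0 = 190, r_inf = 35, fc = 5e4, alpha = 0.9)
  ideal <- cole_impedance(p, grid)
  sig_for <- function(sigma_b, par) {
    buf <- reference_buffer("b", sigma_b,
      apply_parasitics(buffer_impedance(sigma_b, geom, grid), par))
    apply_calibration(build_calibration(buf), apply_parasitics(ideal, par))$sigma
  }
  none <- parasitic_model(0, 0)
  expect_equal(sig_for(0.062, none), sig_for(0.25, none), tolerance = 1e-12)
  some <- parasitic_model()
  d <- abs(sig_for(0.062, some) - sig_for(0.25, some))
  expect_gt(d[256], 0)                          # the two calibrations disagree
  expect_gt(d[256] / sig_for(0.25, some)[256], 1e-4)  # measurably so at 1 MHz
  # and the disagreement is a high-frequency phenomenon
  expect_lt(d[1] / sig_for(0.25, some)[1], d[256] / sig_for(0.25, some)[256])
})
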