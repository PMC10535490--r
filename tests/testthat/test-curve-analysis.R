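test_that("band integration matches the analytic trapezoid with edge cuts", {
  q <- seq(0.01, 0.1, by = 0.01)
  cu <- sans_curve(q, 2 * q + 1)          # integral of 2q+1 is q^2 + q
  anal <- function(a, b) (b^2 + b) - (a^2 + a)
  expect_equal(integrate_band(cu, 0.02, 0.08), anal(0.02, 0.08),
               tolerance = 1e-12)
  # band edges between grid points are linearly interpolated
  expect_equal(integrate_band(cu, 0.025, 0.075), anal(0.025, 0.075),
               tolerance = 1e-12)
  expect_error(integrate_band(cu, 0.2, 0.3))
})

test_that("match-point fit is exact on a noiseless contrast series", {
  fit <- fit_match_point(gen_contrast_series(96.7, noise_frac = 0))
  expect_equal(fit$match_point, 96.7, tolerance = 1e-6)
  expect_s3_class(fit, "matchpoint_fit")
})

test_that("match point extrapolates exactly from a one-sided series", {
  # all measurements below the match point: the |a f + b| fit must still
  # recover the crossing from the extrapolated sign-flip
  fit <- fit_match_point(gen_contrast_series(
    96.7, fractions = c(0, 15, 30, 45, 60), noise_frac = 0))
  expect_equal(fit$match_point, 96.7, tolerance = 1e-6)
})

test_that("skipping the solvent subtraction biases the match point", {
  ser <- gen_contrast_series(96.7, noise_frac = 0)
  with_sub <- fit_match_point(ser, subtract_solvent = TRUE)
  without <- fit_match_point(ser, subtract_solvent = FALSE)
  expect_equal(with_sub$match_point, 96.7, tolerance = 1e-6)
  expect_gt(abs(without$match_point - 96.7), 1)
})

test_that("power-law slope estimation is exact on a pure power law", {
  q <- exp(seq(log(0.01), log(0.3), length.out = 80))
  cu <- sans_curve(q, 7.3 * q^-2.4)
  fit <- porod_slope(cu, c(0.02, 0.2))
  expect_equal(fit$slope, -2.4, tolerance = 1e-10)
  expect_equal(fit$fractal_dimension, 2.4, tolerance = 1e-10)
  # outside the mass-fractal range there is no fractal reading
  rod <- sans_curve(q, q^-1)
  expect_true(is.na(porod_slope(rod, c(0.02, 0.2))$fractal_dimension))
})

test_that("interference peaks are located through a sloping background", {
  cu <- gen_fibrillization_timecourse(times = 30)[[1]]$curve
  rep_t <- detect_peaks(cu)
  expect_gte(nrow(rep_t$peaks), 2L)
  q0 <- 2 * pi / 251
  expect_equal(rep_t$peaks$q[1], q0, tolerance = 0.02)
  expect_equal(rep_t$peaks$q[2], 2 * q0, tolerance = 0.02)
})

test_that("no peaks are reported before fibrils assemble", {
  cu <- gen_fibrillization_timecourse(times = c(1, 30))[[1]]$curve
  rep_t <- detect_peaks(cu)
  expect_equal(nrow(rep_t$peaks), 0L)
})

test_that("harmonic assignment yields the repeat distance, not a multiple", {
  cu <- gen_fibrillization_timecourse(times = 30, noise_frac = 0.01)[[1]]$curve
  rep_t <- assign_harmonics(detect_peaks(cu))
  expect_equal(rep_t$periodicity_A, 251, tolerance = 0.02 * 251)
  expect_equal(rep_t$orders[1:2], c(1, 2))
  # the beta-stacking hump at 0.4 is not a harmonic of the repeat
  expect_true(is.na(rep_t$orders[3]))
})

test_that("Bragg spacing converts peak positions to real-space distances", {
  expect_equal(bragg_spacing(0.025), 2 * pi / 0.025, tolerance = 1e-12)
  expect_equal(round(bragg_spacing(0.025)), 251)
  expect_error(bragg_spacing(0))
})
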