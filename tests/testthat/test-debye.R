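test_that("two-scatterer Debye curve equals the closed form", {
  d <- 37.5
  xyz <- rbind(c(0, 0, 0), c(0, 0, d))
  b <- c(2.5, -1.2)
  q <- c(0.01, 0.05, 0.2, 0.7)
  cu <- unit_debye(xyz, q)
  cu2 <- debye_curve(point_model(xyz),
                     sim_config(q_grid = q, in_vacuum = TRUE), b = b)
  closed <- function(b1, b2) b1^2 + b2^2 + 2 * b1 * b2 * sin(q * d) / (q * d)
  expect_equal(cu$intensity, closed(1, 1), tolerance = 1e-12)
  expect_equal(cu2$intensity, closed(b[1], b[2]), tolerance = 1e-12)
})

test_that("forward scattering obeys the (sum b)^2 sum rule", {
  set.seed(7)
  xyz <- matrix(rnorm(90, sd = 15), 30, 3)
  b <- runif(30, 0.5, 3)
  q <- c(1e-5, 1e-4)
  cu <- debye_curve(point_model(xyz), sim_config(q_grid = q, in_vacuum = TRUE),
                    b = b)
  expect_equal(cu$intensity[1], sum(b)^2, tolerance = 1e-6)
})

test_that("lattice-filled sphere reproduces the analytic form factor", {
  R <- 50
  xyz <- lattice_ball(R, delta = 3)
  q <- exp(seq(log(0.005), log(8 / R), length.out = 60))
  cu <- unit_debye(xyz, q, exact_limit = 10)   # histogram acceleration
  I_num <- cu$intensity / cu$intensity[1] *
    sphere_form_factor(q[1], R)            # normalize at the first point
  I_ref <- sphere_form_factor(q, R)
  rms <- sqrt(mean((I_num - I_ref)^2)) / mean(I_ref)
  expect_lt(rms, 0.02)
})

test_that("histogram acceleration agrees with the exact double sum", {
  set.seed(11)
  xyz <- matrix(rnorm(3 * 1200, sd = 40), ncol = 3)
  b <- runif(1200, 0.2, 2)
  q <- exp(seq(log(0.01), log(0.3), length.out = 40))
  exact <- debye_curve(point_model(xyz),
                       sim_config(q_grid = q, in_vacuum = TRUE,
                                  exact_limit = 5000), b = b)
  hist <- debye_curve(point_model(xyz),
                      sim_config(q_grid = q, in_vacuum = TRUE,
                                 exact_limit = 10), b = b)
  expect_lt(max(abs(hist$intensity / exact$intensity - 1)), 0.005)
})

test_that("pair-distance histogram conserves the total scattering weight", {
  set.seed(3)
  xyz <- matrix(rnorm(150, sd = 10), 50, 3)
  b <- runif(50, 0.5, 2)
  h <- pair_distance_histogram(point_model(xyz), bin = 0.5, b = b)
  expect_equal(sum(h$w) + h$self, sum(b)^2, tolerance = 1e-9)
  expect_equal(h$self, sum(b^2), tolerance = 1e-12)
  expect_equal(h$rmax, max(dist(xyz)), tolerance = 1e-9)
})

test_that("effective lengths follow solvent exchange and excluded volume", {
  m <- atomic_model(c("N", "C"), rbind(c(0, 0, 0), c(10, 0, 0)),
                    n_exch = c(1, 0))
  # vacuum, fully protiated solvent with no exchange: N-H keeps b_H
  b_h2o <- effective_lengths(m, sim_config(solvent = 0, in_vacuum = TRUE))
  expect_equal(b_h2o[1], scattering_length("N") + scattering_length("H"),
               tolerance = 1e-12)
  # full D2O, full exchange: the labile H scatters as D
  b_d2o <- effective_lengths(m, sim_config(solvent = 1,
                                           exchange_efficiency = 1,
                                           in_vacuum = TRUE))
  expect_equal(b_d2o[1], scattering_length("N") + scattering_length("D"),
               tolerance = 1e-12)
  # solvent term only ever lowers the contrast of a protiated group
  b_solv <- effective_lengths(m, sim_config(solvent = 1,
                                            exchange_efficiency = 1))
  expect_true(all(b_solv < b_d2o))
})

test_that("hydration shell volume matches the spherical-shell geometry", {
  m <- atomic_model("C", matrix(0, 1, 3))
  sh <- add_hydration_shell(m, sim_config(shell_thickness = 3))
  r <- 1.7                                 # carbon van der Waals radius
  v_true <- 4 * pi * ((r + 3)^3 - r^3) / 3
  expect_lt(abs(sh$shell_volume_A3 - v_true) / v_true, 0.1)
  # two distant atoms carry twice the shell; a buried pair does not
  m2 <- atomic_model(c("C", "C"), rbind(c(0, 0, 0), c(50, 0, 0)))
  sh2 <- add_hydration_shell(m2, sim_config(shell_thickness = 3))
  expect_equal(sh2$shell_volume_A3, 2 * sh$shell_volume_A3, tolerance = 1e-6)
  m3 <- atomic_model(c("C", "C"), rbind(c(0, 0, 0), c(0.2, 0, 0)))
  sh3 <- add_hydration_shell(m3, sim_config(shell_thickness = 3))
  expect_lt(sh3$shell_volume_A3, 1.3 * sh$shell_volume_A3)
})

test_that("a bulk-matched shell contributes nothing to the scattering", {
  m <- atomic_model(rep("C", 4),
                    rbind(c(0, 0, 0), c(8, 0, 0), c(0, 8, 0), c(0, 0, 8)))
  q <- exp(seq(log(0.01), log(0.5), length.out = 30))
  base <- debye_curve(m, sim_config(q_grid = q))
  null_shell <- debye_curve(m, sim_config(q_grid = q,
                                          hydration_contrast_factor = 1),
                            hydration = TRUE)
  expect_equal(null_shell$intensity, base$intensity, tolerance = 1e-9)
  # a denser shell at high D2O raises the forward scattering
  dense <- debye_curve(m, sim_config(q_grid = q), hydration = TRUE)
  expect_gt(dense$intensity[1], base$intensity[1])
})

test_that("collinear geometries refuse a hydration shell gracefully", {
  m <- atomic_model(rep("C", 5), cbind(seq(0, 20, by = 5), 0, 0))
  expect_warning(out <- add_hydration_shell(m), "collinear")
  expect_equal(nrow(out$xyz), 5L)
})

test_that("monomer-cluster curve records its recommended fractal window", {
  cl <- gen_dla_cluster(3000, monomer_radius = 5, seed = 2)
  cu <- cluster_curve(cl)
  expect_s3_class(cu, "sans_curve")
  w <- cu$meta$fit_window
  expect_lt(w[1], w[2])
  expect_equal(w[2], 0.1, tolerance = 1e-12)
  # dropping the radius removes the scale separation and must error
  cl$monomer_radius <- NULL
  expect_error(cluster_curve(cl), "monomer_radius")
})
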