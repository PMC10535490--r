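test_that("debris generator hits its own fractal slope in the scaling window", {
  q <- exp(seq(log(0.005), log(0.3), length.out = 120))
  cu <- gen_debris_curve(q, fractal_dim = 2.4, rg = 600)
  fit <- porod_slope(cu, c(4 * pi / 600, 0.2))
  expect_equal(fit$slope, -2.4, tolerance = 0.05)
  expect_equal(cu$meta$fractal_dim, 2.4)
})

test_that("generators are reproducible under a fixed seed", {
  q <- seq(0.01, 0.1, length.out = 30)
  a <- gen_debris_curve(q, noise_frac = 0.05, seed = 42)
  b <- gen_debris_curve(q, noise_frac = 0.05, seed = 42)
  d <- gen_debris_curve(q, noise_frac = 0.05, seed = 43)
  expect_identical(a$intensity, b$intensity)
  expect_false(identical(a$intensity, d$intensity))
  c1 <- gen_dla_cluster(300, seed = 9)
  c2 <- gen_dla_cluster(300, seed = 9)
  expect_identical(c1$xyz, c2$xyz)
})

test_that("aggregates are contact-connected and non-overlapping", {
  a <- 5
  cl <- gen_dla_cluster(600, monomer_radius = a, seed = 3)
  d <- as.matrix(dist(cl$xyz))
  diag(d) <- Inf
  nn <- apply(d, 1, min)
  expect_gt(min(nn), 2 * a - 1e-6)         # hard spheres never overlap
  expect_lt(max(nn), 2 * a + 0.02 * a)     # every monomer touches the cluster
})

test_that("aggregate mass grows with the diffusion-limited dimension", {
  cl <- gen_dla_cluster(3000, monomer_radius = 5, seed = 1)
  ctr <- colMeans(cl$xyz)
  r <- sqrt(colSums((t(cl$xyz) - ctr)^2))
  radii <- exp(seq(log(quantile(r, 0.1)), log(quantile(r, 0.8)),
                   length.out = 12))
  mass <- vapply(radii, function(R) sum(r <= R), numeric(1))
  dim_fit <- coef(lm(log(mass) ~ log(radii)))[2]
  expect_gt(dim_fit, 2.1)
  expect_lt(dim_fit, 2.9)
})

test_that("aggregate size scales with the asymptotic DLA dimension", {
  # N ~ Rg^D across a range of cluster sizes; 3D diffusion-limited
  # aggregation has D about 2.5
  ns <- c(750, 1500, 3000, 6000)
  rgs <- vapply(seq_along(ns), function(i) {
    mean(vapply(1:2, function(s) {
      cl <- gen_dla_cluster(ns[i], monomer_radius = 5, seed = 10 * i + s)
      sqrt(mean(rowSums(scale(cl$xyz, scale = FALSE)^2)))
    }, numeric(1)))
  }, numeric(1))
  D <- unname(coef(lm(log(ns) ~ log(rgs)))[2])
  expect_gt(D, 2.2)
  expect_lt(D, 2.9)
})

test_that("contrast series vanishes coherently at its own match point", {
  ser <- gen_contrast_series(80, fractions = c(0, 40, 80, 100),
                             noise_frac = 0)
  coh <- vapply(ser, function(e)
    mean(e$curve$intensity - e$solvent$intensity), numeric(1))
  expect_equal(coh[3], 0, tolerance = 1e-12)     # 80% entry: zero contrast
  expect_true(all(coh[-3] > 0))
  expect_equal(vapply(ser, function(e) e$d2o, numeric(1)),
               c(0, 40, 80, 100))
})

test_that("fibrillization peaks emerge only after the onset time", {
  tc <- gen_fibrillization_timecourse(times = c(2, 6, 12, 30))
  amps <- vapply(tc, function(e) e$curve$meta$peak_amp, numeric(1))
  expect_equal(amps[1], 0)
  expect_true(all(diff(amps) > 0))
  # the late curve carries the first-order peak, the early one does not
  q0 <- 2 * pi / 251
  late <- tc[[4]]$curve
  early <- tc[[1]]$curve
  at_q0 <- function(cu) cu$intensity[which.min(abs(cu$q - q0))]
  expect_gt(at_q0(late) / at_q0(early), 1.5)
})
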