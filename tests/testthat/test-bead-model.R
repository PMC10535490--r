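test_that("hexagonal lattice packs touching beads inside the search volume", {
  lat <- hcp_lattice(10, 120)
  d <- dist(lat$centers)
  expect_equal(min(d), 20, tolerance = 1e-9)          # touching, no overlap
  expect_true(all(sqrt(rowSums(lat$centers^2)) <= 60 + 1e-9))
  expect_gt(nrow(lat$centers), 50)
})

test_that("annealing recovers a solid sphere from its scattering curve", {
  lat <- hcp_lattice(10, 140)
  r <- sqrt(rowSums(lat$centers^2))
  truth <- bead_model(lat$centers, occupied = r <= 60, bead_radius = 10)
  q <- exp(seq(log(0.008), log(0.15), length.out = 50))
  target <- debye_curve(truth, sim_config(q_grid = q))
  target$sigma <- 0.02 * target$intensity
  fit <- bead_fit(target, bead_radius = 10, search_diameter = 140, seed = 3)
  expect_lt(fit$chi2, fit$chi2_init / 10)
  expect_lt(nsd(truth, fit$model), 1.0)
  # the reconstruction is a single connected particle
  expect_s3_class(fit$model, "bead_model")
})

test_that("annealing is reproducible under a fixed seed", {
  lat <- hcp_lattice(12, 120)
  r <- sqrt(rowSums(lat$centers^2))
  truth <- bead_model(lat$centers, occupied = r <= 50, bead_radius = 12)
  q <- exp(seq(log(0.01), log(0.15), length.out = 40))
  target <- debye_curve(truth, sim_config(q_grid = q))
  target$sigma <- 0.02 * target$intensity
  f1 <- bead_fit(target, 12, 120, seed = 5)
  f2 <- bead_fit(target, 12, 120, seed = 5)
  expect_identical(f1$model$occupied, f2$model$occupied)
  expect_equal(f1$chi2, f2$chi2, tolerance = 1e-12)
})

test_that("spatial discrepancy passes identity, shift and oracle checks", {
  set.seed(4)
  A <- matrix(rnorm(30, sd = 20), 10, 3)
  B <- matrix(rnorm(24, sd = 20), 8, 3)
  ma <- bead_model(A, occupied = rep(TRUE, 10), bead_radius = 5)
  mb <- bead_model(B, occupied = rep(TRUE, 8), bead_radius = 5)
  expect_equal(nsd(ma, ma), 0)
  shifted <- ma
  shifted$centers <- sweep(ma$centers, 2, c(100, -50, 30), "+")
  expect_equal(nsd(ma, shifted), 0, tolerance = 1e-9)
  # centered, unaligned value equals the brute-force definition
  expect_equal(nsd(ma, mb, align = FALSE), nsd_oracle(A, B),
               tolerance = 1e-9)
  expect_lte(nsd(ma, mb), nsd(ma, mb, align = FALSE) + 1e-12)
  # axis-flip invariance of the aligned discrepancy
  flipped <- mb
  flipped$centers <- mb$centers %*% diag(c(-1, 1, -1))
  expect_equal(nsd(ma, flipped), nsd(ma, mb), tolerance = 1e-9)
})

test_that("ensemble filtering rejects the inconsistent reconstruction", {
  lat <- hcp_lattice(10, 140)
  r <- sqrt(rowSums(lat$centers^2))
  truth <- bead_model(lat$centers, occupied = r <= 60, bead_radius = 10)
  q <- exp(seq(log(0.008), log(0.15), length.out = 50))
  target <- debye_curve(truth, sim_config(q_grid = q))
  target$sigma <- 0.02 * target$intensity
  fits <- lapply(1:3, function(s) bead_fit(target, 10, 140, seed = s)$model)
  shell <- bead_model(lat$centers, occupied = r > 55 & r <= 70,
                      bead_radius = 10)
  ef <- ensemble_filter(c(fits, list(shell)), threshold = 0.8)
  expect_true(all(ef$kept[1:3]))
  expect_false(ef$kept[4])
  expect_equal(length(ef$accepted), 3L)
  # mutually consistent runs all survive the field's standard cutoff
  ef2 <- ensemble_filter(fits)
  expect_true(all(ef2$kept))
})
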