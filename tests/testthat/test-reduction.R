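# hand-built three-measurement set with known normalization constants
make_reduction_set <- function(q = seq(0.01, 0.1, length.out = 40),
                               c = 0.131) {
  truth <- 5 * q^-2            # the solute signal the reduction must recover
  solv_lvl <- 0.8              # solvent (incoherent) level
  cell_lvl <- 0.3              # empty-cell level
  v_a <- 0.74; w <- 1 - c * v_a
  B <- list(solution = 2e6, solvent = 1.5e6, cell = 1e6)
  T <- list(solution = 0.85, solvent = 0.9, cell = 0.98)
  # invert the reduction equation to synthesize the raw counts
  I_cell <- rep(cell_lvl * B$cell * T$cell, length(q))
  I_solv <- rep((solv_lvl + cell_lvl) * B$solvent * T$solvent, length(q))
  I_soln <- (truth + w * solv_lvl + cell_lvl) * B$solution * T$solution
  list(
    solution = sans_curve(q, I_soln, sigma = 0.01 * I_soln,
                          meta = list(beam_monitor = B$solution,
                                      transmission = T$solution)),
    solvent = sans_curve(q, I_solv, sigma = 0.01 * I_solv,
                         meta = list(beam_monitor = B$solvent,
                                     transmission = T$solvent)),
    cell = sans_curve(q, I_cell, sigma = 0.01 * I_cell,
                      meta = list(beam_monitor = B$cell,
                                  transmission = T$cell)),
    truth = truth, c = c, v_a = v_a, B = B, T = T)
}

test_that("reduction inverts the synthesis equation exactly", {
  s <- make_reduction_set()
  red <- reduce_solute(s$solution, s$solvent, s$cell, c = s$c, v_a = s$v_a)
  expect_equal(red$intensity, s$truth, tolerance = 1e-10)
})

test_that("uncertainties propagate in quadrature with the reduction weights", {
  s <- make_reduction_set()
  red <- reduce_solute(s$solution, s$solvent, s$cell, c = s$c, v_a = s$v_a)
  w <- 1 - s$c * s$v_a
  v_expect <- (s$solution$sigma / (s$B$solution * s$T$solution))^2 +
    w^2 * (s$solvent$sigma / (s$B$solvent * s$T$solvent))^2 +
    (1 - w)^2 * (s$cell$sigma / (s$B$cell * s$T$cell))^2
  expect_equal(red$sigma, sqrt(v_expect), tolerance = 1e-12)
})

test_that("explicit monitor/transmission overrides replace the metadata", {
  s <- make_reduction_set()
  bare <- s
  for (k in c("solution", "solvent", "cell")) bare[[k]]$meta <- list()
  expect_error(reduce_solute(bare$solution, bare$solvent, bare$cell,
                             c = s$c, v_a = s$v_a), "missing")
  red <- reduce_solute(bare$solution, bare$solvent, bare$cell,
                       c = s$c, v_a = s$v_a, B = s$B, T = s$T)
  expect_equal(red$intensity, s$truth, tolerance = 1e-10)
})

test_that("dilute limit reduces to plain solvent subtraction", {
  s <- make_reduction_set(c = 0)
  red <- reduce_solute(s$solution, s$solvent, s$cell, c = 0)
  # at c = 0 the synthesized solution contains truth + solvent + cell, and
  # the reduction subtracts the full solvent term
  expect_equal(red$intensity, s$truth, tolerance = 1e-10)
})

test_that("grid mismatches are refused unless interpolation is requested", {
  s <- make_reduction_set()
  q2 <- seq(0.009, 0.11, length.out = 73)
  shifted <- sans_curve(q2, approx(s$solvent$q, s$solvent$intensity, q2,
                                   rule = 2)$y,
                        meta = s$solvent$meta)
  expect_error(reduce_solute(s$solution, shifted, s$cell, c = s$c),
               "interpolate")
  red <- reduce_solute(s$solution, shifted, s$cell, c = s$c, v_a = s$v_a,
                       interpolate = TRUE)
  expect_equal(red$intensity, s$truth, tolerance = 1e-3)
})

test_that("extrapolation outside the measured range is forbidden", {
  cu <- sans_curve(c(0.02, 0.03, 0.04), c(3, 2, 1))
  expect_error(interpolate_to_grid(cu, c(0.01, 0.02)), "extrapolation")
  out <- interpolate_to_grid(cu, c(0.025, 0.035))
  expect_equal(out$intensity, c(2.5, 1.5))
})

test_that("nonphysical concentrations are rejected", {
  s <- make_reduction_set()
  expect_error(reduce_solute(s$solution, s$solvent, s$cell, c = -0.1))
  expect_error(reduce_solute(s$solution, s$solvent, s$cell, c = 1.4),
               "nonphysical")
})
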