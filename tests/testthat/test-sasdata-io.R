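test_that("curve constructor enforces a physical momentum-transfer grid", {
  expect_error(sans_curve(c(0, 0.01), c(1, 1)), "positive")
  expect_error(sans_curve(c(0.02, 0.01), c(1, 1)), "increasing")
  expect_error(sans_curve(c(0.01, 0.02), c(1, 1), sigma = c(-1, 0)))
  cu <- sans_curve(c(0.01, 0.02), c(2, 1))
  expect_s3_class(cu, "sans_curve")
  # counting-statistics default when no uncertainties are supplied
  expect_equal(cu$sigma, sqrt(c(2, 1)))
})

test_that("ASCII round trip preserves intensities to 1e-9 and metadata", {
  q <- exp(seq(log(0.004), log(0.6), length.out = 80))
  cu <- sans_curve(q, 3.7e-3 * q^-2.4 + 1e-5, sigma = 1e-6 * sqrt(q / q[1]),
                   label = "round trip",
                   meta = list(d2o_percent = 96.7, transmission = 0.883,
                               beam_monitor = 1.25e7))
  f <- withr::local_tempfile(fileext = ".dat")
  write_sans_curve(cu, f)
  back <- read_sans_curve(f)
  expect_equal(back$q, cu$q, tolerance = 1e-9)
  expect_equal(back$intensity, cu$intensity, tolerance = 1e-9)
  expect_equal(back$sigma, cu$sigma, tolerance = 1e-9)
  expect_equal(back$meta$d2o_percent, 96.7)
  expect_equal(back$meta$transmission, 0.883)
  expect_equal(back$meta$beam_monitor, 1.25e7)
})

test_that("reader drops non-positive q rows and rejects malformed files", {
  f <- withr::local_tempfile(fileext = ".dat")
  writeLines(c("# transmission: 0.9",
               "-0.001 5.0 0.1", "0.0 4.0 0.1",
               "0.01 3.0 0.1", "0.02 2.0 0.1"), f)
  expect_message(cu <- read_sans_curve(f), "q <= 0")
  expect_equal(length(cu$q), 2L)

  g <- withr::local_tempfile(fileext = ".dat")
  writeLines(c("0.01 1.0 0.1", "0.02 oops 0.1"), g)
  expect_error(read_sans_curve(g), "malformed")

  h <- withr::local_tempfile(fileext = ".dat")
  writeLines(character(0), h)
  expect_error(read_sans_curve(h))
})

test_that("plain3col dialect refuses commented headers", {
  f <- withr::local_tempfile(fileext = ".dat")
  writeLines(c("# d2o_percent: 40", "0.01 1 0.1"), f)
  expect_error(read_sans_curve(f, dialect = "plain3col"), "header")
  g <- withr::local_tempfile(fileext = ".dat")
  writeLines(c("0.01 1 0.1", "0.02 0.5 0.1"), g)
  cu <- read_sans_curve(g, dialect = "plain3col")
  expect_equal(cu$intensity, c(1, 0.5))
})

test_that("PDB reader takes the first model of a multi-model file", {
  f <- withr::local_tempfile(fileext = ".pdb")
  write_fixture_pdb(f,
    atoms = list(pdb_atom("CA", "GLY", 1, 0, 0, 0, "C"),
                 pdb_atom("N", "GLY", 1, 1.5, 0, 0, "N")),
    model2 = list(pdb_atom("CA", "GLY", 1, 99, 99, 99, "C"),
                  pdb_atom("N", "GLY", 1, 99, 99, 99, "N")))
  m <- read_pdb(f)
  expect_equal(nrow(m$xyz), 2L)
  expect_equal(unname(m$xyz[1, ]), c(0, 0, 0))
  expect_equal(unname(m$xyz[2, ]), c(1.5, 0, 0))
})

test_that("exchangeable hydrogens follow backbone and side-chain chemistry", {
  f <- withr::local_tempfile(fileext = ".pdb")
  # Ser: backbone N carries 1 labile H, hydroxyl O carries 1; Pro N carries 0
  write_fixture_pdb(f, atoms = list(
    pdb_atom("N", "SER", 1, 0, 0, 0, "N"),
    pdb_atom("CA", "SER", 1, 1.5, 0, 0, "C"),
    pdb_atom("OG", "SER", 1, 3, 0, 0, "O"),
    pdb_atom("N", "PRO", 2, 5, 0, 0, "N")))
  m <- read_pdb(f)
  expect_equal(m$element, c("N", "C", "O", "N"))
  expect_equal(m$n_exch, c(1, 0, 1, 0))
})

test_that("model PDB writer round-trips coordinates at format precision", {
  xyz <- matrix(c(1.234, -5.678, 9.012,
                  0.001, 2.5, -3.25), 2, 3, byrow = TRUE)
  m <- atomic_model(c("C", "N"), xyz, n_exch = c(0, 1))
  f <- withr::local_tempfile(fileext = ".pdb")
  write_model_pdb(m, f)
  back <- read_pdb(f)
  expect_equal(back$xyz, m$xyz, tolerance = 1e-3, ignore_attr = TRUE)
  expect_equal(back$element, m$element)
})
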