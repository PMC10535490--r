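# Deterministic point-filled reference shapes used across tests. Lattice
# fills are preferred over Monte Carlo fills: random points leave percent-
# level noise concentrated at form-factor minima, which blunts the oracles.

# cubic-lattice fill of a solid sphere of radius r
lattice_ball <- function(r, delta = 3) {
  g <- seq(-r, r, by = delta)
  xyz <- as.matrix(expand.grid(x = g, y = g, z = g))
  xyz[rowSums(xyz^2) <= r^2, , drop = FALSE]
}

# cubic-lattice fill of a cylinder along z: length len, radius rad
lattice_rod <- function(len, rad, delta = 5) {
  g1 <- seq(-rad, rad, by = delta)
  gz <- seq(-len / 2, len / 2, by = delta)
  xyz <- as.matrix(expand.grid(x = g1, y = g1, z = gz))
  xyz[xyz[, 1]^2 + xyz[, 2]^2 <= rad^2, , drop = FALSE]
}

# unit-scatterer model from bare coordinates
point_model <- function(xyz) atomic_model(rep("X", nrow(xyz)), xyz)

# Debye curve of unit point scatterers (in vacuum, exact or histogram)
unit_debye <- function(xyz, q, exact_limit = 2000) {
  m <- point_model(xyz)
  debye_curve(m, sim_config(q_grid = q, in_vacuum = TRUE,
                            exact_limit = exact_limit),
              b = rep(1, nrow(xyz)))
}

# analytic sphere + rod references
analytic_sphere_I <- function(q, R) sphere_form_factor(q, R)

# brute-force normalized spatial discrepancy between two centered point sets
nsd_oracle <- function(A, B) {
  A <- scale(A, scale = FALSE); B <- scale(B, scale = FALSE)
  nn <- function(X) {
    d <- as.matrix(dist(X)); diag(d) <- Inf; mean(apply(d, 1, min))
  }
  mind2 <- function(X, Y)
    vapply(seq_len(nrow(X)),
           function(i) min(colSums((t(Y) - X[i, ])^2)), numeric(1))
  dA <- nn(A); dB <- nn(B)
  sqrt(0.5 * (sum(mind2(A, B)) / (nrow(A) * dB^2) +
              sum(mind2(B, A)) / (nrow(B) * dA^2)))
}

# minimal single-model PDB writer for parser fixtures
write_fixture_pdb <- function(path, atoms, model2 = NULL) {
  fmt <- function(a, i)
    sprintf("ATOM  %5d  %-4s%3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
            i, a$name, a$res, a$resno, a$x, a$y, a$z, a$elem)
  lines <- character(0)
  if (!is.null(model2)) lines <- c(lines, "MODEL        1")
  lines <- c(lines, vapply(seq_along(atoms),
                           function(i) fmt(atoms[[i]], i), character(1)))
  if (!is.null(model2)) {
    lines <- c(lines, "ENDMDL", "MODEL        2",
               vapply(seq_along(model2),
                      function(i) fmt(model2[[i]], i), character(1)),
               "ENDMDL")
  }
  writeLines(c(lines, "END"), path)
  path
}

pdb_atom <- function(name, res, resno, x, y, z, elem)
  list(name = name, res = res, resno = resno, x = x, y = y, z = z,
       elem = elem)
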