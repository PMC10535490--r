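#' Construct a bead (dummy-atom) model
#'
#' Fixed-radius beads on a lattice with an occupancy mask separating solute
#' beads from solvent sites.
#'
#' @param centers n x 3 matrix of lattice positions, Angstroms.
#' @param bead_radius Bead radius, Angstroms (> 0).
#' @param occupied Logical mask over rows of `centers`; at least one bead
#'   must be occupied.
#' @return An object of class `bead_model`.
#' @export
bead_model <- function(centers, bead_radius, occupied = NULL) {
  centers <- as.matrix(centers)
  if (ncol(centers) != 3) stop("centers must have 3 columns")
  if (bead_radius <= 0) stop("bead_radius must be positive")
  if (is.null(occupied)) occupied <- rep(TRUE, nrow(centers))
  if (length(occupied) != nrow(centers))
    stop("occupied mask must match centers")
  if (!any(occupied)) stop("at least one bead must be occupied")
  dimnames(centers) <- NULL
  structure(list(centers = centers, bead_radius = bead_radius,
                 occupied = as.logical(occupied)),
            class = "bead_model")
}

#' @export
print.bead_model <- function(x, ...) {
  cat(sprintf("Bead model: %d/%d beads occupied, radius %.2f A\n",
              sum(x$occupied), length(x$occupied), x$bead_radius))
  invisible(x)
}

#' Hexagonal-close-packed lattice inside a spherical search volume
#'
#' @param bead_radius Bead radius, Angstroms; lattice constant is
#'   2 * bead_radius (beads in contact).
#' @param diameter Search-volume sphere diameter, Angstroms.
#' @return A [bead_model] with all sites unoccupied-eligible (mask all
#'   TRUE; callers set their own masks).
#' @export
hcp_lattice <- function(bead_radius, diameter) {
  a <- 2 * bead_radius
  Rmax <- diameter / 2
  ni <- ceiling(Rmax / a) + 1
  nj <- ceiling(Rmax / (a * sqrt(3) / 2)) + 1
  nk <- ceiling(Rmax / (a * sqrt(6) / 3)) + 1
  g <- expand.grid(i = -ni:ni, j = -nj:nj, k = -nk:nk)
  x <- a * (g$i + 0.5 * ((g$j + g$k) %% 2))
  y <- a * sqrt(3) / 2 * (g$j + (g$k %% 2) / 3)
  z <- a * sqrt(6) / 3 * g$k
  keep <- x^2 + y^2 + z^2 <= Rmax^2
  bead_model(cbind(x, y, z)[keep, , drop = FALSE], bead_radius)
}

# adjacency lists (0-based, for the C++ annealer) of lattice sites in contact
.lattice_adjacency <- function(centers, a) {
  d <- as.matrix(dist(centers))
  lapply(seq_len(nrow(centers)), function(i)
    as.integer(which(d[i, ] > 0 & d[i, ] < 1.1 * a) - 1L))
}

# largest connected component of the occupied set
.largest_component <- function(occupied, adj) {
  occ <- which(occupied)
  if (!length(occ)) return(occupied)
  seen <- logical(length(occupied))
  best <- integer(0)
  for (s in occ) {
    if (seen[s]) next
    comp <- integer(0)
    queue <- s
    seen[s] <- TRUE
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      comp <- c(comp, v)
      nb <- adj[[v]] + 1L
      nb <- nb[occupied[nb] & !seen[nb]]
      seen[nb] <- TRUE
      queue <- c(queue, nb)
    }
    if (length(comp) > length(best)) best <- comp
  }
  out <- logical(length(occupied))
  out[best] <- TRUE
  out
}

#' Ab initio bead-model fit by simulated annealing
#'
#' Reconstructs a shape from a scattering curve: single-bead flips on a
#' hexagonal-close-packed lattice inside a spherical search volume, with
#' Metropolis acceptance of the energy
#' E = chi^2(I_model, I_target) + looseness_weight * (fraction of occupied
#' beads with fewer than 3 occupied neighbours). The model curve is the
#' Debye sum over occupied bead centers with unit scattering lengths and a
#' free overall scale. On completion only the largest connected occupied
#' component is kept.
#'
#' @param target_curve A [sans_curve] (>= 10 points) to fit.
#' @param bead_radius Bead radius, Angstroms.
#' @param search_diameter Spherical search-volume diameter, Angstroms; must
#'   cover the expected particle extent.
#' @param looseness_weight Penalty coefficient (default 2).
#' @param schedule Annealing schedule: list with `T0` (initial temperature;
#'   `NULL` scales it to a tenth of the starting chi^2), `cool` (geometric
#'   cooling factor), `steps_per_T` (`NULL` = 5 moves per lattice site),
#'   and `T_min_frac` (stop when T < T0 * T_min_frac).
#' @param init_fill Initial random occupancy probability (default 0.3).
#' @param seed RNG seed (default 1) for reproducibility.
#' @return An object of class `bead_fit`: the fitted [bead_model], `chi2`,
#'   `chi2_init`, `scale`, and the model curve `I_model` on the target grid.
#' @export
bead_fit <- function(target_curve, bead_radius, search_diameter,
                     looseness_weight = 2,
                     schedule = list(T0 = NULL, cool = 0.85,
                                     steps_per_T = NULL, T_min_frac = 1e-4),
                     init_fill = 0.3, seed = 1) {
  stopifnot(inherits(target_curve, "sans_curve"))
  if (length(target_curve$q) < 10) stop("target curve shorter than 10 points")
  if (any(target_curve$intensity <= 0)) stop("target curve must be positive")
  lat <- hcp_lattice(bead_radius, search_diameter)
  M <- nrow(lat$centers)
  adj <- .lattice_adjacency(lat$centers, 2 * bead_radius)
  set.seed(seed)
  occ0 <- runif(M) < init_fill
  if (sum(occ0) < 2) occ0[sample.int(M, 2)] <- TRUE
  sig <- pmax(target_curve$sigma, 0.01 * target_curve$intensity)
  sig <- pmax(sig, 1e-12 * max(target_curve$intensity))
  # starting chi^2 sets the temperature scale
  I0 <- cpp_debye_exact(lat$centers[occ0, , drop = FALSE],
                        rep(1, sum(occ0)), target_curve$q)
  s0 <- sum(I0 * target_curve$intensity / sig^2) / sum(I0^2 / sig^2)
  chi2_start <- sum(((s0 * I0 - target_curve$intensity) / sig)^2) /
    max(length(I0) - 1, 1)
  T0 <- if (is.null(schedule$T0)) 0.1 * chi2_start else schedule$T0
  steps <- if (is.null(schedule$steps_per_T)) 5L * M
           else as.integer(schedule$steps_per_T)
  res <- cpp_bead_anneal(lat$centers, occ0, adj, target_curve$q,
                         target_curve$intensity, sig, looseness_weight,
                         T0, schedule$cool, steps, T0 * schedule$T_min_frac)
  occ <- .largest_component(res$occupied, adj)
  model <- bead_model(lat$centers, bead_radius, occ)
  structure(list(model = model, chi2 = res$chi2, chi2_init = res$chi2_init,
                 scale = res$scale,
                 I_model = sans_curve(target_curve$q, pmax(res$I_model, 0),
                                      rep(0, length(target_curve$q))),
                 n_beads = sum(occ), n_lattice = M, seed = seed),
            class = "bead_fit")
}

#' @export
print.bead_fit <- function(x, ...) {
  cat(sprintf("Bead fit: %d beads (of %d sites), chi2 %.4g (start %.4g)\n",
              x$n_beads, x$n_lattice, x$chi2, x$chi2_init))
  invisible(x)
}

# the 48 signed permutation matrices (proper + improper orthogonal)
.ortho48 <- local({
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                c(3, 1, 2), c(3, 2, 1))
  signs <- as.matrix(expand.grid(c(1, -1), c(1, -1), c(1, -1)))
  out <- list()
  for (p in perms) for (s in seq_len(nrow(signs))) {
    m <- matrix(0, 3, 3)
    for (r in 1:3) m[r, p[r]] <- signs[s, r]
    out[[length(out) + 1]] <- m
  }
  out
})

.points_of <- function(m) {
  if (inherits(m, "bead_model")) m$centers[m$occupied, , drop = FALSE]
  else if (inherits(m, "atomic_model")) m$xyz
  else as.matrix(m)
}

#' Normalized spatial discrepancy between two models
#'
#' Symmetric nearest-neighbour shape distance: for each point of one set,
#' the distance to the nearest point of the other, normalized by the
#' reference set's mean nearest-neighbour distance, combined as
#' \deqn{NSD^2 = \tfrac12\left[\frac{1}{N_A d_B^2}\sum_{a}\min_b d^2(a,b) +
#'  \frac{1}{N_B d_A^2}\sum_{b}\min_a d^2(b,a)\right].}
#' Models are superposed by centroid shift and the best of the 48
#' axis-aligned orthogonal transforms (full rotational search is out of
#' scope). Identical shapes give 0; ensembles of reconstructions are
#' conventionally accepted below 1.7.
#'
#' @param a,b [bead_model], [atomic_model], or bare coordinate matrices.
#' @param align Superpose before comparing (default `TRUE`).
#' @return The NSD value (>= 0).
#' @export
nsd <- function(a, b, align = TRUE) {
  A <- .points_of(a); B <- .points_of(b)
  if (!nrow(A) || !nrow(B)) stop("models must be non-empty")
  A <- sweep(A, 2, colMeans(A))
  B <- sweep(B, 2, colMeans(B))
  dA <- if (nrow(A) > 1) mean(.self_nn(A)) else 1
  dB <- if (nrow(B) > 1) mean(.self_nn(B)) else 1
  one <- function(Bt) {
    sAB <- mean(cpp_min_dists(A, Bt)^2)
    sBA <- mean(cpp_min_dists(Bt, A)^2)
    sqrt(0.5 * (sAB / dB^2 + sBA / dA^2))
  }
  if (!align) return(one(B))
  min(vapply(.ortho48, function(R) one(B %*% t(R)), numeric(1)))
}

# mean nearest-neighbour distance within a set
.self_nn <- function(X) {
  n <- nrow(X)
  vapply(seq_len(n), function(i)
    min(sqrt(rowSums((X[-i, , drop = FALSE] -
                        matrix(X[i, ], n - 1, 3, TRUE))^2))), numeric(1))
}

#' Filter an ensemble of reconstructions by mutual NSD
#'
#' Keeps the models whose mean pairwise NSD to the other ensemble members
#' is at most `threshold` (default 1.7, the conventional acceptance bound).
#'
#' @param models List of >= 2 bead models (or coordinate sets).
#' @param threshold Acceptance bound on the mean pairwise NSD.
#' @return List with `accepted` (the retained models), `mean_nsd` per
#'   model, and the pairwise `nsd_matrix`.
#' @export
ensemble_filter <- function(models, threshold = 1.7) {
  n <- length(models)
  if (n < 2) stop("need >= 2 models")
  M <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    M[i, j] <- M[j, i] <- nsd(models[[i]], models[[j]])
  mean_nsd <- rowSums(M) / (n - 1)
  keep <- mean_nsd <= threshold
  list(accepted = models[keep], mean_nsd = mean_nsd, nsd_matrix = M,
       kept = keep)
}
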