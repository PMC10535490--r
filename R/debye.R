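#' Configuration for Debye-formula scattering simulations
#'
#' @param solvent A [solvent_spec] or bare D2O volume fraction; default
#'   0.967 (the inverse-contrast-matching solvent).
#' @param hydration_contrast_factor Ratio of hydration-shell SLD to solvent
#'   SLD; default 1.10 (shell 10% denser than bulk solvent).
#' @param shell_thickness Hydration-shell thickness in Angstroms (default 3).
#' @param exchange_efficiency Fraction of labile H that exchanges with
#'   solvent (default 0.9).
#' @param q_grid Momentum-transfer grid, inverse Angstroms.
#' @param histogram_bin Pair-distance histogram bin width in Angstroms
#'   (default 0.5); caps the usable q at about pi/(2 bin).
#' @param exact_limit Models with at most this many scatterers use the exact
#'   double sum; larger ones the histogram acceleration (default 2000).
#' @param in_vacuum Logical; `TRUE` disables the solvent excluded-volume
#'   term (scattering lengths in vacuum).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(solvent = 0.967, hydration_contrast_factor = 1.10,
                       shell_thickness = 3.0, exchange_efficiency = 0.9,
                       q_grid = exp(seq(log(0.005), log(2), length.out = 200)),
                       histogram_bin = 0.5, exact_limit = 2000,
                       in_vacuum = FALSE) {
  if (hydration_contrast_factor <= 0) stop("hydration factor must be > 0")
  if (histogram_bin <= 0) stop("histogram_bin must be > 0")
  q_grid <- as.numeric(q_grid)
  if (any(q_grid <= 0) || any(diff(q_grid) <= 0))
    stop("q_grid must be positive and increasing")
  f <- if (inherits(solvent, "solvent_spec")) solvent$d2o_volume_fraction
       else as.numeric(solvent)
  structure(list(d2o_fraction = f,
                 hydration_contrast_factor = hydration_contrast_factor,
                 shell_thickness = shell_thickness,
                 exchange_efficiency = exchange_efficiency,
                 q_grid = q_grid, histogram_bin = histogram_bin,
                 exact_limit = exact_limit, in_vacuum = in_vacuum),
            class = "sim_config")
}

#' Per-atom effective neutron scattering lengths
#'
#' For each atom: the element's coherent length, plus its exchangeable
#' hydrogens at the solvent-dependent mixture (1-x) b_H + x b_D with
#' x = D2O fraction times exchange efficiency, minus the solvent term
#' rho_solvent times the displaced volume of the heavy-atom group (the
#' excluded-volume correction; disabled with `in_vacuum = TRUE`). Explicit
#' hydrogen atoms flagged labile (see [read_pdb]) scatter at the same
#' solvent-dependent mixture.
#'
#' @param model An [atomic_model].
#' @param config A [sim_config].
#' @return Effective scattering lengths in fm, one per atom.
#' @export
effective_lengths <- function(model, config = sim_config()) {
  stopifnot(inherits(model, "atomic_model"), inherits(config, "sim_config"))
  x <- config$d2o_fraction * config$exchange_efficiency
  b_hx <- (1 - x) * .b_coh[["H"]] + x * .b_coh[["D"]]
  b <- .b_coh[model$element]
  if (!is.null(model$labile_h) && any(model$labile_h))
    b[model$labile_h] <- b_hx
  b <- b + model$n_exch * b_hx
  if (!config$in_vacuum) {
    rho <- solvent_sld(config$d2o_fraction) / .fm_per_A  # fm / A^3
    v <- .v_excl[model$element] + model$n_exch * .v_excl[["H"]]
    b <- b - rho * v
  }
  unname(b * model$occupancy)
}

#' Orientationally averaged Debye scattering curve
#'
#' Computes I(q) = sum_ij b_i b_j sin(q r_ij)/(q r_ij) over all scatterer
#' pairs, exactly for models up to `config$exact_limit` scatterers and via
#' the b-weighted pair-distance histogram above that. The q -> 0 limit is
#' (sum b)^2. With `hydration = TRUE` a shell of surface pseudo-atoms is
#' added first (see [add_hydration_shell]).
#'
#' @param model An [atomic_model] or [bead_model].
#' @param config A [sim_config].
#' @param hydration Add the hydration shell (default `FALSE`).
#' @param b Optional explicit per-scatterer lengths overriding
#'   [effective_lengths] (bead models default to unit lengths).
#' @return A [sans_curve] (sigma set to 0; simulations are noise-free).
#' @export
debye_curve <- function(model, config = sim_config(), hydration = FALSE,
                        b = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (inherits(model, "bead_model")) {
    xyz <- model$centers[model$occupied, , drop = FALSE]
    if (is.null(b)) b <- rep(1, nrow(xyz))
  } else {
    if (hydration && is.null(model$shell_b))
      model <- add_hydration_shell(model, config)
    xyz <- model$xyz
    if (is.null(b)) {
      ns <- length(model$shell_b)          # 0 or NULL-safe below
      if (is.null(model$shell_b)) {
        b <- effective_lengths(model, config)
      } else {
        core <- model
        keep <- seq_len(nrow(xyz) - ns)
        core$xyz <- xyz[keep, , drop = FALSE]
        core$element <- model$element[keep]
        core$n_exch <- model$n_exch[keep]
        core$occupancy <- model$occupancy[keep]
        if (!is.null(model$labile_h)) core$labile_h <- model$labile_h[keep]
        core$shell_b <- NULL
        b <- c(effective_lengths(core, config), model$shell_b)
      }
    }
  }
  if (nrow(xyz) < 1) stop("model has no scatterers")
  q <- config$q_grid
  if (nrow(xyz) <= config$exact_limit) {
    I <- cpp_debye_exact(xyz, b, q)
  } else {
    h <- cpp_pair_histogram(xyz, b, config$histogram_bin)
    I <- cpp_debye_from_hist(h$r, h$w, h$self, q)
  }
  sans_curve(q, I, sigma = rep(0, length(q)), label = "debye simulation",
             meta = list(n_scatterers = nrow(xyz),
                         d2o_fraction = config$d2o_fraction))
}

#' Sphere form factor
#'
#' Normalized single-sphere form factor
#' P(q) = [3 (sin(qR) - qR cos(qR)) / (qR)^3]^2, with P(0) = 1.
#'
#' @param q Momentum transfer, inverse Angstroms.
#' @param radius Sphere radius, Angstroms.
#' @return P(q), same length as `q`.
#' @export
sphere_form_factor <- function(q, radius) {
  if (radius <= 0) stop("radius must be positive")
  x <- q * radius
  p <- ifelse(x < 1e-4, 1, (3 * (sin(x) - x * cos(x)) / x^3)^2)
  as.numeric(p)
}

#' Scattering curve of a cluster of identical spherical monomers
#'
#' For an aggregate of N identical homogeneous spheres (e.g. a
#' diffusion-limited cluster from [gen_dla_cluster]) the orientationally
#' averaged intensity factorizes as I(q) = P(q) S(q) with P the sphere form
#' factor and S the center-of-mass Debye sum. The mass-fractal dimension
#' lives in the interference part of S, so by default the flat
#' self-scattering term (S -> 1 at large q) is removed before applying P:
#' I(q) = P(q) [S_Debye(q) - N]. Set `coherent_only = FALSE` to keep it.
#'
#' The fractal power law I ~ q^-D is visible only between the cluster and
#' monomer scales; the recommended [porod_slope] window
#' (4 pi / Rg, 0.5 / a) avoids the Guinier knee below and the
#' contact-distance structure (which sets in near q ~ 1 / a for touching
#' hard spheres) above. Note that single finite clusters systematically
#' read shallower than the aggregate's asymptotic mass-radius dimension:
#' the sharp density cutoff at the cluster envelope leaks into the fractal
#' window of the transform.
#'
#' @param cluster An [atomic_model] of monomer centers (typically from
#'   [gen_dla_cluster]).
#' @param q_grid Momentum-transfer grid, inverse Angstroms (default
#'   log-spaced across the recommended fit window, slightly extended).
#' @param monomer_radius Sphere radius in Angstroms; defaults to the
#'   cluster's recorded `monomer_radius`.
#' @param coherent_only Drop the flat self term (default `TRUE`).
#' @return A [sans_curve]; `meta` records Rg, the monomer radius and the
#'   recommended `fit_window`.
#' @export
cluster_curve <- function(cluster, q_grid = NULL, monomer_radius = NULL,
                          coherent_only = TRUE) {
  stopifnot(inherits(cluster, "atomic_model"))
  a <- if (is.null(monomer_radius)) cluster$monomer_radius else monomer_radius
  if (is.null(a) || a <= 0) stop("monomer_radius must be a positive number")
  n <- nrow(cluster$xyz)
  rg <- sqrt(mean(rowSums(scale(cluster$xyz, scale = FALSE)^2)))
  window <- c(4 * pi / rg, 0.5 / a)
  if (window[1] >= window[2])
    stop("no scale separation: cluster Rg too small for this monomer radius")
  q <- if (is.null(q_grid)) {
    exp(seq(log(window[1] * 0.8), log(window[2] * 1.2), length.out = 80))
  } else as.numeric(q_grid)
  cfg <- sim_config(q_grid = q, in_vacuum = TRUE, exact_limit = 5000)
  s <- debye_curve(cluster, cfg, b = rep(1, n))$intensity
  if (coherent_only) s <- pmax(s - n, .Machine$double.xmin)
  I <- sphere_form_factor(q, a) * s
  sans_curve(q, I, sigma = rep(0, length(q)),
             label = "monomer cluster scattering",
             meta = list(n_monomers = n, monomer_radius = a, rg = rg,
                         fit_window = window, coherent_only = coherent_only))
}

#' Add a hydration shell of surface pseudo-atoms
#'
#' Samples the solvent-accessible surface of the model (sphere points of
#' radius r_vdw + t/2 per atom, kept where not buried in a neighbour's
#' sampling sphere) and attaches one pseudo-atom per kept point carrying
#' scattering length (factor - 1) rho_solvent V_point, so that the shell's
#' excess SLD over bulk solvent is (factor - 1) rho_solvent -- 10% of the
#' solvent SLD by default. Shell pseudo-atoms use element "X" and carry
#' their lengths in the `shell_b` attribute consumed by [debye_curve].
#'
#' @param model An [atomic_model].
#' @param config A [sim_config].
#' @param points_per_atom Surface sampling density (default 60).
#' @return The model with shell pseudo-atoms appended; `shell_volume_A3`
#'   holds the estimated shell volume.
#' @export
add_hydration_shell <- function(model, config = sim_config(),
                                points_per_atom = 60) {
  stopifnot(inherits(model, "atomic_model"))
  xyz <- model$xyz
  if (nrow(xyz) >= 3) {
    # collinearity check: degenerate geometry has no meaningful surface
    sv <- svd(scale(xyz, scale = FALSE))$d
    if (sv[2] < 1e-6 * max(sv[1], 1)) {
      warning("degenerate (collinear) geometry: hydration shell skipped")
      return(model)
    }
  }
  radii <- .r_vdw[model$element]
  sp <- cpp_shell_points(xyz, radii, config$shell_thickness, points_per_atom)
  if (!nrow(sp$points)) return(model)
  rho <- solvent_sld(config$d2o_fraction) / .fm_per_A  # fm / A^3
  b_shell <- (config$hydration_contrast_factor - 1) * rho * sp$volume
  out <- model
  out$xyz <- rbind(xyz, sp$points)
  out$element <- c(model$element, rep("X", nrow(sp$points)))
  out$n_exch <- c(model$n_exch, rep(0, nrow(sp$points)))
  out$occupancy <- c(model$occupancy, rep(1, nrow(sp$points)))
  if (!is.null(model$labile_h))
    out$labile_h <- c(model$labile_h, rep(FALSE, nrow(sp$points)))
  out$shell_b <- b_shell
  out$shell_volume_A3 <- sum(sp$volume)
  out
}

#' b-weighted pair-distance histogram
#'
#' Histogram of all pair distances weighted by 2 b_i b_j (plus the self term
#' sum b_i^2 reported separately); the accelerated Debye sum over the
#' histogram reproduces the exact double sum within 0.5% for
#' q < pi / (2 bin).
#'
#' @param model An [atomic_model] or [bead_model].
#' @param bin Bin width in Angstroms.
#' @param b Optional per-scatterer lengths (defaults: vacuum tabulated
#'   lengths for atomic models, unit for beads).
#' @return List with bin centers `r`, weights `w`, the `self` term and
#'   `rmax`.
#' @export
pair_distance_histogram <- function(model, bin = 0.5, b = NULL) {
  if (bin <= 0) stop("bin must be positive")
  if (inherits(model, "bead_model")) {
    xyz <- model$centers[model$occupied, , drop = FALSE]
    if (is.null(b)) b <- rep(1, nrow(xyz))
  } else {
    xyz <- model$xyz
    if (is.null(b)) b <- unname(.b_coh[model$element])
  }
  cpp_pair_histogram(xyz, b, bin)
}
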