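# Synthetic-data generators. Every generator is deterministic under a fixed
# seed and records its ground-truth parameters in the curve metadata so each
# analysis stage can be validated closed-loop.

#' Synthetic polydisperse cell-debris curve
#'
#' Featureless mass-fractal scattering with an incoherent background:
#' I(q) = scale / (1 + (2/(3D)) q^2 Rg^2)^(D/2) + incoherent_level, with
#' multiplicative Gaussian noise. In the window 1/Rg << q << 1/monomer the
#' coherent term decays as q^-D (the mass-fractal Porod regime); debris
#' crowders show D between 2 and 2.5.
#'
#' @param q_grid Momentum-transfer grid, inverse Angstroms.
#' @param fractal_dim Mass-fractal dimension D, in (1, 3); default 2.4.
#' @param rg Aggregate radius of gyration, Angstroms (default 600).
#' @param scale Forward-scattering scale (default 1).
#' @param incoherent_level Flat background (default 0).
#' @param noise_frac Multiplicative Gaussian noise fraction (default 0).
#' @param seed RNG seed (default 1).
#' @return A [sans_curve]; ground truth in `meta`.
#' @export
gen_debris_curve <- function(q_grid, fractal_dim = 2.4, rg = 600, scale = 1,
                             incoherent_level = 0, noise_frac = 0, seed = 1) {
  if (fractal_dim <= 1 || fractal_dim >= 3)
    stop("fractal_dim must be in (1, 3)")
  q <- as.numeric(q_grid)
  I0 <- scale / (1 + (2 / (3 * fractal_dim)) * q^2 * rg^2)^(fractal_dim / 2) +
    incoherent_level
  set.seed(seed)
  I <- I0 * (1 + noise_frac * rnorm(length(q)))
  sans_curve(q, I, sigma = pmax(noise_frac * I0, 0),
             label = "synthetic debris",
             meta = list(fractal_dim = fractal_dim, rg = rg, scale = scale,
                         incoherent_level = incoherent_level,
                         noise_frac = noise_frac, seed = seed))
}

#' Off-lattice 3D diffusion-limited aggregate
#'
#' Grows a cluster by launching monomers that random-walk from a launch
#' sphere and stick on first contact (sticking probability 1); the textbook
#' model whose 3D fractal dimension is about 2.5. Monomer centers are
#' returned as generic unit scatterers.
#'
#' @param n_monomers Cluster size (>= 10).
#' @param monomer_radius Monomer radius, Angstroms (default 5).
#' @param seed RNG seed.
#' @return An [atomic_model] of element-"X" unit scatterers.
#' @export
gen_dla_cluster <- function(n_monomers, monomer_radius = 5, seed = 1) {
  if (n_monomers < 10) stop("need >= 10 monomers")
  set.seed(seed)
  xyz <- cpp_dla_cluster(as.integer(n_monomers), monomer_radius)
  m <- atomic_model(rep("X", n_monomers), xyz)
  m$monomer_radius <- monomer_radius
  m
}

#' Synthetic contrast-variation series
#'
#' One debris curve per solvent D2O percentage: the coherent term of
#' [gen_debris_curve] scaled by the squared contrast (f - match_point)^2,
#' plus an incoherent level decreasing linearly with f (H2O dominates the
#' incoherent background). At the match point only the incoherent term
#' remains.
#'
#' @param match_point_pct True contrast-match point, % D2O (default 96.7).
#' @param fractions D2O percentages of the series (default
#'   `c(0, 20, 40, 60, 80, 100)`).
#' @param q_grid Momentum-transfer grid.
#' @param scale Coherent scale at 100% contrast distance (default 1).
#' @param incoherent_h2o Incoherent level at 0% D2O (default 0.05); decays
#'   linearly to a tenth of that at 100% D2O.
#' @param noise_frac Multiplicative noise fraction.
#' @param fractal_dim,rg Debris shape parameters (see [gen_debris_curve]).
#' @param seed RNG seed.
#' @return List of `list(d2o = f, curve = sans_curve, solvent = sans_curve)`
#'   entries; `solvent` is the matching solvent-only (incoherent) curve, so
#'   the series can be solvent-subtracted exactly as measured series are
#'   (see [fit_match_point]).
#' @export
gen_contrast_series <- function(match_point_pct = 96.7,
                                fractions = c(0, 20, 40, 60, 80, 100),
                                q_grid = seq(0.005, 0.05, length.out = 60),
                                scale = 1, incoherent_h2o = 0.05,
                                noise_frac = 0, fractal_dim = 2.4, rg = 600,
                                seed = 1) {
  if (any(fractions < 0 | fractions > 100))
    stop("fractions must be within [0, 100] % D2O")
  lapply(seq_along(fractions), function(i) {
    f <- fractions[i]
    contrast2 <- ((f - match_point_pct) / 100)^2
    inc <- incoherent_h2o * (1 - 0.9 * f / 100)
    cu <- gen_debris_curve(q_grid, fractal_dim = fractal_dim, rg = rg,
                           scale = scale * contrast2, incoherent_level = inc,
                           noise_frac = noise_frac, seed = seed + i)
    cu$meta$d2o_percent <- f
    cu$meta$match_point_pct <- match_point_pct
    cu$label <- sprintf("debris %g%% D2O", f)
    set.seed(seed + 10000 + i)
    q <- as.numeric(q_grid)
    sv <- sans_curve(q, inc * (1 + noise_frac * rnorm(length(q))),
                     sigma = rep(noise_frac * inc, length(q)),
                     label = sprintf("solvent %g%% D2O", f),
                     meta = list(d2o_percent = f, incoherent_level = inc))
    list(d2o = f, curve = cu, solvent = sv)
  })
}

#' Synthetic fibrillization time course
#'
#' Scattering curves at increasing incubation times: a power-law background
#' whose slope drifts from -2.4 to -2.5 across the series (growing
#' diffusion-limited aggregation), plus first- and second-order Gaussian
#' interference peaks at q0 = 2 pi / periodicity and 2 q0 whose amplitudes
#' are zero before `onset_h` and grow monotonically (saturating
#' exponential) afterwards, and a broad beta-sheet stacking hump fixed at
#' 0.4 inverse Angstroms.
#'
#' @param times Observation times, hours, non-negative increasing.
#' @param q_grid Momentum-transfer grid (default log-spaced 0.006-0.6).
#' @param periodicity True super-assembly periodicity, Angstroms
#'   (default 251).
#' @param onset_h Peak emergence time, hours (default 5).
#' @param growth_rate Peak growth rate, per hour (default 0.15).
#' @param peak_fwhm First-order peak FWHM, inverse Angstroms (default 0.004).
#' @param peak_scale Saturated first-order peak amplitude relative to the
#'   background at q0 (default 1.0); the second order gets half.
#' @param hump_scale Relative amplitude of the 0.4 A^-1 hump (default 0.3).
#' @param noise_frac Multiplicative noise fraction.
#' @param seed RNG seed.
#' @return List of `list(t = hours, curve = sans_curve)` entries.
#' @export
gen_fibrillization_timecourse <- function(times,
                                          q_grid = exp(seq(log(0.006),
                                                           log(0.6),
                                                           length.out = 300)),
                                          periodicity = 251, onset_h = 5,
                                          growth_rate = 0.15,
                                          peak_fwhm = 0.004, peak_scale = 1.0,
                                          hump_scale = 0.3, noise_frac = 0,
                                          seed = 1) {
  if (any(times < 0) || any(diff(times) <= 0 & length(times) > 1))
    stop("times must be non-negative and increasing")
  q <- as.numeric(q_grid)
  q0 <- 2 * pi / periodicity
  sdev <- peak_fwhm / 2.3548
  gauss <- function(mu, s) exp(-0.5 * ((q - mu) / s)^2)
  tmax <- max(times, 1)
  lapply(seq_along(times), function(i) {
    t <- times[i]
    slope <- -2.4 - 0.1 * t / tmax
    bg <- (q / 0.01)^slope
    amp <- if (t > onset_h) 1 - exp(-growth_rate * (t - onset_h)) else 0
    b_q0 <- (q0 / 0.01)^slope          # background level at each peak
    b_2q0 <- (2 * q0 / 0.01)^slope
    b_hump <- (0.4 / 0.01)^slope
    I <- bg +
      amp * peak_scale * b_q0 * gauss(q0, sdev) +
      amp * 0.5 * peak_scale * b_2q0 * gauss(2 * q0, 1.5 * sdev) +
      amp * hump_scale * b_hump * gauss(0.4, 0.06)
    set.seed(seed + i)
    In <- I * (1 + noise_frac * rnorm(length(q)))
    cu <- sans_curve(q, In, sigma = pmax(noise_frac * I, 0),
                     label = sprintf("A-beta %g h", t),
                     meta = list(time_h = t, periodicity = periodicity,
                                 onset_h = onset_h, slope = slope,
                                 peak_amp = amp, seed = seed + i))
    list(t = t, curve = cu)
  })
}
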