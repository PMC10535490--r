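#' Interpolate a curve onto a target q-grid
#'
#' Linear interpolation of intensity and uncertainty; extrapolation outside
#' the source range is refused.
#'
#' @param curve A [sans_curve].
#' @param q_target Strictly increasing positive grid, inverse Angstroms.
#' @return A [sans_curve] on `q_target`.
#' @export
interpolate_to_grid <- function(curve, q_target) {
  stopifnot(inherits(curve, "sans_curve"))
  q_target <- as.numeric(q_target)
  if (min(q_target) < min(curve$q) - 1e-12 ||
      max(q_target) > max(curve$q) + 1e-12)
    stop("q_target outside curve range; extrapolation forbidden")
  I <- approx(curve$q, curve$intensity, q_target)$y
  s <- approx(curve$q, curve$sigma, q_target)$y
  sans_curve(q_target, I, s, label = curve$label, meta = curve$meta)
}

.norm_term <- function(curve, B, T) curve$intensity / (B * T)
.norm_var <- function(curve, B, T) (curve$sigma / (B * T))^2

#' Reduce solution/solvent/empty-cell measurements to a solute curve
#'
#' Monitor- and transmission-normalized background subtraction with the
#' solvent-displacement correction:
#' \deqn{I_{solute}(q) = \left[\frac{I_{solution}}{B_{solution} T_{solution}}
#'   - \frac{I_{cell}}{B_{cell} T_{cell}}\right] - (1 - c\, v_a)
#'   \left[\frac{I_{solvent}}{B_{solvent} T_{solvent}} -
#'   \frac{I_{cell}}{B_{cell} T_{cell}}\right]}
#' where c is the solute concentration (g/cm^3) and v_a its partial specific
#' volume (cm^3/g). Uncertainties propagate in quadrature with the same
#' coefficients. Monitor `B` and transmission `T` are taken from each
#' curve's metadata (`beam_monitor`, `transmission`) unless overridden.
#'
#' Absolute-intensity calibration against a water standard is represented
#' only as the optional multiplicative `abs_scale`.
#'
#' @param solution,solvent,cell [sans_curve] objects; `cell` is the empty
#'   sample cell. Curves must share the solution q-grid, or
#'   `interpolate = TRUE` to interpolate solvent/cell onto it.
#' @param c Solute concentration, g/cm^3 (note 1% w/v = 0.01 g/cm^3).
#' @param v_a Partial specific volume, cm^3/g; default 0.74 (cell debris;
#'   use ~0.73 for protein).
#' @param B,T Optional named lists overriding metadata, with entries
#'   `solution`, `solvent`, `cell`.
#' @param interpolate Interpolate solvent/cell onto the solution grid.
#' @param abs_scale Multiplicative absolute-scale factor (default 1).
#' @param flat_background Optional constant subtracted after reduction
#'   (residual incoherent term), default 0.
#' @return A [sans_curve] with the solute intensity.
#' @export
reduce_solute <- function(solution, solvent, cell, c, v_a = 0.74,
                          B = list(), T = list(), interpolate = FALSE,
                          abs_scale = 1, flat_background = 0) {
  stopifnot(inherits(solution, "sans_curve"), inherits(solvent, "sans_curve"),
            inherits(cell, "sans_curve"))
  if (c < 0) stop("concentration must be non-negative")
  if (c * v_a >= 1) stop("c * v_a >= 1: nonphysical solute volume fraction")
  getBT <- function(ov, curve, key, what) {
    v <- if (!is.null(ov[[key]])) ov[[key]] else curve$meta[[what]]
    if (is.null(v)) stop(sprintf("%s for '%s' curve missing", what, key))
    v
  }
  Bs <- getBT(B, solution, "solution", "beam_monitor")
  Bv <- getBT(B, solvent, "solvent", "beam_monitor")
  Bc <- getBT(B, cell, "cell", "beam_monitor")
  Ts <- getBT(T, solution, "solution", "transmission")
  Tv <- getBT(T, solvent, "solvent", "transmission")
  Tc <- getBT(T, cell, "cell", "transmission")
  if (any(c(Bs, Bv, Bc) <= 0)) stop("beam monitors must be positive")
  if (any(c(Ts, Tv, Tc) <= 0 | c(Ts, Tv, Tc) > 1))
    stop("transmissions must be in (0, 1]")
  same_grid <- function(a, b)
    length(a$q) == length(b$q) && all(abs(a$q - b$q) < 1e-10)
  if (!same_grid(solution, solvent) || !same_grid(solution, cell)) {
    if (!interpolate)
      stop("curves are on different q-grids; set interpolate = TRUE")
    solvent <- interpolate_to_grid(solvent, solution$q)
    cell <- interpolate_to_grid(cell, solution$q)
  }
  w <- 1 - c * v_a
  t_sol <- .norm_term(solution, Bs, Ts)
  t_sv <- .norm_term(solvent, Bv, Tv)
  t_c <- .norm_term(cell, Bc, Tc)
  I <- (t_sol - t_c) - w * (t_sv - t_c)
  var <- .norm_var(solution, Bs, Ts) + w^2 * .norm_var(solvent, Bv, Tv) +
    (1 - w)^2 * .norm_var(cell, Bc, Tc)
  sans_curve(solution$q, abs_scale * (I - flat_background),
             abs_scale * sqrt(var),
             label = paste0(solution$label, " (reduced)"),
             meta = list(concentration = c, v_a = v_a,
                         abs_scale = abs_scale))
}
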