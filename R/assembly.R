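# Rodrigues rotation matrix about a unit axis
.rot_about <- function(axis, theta) {
  u <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

# principal axis of inertia (largest spread) as a fallback fibril axis;
# PDB fibril entries come in arbitrary orientations
.infer_axis <- function(model) {
  ctr <- scale(model$xyz, scale = FALSE)
  ev <- eigen(crossprod(ctr), symmetric = TRUE)
  a <- ev$vectors[, 1]
  a / sqrt(sum(a^2))
}

#' Elongate a fibril unit along its axis
#'
#' Stacks `n_repeats` rigid copies of the unit, the k-th translated by
#' k * rise along the fibril axis and rotated by k * twist about it
#' (pseudo-helical arrangement; twist defaults to 0 as the twist per repeat
#' is a free parameter).
#'
#' @param unit An [atomic_model]; if `unit$axis` is unset the principal
#'   axis of inertia is used.
#' @param n_repeats Number of copies (>= 1).
#' @param rise Axial rise per repeat, Angstroms (> 0); fibril unit heights
#'   are typically 35-55 A, so e.g. 15 repeats at 35 A span ~525 A and 60
#'   repeats ~2100 A.
#' @param twist Rotation per repeat about the axis, degrees (default 0).
#' @return An [atomic_model] with `n_repeats` times the atoms.
#' @export
elongate <- function(unit, n_repeats, rise, twist = 0) {
  stopifnot(inherits(unit, "atomic_model"), n_repeats >= 1)
  if (rise <= 0) stop("rise must be positive")
  axis <- if (!is.null(unit$axis)) unit$axis else .infer_axis(unit)
  ctr <- colMeans(unit$xyz)
  xyz0 <- sweep(unit$xyz, 2, ctr)
  parts <- vector("list", n_repeats)
  for (k in seq_len(n_repeats) - 1) {
    R <- .rot_about(axis, k * twist * pi / 180)
    parts[[k + 1]] <- xyz0 %*% t(R) +
      matrix(ctr + k * rise * axis, nrow(xyz0), 3, byrow = TRUE)
  }
  out <- atomic_model(rep(unit$element, n_repeats), do.call(rbind, parts),
                      n_exch = rep(unit$n_exch, n_repeats),
                      occupancy = rep(unit$occupancy, n_repeats),
                      axis = axis)
  if (!is.null(unit$labile_h)) out$labile_h <- rep(unit$labile_h, n_repeats)
  out
}

#' Place two copies of a fibril model side by side
#'
#' Union of the model and a copy translated by `separation` along a
#' direction perpendicular to the fibril axis; separation is
#' center-of-mass to center-of-mass. Paired fibrils at a few hundred
#' Angstroms produce interference maxima near q ~ 2 pi / separation in the
#' ratio I_pair / I_monomer.
#'
#' @param model An [atomic_model] with an axis (or an inferable one).
#' @param separation Center-to-center distance, Angstroms.
#' @param direction Optional unit vector perpendicular to the axis (within
#'   1e-6); default: an arbitrary perpendicular.
#' @return An [atomic_model] with twice the atoms.
#' @export
lateral_pair <- function(model, separation, direction = NULL) {
  stopifnot(inherits(model, "atomic_model"))
  axis <- if (!is.null(model$axis)) model$axis else .infer_axis(model)
  if (is.null(direction)) {
    ref <- if (abs(axis[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    direction <- ref - sum(ref * axis) * axis
    direction <- direction / sqrt(sum(direction^2))
  } else {
    direction <- as.numeric(direction)
    direction <- direction / sqrt(sum(direction^2))
    if (abs(sum(direction * axis)) > 1e-6)
      stop("direction must be orthogonal to the fibril axis")
  }
  shift <- matrix(separation * direction, nrow(model$xyz), 3, byrow = TRUE)
  out <- atomic_model(rep(model$element, 2), rbind(model$xyz, model$xyz + shift),
                      n_exch = rep(model$n_exch, 2),
                      occupancy = rep(model$occupancy, 2), axis = axis)
  if (!is.null(model$labile_h)) out$labile_h <- rep(model$labile_h, 2)
  out
}

#' Idealized cross-beta unit
#'
#' Deterministic point-scatterer stand-in for a paired beta-sheet
#' protofilament: two flat parallel sheets (separated by
#' `sheet_separation`) of `n_strands` strands each, strands stacked every
#' `strand_spacing` along the fibril axis (the 4.7 A cross-beta repeat) and
#' extending `strand_length` perpendicular to it. No PDB input is needed.
#'
#' @param n_strands Strands per sheet (>= 1).
#' @param strand_spacing Inter-strand stacking distance, Angstroms
#'   (default 4.7).
#' @param sheet_separation Distance between the paired sheets, Angstroms
#'   (default 10).
#' @param strand_length Strand extent, Angstroms (default 30).
#' @param points_per_strand Scatterers per strand (default 20).
#' @return An [atomic_model] of generic unit scatterers (element "X") with
#'   the axis along the stacking direction.
#' @export
make_cross_beta_unit <- function(n_strands, strand_spacing = 4.7,
                                 sheet_separation = 10, strand_length = 30,
                                 points_per_strand = 20) {
  stopifnot(n_strands >= 1)
  s <- seq(0, strand_length, length.out = points_per_strand)
  xyz <- do.call(rbind, lapply(seq_len(n_strands) - 1, function(k) {
    z <- k * strand_spacing
    rbind(cbind(s, 0, z), cbind(s, sheet_separation, z))
  }))
  atomic_model(rep("X", nrow(xyz)), xyz, axis = c(0, 0, 1))
}
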