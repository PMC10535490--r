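#' Trapezoidal band integral of a curve
#'
#' Integrates the intensity over a q-band by the trapezoid rule, with the
#' band edges included by linear interpolation. The default band (set in
#' [fit_match_point]) is the smallest-q window 0.0065-0.009 inverse
#' Angstroms used as a stand-in for the forward scattering I(0).
#'
#' @param curve A [sans_curve].
#' @param q_lo,q_hi Band edges, inverse Angstroms.
#' @return The integral of I over the band.
#' @export
integrate_band <- function(curve, q_lo, q_hi) {
  stopifnot(inherits(curve, "sans_curve"), q_lo < q_hi)
  if (q_hi < min(curve$q) || q_lo > max(curve$q))
    stop("band does not overlap the curve's q-range")
  lo <- max(q_lo, min(curve$q)); hi <- min(q_hi, max(curve$q))
  inside <- curve$q > lo & curve$q < hi
  qq <- c(lo, curve$q[inside], hi)
  II <- c(approx(curve$q, curve$intensity, lo)$y,
          curve$intensity[inside],
          approx(curve$q, curve$intensity, hi)$y)
  sum(diff(qq) * (head(II, -1) + tail(II, -1)) / 2)
}

#' Contrast-match-point regression over a D2O series
#'
#' Computes the square root of the integrated small-q intensity for each
#' curve of a contrast-variation series and fits
#' \eqn{\sqrt{I_{integ}}(f) = |a f + b|} by least squares; the absolute
#' value captures the sign flip of the contrast across the match point, so
#' the fit is robust when no measurement lies beyond the match. The match
#' point is the root -b/a in % D2O, with its standard error from the fit
#' covariance by the delta method.
#'
#' @param series List of `list(d2o = percent, curve = sans_curve)` entries
#'   (optionally with a paired `solvent` curve, see below), or a list of
#'   curves with `d2o_percent` in their metadata.
#' @param q_lo,q_hi Integration band, inverse Angstroms (defaults
#'   0.0065-0.009).
#' @param subtract_solvent When an entry carries a `solvent` curve, subtract
#'   it before integrating (default `TRUE`): the contrast parabola holds for
#'   the coherent solute term only, so series that still contain the
#'   incoherent solvent background must be solvent-subtracted, exactly as
#'   measured series are reduced before this analysis.
#' @return An object of class `matchpoint_fit` with fields `match_point`,
#'   `std_error` (% D2O), `slope`, `intercept`, `q_window`, `data`.
#' @export
fit_match_point <- function(series, q_lo = 0.0065, q_hi = 0.009,
                            subtract_solvent = TRUE) {
  if (inherits(series[[1]], "sans_curve"))
    series <- lapply(series, function(cu)
      list(d2o = cu$meta$d2o_percent, curve = cu))
  f <- vapply(series, function(e) as.numeric(e$d2o), numeric(1))
  if (anyNA(f)) stop("missing d2o percentage in series")
  if (length(unique(f)) < 3) stop("need >= 3 distinct D2O fractions")
  v <- vapply(series, function(e) {
    cu <- e$curve
    if (subtract_solvent && !is.null(e$solvent)) {
      sv <- e$solvent
      if (!isTRUE(all.equal(sv$q, cu$q))) sv <- interpolate_to_grid(sv, cu$q)
      cu <- sans_curve(cu$q, cu$intensity - sv$intensity,
                       sqrt(cu$sigma^2 + sv$sigma^2), meta = cu$meta)
    }
    sqrt(max(integrate_band(cu, q_lo, q_hi), 0))
  }, numeric(1))
  # |a f + b| least squares is linear once the side of each point relative
  # to the crossing is fixed: enumerate every candidate crossing (below the
  # series, between each adjacent pair, above), solve the sign-flipped OLS
  # in closed form, keep the best. Exact on exactly affine data, unlike a
  # gradient method on the kinked objective.
  o <- order(f); fo <- f[o]; vo <- v[o]
  n <- length(f)
  best <- NULL
  for (k in 0:n) {                      # first k points lie below the crossing
    s <- c(rep(-1, k), rep(1, n - k))
    ft <- lm(I(s * vo) ~ fo)
    ssr <- sum(residuals(ft)^2)
    if (is.null(best) || ssr < best$ssr)
      best <- list(ssr = ssr, fit = ft)
  }
  a <- unname(coef(best$fit)[2]); b <- unname(coef(best$fit)[1])
  if (!is.finite(a) || abs(a) < .Machine$double.eps)
    stop("no contrast variation across the series")
  cov <- tryCatch(suppressWarnings(vcov(best$fit))[c(2, 1), c(2, 1)],
                  error = function(e) matrix(NA_real_, 2, 2))
  mp <- -b / a
  # delta method on mp = -b/a
  g <- c(b / a^2, -1 / a)
  se <- sqrt(max(drop(t(g) %*% cov %*% g), 0))
  warn <- NULL
  if (all(f < mp) || all(f > mp)) {
    lev <- max(abs(f - mp)) / max(diff(range(f)), 1e-12)
    if (lev > 3) warn <- "match point far outside the measured series"
  }
  structure(list(match_point = mp, std_error = se, slope = a, intercept = b,
                 q_window = c(q_lo, q_hi),
                 data = data.frame(d2o = f, sqrt_I_integ = v),
                 warning = warn),
            class = "matchpoint_fit")
}

#' @export
print.matchpoint_fit <- function(x, ...) {
  cat(sprintf("Contrast-match point: %.2f +/- %.2f %% D2O\n",
              x$match_point, x$std_error))
  cat(sprintf("  sqrt(I_integ) = |%.4g f %+.4g|, band %.4g-%.4g A^-1, n = %d\n",
              x$slope, x$intercept, x$q_window[1], x$q_window[2],
              nrow(x$data)))
  if (!is.null(x$warning)) cat("  warning:", x$warning, "\n")
  invisible(x)
}

#' Porod-region power-law slope
#'
#' Ordinary least squares of log10 I on log10 q over a q-window. A slope in
#' (-3, -1) is reported as a mass-fractal dimension D = -slope (slopes near
#' -2.5 are the signature of diffusion-limited aggregates; -1 is the
#' thin-rod value; -4 a sharp interface).
#'
#' @param curve A [sans_curve].
#' @param q_window Length-2 window, inverse Angstroms.
#' @return An object of class `porod_fit` with `slope`, `stderr`,
#'   `q_window`, `fractal_dimension` (NA outside the mass-fractal regime),
#'   `n_points`.
#' @export
porod_slope <- function(curve, q_window) {
  stopifnot(inherits(curve, "sans_curve"), length(q_window) == 2)
  sel <- curve$q >= q_window[1] & curve$q <= q_window[2]
  if (sum(sel) < 5) stop("need >= 5 points in the Porod window")
  if (any(curve$intensity[sel] <= 0))
    stop("nonpositive intensities in the Porod window")
  fit <- lm(log10(curve$intensity[sel]) ~ log10(curve$q[sel]))
  sl <- unname(coef(fit)[2])
  se <- suppressWarnings(summary(fit))$coefficients[2, 2]
  structure(list(slope = sl, stderr = se, q_window = as.numeric(q_window),
                 fractal_dimension = if (sl > -3 && sl < -1) -sl else NA_real_,
                 n_points = sum(sel)),
            class = "porod_fit")
}

#' @export
print.porod_fit <- function(x, ...) {
  cat(sprintf("Porod slope: %.3f +/- %.3f over q = %.4g-%.4g A^-1 (%d pts)\n",
              x$slope, x$stderr, x$q_window[1], x$q_window[2], x$n_points))
  if (!is.na(x$fractal_dimension))
    cat(sprintf("  mass-fractal dimension D = %.3f\n", x$fractal_dimension))
  invisible(x)
}

# robust power-law + constant baseline A q^p + c via IRLS around nlsLM,
# downweighting points above the baseline so peaks do not pull the fit
.fit_baseline <- function(q, I) {
  c0 <- max(min(I) * 0.5, .Machine$double.eps)
  p0 <- coef(lm(log(pmax(I - c0, max(I) * 1e-6)) ~ log(q)))
  # pure power-law fallback for degenerate (e.g. exactly featureless) data
  # where the three-parameter least squares is singular
  pure <- coef(lm(log(pmax(I, .Machine$double.xmin)) ~ log(q)))
  fallback <- list(A = exp(unname(pure[1])), p = unname(pure[2]), c = 0)
  start <- list(A = exp(unname(p0[1])), p = unname(p0[2]), c = c0)
  w <- rep(1, length(q))
  fit <- NULL
  for (it in 1:6) {
    fit <- tryCatch(
      minpack.lm::nlsLM(I ~ A * q^p + c, start = start, weights = w,
                        lower = c(A = 0, p = -6, c = 0),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) return(fallback)
    pr <- predict(fit)
    r <- I - pr
    s <- median(abs(r)) * 1.4826 + .Machine$double.eps
    # asymmetric: positive excursions (candidate peaks) are downweighted hard
    w <- ifelse(r > 2 * s, (2 * s / r)^2, 1)
    start <- as.list(coef(fit))
  }
  list(A = coef(fit)[["A"]], p = coef(fit)[["p"]], c = coef(fit)[["c"]])
}

#' Detect interference peaks above a power-law baseline
#'
#' Fits a robust baseline A q^p + c over the whole window, then reports
#' local maxima of I - baseline whose height exceeds
#' `min_prominence * baseline` at the peak position. Peak positions are
#' refined by three-point parabolic interpolation; widths are estimated at
#' half the baseline-subtracted height.
#'
#' @param curve A [sans_curve] with at least 20 points.
#' @param min_prominence Required peak height as a fraction of the local
#'   baseline (default 0.1).
#' @return An object of class `peak_report`: data frame `peaks`
#'   (`q`, `height`, `width`), the `baseline` parameters, and (after
#'   [assign_harmonics]) `orders` and `periodicity_A`.
#' @export
detect_peaks <- function(curve, min_prominence = 0.1) {
  stopifnot(inherits(curve, "sans_curve"))
  if (length(curve$q) < 20) stop("need >= 20 points for peak detection")
  q <- curve$q; I <- curve$intensity
  bl <- .fit_baseline(q, I)
  base <- bl$A * q^bl$p + bl$c
  r <- I - base
  n <- length(q)
  peaks <- data.frame(q = numeric(0), height = numeric(0), width = numeric(0))
  i <- 2
  while (i < n) {
    if (r[i] > r[i - 1] && r[i] >= r[i + 1] &&
        r[i] > min_prominence * base[i]) {
      # parabolic refinement in (q, r) about the sample maximum
      d1 <- r[i] - r[i - 1]; d2 <- r[i] - r[i + 1]
      denom <- d1 + d2
      off <- if (denom > 0) 0.5 * (d1 - d2) / denom else 0
      qp <- q[i] + off * (q[i + 1] - q[i - 1]) / 2
      hp <- r[i] + 0.25 * (d1 - d2) * off
      # half-height width
      half <- hp / 2
      il <- i; while (il > 1 && r[il] > half) il <- il - 1
      ir <- i; while (ir < n && r[ir] > half) ir <- ir + 1
      peaks <- rbind(peaks, data.frame(q = qp, height = hp,
                                       width = q[ir] - q[il]))
      i <- ir
    }
    i <- i + 1
  }
  peaks <- peaks[order(peaks$q), , drop = FALSE]
  structure(list(peaks = peaks, baseline = bl, periodicity_A = NA_real_,
                 orders = rep(NA_integer_, nrow(peaks))),
            class = "peak_report")
}

#' @export
print.peak_report <- function(x, ...) {
  if (!nrow(x$peaks)) {
    cat("Peak report: no peaks\n")
    return(invisible(x))
  }
  cat(sprintf("Peak report: %d peak(s)\n", nrow(x$peaks)))
  for (i in seq_len(nrow(x$peaks)))
    cat(sprintf("  q = %.4g A^-1, height %.4g, width %.4g%s\n",
                x$peaks$q[i], x$peaks$height[i], x$peaks$width[i],
                if (!is.na(x$orders[i]))
                  sprintf(", order %d", x$orders[i]) else ""))
  if (!is.na(x$periodicity_A))
    cat(sprintf("  periodicity: %.1f A\n", x$periodicity_A))
  invisible(x)
}

#' Real-space Bragg spacing from a peak position
#'
#' d = 2 pi / q: the correlation distance of the periodic structure whose
#' first-order interference peak sits at q.
#'
#' @param q_peak Peak position(s), inverse Angstroms, positive.
#' @return Distance(s) in Angstroms.
#' @export
#' @examples
#' bragg_spacing(0.025)  # ~ 251 A
bragg_spacing <- function(q_peak) {
  if (any(q_peak <= 0)) stop("q must be positive")
  2 * pi / q_peak
}

#' Assign harmonic orders to detected peaks
#'
#' Searches for the fundamental q0 (orders restricted to 1-4, fundamental
#' within the observed peak range) minimizing the total relative misfit
#' |q_i - n_i q0| / q_i over integer order assignments; peaks whose best
#' order misses by more than `tol` remain unassigned. The periodicity
#' 2 pi / q0 is attached to the report.
#'
#' @param report A `peak_report` from [detect_peaks].
#' @param tol Relative assignment tolerance (default 0.1).
#' @param max_order Highest harmonic order considered (default 4).
#' @return The report with `orders` and `periodicity_A` filled in.
#' @export
assign_harmonics <- function(report, tol = 0.1, max_order = 4) {
  stopifnot(inherits(report, "peak_report"))
  qs <- report$peaks$q
  if (!length(qs)) return(report)
  cand <- sort(unique(as.numeric(outer(qs, seq_len(max_order), "/"))),
               decreasing = TRUE)
  cand <- cand[cand >= min(qs) / max_order - 1e-12 & cand <= max(qs) + 1e-12]
  best <- NULL
  for (q0 in cand) {
    ords <- pmax(1L, pmin(max_order, as.integer(round(qs / q0))))
    err <- abs(qs - ords * q0) / qs
    ok <- err <= tol
    # prefer the assignment covering the most peaks; among ties the largest
    # fundamental wins (no spurious subharmonics)
    if (is.null(best) || sum(ok) > sum(best$ok))
      best <- list(q0 = q0, ords = ords, ok = ok)
  }
  if (is.null(best) || !any(best$ok)) return(report)
  # refine q0 by least squares over the assigned peaks
  ords <- best$ords[best$ok]
  q0 <- sum(qs[best$ok] * ords) / sum(ords^2)
  report$orders <- ifelse(best$ok, best$ords, NA_integer_)
  report$periodicity_A <- 2 * pi / q0
  report
}
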