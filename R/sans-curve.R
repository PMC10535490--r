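#' Construct a SANS scattering curve
#'
#' The basic currency of the pipeline: a momentum-transfer grid with
#' intensities, 1-sigma uncertainties and acquisition metadata.
#'
#' @param q Momentum transfer grid, inverse Angstroms; strictly increasing,
#'   all positive.
#' @param intensity Scattered intensity per q-point (arbitrary units).
#' @param sigma 1-sigma uncertainty per point; defaults to
#'   `sqrt(pmax(intensity, 0))` (counting statistics).
#' @param label Free-text label.
#' @param meta Named list of acquisition metadata. Recognized keys include
#'   `beam_monitor` (counts), `transmission` (0-1), `concentration` (g/cm^3),
#'   `temperature` (deg C), `exposure_h` (h); arbitrary keys are preserved.
#' @return An object of class `sans_curve`.
#' @export
#' @examples
#' sc <- sans_curve(q = c(0.01, 0.02), intensity = c(5, 4), sigma = c(0.1, 0.1))
#' length(sc$q)
sans_curve <- function(q, intensity, sigma = NULL, label = "", meta = list()) {
  q <- as.numeric(q); intensity <- as.numeric(intensity)
  if (length(q) != length(intensity))
    stop("q and intensity must have equal length")
  if (any(!is.finite(q)) || any(q <= 0))
    stop("q must be finite and positive")
  if (any(diff(q) <= 0)) stop("q must be strictly increasing")
  if (is.null(sigma)) sigma <- sqrt(pmax(intensity, 0))
  sigma <- as.numeric(sigma)
  if (length(sigma) != length(q)) stop("sigma must match q in length")
  if (any(sigma < 0, na.rm = TRUE)) stop("sigma must be non-negative")
  tr <- meta$transmission
  if (!is.null(tr) && (tr <= 0 || tr > 1))
    stop("transmission must be in (0, 1]")
  structure(list(q = q, intensity = intensity, sigma = sigma,
                 label = as.character(label), meta = meta),
            class = "sans_curve")
}

#' @export
print.sans_curve <- function(x, ...) {
  cat(sprintf("SANS curve%s: %d points, q in [%.4g, %.4g] A^-1\n",
              if (nzchar(x$label)) paste0(" '", x$label, "'") else "",
              length(x$q), min(x$q), max(x$q)))
  if (length(x$meta))
    cat("  meta:", paste(names(x$meta), unlist(lapply(x$meta, format)),
                         sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.data.frame.sans_curve <- function(x, ...) {
  data.frame(q = x$q, intensity = x$intensity, sigma = x$sigma)
}

#' @export
plot.sans_curve <- function(x, log = "xy", ...) {
  pos <- x$intensity > 0
  graphics::plot(x$q[pos], x$intensity[pos], log = log, type = "l",
                 xlab = expression(q ~ (ring(A)^-1)), ylab = "I(q)",
                 main = x$label, ...)
  invisible(x)
}

#' Read a SANS curve from an ASCII file
#'
#' Parses whitespace-separated three-column files (q, I, sigma), optionally
#' preceded by `# key: value` header lines holding acquisition metadata.
#' Rows with q <= 0 are dropped (with a message reporting the count); a
#' missing third column yields counting-statistics uncertainties.
#'
#' @param path File path.
#' @param dialect `"auto"` accepts both a bare 3-column body and a
#'   `#`-headered file; `"plain3col"` refuses header lines.
#' @return A [sans_curve].
#' @export
read_sans_curve <- function(path, dialect = c("auto", "plain3col")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty curve file: ", path)
  hdr <- grepl("^\\s*#", lines)
  if (dialect == "plain3col" && any(hdr))
    stop("header lines present but dialect is 'plain3col'")
  meta <- list()
  for (h in lines[hdr]) {
    m <- regmatches(h, regexec("^\\s*#\\s*([^:]+):\\s*(.*)$", h))[[1]]
    if (length(m) == 3) {
      key <- trimws(m[2]); val <- trimws(m[3])
      num <- suppressWarnings(as.numeric(val))
      meta[[key]] <- if (!is.na(num)) num else val
    }
  }
  body <- lines[!hdr]
  if (!length(body)) stop("no data rows in ", path)
  rows <- strsplit(trimws(body), "\\s+")
  ncol <- min(lengths(rows))
  if (ncol < 2) stop("need at least q and intensity columns in ", path)
  mat <- matrix(NA_real_, nrow = length(rows), ncol = min(ncol, 3))
  for (i in seq_along(rows)) {
    v <- suppressWarnings(as.numeric(rows[[i]][seq_len(ncol(mat))]))
    if (anyNA(v))
      stop(sprintf("malformed numeric row at data line %d of %s", i, path))
    mat[i, ] <- v
  }
  keep <- mat[, 1] > 0
  if (any(!keep))
    message(sum(!keep), " row(s) with q <= 0 dropped from ", basename(path))
  mat <- mat[keep, , drop = FALSE]
  if (!nrow(mat)) stop("no rows with q > 0 in ", path)
  o <- order(mat[, 1])
  mat <- mat[o, , drop = FALSE]
  sans_curve(q = mat[, 1], intensity = mat[, 2],
             sigma = if (ncol(mat) >= 3) mat[, 3] else NULL,
             label = basename(path), meta = meta)
}

#' Write a SANS curve to an ASCII file
#'
#' Emits `# key: value` header lines for the metadata followed by three
#' whitespace-separated columns (q, I, sigma) at 10 significant digits.
#' The written file round-trips through [read_sans_curve] losslessly (to
#' 1e-9 relative) for q, I, sigma and string metadata.
#'
#' @param curve A [sans_curve].
#' @param path Output file path.
#' @export
write_sans_curve <- function(curve, path) {
  stopifnot(inherits(curve, "sans_curve"))
  con <- tryCatch(file(path, "w"), error = function(e)
    stop("cannot open for writing: ", path))
  on.exit(close(con))
  for (k in names(curve$meta))
    writeLines(sprintf("# %s: %s", k, format(curve$meta[[k]], digits = 15)),
               con)
  writeLines(sprintf("%.10g %.10g %.10g", curve$q, curve$intensity, curve$sigma),
             con)
  invisible(path)
}
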