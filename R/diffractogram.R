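#' One-dimensional diffractogram
#'
#' Container for a single background-subtractable 1D diffraction scan:
#' a strictly increasing scattering-vector grid \code{q} (\eqn{\AA^{-1}}),
#' intensities (arbitrary units), optional per-point uncertainties, and
#' condition metadata (temperature, relative humidity, D2O fraction,
#' wavelength, label).
#'
#' @param q strictly increasing numeric vector of scattering vectors
#'   (\eqn{\AA^{-1}}).
#' @param intensity numeric vector of intensities (a.u.), same length as
#'   \code{q}; slightly negative values are permitted (noise after
#'   background subtraction).
#' @param sigma optional numeric vector of strictly positive 1-sigma
#'   uncertainties (a.u.).  If \code{NULL}, downstream fits fall back to
#'   unweighted least squares.
#' @param meta named list of metadata.  Recognised keys:
#'   \code{temperature_C}, \code{relative_humidity}, \code{x_D2O},
#'   \code{wavelength_A}, \code{label}; extra keys are carried along.
#' @return An object of class \code{"diffractogram"}.
#' @export
diffractogram <- function(q, intensity, sigma = NULL, meta = list()) {
  q <- as.numeric(q); intensity <- as.numeric(intensity)
  if (length(q) < 2L) stop("a diffractogram needs at least 2 points")
  if (any(!is.finite(q)) || any(!is.finite(intensity)))
    stop("q and intensity must be finite")
  if (any(diff(q) <= 0)) {
    bad <- which(diff(q) <= 0)[1L] + 1L
    stop("q must be strictly increasing; first violation at point ", bad)
  }
  if (length(intensity) != length(q))
    stop("q and intensity lengths differ (", length(q), " vs ",
         length(intensity), ")")
  if (!is.null(sigma)) {
    sigma <- as.numeric(sigma)
    if (length(sigma) != length(q))
      stop("sigma length differs from q")
    if (any(!is.finite(sigma)) || any(sigma <= 0))
      stop("sigma must be strictly positive")
  }
  if (!is.null(meta$x_D2O)) {
    if (meta$x_D2O < 0 || meta$x_D2O > 1)
      stop("metadata x_D2O must lie in [0, 1]")
  }
  structure(list(q = q, intensity = intensity, sigma = sigma, meta = meta),
            class = "diffractogram")
}

#' @export
print.diffractogram <- function(x, ...) {
  cat("<diffractogram> ", length(x$q), " points, q in [",
      format(min(x$q), digits = 4), ", ", format(max(x$q), digits = 4),
      "] A^-1\n", sep = "")
  m <- x$meta
  keys <- c("label", "temperature_C", "relative_humidity", "x_D2O",
            "wavelength_A")
  shown <- m[intersect(keys, names(m))]
  if (length(shown))
    cat("  ", paste(names(shown), unlist(shown), sep = "=", collapse = "  "),
        "\n", sep = "")
  invisible(x)
}

#' @export
plot.diffractogram <- function(x, log = "y", ...) {
  y <- x$intensity
  if (grepl("y", log)) y <- pmax(y, max(y, na.rm = TRUE) * 1e-6)
  plot(x$q, y, type = "l", log = log,
       xlab = expression(q ~ (ring(A)^-1)), ylab = "intensity (a.u.)", ...)
  invisible(x)
}

# metadata keys the file dialect knows about, with their parsers
.meta_keys <- list(
  temperature_C     = as.numeric,
  relative_humidity = as.numeric,
  x_D2O             = as.numeric,
  wavelength_A      = as.numeric,
  seed              = as.numeric,
  label             = identity
)

#' Read a diffractogram from an ASCII column file
#'
#' The file dialect is plain text: \code{#}-prefixed header lines carrying
#' \code{key=value} metadata, followed by whitespace-separated numeric rows
#' of \code{q intensity [sigma]}.  This is the same dialect written by
#' \code{\link{write_diffractogram}}.
#'
#' If the sigma column is absent, uncertainties are synthesised as
#' \code{sqrt(max(intensity, 1))} (counting-statistics floor) with a warning.
#'
#' @param path path to the file.
#' @return A \code{\link{diffractogram}}.
#' @export
read_diffractogram <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  meta <- list()
  rows <- list()
  ncol_seen <- NA_integer_
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln)) next
    if (startsWith(ln, "#")) {
      body <- trimws(sub("^#+", "", ln))
      if (!nzchar(body)) next
      if (!grepl("=", body, fixed = TRUE))
        stop("line ", i, ": header comment is not key=value: '", ln, "'")
      key <- trimws(sub("=.*$", "", body))
      val <- trimws(sub("^[^=]*=", "", body))
      if (!key %in% names(.meta_keys))
        stop("line ", i, ": unknown metadata key '", key, "'")
      meta[[key]] <- .meta_keys[[key]](val)
      next
    }
    fields <- strsplit(ln, "[[:space:],]+")[[1]]
    vals <- suppressWarnings(as.numeric(fields))
    if (any(is.na(vals)))
      stop("line ", i, ": non-numeric data row: '", ln, "'")
    if (!length(vals) %in% c(2L, 3L))
      stop("line ", i, ": expected 2 or 3 columns, got ", length(vals))
    if (is.na(ncol_seen)) ncol_seen <- length(vals)
    if (length(vals) != ncol_seen)
      stop("line ", i, ": inconsistent column count")
    rows[[length(rows) + 1L]] <- c(vals, line = i)
  }
  if (!length(rows)) stop("no data rows in ", path)
  m <- do.call(rbind, rows)
  q <- m[, 1]; intensity <- m[, 2]
  if (any(diff(q) <= 0)) {
    bad <- which(diff(q) <= 0)[1L] + 1L
    stop("q not strictly increasing at file line ", m[bad, "line"])
  }
  sigma <- if (ncol_seen == 3L) m[, 3] else NULL
  if (is.null(sigma)) {
    warning("no sigma column in ", basename(path),
            "; using sqrt(max(intensity, 1))")
    sigma <- sqrt(pmax(intensity, 1))
  }
  diffractogram(q, intensity, sigma, meta)
}

#' Write a diffractogram to an ASCII column file
#'
#' Emits the dialect consumed by \code{\link{read_diffractogram}}:
#' \code{# key=value} header lines for the scalar metadata, then columns
#' \code{q intensity [sigma]}.
#'
#' @param d a \code{\link{diffractogram}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_diffractogram <- function(d, path) {
  stopifnot(inherits(d, "diffractogram"))
  con <- file(path, "w"); on.exit(close(con))
  for (key in intersect(names(.meta_keys), names(d$meta))) {
    val <- d$meta[[key]]
    if (is.null(val) || length(val) != 1L) next
    writeLines(sprintf("# %s=%s", key, format(val, digits = 15)), con)
  }
  if (is.null(d$sigma)) {
    writeLines(sprintf("%.10g %.10g", d$q, d$intensity), con)
  } else {
    writeLines(sprintf("%.10g %.10g %.10g", d$q, d$intensity, d$sigma), con)
  }
  invisible(path)
}

#' Convert scattering angle to scattering vector
#'
#' \eqn{q = 2\pi \sin(2\theta) / \lambda}, with \eqn{2\theta} the scattered
#' angle in degrees.  Provided for completeness; all package interfaces use
#' q in \eqn{\AA^{-1}} directly.
#'
#' @param two_theta_deg scattered angle \eqn{2\theta} in degrees.
#' @param wavelength_A incident wavelength in \eqn{\AA} (4.55 for a typical
#'   cold-neutron membrane diffractometer setting).
#' @return q in \eqn{\AA^{-1}}.
#' @export
two_theta_to_q <- function(two_theta_deg, wavelength_A = 4.55) {
  if (any(wavelength_A <= 0)) stop("wavelength must be positive")
  2 * pi * sin(two_theta_deg * pi / 180) / wavelength_A
}
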