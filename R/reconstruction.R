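#' Fourier synthesis of the NSLD profile
#'
#' Evaluates the truncated cosine series
#' \deqn{\rho(z) = \frac{2}{D} \sum_{n=1}^{M} f_n \nu_n
#'   \cos\!\left(\frac{2\pi n z}{D}\right)}
#' on a symmetric grid over one unit cell \eqn{[-D/2, D/2]}.  The zeroth
#' order (mean) is not measured, so the profile is relative: mean zero over
#' the cell, arbitrary overall scale (a.u.).
#'
#' @param sf a \code{"sf_table"} at a single contrast.
#' @param phases a \code{"phase_assignment"} covering every order present
#'   in \code{sf}, or a bare sign vector (values in \code{\{-1, +1\}},
#'   one per order of \code{sf}, in increasing order).
#' @param grid_step grid spacing in \eqn{\AA} (default 0.1).
#' @return An \code{"nsld_profile"}: list with \code{z}, \code{rho},
#'   \code{D}, \code{M}, \code{nu}, \code{x_D2O}.
#' @export
reconstruct_nsld <- function(sf, phases, grid_step = 0.1) {
  stopifnot(inherits(sf, "sf_table"))
  if (grid_step <= 0) stop("grid_step must be positive")
  if (length(unique(sf$x_D2O)) != 1L)
    stop("sf must contain a single contrast; use combine_sf/subset first")
  D <- attr(sf, "D")
  sf <- sf[order(sf$order), ]
  orders <- sf$order
  if (inherits(phases, "phase_assignment")) {
    missing <- setdiff(orders, phases$orders)
    if (length(missing))
      stop("no phase assigned for order(s) ", paste(missing, collapse = ", "))
    nu <- phases$nu[match(orders, phases$orders)]
  } else {
    nu <- as.integer(phases)
    if (length(nu) != length(orders) || any(abs(nu) != 1L))
      stop("phases must be a vector of +1/-1, one per order")
  }
  half <- ceiling((D / 2) / grid_step)
  z <- seq(-half, half) * (D / 2) / half
  rho <- rep(0, length(z))
  for (i in seq_along(orders))
    rho <- rho + (2 / D) * sf$amplitude[i] * nu[i] *
      cos(2 * pi * orders[i] * z / D)
  structure(list(z = z, rho = rho, D = D, M = max(orders),
                 nu = setNames(nu, paste0("n", orders)), orders = orders,
                 amplitudes = sf$amplitude, x_D2O = sf$x_D2O[1]),
            class = "nsld_profile")
}

#' @export
print.nsld_profile <- function(x, ...) {
  cat("<nsld_profile> D =", format(x$D, digits = 5), "A, orders",
      paste(x$orders, collapse = ","), " x_D2O =", x$x_D2O, "\n")
  cat("  signs:", paste(ifelse(x$nu > 0, "+", "-"), collapse = " "), "\n")
  invisible(x)
}

#' @export
plot.nsld_profile <- function(x, ...) {
  plot(x$z, x$rho, type = "l", xlab = expression(z ~ (ring(A))),
       ylab = "relative NSLD (a.u.)", ...)
  abline(h = 0, lty = 3)
  invisible(x)
}

#' Write / read an NSLD profile as 2-column ASCII
#'
#' Columns z (\eqn{\AA}) and relative density (a.u.), with \code{#}
#' metadata header lines.
#'
#' @param profile an \code{"nsld_profile"}.
#' @param path file path.
#' @return \code{write_nsld_profile}: \code{path} invisibly;
#'   \code{read_nsld_profile}: an \code{"nsld_profile"}.
#' @export
write_nsld_profile <- function(profile, path) {
  stopifnot(inherits(profile, "nsld_profile"))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(sprintf("# D=%.10g", profile$D),
               sprintf("# x_D2O=%.10g", profile$x_D2O),
               sprintf("# orders=%s", paste(profile$orders, collapse = ",")),
               sprintf("# nu=%s", paste(profile$nu, collapse = ","))), con)
  writeLines(sprintf("%.10g %.10g", profile$z, profile$rho), con)
  invisible(path)
}

#' @rdname write_nsld_profile
#' @export
read_nsld_profile <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^#", lines, value = TRUE)
  getv <- function(key) {
    ln <- grep(paste0("^#\\s*", key, "="), hdr, value = TRUE)
    if (!length(ln)) return(NULL)
    sub(paste0("^#\\s*", key, "="), "", ln[1])
  }
  dat <- do.call(rbind, lapply(strsplit(trimws(grep("^[^#]", lines,
                                                    value = TRUE)), "\\s+"),
                               as.numeric))
  orders <- as.integer(strsplit(getv("orders"), ",")[[1]])
  nu <- as.integer(strsplit(getv("nu"), ",")[[1]])
  structure(list(z = dat[, 1], rho = dat[, 2], D = as.numeric(getv("D")),
                 M = max(orders), nu = setNames(nu, paste0("n", orders)),
                 orders = orders, amplitudes = NULL,
                 x_D2O = as.numeric(getv("x_D2O"))),
            class = "nsld_profile")
}

#' Truncation error of the M-order Fourier reconstruction
#'
#' L2 distance, over one unit cell, between the centred model profile and
#' its M-order Fourier partial sum:
#' \eqn{\|(\rho - \bar\rho) - S_M\|_{L^2}}.  Quantifies the resolution
#' limit imposed by the number of observable Bragg orders (four, for a
#' weakly ordered bilayer stack).  \code{M = 0} (empty sum) returns the L2
#' norm of the centred profile itself.  By orthogonality of the cosine
#' basis the error is non-increasing in M.
#'
#' @param model a \code{\link{bilayer_model}}.
#' @param M number of orders retained (>= 0).
#' @param n_grid quadrature grid size.
#' @return L2 error (a.u.).
#' @export
truncation_error <- function(model, M, n_grid = 4096) {
  stopifnot(inherits(model, "bilayer_model"))
  M <- as.integer(M)
  if (M < 0) stop("M must be >= 0")
  D <- model$D
  z <- seq(-D / 2, D / 2, length.out = n_grid + 1L)
  rho <- model_profile(model, z)
  rho_c <- rho - .trapz(z, rho) / D
  sM <- rep(0, length(z))
  if (M >= 1) {
    f <- model_form_factors(model, M)
    for (n in seq_len(M))
      sM <- sM + (2 / D) * f[n] * cos(2 * pi * n * z / D)
  }
  sqrt(.trapz(z, (rho_c - sM)^2))
}
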