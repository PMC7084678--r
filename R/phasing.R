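#' Lorentz-correct integrated intensities to structure-factor amplitudes
#'
#' For oriented multilayers the integrated intensity of the n-th Bragg
#' peak and the structure-factor amplitude are related through a power of
#' the peak position: \eqn{|f_n| = \sqrt{I_n q_n^{p}}}.  The default
#' exponent \code{p = 1} is the standard correction for oriented samples;
#' \code{p = 0} disables the correction and \code{p = -1} gives the
#' alternative convention \eqn{|f_n| = \sqrt{I_n / q_n}}.
#'
#' Standard errors are propagated as
#' \eqn{SE(|f_n|) = q_n^{p} SE(I_n) / (2 |f_n|)}.  Negative integrated
#' intensities (possible after background subtraction) give amplitude 0
#' with a flag.
#'
#' @param peaks a \code{"peak_set"} indexed on a single lamellar lattice
#'   (the \code{order} column must be filled in), or a
#'   \code{"lattice_assignment"} of class lamellar.
#' @param p Lorentz exponent (default 1).
#' @param x_D2O D2O fraction of the scan; taken from the peak set's
#'   metadata when omitted.
#' @param D lamellar repeat (\eqn{\AA}); taken from the assignment when a
#'   \code{"lattice_assignment"} is supplied.
#' @return A \code{"sf_table"} data frame with columns \code{order},
#'   \code{x_D2O}, \code{amplitude}, \code{se}, \code{flagged}; attributes
#'   \code{p} and \code{D}.
#' @export
lorentz_correct <- function(peaks, p = 1, x_D2O = NULL, D = NULL) {
  if (inherits(peaks, "lattice_assignment")) {
    if (peaks$phase_class != "lamellar")
      stop("Lorentz correction requires a single lamellar lattice (got ",
           peaks$phase_class, ")")
    if (is.null(D)) D <- peaks$lattices[[1]]$D
    peaks <- peaks$peaks
  }
  stopifnot(inherits(peaks, "peak_set"))
  if (anyNA(peaks$order))
    stop("peaks must be indexed before Lorentz correction")
  if (any(peaks$lattice_id != 1L, na.rm = TRUE))
    stop("all peaks must belong to one lattice")
  if (is.null(x_D2O)) x_D2O <- attr(peaks, "x_D2O")
  if (is.null(x_D2O)) stop("x_D2O unknown: pass it explicitly")
  qn <- peaks$center
  I <- peaks$intensity
  I_se <- peaks$intensity_se
  flagged <- I < 0
  amp <- sqrt(pmax(I, 0) * qn^p)
  se <- ifelse(amp > 0, qn^p * I_se / (2 * amp), NA_real_)
  out <- data.frame(order = peaks$order, x_D2O = x_D2O, amplitude = amp,
                    se = se, flagged = flagged)
  out <- out[order(out$order), ]
  rownames(out) <- NULL
  if (anyDuplicated(out$order))
    stop("duplicated order in one scan")
  structure(out, class = c("sf_table", "data.frame"), p = p,
            D = if (is.null(D)) 2 * pi * mean(out$order / qn[order(peaks$order)]) else D)
}

#' Combine structure-factor tables from several contrasts
#'
#' @param ... \code{"sf_table"} objects sharing one lattice and one
#'   Lorentz exponent.
#' @param rel_tol relative tolerance on the repeat distances of the
#'   combined tables.
#' @return A single \code{"sf_table"} with one row per (order, x_D2O).
#' @export
combine_sf <- function(..., rel_tol = 0.02) {
  tabs <- list(...)
  if (length(tabs) == 1L && is.list(tabs[[1]]) &&
      !inherits(tabs[[1]], "sf_table")) tabs <- tabs[[1]]
  stopifnot(all(vapply(tabs, inherits, TRUE, "sf_table")))
  ps <- vapply(tabs, attr, 0, "p")
  if (length(unique(ps)) != 1L) stop("mixed Lorentz exponents")
  Ds <- vapply(tabs, attr, 0, "D")
  if (diff(range(Ds)) / mean(Ds) > rel_tol)
    stop("tables come from incompatible lattices: D = ",
         paste(round(Ds, 2), collapse = ", "))
  out <- do.call(rbind, lapply(tabs, as.data.frame))
  if (anyDuplicated(out[, c("order", "x_D2O")]))
    stop("duplicated (order, x_D2O) pair")
  out <- out[order(out$order, out$x_D2O), ]
  rownames(out) <- NULL
  structure(out, class = c("sf_table", "data.frame"), p = ps[1],
            D = stats::weighted.mean(Ds))
}

# weighted least squares y ~ a + b x; returns fit and weighted R^2
.wls_line <- function(x, y, w) {
  W <- sum(w); xb <- sum(w * x) / W; yb <- sum(w * y) / W
  sxx <- sum(w * (x - xb)^2); sxy <- sum(w * (x - xb) * (y - yb))
  b <- sxy / sxx; a <- yb - b * xb
  ss_res <- sum(w * (y - a - b * x)^2)
  ss_tot <- sum(w * (y - yb)^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  list(intercept = a, slope = b, r2 = max(min(r2, 1), 0))
}

# magnitude template of the water-slab cosine transform:
# |T_n(c, s)| = |2 sin(k_n c) / k_n| exp(-k_n^2 s^2 / 2)
# and its sign, -sign(sin(k_n c)): adding D2O raises the SLD of the water
# region (everything beyond the lipid/water boundary at |z| = c), so the
# slope of the signed f_n against x_D2O must carry these signs.
.water_template <- function(orders, D, c_frac, s_w) {
  k <- 2 * pi * orders / D
  t <- -2 * sin(k * c_frac * D) / k * exp(-k^2 * s_w^2 / 2)
  t
}

#' Determine structure-factor signs from a D2O contrast series
#'
#' For a centrosymmetric unit cell each structure factor is real and the
#' signed \eqn{f_n} is an affine function of the D2O fraction.  Per order,
#' all \eqn{2^{c-1}} sign patterns over the c contrasts (first contrast
#' fixed +) are enumerated; a weighted least-squares line of the signed
#' amplitudes against \code{x_D2O} is fitted for each pattern and the
#' pattern with maximal weighted \eqn{R^2} is kept.  Orders whose best and
#' second-best \eqn{R^2} differ by less than \code{delta_r2} are flagged
#' ambiguous (they still receive the best-\eqn{R^2} sign).
#'
#' Linearity fixes each order's sign sequence only up to an overall flip of
#' that order's line, so the orders are tied together physically: the slope
#' of the signed \eqn{f_n} versus \code{x_D2O} is the n-th cosine transform
#' of the water distribution, whose sign pattern is
#' \eqn{-\mathrm{sign}(\sin(2\pi n c / D))} for a water slab beyond the
#' lipid/water boundary at \eqn{|z| = c}.  The boundary position (and an
#' effective smoothing width) is estimated by matching the fitted slope
#' magnitudes to the template \eqn{|2\sin(k_n c)/k_n| e^{-k_n^2 s^2/2}},
#' and each order's line is flipped so its slope sign agrees with the
#' template.  Finally the global sign of the whole vector is fixed by the
#' convention that the reconstructed profile at the reference contrast has
#' its minimum at z = 0 (the terminal-methyl trough).
#'
#' @param sf a combined \code{"sf_table"} covering at least two distinct
#'   D2O fractions.
#' @param reference_fraction the contrast whose signed values feed the
#'   reconstruction (default 0.08); must be one of the measured fractions.
#' @param delta_r2 ambiguity threshold on the \eqn{R^2} gap (default 0.01).
#' @return A \code{"phase_assignment"}: list with \code{nu} (named vector
#'   of signs, one per order), \code{fits} (per-order data frame with
#'   slope, intercept, r2, r2_gap, ambiguous), \code{reference_fraction},
#'   \code{boundary_c} (estimated lipid/water boundary, \eqn{\AA}), and
#'   \code{D}.
#' @export
assign_phases <- function(sf, reference_fraction = 0.08, delta_r2 = 0.01) {
  stopifnot(inherits(sf, "sf_table"))
  fr <- sort(unique(sf$x_D2O))
  if (length(fr) < 2L)
    stop("phases undeterminable from one contrast")
  D <- attr(sf, "D")
  if (!any(abs(fr - reference_fraction) < 1e-9)) {
    reference_fraction <- fr[which.min(abs(fr - reference_fraction))]
    warning("reference fraction not measured; using nearest (",
            reference_fraction, ")")
  }
  orders <- sort(unique(sf$order))

  per_order <- lapply(orders, function(n) {
    rows <- sf[sf$order == n, ]
    rows <- rows[order(rows$x_D2O), ]
    amp <- rows$amplitude
    w <- if (all(is.finite(rows$se)) && all(rows$se > 0, na.rm = TRUE))
      1 / rows$se^2 else rep(1, nrow(rows))
    w[!is.finite(w)] <- min(w[is.finite(w)], 1)
    c_n <- nrow(rows)
    if (c_n < 2L) return(NULL)
    signs_mat <- as.matrix(expand.grid(
      rep(list(c(1, -1)), c_n - 1L)))[, rev(seq_len(c_n - 1L)), drop = FALSE]
    r2s <- numeric(nrow(signs_mat)); fits <- vector("list", nrow(signs_mat))
    for (i in seq_len(nrow(signs_mat))) {
      s <- c(1, signs_mat[i, ])
      fits[[i]] <- .wls_line(rows$x_D2O, s * amp, w)
      r2s[i] <- fits[[i]]$r2
    }
    ord <- order(-r2s)
    best <- ord[1]
    gap <- if (length(r2s) > 1) r2s[best] - r2s[ord[2]] else 1
    list(order = n, x = rows$x_D2O, amp = amp, w = w,
         pattern = c(1, signs_mat[best, ]), fit = fits[[best]],
         r2 = r2s[best], r2_gap = gap, ambiguous = gap < delta_r2)
  })
  per_order <- Filter(Negate(is.null), per_order)
  if (!length(per_order)) stop("no order has two or more contrasts")
  orders <- vapply(per_order, `[[`, 0, "order")

  # inter-order linkage: match |slope| pattern to the water-slab template
  slopes <- vapply(per_order, function(p) p$fit$slope, 0)
  mag <- abs(slopes)
  # |T_n| is invariant under c -> D/2 - c while the even-order signs are
  # not; the mirror solution would put more water than lipid in the cell.
  # Restricting the boundary to c >= D/4 (bilayer fills at least half the
  # repeat, true for any lamellar stack this analysis applies to) removes
  # the degeneracy.
  cf_lo <- 0.25; cf_hi <- 0.49
  best <- list(score = -Inf, c_frac = NA, s_w = NA)
  if (sum(mag) > 0) {
    u <- mag / sqrt(sum(mag^2))
    score_fun <- function(cf, s_w) {
      t <- abs(.water_template(orders, D, cf, s_w))
      nt <- sqrt(sum(t^2))
      if (nt == 0) return(-Inf)
      sum(u * t) / nt
    }
    # the template's sign pattern is piecewise constant in c with |sin|
    # cusps at c/D = j/(2n); optimise the (smooth) magnitude match inside
    # each inter-cusp interval separately so a cusp cannot trap the search
    bnd <- sort(unique(unlist(lapply(orders, function(n)
      (1:(2 * n)) / (2 * n)))))
    bnd <- c(cf_lo, bnd[bnd > cf_lo & bnd < cf_hi], cf_hi)
    for (i in seq_len(length(bnd) - 1L)) {
      lo <- bnd[i] + 1e-9; hi <- bnd[i + 1] - 1e-9
      for (s0 in c(0.5, 2, 4)) {
        for (cq in c(0.02, 0.25, 0.5, 0.75, 0.98)) {
          opt <- stats::optim(c(lo + cq * (hi - lo), s0),
                              function(p) -score_fun(p[1], p[2]),
                              method = "L-BFGS-B",
                              lower = c(lo, 0), upper = c(hi, 6),
                              control = list(factr = 1e4))
          if (-opt$value > best$score + 1e-12)
            best <- list(score = -opt$value, c_frac = opt$par[1],
                         s_w = opt$par[2])
        }
      }
    }
  } else best <- list(score = NA, c_frac = 0.37, s_w = 3)
  templ <- .water_template(orders, D, best$c_frac, best$s_w)

  nu <- integer(length(per_order))
  fit_rows <- vector("list", length(per_order))
  for (i in seq_along(per_order)) {
    p <- per_order[[i]]
    flip <- if (abs(p$fit$slope) > 0 && templ[i] != 0 &&
                sign(p$fit$slope) != sign(templ[i])) -1 else 1
    a <- flip * p$fit$intercept; b <- flip * p$fit$slope
    yref <- a + b * reference_fraction
    nu[i] <- if (yref >= 0) 1L else -1L
    fit_rows[[i]] <- data.frame(order = p$order, slope = b, intercept = a,
                                r2 = p$r2, r2_gap = p$r2_gap,
                                ambiguous = p$ambiguous,
                                amp_ref = abs(yref))
  }
  fits <- do.call(rbind, fit_rows)

  # global sign convention: minimum of the reconstructed reference-contrast
  # profile at the bilayer centre (methyl trough)
  ref_amp <- vapply(per_order, function(p) {
    i <- which(abs(p$x - reference_fraction) < 1e-9)
    if (length(i)) p$amp[i[1]] else NA_real_
  }, 0)
  use <- is.finite(ref_amp)
  if (any(use)) {
    zz <- seq(-D / 2, D / 2, length.out = 501)
    prof <- function(s) {
      r <- 0
      for (i in which(use))
        r <- r + s * nu[i] * ref_amp[i] * cos(2 * pi * orders[i] * zz / D)
      r
    }
    gap_plus <- prof(1)[251] - min(prof(1))
    gap_minus <- prof(-1)[251] - min(prof(-1))
    if (gap_minus < gap_plus - 1e-12) nu <- -nu
  }

  structure(list(nu = setNames(nu, paste0("n", orders)), orders = orders,
                 fits = fits, reference_fraction = reference_fraction,
                 boundary_c = best$c_frac * D, template_score = best$score,
                 D = D),
            class = "phase_assignment")
}

#' @export
print.phase_assignment <- function(x, ...) {
  cat("<phase_assignment> orders", paste(x$orders, collapse = ", "),
      " reference x_D2O =", x$reference_fraction, "\n")
  sgn <- ifelse(x$nu > 0, "+", "-")
  flag <- ifelse(x$fits$ambiguous, " (ambiguous)", "")
  for (i in seq_along(x$orders))
    cat(sprintf("  order %d: %s  R2 = %.4f%s\n", x$orders[i], sgn[i],
                x$fits$r2[i], flag[i]))
  cat(sprintf("  water boundary estimate: %.1f A\n", x$boundary_c))
  invisible(x)
}
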