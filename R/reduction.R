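#' Subtract a smooth baseline from a diffractogram
#'
#' Fits a polynomial baseline (constant, linear, or degree-k) to the
#' non-excluded points of the scan and subtracts it everywhere.  Exclusion
#' windows should cover the Bragg peaks so the baseline is estimated from
#' peak-free regions only.  Post-subtraction intensities may be slightly
#' negative where the data scatter below the baseline; they are deliberately
#' not clipped, to avoid biasing integrated peak intensities.
#'
#' @param d a \code{\link{diffractogram}}.
#' @param method one of \code{"constant"}, \code{"linear"},
#'   \code{"polynomial"}.
#' @param degree polynomial degree when \code{method = "polynomial"}.
#' @param exclude list of 2-vectors \code{c(qlo, qhi)} (or a 2-column
#'   matrix) of q windows excluded from the baseline fit.
#' @return A \code{\link{diffractogram}} with baseline removed; the fit
#'   method and coefficients are logged in
#'   \code{meta$background_fit}.
#' @export
subtract_background <- function(d, method = c("constant", "linear",
                                              "polynomial"),
                                degree = 2, exclude = list()) {
  stopifnot(inherits(d, "diffractogram"))
  method <- match.arg(method)
  deg <- switch(method, constant = 0L, linear = 1L,
                polynomial = as.integer(degree))
  if (is.matrix(exclude)) exclude <- asplit(exclude, 1)
  keep <- rep(TRUE, length(d$q))
  for (w in exclude) {
    if (length(w) != 2L) stop("each exclusion window must be c(qlo, qhi)")
    if (w[1] > max(d$q) || w[2] < min(d$q))
      stop("exclusion window [", w[1], ", ", w[2], "] outside the q range")
    keep <- keep & !(d$q >= w[1] & d$q <= w[2])
  }
  if (!any(keep)) stop("all points excluded; cannot fit a baseline")
  X <- outer(d$q, 0:deg, `^`)
  w <- if (!is.null(d$sigma)) 1 / d$sigma^2 else rep(1, length(d$q))
  fit <- lm.wfit(X[keep, , drop = FALSE], d$intensity[keep], w[keep])
  coefs <- fit$coefficients
  coefs[is.na(coefs)] <- 0
  baseline <- drop(X %*% coefs)
  out <- d
  out$intensity <- d$intensity - baseline
  out$meta$background_fit <- list(method = method, degree = deg,
                                  coefficients = unname(coefs))
  out
}

#' Fit Bragg peaks in a diffractogram
#'
#' Detects candidate peaks (local maxima with prominence above a
#' noise-based threshold, via \code{pracma::findpeaks}) or takes
#' user-supplied position guesses, then fits each group of overlapping
#' peaks (centres within 3 widths of each other) with a sum of Gaussians
#' plus a local linear baseline by weighted Levenberg--Marquardt least
#' squares.  The integrated intensity of a peak is
#' \eqn{A \sigma \sqrt{2\pi}}, with its standard error propagated from the
#' fit covariance (including the A--sigma covariance).
#'
#' Peaks whose fit fails to converge are excluded with a warning, never
#' silently dropped.
#'
#' @param d a \code{\link{diffractogram}} (ideally background-subtracted).
#' @param guesses optional numeric vector of approximate peak positions
#'   (\eqn{\AA^{-1}}); when given, detection is skipped.
#' @param prominence detection threshold in units of the noise level
#'   (default 5).
#' @return A \code{"peak_set"}: a data frame with columns \code{center},
#'   \code{center_se}, \code{width}, \code{width_se}, \code{intensity},
#'   \code{intensity_se}, \code{order}, \code{lattice_id}.
#' @export
fit_peaks <- function(d, guesses = NULL, prominence = 5) {
  stopifnot(inherits(d, "diffractogram"))
  q <- d$q; y <- d$intensity
  dq <- median(diff(q))
  noise <- if (!is.null(d$sigma)) median(d$sigma) else
    mad(diff(y)) / sqrt(2)
  if (is.null(guesses)) {
    minh <- median(y) + prominence * noise
    mind <- max(3L, round(0.008 / dq))
    pk <- pracma::findpeaks(y, minpeakheight = minh,
                            minpeakdistance = mind, sortstr = TRUE)
    if (is.null(pk))
      stop("no peak above the prominence threshold; supply guesses")
    # greedy dedup (tallest first): one candidate per resolvable maximum
    keep_idx <- integer(0)
    for (i in pk[, 2]) {
      if (!length(keep_idx) || all(abs(keep_idx - i) >= mind))
        keep_idx <- c(keep_idx, i)
    }
    # topographic prominence: a bump on the flank of a taller peak is not a
    # peak; require prominence above the local noise level
    prom_of <- function(i) {
      lmin <- Inf; j <- i
      while (j > 1 && y[j] <= y[i]) { j <- j - 1; lmin <- min(lmin, y[j]) }
      if (y[j] <= y[i]) lmin <- min(y[seq_len(i)])
      rmin <- Inf; j <- i
      while (j < length(y) && y[j] <= y[i]) { j <- j + 1
        rmin <- min(rmin, y[j]) }
      if (y[j] <= y[i]) rmin <- min(y[i:length(y)])
      y[i] - max(lmin, rmin)
    }
    loc_noise <- if (!is.null(d$sigma)) d$sigma[keep_idx]
                 else rep(noise, length(keep_idx))
    keep_idx <- keep_idx[vapply(keep_idx, prom_of, 0) >
                           prominence * loc_noise]
    if (!length(keep_idx))
      stop("no peak above the prominence threshold; supply guesses")
    centers <- sort(q[keep_idx])
  } else {
    centers <- sort(as.numeric(guesses))
    if (any(centers < min(q) | centers > max(q)))
      stop("guesses outside the q range")
  }
  # initial width from half-maximum crossings; the walk is confined to the
  # midpoints towards neighbouring candidates so that partially resolved
  # doublets (valley above half maximum) do not inflate the estimate
  widths <- vapply(seq_along(centers), function(j) {
    c0 <- centers[j]
    i0 <- which.min(abs(q - c0))
    lo_q <- if (j > 1) (centers[j - 1] + c0) / 2 else min(q)
    hi_q <- if (j < length(centers)) (centers[j + 1] + c0) / 2 else max(q)
    base <- median(y)
    half <- base + (y[i0] - base) / 2
    iL <- i0; while (iL > 1 && y[iL] > half && q[iL] > lo_q) iL <- iL - 1
    iR <- i0; while (iR < length(y) && y[iR] > half && q[iR] < hi_q)
      iR <- iR + 1
    max((q[iR] - q[iL]) / 2.355, 2 * dq)
  }, 0)

  # co-fit peaks closer than three widths of each other
  grp <- integer(length(centers)); g <- 1L; grp[1] <- 1L
  if (length(centers) > 1) for (i in 2:length(centers)) {
    if (centers[i] - centers[i - 1] < 3 * (widths[i] + widths[i - 1]))
      grp[i] <- g else { g <- g + 1L; grp[i] <- g }
  }

  rows <- list()
  for (gi in unique(grp)) {
    idx <- which(grp == gi)
    lo <- min(centers[idx]) - 6 * max(widths[idx])
    hi <- max(centers[idx]) + 6 * max(widths[idx])
    # never let the window reach into a neighbouring group
    prev <- centers[grp < gi]
    nxt <- centers[grp > gi]
    if (length(prev)) lo <- max(lo, (max(prev) + min(centers[idx])) / 2)
    if (length(nxt)) hi <- min(hi, (min(nxt) + max(centers[idx])) / 2)
    sel <- q >= lo & q <= hi
    if (sum(sel) < 5 + 3 * length(idx)) {
      warning("too few points around peak near q=", round(centers[idx][1], 4),
              "; peak excluded")
      next
    }
    qs <- q[sel]; ys <- y[sel]
    ws <- if (!is.null(d$sigma)) 1 / d$sigma[sel]^2 else rep(1, sum(sel))
    np <- length(idx)
    start <- c(b0 = min(ys), b1 = 0)
    lower <- c(-Inf, -Inf); upper <- c(Inf, Inf)
    form <- "ys ~ b0 + b1 * (qs - mean(qs))"
    for (j in seq_len(np)) {
      start[[paste0("A", j)]] <- max(ys[which.min(abs(qs - centers[idx[j]]))] -
                                       min(ys), noise)
      start[[paste0("mu", j)]] <- centers[idx[j]]
      start[[paste0("s", j)]] <- widths[idx[j]]
      lower <- c(lower, 0, lo, dq / 2)
      upper <- c(upper, Inf, hi, (hi - lo))
      form <- paste0(form, sprintf(
        " + A%d * exp(-(qs - mu%d)^2 / (2 * s%d^2))", j, j, j))
    }
    fit <- tryCatch(
      minpack.lm::nlsLM(stats::as.formula(form),
                        data = list(qs = qs, ys = ys),
                        start = start, weights = ws,
                        lower = lower, upper = upper,
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) e)
    if (inherits(fit, "error")) {
      warning("peak fit near q=", round(centers[idx][1], 4),
              " did not converge (", conditionMessage(fit),
              "); peak excluded")
      next
    }
    cf <- coef(fit); V <- vcov(fit)
    for (j in seq_len(np)) {
      A <- cf[[paste0("A", j)]]; mu <- cf[[paste0("mu", j)]]
      s <- cf[[paste0("s", j)]]
      nm <- paste0(c("A", "mu", "s"), j)
      Vj <- V[nm, nm]
      I <- A * s * sqrt(2 * pi)
      # delta method on I = A * s * sqrt(2*pi)
      gr <- c(s, 0, A) * sqrt(2 * pi)
      I_se <- sqrt(max(drop(t(gr) %*% Vj %*% gr), 0))
      rows[[length(rows) + 1L]] <- data.frame(
        center = mu, center_se = sqrt(Vj[2, 2]),
        width = s, width_se = sqrt(Vj[3, 3]),
        intensity = I, intensity_se = I_se)
    }
  }
  if (!length(rows)) stop("no peak could be fitted")
  out <- do.call(rbind, rows)
  out <- out[order(out$center), ]
  rownames(out) <- NULL
  out$order <- NA_integer_
  out$lattice_id <- NA_integer_
  structure(out, class = c("peak_set", "data.frame"),
            q_range = range(d$q), x_D2O = d$meta$x_D2O)
}

# weighted least-squares line through the origin of q vs order:
# q_n = slope * n;  D = 2*pi/slope
.lamellar_wls <- function(qv, se, orders) {
  w <- if (all(is.finite(se)) && all(se > 0)) 1 / se^2 else rep(1, length(qv))
  slope <- sum(w * orders * qv) / sum(w * orders^2)
  se_slope <- sqrt(1 / sum(w * orders^2))
  D <- 2 * pi / slope
  list(D = D, D_se = 2 * pi * se_slope / slope^2, slope = slope,
       residuals = abs(qv - orders * slope) / qv)
}

.gcd <- function(v) Reduce(function(a, b) if (b == 0) a else Recall(b, a %% b), v)

# candidate order assignment for a single lamellar lattice:
# try the first peak as order n1 = 1..4, round the rest; order sets are
# reduced by their gcd so (2,4,6,8) collapses to (1,2,3,4)
.try_lamellar <- function(qv, se, tolerance) {
  best <- NULL
  for (n1 in 1:4) {
    slope0 <- qv[1] / n1
    orders <- pmax(1L, as.integer(round(qv / slope0)))
    if (anyDuplicated(orders)) next
    fit <- .lamellar_wls(qv, se, orders)
    orders2 <- pmax(1L, as.integer(round(qv / fit$slope)))
    if (anyDuplicated(orders2)) orders2 <- orders
    orders2 <- orders2 %/% .gcd(orders2)
    fit <- .lamellar_wls(qv, se, orders2)
    if (max(fit$residuals) > tolerance) next
    score <- max(fit$residuals)
    if (is.null(best) || score < best$score * 0.9)
      best <- c(fit, list(orders = orders2, score = score))
  }
  best
}

.hex_ratios <- sqrt(c(1, 3, 4, 7, 9, 12, 13, 16, 19, 21))

.try_hexagonal <- function(qv, se, tolerance) {
  r <- qv / qv[1]
  idx <- vapply(r, function(x) which.min(abs(.hex_ratios - x)), 0L)
  resid <- abs(r - .hex_ratios[idx]) / r
  if (anyDuplicated(idx) || max(resid) > tolerance) return(NULL)
  # require a genuinely hexagonal signature (a sqrt(3) or sqrt(7) spot);
  # an all-integer-ratio series is indistinguishable from lamellar and
  # is claimed by the lamellar hypothesis first anyway
  if (!any(idx %in% c(2L, 4L)) && length(qv) > 1) return(NULL)
  w <- if (all(is.finite(se)) && all(se > 0)) 1 / se^2 else rep(1, length(qv))
  m <- .hex_ratios[idx]
  q1 <- sum(w * m * qv) / sum(w * m^2)
  q1_se <- sqrt(1 / sum(w * m^2))
  list(q1 = q1, d10 = 2 * pi / q1, d10_se = 2 * pi * q1_se / q1^2,
       index = idx, residuals = resid)
}

# greedy two-lattice decomposition: candidate repeat distances from every
# (peak, order) pair; the candidate explaining most peaks seeds lattice 1
.try_coexistence <- function(qv, se, tolerance) {
  cand <- unique(as.vector(outer(1:4, qv, function(n, q) 2 * pi * n / q)))
  score_cand <- function(D) {
    qn_pred <- 2 * pi * seq_len(12) / D
    ok <- vapply(qv, function(qi)
      min(abs(qi - qn_pred) / qi) <= tolerance, TRUE)
    resid <- vapply(qv, function(qi) min(abs(qi - qn_pred) / qi), 0)
    list(ok = ok, mean_resid = mean(resid[ok]))
  }
  pick_best <- function(mask) {
    best <- NULL
    for (D in cand) {
      sc <- score_cand(D)
      sc$ok <- sc$ok & mask
      n_ok <- sum(sc$ok)
      if (n_ok < 2) next
      if (is.null(best) || n_ok > best$n_ok ||
          (n_ok == best$n_ok && sc$mean_resid < best$mean_resid - 1e-12))
        best <- list(D0 = D, ok = sc$ok, n_ok = n_ok,
                     mean_resid = sc$mean_resid)
    }
    best
  }
  b1 <- pick_best(rep(TRUE, length(qv)))
  if (is.null(b1)) return(NULL)
  orders1 <- as.integer(round(qv[b1$ok] * b1$D0 / (2 * pi)))
  orders1 <- orders1 %/% .gcd(orders1)
  fit1 <- .lamellar_wls(qv[b1$ok], se[b1$ok], orders1)
  rest <- !b1$ok
  if (sum(rest) < 2) return(NULL)
  b2 <- pick_best(rest)
  if (is.null(b2) || !all(b2$ok == rest)) return(NULL)
  orders2 <- as.integer(round(qv[b2$ok] * b2$D0 / (2 * pi)))
  orders2 <- orders2 %/% .gcd(orders2)
  fit2 <- .lamellar_wls(qv[b2$ok], se[b2$ok], orders2)
  if (max(fit1$residuals) > tolerance || max(fit2$residuals) > tolerance)
    return(NULL)
  # report the larger-D lattice first (lower-q series)
  lat <- list(list(fit = fit1, ok = b1$ok, orders = orders1),
              list(fit = fit2, ok = b2$ok, orders = orders2))
  lat[order(vapply(lat, function(l) -l$fit$D, 0))]
}

#' Index fitted Bragg peaks onto candidate lattices
#'
#' Tests three hypotheses, in order of parsimony: a single lamellar lattice
#' (positions \eqn{q_n = 2\pi n / D}, D from a weighted least-squares line
#' through the origin of q versus order), a 2D hexagonal lattice (positions
#' proportional to \eqn{\{1, \sqrt3, \sqrt4, \sqrt7, \dots\}}), and two
#' coexisting lamellar lattices (two interleaved series, each with at least
#' two orders).  The first hypothesis that explains every peak within the
#' relative tolerance wins; otherwise the peaks are \code{"unindexed"}.
#'
#' A single detected peak is indexed as a first-order lamellar reflection
#' and flagged low-confidence.
#'
#' @param peaks a \code{"peak_set"} from \code{\link{fit_peaks}}.
#' @param tolerance relative tolerance on peak positions (default 0.01).
#' @return A \code{"lattice_assignment"}: list with \code{phase_class}
#'   (\code{"lamellar"}, \code{"hexagonal"}, \code{"coexisting_lamellar"},
#'   or \code{"unindexed"}), \code{lattices} (each with \code{D} and
#'   \code{D_se} in \eqn{\AA}), the per-peak \code{assignment}
#'   (lattice id and order), \code{residuals}, and \code{peaks} (the input
#'   with \code{order} and \code{lattice_id} filled in).
#' @export
index_lattice <- function(peaks, tolerance = 0.01) {
  stopifnot(inherits(peaks, "peak_set"))
  qv <- peaks$center; se <- peaks$center_se
  out <- list(phase_class = "unindexed", lattices = list(),
              assignment = data.frame(), residuals = numeric(0),
              tolerance = tolerance, low_confidence = FALSE, peaks = peaks)
  class(out) <- "lattice_assignment"

  if (length(qv) == 1L) {
    out$phase_class <- "lamellar"
    out$lattices <- list(list(D = 2 * pi / qv, D_se = 2 * pi * se / qv^2))
    out$low_confidence <- TRUE
    out$peaks$order <- 1L; out$peaks$lattice_id <- 1L
    out$assignment <- data.frame(peak = 1L, lattice_id = 1L, order = 1L)
    out$residuals <- 0
    return(out)
  }

  lam <- .try_lamellar(qv, se, tolerance)
  if (!is.null(lam)) {
    out$phase_class <- "lamellar"
    out$lattices <- list(list(D = lam$D, D_se = lam$D_se))
    out$peaks$order <- lam$orders; out$peaks$lattice_id <- 1L
    out$assignment <- data.frame(peak = seq_along(qv), lattice_id = 1L,
                                 order = lam$orders)
    out$residuals <- lam$residuals
    return(out)
  }

  hex <- .try_hexagonal(qv, se, tolerance)
  if (!is.null(hex)) {
    out$phase_class <- "hexagonal"
    out$lattices <- list(list(D = hex$d10, D_se = hex$d10_se,
                              note = "d-spacing of the (1,0) reflection"))
    out$peaks$order <- hex$index; out$peaks$lattice_id <- 1L
    out$assignment <- data.frame(peak = seq_along(qv), lattice_id = 1L,
                                 order = hex$index)
    out$residuals <- hex$residuals
    return(out)
  }

  co <- .try_coexistence(qv, se, tolerance)
  if (!is.null(co)) {
    out$phase_class <- "coexisting_lamellar"
    out$lattices <- lapply(co, function(l)
      list(D = l$fit$D, D_se = l$fit$D_se))
    ord <- integer(length(qv)); lid <- integer(length(qv))
    res <- numeric(length(qv))
    for (i in seq_along(co)) {
      ord[co[[i]]$ok] <- co[[i]]$orders
      lid[co[[i]]$ok] <- i
      res[co[[i]]$ok] <- co[[i]]$fit$residuals
    }
    out$peaks$order <- ord; out$peaks$lattice_id <- lid
    out$assignment <- data.frame(peak = seq_along(qv), lattice_id = lid,
                                 order = ord)
    out$residuals <- res
    return(out)
  }
  out
}

#' @export
print.lattice_assignment <- function(x, ...) {
  cat("<lattice_assignment> phase:", x$phase_class, "\n")
  for (i in seq_along(x$lattices))
    cat(sprintf("  lattice %d: D = %.3f +/- %.3f A\n", i,
                x$lattices[[i]]$D, x$lattices[[i]]$D_se))
  if (length(x$residuals))
    cat(sprintf("  max relative residual: %.2e (tolerance %.2e)\n",
                max(x$residuals), x$tolerance))
  if (x$low_confidence) cat("  [low confidence: single peak]\n")
  invisible(x)
}

#' Classify the mesophase of an indexed peak set
#'
#' Returns the phase class of a \code{\link{index_lattice}} result together
#' with a human-readable rationale (observed position ratios and residuals).
#'
#' @param assignment a \code{"lattice_assignment"}.
#' @return A character scalar (\code{"lamellar"}, \code{"hexagonal"},
#'   \code{"coexisting_lamellar"}, or \code{"unindexed"}) with a
#'   \code{"rationale"} attribute.
#' @export
classify_phase <- function(assignment) {
  stopifnot(inherits(assignment, "lattice_assignment"))
  qv <- assignment$peaks$center
  ratios <- paste(round(qv / qv[1], 3), collapse = ":")
  rationale <- switch(assignment$phase_class,
    lamellar = sprintf(
      "position ratios %s match integers n = %s; D = %.2f A (max residual %.2e)",
      ratios, paste(assignment$peaks$order, collapse = ":"),
      assignment$lattices[[1]]$D,
      if (length(assignment$residuals)) max(assignment$residuals) else 0),
    hexagonal = sprintf(
      "position ratios %s match sqrt(1, 3, 4, 7, ...); d10 = %.2f A",
      ratios, assignment$lattices[[1]]$D),
    coexisting_lamellar = sprintf(
      "two interleaved lamellar series: D = %.2f A and %.2f A",
      assignment$lattices[[1]]$D, assignment$lattices[[2]]$D),
    unindexed = sprintf(
      "position ratios %s fit no lamellar or hexagonal series within tolerance %.3g",
      ratios, assignment$tolerance))
  structure(assignment$phase_class, rationale = rationale)
}
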