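#' Lipid and water molecular volumes
#'
#' Volume constants entering the Luzzati parameter chain: the lipid
#' molecular volume \code{V_l}, the lipid hydrophobic-core volume
#' \code{V_c}, and the water molecular volume \code{V_w}.  The defaults
#' (\code{V_l} = 1400 \eqn{\AA^3}, \code{V_c} = 1175 \eqn{\AA^3}) are
#' approximate values for a diphytanyl phosphatidylcholine-type lipid,
#' chosen for internal consistency of the parameter chain at full
#' hydration; users with measured volumes should supply their own.
#'
#' @param V_l lipid molecular volume (\eqn{\AA^3}).
#' @param V_c lipid hydrophobic-core volume (\eqn{\AA^3});
#'   \code{0 < V_c < V_l}.
#' @param V_w water molecular volume (\eqn{\AA^3}, default 30).
#' @return An object of class \code{"volume_set"}.
#' @export
volume_set <- function(V_l = 1400, V_c = 1175, V_w = 30) {
  if (V_w <= 0) stop("V_w must be positive")
  if (V_c <= 0 || V_c >= V_l) stop("need 0 < V_c < V_l")
  structure(list(V_l = V_l, V_c = V_c, V_w = V_w), class = "volume_set")
}

#' Headgroup peak-to-peak distance from an NSLD profile
#'
#' The Gibbs--Luzzati bilayer thickness \eqn{D_B} is read off the NSLD
#' profile as the distance between the two headgroup maxima.  Each maximum
#' is located by fitting a Gaussian (plus constant offset) to the peak
#' region; the fit window extends from the peak to its nearest inflection
#' point, applied symmetrically to both peaks.  The standard error combines
#' both Gaussian-centre uncertainties in quadrature.
#'
#' @param profile an \code{"nsld_profile"} with exactly one maximum per
#'   half-cell away from the centre.
#' @return List with \code{value} (\eqn{D_B}, \eqn{\AA}), \code{se},
#'   \code{z_pos}, \code{z_neg} (fitted peak centres), and
#'   \code{symmetry_ok} (whether \eqn{z_+ = -z_-} within combined SE).
#' @export
headgroup_peak_to_peak <- function(profile) {
  stopifnot(inherits(profile, "nsld_profile"))
  z <- profile$z; rho <- profile$rho
  if (diff(range(rho)) <= .Machine$double.eps * max(abs(rho), 1))
    stop("no headgroup peaks: profile is flat")
  pos <- z > 1e-9
  # local maxima strictly inside the half cell
  i_all <- which(pos)[-c(1, sum(pos))]
  loc <- i_all[rho[i_all] > rho[i_all - 1] & rho[i_all] >= rho[i_all + 1]]
  if (!length(loc))
    stop("no headgroup peaks: no interior maximum in the half-cell")
  i_pk <- loc[which.max(rho[loc])]

  # inflection points of the (noise-free, band-limited) profile
  d2 <- c(NA, diff(rho, differences = 2), NA)
  sgn <- sign(d2)
  infl_up <- which(diff(sgn) != 0 & !is.na(diff(sgn)))
  if (length(infl_up)) {
    d_infl <- abs(z[infl_up] - z[i_pk])
    win <- min(d_infl[d_infl > 2 * (z[2] - z[1])])
  } else win <- profile$D / 8

  fit_one <- function(z0) {
    sel <- abs(z - z0) <= win
    zz <- z[sel]; yy <- rho[sel]
    st <- list(c0 = min(yy), A = max(yy) - min(yy), mu = z0, s = win / 2)
    fit <- tryCatch(
      minpack.lm::nlsLM(yy ~ c0 + A * exp(-(zz - mu)^2 / (2 * s^2)),
                        data = list(zz = zz, yy = yy), start = st,
                        lower = c(-Inf, 0, min(zz), (z[2] - z[1]) / 2),
                        upper = c(Inf, Inf, max(zz), diff(range(zz)))),
      error = function(e) stop("headgroup Gaussian fit failed: ",
                               conditionMessage(e)))
    cf <- coef(fit)
    list(mu = cf[["mu"]], se = sqrt(vcov(fit)["mu", "mu"]))
  }
  fp <- fit_one(z[i_pk])
  fn <- fit_one(-z[i_pk])
  se <- sqrt(fp$se^2 + fn$se^2)
  list(value = fp$mu - fn$mu, se = se, z_pos = fp$mu, z_neg = fn$mu,
       symmetry_ok = abs(fp$mu + fn$mu) <= max(3 * se, 1e-6))
}

#' Water layer thickness
#'
#' \eqn{D_w = D - D_B}, the thickness of the water layer between adjacent
#' bilayers, with \eqn{SE = \sqrt{SE_D^2 + SE_{D_B}^2}}.
#'
#' @param D lamellar repeat (\eqn{\AA}).
#' @param D_B bilayer (headgroup peak-to-peak) thickness (\eqn{\AA});
#'   must be smaller than \code{D}.
#' @param se_D,se_D_B standard errors (default 0).
#' @return List with \code{value} and \code{se}.
#' @export
#' @examples
#' water_thickness(50.4, 37.4)  # 13.0 A
water_thickness <- function(D, D_B, se_D = 0, se_D_B = 0) {
  if (D <= D_B) stop("non-physical water layer: D <= D_B")
  list(value = D - D_B, se = sqrt(se_D^2 + se_D_B^2))
}

#' Area per lipid from the Luzzati relation
#'
#' \eqn{A = 2 V_l / D_B}: two lipid monolayers of volume \eqn{V_l} each
#' fill the bilayer slab of thickness \eqn{D_B}.  First-order error
#' propagation: \eqn{SE_A / A = SE_{D_B} / D_B}.
#'
#' @param D_B bilayer thickness (\eqn{\AA}), positive.
#' @param vols a \code{\link{volume_set}}.
#' @param se_D_B standard error of \code{D_B}.
#' @return List with \code{value} (\eqn{\AA^2}) and \code{se}.
#' @export
area_per_lipid <- function(D_B, vols = volume_set(), se_D_B = 0) {
  if (D_B <= 0) stop("D_B must be positive")
  A <- 2 * vols$V_l / D_B
  list(value = A, se = A * se_D_B / D_B)
}

#' Hydrophobic core thickness
#'
#' \eqn{2 D_c = 2 V_c / A}, from the core volume and the area per lipid.
#' Note the exact identity \eqn{2 D_c / D_B = V_c / V_l} when A comes from
#' \code{\link{area_per_lipid}} with the same volumes.
#'
#' @param A area per lipid (\eqn{\AA^2}), positive.
#' @param vols a \code{\link{volume_set}}.
#' @param se_A standard error of \code{A}.
#' @return List with \code{value} (\eqn{2 D_c}, \eqn{\AA}) and \code{se}.
#' @export
hydrophobic_thickness <- function(A, vols = volume_set(), se_A = 0) {
  if (A <= 0) stop("A must be positive")
  v <- 2 * vols$V_c / A
  list(value = v, se = v * se_A / A)
}

#' Waters per lipid
#'
#' \eqn{n_w = A D_w / (2 V_w)}: the interbilayer water slab of thickness
#' \eqn{D_w} is shared by the two apposed monolayers, so each lipid of
#' interfacial area A accounts for a water column of height \eqn{D_w/2}.
#'
#' @param A area per lipid (\eqn{\AA^2}), positive.
#' @param D_w water layer thickness (\eqn{\AA}), non-negative.
#' @param vols a \code{\link{volume_set}}.
#' @param se_A,se_D_w standard errors.
#' @return List with \code{value} (dimensionless) and \code{se}.
#' @export
waters_per_lipid <- function(A, D_w, vols = volume_set(),
                             se_A = 0, se_D_w = 0) {
  if (A <= 0) stop("A must be positive")
  if (D_w < 0) stop("D_w must be non-negative")
  v <- A * D_w / (2 * vols$V_w)
  se <- if (D_w > 0) v * sqrt((se_A / A)^2 + (se_D_w / D_w)^2)
        else A * se_D_w / (2 * vols$V_w)
  list(value = v, se = se)
}

#' Bilayer structural parameters with propagated uncertainties
#'
#' Runs the full Luzzati chain from the lattice constant D and the
#' headgroup peak-to-peak distance \eqn{D_B}:
#' \eqn{D_w = D - D_B}, \eqn{A = 2 V_l / D_B}, \eqn{2 D_c = 2 V_c / A},
#' \eqn{n_w = A D_w / (2 V_w)}.  Standard errors are propagated to first
#' order (delta method); \code{method = "mc"} instead resamples D and
#' \eqn{D_B} from independent normal distributions and reports the sample
#' standard deviations, as a cross-check of the linearisation.
#'
#' @param D lamellar repeat (\eqn{\AA}).
#' @param D_B bilayer thickness (\eqn{\AA}).
#' @param se_D,se_D_B standard errors; must be positive finite for
#'   \code{method = "mc"}.
#' @param vols a \code{\link{volume_set}}.
#' @param method \code{"delta"} (first-order propagation) or \code{"mc"}
#'   (Monte-Carlo resampling).
#' @param n_draws number of Monte-Carlo draws.
#' @param seed RNG seed for \code{method = "mc"}.
#' @param meta optional condition metadata list (temperature, RH, ...).
#' @return A \code{"bilayer_parameters"} object: list of
#'   \code{value}/\code{se} pairs \code{D}, \code{D_B}, \code{two_Dc},
#'   \code{D_w}, \code{A}, \code{n_w}, plus \code{vols}, \code{meta},
#'   \code{method}.  The identity \code{D_w = D - D_B} is exact, and
#'   \code{A = 2 V_l / D_B}, \code{two_Dc = 2 V_c / A} hold by
#'   construction.
#' @export
#' @examples
#' p <- bilayer_parameters(50.4, 37.4, se_D = 0.1, se_D_B = 0.2)
#' p$n_w$value  # about 16.2 with the default volumes
bilayer_parameters <- function(D, D_B, se_D = 0, se_D_B = 0,
                               vols = volume_set(),
                               method = c("delta", "mc"),
                               n_draws = 1e5, seed = 1L, meta = list()) {
  method <- match.arg(method)
  if (D <= D_B) stop("non-physical water layer: D <= D_B")
  if (D_B <= 0) stop("D_B must be positive")
  dw <- water_thickness(D, D_B, se_D, se_D_B)
  a <- area_per_lipid(D_B, vols, se_D_B)
  tdc <- hydrophobic_thickness(a$value, vols, a$se)
  nw <- waters_per_lipid(a$value, dw$value, vols, a$se, dw$se)
  # A and D_w are both functions of D_B, so their errors are correlated;
  # n_w = V_l (D - D_B) / (V_w D_B) propagated in the independent inputs
  # (D, D_B) rather than in (A, D_w)
  g_D <- vols$V_l / (vols$V_w * D_B)
  g_DB <- -vols$V_l * D / (vols$V_w * D_B^2)
  nw$se <- sqrt((g_D * se_D)^2 + (g_DB * se_D_B)^2)
  out <- list(D = list(value = D, se = se_D),
              D_B = list(value = D_B, se = se_D_B),
              two_Dc = tdc, D_w = dw, A = a, n_w = nw,
              vols = vols, meta = meta, method = method)
  if (method == "mc") {
    if (se_D <= 0 || se_D_B <= 0 || !is.finite(se_D) || !is.finite(se_D_B))
      stop("Monte-Carlo propagation needs positive finite SEs")
    draws <- .with_seed(seed, {
      Ds <- rnorm(n_draws, D, se_D)
      DBs <- rnorm(n_draws, D_B, se_D_B)
      ok <- Ds > DBs & DBs > 0
      Ds <- Ds[ok]; DBs <- DBs[ok]
      As <- 2 * vols$V_l / DBs
      Dws <- Ds - DBs
      list(A = As, D_w = Dws, two_Dc = 2 * vols$V_c / As,
           n_w = As * Dws / (2 * vols$V_w))
    })
    out$D_w$se <- sd(draws$D_w)
    out$A$se <- sd(draws$A)
    out$two_Dc$se <- sd(draws$two_Dc)
    out$n_w$se <- sd(draws$n_w)
  }
  if (!(tdc$value < D_B))
    warning("hydrophobic thickness >= bilayer thickness: check volumes")
  class(out) <- "bilayer_parameters"
  out
}

#' @export
print.bilayer_parameters <- function(x, ...) {
  cat("<bilayer_parameters>", if (length(x$meta))
    paste0("[", paste(names(x$meta), unlist(x$meta), sep = "=",
                      collapse = ", "), "]"), "\n")
  fmt <- function(nm, lab, unit) {
    v <- x[[nm]]
    cat(sprintf("  %-6s %6.1f +/- %.1f %s\n", lab, v$value, v$se, unit))
  }
  fmt("D", "D", "A"); fmt("D_B", "D_B", "A"); fmt("two_Dc", "2D_c", "A")
  fmt("D_w", "D_w", "A"); fmt("A", "A", "A^2"); fmt("n_w", "n_w", "")
  invisible(x)
}

#' First-order and Monte-Carlo error propagation through the parameter chain
#'
#' Convenience wrapper returning both the delta-method and Monte-Carlo
#' standard errors for the derived parameters, for cross-checking the
#' linearisation at given input uncertainties.
#'
#' @inheritParams bilayer_parameters
#' @return Data frame with rows \code{A}, \code{two_Dc}, \code{D_w},
#'   \code{n_w} and columns \code{se_delta}, \code{se_mc}.
#' @export
propagate_parameters <- function(D, D_B, se_D, se_D_B, vols = volume_set(),
                                 n_draws = 1e5, seed = 1L) {
  if (se_D <= 0 || se_D_B <= 0) stop("SEs must be positive")
  pd <- bilayer_parameters(D, D_B, se_D, se_D_B, vols, method = "delta")
  pm <- bilayer_parameters(D, D_B, se_D, se_D_B, vols, method = "mc",
                           n_draws = n_draws, seed = seed)
  data.frame(
    row.names = c("A", "two_Dc", "D_w", "n_w"),
    se_delta = c(pd$A$se, pd$two_Dc$se, pd$D_w$se, pd$n_w$se),
    se_mc = c(pm$A$se, pm$two_Dc$se, pm$D_w$se, pm$n_w$se))
}
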