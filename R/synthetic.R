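#' Parametric model of a centrosymmetric bilayer unit cell
#'
#' Minimal real-space parameterisation of one lamellar unit cell of a
#' stacked bilayer: a hydrocarbon slab of SLD \code{rho_CH} between
#' \code{-z_H} and \code{+z_H} (edges smoothed with an error function of
#' width \code{sigma_H}), Gaussian headgroup peaks of amplitude
#' \code{rho_H - rho_CH} centred at \eqn{\pm z_H}, a Gaussian methyl trough
#' at the bilayer centre, and water of SLD \code{\link{water_sld}(x_D2O)}
#' beyond the headgroups.  The profile is periodised over the lamellar
#' repeat \code{D}, so it is exactly even and exactly periodic.
#'
#' Defaults describe a PC-like bilayer with repeat 50.4 \eqn{\AA} and a
#' headgroup peak-to-peak distance of 37.4 \eqn{\AA}: headgroup SLD above
#' the hydrocarbon plateau, methyl trough below it.
#'
#' @param D lamellar repeat distance (\eqn{\AA}).
#' @param z_H headgroup peak position from the bilayer centre (\eqn{\AA});
#'   must satisfy \code{0 < z_H < D/2}.
#' @param sigma_H headgroup Gaussian width (\eqn{\AA}).
#' @param rho_H headgroup SLD amplitude (\eqn{\AA^{-2}}).
#' @param rho_CH hydrocarbon plateau SLD (\eqn{\AA^{-2}}).
#' @param rho_CH3 methyl-trough SLD minimum (\eqn{\AA^{-2}}).
#' @param sigma_CH3 methyl trough Gaussian width (\eqn{\AA}).
#' @param x_D2O D2O volume fraction of the hydration water.
#' @return An object of class \code{"bilayer_model"}; the derived field
#'   \code{D_B_true = 2 * z_H} is the true headgroup peak-to-peak distance.
#' @export
#' @examples
#' m <- bilayer_model()
#' m$D_B_true
#' model_form_factors(m, 4)
bilayer_model <- function(D = 50.4, z_H = 18.7, sigma_H = 3.0,
                          rho_H = 2.0e-6, rho_CH = -0.4e-6,
                          rho_CH3 = -1.0e-6, sigma_CH3 = 3.0,
                          x_D2O = 0.08) {
  if (D <= 0) stop("D must be positive")
  if (z_H <= 0 || z_H >= D / 2) stop("z_H must satisfy 0 < z_H < D/2")
  if (sigma_H <= 0) stop("sigma_H must be positive")
  if (sigma_CH3 <= 0) stop("sigma_CH3 must be positive")
  if (x_D2O < 0 || x_D2O > 1) stop("x_D2O must lie in [0, 1]")
  structure(list(D = D, z_H = z_H, sigma_H = sigma_H, rho_H = rho_H,
                 rho_CH = rho_CH, rho_CH3 = rho_CH3, sigma_CH3 = sigma_CH3,
                 x_D2O = x_D2O, D_B_true = 2 * z_H),
            class = "bilayer_model")
}

#' @export
print.bilayer_model <- function(x, ...) {
  cat("<bilayer_model> D =", x$D, "A, z_H =", x$z_H,
      "A (D_B_true =", x$D_B_true, "A), x_D2O =", x$x_D2O, "\n")
  cat("  sigma_H =", x$sigma_H, " rho_H =", x$rho_H,
      " rho_CH =", x$rho_CH, " rho_CH3 =", x$rho_CH3,
      " sigma_CH3 =", x$sigma_CH3, "\n")
  invisible(x)
}

#' Acquisition settings for synthetic diffractograms
#'
#' Instrument-side parameters of the synthetic forward model: q grid,
#' Gaussian instrumental peak width, polynomial background, counting-noise
#' scale, Lorentz exponent applied by the "instrument" (intensities carry a
#' factor \eqn{q_n^{-p}}), an overall intensity scale (a.u.), and the RNG
#' seed.
#'
#' @param q_grid strictly increasing positive q grid (\eqn{\AA^{-1}});
#'   default covers 0.06--0.51 \eqn{\AA^{-1}}.
#' @param peak_width instrumental Gaussian sigma (\eqn{\AA^{-1}}).
#' @param background numeric vector of polynomial coefficients (constant
#'   first), evaluated in q, added to the signal (a.u.).
#' @param noise_scale multiplier for counting noise: noise sd is
#'   \code{noise_scale * sqrt(max(intensity, 1))}; 0 disables noise.
#' @param lorentz_exponent power p applied as \eqn{q^{-p}} to the Bragg
#'   intensities (default 1, the oriented-sample convention).
#' @param intensity_scale overall scale converting squared structure
#'   factors to detector-like arbitrary units.
#' @param seed integer seed for reproducible noise.
#' @return An object of class \code{"acquisition_model"}.
#' @export
acquisition_model <- function(q_grid = seq(0.06, 0.51, by = 5e-4),
                              peak_width = 0.004, background = 0,
                              noise_scale = 0, lorentz_exponent = 1,
                              intensity_scale = 1e12, seed = 1L) {
  if (any(q_grid <= 0)) stop("q_grid must be positive")
  if (any(diff(q_grid) <= 0)) stop("q_grid must be strictly increasing")
  if (peak_width <= 0) stop("peak_width must be positive")
  if (noise_scale < 0) stop("noise_scale must be >= 0")
  if (intensity_scale <= 0) stop("intensity_scale must be positive")
  structure(list(q_grid = q_grid, peak_width = peak_width,
                 background = background, noise_scale = noise_scale,
                 lorentz_exponent = lorentz_exponent,
                 intensity_scale = intensity_scale,
                 seed = as.integer(seed)),
            class = "acquisition_model")
}

# one motif of the periodised profile, relative to the water level:
# hydrocarbon slab + headgroup Gaussians + methyl trough
.model_motif <- function(m, z, rho_w) {
  box <- 0.5 * (pracma::erf((z + m$z_H) / (sqrt(2) * m$sigma_H)) -
                pracma::erf((z - m$z_H) / (sqrt(2) * m$sigma_H)))
  (m$rho_CH - rho_w) * box +
    (m$rho_H - m$rho_CH) * (exp(-(z - m$z_H)^2 / (2 * m$sigma_H^2)) +
                            exp(-(z + m$z_H)^2 / (2 * m$sigma_H^2))) +
    (m$rho_CH3 - m$rho_CH) * exp(-z^2 / (2 * m$sigma_CH3^2))
}

#' Real-space SLD profile of a bilayer model
#'
#' Evaluates the model's neutron scattering length density at positions
#' \code{z} within one unit cell, \eqn{|z| \le D/2}.  The profile is the
#' periodised sum of the single-cell motif, so it is exactly even in z and
#' exactly D-periodic; beyond the headgroups it tends to the water SLD
#' \code{\link{water_sld}(x_D2O)}.
#'
#' @param model a \code{\link{bilayer_model}}.
#' @param z positions (\eqn{\AA}) with \code{abs(z) <= D/2}.
#' @return SLD values (\eqn{\AA^{-2}}).
#' @export
model_profile <- function(model, z) {
  stopifnot(inherits(model, "bilayer_model"))
  if (any(abs(z) > model$D / 2 + 1e-9))
    stop("z outside the unit cell [-D/2, D/2]")
  rho_w <- water_sld(model$x_D2O)
  za <- abs(z)  # the profile is even; |z| makes that exact in floating point
  out <- rep(rho_w, length(z))
  for (img in -3:3) out <- out + .model_motif(model, za - img * model$D, rho_w)
  out
}

#' Closed-form Fourier coefficients (form factors) of a bilayer model
#'
#' The n-th coefficient is
#' \eqn{f_n = \int_{-D/2}^{D/2} (\rho(z) - \bar\rho)\cos(2\pi n z / D)\,dz}.
#' Because the profile is a periodised sum of Gaussians and an erf-smoothed
#' slab, the unit-cell integral of the periodic profile equals the
#' infinite-domain integral of one motif, which has a closed form:
#' the slab contributes \eqn{(\rho_{CH}-\rho_w)\,(2\sin(k z_H)/k)\,
#' e^{-k^2\sigma_H^2/2}}, each Gaussian component
#' \eqn{A\,\sigma\sqrt{2\pi}\,e^{-k^2\sigma^2/2}\cos(k z_0)}, with
#' \eqn{k = 2\pi n / D}.  The sign of \eqn{f_n} carries the true phase
#' \eqn{\nu_n}.
#'
#' @param model a \code{\link{bilayer_model}}.
#' @param orders integer vector of Bragg orders (n >= 1), or a single
#'   integer M meaning orders \code{1:M}.
#' @return Named numeric vector of signed coefficients (a.u.,
#'   \eqn{\AA^{-2}\cdot\AA}).
#' @export
model_form_factors <- function(model, orders) {
  stopifnot(inherits(model, "bilayer_model"))
  orders <- as.integer(orders)
  if (length(orders) == 1L && orders >= 1L) orders <- seq_len(orders)
  if (any(orders < 1L)) stop("orders must be >= 1")
  rho_w <- water_sld(model$x_D2O)
  k <- 2 * pi * orders / model$D
  slab <- (model$rho_CH - rho_w) * (2 * sin(k * model$z_H) / k) *
    exp(-k^2 * model$sigma_H^2 / 2)
  head <- (model$rho_H - model$rho_CH) * model$sigma_H * sqrt(2 * pi) *
    exp(-k^2 * model$sigma_H^2 / 2) * 2 * cos(k * model$z_H)
  methyl <- (model$rho_CH3 - model$rho_CH) * model$sigma_CH3 * sqrt(2 * pi) *
    exp(-k^2 * model$sigma_CH3^2 / 2)
  setNames(slab + head + methyl, paste0("f", orders))
}

#' Synthesize a diffractogram from a bilayer model
#'
#' Forward model: Bragg peaks at \eqn{q_n = 2\pi n / D} with integrated
#' intensities \eqn{f_n^2 q_n^{-p}} (p the Lorentz exponent), convolved with
#' a Gaussian instrumental line shape, plus a polynomial background and
#' Gaussian counting noise (sd \code{noise_scale * sqrt(intensity)}).
#' The returned metadata records the D2O fraction, seed, and the full truth
#' parameters for recovery tests.
#'
#' @param model a \code{\link{bilayer_model}}.
#' @param acq an \code{\link{acquisition_model}}.
#' @return A \code{\link{diffractogram}} with populated sigma column.
#' @export
synthesize_diffractogram <- function(model, acq = acquisition_model()) {
  stopifnot(inherits(model, "bilayer_model"),
            inherits(acq, "acquisition_model"))
  q <- acq$q_grid
  p <- acq$lorentz_exponent
  n_max <- floor(max(q) * model$D / (2 * pi)) + 1L
  orders <- seq_len(max(n_max, 1L))
  qn <- 2 * pi * orders / model$D
  visible <- qn > min(q) - 4 * acq$peak_width &
             qn < max(q) + 4 * acq$peak_width
  warn <- NULL
  if (!any(visible))
    warn <- "no Bragg peak of this lattice falls inside the q window"
  f <- model_form_factors(model, orders)
  clean <- .poly_eval(acq$background, q)
  for (i in which(visible)) {
    clean <- clean + acq$intensity_scale * f[i]^2 * qn[i]^(-p) *
      dnorm(q, qn[i], acq$peak_width)
  }
  sd_noise <- acq$noise_scale * sqrt(pmax(clean, 1))
  noise <- if (acq$noise_scale > 0)
    .with_seed(acq$seed, rnorm(length(q), 0, sd_noise)) else 0
  sigma <- pmax(sd_noise, 1e-12 * max(abs(clean), 1))
  meta <- list(x_D2O = model$x_D2O, seed = acq$seed,
               label = sprintf("synthetic x_D2O=%g", model$x_D2O))
  d <- diffractogram(q, clean + noise, sigma, meta)
  d$meta$truth <- unclass(model)
  d$meta$warning <- warn
  if (!is.null(warn)) warning(warn)
  d
}

.poly_eval <- function(coefs, x) {
  out <- 0
  for (j in seq_along(coefs)) out <- out + coefs[j] * x^(j - 1)
  out
}

#' Synthesize a D2O contrast series
#'
#' One diffractogram per D2O fraction, sharing all model parameters except
#' the water SLD.  Per-fraction seeds are derived deterministically from the
#' base seed, so the series is reproducible and independent of the order in
#' which fractions are listed.
#'
#' @param model a \code{\link{bilayer_model}} (its \code{x_D2O} is ignored).
#' @param fractions numeric vector of D2O volume fractions in \code{[0, 1]}.
#' @param acq an \code{\link{acquisition_model}}.
#' @return A list of \code{\link{diffractogram}} objects, one per fraction.
#' @export
synthesize_contrast_series <- function(model, fractions = c(0.08, 0.2, 0.5, 1.0),
                                       acq = acquisition_model()) {
  if (!length(fractions)) stop("empty fraction list")
  if (any(fractions < 0 | fractions > 1)) stop("fractions must lie in [0, 1]")
  lapply(seq_along(fractions), function(i) {
    m <- model
    m$x_D2O <- fractions[i]
    a <- acq
    # seed keyed to the fraction value, not the list position
    a$seed <- as.integer((acq$seed + round(1e4 * fractions[i]) * 7919L) %%
                           .Machine$integer.max)
    synthesize_diffractogram(m, a)
  })
}

#' Synthesize a hexagonal-phase diffractogram
#'
#' Places peaks at \eqn{q_1 \{1, \sqrt3, \sqrt4, \sqrt7, 3, ...\}}, the
#' position series of a 2D hexagonal lattice, with given positive
#' integrated amplitudes.
#'
#' @param q1 position of the (1,0) reflection (\eqn{\AA^{-1}}).
#' @param amplitudes integrated intensities (a.u.) for successive
#'   reflections; zeros give a background-only scan.
#' @param acq an \code{\link{acquisition_model}}.
#' @return A \code{\link{diffractogram}}.
#' @export
synthesize_nonlamellar <- function(q1, amplitudes = c(1, 0.6, 0.4, 0.25) * 1e-8,
                                   acq = acquisition_model()) {
  if (q1 <= 0) stop("q1 must be positive")
  if (any(amplitudes < 0)) stop("amplitudes must be non-negative")
  ratios <- sqrt(c(1, 3, 4, 7, 9, 12, 13, 16))[seq_along(amplitudes)]
  qpk <- q1 * ratios
  q <- acq$q_grid
  clean <- .poly_eval(acq$background, q)
  for (i in seq_along(qpk)) {
    if (qpk[i] > max(q) + 4 * acq$peak_width) next
    clean <- clean + acq$intensity_scale * amplitudes[i] *
      dnorm(q, qpk[i], acq$peak_width)
  }
  sd_noise <- acq$noise_scale * sqrt(pmax(clean, 1))
  noise <- if (acq$noise_scale > 0)
    .with_seed(acq$seed, rnorm(length(q), 0, sd_noise)) else 0
  sigma <- pmax(sd_noise, 1e-12 * max(abs(clean), 1))
  diffractogram(q, clean + noise, sigma,
                list(label = sprintf("synthetic hexagonal q1=%g", q1),
                     seed = acq$seed))
}

#' Write / read a ground-truth sidecar file
#'
#' Key-value text file recording all parameters of a
#' \code{\link{bilayer_model}}, so that synthetic data written to disk can
#' be paired with their generating truth in recovery tests.
#'
#' @param model a \code{\link{bilayer_model}}.
#' @param path file path.
#' @return \code{write_truth}: \code{path} invisibly;
#'   \code{read_truth}: a \code{\link{bilayer_model}}.
#' @export
write_truth <- function(model, path) {
  stopifnot(inherits(model, "bilayer_model"))
  flds <- c("D", "z_H", "sigma_H", "rho_H", "rho_CH", "rho_CH3",
            "sigma_CH3", "x_D2O")
  writeLines(sprintf("%s=%s", flds,
                     vapply(model[flds], format, "", digits = 15)), path)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  kv <- strsplit(lines, "=", fixed = TRUE)
  vals <- setNames(as.numeric(vapply(kv, `[`, "", 2L)),
                   trimws(vapply(kv, `[`, "", 1L)))
  do.call(bilayer_model, as.list(vals))
}
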