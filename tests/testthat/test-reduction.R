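# background subtraction, peak fitting, lattice indexing, classification

test_that("constant and linear baselines are recovered and removed", {
  m <- default_model()
  base <- synthesize_diffractogram(m, clean_acq())
  win <- lapply(2 * pi * (1:4) / m$D, function(qn) c(qn - 0.03, qn + 0.03))

  d_c <- base; d_c$intensity <- d_c$intensity + 250
  s <- subtract_background(d_c, "constant", exclude = win)
  expect_equal(s$meta$background_fit$coefficients, 250, tolerance = 1e-3)
  expect_equal(s$intensity, base$intensity, tolerance = 1e-3)

  d_l <- base; d_l$intensity <- d_l$intensity + (100 + 400 * d_l$q)
  s <- subtract_background(d_l, "linear", exclude = win)
  expect_equal(s$meta$background_fit$coefficients, c(100, 400),
               tolerance = 2e-3)
  expect_equal(s$intensity, base$intensity, tolerance = 1e-3)

  expect_error(subtract_background(base, exclude = list(c(0, 1))),
               "all points excluded")
  expect_error(subtract_background(base, exclude = list(c(0.6, 0.7))),
               "outside the q range")
})

test_that("polynomial background leaves integrated intensities unchanged within 3 SE", {
  m <- default_model()
  ns <- noise_for_relative(m, acquisition_model(), rel = 0.01)
  acq0 <- acquisition_model(noise_scale = ns, seed = 21)
  acq_bg <- acquisition_model(noise_scale = ns, seed = 21,
                              background = c(400, -1200, 1800))
  d0 <- synthesize_diffractogram(m, acq0)
  dbg <- synthesize_diffractogram(m, acq_bg)
  win <- lapply(2 * pi * (1:4) / m$D, function(qn) c(qn - 0.02, qn + 0.02))
  s <- subtract_background(dbg, "polynomial", degree = 2, exclude = win)
  pk0 <- fit_peaks(d0)
  pks <- fit_peaks(s)
  expect_equal(nrow(pk0), nrow(pks))
  for (i in seq_len(nrow(pk0))) {
    se <- sqrt(pk0$intensity_se[i]^2 + pks$intensity_se[i]^2)
    expect_lt(abs(pk0$intensity[i] - pks$intensity[i]), 3 * se)
  }
})

test_that("a single noiseless Gaussian integrates to A*sigma*sqrt(2*pi)", {
  q <- seq(0.05, 0.25, by = 2e-4)
  A0 <- 1234; s0 <- 0.005
  d <- diffractogram(q, A0 * exp(-(q - 0.15)^2 / (2 * s0^2)),
                     sigma = rep(1, length(q)))
  pk <- fit_peaks(d)
  expect_equal(nrow(pk), 1L)
  expect_equal(pk$intensity, A0 * s0 * sqrt(2 * pi), tolerance = 1e-8)
  expect_equal(pk$center, 0.15, tolerance = 1e-10)
  expect_equal(pk$width, s0, tolerance = 1e-8)
})

test_that("a 5-sigma-separated doublet is recovered within 1 percent", {
  q <- seq(0.05, 0.35, by = 2e-4)
  s0 <- 0.004
  y <- 1000 * exp(-(q - 0.15)^2 / (2 * s0^2)) +
       600 * exp(-(q - 0.17)^2 / (2 * s0^2))
  d <- diffractogram(q, y, sigma = rep(0.5, length(q)))
  pk <- fit_peaks(d)
  expect_equal(nrow(pk), 2L)
  truth <- c(1000, 600) * s0 * sqrt(2 * pi)
  expect_lt(max(abs(pk$intensity - truth) / truth), 0.01)
  expect_lt(max(abs(pk$center - c(0.15, 0.17))), 1e-4)
})

test_that("3-SE intervals from noisy single-peak fits cover truth at >= 95%", {
  q <- seq(0.10, 0.20, by = 2.5e-4)
  A0 <- 800; s0 <- 0.004; c0 <- 0.15
  truth_I <- A0 * s0 * sqrt(2 * pi)
  sig <- 8
  hits <- 0L; n_rep <- 200L
  set.seed(1234)
  for (r in seq_len(n_rep)) {
    y <- A0 * exp(-(q - c0)^2 / (2 * s0^2)) + rnorm(length(q), 0, sig)
    d <- diffractogram(q, y, sigma = rep(sig, length(q)))
    pk <- tryCatch(suppressWarnings(fit_peaks(d)), error = function(e) NULL)
    if (is.null(pk) || nrow(pk) < 1) next
    i <- which.max(pk$intensity)
    if (abs(pk$intensity[i] - truth_I) <= 3 * pk$intensity_se[i])
      hits <- hits + 1L
  }
  expect_gte(hits / n_rep, 0.95)
})

test_that("exact lamellar series indexes to the generating lattice", {
  mk_peaks <- function(q, se = 1e-5) {
    structure(data.frame(center = q, center_se = se, width = 0.004,
                         width_se = 1e-4, intensity = 100,
                         intensity_se = 1, order = NA_integer_,
                         lattice_id = NA_integer_),
              class = c("peak_set", "data.frame"),
              q_range = range(q) + c(-0.01, 0.01), x_D2O = 0.08)
  }
  idx <- index_lattice(mk_peaks(2 * pi * (1:4) / 50))
  expect_equal(idx$phase_class, "lamellar")
  expect_equal(idx$lattices[[1]]$D, 50, tolerance = 1e-9)
  expect_equal(idx$peaks$order, 1:4)

  # single peak: first-order assumption, low confidence
  idx1 <- index_lattice(mk_peaks(0.1247))
  expect_equal(idx1$phase_class, "lamellar")
  expect_true(idx1$low_confidence)
  expect_equal(idx1$lattices[[1]]$D, 2 * pi / 0.1247, tolerance = 1e-9)
  expect_equal(idx1$lattices[[1]]$D, 50.38, tolerance = 1e-3)
})

test_that("least-squares D agrees with a brute-force grid search", {
  # oracle: residual-minimising D over a dense grid in [30, 80] A
  set.seed(8)
  for (rep in 1:4) {
    D_true <- runif(1, 35, 70)
    orders <- 1:4
    q <- 2 * pi * orders / D_true
    pk <- structure(data.frame(center = q, center_se = 1e-6, width = 0.004,
                               width_se = 1e-4, intensity = 10,
                               intensity_se = 0.1, order = NA_integer_,
                               lattice_id = NA_integer_),
                    class = c("peak_set", "data.frame"),
                    q_range = range(q) + c(-0.01, 0.01), x_D2O = 0.08)
    D_ls <- index_lattice(pk)$lattices[[1]]$D
    grid <- seq(30, 80, by = 1e-3)
    rss <- vapply(grid, function(Dg)
      sum((q - 2 * pi * round(q * Dg / (2 * pi)) / Dg)^2), 0)
    D_bf <- grid[which.min(rss)]
    D_bf <- optimize(function(Dg)
      sum((q - 2 * pi * round(q * D_bf / (2 * pi)) / Dg)^2),
      c(D_bf - 0.01, D_bf + 0.01), tol = 1e-10)$minimum
    expect_rel_equal(D_ls, D_bf, 1e-6)
    expect_rel_equal(D_ls, D_true, 1e-9)
  }
})

test_that("two interleaved lamellar series are resolved as coexistence", {
  acq <- clean_acq()
  m1 <- bilayer_model(D = 45.2, z_H = 17)
  m2 <- bilayer_model(D = 48.6, z_H = 18)
  d1 <- synthesize_diffractogram(m1, acq)
  d2 <- synthesize_diffractogram(m2, acq)
  d <- diffractogram(d1$q, d1$intensity + d2$intensity,
                     sqrt(d1$sigma^2 + d2$sigma^2), d1$meta)
  idx <- index_lattice(fit_peaks(d))
  expect_equal(idx$phase_class, "coexisting_lamellar")
  Ds <- sort(vapply(idx$lattices, `[[`, 0, "D"))
  expect_lt(abs(Ds[1] - 45.2) / 45.2, 0.005)
  expect_lt(abs(Ds[2] - 48.6) / 48.6, 0.005)
  # every lattice carries at least two orders
  expect_true(all(table(idx$peaks$lattice_id) >= 2))
})

test_that("phase classification follows the position ratios", {
  mk_peaks <- function(q) {
    structure(data.frame(center = q, center_se = 1e-5, width = 0.004,
                         width_se = 1e-4, intensity = 100,
                         intensity_se = 1, order = NA_integer_,
                         lattice_id = NA_integer_),
              class = c("peak_set", "data.frame"),
              q_range = range(q) + c(-0.01, 0.01), x_D2O = 0.08)
  }
  lam <- classify_phase(index_lattice(mk_peaks(0.12 * (1:4))))
  expect_equal(as.character(lam), "lamellar")
  hex <- classify_phase(index_lattice(mk_peaks(
    0.15 * c(1, 1.732, 2.000, 2.646))))
  expect_equal(as.character(hex), "hexagonal")
  expect_match(attr(hex, "rationale"), "sqrt")
  # generated hexagonal scan round-trips through the classifier
  dh <- synthesize_nonlamellar(0.15, acq = clean_acq())
  expect_equal(as.character(classify_phase(index_lattice(fit_peaks(dh)))),
               "hexagonal")
})

test_that("classification is invariant under uniform q rescaling", {
  mk_peaks <- function(q) {
    structure(data.frame(center = q, center_se = 1e-5, width = 0.004,
                         width_se = 1e-4, intensity = 100,
                         intensity_se = 1, order = NA_integer_,
                         lattice_id = NA_integer_),
              class = c("peak_set", "data.frame"),
              q_range = range(q) + c(-0.01, 0.01), x_D2O = 0.08)
  }
  for (u in c(0.8, 1.25)) {
    lam <- index_lattice(mk_peaks(0.12 * (1:4) * u))
    expect_equal(lam$phase_class, "lamellar")
    expect_rel_equal(lam$lattices[[1]]$D, 2 * pi / (0.12 * u), 1e-9)
    hexp <- index_lattice(mk_peaks(0.15 * c(1, sqrt(3), 2, sqrt(7)) * u))
    expect_equal(hexp$phase_class, "hexagonal")
  }
})
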