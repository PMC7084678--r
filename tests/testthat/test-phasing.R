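# Lorentz correction and contrast-variation phasing

mk_indexed_peaks <- function(q, I, I_se = 0.01 * I, orders = seq_along(q),
                             x_D2O = 0.08) {
  structure(data.frame(center = q, center_se = 1e-5, width = 0.004,
                       width_se = 1e-4, intensity = I, intensity_se = I_se,
                       order = orders, lattice_id = 1L),
            class = c("peak_set", "data.frame"),
            q_range = range(q) + c(-0.01, 0.01), x_D2O = x_D2O)
}

test_that("Lorentz correction follows |f| = sqrt(I * q^p)", {
  pk <- mk_indexed_peaks(q = 1, I = 4, orders = 1L)
  sf <- lorentz_correct(pk, p = 1)
  expect_equal(sf$amplitude, 2)
  pk <- mk_indexed_peaks(q = 0.25, I = 4, orders = 1L)
  expect_equal(lorentz_correct(pk, p = 0)$amplitude, 2)
  expect_equal(lorentz_correct(pk, p = 1)$amplitude, 1)
  # SE propagation: SE(|f|) = q^p SE(I) / (2 |f|)
  pk <- mk_indexed_peaks(q = 0.5, I = 8, I_se = 0.4, orders = 1L)
  sf <- lorentz_correct(pk, p = 1)
  expect_equal(sf$se, 0.5 * 0.4 / (2 * 2))
  # negative intensity -> zero amplitude, flagged
  pk <- mk_indexed_peaks(q = c(0.1, 0.2), I = c(9, -1), orders = 1:2)
  sf <- lorentz_correct(pk, p = 1)
  expect_equal(sf$amplitude[2], 0)
  expect_true(sf$flagged[2])
  # unindexed peaks are rejected
  pk$order <- NA_integer_
  expect_error(lorentz_correct(pk), "indexed")
})

test_that("generator q^-1 and correction q^+1 cancel: |f_n| recovered across orders", {
  m <- default_model()
  d <- synthesize_diffractogram(m, clean_acq())
  idx <- index_lattice(fit_peaks(d))
  sf <- lorentz_correct(idx, p = 1, x_D2O = m$x_D2O)
  f_true <- abs(model_form_factors(m, max(sf$order)))[sf$order]
  ratio <- sf$amplitude / (f_true * sqrt(1e12))  # generator a.u. scale
  expect_lt(diff(range(ratio)) / mean(ratio), 1e-4)
})

test_that("affine noiseless amplitudes give perfect per-order lines", {
  # all-positive signed truth: f_n(x) = a_n + b_n x, a_n, b_n > 0
  x <- c(0.08, 0.2, 0.5, 1.0)
  a <- c(5, 4, 3, 2); b <- c(3, 2, 1, 0.5)
  tabs <- lapply(x, function(xx)
    structure(data.frame(order = 1:4, x_D2O = xx,
                         amplitude = a + b * xx, se = NA_real_,
                         flagged = FALSE),
              class = c("sf_table", "data.frame"), p = 1, D = 50))
  ph <- assign_phases(do.call(combine_sf, tabs))
  expect_true(all(ph$fits$r2 > 1 - 1e-10))
  # one consistent sign per order across all contrasts (modulo the global
  # orientation conventions): the signed line never crosses zero here
  expect_true(all(abs(ph$nu) == 1))
  expect_true(all(ph$fits$amp_ref > 0))
})

test_that("default synthetic contrast series yields phases (-, -, +, -)", {
  m <- default_model()
  sf <- sf_from_truth(m, c(0.08, 0.2, 0.5, 1.0))
  ph <- assign_phases(sf)
  expect_equal(unname(ph$nu), c(-1, -1, 1, -1))
  expect_true(all(ph$fits$r2 > 1 - 1e-9))
  # signs equal the analytic signs of the form factors at the reference
  expect_equal(unname(ph$nu), unname(analytic_signs(m)))
  # boundary estimate recovers the true lipid/water boundary
  expect_equal(ph$boundary_c, m$z_H, tolerance = 0.1)
})

test_that("sign recovery matches analytic signs on randomized models", {
  set.seed(31)
  n_ok <- 0L; n_tot <- 25L
  for (i in seq_len(n_tot)) {
    m <- random_model()
    sf <- sf_from_truth(m, c(0.08, 0.2, 0.5, 1.0))
    ph <- assign_phases(sf)
    if (all(ph$nu == analytic_signs(m))) n_ok <- n_ok + 1L
  }
  expect_gte(n_ok / n_tot, 0.95)
})

test_that("phase assignment is invariant to uniform amplitude rescaling", {
  m <- default_model()
  sf <- sf_from_truth(m, c(0.08, 0.2, 0.5, 1.0))
  ph1 <- assign_phases(sf)
  sf2 <- sf; sf2$amplitude <- sf2$amplitude * 137
  attr(sf2, "D") <- attr(sf, "D"); attr(sf2, "p") <- attr(sf, "p")
  ph2 <- assign_phases(sf2)
  expect_identical(ph1$nu, ph2$nu)
  expect_equal(ph1$boundary_c, ph2$boundary_c, tolerance = 1e-6)
})

test_that("restricted pattern search equals brute force modulo global sign", {
  # 2^(c-1) patterns with the first sign fixed + span all 2^c patterns up
  # to an overall flip, which leaves the weighted R^2 unchanged
  wls_r2 <- function(x, y) {
    fit <- lm(y ~ x)
    summary(fit)$r.squared
  }
  set.seed(5)
  x <- c(0.08, 0.2, 0.5, 1.0)
  for (rep in 1:20) {
    amp <- abs(rnorm(4, 5, 2))
    pats_half <- expand.grid(rep(list(c(1, -1)), 3))
    best_half <- max(apply(pats_half, 1, function(s)
      wls_r2(x, c(1, s) * amp)))
    pats_full <- expand.grid(rep(list(c(1, -1)), 4))
    best_full <- max(apply(pats_full, 1, function(s)
      wls_r2(x, unlist(s) * amp)))
    expect_equal(best_half, best_full, tolerance = 1e-12)
  }
})

test_that("a single contrast cannot be phased", {
  m <- default_model()
  sf <- sf_from_truth(m, 0.08)
  expect_error(assign_phases(sf), "one contrast")
})
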