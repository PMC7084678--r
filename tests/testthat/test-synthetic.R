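# forward model: water SLD, profile, closed-form Fourier coefficients,
# diffractogram synthesis

test_that("water SLD endpoints and contrast match point are correct", {
  # Sum b_coh(H2O) = 2(-3.739) + 5.803 fm over 30 A^3 = -5.583e-7 A^-2
  expect_equal(water_sld(0), -5.5833e-7, tolerance = 1e-4)
  # Sum b_coh(D2O) = 2(6.671) + 5.803 fm over 30 A^3 = 6.3817e-6 A^-2
  expect_equal(water_sld(1), 6.3817e-6, tolerance = 1e-4)
  # zero crossing of the linear mix
  x_match <- 5.5833e-7 / (6.3817e-6 + 5.5833e-7)
  expect_lt(abs(water_sld(x_match)), 1e-10)
  expect_lt(abs(x_match - 0.08), 0.005)
  expect_error(water_sld(-0.1), "0, 1")
  expect_error(water_sld(1.5), "0, 1")
})

test_that("model profile is even, continuous into water, and shaped like a bilayer", {
  set.seed(42)
  for (i in 1:5) {
    m <- random_model()
    z <- seq(0, m$D / 2, length.out = 211)
    expect_identical(model_profile(m, z), model_profile(m, -z))
  }
  m <- default_model()
  # water level beyond the headgroups
  expect_equal(model_profile(m, m$D / 2), water_sld(m$x_D2O),
               tolerance = 1e-3)
  # global maximum near +/- z_H, local minimum at the centre
  z <- seq(-m$D / 2, m$D / 2, by = 0.05)
  rho <- model_profile(m, z)
  expect_equal(abs(z[which.max(rho)]), m$z_H, tolerance = 0.05)
  i0 <- which(z == 0)
  expect_true(all(rho[i0] < rho[c(i0 - 40, i0 + 40)]))
  expect_error(model_profile(m, m$D), "unit cell")
})

test_that("contrast-free model gives a constant profile and zero coefficients", {
  rw <- water_sld(0.2)
  m <- bilayer_model(rho_H = rw, rho_CH = rw, rho_CH3 = rw, x_D2O = 0.2)
  z <- seq(-m$D / 2, m$D / 2, by = 0.5)
  expect_equal(model_profile(m, z), rep(rw, length(z)), tolerance = 1e-12)
  expect_equal(unname(model_form_factors(m, 6)), rep(0, 6),
               tolerance = 1e-20)
})

test_that("closed-form coefficients agree with adaptive quadrature", {
  set.seed(7)
  for (i in 1:8) {
    m <- random_model()
    f <- model_form_factors(m, 8)
    fq <- vapply(1:8, function(n)
      integrate(function(z) model_profile(m, z) * cos(2 * pi * n * z / m$D),
                -m$D / 2, m$D / 2, rel.tol = 1e-10,
                subdivisions = 500L)$value, 0)
    expect_lt(max(abs(f - fq)) / max(abs(f)), 1e-6)
  }
})

test_that("synthesized Bragg peaks sit at 2*pi*n/D with I = f_n^2/q_n", {
  m <- default_model()
  acq <- clean_acq()
  d <- synthesize_diffractogram(m, acq)
  qn <- 2 * pi * (1:4) / m$D
  f <- model_form_factors(m, 4)
  for (n in 1:4) {
    i <- which.min(abs(d$q - qn[n]))
    # peak apex = integrated intensity x Gaussian normalisation
    expect_rel_equal(d$intensity[i],
                     acq$intensity_scale * f[n]^2 / qn[n] *
                       dnorm(d$q[i], qn[n], acq$peak_width), 1e-3)
  }
  expect_equal(d$meta$x_D2O, m$x_D2O)
})

test_that("seeded synthesis is bit-reproducible and seeds differ by fraction", {
  m <- default_model()
  acq <- acquisition_model(noise_scale = 5, seed = 123)
  d1 <- synthesize_diffractogram(m, acq)
  d2 <- synthesize_diffractogram(m, acq)
  expect_identical(d1$intensity, d2$intensity)
  s <- synthesize_contrast_series(m, c(0.08, 1.0), acq)
  expect_false(identical(s[[1]]$intensity, s[[2]]$intensity))
})

test_that("contrast series carries per-fraction metadata regardless of order", {
  m <- default_model()
  acq <- acquisition_model(noise_scale = 3, seed = 5)
  fwd <- synthesize_contrast_series(m, c(0.08, 0.5, 1.0), acq)
  rev <- synthesize_contrast_series(m, c(1.0, 0.5, 0.08), acq)
  expect_equal(vapply(fwd, function(d) d$meta$x_D2O, 0), c(0.08, 0.5, 1.0))
  # same fraction -> identical scan, independent of list position
  expect_identical(fwd[[1]]$intensity, rev[[3]]$intensity)
  expect_identical(fwd[[3]]$intensity, rev[[1]]$intensity)
  expect_error(synthesize_contrast_series(m, numeric(0)), "empty")
})

test_that("signed first-order coefficient is affine in the D2O fraction", {
  m <- default_model()
  x <- c(0.08, 0.2, 0.5, 1.0)
  f1 <- vapply(x, function(xx) {
    m$x_D2O <- xx; model_form_factors(m, 1)[[1]]
  }, 0)
  fit <- lm(f1 ~ x)
  r2 <- 1 - sum(residuals(fit)^2) / sum((f1 - mean(f1))^2)
  expect_gt(r2, 1 - 1e-12)
})

test_that("hexagonal generator places peaks at q1*sqrt(1,3,4,7)", {
  acq <- clean_acq()
  amps <- c(1, 0.6, 0.4, 0.25) * 1e-8
  d <- synthesize_nonlamellar(0.15, amplitudes = amps, acq = acq)
  expected <- 0.15 * sqrt(c(1, 3, 4, 7))
  for (j in seq_along(expected)) {
    i <- which.min(abs(d$q - expected[j]))
    apex <- acq$intensity_scale * amps[j] *
      dnorm(d$q[i], expected[j], acq$peak_width)
    expect_rel_equal(d$intensity[i], apex, 1e-3)
  }
  d0 <- synthesize_nonlamellar(0.15, amplitudes = rep(0, 4),
                               acq = acquisition_model(noise_scale = 0,
                                                       background = 7))
  expect_equal(d0$intensity, rep(7, length(d0$q)))
})

test_that("truth sidecar files round-trip the generating model", {
  m <- random_model()
  path <- withr::local_tempfile(fileext = ".txt")
  write_truth(m, path)
  m2 <- read_truth(path)
  expect_equal(m2$D, m$D, tolerance = 1e-12)
  expect_equal(m2$z_H, m$z_H, tolerance = 1e-12)
  expect_equal(m2$rho_CH3, m$rho_CH3, tolerance = 1e-12)
  expect_equal(m2$D_B_true, m$D_B_true, tolerance = 1e-12)
})
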