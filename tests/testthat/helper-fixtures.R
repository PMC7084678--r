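# shared fixtures: all synthetic, built in code

default_model <- function(...) bilayer_model(...)

clean_acq <- function(...) acquisition_model(noise_scale = 0, ...)

# noise_scale giving a target relative noise at the strongest Bragg peak
noise_for_relative <- function(model, acq, rel = 0.01) {
  acq$noise_scale <- 0
  clean <- synthesize_diffractogram(model, acq)
  rel * sqrt(max(clean$intensity))
}

# a randomized but physically sensible bilayer model
random_model <- function() {
  D <- runif(1, 42, 60)
  r <- runif(1, 0.30, 0.42)
  bilayer_model(D = D, z_H = r * D, sigma_H = runif(1, 2, 4),
                rho_H = runif(1, 1.5, 3) * 1e-6,
                rho_CH = runif(1, -0.6, -0.2) * 1e-6,
                rho_CH3 = runif(1, -1.4, -0.7) * 1e-6,
                sigma_CH3 = runif(1, 2, 4))
}

# structure-factor table built from the analytic (closed-form) form
# factors of a model, bypassing the reduction stage
sf_from_truth <- function(model, fractions, orders = 1:4, p = 1) {
  tabs <- lapply(fractions, function(x) {
    m <- model; m$x_D2O <- x
    f <- model_form_factors(m, orders)
    structure(data.frame(order = orders, x_D2O = x, amplitude = abs(f),
                         se = NA_real_, flagged = FALSE),
              class = c("sf_table", "data.frame"), p = p, D = model$D)
  })
  if (length(tabs) == 1L) tabs[[1]] else do.call(combine_sf, tabs)
}

analytic_signs <- function(model, x_ref = 0.08, orders = 1:4) {
  m <- model; m$x_D2O <- x_ref
  ifelse(model_form_factors(m, orders) >= 0, 1L, -1L)
}

expect_rel_equal <- function(object, expected, rel) {
  expect_lt(abs(object - expected) / abs(expected), rel)
}
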