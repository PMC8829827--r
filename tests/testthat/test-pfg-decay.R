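test_that("b-factor follows the bipolar-pair law", {
  p <- ref_pulse()
  expect_equal(b_factor(p, 0), 0)
  # hand evaluation of (gamma g delta)^2 (Delta - delta/3 - tau/2) at
  # g = 2.65 T/m, delta = 2 ms, Delta = 20 ms, tau = 0.2 ms
  expect_equal(b_factor(p, 2.65), 2.70e9, tolerance = 5e-3)
  expect_equal(b_factor(p, 2), 4 * b_factor(p, 1))
  expect_error(pulse_params(delta = 60e-3, Delta = 20e-3),
               "effective diffusion time")
})

test_that("attenuation reproduces the strong- vs conventional-gradient bounds", {
  p <- ref_pulse()
  D <- diffusion_to_si(0.883)
  expect_equal(attenuation(D, p, 0), 1)
  expect_gte(1 - attenuation(D, p, gradient_to_si(265)), 0.85)
  expect_lte(1 - attenuation(D, p, gradient_to_si(55)), 0.10)
  # monotone decreasing in D and in g
  Ds <- seq(0.1e-9, 2e-9, length.out = 7)
  expect_true(all(diff(attenuation(Ds[1], p, seq(0.1, 2.65, length.out = 9))) < 0))
  expect_true(all(diff(sapply(Ds, attenuation, params = p, g = 1)) < 0))
  # longer encoding attenuates more
  p2 <- pulse_params(delta = 3e-3, Delta = 20e-3)
  expect_lt(attenuation(1e-9, p2, 1), attenuation(1e-9, p, 1))
})

test_that("fit_diffusion recovers noiseless data and matches the two-point closed form", {
  p <- ref_pulse()
  g <- default_gradient_grid()
  series <- gen_decay_series(1.0e-9, p, g, noise_model(sigma = 0))
  fit <- fit_diffusion(series)
  expect_equal(fit$D, 1.0e-9, tolerance = 1e-6)
  expect_true(fit$converged)
  expect_length(fit$residuals, nrow(series))

  # algebraic oracle: on exact data, D = ln(I1/I2)/(b2 - b1) for any pair
  b <- b_factor(p, series$g)
  D_closed <- log(series$I[1] / series$I[20]) / (b[20] - b[1])
  expect_equal(fit$D, D_closed, tolerance = 1e-10)

  # scale invariance: intensity units do not affect D
  series2 <- series
  series2$I <- series$I * 1234.5
  fit2 <- fit_diffusion(series2)
  expect_equal(fit2$D, fit$D, tolerance = 1e-10)
  expect_equal(fit2$I0, fit$I0 * 1234.5, tolerance = 1e-6)

  # residuals of ln I vs b have zero slope under the fitted parameters
  lnres <- log(series$I) - (log(fit$I0) - fit$D * b)
  slope <- stats::coef(stats::lm(lnres ~ b))[[2]]
  expect_lt(abs(slope), 1e-8)

  expect_error(decay_series(c(1, 1, 1), c(1, 2, 3), p), "distinct")
})

test_that("fit_diffusion recovers the buffer diffusion coefficient under noise", {
  p <- ref_pulse()
  g <- default_gradient_grid(25)
  Ds <- vapply(1:100, function(s) {
    series <- gen_decay_series(1.251e-9, p, g,
                               noise_model(sigma = 0.01, seed = s, n_replicates = 1))
    fit_diffusion(series)$D
  }, numeric(1))
  expect_equal(mean(Ds), 1.251e-9, tolerance = 0.02)
})

test_that("replicate fits report mean and SEM; pooled mode fits jointly", {
  p <- ref_pulse()
  series <- gen_decay_series(1.0e-9, p, noise = noise_model(sigma = 0.01, seed = 3))
  fit <- fit_diffusion(series)
  expect_length(fit$replicate_D, 3)
  expect_equal(fit$D, mean(fit$replicate_D))
  expect_equal(fit$se_D, stats::sd(fit$replicate_D) / sqrt(3))
  pooled <- fit_diffusion(series, replicates = "pooled")
  expect_equal(pooled$D, fit$D, tolerance = 0.05)
})

test_that("gradient calibration returns the quadratic scale factor", {
  p <- ref_pulse()
  D_ref <- diffusion_to_si(1.63)  # DMF self-diffusion standard
  series <- gen_decay_series(D_ref, p, noise = noise_model(sigma = 0))
  expect_equal(calibrate_gradient(series, D_ref)$scale, 1, tolerance = 1e-6)
  # gradients overstated by 10%: simulate with true gradients 1.1x nominal
  g_nom <- default_gradient_grid()
  truth <- attenuation(D_ref, p, 1.1 * g_nom)
  series_over <- decay_series(g_nom, truth, p)
  expect_equal(calibrate_gradient(series_over, D_ref)$scale, 1.1,
               tolerance = 1e-6)
  expect_equal(calibrate_gradient(
    decay_series(g_nom, attenuation(4 * D_ref, p, g_nom), p), D_ref)$scale,
    2, tolerance = 1e-6)
})

test_that("storage-delay decay fits a monoexponential", {
  TL <- seq(0.005, 0.3, length.out = 8)
  fit <- fit_storage_decay(TL, 50 * exp(-20 * TL))
  expect_equal(fit$rate, 20, tolerance = 1e-6)
  expect_equal(fit_storage_decay(TL, rep(7, 8))$rate, 0, tolerance = 1e-8)
  # two-point closed form on exact data
  closed <- log((50 * exp(-20 * TL[1])) / (50 * exp(-20 * TL[8]))) / (TL[8] - TL[1])
  expect_equal(fit$rate, closed, tolerance = 1e-10)
  expect_error(fit_storage_decay(TL, -TL), "positive")
  expect_error(fit_storage_decay(TL[1:2], c(1, 2)), "3 points")
})
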