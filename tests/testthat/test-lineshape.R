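test_that("the Lorentzian parameterization reads out R2 directly", {
  f <- seq(-200, 200, length.out = 1001)
  y <- lorentzian(f, 0, pi * 10, area = 2)  # FWHM 10 Hz
  # peak height 2A/(pi w)
  expect_equal(max(y), 2 * 2 / (pi * 10), tolerance = 1e-6)
  # half maximum at +/- FWHM/2
  expect_equal(lorentzian(5, 0, pi * 10, 2), max(y) / 2, tolerance = 1e-9)
  # area by trapezoid over a wide window approaches A
  wide <- seq(-5e4, 5e4, length.out = 2e5)
  yw <- lorentzian(wide, 0, pi * 10, 2)
  expect_equal(sum(yw) * diff(wide)[1], 2, tolerance = 1e-3)
})

test_that("a single synthetic line is fitted to R2 = pi x FWHM", {
  f <- seq(-200, 200, length.out = 512)
  spec <- gen_spectrum(data.frame(center = 3, R2 = pi * 10, area = 1.7), f)
  fit <- fit_lorentzians(spec, init_centers = 0)
  expect_equal(fit$components$R2, pi * 10, tolerance = 1e-6)
  expect_equal(fit$components$center, 3, tolerance = 1e-6)
  expect_equal(fit$components$area, 1.7, tolerance = 1e-6)
  expect_true(fit$converged)
  expect_false(fit$flagged_overlap)
  # a buffer-like line generated at the free-state rate is recovered
  spec_f <- gen_spectrum(data.frame(center = 0, R2 = ref$R_f, area = 1), f)
  fit_f <- fit_lorentzians(spec_f, 0)
  expect_equal(fit_f$components$R2, ref$R_f, tolerance = 1e-6)
})

test_that("R2 is invariant and area covariant under intensity scaling", {
  f <- seq(-150, 150, length.out = 400)
  spec <- gen_spectrum(data.frame(center = -5, R2 = 40, area = 1), f)
  spec2 <- spectrum1d(spec$freq, spec$intensity * 250)
  f1 <- fit_lorentzians(spec, -5)
  f2 <- fit_lorentzians(spec2, -5)
  expect_equal(f2$components$R2, f1$components$R2, tolerance = 1e-6)
  expect_equal(f2$components$area, 250 * f1$components$area, tolerance = 1e-6)
})

test_that("two coaxial-like lines are resolved and recovered under noise", {
  # two signals separated by 1.857 ppm at a 198 MHz carrier (~368 Hz), one
  # buffer-like and one reference-like in width
  sep <- 1.857e-6 * 198e6
  comps <- data.frame(center = c(0, sep), R2 = c(55, 25), area = c(1, 0.6))
  f <- seq(-400, 800, length.out = 1024)
  R2s <- sapply(1:20, function(s) {
    spec <- gen_spectrum(comps, f,
                         noise_model("absolute-gaussian",
                                     sigma = 0.01 * 2 * 1 / (pi * 55 / pi),
                                     seed = s))
    fit <- fit_lorentzians(spec, init_centers = c(0, sep))
    fit$components$R2
  })
  expect_equal(mean(R2s[1, ]), 55, tolerance = 0.01)
  expect_equal(mean(R2s[2, ]), 25, tolerance = 0.01)
})

test_that("the apparent R2 model is the two-state population average", {
  pars <- r2_exchange_params(ref$R_f, ref$R_b, ref$a, ref$Na_buffer)
  expect_equal(r2_apparent_model(pars, 0), ref$R_f)
  # at the top of the titration the model sits near the printed upper band
  expect_equal(r2_apparent_model(pars, 1.74e-3), 55.7, tolerance = 1e-3)
  # the model span over the measured concentrations covers the printed
  # observation band 30.5-54.4 s^-1
  span <- r2_apparent_model(pars, range(default_dna_concentrations()))
  expect_lt(span[1], 30.5)
  expect_gt(span[2], 54.4)
  expect_true(all(diff(r2_apparent_model(pars, default_dna_concentrations())) > 0))
  flat <- r2_exchange_params(ref$R_f, ref$R_f, ref$a, ref$Na_buffer)
  expect_equal(r2_apparent_model(flat, default_dna_concentrations()),
               rep(ref$R_f, 8))
  expect_warning(r2_exchange_params(20, 10, 25, 0.02), "unusual")
})

test_that("R_b is recovered by the one-parameter titration fit", {
  pars <- r2_exchange_params(ref$R_f, ref$R_b, ref$a, ref$Na_buffer)
  tit <- gen_r2_titration(pars, noise = noise_model(sigma = 0))
  fit <- fit_Rb(tit$C_M, tit$R2_app, ref$R_f, ref$a, ref$Na_buffer)
  expect_equal(fit$estimate, ref$R_b, tolerance = 1e-6)
  expect_true(fit$converged)
  # grid-search oracle within one grid step
  grid <- seq(ref$R_f, 200, by = 0.01)
  loss <- function(Rb) {
    pb <- ref$a * tit$C_M / (ref$Na_buffer + ref$a * tit$C_M)
    sum((tit$R2_app - ((1 - pb) * ref$R_f + pb * Rb))^2)
  }
  expect_lt(abs(fit$estimate - grid_argmin(grid, loss)), 0.01 + 1e-9)
})
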