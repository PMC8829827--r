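test_that("generators are deterministic in the seed", {
  p <- ref_pulse()
  nm <- noise_model(sigma = 0.02, seed = 123)
  a <- gen_decay_series(1e-9, p, noise = nm)
  b <- gen_decay_series(1e-9, p, noise = nm)
  expect_identical(a$I, b$I)
  c <- gen_decay_series(1e-9, p, noise = noise_model(sigma = 0.02, seed = 124))
  expect_false(identical(a$I, c$I))
  ex <- exchange_params(ref$D_f, ref$D_b, ref$a, ref$Na_buffer)
  expect_identical(gen_dna_titration(ex, noise = nm),
                   gen_dna_titration(ex, noise = nm))
})

test_that("generators do not disturb the global random stream", {
  set.seed(55)
  expected <- rnorm(3)
  set.seed(55)
  invisible(gen_quant_series(25.5, 0.020,
                             noise = noise_model(sigma = 0.01, seed = 999)))
  expect_identical(rnorm(3), expected)
})

test_that("zero-noise output of every generator round-trips through its fitter", {
  p <- ref_pulse()
  quiet <- noise_model(sigma = 0)

  dec <- gen_decay_series(1.251e-9, p, noise = quiet)
  expect_equal(fit_diffusion(dec)$D, 1.251e-9, tolerance = 1e-6)

  ex <- exchange_params(ref$D_f, ref$D_b, ref$a, ref$Na_buffer)
  tit <- gen_dna_titration(ex, noise = quiet)
  expect_equal(fit_Db(tit$C_M, tit$D_app, ref$D_f, ref$a, ref$Na_buffer)$estimate,
               ref$D_b, tolerance = 1e-6)
  expect_equal(gen_dna_titration(ex, 0, quiet)$D_app, ref$D_f)

  sys <- competition_system(ref$Na_total, 0, ref$T_cap, ref$Q, ref$D_f, ref$D_b)
  comp <- gen_competition_series(sys, seq(0, 0.15, length.out = 10), quiet)
  expect_equal(fit_Q(comp$K_total, comp$D_app, ref$Na_total, ref$T_cap,
                     ref$D_f, ref$D_b)$estimate, ref$Q, tolerance = 1e-6)

  qs <- gen_quant_series(25.5, 0.020, noise = quiet)
  expect_equal(fit_ion_excess(qs$C_M, qs$Na_total)$a, 25.5, tolerance = 1e-6)

  f <- seq(-200, 200, length.out = 512)
  spec <- gen_spectrum(data.frame(center = 0, R2 = 31, area = 1), f)
  expect_equal(fit_lorentzians(spec, 0)$components$R2, 31, tolerance = 1e-6)

  r2p <- r2_exchange_params(ref$R_f, ref$R_b, ref$a, ref$Na_buffer)
  r2t <- gen_r2_titration(r2p, noise = quiet)
  expect_equal(fit_Rb(r2t$C_M, r2t$R2_app, ref$R_f, ref$a, ref$Na_buffer)$estimate,
               ref$R_b, tolerance = 1e-6)
})

test_that("noisy replicate means converge to the noiseless curve", {
  p <- ref_pulse()
  g <- default_gradient_grid(10)
  truth <- attenuation(1e-9, p, g)
  series <- gen_decay_series(1e-9, p, g,
                             noise_model(sigma = 0.05, seed = 2,
                                         n_replicates = 400))
  means <- tapply(series$I, series$g, mean)
  means <- means[match(as.character(g), names(means))]
  # law of large numbers: within 4 sigma/sqrt(n) of the truth, per point
  expect_true(all(abs(means - truth) < 4 * 0.05 * truth / sqrt(400)))
})

test_that("generated curves carry the model's monotone structure before noise", {
  ex <- exchange_params(ref$D_f, ref$D_b, ref$a, ref$Na_buffer)
  quiet <- noise_model(sigma = 0)
  expect_true(all(diff(gen_dna_titration(ex, noise = quiet)$D_app) < 0))
  sys <- competition_system(ref$Na_total, 0, ref$T_cap, ref$Q, ref$D_f, ref$D_b)
  expect_true(all(diff(gen_competition_series(sys, seq(0, 0.15, length.out = 8),
                                              quiet)$D_app) > 0))
  r2p <- r2_exchange_params(ref$R_f, ref$R_b, ref$a, ref$Na_buffer)
  expect_true(all(diff(gen_r2_titration(r2p, noise = quiet)$R2_app) > 0))
  quant <- gen_quant_series(25.5, 0.020, noise = quiet)
  expect_equal(quant$Na_total[1], 0.020 + 25.5 * quant$C_M[1])
})

test_that("the default gradient grid spans the strong-gradient experiment", {
  g <- default_gradient_grid()
  expect_length(g, 25)
  expect_equal(gradient_from_si(range(g)), c(2, 265))
  expect_equal(conc_from_si(range(default_dna_concentrations())), c(0.21, 1.74))
})
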