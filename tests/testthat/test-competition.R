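ref_comp <- function(K = 0.100, Q = ref$Q) {
  competition_system(ref$Na_total, K, ref$T_cap, Q, ref$D_f, ref$D_b)
}

test_that("zero competitor fills the atmosphere with the probed cation", {
  sys <- ref_comp(K = 0)
  expect_equal(bound_sodium(sys), ref$T_cap)
  # and the apparent D equals the single-cation two-state prediction
  ex <- exchange_params(ref$D_f, ref$D_b, ref$a, ref$Na_buffer)
  expect_equal(apparent_D_competition(sys), apparent_D(ex, ref$C_M_max),
               tolerance = 1e-10)
})

test_that("no-preference and preferred-competitor solutions match hand values", {
  # Q = 1: N_b = Na T / (Na + K)
  sys1 <- ref_comp(Q = 1)
  expect_equal(conc_from_si(bound_sodium(sys1)),
               64.37 * 44.37 / 164.37, tolerance = 1e-9)
  # Q = 0.58 at 100 mM competitor: bisection oracle gives about 13.3 mM
  sys <- ref_comp()
  expect_equal(bound_sodium(sys),
               bisect_bound(ref$Na_total, 0.100, ref$T_cap, ref$Q),
               tolerance = 1e-9)
  expect_equal(conc_from_si(bound_sodium(sys)), 13.3, tolerance = 3e-3)
  expect_equal(diffusion_from_si(apparent_D_competition(sys)), 1.14,
               tolerance = 2e-3)
})

test_that("the quadratic closed form agrees with the bisection oracle on a grid", {
  Qs <- exp(seq(log(0.05), log(20), length.out = 10))
  Ks <- seq(0.005, 0.3, length.out = 10)
  Ts <- seq(0.002, 0.06, length.out = 10)
  for (Q in Qs) for (K in Ks) for (T_cap in Ts) {
    got <- iondiff:::solve_bound(ref$Na_total, K, T_cap, Q)
    want <- bisect_bound(ref$Na_total, K, T_cap, Q)
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("the solver is continuous across Q = 1 and conserves mass", {
  for (dQ in c(-1e-10, 1e-10)) {
    near <- iondiff:::solve_bound(ref$Na_total, 0.1, ref$T_cap, 1 + dQ)
    at1 <- iondiff:::solve_bound(ref$Na_total, 0.1, ref$T_cap, 1)
    expect_equal(near, at1, tolerance = 1e-9)
  }
  # conservation and physical bounds over assorted systems
  set.seed(7)
  for (i in 1:25) {
    Q <- exp(runif(1, log(0.1), log(10)))
    K <- runif(1, 0.001, 0.2)
    T_cap <- runif(1, 0.001, 0.05)
    Nb <- iondiff:::solve_bound(ref$Na_total, K, T_cap, Q)
    Kb <- T_cap - Nb
    expect_gte(Nb, 0); expect_lte(Nb, min(T_cap, ref$Na_total))
    expect_gte(Kb, -1e-12); expect_lte(Kb, K + 1e-12)
  }
})

test_that("species relabeling inverts the quotient", {
  # the competitor's bound share under quotient 1/Q with the roles swapped
  # must complement the probed cation's share to the full capacity
  for (Q in c(0.3, 0.58, 1.89, 4)) {
    Nb <- iondiff:::solve_bound(ref$Na_total, 0.1, ref$T_cap, Q)
    Kb <- iondiff:::solve_bound(0.1, ref$Na_total, ref$T_cap, 1 / Q)
    expect_equal(Nb + Kb, ref$T_cap, tolerance = 1e-9)
  }
})

test_that("apparent D rises with competitor and approaches the free value", {
  K_grid <- seq(0, 0.15, length.out = 10)
  sys <- ref_comp(K = K_grid)
  Dv <- apparent_D_competition(sys)
  expect_true(all(diff(Dv) > 0))
  sys_inf <- ref_comp(K = 100)
  expect_equal(apparent_D_competition(sys_inf), ref$D_f, tolerance = 1e-3)
  # larger atmosphere capacity slows apparent diffusion
  sys_big <- competition_system(ref$Na_total, 0.1, 1.2 * ref$T_cap, ref$Q,
                                ref$D_f, ref$D_b)
  expect_lt(apparent_D_competition(sys_big), apparent_D_competition(ref_comp()))
})

test_that("the preference quotient is recovered by the one-parameter fit", {
  K_grid <- seq(0, 0.15, length.out = 10)
  sys <- ref_comp(K = 0)
  ser <- gen_competition_series(sys, K_grid, noise_model(sigma = 0))
  fit <- fit_Q(ser$K_total, ser$D_app, ref$Na_total, ref$T_cap,
               ref$D_f, ref$D_b)
  expect_equal(fit$estimate, ref$Q, tolerance = 1e-6)
  expect_true(fit$converged)
  expect_false(fit$at_bounds)
  # a series generated with the reciprocal quotient fits to the reciprocal:
  # measuring the other species of the same pair reports 1/Q
  ser_r <- gen_competition_series(
    competition_system(ref$Na_total, 0, ref$T_cap, 1 / ref$Q, ref$D_f, ref$D_b),
    K_grid, noise_model(sigma = 0))
  fit_r <- fit_Q(ser_r$K_total, ser_r$D_app, ref$Na_total, ref$T_cap,
                 ref$D_f, ref$D_b)
  expect_equal(fit_r$estimate, 1 / ref$Q, tolerance = 1e-6)
})

test_that("invalid competition systems are rejected", {
  expect_error(competition_system(0.064, 0.1, 0.2, 0.58, 1.2e-9, 0.7e-9),
               "total cation pool")
  expect_error(competition_system(0.064, 0.1, 0.04, -1, 1.2e-9, 0.7e-9),
               "positive")
})
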