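#' Two-cation competition system for the ion atmosphere
#'
#' Parameters of the mass-balance model for two monovalent cations (here
#' written as Na+ and K+) competing for the ion atmosphere of a
#' polyelectrolyte. The atmosphere is assumed to hold a fixed total of
#' `T_capacity` = n_c x \[macromolecule\] monovalent cations at every
#' competitor concentration (the counterion-condensation assumption), and
#' the relative preference is expressed by the equilibrium quotient
#' Q = (\[Na_b\]\[K_f\]) / (\[Na_f\]\[K_b\]); Q < 1 means the atmosphere
#' prefers the competitor.
#'
#' @param Na_total total probed-cation concentration, mol/L
#' @param K_total total competitor concentration (added salt), mol/L
#' @param T_capacity atmosphere capacity n_c x \[macromolecule\], mol/L;
#'   must be below Na_total + K_total
#' @param Q preference quotient, > 0
#' @param D_f,D_b free and atmosphere diffusion coefficients, m^2/s
#' @return object of class `competition_system`
#' @export
competition_system <- function(Na_total, K_total, T_capacity, Q, D_f, D_b) {
  stopifnot(is.numeric(Na_total), is.numeric(K_total), is.numeric(T_capacity),
            is.numeric(Q), is.numeric(D_f), is.numeric(D_b))
  if (Q <= 0) stop("Q must be positive", call. = FALSE)
  if (T_capacity < 0) stop("T_capacity must be non-negative", call. = FALSE)
  if (any(T_capacity >= Na_total + K_total)) {
    stop("T_capacity must be below the total cation pool Na_total + K_total",
         call. = FALSE)
  }
  if (D_b <= 0 || D_b > D_f) stop("require 0 < D_b <= D_f", call. = FALSE)
  structure(list(Na_total = Na_total, K_total = K_total,
                 T_capacity = T_capacity, Q = Q, D_f = D_f, D_b = D_b),
            class = "competition_system")
}

# Core mass-balance solution, vectorized over K_total. The equilibrium
# Q = (N_b K_f)/(N_f K_b) with the balances N_b + N_f = Na, K_b + K_f = K,
# N_b + K_b = T reduces to (C/T) N_b^2 + B N_b - Na T = 0 with
# C = T (1/Q - 1) and B = Na + K/Q - C. Near Q = 1 the quadratic degenerates
# and the linear branch N_b = Na T / B is used.
solve_bound <- function(Na, K, T_cap, Q, tol_Q1 = 1e-10) {
  n <- max(length(K), 1L)
  K <- rep_len(K, n)
  out <- numeric(n)
  for (i in seq_len(n)) {
    Ki <- K[i]
    if (T_cap == 0) { out[i] <- 0; next }
    if (Ki == 0) { out[i] <- T_cap; next }
    Cc <- T_cap * (1 / Q - 1)
    B <- Na + Ki / Q - Cc
    if (abs(Q - 1) < tol_Q1) {
      out[i] <- Na * T_cap / B
      next
    }
    a <- Cc / T_cap
    c <- -Na * T_cap
    disc <- B^2 - 4 * a * c
    if (disc < 0) stop("no real root: inconsistent competition inputs", call. = FALSE)
    # numerically stable quadratic roots
    q <- -0.5 * (B + sign(B) * sqrt(disc))
    roots <- c(q / a, c / q)
    upper <- min(T_cap, Na)
    eps <- 1e-9 * max(upper, 1e-12)
    ok <- roots >= -eps & roots <= upper + eps
    if (!any(ok)) stop("no root in the physical interval [0, min(T, Na_total)]",
                       call. = FALSE)
    out[i] <- min(max(roots[ok][1], 0), upper)
  }
  out
}

#' Bound probed-cation concentration under two-cation competition
#'
#' Solves the quadratic mass balance for the concentration of the probed
#' cation held in the ion atmosphere given the preference quotient Q and
#' a fixed atmosphere capacity. At zero competitor the atmosphere is
#' entirely probed cation (N_b = T_capacity), recovering the single-cation
#' population model.
#'
#' @param system a [competition_system()] object
#' @return bound concentration(s), mol/L, one per `K_total` value; always
#'   within \[0, min(T_capacity, Na_total)\]
#' @export
bound_sodium <- function(system) {
  stopifnot(inherits(system, "competition_system"))
  solve_bound(system$Na_total, system$K_total, system$T_capacity, system$Q)
}

#' Apparent diffusion coefficient in the presence of a competitor cation
#'
#' D_app = D_f - (D_f - D_b) N_b / Na_total, with N_b from the competition
#' mass balance. Monotone non-decreasing in the competitor concentration:
#' added competitor displaces probed cations from the atmosphere into the
#' faster free state.
#'
#' @param system a [competition_system()] object
#' @return apparent diffusion coefficient(s), m^2/s
#' @export
apparent_D_competition <- function(system) {
  Nb <- bound_sodium(system)
  system$D_f - (system$D_f - system$D_b) * Nb / system$Na_total
}

#' Fit the cation preference quotient from a competitor titration
#'
#' One-parameter nonlinear least squares for Q against apparent diffusion
#' coefficients measured at a series of competitor concentrations, with
#' Na_total, the atmosphere capacity, D_f and D_b fixed at their
#' independently measured values.
#'
#' @param K_total competitor concentrations, mol/L (>= 2 points)
#' @param D_app measured apparent diffusion coefficients, m^2/s
#' @param Na_total total probed-cation concentration, mol/L
#' @param T_capacity atmosphere capacity n_c x \[macromolecule\], mol/L
#' @param D_f,D_b free and atmosphere diffusion coefficients, m^2/s
#' @param se_D optional standard errors for weighting
#' @param weighting `"none"` or `"inverse-variance"`
#' @param bootstrap residual-bootstrap resamples for the SE (0 = none)
#' @param seed bootstrap seed
#' @return object of class `fit_result` with `estimate` = Q
#' @export
fit_Q <- function(K_total, D_app, Na_total, T_capacity, D_f, D_b,
                  se_D = NULL, weighting = c("none", "inverse-variance"),
                  bootstrap = 0, seed = 1L) {
  weighting <- match.arg(weighting)
  stopifnot(length(K_total) == length(D_app))
  if (length(K_total) < 2L) stop("at least 2 competitor points required", call. = FALSE)
  model <- function(Q, K) {
    Nb <- solve_bound(Na_total, K, T_capacity, Q)
    D_f - (D_f - D_b) * Nb / Na_total
  }
  w <- NULL
  if (weighting == "inverse-variance") {
    if (is.null(se_D)) stop("inverse-variance weighting requires se_D", call. = FALSE)
    w <- 1 / se_D^2
  }
  one_fit <- function(y) {
    args <- list(y ~ model(Q, K_total),
                 data = list(y = y, K_total = K_total),
                 start = list(Q = 1),
                 lower = c(Q = 1e-4), upper = c(Q = 1e4),
                 control = minpack.lm::nls.lm.control(maxiter = 200))
    if (!is.null(w)) args$weights <- w
    do.call(minpack.lm::nlsLM, args)
  }
  fit <- one_fit(D_app)
  est <- unname(stats::coef(fit)[["Q"]])
  se <- tryCatch(summary(fit)$coefficients["Q", "Std. Error"],
                 error = function(e) NA_real_)
  resid <- D_app - model(est, K_total)
  se_boot <- NA_real_
  if (bootstrap > 0) {
    set.seed(seed)
    boots <- replicate(bootstrap, {
      y <- model(est, K_total) + sample(resid, replace = TRUE)
      unname(stats::coef(one_fit(y))[["Q"]])
    })
    se_boot <- stats::sd(boots)
  }
  structure(list(estimate = est, se = unname(se), se_boot = se_boot,
                 residuals = resid, converged = fit$convInfo$isConv,
                 at_bounds = est <= 1.01e-4 || est >= 0.99e4,
                 parameter = "Q"),
            class = "fit_result")
}
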