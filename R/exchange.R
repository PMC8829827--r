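#' Two-state fast-exchange parameters
#'
#' State of the two-state model for cations exchanging between the free
#' solution and the ion atmosphere of a macromolecule: free and bound
#' diffusion coefficients, the number of atmosphere cations per
#' macromolecule, and the buffer cation concentration.
#'
#' @param D_f free-ion diffusion coefficient, m^2/s
#' @param D_b ion-atmosphere diffusion coefficient, m^2/s; must satisfy
#'   0 < D_b <= D_f (territorially bound ions are never faster than free)
#' @param a atmosphere cations per macromolecule (>= 0)
#' @param Na_buffer buffer cation concentration, mol/L
#' @return object of class `exchange_params`
#' @export
exchange_params <- function(D_f, D_b, a, Na_buffer) {
  stopifnot(is.numeric(D_f), is.numeric(D_b), is.numeric(a), is.numeric(Na_buffer))
  if (D_b <= 0 || D_f <= 0) stop("diffusion coefficients must be positive", call. = FALSE)
  if (D_b > D_f) stop("D_b must not exceed D_f", call. = FALSE)
  if (a < 0) stop("a must be non-negative", call. = FALSE)
  if (Na_buffer < 0) stop("Na_buffer must be non-negative", call. = FALSE)
  structure(list(D_f = D_f, D_b = D_b, a = a, Na_buffer = Na_buffer),
            class = "exchange_params")
}

#' Bound-state population of the two-state exchange model
#'
#' In a solution where the probed cation is the only cation species, the
#' atmosphere holds a C_M of the Na_buffer + a C_M total, so
#' p_b = a C_M / (Na_buffer + a C_M).
#'
#' @param params an [exchange_params()] object (only `a` and `Na_buffer`
#'   are used)
#' @param C_M macromolecule concentration(s), mol/L
#' @return bound fraction(s) in \[0, 1)
#' @export
p_bound <- function(params, C_M) {
  stopifnot(inherits(params, "exchange_params"), is.numeric(C_M), all(C_M >= 0))
  denom <- params$Na_buffer + params$a * C_M
  if (any(denom == 0)) stop("total cation concentration is zero", call. = FALSE)
  params$a * C_M / denom
}

#' Apparent diffusion coefficient under fast exchange
#'
#' The population-weighted average D_app = p_f D_f + p_b D_b, the observable
#' when exchange between the free state and the ion atmosphere is fast on
#' the diffusion timescale.
#'
#' @inheritParams p_bound
#' @return apparent diffusion coefficient(s), m^2/s, always within
#'   \[D_b, D_f\]
#' @examples
#' pars <- exchange_params(1.251e-9, 0.71e-9, 25.5, 0.020)
#' diffusion_from_si(apparent_D(pars, 1.52e-3))  # about 0.894
#' @export
apparent_D <- function(params, C_M) {
  pb <- p_bound(params, C_M)
  (1 - pb) * params$D_f + pb * params$D_b
}

#' Fit the ion-atmosphere diffusion coefficient from a titration
#'
#' One-parameter nonlinear least squares for D_b in the two-state
#' fast-exchange model, with D_f and the ion count a fixed at their
#' independently measured values (D_f is measured directly on the buffer;
#' a comes from ion quantification). Optional inverse-variance weighting by
#' the per-point standard errors, and an optional seeded residual bootstrap
#' for the standard error.
#'
#' @param C_M macromolecule concentrations, mol/L (>= 2 distinct)
#' @param D_app measured apparent diffusion coefficients, m^2/s
#' @param D_f free-ion diffusion coefficient, m^2/s (measured, not fitted)
#' @param a atmosphere cations per macromolecule (measured upstream)
#' @param Na_buffer buffer cation concentration, mol/L
#' @param se_D optional standard errors of `D_app` for weighting
#' @param weighting `"none"` or `"inverse-variance"`
#' @param bootstrap number of residual-bootstrap resamples for the SE
#'   (0 = covariance-based SE only)
#' @param seed seed for the bootstrap
#' @return object of class `fit_result`: list with `estimate` (D_b, m^2/s),
#'   `se`, `se_boot` (NA unless bootstrapped), `residuals`, `converged`,
#'   `at_bounds`, `parameter`
#' @export
fit_Db <- function(C_M, D_app, D_f, a, Na_buffer, se_D = NULL,
                   weighting = c("none", "inverse-variance"),
                   bootstrap = 0, seed = 1L) {
  weighting <- match.arg(weighting)
  stopifnot(is.numeric(C_M), is.numeric(D_app), length(C_M) == length(D_app))
  if (length(unique(C_M)) < 2L) stop("at least 2 distinct concentrations required", call. = FALSE)
  model <- function(Db, C) {
    pars <- list(D_f = D_f, D_b = Db, a = a, Na_buffer = Na_buffer)
    class(pars) <- "exchange_params"
    apparent_D(pars, C)
  }
  one_fit <- function(y, w) {
    args <- list(y ~ model(Db, C_M),
                 data = list(y = y, C_M = C_M),
                 start = list(Db = 0.5 * D_f),
                 lower = c(Db = 1e-13), upper = c(Db = D_f),
                 control = minpack.lm::nls.lm.control(maxiter = 200))
    if (!is.null(w)) args$weights <- w
    do.call(minpack.lm::nlsLM, args)
  }
  w <- NULL
  if (weighting == "inverse-variance") {
    if (is.null(se_D)) stop("inverse-variance weighting requires se_D", call. = FALSE)
    w <- 1 / se_D^2
  }
  fit <- one_fit(D_app, w)
  est <- unname(stats::coef(fit)[["Db"]])
  se <- tryCatch(summary(fit)$coefficients["Db", "Std. Error"],
                 error = function(e) NA_real_)
  resid <- D_app - model(est, C_M)
  se_boot <- NA_real_
  if (bootstrap > 0) {
    set.seed(seed)
    boots <- replicate(bootstrap, {
      y <- model(est, C_M) + sample(resid, replace = TRUE)
      unname(stats::coef(one_fit(y, w))[["Db"]])
    })
    se_boot <- stats::sd(boots)
  }
  structure(list(estimate = est, se = unname(se), se_boot = se_boot,
                 residuals = resid, converged = fit$convInfo$isConv,
                 at_bounds = est <= 1.0000001e-13 || est >= D_f * (1 - 1e-9),
                 parameter = "D_b"),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> %s = %.6g (SE %.3g), converged: %s%s\n",
              x$parameter, x$estimate, x$se, x$converged,
              if (isTRUE(x$at_bounds)) " [at bounds]" else ""))
  invisible(x)
}

#' Per-ion entropy of release from the ion atmosphere
#'
#' The Seki-Bagchi relation between diffusion and entropy gives the entropy
#' change upon releasing one cation from the ion atmosphere as
#' -k_B ln(D_b/D_f); on the molar scale (multiplying by Avogadro's number)
#' this is -R ln(D_b/D_f), reported in entropy units
#' (eu = cal mol^-1 K^-1).
#'
#' @param D_b ion-atmosphere diffusion coefficient (any units, as long as
#'   they match `D_f`)
#' @param D_f free-ion diffusion coefficient
#' @return list with `ratio` (D_b/D_f), `dS_per_ion_kB` (multiples of k_B)
#'   and `dS_per_ion_eu` (cal mol^-1 K^-1)
#' @examples
#' entropy_of_release(0.71, 1.251)$dS_per_ion_eu  # about 1.13
#' @export
entropy_of_release <- function(D_b, D_f) {
  stopifnot(is.numeric(D_b), is.numeric(D_f))
  if (any(D_b <= 0) || any(D_f <= 0)) {
    stop("diffusion coefficients must be positive", call. = FALSE)
  }
  ratio <- D_b / D_f
  kB_mult <- -log(ratio)
  list(ratio = ratio,
       dS_per_ion_kB = kB_mult,
       dS_per_ion_eu = physical_constants$R_cal * kB_mult)
}
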