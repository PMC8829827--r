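#' Acquisition timing parameters for a bipolar-gradient diffusion experiment
#'
#' Container for the timing of a BPP-LED (bipolar pulsed-gradient pair,
#' longitudinal eddy-current delay) experiment. `delta` is the *total*
#' length of a pair of bipolar gradients (so a pair of 1 ms lobes gives
#' `delta = 2e-3`), `Delta` the time between the beginning points of the two
#' spin-echo periods, `tau` the time between the two gradients within each
#' spin echo, and `TL` the longitudinal storage delay.
#'
#' @param delta total bipolar-pair gradient length, s
#' @param Delta diffusion delay, s; must exceed `delta/3 + tau/2` so that the
#'   effective diffusion time is positive
#' @param tau inter-gradient delay within each spin echo, s. Defaults to
#'   0.2 ms, a typical value whose contribution to the effective diffusion
#'   time is below 1 percent.
#' @param TL longitudinal storage delay, s (not used by the attenuation law;
#'   recorded for provenance)
#' @param nucleus nucleus label, see [gamma_for()]
#' @return an object of class `pulse_params`
#' @examples
#' pulse_params(delta = 2e-3, Delta = 20e-3)
#' @export
pulse_params <- function(delta, Delta, tau = 0.2e-3, TL = 0, nucleus = "23Na") {
  stopifnot(is.numeric(delta), is.numeric(Delta), is.numeric(tau), is.numeric(TL))
  if (delta <= 0) stop("delta must be positive", call. = FALSE)
  if (tau < 0 || TL < 0) stop("tau and TL must be non-negative", call. = FALSE)
  if (Delta <= delta / 3 + tau / 2) {
    stop("Delta must exceed delta/3 + tau/2 (non-positive effective diffusion time)",
         call. = FALSE)
  }
  gamma_for(nucleus)  # validates the label
  structure(list(delta = delta, Delta = Delta, tau = tau, TL = TL,
                 nucleus = nucleus),
            class = "pulse_params")
}

#' @export
print.pulse_params <- function(x, ...) {
  cat(sprintf("<pulse_params> %s: delta = %g ms, Delta = %g ms, tau = %g ms, TL = %g ms\n",
              x$nucleus, x$delta * 1e3, x$Delta * 1e3, x$tau * 1e3, x$TL * 1e3))
  invisible(x)
}

#' A gradient-series diffusion decay measurement
#'
#' One diffusion measurement: signal integrals recorded at a series of
#' gradient strengths under fixed acquisition timing. Gradients are stored
#' internally in T/m.
#'
#' @param g gradient strengths, T/m (use [gradient_to_si()] for G/cm input)
#' @param I signal integrals (arbitrary units)
#' @param params a [pulse_params()] object
#' @param replicate replicate identifier(s); scalar or one per point
#' @param sigma_I optional per-point noise standard deviations
#' @return an object of class `decay_series`: a data frame with columns
#'   `g`, `I`, `replicate` and attributes `params`, `sigma_I`
#' @export
decay_series <- function(g, I, params, replicate = 1L, sigma_I = NULL) {
  stopifnot(inherits(params, "pulse_params"), is.numeric(g), is.numeric(I))
  if (length(g) != length(I)) stop("g and I must have equal length", call. = FALSE)
  if (any(g < 0)) stop("gradient strengths must be non-negative", call. = FALSE)
  if (any(!is.finite(I))) stop("signal integrals must be finite", call. = FALSE)
  if (length(unique(g)) < 3L) {
    stop("at least 3 distinct gradient strengths are required", call. = FALSE)
  }
  if (!is.null(sigma_I) && length(sigma_I) != length(I)) {
    stop("sigma_I must match I in length", call. = FALSE)
  }
  replicate <- rep_len(replicate, length(g))
  out <- data.frame(g = g, I = I, replicate = replicate)
  structure(out, params = params, sigma_I = sigma_I,
            class = c("decay_series", "data.frame"))
}

#' Gradient-encoding b-factor of the bipolar Stejskal-Tanner law
#'
#' Computes b = gamma^2 g^2 delta^2 (Delta - delta/3 - tau/2), the
#' coefficient multiplying the diffusion coefficient in the exponential
#' attenuation law for a bipolar gradient pair.
#'
#' @param params a [pulse_params()] object
#' @param g gradient strength(s), T/m
#' @return b-factor(s), s m^-2
#' @export
b_factor <- function(params, g) {
  stopifnot(inherits(params, "pulse_params"))
  t_eff <- params$Delta - params$delta / 3 - params$tau / 2
  if (t_eff <= 0) stop("non-positive effective diffusion time", call. = FALSE)
  gam <- gamma_for(params$nucleus)
  (gam * g * params$delta)^2 * t_eff
}

#' Fractional signal retained after diffusion encoding
#'
#' I/I0 = exp(-D b(g)) for the bipolar-pair attenuation law.
#'
#' @param D diffusion coefficient, m^2/s
#' @param params a [pulse_params()] object
#' @param g gradient strength(s), T/m
#' @return attenuation factor(s) in (0, 1]
#' @examples
#' p <- pulse_params(delta = 2e-3, Delta = 20e-3)
#' attenuation(0.883e-9, p, gradient_to_si(265))  # < 0.15: >85% attenuated
#' @export
attenuation <- function(D, params, g) {
  stopifnot(is.numeric(D), all(D >= 0))
  exp(-D * b_factor(params, g))
}

# Log-linear initialization: slope of ln I vs b. Non-positive intensities are
# dropped for the init only (the nonlinear fit uses all points).
init_from_loglinear <- function(b, I) {
  keep <- I > 0
  if (sum(keep) < 2L) return(list(I0 = max(I), D = 1e-9))
  co <- stats::coef(stats::lm(log(I[keep]) ~ b[keep]))
  list(I0 = exp(co[[1]]), D = max(-co[[2]], 1e-13))
}

fit_single_decay <- function(g, I, params, weighting, sigma_I) {
  b <- b_factor(params, g)
  init <- init_from_loglinear(b, I)
  w <- NULL
  if (weighting == "inverse-variance") {
    if (is.null(sigma_I)) stop("inverse-variance weighting requires sigma_I", call. = FALSE)
    w <- 1 / sigma_I^2
  }
  df <- data.frame(I = I, b = b)
  args <- list(I ~ I0 * exp(-D * b),
               data = df,
               start = list(I0 = init$I0, D = init$D),
               lower = c(I0 = 0, D = 1e-13),
               upper = c(I0 = 10 * max(I), D = 1e-7),
               control = minpack.lm::nls.lm.control(maxiter = 200))
  if (!is.null(w)) args$weights <- w
  fit <- do.call(minpack.lm::nlsLM, args)
  est <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) c(I0 = NA_real_, D = NA_real_))
  structure(list(
    D = unname(est[["D"]]),
    I0 = unname(est[["I0"]]),
    se_D = unname(se[["D"]]),
    residuals = I - unname(est[["I0"]]) * exp(-unname(est[["D"]]) * b),
    converged = fit$convInfo$isConv,
    n_points = length(g),
    at_bounds = unname(est[["D"]]) <= 1.0000001e-13 || unname(est[["D"]]) >= 0.9999999e-7
  ), class = "diffusion_fit")
}

#' Fit a diffusion coefficient to a gradient decay series
#'
#' Nonlinear least squares of I = I0 exp(-D b(g)) against the raw signal
#' integrals. Initialization comes from a log-linear regression of ln I on
#' b; the residual minimized is on the raw intensity scale. When the series
#' holds several replicates the default is to fit each independently and
#' report the mean D with its standard error of the mean, matching the
#' replicate convention of diffusion NMR practice; `replicates = "pooled"`
#' fits all points jointly.
#'
#' @param series a [decay_series()]
#' @param weighting `"none"` (default) or `"inverse-variance"` (requires
#'   `sigma_I` on the series)
#' @param replicates `"sem"` (fit each replicate, report mean and SEM) or
#'   `"pooled"` (single joint fit)
#' @return an object of class `diffusion_fit` with elements `D`, `I0`,
#'   `se_D` (m^2/s), `residuals`, `converged`, `n_points`; for `"sem"` also
#'   `replicate_D`, the per-replicate estimates
#' @export
fit_diffusion <- function(series, weighting = c("none", "inverse-variance"),
                          replicates = c("sem", "pooled")) {
  stopifnot(inherits(series, "decay_series"))
  weighting <- match.arg(weighting)
  replicates <- match.arg(replicates)
  params <- attr(series, "params")
  sigma_I <- attr(series, "sigma_I")
  ids <- unique(series$replicate)
  if (replicates == "pooled" || length(ids) == 1L) {
    return(fit_single_decay(series$g, series$I, params, weighting, sigma_I))
  }
  fits <- lapply(ids, function(id) {
    sel <- series$replicate == id
    fit_single_decay(series$g[sel], series$I[sel], params, weighting, sigma_I[sel])
  })
  Ds <- vapply(fits, `[[`, numeric(1), "D")
  structure(list(
    D = mean(Ds),
    I0 = mean(vapply(fits, `[[`, numeric(1), "I0")),
    se_D = stats::sd(Ds) / sqrt(length(Ds)),
    residuals = unlist(lapply(fits, `[[`, "residuals")),
    converged = all(vapply(fits, `[[`, logical(1), "converged")),
    n_points = nrow(series),
    replicate_D = Ds
  ), class = "diffusion_fit")
}

#' @export
print.diffusion_fit <- function(x, ...) {
  cat(sprintf("<diffusion_fit> D = %.3f x 1e-5 cm^2/s (SE %.3f), n = %d, converged: %s\n",
              diffusion_from_si(x$D),
              ifelse(is.na(x$se_D), NA, diffusion_from_si(x$se_D)),
              x$n_points, x$converged))
  invisible(x)
}

#' Calibrate gradient strength against a diffusion reference standard
#'
#' Fits a decay series recorded on a standard of known self-diffusion
#' coefficient (e.g. neat N,N-dimethylformamide, 1.63e-5 cm^2/s at 25 C)
#' with the nominal gradient values, and returns the multiplicative scale
#' factor s such that true gradient = s x nominal. Because the b-factor is
#' quadratic in g, s = sqrt(D_fitted / D_reference).
#'
#' @param series a [decay_series()] measured on the standard with nominal
#'   gradient values
#' @param D_reference known self-diffusion coefficient of the standard, m^2/s
#' @param ... passed to [fit_diffusion()]
#' @return list with `scale` (the factor s), `D_fitted`, and `fit`
#' @export
calibrate_gradient <- function(series, D_reference, ...) {
  stopifnot(is.numeric(D_reference), D_reference > 0)
  fit <- fit_diffusion(series, ...)
  list(scale = sqrt(fit$D / D_reference), D_fitted = fit$D, fit = fit)
}

#' Fit a monoexponential storage-delay relaxation decay
#'
#' Signal loss during the longitudinal storage delay TL of a BPP-LED
#' experiment is monoexponential; this fits I = I0 exp(-rate TL).
#'
#' @param TL storage delays, s (at least 3)
#' @param I signal intensities, positive
#' @return list with `rate` (s^-1), `I0`, `se_rate`, `residuals`, `converged`
#' @export
fit_storage_decay <- function(TL, I) {
  stopifnot(is.numeric(TL), is.numeric(I), length(TL) == length(I))
  if (length(TL) < 3L) stop("at least 3 points are required", call. = FALSE)
  if (any(I <= 0)) stop("intensities must be positive", call. = FALSE)
  co <- stats::coef(stats::lm(log(I) ~ TL))
  start <- list(I0 = exp(co[[1]]), rate = max(-co[[2]], 0))
  df <- data.frame(I = I, TL = TL)
  fit <- minpack.lm::nlsLM(I ~ I0 * exp(-rate * TL), data = df,
                           start = start,
                           lower = c(I0 = 0, rate = 0),
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  est <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) c(I0 = NA_real_, rate = NA_real_))
  list(rate = unname(est[["rate"]]), I0 = unname(est[["I0"]]),
       se_rate = unname(se[["rate"]]),
       residuals = I - unname(est[["I0"]]) * exp(-unname(est[["rate"]]) * TL),
       converged = fit$convInfo$isConv)
}
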