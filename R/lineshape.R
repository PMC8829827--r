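#' A sampled 1D NMR spectrum
#'
#' @param freq frequencies, Hz, strictly monotone; at least 16 points
#' @param intensity intensities, same length
#' @return object of class `spectrum1d`: data frame with columns `freq`,
#'   `intensity`
#' @export
spectrum1d <- function(freq, intensity) {
  stopifnot(is.numeric(freq), is.numeric(intensity),
            length(freq) == length(intensity))
  if (length(freq) < 16L) stop("at least 16 points are required", call. = FALSE)
  d <- diff(freq)
  if (!(all(d > 0) || all(d < 0))) stop("freq must be strictly monotone", call. = FALSE)
  structure(data.frame(freq = freq, intensity = intensity),
            class = c("spectrum1d", "data.frame"))
}

#' Absorption-mode Lorentzian line
#'
#' Parameterized directly in the transverse relaxation rate R2: the full
#' width at half maximum is R2/pi, and the curve is
#' L(f) = (2 A / pi) w / (4 (f - f0)^2 + w^2) with w = FWHM, so that the
#' integral equals the area A and the peak height is 2A/(pi w).
#'
#' @param freq frequencies, Hz
#' @param center line center f0, Hz
#' @param R2 transverse relaxation rate, s^-1 (> 0)
#' @param area integrated area A
#' @return intensities at `freq`
#' @export
lorentzian <- function(freq, center, R2, area) {
  stopifnot(R2 > 0)
  w <- R2 / pi
  (2 * area / pi) * w / (4 * (freq - center)^2 + w^2)
}

#' Fit a sum of Lorentzian lines to a 1D spectrum
#'
#' Least-squares fit of `n_components` absorption Lorentzians plus a
#' constant baseline. Line widths are read out directly as R2 = pi x FWHM.
#' Components whose parameters are correlated above 0.99 (unresolvable
#' overlap) are flagged.
#'
#' @param spec a [spectrum1d()]
#' @param init_centers initial line centers, Hz, one per component; must lie
#'   within the spectral window
#' @param baseline fit a constant baseline offset (default TRUE)
#' @return list with `components` (data frame: center, R2, area, height,
#'   se_R2), `baseline`, `residuals`, `converged`, `flagged_overlap`
#' @export
fit_lorentzians <- function(spec, init_centers, baseline = TRUE) {
  stopifnot(inherits(spec, "spectrum1d"), is.numeric(init_centers),
            length(init_centers) >= 1L)
  f <- spec$freq; y <- spec$intensity
  if (any(init_centers < min(f)) || any(init_centers > max(f))) {
    stop("initial centers must lie within the spectral window", call. = FALSE)
  }
  n <- length(init_centers)
  span <- diff(range(f))
  base0 <- min(y)
  # data-driven start: peak height at each init center and the contiguous
  # extent above half that height as the FWHM guess
  init_one <- function(f0) {
    i0 <- which.min(abs(f - f0))
    h <- y[i0] - base0
    if (h <= 0) return(c(span / 20, max(y) * span / 20))
    above <- y - base0 > h / 2
    lo <- i0; while (lo > 1L && above[lo - 1L]) lo <- lo - 1L
    hi <- i0; while (hi < length(f) && above[hi + 1L]) hi <- hi + 1L
    w <- max(abs(f[hi] - f[lo]), span / length(f))
    c(w, h * w * pi / 2)
  }
  inits <- vapply(init_centers, init_one, numeric(2))
  par0 <- c(rbind(init_centers, inits[1, ], inits[2, ]))
  if (baseline) par0 <- c(par0, base0)
  model <- function(p) {
    out <- if (baseline) rep(p[3 * n + 1], length(f)) else numeric(length(f))
    for (k in seq_len(n)) {
      f0 <- p[3 * (k - 1) + 1]; w <- p[3 * (k - 1) + 2]; A <- p[3 * (k - 1) + 3]
      out <- out + (2 * A / pi) * w / (4 * (f - f0)^2 + w^2)
    }
    out
  }
  lower <- c(rbind(rep(min(f), n), rep(span * 1e-6, n), rep(0, n)))
  upper <- c(rbind(rep(max(f), n), rep(span, n), rep(Inf, n)))
  if (baseline) { lower <- c(lower, -Inf); upper <- c(upper, Inf) }
  fit <- minpack.lm::nls.lm(par = par0,
                            fn = function(p) y - model(p),
                            lower = lower, upper = upper,
                            control = minpack.lm::nls.lm.control(maxiter = 500))
  p <- fit$par
  # covariance for SEs and the overlap diagnostic
  covm <- tryCatch({
    s2 <- sum(fit$fvec^2) / (length(y) - length(p))
    s2 * solve(fit$hessian / 2)
  }, error = function(e) NULL)
  flagged <- FALSE
  se_w <- rep(NA_real_, n)
  if (!is.null(covm)) {
    dcov <- sqrt(pmax(diag(covm), 0))
    corm <- covm / (dcov %o% dcov)
    corm[!is.finite(corm)] <- 0
    diag(corm) <- 0
    flagged <- any(abs(corm) > 0.99)
    se_w <- dcov[3 * (seq_len(n) - 1) + 2]
  }
  comp <- data.frame(
    center = p[3 * (seq_len(n) - 1) + 1],
    R2 = pi * p[3 * (seq_len(n) - 1) + 2],
    area = p[3 * (seq_len(n) - 1) + 3],
    height = 2 * p[3 * (seq_len(n) - 1) + 3] / (pi * p[3 * (seq_len(n) - 1) + 2]),
    se_R2 = pi * se_w
  )
  comp <- comp[order(comp$center), , drop = FALSE]
  rownames(comp) <- NULL
  # warn on asymmetric residuals, a signature of phase error
  res <- y - model(p)
  list(components = comp,
       baseline = if (baseline) p[3 * n + 1] else 0,
       residuals = res,
       converged = fit$info %in% 1:4,
       flagged_overlap = flagged)
}

#' Two-state R2 exchange parameters
#'
#' @param R_f free-state transverse relaxation rate, s^-1
#' @param R_b ion-atmosphere transverse relaxation rate, s^-1; for
#'   quadrupolar nuclei bound to a macromolecule R_b >= R_f is expected and
#'   a violation is flagged with a warning
#' @param a atmosphere cations per macromolecule
#' @param Na_buffer buffer cation concentration, mol/L
#' @return object of class `r2_exchange_params`
#' @export
r2_exchange_params <- function(R_f, R_b, a, Na_buffer) {
  stopifnot(R_f > 0, R_b > 0, a >= 0, Na_buffer >= 0)
  if (R_b < R_f) warning("R_b < R_f is unusual for macromolecule-bound quadrupolar nuclei")
  structure(list(R_f = R_f, R_b = R_b, a = a, Na_buffer = Na_buffer),
            class = "r2_exchange_params")
}

#' Apparent R2 under two-state fast exchange
#'
#' R_2,app = p_f R_f + p_b R_b with the bound population from the
#' single-cation model p_b = a C_M / (Na_buffer + a C_M). No exchange
#' contribution term is included: the model is the population average
#' alone.
#'
#' @param params an [r2_exchange_params()] object
#' @param C_M macromolecule concentration(s), mol/L
#' @return apparent relaxation rate(s), s^-1, within \[R_f, R_b\]
#' @export
r2_apparent_model <- function(params, C_M) {
  stopifnot(inherits(params, "r2_exchange_params"), all(C_M >= 0))
  pb <- params$a * C_M / (params$Na_buffer + params$a * C_M)
  (1 - pb) * params$R_f + pb * params$R_b
}

#' Fit the ion-atmosphere R2 from a concentration titration
#'
#' One-parameter least squares for R_b in the two-state population-average
#' model, with R_f, the ion count and the buffer concentration fixed at
#' their measured values.
#'
#' @param C_M macromolecule concentrations, mol/L (>= 2 points)
#' @param R2_app measured apparent relaxation rates, s^-1
#' @param R_f free-state rate, s^-1 (measured on buffer alone)
#' @param a atmosphere cations per macromolecule
#' @param Na_buffer buffer cation concentration, mol/L
#' @param se_R2 optional standard errors for weighting
#' @param weighting `"none"` or `"inverse-variance"`
#' @param bootstrap residual-bootstrap resamples for the SE (0 = none)
#' @param seed bootstrap seed
#' @return object of class `fit_result` with `estimate` = R_b (s^-1)
#' @export
fit_Rb <- function(C_M, R2_app, R_f, a, Na_buffer, se_R2 = NULL,
                   weighting = c("none", "inverse-variance"),
                   bootstrap = 0, seed = 1L) {
  weighting <- match.arg(weighting)
  stopifnot(length(C_M) == length(R2_app))
  if (length(C_M) < 2L) stop("at least 2 points required", call. = FALSE)
  model <- function(Rb, C) {
    pb <- a * C / (Na_buffer + a * C)
    (1 - pb) * R_f + pb * Rb
  }
  w <- NULL
  if (weighting == "inverse-variance") {
    if (is.null(se_R2)) stop("inverse-variance weighting requires se_R2", call. = FALSE)
    w <- 1 / se_R2^2
  }
  one_fit <- function(y) {
    args <- list(y ~ model(Rb, C_M),
                 data = list(y = y, C_M = C_M),
                 start = list(Rb = 2 * R_f),
                 lower = c(Rb = 1e-6), upper = c(Rb = 1e6),
                 control = minpack.lm::nls.lm.control(maxiter = 200))
    if (!is.null(w)) args$weights <- w
    do.call(minpack.lm::nlsLM, args)
  }
  fit <- one_fit(R2_app)
  est <- unname(stats::coef(fit)[["Rb"]])
  se <- tryCatch(summary(fit)$coefficients["Rb", "Std. Error"],
                 error = function(e) NA_real_)
  resid <- R2_app - model(est, C_M)
  se_boot <- NA_real_
  if (bootstrap > 0) {
    set.seed(seed)
    boots <- replicate(bootstrap, {
      y <- model(est, C_M) + sample(resid, replace = TRUE)
      unname(stats::coef(one_fit(y))[["Rb"]])
    })
    se_boot <- stats::sd(boots)
  }
  structure(list(estimate = est, se = unname(se), se_boot = se_boot,
                 residuals = resid, converged = fit$convInfo$isConv,
                 at_bounds = est <= 1.01e-6 || est >= 0.99e6,
                 parameter = "R_b"),
            class = "fit_result")
}
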