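#' Total cation concentration from a signal-integral ratio
#'
#' A coaxial reference solution gives a fixed signal; the ratio
#' r = I/I_ref for a macromolecular sample, divided by the same ratio for
#' buffer alone (whose cation concentration is known), yields the total
#' cation concentration: Na_total = Na_buffer x r_sample / r_buffer.
#'
#' @param r_sample integral ratio I/I_ref for the sample
#' @param r_buffer integral ratio I/I_ref for buffer alone
#' @param Na_buffer cation concentration of the buffer, mol/L (default
#'   0.020, i.e. 20 mM)
#' @return total cation concentration, mol/L
#' @examples
#' conc_from_si(na_total(3.2185, 1))  # 64.37 mM
#' @export
na_total <- function(r_sample, r_buffer, Na_buffer = 0.020) {
  stopifnot(is.numeric(r_sample), is.numeric(r_buffer), is.numeric(Na_buffer))
  if (any(r_buffer == 0)) stop("r_buffer must be non-zero", call. = FALSE)
  if (any(r_sample <= 0) || any(r_buffer < 0)) {
    stop("integral ratios must be positive", call. = FALSE)
  }
  Na_buffer * r_sample / r_buffer
}

#' Count ions per macromolecule from concentration-dependent totals
#'
#' Counterion condensation predicts the number of cations accumulated per
#' macromolecule to be independent of the free-ion concentration, so the
#' total cation concentration is linear in the macromolecule concentration:
#' Na_total = Na_buffer + a C_M, with slope a the ion count (for a
#' single-cation solution, the ion excess). Default is a free-intercept
#' ordinary least-squares fit, with a warning when the fitted intercept
#' strays from the stated buffer concentration by more than twice its
#' standard error; `fix_intercept` forces the regression through a known
#' buffer concentration.
#'
#' @param C_M macromolecule concentrations, mol/L
#' @param Na_tot total cation concentrations, mol/L
#' @param fix_intercept optional known intercept, mol/L; when given a
#'   one-parameter regression through that intercept is used
#' @param Na_buffer buffer concentration used for the intercept sanity
#'   check, mol/L (default 0.020)
#' @return object of class `ion_excess_fit`: list with `a` (ions per
#'   macromolecule), `intercept` (mol/L), `se_a`, `se_intercept`,
#'   `n_points`, `residuals`
#' @export
fit_ion_excess <- function(C_M, Na_tot, fix_intercept = NULL, Na_buffer = 0.020) {
  stopifnot(is.numeric(C_M), is.numeric(Na_tot), length(C_M) == length(Na_tot))
  if (length(unique(C_M)) < 2L && is.null(fix_intercept)) {
    stop("slope unidentifiable: all C_M identical", call. = FALSE)
  }
  if (is.null(fix_intercept)) {
    if (length(C_M) < 2L) stop("at least 2 points required", call. = FALSE)
    fit <- stats::lm(Na_tot ~ C_M)
    sm <- suppressWarnings(summary(fit))$coefficients
    a <- unname(stats::coef(fit)[["C_M"]])
    intercept <- unname(stats::coef(fit)[["(Intercept)"]])
    se_a <- if (nrow(sm) == 2 && ncol(sm) >= 2) sm["C_M", "Std. Error"] else NA_real_
    se_int <- if (nrow(sm) == 2 && ncol(sm) >= 2) sm["(Intercept)", "Std. Error"] else NA_real_
    # warn only on deviations that are both statistically and practically
    # meaningful (beyond 2 SE and beyond 1% of the buffer concentration)
    if (is.finite(se_int) && se_int > 0 &&
        abs(intercept - Na_buffer) > 2 * se_int &&
        abs(intercept - Na_buffer) > 0.01 * Na_buffer) {
      warning(sprintf(
        "fitted intercept %.2f mM deviates from buffer %.2f mM by > 2 SE; possible quantification bias",
        conc_from_si(intercept), conc_from_si(Na_buffer)))
    }
  } else {
    if (length(C_M) < 1L) stop("at least 1 point required", call. = FALSE)
    if (all(C_M == 0)) stop("slope unidentifiable: all C_M zero", call. = FALSE)
    y <- Na_tot - fix_intercept
    fit <- stats::lm(y ~ 0 + C_M)
    sm <- suppressWarnings(summary(fit))$coefficients
    a <- unname(stats::coef(fit)[["C_M"]])
    intercept <- fix_intercept
    se_a <- if (ncol(sm) >= 2) sm["C_M", "Std. Error"] else NA_real_
    se_int <- 0
  }
  structure(list(a = a, intercept = intercept, se_a = unname(se_a),
                 se_intercept = unname(se_int), n_points = length(C_M),
                 residuals = Na_tot - (intercept + a * C_M)),
            class = "ion_excess_fit")
}

#' @export
print.ion_excess_fit <- function(x, ...) {
  cat(sprintf("<ion_excess_fit> a = %.2f ions per macromolecule (SE %.2f), intercept = %.2f mM, n = %d\n",
              x$a, x$se_a, conc_from_si(x$intercept), x$n_points))
  invisible(x)
}

#' Percent deviation of a measured ion count from a prediction
#'
#' @param a_measured measured ions per macromolecule
#' @param a_predicted predicted ions per macromolecule (e.g. from a
#'   Poisson-Boltzmann calculation); must be non-zero
#' @return percent difference, 100 (a_measured - a_predicted) / a_predicted
#' @examples
#' percent_vs_prediction(25.5, 21.6)  # about 18
#' @export
percent_vs_prediction <- function(a_measured, a_predicted) {
  stopifnot(is.numeric(a_measured), is.numeric(a_predicted))
  if (any(a_predicted == 0)) stop("a_predicted must be non-zero", call. = FALSE)
  100 * (a_measured - a_predicted) / a_predicted
}
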