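#' Number of counterions released upon protein-DNA association
#'
#' Applying the two-state fast-exchange diffusion model to a protein-DNA
#' sample and a matched DNA-only sample, the number of cations released per
#' complex is n_R = n_c (D_PD - D_D) / ((D_f - D_D) p_complex): the
#' observed shift of the apparent diffusion coefficient toward the free
#' value, expressed as a fraction of the maximum possible shift and scaled
#' by the atmosphere count per complexed macromolecule. The three diffusion
#' coefficients may be supplied in any common unit.
#'
#' The standard error is obtained by first-order propagation of the
#' uncertainties of the three diffusion coefficients (the ion count and
#' complex fraction are treated as exact unless their SEs are supplied).
#'
#' @param D_PD apparent diffusion coefficient of the protein-DNA sample
#' @param D_D apparent diffusion coefficient of the DNA-only sample at
#'   matched DNA concentration
#' @param D_f free-ion diffusion coefficient; must differ from `D_D`
#' @param n_c atmosphere cations per macromolecule
#' @param p_complex fraction of macromolecule bound by protein, in (0, 1]
#' @param se_D_PD,se_D_D,se_D_f standard errors of the diffusion
#'   coefficients (same units)
#' @param se_n_c,se_p_complex optional standard errors of the ion count and
#'   complex fraction
#' @return list with `n_R` (ions), `se` (first-order propagated), and
#'   `flagged` (TRUE when the ordering D_D <= D_PD <= D_f is violated,
#'   implying n_R outside \[0, n_c/p_complex\])
#' @examples
#' released_ions(1.036, 0.883, 1.251, 25.5, 1.10 / 1.52)$n_R  # about 14.7
#' @export
released_ions <- function(D_PD, D_D, D_f, n_c, p_complex,
                          se_D_PD = 0, se_D_D = 0, se_D_f = 0,
                          se_n_c = 0, se_p_complex = 0) {
  stopifnot(is.numeric(D_PD), is.numeric(D_D), is.numeric(D_f),
            is.numeric(n_c), is.numeric(p_complex))
  if (p_complex <= 0 || p_complex > 1) stop("p_complex must be in (0, 1]", call. = FALSE)
  if (D_f == D_D) stop("D_f equals D_D: no bound population to release", call. = FALSE)
  flagged <- !(D_D <= D_PD && D_PD <= D_f)
  if (flagged) {
    warning("diffusion coefficients violate D_D <= D_PD <= D_f; n_R will fall outside [0, n_c/p_complex]")
  }
  n_R <- n_c * (D_PD - D_D) / ((D_f - D_D) * p_complex)
  # first-order propagation: partial derivatives of n_R
  d_PD <- n_c / ((D_f - D_D) * p_complex)
  d_f <- -n_c * (D_PD - D_D) / ((D_f - D_D)^2 * p_complex)
  d_D <- -d_PD - d_f  # d n_R/d D_D = n_c (D_PD - D_f)/((D_f - D_D)^2 p)
  d_nc <- n_R / n_c
  d_p <- -n_R / p_complex
  se <- sqrt((d_PD * se_D_PD)^2 + (d_D * se_D_D)^2 + (d_f * se_D_f)^2 +
               (d_nc * se_n_c)^2 + (d_p * se_p_complex)^2)
  list(n_R = n_R, se = se, flagged = flagged)
}

#' Fraction of macromolecule bound by protein
#'
#' In the tight-binding limit (dissociation constant far below the working
#' concentrations) every protein is bound, so the complexed fraction of the
#' macromolecule is min(P_total, M_total)/M_total. With a finite `K_d` the
#' exact 1:1 binding quadratic is solved instead.
#'
#' @param P_total total protein concentration, mol/L
#' @param M_total total macromolecule (e.g. DNA duplex) concentration, mol/L
#' @param K_d optional dissociation constant, mol/L; `NULL` (default) is the
#'   tight-binding limit
#' @return bound fraction of the macromolecule, in \[0, 1\]
#' @examples
#' complex_fraction(1.10e-3, 1.52e-3)  # 0.724
#' @export
complex_fraction <- function(P_total, M_total, K_d = NULL) {
  stopifnot(is.numeric(P_total), is.numeric(M_total),
            P_total > 0, M_total > 0)
  if (is.null(K_d)) {
    return(min(P_total, M_total) / M_total)
  }
  stopifnot(is.numeric(K_d), K_d >= 0)
  # [PM] is the smaller root of PM^2 - (P + M + Kd) PM + P M = 0
  b <- P_total + M_total + K_d
  disc <- b^2 - 4 * P_total * M_total
  PM <- (b - sqrt(disc)) / 2
  PM / M_total
}
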