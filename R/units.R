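#' Physical constants used throughout the package
#'
#' All internal computation is in SI units (m, s, T, mol/L); conversion to
#' the reporting units conventional in diffusion NMR (gradients in G/cm,
#' diffusion coefficients in 1e-5 cm^2/s, concentrations in mM) happens only
#' at input/output boundaries.
#'
#' The gyromagnetic ratio of 23Na is derived from the 1H value via the
#' dimensionless ratio 0.2645, the convention used in low-gamma diffusion
#' NMR work, rather than taken from an external table.
#'
#' @format A list with elements:
#' \describe{
#'   \item{gamma_1H}{1H gyromagnetic ratio, rad s^-1 T^-1}
#'   \item{gamma_ratio_23Na}{gamma(23Na)/gamma(1H), dimensionless}
#'   \item{R_cal}{gas constant in cal mol^-1 K^-1 (entropy units, eu)}
#'   \item{temperature}{default temperature, K}
#' }
#' @export
physical_constants <- list(
  gamma_1H = 2.675222e8,
  gamma_ratio_23Na = 0.2645,
  R_cal = 1.98720,
  temperature = 298.15
)

#' Gyromagnetic ratio for a registered nucleus
#'
#' @param nucleus character label, one of `"1H"` or `"23Na"`. The registry is
#'   a named list so further nuclei can be added by extending
#'   [nucleus_registry()].
#' @return gyromagnetic ratio in rad s^-1 T^-1
#' @examples
#' gamma_for("23Na") / gamma_for("1H")  # 0.2645
#' @export
gamma_for <- function(nucleus) {
  reg <- nucleus_registry()
  if (!is.character(nucleus) || length(nucleus) != 1L || !nucleus %in% names(reg)) {
    stop("unknown nucleus '", paste(nucleus, collapse = ","),
         "'; registered nuclei: ", paste(names(reg), collapse = ", "),
         call. = FALSE)
  }
  reg[[nucleus]]
}

#' Registry of gyromagnetic ratios
#'
#' @return named numeric vector of gyromagnetic ratios (rad s^-1 T^-1)
#' @export
nucleus_registry <- function() {
  c("1H" = physical_constants$gamma_1H,
    "23Na" = physical_constants$gamma_ratio_23Na * physical_constants$gamma_1H)
}

#' Unit conversions at the I/O boundary
#'
#' Gradient strengths are reported in G/cm and held internally in T/m
#' (1 G/cm = 0.01 T/m). Diffusion coefficients are reported in
#' 1e-5 cm^2 s^-1 and held internally in m^2 s^-1
#' (1e-5 cm^2 s^-1 = 1e-9 m^2 s^-1). Concentrations are reported in mM and
#' held internally in mol/L.
#'
#' @param value numeric vector to convert
#' @return converted numeric vector
#' @name unit_conversions
NULL

#' @rdname unit_conversions
#' @export
gradient_to_si <- function(value) {
  stopifnot(is.numeric(value), all(is.finite(value)))
  value * 0.01
}

#' @rdname unit_conversions
#' @export
gradient_from_si <- function(value) value / 0.01

#' @rdname unit_conversions
#' @export
diffusion_to_si <- function(value) value * 1e-9

#' @rdname unit_conversions
#' @export
diffusion_from_si <- function(value) value / 1e-9

#' @rdname unit_conversions
#' @export
conc_to_si <- function(value) value * 1e-3

#' @rdname unit_conversions
#' @export
conc_from_si <- function(value) value / 1e-3
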