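#' Noise model for the synthetic-data generators
#'
#' All generators add seeded Gaussian noise under a common description:
#' relative noise multiplies each true value by (1 + e) with
#' e ~ N(0, sigma^2); absolute noise adds e ~ N(0, sigma^2) in the units of
#' the generated quantity. The default sigma of 1 percent relative matches
#' the precision typical of replicated diffusion measurements, and three
#' replicates per condition exercise the standard-error-of-the-mean
#' pathway.
#'
#' @param kind `"relative-gaussian"` or `"absolute-gaussian"`
#' @param sigma noise level: a fraction for relative noise, intensity units
#'   for absolute
#' @param seed integer seed; identical seeds give bit-identical output
#' @param n_replicates replicates per condition (default 3)
#' @return object of class `noise_model`
#' @export
noise_model <- function(kind = c("relative-gaussian", "absolute-gaussian"),
                        sigma = 0.01, seed = 1L, n_replicates = 3L) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(sigma), sigma >= 0, is.numeric(seed),
            n_replicates >= 1L)
  structure(list(kind = kind, sigma = sigma, seed = as.integer(seed),
                 n_replicates = as.integer(n_replicates)),
            class = "noise_model")
}

apply_noise <- function(truth, noise) {
  if (noise$sigma == 0) return(truth)
  eps <- stats::rnorm(length(truth), 0, noise$sigma)
  if (noise$kind == "relative-gaussian") truth * (1 + eps) else truth + eps
}

with_noise_seed <- function(noise, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(noise$seed)
  expr
}

#' Default gradient grid of a strong-gradient diffusion experiment
#'
#' 25 gradient strengths evenly spanning 2 to 265 G/cm, returned in T/m.
#'
#' @param n number of gradient strengths (default 25)
#' @return gradient strengths, T/m
#' @export
default_gradient_grid <- function(n = 25L) {
  gradient_to_si(seq(2, 265, length.out = n))
}

#' Eight-point DNA-duplex concentration grid
#'
#' The working concentrations of a typical duplex titration
#' (0.21 to 1.74 mM), returned in mol/L.
#'
#' @return concentrations, mol/L
#' @export
default_dna_concentrations <- function() {
  conc_to_si(c(0.21, 0.47, 0.66, 0.88, 1.09, 1.44, 1.52, 1.74))
}

#' Simulate a gradient-series diffusion decay
#'
#' Forward-simulates I = I0 exp(-D b(g)) with multiplicative Gaussian noise
#' per point and replicate.
#'
#' @param D true diffusion coefficient, m^2/s
#' @param params a [pulse_params()] object
#' @param gradients gradient strengths, T/m (default [default_gradient_grid()])
#' @param noise a [noise_model()]
#' @param I0 noiseless amplitude (default 1)
#' @return a [decay_series()] with `noise$n_replicates` replicates
#' @export
gen_decay_series <- function(D, params, gradients = default_gradient_grid(),
                             noise = noise_model(), I0 = 1) {
  truth <- I0 * attenuation(D, params, gradients)
  with_noise_seed(noise, {
    g <- rep(gradients, noise$n_replicates)
    I <- unlist(lapply(seq_len(noise$n_replicates),
                       function(r) apply_noise(truth, noise)))
    decay_series(g, I, params,
                 replicate = rep(seq_len(noise$n_replicates),
                                 each = length(gradients)))
  })
}

#' Simulate an apparent-D titration over macromolecule concentration
#'
#' Forward-simulates the two-state fast-exchange model at a concentration
#' grid and averages `noise$n_replicates` noisy draws per point, reporting
#' the replicate mean and its standard error.
#'
#' @param params an [exchange_params()] object
#' @param concentrations macromolecule concentrations, mol/L
#'   (default [default_dna_concentrations()])
#' @param noise a [noise_model()]
#' @return data frame with columns `C_M` (mol/L), `D_app` (m^2/s), `se_D`
#' @export
gen_dna_titration <- function(params,
                              concentrations = default_dna_concentrations(),
                              noise = noise_model()) {
  truth <- apparent_D(params, concentrations)
  with_noise_seed(noise, {
    draws <- replicate(noise$n_replicates, apply_noise(truth, noise))
    draws <- matrix(draws, nrow = length(truth))
    data.frame(C_M = concentrations,
               D_app = rowMeans(draws),
               se_D = apply(draws, 1, stats::sd) / sqrt(noise$n_replicates))
  })
}

#' Simulate an apparent-D titration over competitor concentration
#'
#' @param system a [competition_system()] template; its `K_total` is
#'   ignored in favor of `K_grid`
#' @param K_grid competitor concentrations, mol/L
#' @param noise a [noise_model()]
#' @return data frame with columns `K_total`, `D_app`, `se_D`
#' @export
gen_competition_series <- function(system, K_grid, noise = noise_model()) {
  sys <- system
  sys$K_total <- K_grid
  truth <- apparent_D_competition(sys)
  with_noise_seed(noise, {
    draws <- matrix(replicate(noise$n_replicates, apply_noise(truth, noise)),
                    nrow = length(truth))
    data.frame(K_total = K_grid,
               D_app = rowMeans(draws),
               se_D = apply(draws, 1, stats::sd) / sqrt(noise$n_replicates))
  })
}

#' Simulate a total-cation quantification series
#'
#' Forward-simulates the linear law Na_total = intercept + a C_M.
#'
#' @param a true ions per macromolecule
#' @param intercept buffer cation concentration, mol/L
#' @param C_M_grid macromolecule concentrations, mol/L
#' @param noise a [noise_model()]
#' @return data frame with columns `C_M`, `Na_total` (mol/L)
#' @export
gen_quant_series <- function(a, intercept,
                             C_M_grid = default_dna_concentrations(),
                             noise = noise_model()) {
  truth <- intercept + a * C_M_grid
  with_noise_seed(noise, {
    draws <- matrix(replicate(noise$n_replicates, apply_noise(truth, noise)),
                    nrow = length(truth))
    data.frame(C_M = C_M_grid, Na_total = rowMeans(draws))
  })
}

#' Simulate a sampled 1D spectrum from Lorentzian components
#'
#' @param components data frame with columns `center` (Hz), `R2` (s^-1),
#'   `area`
#' @param freq_grid frequencies, Hz
#' @param noise a [noise_model()]; absolute noise is the natural choice for
#'   spectra (relative noise vanishes in the baseline)
#' @param baseline constant baseline offset
#' @return a [spectrum1d()]
#' @export
gen_spectrum <- function(components, freq_grid,
                         noise = noise_model("absolute-gaussian", sigma = 0),
                         baseline = 0) {
  stopifnot(is.data.frame(components),
            all(c("center", "R2", "area") %in% names(components)))
  truth <- rep(baseline, length(freq_grid))
  for (k in seq_len(nrow(components))) {
    truth <- truth + lorentzian(freq_grid, components$center[k],
                                components$R2[k], components$area[k])
  }
  with_noise_seed(noise, spectrum1d(freq_grid, apply_noise(truth, noise)))
}

#' Simulate an apparent-R2 titration over macromolecule concentration
#'
#' @param params an [r2_exchange_params()] object
#' @param C_M_grid macromolecule concentrations, mol/L
#' @param noise a [noise_model()]
#' @return data frame with columns `C_M`, `R2_app` (s^-1), `se_R2`
#' @export
gen_r2_titration <- function(params, C_M_grid = default_dna_concentrations(),
                             noise = noise_model()) {
  truth <- r2_apparent_model(params, C_M_grid)
  with_noise_seed(noise, {
    draws <- matrix(replicate(noise$n_replicates, apply_noise(truth, noise)),
                    nrow = length(truth))
    data.frame(C_M = C_M_grid,
               R2_app = rowMeans(draws),
               se_R2 = apply(draws, 1, stats::sd) / sqrt(noise$n_replicates))
  })
}
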