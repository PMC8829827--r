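# iondiff

Quantitative analysis of cation diffusion NMR data for biomolecular ion
atmospheres.

Charged macromolecules such as DNA attract a diffuse cloud of territorially
bound counterions — the ion atmosphere. Because those ions exchange rapidly
with free ions in solution, a single population-averaged NMR signal is
observed, and pulsed-field-gradient (PFG) diffusion measurements on the
cation itself (e.g. ²³Na at strong gradients) report directly on how mobile
the atmosphere ions are, how many there are, which cation the atmosphere
prefers, and how many are released when a protein binds the DNA. `iondiff`
implements the full chain of quantitative analysis for such experiments,
together with seeded synthetic-data generators so every stage can be tested
end to end without a spectrometer.

## Models

**Signal attenuation (bipolar gradient pair).** A BPP-LED gradient series
decays as

    I(g) = I₀ exp(−D γ² g² δ² (Δ − δ/3 − τ/2))

where γ is the nuclear gyromagnetic ratio (γ(²³Na) = 0.2645 γ(¹H)), g the
gradient strength, δ the total length of a bipolar gradient pair, Δ the
diffusion delay and τ the intra-echo gradient spacing. `fit_diffusion()`
estimates (I₀, D) by nonlinear least squares on the raw integrals;
`calibrate_gradient()` scales nominal gradients against a reference standard.

**Ion counting.** With a coaxial reference signal, integral ratios give the
total cation concentration, which is linear in the macromolecule
concentration: [Na⁺]_total = [Na⁺]_buffer + a·C_M. The slope a
(`fit_ion_excess()`) counts atmosphere cations per macromolecule — for a
single-cation solution, the ion excess ΔN_cation.

**Two-state fast exchange.** The apparent diffusion coefficient is the
population average D_app = p_f·D_f + p_b·D_b with
p_b = a·C_M/([Na⁺]_buffer + a·C_M). `fit_Db()` fits the single unknown D_b
from a titration; `entropy_of_release()` converts the mobility ratio into a
per-ion entropy of release, ΔS = −R ln(D_b/D_f), in entropy units
(cal mol⁻¹ K⁻¹). The same population average applied to transverse
relaxation gives `fit_Rb()` for R₂ data extracted by Lorentzian line-shape
fitting (`fit_lorentzians()`, FWHM = R₂/π).

**Ionic competition.** Two monovalent cations sharing a fixed atmosphere
capacity n_c·[DNA] obey the equilibrium quotient
Q = ([Na⁺_b][K⁺_f])/([Na⁺_f][K⁺_b]); `bound_sodium()` solves the resulting
quadratic mass balance and `fit_Q()` fits Q from the rise of D_app with
added competitor salt (Q < 1 means the competitor is preferred).

**Counterion release.** Comparing a protein–DNA sample with a matched
DNA-only sample, `released_ions()` evaluates
n_R = n_c (D_PD − D_D)/((D_f − D_D) p_complex), the number of cations
released per complex.

## Worked example

```r
library(iondiff)

## gradient-series decay for free Na+ in buffer, 1% noise, 3 replicates
p <- pulse_params(delta = 2e-3, Delta = 20e-3)
series <- gen_decay_series(D = 1.251e-9, params = p,
                           noise = noise_model(sigma = 0.01, seed = 7))
fit_diffusion(series)
#> <diffusion_fit> D = 1.247 x 1e-5 cm^2/s (SE 0.005), n = 75, converged: TRUE

## DNA titration -> ion-atmosphere diffusion coefficient and entropy
ex <- exchange_params(D_f = 1.251e-9, D_b = 0.71e-9, a = 25.5, Na_buffer = 0.020)
tit <- gen_dna_titration(ex, noise = noise_model(sigma = 0.01, seed = 7))
fit <- fit_Db(tit$C_M, tit$D_app, D_f = 1.251e-9, a = 25.5, Na_buffer = 0.020)
fit
#> <fit_result> D_b = 7.1724e-10 (SE 3.7e-12), converged: TRUE
ent <- entropy_of_release(fit$estimate, 1.251e-9)
#> D_b/D_f = 0.57; dS_release = 1.11 eu per ion

## counterion release upon protein-DNA association (units: 1e-5 cm^2/s)
released_ions(1.036, 0.883, 1.251, 25.5, complex_fraction(1.10e-3, 1.52e-3))$n_R
#> 14.6
```

The decay fit recovers the free-ion diffusion coefficient to within its
standard error; the titration fit recovers the generating atmosphere
mobility (D_b ≈ 0.717 × 10⁻⁵ cm² s⁻¹ from this noisy draw against a true
0.71), whose ratio to the free value yields roughly one entropy unit gained
per released ion; and the release equation converts the diffusion shift of
a protein–DNA sample into ~15 ions released per complex.

A YAML-driven pipeline (`run_pipeline()`, `read_config()`) chains the
stages — decay fitting, calibration, quantification, exchange, competition,
release, line shape — and writes a results table plus a log of every fitted
parameter and modeling assumption. A thin command-line wrapper lives at
`inst/cli/iondiff.R` (subcommands `run`, `release`, `simulate`).

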