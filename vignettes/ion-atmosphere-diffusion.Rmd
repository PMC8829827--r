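---
title: "Quantifying cation dynamics around biomolecules from diffusion NMR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying cation dynamics around biomolecules from diffusion NMR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iondiff)
```

## The measurement and the models

A monovalent cation such as Na⁺ in a solution of a charged macromolecule
lives in two environments: free in bulk solvent, and territorially bound in
the diffuse ion atmosphere around the macromolecule. Exchange between the
two is fast on every NMR timescale involved, so each observable — the
apparent diffusion coefficient from a pulsed-field-gradient experiment, or
the apparent transverse relaxation rate from a line width — is a single
population-weighted average. Everything this package computes follows from
that premise plus mass balance.

**Decay fitting.** A bipolar-gradient (BPP-LED) series attenuates as
$I(g) = I_0 \exp(-D\,\gamma^2 g^2 \delta^2(\Delta - \delta/3 - \tau/2))$.
`fit_diffusion()` minimizes residuals on the *raw* integrals (the quantity
actually measured), using the log-linear regression of $\ln I$ on the
b-factor only to initialize. The parameters are bounded in a generous
physical envelope ($D \in (10^{-13}, 10^{-7})\,\mathrm{m^2\,s^{-1}}$,
$I_0 \in (0, 10\max I)$) to prevent sign flips, not to constrain the answer.
When a series carries replicates the default is to fit each independently
and report the mean with its standard error of the mean — the convention of
replicated diffusion measurements — with a pooled joint fit as an option.

**Timing conventions.** $\delta$ is the *total* length of a pair of bipolar
gradient lobes: an experiment described as using 1 ms gradients per lobe has
$\delta = 2$ ms. This is the only reading under which the published
attenuation benchmarks for a slowly diffusing DNA-solution cation (over 85 %
attenuation at 265 G/cm, under 10 % at a conventional probe's 55 G/cm) are
reproduced, and the package's tests pin both bounds. $\tau$ is rarely
printed; its default of 0.2 ms contributes less than 1 % to the effective
diffusion time and is configurable.

**Ion counting.** Integral ratios against a coaxial reference signal give
total cation concentrations; their slope against macromolecule concentration
(`fit_ion_excess()`) counts atmosphere ions per macromolecule. The default
fit leaves the intercept free and *warns* if it strays from the known buffer
concentration by more than twice its standard error and more than 1 % of the
buffer value — a free intercept exposes systematic quantification bias that
a hard-coded one would hide. The hard-coded variant (`fix_intercept`) is
provided because the published analysis constrains the intercept to the
buffer concentration; on clean data the two agree, and whether the published
slope used a fixed intercept is not stated, so both modes are first-class.

**Two-state exchange fits.** `fit_Db()` and `fit_Rb()` fit a single
parameter (the atmosphere diffusion coefficient or relaxation rate) with the
free-state value, the ion count and the buffer concentration fixed at their
independently measured values — deliberately mirroring how such titrations
are analyzed: the free value is measured directly on buffer, the ion count
comes from quantification, and only the bound-state property is unknown.
Weighting defaults to unweighted residuals (published eight-point fits of
this kind do not mention weights); inverse-variance weighting by the
supplied standard errors is available, and both a covariance standard error
and a seeded residual bootstrap are reported. The exchange model for R₂
contains no exchange-broadening term $R_{ex}$: residence times in the
atmosphere are far shorter than the inverse shift difference, and residual
structure in the fit would be the diagnostic that this assumption failed.

**Competition.** With two cations sharing an atmosphere of fixed total
capacity $n_c[\mathrm{DNA}]$ (the counterion-condensation assumption — the
capacity does not change as competitor salt is added, only its composition),
the preference quotient
$Q = [\mathrm{Na^+_b}][\mathrm{K^+_f}]/([\mathrm{Na^+_f}][\mathrm{K^+_b}])$
plus three mass balances reduces to a quadratic in the bound probed-cation
concentration, $({C}/{T})N_b^2 + B N_b - \mathrm{Na_{total}}T = 0$ with
$C = T(Q^{-1}-1)$ and $B = \mathrm{Na_{total}} + Q^{-1}[\mathrm{KCl}] - C$.
This orientation of $Q$ is the one under which $Q < 1$ means the atmosphere
prefers the competitor. Numerically, the root is taken with the stable
quadratic formula (avoiding cancellation when $B^2 \gg 4C\,\mathrm{Na}$),
the root selected is the one in $[0, \min(T, \mathrm{Na_{total}})]$, and
$|Q-1| < 10^{-10}$ switches to the linear branch
$N_b = \mathrm{Na_{total}}T/B$; the tests verify continuity across the
switch and agreement with an independent bisection solve of the primitive
equilibrium over a 1000-point parameter grid.

**Release.** The release count
$n_R = n_c(D_{PD}-D_D)/((D_f-D_D)\,p_{complex})$ is the exact algebraic
inversion of the two-state model applied to a protein–DNA and a matched
DNA-only sample whose complexed fraction carries a reduced atmosphere
($n_c - n_R$); the test suite inverts that forward premise to machine
precision. Two assumptions are logged whenever the pipeline runs the stage:
the two samples share the same total cation concentration (they are prepared
from the same equilibrated stocks), and the positively charged protein
carries no cation atmosphere of its own (protein titrations show essentially
flat ion counts and diffusion coefficients). The complexed fraction defaults
to the tight-binding limit $\min(P, M)/M$ — appropriate for nanomolar
dissociation constants at millimolar concentrations — with the exact 1:1
quadratic available for finite affinity. Uncertainty is first-order
propagation of the three diffusion-coefficient errors; replicate-based
errors can be compared when replicate fits exist, since which convention a
published ±  follows is often unstated.

**Line shapes.** Spectra are modeled as sums of absorption-mode Lorentzians
parameterized directly in $R_2$ (FWHM $= R_2/\pi$), plus a constant
baseline; phase errors are not modeled, but asymmetric residuals flag them.
Initialization is data-driven (peak height at each initial center, local
half-height extent as the width guess), which keeps multi-line fits out of
local minima. Components whose parameters correlate above 0.99 are flagged
as unresolved rather than reported silently.

## Units and constants

Internally everything is SI (m² s⁻¹, T m⁻¹, s, mol L⁻¹); conversion to the
reporting units of the field (G cm⁻¹, 10⁻⁵ cm² s⁻¹, mM) happens only at
I/O boundaries, which eliminates the unit mixing the b-factor invites.
γ(²³Na) is derived from γ(¹H) through the dimensionless ratio 0.2645 rather
than taken from an external table, so the constant matches the convention
used in low-γ diffusion work. The entropy of release is reported on the
molar scale, $-R\ln(D_b/D_f)$ with $R = 1.98720$ cal mol⁻¹ K⁻¹, i.e. in
entropy units (eu) per ion; this interpretation of "eu per ion" is validated
by the tests against tabulated per-ion values computed from the same
diffusion coefficients.

## What the synthetic data emulate — and what they do not

Every input the fitters consume has a seeded generator
(`gen_decay_series()`, `gen_dna_titration()`, `gen_competition_series()`,
`gen_quant_series()`, `gen_spectrum()`, `gen_r2_titration()`) that draws
from the corresponding forward model with Gaussian noise — by default 1 %
relative, consistent with the ~1–2 % standard errors typical of replicated
diffusion measurements, and three replicates per condition to exercise the
SEM pathway. The generators reproduce the *statistical structure the
analysis assumes*: monoexponential decays in $g^2$, population-averaged
titrations, Lorentzian lines, independent Gaussian noise. They deliberately
do not simulate eddy currents, convection, phase errors, baseline roll,
$B_1$ inhomogeneity or temperature drift. Passing round-trip tests
therefore demonstrates correctness of the estimators under the model, not
robustness to instrumental artifacts — the hardware mitigations (coaxial
geometry, eddy-current delays) that justify the clean model are experimental
context, not computation.

Default study conditions are those of the reference system the package is
tested against: a 15-bp DNA duplex titrated at eight concentrations between
0.21 and 1.74 mM in a 20 mM Na⁺ buffer, gradient grids of 25 strengths
spanning 2–265 G/cm, a free-ion diffusion coefficient of
1.251 × 10⁻⁵ cm² s⁻¹, and an atmosphere of 25.5 ions per duplex.

## Numerical choices and problem sizes

All nonlinear fits use Levenberg–Marquardt with box bounds
(`minpack.lm`), initialized from closed-form or data-driven guesses, with
convergence and bound-hitting always surfaced in the result object rather
than silently accepted. One-parameter fits are additionally checked against
brute-force grid searches in the tests. Monte-Carlo recovery studies — in
the test suite and the acceptance script — use 200 simulated titrations per
fitter at the noise level of the study conditions; at these sizes the full
suite runs in seconds while the recovery means are stable to well within
the published uncertainties of the corresponding parameters.

## Known limitations

* Strictly two states: no multi-site or multi-state exchange models.
* The competition stage fits diffusion data only; the analogous fit to
  relaxation rates is known to show systematic deviations (bound and free
  R₂ may themselves depend on the competitor concentration), so the package
  exposes the R₂ data path for diagnostics but does not fit a relaxation
  competition model.
* No quadrupolar relaxation theory: fitted R₂ values are descriptive, and
  the bound-state rate is not interpreted mechanistically.
* No time-domain processing: spectra are consumed (and generated) in the
  frequency domain; vendor raw-data directories are out of scope behind a
  single reader seam.
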