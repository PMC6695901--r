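---
title: "Models and methods for mucin film analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for mucin film analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mucofilm)
```

Mucus owes its barrier and clearance properties to mucin, a densely
glycosylated gel-forming protein. This package implements the analysis
chain used to characterise mucin at three levels — the bulk solution mesh
(SAXS), deposited thin films (QCM-D) and films on model membranes
(neutron reflectometry) — together with synthetic-data generators that
let the whole chain be validated by parameter recovery. This vignette
documents the models, the defaults and why they were chosen, the
numerical tactics, and the limits of what the validation shows.

## Bulk solution: SAXS models

The working decomposition is $I(q) = N V^2 \Delta\rho^2 P(q) S(q)$ with
interparticle interference neglected for dilute polymer solutions
($S \approx 1$).

**Gaussian coil.** `debye_form_factor()` is the Debye function
$P(q) = 2(e^{-x} + x - 1)/x^2$, $x = (q R_g)^2$. For $x < 10^{-4}$ a
four-term Taylor series replaces the closed form, which otherwise loses
all precision to cancellation; the series switch is continuous to better
than $10^{-9}$. `fit_gaussian_coil()` wraps the model in bounded
Levenberg–Marquardt least squares (weights $1/\sigma$ when the curve has
uncertainties, unweighted otherwise). Identifiability needs data spanning
$qR_g$ from below 1 to beyond 2; on a featureless curve the fit honestly
reports non-convergence or a standard error exceeding the estimate.

**Guinier analysis.** `guinier_fit()` regresses $\ln I$ on $q^2$ inside a
self-consistent window: fit, recompute $q_\mathrm{max} = $
`qrg_limit`$/R_g$ from the current estimate, repeat to a fixed point
(relative tolerance $10^{-3}$ on $R_g$, at most 50 iterations, ties
resolved toward the widest admissible window). Two behaviours are
deliberate:

* On data generated by the Debye model the Guinier estimate is biased
  *low* by a few percent at the default `qrg_limit = 1` (the Debye
  expansion $1 - x/3 + x^2/12$ lies above the Gaussian
  $e^{-x/3}$); the test suite pins this bias below 5%.
* When even the smallest measured $q$ violates $q_\mathrm{min} R_g < 1$
  the radius is only a lower bound and `is_lower_bound` is set — the
  correct way to report clusters larger than the window resolves, and the
  gyration (not hard-sphere) convention is used throughout.

**Dumbbell mucin model.** `dumbbell_intensity()` sums a "peptide" term —
an Ornstein–Zernike lorentzian of correlation length $\xi$ plus a low-$q$
power law $I_2/(\Xi q)^n$ — and a "globule" term of Schulz-polydisperse
spheres with a Percus–Yevick hard-sphere structure factor. The additive
OZ-plus-power-law reading is the standard mucin chain model in the
scattering literature; the alternative readings of the chain term differ
only in how the two amplitudes are parameterised and can be swapped in by
calling the component functions directly. Polydispersity uses a Schulz
(gamma) radius distribution (default relative width 0.2, a typical value
for biological globule populations) averaged with $V^2$ intensity
weighting over a 61-node quantile grid, and the structure factor is
applied at the mean radius in the local-monodisperse sense — adequate at
the moderate polydispersity and volume fractions used here.

**Percus–Yevick structure factor.** `py_structure_factor()` evaluates the
analytic Ashcroft–Lekner solution for monodisperse hard spheres. The
three trigonometric brackets cancel to leading orders $A^4$–$A^6$ in the
scaled variable $A = 2qR$, so below $A = 0.3$ the code switches to an
$O(A^4)$ Taylor series; at $A = 0$ this reproduces the compressibility
limit $S(0) = (1-\varphi)^4/(1+2\varphi)^2$ to floating-point accuracy,
which the tests assert for $\varphi$ up to 0.5.

**Mixture diagnostic.** For a mucin/polymer mixture that does not
interact, the intensity is the pointwise sum
$I_\mathrm{mixed} = I_\mathrm{mucin} + A\,I_\mathrm{polymer}$ with $A$
the polymer weight factor (1 and 2 for the 1:1 and 1:2 weight ratios).
`mixture_model()` implements exactly this — mismatched $q$ grids are an
error, never silently interpolated — and `excess_intensity()` subtracts
the null from a measurement. A positive low-$q$ excess with a steep
power-law slope (the synthetic truth uses $-3.7$, in the surface-fractal
band $(-4, -3]$) indicates compact clusters; slopes in $(-3, -1.5]$
indicate mass-fractal networks. The classification bands are inclusive at
their steep edge.

## Thin films: QCM-D

`dissipation_factor()` implements $D = 1/(f\tau_0)$ from the ring-down
decay time as the primary form, because that is the relation the
instrument software applies; the conventional $D = 1/(\pi f \tau)$ is
available via `pi_convention = TRUE` (the two differ by the constant
$\pi$ and never mix within an analysis).

`sauerbrey_constant()` computes $C = \sqrt{\rho_q \mu_q}/(2 f_0^2)$; with
the standard AT-cut quartz values $\rho_q = 2648$ kg/m³ and
$\mu_q = 2.947\times10^{10}$ Pa at $f_0 = 5$ MHz this gives
17.7 ng/(cm²·Hz), and it scales as $f_0^{-2}$.

`segment_trace()` splits a trace at annotated injection/rinse events and
estimates each step's plateau as the **median of the trailing 20%** of
the window — robust to injection transients; the fraction is an argument,
and windows with fewer than five samples fall back to the whole window
with a warning. Step shifts are reported raw and overtone-normalised, and
the harmonic spread (max − min of $\Delta f/n$ across overtones) measures
how ideal-rigid the film is: zero for a perfectly rigid coupled mass.

The Sauerbrey conversion is only applied as an *estimate* and is guarded
by `rigidity_check()`: a step is rigid when the largest dissipation
change stays at or below $0.5\times10^{-6}$ (inclusive). Viscoelastic
(Voigt) modelling is out of scope by design — for the thin, low-$\Delta D$
films targeted here the correction is smaller than the calibration
uncertainty.

One arithmetic point the package reports honestly: a film of 55 ng/cm² at
$\rho = 1.05$ g/cm³ is $d = \Delta m/\rho \approx 5.2$ Å. A
reflectometry fit of the same film gives 22 Å because NR sees the
*solvated* layer while the Sauerbrey mass here reflects the adsorbed
material; `thickness_from_mass()` never rescales one to match the other.

## Films at interfaces: neutron reflectometry

**Forward model.** `abeles_reflectivity()` is the exact recursive optical
matrix (Parratt) calculation over homogeneous slabs, with normal
wavevectors $k_j = \sqrt{(q/2)^2 - 4\pi(\rho_j - \rho_\mathrm{fronting})}$
(complex below an interface's critical edge) and Gaussian interfacial
roughness via the Névot–Croce factor $e^{-2 k_j k_{j+1}\sigma^2}$ on each
Fresnel coefficient. $\sigma = 0$ reproduces the sharp-interface result
exactly; total reflection $R = 1$ holds below
$q_c = \sqrt{16\pi\,\Delta\rho}$; and $0 \le R \le 1$ always (asserted on
randomized stacks). A slab's roughness belongs to its interface with the
slab above (toward the silicon fronting); the backing interface has its
own value. Roughness exceeding half the smaller adjacent thickness
triggers a warning because the slab picture degrades there.

**Kinematic cross-check.** `born_reflectivity()` evaluates the
single-scattering form
$R = 16\pi^2 |\sum_i \Delta\rho_i e^{iqz_i} e^{-q^2\sigma_i^2/2}|^2 / (q^2 q'^2)$
from the analytic Fourier transform of the roughness-smoothed
piecewise-constant profile. By default the second denominator factor is
the refraction-corrected $q'^2 = q^2 - q_c^2$ of the fronting/backing
edge — the standard distorted-wave substitution, without which the raw
kinematic $1/q^4$ form only converges to the matrix result as
$(q_c/q)^2$ and misses the 5% level until $q \gtrsim 5 q_c$;
`refraction = "none"` recovers the raw form. With the correction, matrix
and kinematic calculations agree within 5% above $3q_c$ for
weak-contrast slabs, *except* in the immediate vicinity of deep
destructive Kiessig minima, where a relative comparison of two
near-zeros is meaningless; validation geometries therefore use unequal
interface steps so minima stay shallow.

**Resolution.** `smear()` convolves with a Gaussian of pointwise width
$\sigma_q = (dq/q)\,q$, evaluated by 15-node Gauss–Hermite quadrature
with linear interpolation between grid points. The instrument-style
"10% wavelength spread" is treated as FWHM-like, so the default is
$\sigma/q = 0.1/2.355$; `convention = "sigma"` takes the number as is.
`reflectivity_model()` computes the unsmeared curve on an internally
extended, three-fold oversampled grid before convolving, so edge effects
never bias the model inside the measurement window.

**Materials and contrast.** SLDs come from $\rho = \sum_j b_j n_j$ over
the formula unit, with an embedded table of coherent scattering lengths
(Sears values; H and D distinct) and the formula-unit volume fixed by the
protiated molar mass and mass density. Each labile hydrogen contributes
$b_H + x\,e\,(b_D - b_H)$, with $x$ the solvent D₂O fraction and $e$ the
exchange efficiency (default 0.9 — the common allowance for partially
buried –OH/–NH sites; exposed as an argument). Because this is linear in
$x$, a dry SLD is fully specified by its H₂O and D₂O endpoint values, and
slabs accept exactly that affine pair. Solvent SLD interpolates linearly
between pure H₂O ($-0.56\times10^{-6}$ Å⁻², 1.000 g/cm³) and pure D₂O
($6.36\times10^{-6}$ Å⁻², 1.105 g/cm³); physiological salt shifts the
value by under 1% and is recorded as a label only. Mucin's dry
composition is not known well enough to compute its SLD from a formula,
so the scenario stacks carry the affine pair inferred from fitted layer
SLDs via `infer_dry_sld()` ($4.54/5.09\times10^{-6}$ Å⁻² at 60%
occupation), and a fit is free to move it.

**Co-refinement.** `corefine()` minimises the summed per-contrast
$\chi^2$ with structural parameters shared across solvents and an
intensity scale and constant background per dataset as nuisance
parameters (beamline normalisation is never assumed perfect). The
optimizer is Levenberg–Marquardt with box bounds
(`minpack.lm::nls.lm`, 200 iterations), restarted from five jittered
starting points (deterministic given `seed`; jitter ±30% within bounds)
to guard against local minima; the best run wins. Standard errors come
from the local covariance at the optimum, and per-contrast $\chi^2$ is
reported so a contrast that misfits cannot hide in the sum. Default
bounds are physical: $\varphi \in [0,1]$, roughness in $[0,15]$ Å,
thickness in $[0, \max(3\times\text{start}, 100)]$ Å, scale in
$[0.3, 3]$.

**Scenario stacks.** `stack_scenario()` encodes the five interface models
used across the package, with two kinds of defaults deliberately
distinguished: film parameters taken as *generating truths* for the
synthetic studies (mucin 22 Å at 60% occupation; post-rinse 20 Å at 50%;
a highly hydrated 70 Å polymer overlayer; 30 Å mucin on the
GM1-containing membrane, whose lipid region carries 30–35% solvent), and
*declared assumptions* where no published value exists (SiO₂ 12 Å at SLD
$3.47\times10^{-6}$ Å⁻², roughnesses 2–4 Å, a 6 Å water gap under
supported bilayers, DPPC headgroup/tail SLDs $1.88/-0.4\times10^{-6}$
Å⁻² with 8/30/8 Å thicknesses — standard supported-DPPC practice). The
reporting layer of `run_pipeline()` states which parameters were fitted
and which held at these defaults.

## Synthetic data: what it emulates, and what it does not

* `make_saxs_dataset()` — component curves, the additive mixture, and a
  "clustered" mixture with a $q^{-3.7}$ low-$q$ tail, on the
  experimental window $7\times10^{-3}$–6 nm⁻¹, with relative Gaussian
  noise (default 2%).
* `make_nr_dataset()` — smeared two-contrast reflectivity on a log grid
  0.008–0.25 Å⁻¹ (90 points per contrast), with relative errors growing
  as $R^{-1/3}$ from a 1% floor to a 20% ceiling, emulating counting
  statistics without modelling the instrument; a Poisson-counts mode is
  available.
* `make_qcmd_trace()` — the five-step injection/rinse staircase
  (baseline, mucin adsorption at 55 ng/cm² with $\Delta D = 0.3\times
  10^{-6}$, rinse, polymer at $\Delta f/n = -6$ Hz, final rinse with
  material loss) with exponential plateau approach (time constant 30 s,
  consistent with equilibration within minutes) and optional drift.

All generators are deterministic given their seed, restore the caller's
random stream, and serialise their truth parameters with the data, so
recovery tests never re-enter values by hand.

What passing these tests demonstrates: the estimators are unbiased and
precise *when the model class matches the data-generating process and
the noise is as assumed*. What they cannot demonstrate: robustness to
instrument backgrounds, off-specular scattering, multiple scattering,
imperfect buffer subtraction, or sample-to-sample biological
variability — none of which the generators model, all of which real
beamline data contain.

## Problem sizes and determinism

The validation studies use 140-point SAXS curves, 90 points per
reflectivity contrast, five-overtone QCM-D traces sampled at 1 Hz over
50 minutes, and ten independent noise seeds for the recovery experiment —
sizes at which every individual fit completes in seconds and the full
suite in about a minute, while leaving the estimators' uncertainties
clearly resolvable. Every random draw is seed-controlled; rerunning the
pipeline with the same configuration and seed produces a byte-identical
machine-readable summary.

## Known limitations

* Viscoelastic QCM-D modelling and coupled-water partitioning are not
  implemented; Sauerbrey numbers for non-rigid steps are flagged, not
  corrected.
* The dumbbell model's peptide amplitudes are reported as fitted
  quantities only; absolute-scale molecular-weight extraction from
  $NV^2$ is out of scope, as are X-ray contrasts computed from atomic
  form factors (SAXS fits operate on relative intensities).
* The local-monodisperse polydispersity approximation degrades above
  hard-sphere volume fractions of roughly 0.4 combined with broad size
  distributions.
* Freeform SLD profiles, off-specular and magnetic reflectometry, and
  instrument-specific resolution kernels beyond Gaussian $dq/q$ are not
  supported.
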