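---
title: "Methods: second-harmonic scattering titrations of protein adsorption"
author: "shsbind"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: second-harmonic scattering titrations of protein adsorption}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shsbind)
```

## The physical model

Nonresonant second-harmonic scattering (SHS) from a suspension of charged
spheres has two coherent sources. The interface itself breaks
centrosymmetry and contributes an effective second-order susceptibility
$\chi^{(2)}$. In addition, the static field of the electrical double
layer aligns and polarises water molecules over a shell of thickness
$\sim 1/\kappa$ (the Debye length), contributing a third-order term
proportional to the surface potential $\Phi_0$. For one particle of
radius $R$,

$$ I(2\omega) \;\propto\; \bigl|\,F_{\mathrm{surf}}(qR)\,\chi^{(2)}
   + F_3(\kappa R, qR)\,\Phi_0\,\chi^{(3)}\bigr|^2 ,$$

with the scattering vector $q = (8\pi n/\lambda)\sin(\theta/2)$ (the
medium is taken dispersionless, so the fundamental and second-harmonic
wave vectors have magnitudes in ratio 1:2). The suspension adds
incoherently, so the intensity scales linearly with particle number
density.

**Form factors.** `surface_form_factor()` evaluates the surface integral
of $e^{i\mathbf q\cdot\mathbf r}$ times powers $m = 0..3$ of the normal
projection $\hat n\cdot\hat q$, which reduce to closed forms in spherical
Bessel functions ($4\pi R^2 j_0$, $4\pi R^2 i\, j_1$,
$\tfrac{4\pi R^2}{3}(j_0 - 2j_2)$,
$\tfrac{4\pi R^2}{5} i\,(3 j_1 - 2 j_3)$). The full polarisation tensor
algebra is deliberately reduced to two scalar channels built from these
moments: *ppp* uses the longitudinal weight $\mu$ ($\propto j_1$), *pss*
the transverse weight $\mu(1-\mu^2)$ ($\propto \tfrac{2}{5}(j_1+j_3)$).
This keeps every qualitative feature that matters for titrations (a
forward null, a finite-angle maximum, screening sensitivity) while
avoiding full 2$\omega$ polarimetry, which is out of scope.

**The $\chi^{(3)}$ term.** `bulk_chi3_form_factor()` integrates the
radial static field of the linearised (Debye–Hückel) potential
$\Phi(r) = \Phi_0 (R/r) e^{-\kappa(r-R)}$ over the volume outside the
sphere, weighted by $e^{i\mathbf q\cdot\mathbf r}$ and the channel
weight. The angular part is analytic; the radial integral is evaluated
by composite Simpson quadrature with the node count scaled to the number
of oscillations, truncated at $r = R + 20/\kappa$ (the neglected tail is
below $3\times10^{-9}$ of the integrand scale). The linearised profile is
consistent with the diffuse-layer, low-potential assumption behind the
sphere charge–potential relation below; a nonlinear profile is a
limitation, not an option.

## Electrostatics

All double-layer quantities derive from `solution_conditions()`
(temperature, relative permittivity, valence $z$ of the symmetric
electrolyte, bulk concentration) and CODATA constants
(`physical_constants()`).

* Planar surfaces follow the Grahame equation
  $\sigma_0 = (2\varepsilon_0\varepsilon_r \kappa k_BT/ze)
  \sinh(ze\Phi_0/2k_BT)$, inverted in closed form through
  $\mathrm{asinh}$.
* Spheres use the Ohshima–Healy–White approximation, the Grahame
  prefactor times
  $\sqrt{1 + \frac{1}{\kappa R}\frac{2}{\cosh^2(y/4)} +
  \frac{1}{(\kappa R)^2}\frac{8\ln\cosh(y/4)}{\sinh^2(y/2)}}$ with
  $y = ze\Phi_0/k_BT$. The $y\to0$ limit of the bracket is taken
  analytically ($\to (1 + 1/\kappa R)^2$, the exact Debye–Hückel sphere
  capacitance); numerically the series switch is at $|y| < 10^{-5}$.
* No closed-form inverse exists for the sphere, so
  `potential_from_sigma_sphere()` exploits strict monotonicity:
  safeguarded bracketing from the Debye–Hückel estimate (which always
  over-brackets, since the relation is superlinear), `uniroot` with
  interval extension, then Newton polishing until the residual in
  $\sigma$ is below $10^{-10}$ relative. Robustness was preferred over
  speed; the inversion is never in an inner loop.
* ζ-potentials are converted by treating ζ as equal to $\Phi_0$. This is
  an approximation (the slip plane lies outside the surface) and is
  flagged in the metadata of every `zeta_to_sigma()` result.

Defaults $\varepsilon_r = 78.4$ and $T = 298.15$ K correspond to the
temperature at which ζ-potentials are conventionally measured; both are
plain arguments. Only symmetric $z\!:\!z$ electrolytes are supported;
mixed electrolytes, Stern layers and charge regulation are out of scope.
A high-valence electrolyte is also how a multivalent protein environment
is emulated: at $z = 4$ the sphere relation collapses onto the planar
one over the ±150 mV window at the full scale of the curve.

## Adsorption and thermodynamics

Monolayer adsorption with bulk depletion couples the Langmuir isotherm
to the mass balance:

$$ \mathrm{ads} = \frac{N_{\max}\,K\,c_{\mathrm{free}}}
   {1 + K\,c_{\mathrm{free}}},\qquad
   c_{\mathrm{free}} = c_{\mathrm{tot}} - \mathrm{ads}. $$

Eliminating $c_{\mathrm{free}}$ gives a quadratic whose physical root is
evaluated as
$\mathrm{ads} = 2\,c_{\mathrm{tot}} N_{\max} /
\bigl(S + \sqrt{S^2 - 4 c_{\mathrm{tot}} N_{\max}}\bigr)$ with
$S = c_{\mathrm{tot}} + N_{\max} + 1/K$. This form avoids the
subtraction cancellation of the textbook root exactly where the physics
lives: in the strong-binding regime with $c_{\mathrm{tot}}\approx
N_{\max}$ the discriminant nearly vanishes. The tests verify agreement
with a bisection fixed-point oracle to $10^{-10}$ relative across six
decades in each of $c_{\mathrm{tot}}$, $K$ and $N_{\max}$.

**Parameter conventions.** $K_{\mathrm{app}}$ is parameterised in
1/molar, so the half-saturation *free* concentration is
$1/K_{\mathrm{app}}$; the solvent-molarity factor that sometimes
appears in this isotherm is absorbed into $K_{\mathrm{app}}$. The
apparent free energy uses the 1 M standard state,
$\Delta G^0_{\mathrm{app}} = -RT\ln(K_{\mathrm{app}}\cdot 1\,\mathrm M)$
at $T = 298.15$ K by default: this convention reproduces all nine
internally consistent $(K, \Delta G)$ pairs the package's presets carry,
whereas the 55.5 M convention does not. Both the standard state and the
temperature are arguments. Uncertainty propagates first order through
the logarithm, $\delta\Delta G = RT\,\delta K/K$.

**Charge bookkeeping on adsorption.** The magnitude of the surface
potential is observed to shrink when proteins adsorb, *even when protein
and surface carry the same charge sign* — counterion rearrangement that
no mean-field bookkeeping captures. `surface_charge_after_adsorption()`
therefore models the adsorbed layer as *screening* the bare charge:
$\sigma(\theta) = \sigma_{\mathrm{bare}} - \eta\,\theta\,
N_{\max}|z_p|e/(\pi D^2)\cdot\mathrm{sign}(\sigma_{\mathrm{bare}})$,
with an efficiency $\eta\in[0,1]$. A signed-valence form (adding
$z_p e$ per protein) was considered and rejected: for like-charged
proteins it *increases* $|\sigma|$ and makes an $\eta\in[0,1]$
calibration impossible. `charge_efficiency_from_endpoints()` calibrates
$\eta$ from a bare/saturated potential pair; the −42 mV → −31 mV
endpoints of serum albumin on 100 nm polystyrene give $\eta \approx
0.11$, i.e. each adsorbed protein effectively neutralises about one
elementary charge.

## The titration link and the fit

At fixed angle and ionic strength the form factors are constants and the
titration response reduces to two amplitudes. The default link takes the
scattered *field* linear in coverage
($\sqrt I = a - b\,\theta$, `field_linear`), because the
signal→potential→charge→coverage chain is linear at the field level
(linearised charge–potential map); an `intensity_linear` link exists for
sensitivity analysis. The headline derived quantities — $\Delta G$ from
$K$, areas from $N_{\max}$ — are robust to this choice. Saturated but
still-charged surfaces keep a finite residual intensity
($I_{\mathrm{sat}} > 0$); $I_{\mathrm{sat}} > I_0$ (charge-increasing
adsorbates) is allowed but warned about.

`fit_titration()` minimises
$\sum_i \bigl[(I_i^{\mathrm{obs}} - I_i^{\mathrm{model}})/\sigma_i\bigr]^2$
by Levenberg–Marquardt (`minpack.lm::nls.lm`), unweighted when no errors
are supplied. $K$ and $N_{\max}$ are shared across curves (the global
fit); $(I_0, I_{\mathrm{sat}})$ are per curve. Positivity is enforced by
fitting $\log K$ and $\log N_{\max}$; box constraints (defaults
$K \in [10^3, 10^{15}]$ 1/M, $N_{\max}^{\mathrm{vol}} \in [10^{-13},
10^{-1}]$ M) span everything physically plausible for protein adsorption
and only matter when a saturated titration leaves $K$ unidentified
upward. Initialisation: plateau means for the amplitudes, the half-drop
of $\sqrt I$ for the capacity (in the depletion regime adsorption is
stoichiometric, so the breakpoint sits near $N_{\max}^{\mathrm{vol}}$),
$K$ seeded at $10^9$ 1/M; a 3×3 multi-start grid (±1 decade in $K$,
±0.5 in $N_{\max}$) guards against local minima, best $\chi^2$ wins and
ties below $10^{-9}$ relative resolve toward the smaller $K$.
Non-monotone inputs trigger a coarse log-grid search before the local
optimiser.

**Identifiability.** In the strong-depletion regime
($1/K \ll N_{\max}^{\mathrm{vol}}$) nearly every added protein adsorbs
below saturation regardless of $K$: the curve determines the capacity
tightly while $K$ is constrained only by the softness of the breakpoint.
Wide, asymmetric $K$ intervals are therefore the *correct* answer there,
not a fitting failure. Flat curves are flagged (`identifiable_k`).

**Uncertainties.** `bootstrap_uncertainties()` refits resampled data
from the fitted optimum. Two resampling modes: (i) residual resampling
within each curve, standardised by the weights and inflated by
$\sqrt{n/\mathrm{dof}}$ (fitted residuals underestimate the noise
variance because the parameters absorb part of it); (ii) when the data
are replicate-averaged points with recorded standard errors,
`measurement_replicates` regenerates the whole acquisition — $m$ draws
per point, mean and re-estimated standard error — so that the sampling
noise of the error bars themselves, which feeds the fit weights, is also
propagated. Intervals span both the percentile and the basic (reflected)
bootstrap limits — a deliberately conservative construction, on the log
scale for $K$ (positive, strongly right-skewed) and the natural scale
for $N_{\max}$; a studentised (bootstrap-t) construction was evaluated
and rejected because curvature standard errors are unstable exactly in
the flat-likelihood cases that need the correction. $\Delta G$ intervals
map from the $K$ interval (linear in $\log K$); the analytic
$RT\,\delta K/K$ is reported alongside for comparison. The bootstrap
seed is mandatory; all runs are bit-reproducible.

## Synthetic data

`scenario_presets()` carries the nine studied systems — six 100 nm
particle/protein combinations (plain and carboxylated polystyrene with
fibrinogen, serum albumin, transferrin) and the serum-albumin size
series — with the reported $(K_{\mathrm{app}}, N_{\max})$ values as
ground truth, the corresponding number densities
($4.55\times10^{14}$, $1.31\times10^{13}$, $1.81\times10^{12}$ per
litre), ζ-potentials (−42/−44/−50/−54 mV) and size-specific detection
angles. Defaults chosen once:

* concentration grid: 15 log-spaced points, 1 nM–10 µM, straddling the
  depletion breakpoint of every preset;
* noise: multiplicative Gaussian, 2 % relative per measurement, each
  point the mean of 10 replicate draws with the standard error of the
  mean recorded — matching replicate-averaged fixed-angle acquisition;
* amplitudes: $I_0 = 1$, $I_{\mathrm{sat}}/I_0 = 0.545$, calibrated once
  from the only reported bare/saturated ζ pair (−42 → −31 mV) through
  the field-linear link ($ (31/42)^2 $);
* titrations in ultrapure water: residual ionic strength $10^{-6}$ M,
  with ζ-potentials referring to their 1 mM measurement conditions;
* protein net valences: −8 for serum albumin (reported near pH 6.6);
  −10 for fibrinogen and −2 for transferrin are nominal near-neutral-pH
  literature-scale values — they enter only the optional charge-update
  operation, never the fits.

`make_pattern()` builds paired low/high ionic-strength pattern datasets
by holding the ζ-derived surface *charge* fixed and re-inverting for the
potential at each salt level — the composition of the electrostatics and
optics modules that the screening experiments probe.

What the generator emulates: the noise structure, depletion-regime curve
shapes, replicate averaging, angle tagging and the screening phenomenology.
What it does not: instrument drift, stirring and sedimentation,
aggregation events (relevant for near-neutral adsorbates), polydispersity,
multilayer or competitive (Vroman) adsorption, and the unknown true
experimental concentration spacings, which are only regime-matched.
Passing tests on synthetic data therefore demonstrate internal
consistency and statistical calibration of the estimator under the
assumed noise model — not that real titrations obey the modified
Langmuir model.

## Default optical amplitudes

`optical_amplitudes()` defaults to $\chi^{(2)} = 1$,
$\chi^{(3)} = 2\times10^{4}$ per volt (arbitrary common units): the
double-layer term then dominates at low ionic strength — consistent with
the signal originating mainly from field-aligned water — and the
low-salt *ppp* pattern of a 100 nm particle peaks near 35–40°. The
wavelength (1028 nm) and refractive index (1.33) are config keys; all
qualitative screening properties asserted by the tests (peak dimming
with salt, outward peak shift, enhanced sensitivity at the pattern
maximum versus 90°) are robust to these choices, and only the sign and
monotonicity of the peak shift are asserted — its magnitude depends on
unreported amplitude ratios.

## Problem sizes and numerical tolerances

The test suite runs the full estimator-calibration study at 100 seeded
replicates of the serum-albumin/100 nm preset (15 points, 2 % noise)
with 200 bootstrap refits each, a size chosen to estimate 95 % coverage
to a few percent while keeping the suite fast; the oracle-equivalence
checks use 6-decade parameter grids (isotherm), $qR \le 50$ (surface
form factors, $10^{-6}$ relative) and coarse 2-D quadrature
($\chi^{(3)}$, $10^{-4}$ relative). Inversion tolerances: $10^{-10}$
relative in $\sigma$; round trips verified at $10^{-8}$ V.

## Known limitations

* The Langmuir picture is a deliberate simplification: cooperativity,
  conformational spreading and competitive adsorption all bias
  $K_{\mathrm{app}}$ (typically downward), which is why every derived
  quantity is "apparent".
* ζ ≈ Φ₀ ignores the slip-plane offset; the resulting σ values for
  larger particles are expected to be a few-to-ten percent low.
* The χ⁽³⁾ model uses the linearised double-layer profile and scalar
  polarisation channels; Mie corrections, resonant enhancement and
  multiple scattering are out of scope.
* Equilibrium only: no kinetics, and $k_a$, $k_d$ are never separated.
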