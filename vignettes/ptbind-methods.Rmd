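---
title: "Models and methods behind ptbind"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ptbind}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ptbind)
```

ptbind implements the quantitative analyses used to characterize how
cationic Pt(II) phenyl-terpyridine complexes bind small model proteins
(hen egg-white lysozyme, HEWL; ribonuclease A): binding constants from
differential UV-Vis titrations, two-state unfolding thermodynamics from
DSC, and adduct mass bookkeeping for deconvolved intact-protein ESI-MS.
Because raw instrument files for such studies are rarely deposited, each
analysis is paired with a seeded simulator that generates data with
exactly the statistical structure the estimator assumes, so the whole
chain is testable end to end with known ground truth.

## 1. Spectrophotometric binding analysis

### Model

For the equilibrium `protein + PtL <=> protein-PtL` with binding constant
$K$, total (analytical) concentrations $C_\mathrm{PtL}$ and $C_P$, and $n$
independent equivalent sites per protein, the bound concentration $x$
solves the mass-action quadratic

$$K x^2 - \bigl(K (C_\mathrm{PtL} + n C_P) + 1\bigr) x
  + K\, n C_P C_\mathrm{PtL} = 0 .$$

`solve_equilibrium()` takes the physical (smaller) root in the stable form
$2c/(b + \sqrt{b^2 - 4ac})$, which is exact from $K = 0$ up to the
stoichiometric limit. The observable is the differential absorbance at an
analysis wavelength, $\Delta A = A - \varepsilon_\mathrm{PtL}
C_\mathrm{PtL} l = \Delta\varepsilon\, l\, x$, where $\Delta\varepsilon$
is the bound-minus-free absorptivity difference (negative for
hypochromism).

### The iterative linearized estimator

`fit_binding()` uses the classical linearization: with
$X = C_\mathrm{PtL} + C_P$ and
$Y = C_\mathrm{PtL} C_P/\Delta A + \Delta A/\Delta\varepsilon^2$, 1:1
mass-action data fall on a straight line with slope $1/\Delta\varepsilon$
and intercept $1/(K\Delta\varepsilon)$, so $K$ is the slope/intercept
ratio. Since $\Delta\varepsilon$ appears in $Y$, the first pass drops the
$\Delta A/\Delta\varepsilon^2$ term and the reciprocal slope is then
re-fed until self-consistent.

Two numerical facts shape the implementation:

* Because $Y$ is *linear* in $1/\Delta\varepsilon^2$, the self-consistency
  condition $\Delta\varepsilon = 1/\mathrm{slope}(\Delta\varepsilon)$ is a
  quadratic $a\Delta\varepsilon^2 - \Delta\varepsilon + c = 0$ in
  $\Delta\varepsilon$, with $a, c$ computable from the data once. The
  fixed-point iteration can possess two roots; for strongly bound
  isotherms ($K \gtrsim 3\times 10^4$ M$^{-1}$ in the default
  concentration regime) the naive reciprocal-slope update is attracted to
  the unphysical one. `fit_binding()` therefore runs the iteration for its
  diagnostic trace and then snaps to the closed-form root at which the
  transformed points are most nearly collinear — exactly collinear for
  model data. Convergence tolerance is $10^{-6}$ relative on
  $\Delta\varepsilon$.
* The regression is ordinary unweighted least squares on the transformed
  variables, matching the straight-line treatment standard in this field.
  The transform makes absorbance noise heteroscedastic, so the reported
  regression standard errors are optimistic under noise; the direct
  nonlinear fit below carries the calibrated uncertainties.

Points with $C_P = 0$ are excluded; $\Delta A = 0$ points are dropped with
a warning; if $\Delta A$ changes sign across the series (isosbestic
drift), the minority-sign points are dropped with a warning; fewer than 4
usable points is a hard error. When the intercept is statistically
indistinguishable from zero ($|t| < 2$) the isotherm carries no curvature
information and `K_unreliable` is flagged.

### Scatchard analysis

`fit_scatchard()` fits the equivalent-sites line
$C_P (C_\mathrm{PtL}\Delta\varepsilon - \Delta A)/\Delta A =
 1/(nK) + (C_\mathrm{PtL}\Delta\varepsilon - \Delta A)/ (n\Delta\varepsilon)$,
i.e. the classical $[L]/r$ versus $[L]$ form written in absorbance
variables ($C_\mathrm{PtL}\Delta\varepsilon - \Delta A =
\Delta\varepsilon\,[\mathrm{PtL}]_\mathrm{free}$). $\Delta\varepsilon$ is
an input — it comes from the isotherm amplitude and is confirmed by the
1:1 analysis — and the fit returns the site number $n$ and $K$. When the
free-ligand abscissa spans less than a decade, $n$ is flagged poorly
determined.

### The direct nonlinear reference fit

`fit_binding_nls()` minimizes
$\sum(\Delta A_i - \Delta\varepsilon\, x(K))^2$ directly. For fixed $K$
the optimal $\Delta\varepsilon$ is a linear projection, so the objective
is profiled to one dimension and minimized over $\log_{10} K$ from a
coarse grid. This fit exists to expose linearization bias: on noiseless
data it must agree with the iterative estimator (the package tests
require agreement to $10^{-3}$ relative over
$K = 10^2\ldots10^5$ M$^{-1}$), and under noise its asymptotic standard
errors are the calibrated ones — the test suite verifies at least 80%
empirical coverage of the $\pm 2$ SE interval over 400 simulated
titrations at $\sigma_A = 0.002$ AU, a calibration the linearized OLS
errors do not reach.

### Defaults, with units and reasons

| parameter | default | why |
|---|---|---|
| $C_\mathrm{PtL,0}$ | $1.304\times10^{-4}$ M | 150 µL of a $10^{-3}$ M stock diluted into 1.15 mL |
| protein stock | $2.0\times10^{-3}$ M | titrant concentration used in the cell |
| addition volume | 8.2 µL | one turn of the micrometric-screw syringe |
| additions | 15 | reaches $C_P \approx 2\times10^{-4}$ M, i.e. $K C_P \approx 1\ldots3$ for the reported affinities |
| $\sigma_A$ | 0.002 AU | realistic dual-beam spectrophotometer noise |
| path length | 1.0 cm | quartz cuvette |
| analysis wavelength | argmax of the first/last spectral change | band positions are known (378 nm, ~450 nm) but no analysis wavelength is reported; the choice is overridable |
| tol, max_iter | $10^{-6}$, 100 | iteration control; the closed-form snap makes this generous |

### Dilution conventions

Real titrations dilute the complex as titrant is added. Two mutually
consistent conventions are supported:

* **actual-totals** (default, exact): spectra as recorded, with the true
  per-point analytical totals. The mass-action model is exact here, so
  noiseless simulated data are recovered to numerical precision.
* **initial-volume** (instrument convention): spectra multiplied by
  $(V_0 + V)/V_0$ (`correct_dilution()`) with totals on the same scale.
  In this convention a two-species system shows a volume-independent
  isosbestic point, but the equilibrium quotient is not exactly invariant
  under the common rescaling, so fits in this convention carry a small
  ($\sim$ dilution-sized) systematic error.

The simulator emits the first convention and reports the isosbestic
wavelength in its ground-truth attribute; the isosbestic constancy is a
property of the corrected spectra.

## 2. DSC two-state analysis

### Model

The single-step equilibrium (two-state) excess molar heat capacity is

$$\Delta G(T) = \Delta H_{vH}\Bigl(1 - \frac{T}{T_d}\Bigr)
 + \Delta C_p\Bigl[(T - T_d) - T\ln\frac{T}{T_d}\Bigr], \qquad
 f_D = \frac{e^{-\Delta G/RT}}{1 + e^{-\Delta G/RT}},$$

$$C_p^{exc}(T) = \Delta H(T)\,\frac{df_D}{dT} + f_D\,\Delta C_p,
 \qquad \frac{df_D}{dT} = \frac{\Delta H(T)\, f_D (1 - f_D)}{R T^2},$$

with $\Delta H(T) = \Delta H_{vH} + \Delta C_p (T - T_d)$. With
$\Delta C_p = 0$ the curve's area equals $\Delta H_{vH}$ and its value at
$T_d$ equals $\Delta H_{vH}^2/(4 R T_d^2)$. Note the *maximum* of
$C_p^{exc}$ sits slightly below $T_d$ — the offset shrinks as
$1/\Delta H^2$ and stays under 0.1 K for the enthalpies relevant here:
`find_td()` reports the peak position, whereas the fitted $T_d$ is the
true midpoint. $\Delta C_p$ defaults to 0 (the analysis reports $T_d$ and
$\Delta H$ only) and can be freed with a flag. Internally everything is in
K and kJ/mol; files are read and written in °C with the exact offset
273.15.

### Procedure

1. `subtract_baseline()` removes the chemical baseline with a sigmoidal
   progress construction: straight-line fits in a pre- and post-transition
   window (defaults: first and last 10% of the scan) joined by the
   normalized running integral of the signal, iterated twice. Windows must
   not overlap the transition — with a 20–95 °C scan this precondition
   fails for transitions whose tails reach past ~88 °C, and the function
   rejects windows containing the peak.
2. `integrate_enthalpy()` gives the calorimetric enthalpy as the
   trapezoidal peak area.
3. `fit_two_state()` fits $(\Delta H_{vH}, T_d)$ by Levenberg–Marquardt
   (minpack.lm), started from the peak position and area. The
   $\Delta H_{vH}/\Delta H_{cal}$ ratio diagnoses cooperativity, and the
   fit is declared **FAILED** when the RMS residual exceeds 5% of the peak
   height. This threshold is a package decision: heterogeneous
   protein–ligand populations produce shouldered, asymmetric endotherms
   that a single two-state curve cannot track. A 0.6/0.4 mixture of
   components 6 K apart fails robustly, while components only 4 K apart
   are still absorbed by a single two-state shape (both asserted by the
   test suite): the diagnostic catches separations from roughly 0.75 of
   the transition width (FWHM ≈ 8 K at 450 kJ/mol) upward.
4. `entropy_at_td()` applies $\Delta S_d = \Delta H/T_d$ (from
   $\Delta G(T_d) = 0$), the quantity through which destabilization at
   constant enthalpy reads as entropic.
5. `correct_native_loss()` rescales thermograms of incubated samples by
   $1/\prod(1 - \mathrm{loss})$, composing sequential losses (e.g. 12%
   after 24 h and a further 9% over the next 24 h gives
   $1/(0.88 \times 0.91)$). Irreversible-denaturation kinetics are only
   diagnosed through this enthalpy decrease, not modelled.

## 3. ESI-MS adduct bookkeeping

Deconvolved intact-protein masses are average-mass scale, so all adduct
arithmetic uses average atomic masses from an embedded table (IUPAC 2021
conventional values), fixed at build time for bit-for-bit reproducibility.
A bound metal fragment of charge $q$ displaces $q$ protons:

$$M(k) = M_0 + k\,\bigl(\bar m_\mathrm{frag} - q\, m_H\bigr).$$

For the dicationic Pt(phenyl-terpyridine) fragment (C21H15N3Pt, 504.46 Da
average) with $q = 2$ this increment is 502.44 Da, reproducing the printed
RNase A mono-adduct (13682 → 14184 Da) and bis-adduct (14687 predicted vs
14686 printed) within 1 Da. The printed HEWL adduct (14807 Da) is 1 Da
above the $q = 2$ prediction; whether that peak retains one proton
($q = 1$) or is within experimental error cannot be decided from the
masses alone, so $q$ is configurable per fragment and defaults to 2.
Free-protein masses are inputs, not computed from sequence.

`assign_adducts()` matches peaks against
protein + $k\times$fragment (+ at most one small-anion adduct) with a
1.5 Da default tolerance, reflecting the 1 Da-scale spread of deconvolved
masses. Sulphuric and phosphoric acid (both ≈ +98 Da, 0.078 Da apart)
are the default small adducts; any two candidate compositions within
tolerance and within 0.5 Da of each other are flagged ambiguous and both
reported, never silently resolved.

`deconvolve_envelope()` is a minimal re-implementation of charge-envelope
deconvolution for the simulators' profile spectra: detect centroids,
propose a neutral mass from every centroid/charge pair, score each
candidate by summed matched intensity across the charge range (0.5 m/z
matching tolerance), require at least 3 matched charge states, and refine
accepted masses as intensity-weighted means of the implied masses. It
recovers 10–20 kDa species to well under 1 Da noiseless and under 2 Da at
2% multiplicative intensity noise. It is not an isotope-resolved or
Bayesian deconvolver and is not intended for real crowded spectra.

## 4. What the simulators do and do not emulate

`simulate_titration()` builds spectra from two Gaussian absorptivity bands
(free, and bound = shifted + rescaled so the change at the free band
maximum equals $\Delta\varepsilon$), which guarantees Beer–Lambert
linearity, a single isosbestic crossing, and zero protein absorbance (the
differential two-cell design). Real band shapes, baseline drift,
scattering from incipient precipitation, slow kinetics and cooperative
multi-equilibria are *not* emulated — so passing recovery tests shows the
estimators are correct for the model they assume, not that real isotherms
are always this well behaved. Distorted isotherms in real data are
flagged through the residual runs test in `summary()` rather than fitted
with multi-equilibrium models.

`simulate_dsc()` superposes two-state components with Gaussian noise
scaled to peak height (default 1%); it does not simulate scan-rate
effects, aggregation exotherms, or Lumry–Eyring kinetics.
`simulate_esi_spectrum()` places Gaussian peaks on a uniform m/z grid with
a Gaussian charge-state envelope and multiplicative noise; it does not
model isotope structure, adduct ionization bias, or detector saturation
(which is why occupancy is never quantified from intensities).

All three simulators are deterministic given a seed; the noiseless output
of each is exactly the forward model its estimator inverts, a property the
test suite asserts directly.

## 5. Problem sizes and reproducibility

The package tests run the full chains at the default sizes: 15-addition
titrations (16 spectra × 201 wavelengths), 751-point thermograms
(20–95 °C at 0.1 K), and 6401-point m/z traces. Monte-Carlo calibrations
use 400 titration replicates (coverage), 100 DSC replicates and 50 ESI
replicates under fixed seeds; a full run takes a few seconds. The
`scripts/acceptance.R` entry point re-derives the adduct-mass roster and
the median recovered binding parameters (200 replicates per scenario)
from a single command-line seed.

## 6. Known limitations

* Linearized estimates under noise inherit transformation bias; treat the
  NLS fit as the reference when the two disagree materially.
* OLS is applied to the linearized variables as is conventional; an
  errors-in-variables (Deming) treatment is not implemented.
* The Scatchard fit requires an externally supplied
  $\Delta\varepsilon$; with weak binding both its inputs and its flags
  degrade together.
* No multi-equilibrium (Hill/Adair), multi-state DSC, or mixture
  deconvolution models: systems that need them are *flagged* (runs test,
  FAILED status, multimodality warning), by design.
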