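# ptbind

Binding thermodynamics of Pt(II) complexes with model proteins.

Cationic platinum(II) phenyl-terpyridine complexes are candidate
cisplatin substitutes whose pharmacology is shaped less by DNA binding
than by how they interact with proteins. Characterizing that interaction
for model proteins (hen egg-white lysozyme, ribonuclease A) rests on
three instrumental probes, each with its own quantitative analysis:

* **UV-Vis differential titrations** — for the 1:1 equilibrium
  `protein + PtL ⇌ protein·PtL`, the differential signal
  ΔA = A − ε_PtL·C_PtL obeys the linearization

  ```
  C_PtL·C_P/ΔA + ΔA/Δε² = (C_PtL + C_P)·(1/Δε) + 1/(K·Δε)
  ```

  fitted iteratively (Δε enters its own ordinate), with K given by the
  slope/intercept ratio; the Scatchard form
  `C_P·(C_PtL·Δε − ΔA)/ΔA = 1/(nK) + (C_PtL·Δε − ΔA)/(nΔε)` adds the
  number of equivalent sites n. An exact mass-action solver and a direct
  nonlinear least-squares fit serve as the independent reference.
* **Differential scanning calorimetry** — two-state van't Hoff analysis
  of the excess heat capacity: Cp_exc(T) = ΔH(T)·df_D/dT + f_D·ΔCp, with
  baseline subtraction, calorimetric enthalpy as the peak area, T_d,
  ΔS_d = ΔH/T_d, the ΔH_vH/ΔH_cal cooperativity ratio, a FAILED verdict
  for thermograms a single two-state model cannot describe, and the
  native-loss correction for incubated samples.
* **ESI-MS adduct assignment** — average-mass bookkeeping for
  protein + k×(metal fragment) (+ small-anion) compositions after labile
  halide loss, with the charge-q fragment displacing q protons, isobaric
  sulphate/phosphate flagging, and a minimal multi-charge envelope
  deconvolver.

Seeded simulators generate titration spectra, thermograms and ESI
envelopes with known ground truth, so every estimator is testable end to
end without instrument files. See `vignettes/ptbind-methods.Rmd` for the
models, numerical choices and limitations.

## Worked example

```r
library(ptbind)

# a titration at K = 1e4 M^-1, delta_eps = -5000 M^-1 cm^-1,
# 0.002 AU noise, 15 additions of 2e-3 M protein
ser <- simulate_titration(K = 1e4, delta_eps = -5000, sigma_A = 0.002,
                          seed = 42)
iso <- build_isotherm(ser)
fit_binding(iso)
#> 1:1 binding fit (iterative linearization)
#>   K         = 1.187e+04 M^-1  (SE  598)
#>   delta_eps = -5249 M^-1 cm^-1
#>   lambda*   =    368 nm
fit_binding_nls(iso)
#> 1:1 binding fit (nls)
#>   K         =  9699 M^-1  (SE  875)
#>   delta_eps = -5670 M^-1 cm^-1
#>   lambda*   =    368 nm
```

The analysis wavelength defaults to the largest first-to-last spectral
change (368 nm here, on the hypochromic flank of the 378 nm band). At
this noise level a single titration determines K to roughly ±10–20%: the
iterative linearized estimate (1.19e4) and the direct nonlinear reference
(0.97e4) bracket the true 1e4, and the nonlinear fit's standard errors
are the calibrated ones (truth within ±2 SE).

```r
tg <- simulate_dsc(T_d = 345, dH = 450, sigma_frac = 0.01, seed = 7)
fit_two_state(tg)
#> Two-state DSC fit [OK]
#>   T_d    =    345 K (71.85 degC)
#>   dH_vH  = 449.58 kJ/mol;  dH_cal = 451.11 kJ/mol
#>   dS_d   = 1.308 kJ/(mol K)
#>   dH_vH/dH_cal = 0.997
#>   RMS residual = 0.504 (0.974% of peak)
```

A cooperativity ratio of ~1 and sub-percent residuals mark a genuine
two-state transition; shouldered multi-population thermograms return
status FAILED instead.

```r
frag <- fragment_spec("Pt(phterpy)", "PtC21H15N3", charge_displaced = 2)
assign_adducts(c(13682, 13780, 14184, 14283, 14686), M0 = 13682,
               fragments = frag)
#>   observed predicted                     composition   error_da ambiguous
#> 1    13682  13682.00                         protein  0.0000000     FALSE
#> 2    13780  13779.99                 protein + H3PO4  0.0060000      TRUE
#> 3    14184  14184.44         protein + 1xPt(phterpy) -0.4403499     FALSE
#> 4    14283  14282.51 protein + 1xPt(phterpy) + H2SO4  0.4876501      TRUE
#> 5    14686  14686.88         protein + 2xPt(phterpy) -0.8806999     FALSE
```

The full deconvolved RNase A peak roster is reproduced from the free
protein mass and the fragment formula alone; the +98 Da sulphuric /
phosphoric acid adducts are isobaric and flagged as such rather than
silently resolved.

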