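# dlvoreg

Charge-regulated DLVO analysis of surface force balance (SFB) measurements.

SFB experiments measure the force between two atomically smooth, charged
mica surfaces across an aqueous electrolyte as a function of their absolute
separation `D`, with sub-nanometre distance resolution. `dlvoreg` is for
researchers analysing such force–distance curves — here, for solutions of
the zwitterionic osmolyte proline with and without added KCl — and for
anyone who wants a reproducible synthetic testbed for that analysis.

At its core is the interaction free energy per unit area of two identical
plates,

```
W(D) = −A/(12 π D²) + 2 ε₀ ε_e κ ψ_eff² e^(−κD) / (1 + (1 − 2p) e^(−κD))
```

the sum of a non-retarded van der Waals attraction (Hamaker constant `A`)
and an electric double-layer repulsion in the constant regulation
approximation: `κ⁻¹` is the Debye screening length, `ψ_eff` the effective
surface potential, and `p ∈ [0, 1]` the regulation parameter interpolating
between constant potential (`p = 0`) and constant charge (`p = 1`)
boundary conditions. The crossed-cylinder force maps to `W` through the
Derjaguin relation `W = F / 2πR`.

The package provides:

* **Electrolyte utilities** — molality→molarity conversion, ionic strength,
  Debye length and its exact inverse, the Grahame equation (full and
  linearized), thermal-voltage conversions, ideal osmotic pressure.
* **A numerical Poisson–Boltzmann solver** for two charge-regulating
  plates, used as an independent oracle validating the weak-overlap model
  (they agree within 5% for `κD ≥ 3`, potentials ≤ 25 mV).
* **A quasi-static SFB simulator** — drive + spring + interaction law —
  that generates approach/retraction curves with spring-instability
  jump-ins, molecular squeeze-out steps, adhesive pull-off and seeded
  Gaussian noise, plus a deterministic dataset generator with a manifest.
* **An analysis pipeline** — windowed Levenberg–Marquardt fits of the
  model with `p` constrained to [0, 1], jump/step/adhesion feature
  extraction, uncertainty estimation (Jacobian or bootstrap), and rounded
  parameter-table reports.
* **A CLI** (`inst/cli/dlvoreg.R`, or `sfb_cli()` from R) with
  `simulate | fit | features | report | validate-pb` subcommands driven by
  a YAML run configuration.

## Worked example

Simulate a noisy approach curve for a 0.46 m proline + 0.01 m KCl solution
(effective potential 49 mV, screening length 3.0 nm, `p` = 0.61) and
recover the parameters:

```r
library(dlvoreg)

pars <- study_dlvo_params("pro046_kcl001")      # 49 mV, 3.0 nm, p = 0.61
D <- seq(1.5, 25, length.out = 300) * 1e-9
set.seed(42)
W <- total_energy(D, pars) + rnorm(300, 0, 0.005e-3)   # σ = 0.005 mJ/m²
curve <- force_curve(rev(D), rev(W), "approach")

fit <- fit_dlvo(curve, spec = proline_solution(0.46, 0.01),
                config = fit_config(c(1.5e-9, 20e-9)))
fit
#> <fit_result> psi_eff = 48.7 mV, kappa^-1 = 3.01 nm, p = 0.622 (converged)
#>   residual RMS 0.00481 mJ/m^2 over 236 points in [1.5, 20] nm

fit_report(list(fit), list(proline_solution(0.46, 0.01)))
#>   c_pro_molal c_kcl_molal psi_eff_mV psi_eff_sd_mV kappa_inv_nm ...    p kappa_pred_nm
#> 1        0.46        0.01         49           0.3            3 ... 0.62             3
```

The fitted potential, screening length and regulation parameter come back
within their 1σ uncertainties of the generating values, and the predicted
screening length from the KCl content (3.0 nm, closed form 3.043 nm) sits
beside the measured one. Salt-free (zwitterion-only) solutions carry no
predicted screening length — `debye_length()` refuses and the fit treats
`κ` as free; the ionic strength implied by a fitted `κ⁻¹` is then
available from `ionic_strength_from_kappa()` (40 nm → 6 × 10⁻⁵ M).

The methods vignette (`vignettes/charge-regulated-dlvo.Rmd`) documents the
model assumptions, the simulator mechanics, the numerical choices and the
known limitations.

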