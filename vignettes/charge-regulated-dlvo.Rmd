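---
title: "Charge-regulated DLVO analysis of surface force balance curves"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Charge-regulated DLVO analysis of surface force balance curves}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dlvoreg)
```

## The model

The surface force balance (SFB) measures the force $F(D)$ between two
crossed-cylinder mica surfaces of radius $R \approx 10$ mm as a function of
their absolute separation $D$. In the Derjaguin approximation
($R \gg D$) this maps onto the interaction free energy per unit area of
parallel plates, $W(D) = F(D)/2\pi R$. For two identical charged surfaces in
a 1:1 aqueous electrolyte, `dlvoreg` models $W$ as the sum of a non-retarded
van der Waals attraction and an electric double-layer repulsion in the
*constant regulation* approximation:

$$
W(D) \;=\; -\frac{A}{12\pi D^2}
\;+\; \frac{2\,\epsilon_0 \epsilon_e\, \kappa\, \psi_{\mathrm{eff}}^2\,
       e^{-\kappa D}}{1 + (1-2p)\,e^{-\kappa D}} .
$$

Here $A$ is the Hamaker constant, $\epsilon_e$ the electrolyte relative
permittivity, $\kappa^{-1}$ the Debye screening length,
$\psi_{\mathrm{eff}}$ the effective surface potential extrapolated from the
diffuse-layer decay, and $p \in [0,1]$ the regulation parameter: $p = 0$ is
the constant-potential boundary condition, $p = 1$ constant charge, and
intermediate values interpolate linearly between them through an effective
inner-layer capacitance, $p = C_D/(C_D + C_i)$ with
$C_D = \epsilon_0\epsilon_e\kappa$. The model assumes identical symmetric
surfaces, a 1:1 electrolyte, weak double-layer overlap, and non-retarded
dispersion forces; ion-size (Stern) corrections, dielectric saturation and
activity coefficients are outside its scope.

Sign conventions: repulsion is positive, $\psi_{\mathrm{eff}}$ is stored as
a magnitude (the double-layer term is even in the potential for identical
surfaces).

## Parameters, units and defaults

| Parameter | Units | Default | Why |
|---|---|---|---|
| temperature | K | 298.15 | room-temperature measurements; configurable in `solution_spec()` |
| $\epsilon_e$ (pure water) | -- | 78.3 | fixed constant rather than a $T$-correlation, so 2-s.f. screening-length predictions are reproducible |
| $A$ (mica--water--mica) | J | $2.2\times 10^{-20}$ | literature value for this system; always configurable and recorded in outputs |
| $k_N$ (spring constant) | N/m | 150 | typical SFB normal spring; declared, not inferred |
| $R$ (lens radius) | m | $10^{-2}$ | standard crossed-cylinder lens |
| 1 e/nm$^2$ | C/m$^2$ | 0.1602 | CODATA elementary charge |

Concentrations enter as molalities (mol per kg water, the unit solutions
are prepared in) and are converted to molarities by the volume model
$V = m_{\mathrm{water}}/\rho_w(T) + \sum_i n_i \bar V_i$, with $\rho_w$ from
the Kell (1975) correlation and partial molar volumes $\bar V_i$ optional
(neglected by default, since densities for the studied mixtures are not
available). Zwitterions such as proline carry zero valence: they contribute
to osmotic pressure and (optionally) to the permittivity through a per-species
dielectric increment, but not to the ionic strength. We deliberately default
the proline dielectric increment to zero rather than guess one; as a result
the predicted screening length of a proline--KCl mixture equals that of the
KCl alone.

```{r electrolyte}
debye_length(kcl_solution(0.01)) * 1e9          # nm
ionic_strength_from_kappa(40e-9)                 # mol/L
osmotic_pressure_vant_hoff(proline_solution(0.90)) / 1e6  # MPa, ideal
```

A note on rounding: reported tables use 2 significant figures with half-up
ties (`signif_half_up()`). The exact closed form for 0.01 m KCl gives
$\kappa^{-1} = 3.04$ nm, which rounds to 3.0 nm; published predictions of
3.1 nm for this composition correspond to slightly different constant
choices (e.g. $\epsilon_e$ at 20 °C) and agree with ours within 2%.

## The Poisson--Boltzmann oracle

Because the closed form above is a weak-overlap approximation, the package
carries an independent numerical check: `solve_two_plate()` solves the full
nonlinear Poisson--Boltzmann equation $y'' = \sinh y$ (thermal units) on the
half-domain between two plates, with a symmetric midplane condition and the
linear-regulation wall condition
$\sigma(\psi_s) = \sigma_\infty + C_i(\psi_\infty - \psi_s)$. The
discretization is second-order finite differences with damped Newton
iteration, initialized from superposed isolated Gouy--Chapman profiles and
refined by grid doubling until the disjoining pressure changes by less than
0.1%. The disjoining pressure is evaluated at the midplane
($P = 2c_0 k_B T(\cosh y_m - 1)$) and cross-checked at the wall via the
contact-value theorem; integrating $P$ inward from the far field gives the
energy. For $\kappa D \ge 3$ and isolated potentials up to 25 mV the
numerical energy agrees with the analytic regulation term within 5% (with
$\psi_{\mathrm{eff}}$ taken as the Gouy--Chapman far-field amplitude
$4(k_BT/e)\tanh(e\psi_\infty/4k_BT)$), which is the regime where the fits
operate. The fitting model is always the closed form; the solver is its
validity oracle, never the estimator.

## The synthetic-data generator

`simulate_quasistatic()` emulates the SFB mechanics rather than drawing
noisy model curves: the lower surface sits on a spring of constant $k_N$,
the drive position $X$ advances in fixed steps, and the recorded separation
is the mechanically stable equilibrium $k_N(D - X) = F(D)$ with
$\mathrm{d}F/\mathrm{d}D < k_N$, found by scanning a dense logarithmic
separation grid. Where the current branch loses stability the recorded
curve jumps to the next stable branch -- inward on approach, outward on
retraction -- which reproduces jump-in, squeeze-out steps, pull-off and the
approach/retraction hysteresis with a single mechanism. Note that with a
soft spring the drive must pass well below zero nominal separation before
contact: the spring compresses by $F/k_N$, hundreds of nm at mJ/m$^2$
loads. Approach simulations therefore run open-ended by default and stop
just above the hard wall.

Ground truths combine the DLVO parameters of the studied solutions
(`proline_study_params()`) with:

* an optional layered structural term,
  $A_s[e^{-x/\lambda}\cos(2\pi(x - \phi)/d) + (D_0/D)^{12}]$ with
  $x = D - D_0$: a decaying oscillation of period $d$ (the layer thickness)
  on a steep power-law wall at the closest-approach distance $D_0$. For the
  layered scenarios we place $D_0$ at 1.0 nm, an intermediate-distance hard
  wall representing the last un-squeezable adsorbed layers: a
  mechanical-stability analysis shows that with the wall at mica contact
  the $D^{-2}$ dispersion term at sub-nm separations overwhelms a 1 mJ/m$^2$
  layering amplitude and the spring crashes through every layer, whereas
  with the wall at 1 nm the observed cascade of single-layer squeeze-outs
  emerges;
* an optional adhesion override: a Gaussian depth correction, centred at
  the contact minimum and calibrated iteratively, pins the minimum of the
  total energy law at the configured pull-off energy (verified to 0.1%
  inside the generator);
* seeded iid Gaussian noise on the energy signal. Seeds are mandatory for
  any noisy output and recorded in the dataset manifest, making
  `generate_dataset()` byte-reproducible.

What the generator does *not* emulate: interferometric fringe conversion,
thermal drift, hydrodynamic drainage, and instrument-specific calibration
errors. Passing recovery tests on these curves therefore demonstrates that
the estimator is consistent and well-calibrated for the assumed noise
model, not that real SFB data are free of systematic distance or
calibration offsets (for real data the additive distance offset should be
freed in the fit).

## Fitting and feature extraction

`fit_dlvo()` performs windowed nonlinear least squares
(Levenberg--Marquardt via `minpack.lm`). Numerical choices:

* positivity of $\psi_{\mathrm{eff}}$, $\kappa$, $A$ by log-reparameterization;
  $p$ constrained by the smooth map $p = \sin^2\theta$, which attains both
  boundaries at finite $\theta$ (the constant-charge limit $p = 1$ is a real
  fit outcome, reported as "1.0");
* multi-start over $p_0 \in \{0.1, 0.5, 0.9\}$ to escape shallow local
  minima in the regulation denominator, tie-broken by residual then smaller
  $p$; starting $\kappa$ from the composition when the ionic strength is
  positive, otherwise from the log-slope of the outer tail;
* $p$ estimates within $10^{-3}$ of a boundary are reported at the boundary;
* uncertainties from the Jacobian covariance by default, or a seeded
  residual bootstrap on request (run-to-run spreads and fit covariances are
  both legitimate readings of reported uncertainties, so both are offered);
* the default window starts one layer thickness beyond the first inward
  jump and ends where the signal falls below three times the noise level
  (`auto_fit_window()`); the convergence flag is honest and windows with
  fewer than 10 samples are rejected.

Feature extraction is direction-aware. `detect_jumps()` flags separation
changes above three drive steps and merges consecutive flagged samples into
one event (the spring compliance diverges at a fold, so the samples just
before a jump already move super-threshold). `step_heights()` reports the
squeeze-out step size as the spacing between successive fold positions
rather than the raw jump drop: the curve climbs each layer's steep wall
before the instability, so fold positions mark the walls and their spacing
recovers the layer period within a few percent, whereas raw drops are
biased low by wherever the landing happens to sit on the next wall
(15--20% for the studied geometry). Spacings more than 1.5x the smallest
are discarded as multi-layer events. `adhesion_energy()` reads the minimum
recorded energy at the last stable retraction point before the outward
jump, and distinguishes "no jump-out" (`NA`) from zero adhesion.

## A worked recovery

```{r recovery}
pars <- study_dlvo_params("pro046_kcl001")   # 49 mV, 3.0 nm, p = 0.61
D <- seq(1.5, 25, length.out = 300) * 1e-9
set.seed(42)
W <- total_energy(D, pars) + rnorm(300, 0, 0.005e-3)
curve <- force_curve(rev(D), rev(W), "approach")
fit <- fit_dlvo(curve, spec = proline_solution(0.46, 0.01),
                config = fit_config(c(1.5e-9, 20e-9)))
fit
fit_report(list(fit), list(proline_solution(0.46, 0.01)))
```

## Problem sizes

The shipped tests and the acceptance script use the study conditions
directly: recovery experiments run 50 replicate curves of 300 points each;
quasi-static simulations use 0.01--0.05 nm drive steps on a 20,000-point
stability grid; the PB validation solves on grids of 200--12,800 intervals
with pressure-integration steps of 0.2 Debye lengths over ten decay
lengths of tail. The full suite completes in well under a minute on one
core.

## Known limitations

* The electrolyte model is strictly 1:1 for the full Grahame relation and
  the PB solver; multivalent salts are rejected, not approximated.
* The effective surface charge computed from a fitted
  $\psi_{\mathrm{eff}}$ depends on which Grahame variant (full vs
  linearized) and which permittivity is used -- for the dilute-proline
  parameters the two variants give 6.8--8.7 $\times 10^{-3}$ e/nm$^2$.
  Both are exposed; neither is privileged.
* Quasi-static mechanics only: drainage forces and drive-rate effects are
  not modelled, so simulated hysteresis arises solely from spring
  instability.
* The layered structural term is a phenomenological decaying oscillation;
  its parameters are detected, never fitted.
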