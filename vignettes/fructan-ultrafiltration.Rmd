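---
title: "Modeling the fractionation of agave fructans by tight ultrafiltration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling the fractionation of agave fructans by tight ultrafiltration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fructanUF)
```

## The problem

Native agave fructans are a mixture of three carbohydrate size classes:
long chains (Fc, degree of polymerization above 10), fructooligosaccharides
(FOS, DP 3–10) and mono-/disaccharides (MD, DP 1–2). The two fructan
fractions have distinct prebiotic and technological uses, so separating
them is commercially interesting. Tight ultrafiltration (a 1 kDa ceramic
membrane at pilot scale, 0.5 m² of area) can fractionate them: short chains
preferentially cross into the permeate while long chains are retained.

`fructanUF` implements the two computational pillars of that process
analysis:

1. a **design-of-experiments layer**: a three-factor Box–Behnken design over
   temperature, transmembrane pressure (TMP) and feed concentration,
   second-order response-surface fits with Type-III ANOVA, and
   desirability-function optimization of the operating conditions; and
2. a **dynamic process model**: a batch-mode ultrafiltration simulator whose
   permeate flux follows a concentration-polarization limiting-flux law,
   plus the calibration tools that estimate its parameters from
   flux-versus-concentration data and correlate solute rejections with the
   feed composition.

## Metrics

Fractionation quality is measured by the *separation factor*

$$SF = \frac{(\mathrm{FOS{:}Fc})_P}{(\mathrm{FOS{:}Fc})_F},$$

the permeate-to-feed quotient of the FOS:Fc mass ratio; $SF > 1$ means the
permeate is enriched in short chains. Mono-/disaccharides are carried in
every composition but never enter $SF$. Productivity is the *solute flux*
$J_i = F_P C_P / A$, reported in kg h⁻¹ m⁻² (inputs are SI; conversion
happens only at the reporting boundary). Membrane selectivity per solute is
the *apparent rejection* $R_o = 1 - C_{P}/C$, assumed constant over a run.
Compositions are validated at construction — fractions in $[0,1]$ summing
to 1 — and renormalization is only ever explicit
(`normalize_composition()`), never silent.

## The designed experiment

The study region is 30–60 °C, 1–5 bar and 50–150 kg m⁻³, coded so the
low/centre/high levels map to −1/0/+1 per factor
(`design_levels()`, `code_conditions()`). The packaged 16-run design
(`agave_design()`) is the standard 3-factor Box–Behnken: 12 edge midpoints
of the factor cube plus 4 centre replicates, which supply the pure-error
estimate.

Model fitting (`fit_rsm()`) is ordinary least squares on the coded basis.
The separation factor uses a *reduced quadratic* form: the full second-order
model minus the temperature–TMP and TMP–concentration interactions, which
the ANOVA shows to be insignificant; dropping a term refits the reduced
basis rather than zeroing a coefficient. The solute flux is adequately
described by a main-effects *linear* model. Two conventions deserve
emphasis:

* **Coefficients live in coded units.** The published linear flux model,
  although labelled as being in actual values, is dimensionally meaningful
  only in coded units (its coefficients equal the orthogonal-contrast
  closed form $(\bar Y_{+1} - \bar Y_{-1})/2$ on the design data, and
  evaluating it against actual temperatures in °C produces absurd
  magnitudes). `fit_rsm()` therefore always fits in coded units;
  `actual_coefficients()` provides the actual-unit view by exact polynomial
  re-expansion through the affine coding map, never by refitting, so
  predictions are identical in either representation (tested to 1e-9).
* **ANOVA uses partial (Type-III) sums of squares**, the convention of
  design-of-experiments software: each term's SS is the increase in
  residual SS when that term alone is deleted. On a Box–Behnken design the
  linear and interaction columns are mutually orthogonal, so sequential and
  partial SS coincide for them; the quadratic terms are not orthogonal to
  the intercept, where the distinction matters. The residual splits exactly
  into lack-of-fit plus pure error (centre replicates), and the
  lack-of-fit F uses the pure-error mean square.

On the packaged design the reduced quadratic SF model achieves
R² = 97.8% / adjusted 94.6% (full quadratic ANOVA), and the linear flux
model R² = 75.0%.

## Desirability optimization

To pick operating conditions, each predicted response is rescaled to a
desirability score $d = \mathrm{clip}\{(Y - L)/(H - L),\,0,\,1\}$ with the
anchors $L, H$ defaulting to the observed extremes of that response in the
design (user-overridable via `desirability_spec()`), and the scores are
aggregated as a weighted **geometric mean**
$D = (\prod_k d_k^{w_k})^{1/\sum w_k}$. The geometric mean is the standard
aggregation for multi-response desirability (a zero on any response kills
the optimum) and is the only aggregation that reproduces the study's
reported overall desirabilities; an arithmetic "sum of desires" does not.

The optimizer is deterministic: L-BFGS-B from a fixed 27-point start grid
over the coded box $[-1,1]^3$, followed by a pattern-search polish on a
0.01-step coded lattice, so the returned point is stationary with respect
to its lattice neighbours. On the packaged design the SF-only optimum sits
at ≈46.6 °C, 3.3 bar, 85 kg m⁻³ with $D \approx 0.95$; maximizing SF and
flux jointly moves the optimum to ≈53 °C, 4.1 bar, 117 kg m⁻³ with
$D \approx 0.71$ — selectivity is traded for productivity.

## The batch ultrafiltration model

In batch concentration mode the permeate is withdrawn while the retentate
recirculates, so the tank volume falls and retained solutes concentrate.
With the solute concentration assumed uniform across tank, feed and
retentate lines, the balances are

$$\frac{dV}{dt} = -J_{\lim} A, \qquad
  \frac{dC_i}{dt} = \frac{C_i}{V} J_{\lim} A R_{o,i}, \qquad i = \mathrm{Fc}, \mathrm{FOS},$$

with permeate concentrations $C_{P,i} = C_i (1 - R_{o,i})$ derived
pointwise. (A dimensionally inconsistent intermediate form of the
concentration balance appears in print; the per-volume form above is the
one implemented — it is the exact consequence of the mass balance
$d(C_i V)/dt = -C_{P,i} J_{\lim} A$.) The permeate flux follows the
concentration-polarization limiting-flux law

$$J_{\lim} = k \,\ln\!\Big(\frac{C_{\lim}}{R_o\,C} - \frac{1-R_o}{R_o}\Big),$$

whose argument equals 1 exactly at $C = C_{\lim}$ for any rejection, so the
flux vanishes at the limit concentration; at $R_o = 1$ it reduces to the
classical gel-polarization form $k \ln(C_{\lim}/C)$. The driving
concentration defaults to the long-chain fraction $C_{Fc}$ with the Fc
rejection, since the long chains dominate the polarized layer; a `"total"`
option drives the law with $C_{Fc} + C_{FOS}$ instead. Both solutes see the
*same* flux — one membrane, one boundary layer. Osmotic pressure and
fouling resistance are outside the model's assumptions, and rejections are
held constant over a run.

### Numerics

`simulate_uf()` integrates with `deSolve::lsoda` at `rtol = 1e-8`,
`atol = 1e-10`, with two terminal root functions: tank volume reaching
`v_min_frac * v0` (default 5%) and the limiting flux reaching zero. A feed
already at or above $C_{\lim}$ returns a single-row trajectory flagged
`flux_zero`. Two auxiliary states accumulate the permeate mass of each
solute so the mass balance can be audited on every trajectory; the suite
checks volume closure to 1e-9, per-solute mass closure to 1e-6 relative,
the total-retention invariant $C_i V = C_{i,0} V_0$ to 1e-8, and agreement
with an independent fixed-step RK4 integration (dt = 0.1 s over one hour)
to 1e-5 relative. Interpolation of trajectories at observation times uses
monotone (Fritsch–Carlson) cubic splines, which cannot overshoot between
grid points.

## Calibration

The limiting-flux law predicts flux linear in $\ln C$, so
`fit_flux_params()` regresses measured flux on log-concentration: $k$ is
minus the slope and $C_{\lim}$ the concentration where the fitted line
crosses zero flux. A rising trend is rejected as a model violation. Fluxes
supplied in kg h⁻¹ m⁻² are converted to m s⁻¹ under a permeate density of
1000 kg m⁻³ (dilute-solution convention; a message logs it). The study's
calibrated values, $k = 6.31\times10^{-6}$ m s⁻¹ and
$C_{\lim} = 337.61$ kg m⁻³ (measured at 3 bar, 45 °C, 3 m s⁻¹ crossflow,
50–250 kg m⁻³), are used throughout the analysis scripts.

Rejections are tied to feed composition by
`fit_rejection_correlation()`: over the observed FOS:Fc range 0.23–0.39,
the FOS rejection falls steeply (55% → 18.5%) and is modelled linearly from
the two printed endpoints, while the Fc rejection stays within 76–83% and
defaults to the constant mean 0.795 — the direction of the small Fc trend
versus ratio is not recorded, so a constant is the defensible default (both
forms are overridable). Predictions are clipped to $[0,1]$ with a logged
message. Simulated-versus-observed profiles are scored per stream and
solute by the sum of squared errors (`validate_profiles()`).

## Synthetic data: what it does and does not show

No raw instrument data are distributed, so every estimator is validated
against seeded generators (`gen_batches()`, `gen_bbd_responses()`,
`gen_flux_curve()`, `gen_uf_timeseries()`), all pure functions of their
seed that leave the global RNG stream untouched.

* Batch compositions draw Fc% uniformly on 60–75 and MD% from a truncated
  normal around 10% (sd 1, bounds 7–13), FOS% taking the remainder. This
  reproduces the linear FOS-versus-Fc trade-off across commercial batches
  and a FOS:Fc span (≈0.18–0.51) that brackets the observed 0.23–0.44, but
  it is not a point-for-point emulation of any real batch set.
* Design responses add Gaussian noise (σ = 0.07 ≈ the design's residual
  standard deviation) to a known polynomial; flux curves use multiplicative
  noise (2% CV) because fluxes span an order of magnitude; UF time series
  add Gaussian noise (σ = 2–3 kg m⁻³) to simulated profiles. The noise
  models are synthetic conventions — the study reports no error model.
* Zero-noise closure holds throughout: each generator composed with its
  estimator is the identity on the truth parameters to numerical precision.

Passing these tests shows the estimators are correctly inverting the models
they assume. It does not show the models capture everything in real
operation: membrane fouling, osmotic-pressure effects and
composition-dependent boundary layers are explicitly outside the model, and
the validation experiments on real batches show larger deviations for
Fc-rich feeds than the synthetic noise level would predict.

## Problem sizes and defaults

The analysis scripts and test suite run the 16-run design, trajectories of
a few hundred output points over 1–4 h horizons, a 10-point flux curve and
a 46-point rejection grid search; the brute-force check of the optimizer
evaluates the SF surface on a 151×101×101 lattice over the design box. The
simulated scenario uses a 100 L working volume (`v0 = 0.1` m³) in the
150 L pilot tank at 100 kg m⁻³ total feed — the validated operating
concentration — because the study does not record the volumes or sampling
times of its own validation runs (their profile SSE values are therefore
not reproducible and are not targeted).

## Known limitations

* Only the 3-factor Box–Behnken is generated; no general k-factor design
  catalog.
* Which terms to drop from the quadratic model is an input, not an
  automatic significance-driven selection.
* The rejection correlation rests on two printed endpoints per solute;
  interior behaviour is interpolated.
* The simulator covers the two fructan fractions only; mono-/disaccharides
  are carried in compositions but not simulated, and fouling and osmotic
  effects are out of scope.
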