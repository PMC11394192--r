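---
title: "Modelling osmodehydrofreezing: response surfaces, desirability and frozen-storage kinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling osmodehydrofreezing: response surfaces, desirability and frozen-storage kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(osmofreeze)
```

## The process and the questions

Osmodehydrofreezing (ODF) is a two-stage preservation route for delicate
plant tissue such as cherry tomato: the fruit is first partially dehydrated
by immersion in a hypertonic solution (here glycerol with NaCl and CaCl~2~),
then frozen and stored.  The osmotic step lowers water activity and
impregnates solids, which protects texture, colour and labile nutrients
during the frozen stage.  Two quantitative questions drive the analysis this
package implements:

1. **Which osmotic-dehydration (OD) settings are best?**  Temperature,
   immersion time and glycerol concentration jointly control water loss
   (WL), solid gain (SG), water activity (a~w~), colour change (ΔE) and
   firmness.  The package fits second-order response surfaces on a
   Box–Behnken design and selects settings by composite desirability.
2. **How long does the frozen product keep, including under temperature
   abuse?**  Vitamin C and lycopene decay follow apparent first-order
   kinetics, the sensory overall score apparent zero-order kinetics; their
   temperature dependence is Arrhenius.  The package fits these models,
   computes shelf lives, and propagates fluctuating storage-temperature
   profiles through the effective-temperature concept.

## Mass-transfer and quality indices

`water_loss()` and `solid_gain()` are normalized by the *initial dry mass*
(g/g i.d.m.).  This matters: much of the OD literature normalizes by initial
total mass, and the two conventions differ by roughly the dry-matter
fraction (an order of magnitude for a watery fruit).  Negative values are
returned unclipped — water uptake and solids leaching are physically real,
and clipping would bias the fitted surfaces.  `delta_e()` is the Euclidean
CIELab distance; the conventional visibility threshold of 2 is exposed as
`DELTA_E_VISIBLE` and applied only by the separate helper
`is_visible_difference()`, never baked into the numeric value.

## Design, coding and the quadratic model

`bbd_design()` generates the classical 15-run, three-factor Box–Behnken
design: the 12 midpoints of the cube edges plus `n_center = 3` center
replicates.  The default factor space is 25–45 °C, 30–90 min, 50–70 % w/w
glycerol.  Coding is the affine map `x = (X - center)/half_range`, so each
coded column is balanced (sum 0) with sum of squares 8, and columns are
mutually orthogonal.  Coding is defined by magnitude — the smaller actual
level is −1 — so that coefficient signs read as physical effects.

`fit_quadratic()` estimates the 10-term polynomial
$y = a_0 + \sum a_i x_i + \sum a_{ii} x_i^2 + \sum_{i<j} a_{ij} x_i x_j$
by ordinary least squares in coded units and converts to actual-unit
coefficients by exact algebraic expansion of the coding map, so the two
prediction paths agree to machine precision (tested at 10^−8^ over the
cube).  Diagnostics follow standard response-surface practice: R², adjusted
R², the overall model F test, per-coefficient t tests starred at 95 %
confidence (`anova_table()`), and a lack-of-fit F test whose pure error
comes from the replicated center points — the only replicated setting in
this design, giving 2 pure-error degrees of freedom.  With a single center
run the lack-of-fit p-value is reported as missing rather than zero.
No multiple-testing correction is applied to the coefficient tests; stars
are descriptive, as is conventional in RSM reporting.

The published cherry-tomato surfaces ship as `od_surface_coefficients()` /
`od_reference_models()`.  Two printing defects in the source equations are
handled once, here: the solid-gain equation prints two temperature-by-
concentration interactions, the second of which is read as the otherwise
missing time-by-concentration term; and the high/low labels of the printed
factor table are swapped relative to the coded signs, resolved by the
magnitude convention above.

## Desirability optimization

Each response is mapped to a score d ∈ [0, 1] by a Derringer linear ramp
(`criterion()`, `individual_desirability()`), and settings are ranked by the
composite desirability `D`, the geometric mean of the individual scores —
zero whenever any criterion scores zero.  Criterion weights act as ramp
exponents: raising a weight sharpens the penalty for being away from the
ideal end.

The canonical criteria for this process (`od_default_criteria()`) are:
minimize a~w~ over its fitted range on the cube, and keep WL ≤ 5 g/g i.d.m.
and ΔE ≤ 8.  The caps are implemented as *soft constraints*: desirability is
1 anywhere at or below the cap and ramps to 0 at the surface maximum.  The
design choice was genuinely open — a cap can also be read as "smaller is
better all the way down" — but the soft-constraint form is the one under
which the optimizer reproduces the study's reported behaviour: the optimum
lands at ≈(36 °C, 64 min, 61 % w/w) with D ≈ 0.999 and every individual
d ≈ 1, consistent with a reported optimum of (36, 72, 61.5) at D = 0.99.
Under the smaller-is-better reading the WL criterion would drag the optimum
to the cold, dilute corner of the cube and score d(WL) ≈ 0.7 there, which
matches neither the reported settings nor the reported desirability.

`optimize_desirability()` searches deterministically: a coarse grid over the
closed cube (default 21 points per factor; unresolved ramp bounds are taken
from a 51³ evaluation of the surface), ties broken towards the cheapest
process (lowest temperature, then time, then concentration), followed by
Nelder–Mead refinement clamped to the cube.  No randomness is involved, so
repeated calls are bit-identical; the refinement result is kept only if it
does not fall below the best grid value.  The search never extrapolates:
response surfaces from a local design are not valid outside the studied
ranges.  In tests the optimizer is held to an exhaustive 101³ grid oracle to
within one oracle cell.

`validation_error()` expresses the deviation of a model prediction from an
independent validation measurement as a signed percentage of the
experimental value, with the field's 20 % acceptance band.  Of the shipped
validation pairs, WL, SG and a~w~ validate comfortably, firmness fails
(tomato-variety texture variation), and the colour pair recomputes to
−20.03 % — marginally outside the band, although it was reported as
acceptable at a printed −18 %.

## Frozen-storage kinetics

`fit_rate()` fits one isothermal series: first-order decay on the log scale
(a homoscedastic multiplicative-error assumption, the usual choice for
concentration data) or zero-order decay on the raw scale for sensory
scores.  A non-negative fitted slope is reported with a "no degradation"
flag rather than silently clipped.

`fit_arrhenius()` pools rates across temperatures through
$k(T) = k_{ref}\,\exp\!\left[-\frac{E_a}{R}\left(\frac{1}{T}-\frac{1}{T_{ref}}\right)\right]$
with temperatures in Kelvin (273.15 offset), R = 8.314 J mol^−1^ K^−1^ and
T~ref~ = −18 °C by default, so k increases with temperature for positive
activation energy.  The fit is linear in ln k versus (1/T − 1/T~ref~) and is
exact for two temperatures.

`shelf_life()` inverts the decay law at the acceptance limit:
ln(initial/limit)/k for first order (ln 2/k at the standard 50 % loss limit
for vitamin C and lycopene), (initial − limit)/k for zero order.  The
sensory limit is always an explicit argument; both conventional cut-offs on
the 9-point hedonic scale ship as `sensory_limits` (midpoint 5, rejection
4).  Kinetic parameter presets for untreated and OD-treated cherry tomato
are in `kinetic_presets()`.  The separately reported per-temperature shelf
lives (`reported_shelf_lives()`) derive from per-temperature fits on raw
data that are not public and are *not* reproducible from the presets (e.g.
ln 2/0.0033 d^−1^ = 210 d, not the 166 d reported at −18 °C); they are kept
as reference data for ratio-level statements only, such as the up-to-3.5-fold
sensory shelf-life extension by OD.

### Fluctuating temperatures

A piecewise-constant profile (`temperature_profile()`,
`make_cycle_profile()`; durations in hours, the natural unit of abuse
cycles) is summarized by its effective temperature: the constant temperature
giving the same quality loss over the same total time.
`effective_temperature()` computes the time-weighted mean rate
$k_{eff} = \sum_i k(T_i)\,t_i / t_{tot}$ and inverts the Arrhenius relation
in closed form.  T~eff~ depends only on E~a~, always lies within the range
of segment temperatures, exceeds the time-weighted arithmetic mean for a
non-constant profile (rates are convex in temperature), and increases with
E~a~.  For the study's abuse scenario — three cycles of −12/−5/−8 °C at 24 h
each — T~eff~ is ≈ −7.8 °C at E~a~ = 88.8 kJ/mol, against a −8.33 °C
arithmetic mean.  In the E~a~ = 0 limit the rate is temperature-independent
and the harmonic-mean temperature is returned with a warning.

`predict_nonisothermal()` integrates the decay segment-by-segment in closed
form.  By construction its end value equals the constant-T~eff~ prediction
of the same duration (tested to 10^−10^ relative).  Zero-order predictions
are not floored at the scale minimum: values past the limit are returned and
flagged, so abuse scenarios show how far past rejection they drive the
product.

## Synthetic data: what it emulates and what it does not

The generators exist so every stage is testable without the original raw
data.  `simulate_od_experiment()` draws design responses as surface value
plus additive Gaussian noise; `simulate_degradation()` draws storage series
as first-order decay with multiplicative lognormal noise (σ = 5 %) or
zero-order sensory decline with additive noise (SD 0.3 score units),
truncated at the scale floor of 1 with a warning.  The noise scales were
chosen once to be realistic for the respective instruments (a~w~ meter
0.005, WL 0.3 g/g, SG 0.05 g/g, ΔE 0.5, texture 0.15 N) — the source study
does not state error models.  Default study conditions mirror the original
design: the 15-run BBD, storage at −5/−8/−14/−23 °C, sampling every 15 days
to day 90 with two replicates.

These simulations share the fitted models' own functional form, so passing
recovery tests demonstrates statistical identifiability and correctness of
the fitting code — not that real tomatoes follow quadratic surfaces or
strict Arrhenius kinetics.  Real data add model misfit (e.g. glass-
transition deviations below the studied temperature range, non-quadratic
curvature, panel drift in sensory scores) that no test here exercises.

Problem sizes in the shipped tests were chosen for tight statistical checks
at interactive runtimes: 100–500 simulated studies for bias checks of
fitted rates and activation energies, 200 replicate designs for the
coefficient star-pattern rates, and a 101³ grid for the optimizer oracle.

## Numerical choices and degenerate inputs

* Coding is exact algebra, not refitting: coefficient conversion between
  coded and actual units is closed-form in both directions.
* Rank-deficient designs raise an error rather than dropping terms.
* The optimizer treats `D` ties to 10^−12^ as exact and breaks them
  deterministically; with all-zero desirability it names the binding
  criterion instead of returning an arbitrary point.
* First-order fits refuse non-positive values; zero-order simulation
  truncates at the sensory floor but zero-order *prediction* never does.
* All temperatures at the interface are °C; Kelvin appears only inside the
  Arrhenius algebra.

## Known limitations

Only the 3-factor Box–Behnken design is generated (no central-composite or
blocked designs); desirability ramps are linear (no smooth Harrington
forms); kinetics are strictly zero/first order with Arrhenius temperature
dependence (no Weibull or WLF glass-transition corrections); and the
optimizer is local-deterministic by design — adequate for smooth quadratics
on a box, not a global optimizer for arbitrary response models.
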