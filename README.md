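# osmofreeze

Process analysis for **osmodehydrofreezing** (ODF): osmotic dehydration of a
plant food matrix followed by freezing and frozen storage.  The package is
written around a cherry-tomato study design but its machinery is generic:

* **Quality indices** — water loss and solid gain per g initial dry mass,
  CIELab total colour change ΔE, percent drip loss on thawing.
* **Design of experiments & RSM** — the 15-run three-factor Box–Behnken
  design, actual↔coded factor mapping, second-order polynomial fits
  `y = a₀ + Σaᵢxᵢ + Σaᵢᵢxᵢ² + Σaᵢⱼxᵢxⱼ` with R², model F, per-coefficient
  t tests and a center-replicate lack-of-fit test.
* **Multi-response optimization** — Derringer desirability ramps per
  response, composite (geometric-mean) desirability, deterministic
  grid + simplex search over the experimental cube.
* **Shelf-life kinetics** — apparent first-order (vitamin C, lycopene) and
  zero-order (sensory score) degradation, Arrhenius temperature dependence
  `k(T) = k_ref · exp[−(E_a/R)(1/T − 1/T_ref)]`, shelf-life computation,
  effective temperature of fluctuating storage profiles, and closed-form
  non-isothermal prediction.
* **Synthetic data** — generators that emulate the study's design responses
  and isothermal storage series, so the full pipeline is testable end to
  end.

## Worked example

```r
library(osmofreeze)

# published response surfaces for osmodehydrated cherry tomato
models <- od_reference_models()
predict_at <- c(temperature = 36, time = 72, glycerol = 61.5)
round(sapply(models, predict, newdata = predict_at), 4)
#>       aw       WL       SG       dE firmness
#>   0.9118   4.9579   0.1730   7.9379   1.5167
```

The predicted water activity at the optimal OD settings (36 °C, 72 min,
61.5 % w/w glycerol) is 0.912: the osmotic step lowers a_w from ~0.95 to
~0.91, while keeping water loss near 5 g/g i.d.m. and colour change under 8.

```r
# find those settings: minimize a_w subject to WL <= 5 and dE <= 8
optimize_desirability(models[c("aw", "WL", "dE")], od_default_criteria())
#> Desirability optimum (actual units):
#> temperature        time    glycerol
#>      36.037      64.135      60.962
#> Individual desirabilities:
#>     aw     WL     dE
#> 0.9999 1.0000 1.0000
#> Composite desirability D = 1.0000
```

Every individual desirability is ≈ 1, i.e. the optimum fully satisfies the
caps while sitting at the a_w minimum of the feasible region.

```r
# frozen-storage kinetics: sensory shelf life of the OD product
m <- preset_model("sensory", "od")
round(shelf_life(m, c(-5, -8, -14, -23)), 1)
#> [1] 150.7 201.3 366.7 951.5

# effective temperature of 3 cycles of -12/-5/-8 degC, 24 h each
p <- make_cycle_profile(c(-12, -5, -8), c(24, 24, 24), repeats = 3)
round(effective_temperature(p, preset_model("vitamin_c", "untreated")), 2)
#> [1] -7.77
```

The effective temperature −7.8 °C is warmer than the −8.33 °C arithmetic
mean of the cycle: quality-loss rates are convex in temperature, so warm
excursions dominate.

`reproduce_report()` chains all of the above — optimum predictions,
validation errors, desirability search, shelf-life tables and the
effective-temperature map — into one deterministic, JSON-serializable
report.

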