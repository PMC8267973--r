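# imtgrowth

Logistic growth modelling of carotid intima-media thickness (IMT), for
biostatisticians and clinical researchers studying atherosclerosis
progression and statin treatment timing.

IMT — the ultrasound-measured thickness of the inner two layers of the
carotid artery wall, in mm — is a standard surrogate of atherosclerotic
burden. The package models its age trajectory as a logistic curve

```
x(t) = c·x0·e^{a·t} / (c + x0·(e^{a·t} − 1)),      dx/dt = a·x·(1 − x/c)
```

with `x0` the (model) IMT at birth, `c` the carrying capacity (terminal
IMT) and `a` the growth-rate coefficient. Everything clinically
interesting is analytic in the parameters: the curve is steepest at the
inflection age `t* = ln((c − x0)/x0)/a`, where IMT equals `c/2` and the
growth rate peaks at `a·c/4`. Because a treatment-induced reduction in the
curve's slope removes the most future thickening where the curve is
steepest, the rounded inflection age is the recommended age to start
statin therapy for the group the curve was fitted to.

The package provides:

* curve analytics — `logistic_params()`, `imt_at_age()`, `growth_rate()`,
  `inflection()`, `mean_slope()`, `slope_profile()`;
* calibration — `fit_logistic()` (bounded multi-start least squares, or a
  coarse-grid mode), `goodness_of_fit()`, `rmse_from_sse()` with both RMSE
  denominator dialects found in published tables;
* synthetic cohorts — `cohort_spec()`, `generate_cohort()`,
  `cohort_presets()` mirroring the published group structures
  (62 / 18 / 44 / 11 artery measurements);
* timing decisions — `recommend_start_age()`, `compare_groups()`,
  `slope_figure_table()`, `plot_slope_profiles()`;
* data I/O and a CLI — `read_imt_dataset()` / `write_imt_dataset()`
  (CSV/TSV), fit JSON round-tripping, `cohort_report()`, and an
  `inst/exec/imtcurve` script with `simulate | fit | recommend | compare |
  report` subcommands (`imt_cli()`).

## Worked example

The published curve for the aggregate of severely sick men is
`(x0, c, a) = (0.3, 1.2, 0.02875)`:

```r
library(imtgrowth)

aggregate <- logistic_params(0.3, 1.2, 0.02875)
inflection(aggregate)
#> Inflection at age 38.2 y (~38): IMT 0.6 mm, max slope 0.008625 mm/year

recommend_start_age(aggregate)
#> Recommended statin start age: 38 years
#> IMT growth is fastest at the inflection point (age 38.2 y, slope
#> 0.008625 mm/year); slope reduction by statins removes the most future
#> thickening when started there.
```

The curve's growth peaks at 0.008625 mm/year at age 38.2 — so for this
group, treatment started around age 38 acts on the fastest phase of
plaque thickening. Comparing against the non-medicated subgroup's curve
`(0.275, 0.9, 0.03962)`:

```r
cmp <- compare_groups(aggregate, logistic_params(0.275, 0.9, 0.03962),
                      labels = c("aggregate", "non_medicated"))
cmp
#> Group comparison (aggregate vs non_medicated):
#>   inflection age difference: +17 years
#>   max slope ratio: 0.9675, difference: -0.0002895 mm/year
```

The non-medicated subgroup peaks 17 years earlier (age 21 vs 38) and
slightly faster (0.008915 vs 0.008625 mm/year), then flattens at a much
lower plateau (c = 0.9 vs 1.2 mm).

A full pipeline run on synthetic data, from generation to refit:

```r
cohort <- generate_cohort(cohort_presets(seed = 20)$aggregate)  # 62 rows
fit <- fit_logistic(cohort, fit_config(seed = 1), group = "aggregate")
fit
#> Logistic IMT growth fit (group: aggregate)
#>   x0 = 0.408616 mm, c = 1.55173 mm, a = 0.0163698 /year  (n = 62)
#>   SSE = 1.662 mm^2, RMSE = 0.1651 mm (n_minus_1), R^2 = 0.306
#>   inflection [~63 y, 0.7759 mm], max slope 0.00635 mm/year
```

At n = 62 with realistic 0.17 mm measurement noise the refit's inflection
age lands at 63 rather than the generating curve's 38 — a deliberate
illustration of how wide the sampling spread of `(c, a)` is when the
curve's plateau is never observed; see the methods vignette
(`vignettes/imt-logistic-growth.Rmd`) for the identifiability analysis.

The same pipeline from a shell:

```sh
imtcurve=$(Rscript -e 'cat(system.file("exec", "imtcurve", package = "imtgrowth"))')
Rscript "$imtcurve" simulate --preset aggregate --seed 20 --out cohort.csv
Rscript "$imtcurve" fit --data cohort.csv --seed 1 --out fit.json
Rscript "$imtcurve" recommend --fit fit.json
Rscript "$imtcurve" report --data cohort.csv --out report.csv
```

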