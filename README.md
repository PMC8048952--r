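# grassfire

Fire shapes which grasses persist where — some species survive a burn by
resprouting from protected buds (resprouters), others die and return from
seed (seeders). `grassfire` turns raw occurrence records, satellite burn
histories, fire-radiative-power detections and monthly rainfall into
species-level fire-regime statistics, and then asks how the binary
persistence strategy sorts along fire and drought gradients once shared
ancestry is accounted for. It is written for comparative ecologists working
with species-by-environment tables and dated phylogenies.

## What it computes

* **Occurrence QC** — coordinate validity/precision filters, human-influence
  exclusion with protected-area exemption, date and sampling floors, and
  equal-area spatial thinning, with per-step attrition reports.
* **Fire return interval (FRI)** — inter-fire intervals from burn-date
  series inside a fixed observation window, with the open tails treated as
  right-censored; a censored Weibull(scale *b*, shape *c*) fit per species,
  and the median interval

  FRI = *b* (ln 2)^(1/*c*).

  The likelihood is conditioned on each pooled window containing at least
  one fire, which removes the length-bias of window sampling (see the
  methods vignette). Species are classed fire-prone via a break-point
  regression on the species-count-versus-proportion-burned curve; FRIs
  outside [1, 100] yr are set undefined.
* **Fire intensity** — 95th quantile of confident (≥ 50%) FRP detections
  per species.
* **Drought** — Foley's drought index: rolling 3-year rainfall deficit
  normalized by 1901–2003 mean annual precipitation, averaged per species.
* **Comparative models** — phylogenetic logistic regression of strategy
  (0 = seeder, 1 = resprouter) on log FRI or log FRP plus drought, using a
  Firth-penalized estimator whose residual correlation follows a
  mean-reverting process on the tree (signal parameter α), with parametric
  bootstrap confidence intervals; PGLS among the fire/drought variables;
  and a sign-fixed PCA of leaf economic traits.
* **Synthetic data** — seeded generators for Weibull-renewal fire
  histories, seasonal rainfall with drought episodes, birth–death trees and
  binary traits with tunable phylogenetic signal, bundled with a
  ground-truth manifest so the whole pipeline is testable offline.

## Worked example

```r
library(grassfire)

# a seeded synthetic benchmark: occurrences, burn histories, FRP, rainfall,
# a 150-tip tree, strategies, and the true parameters behind them
bundle <- make_benchmark_bundle(simulation_config(seed = 42))
res <- run_pipeline(bundle, params = list(boot = 200))

res$report$n_fire_prone
#> [1] 116
head(res$profiles[!is.na(res$profiles$median_fri),
                  c("species", "proportion_burned", "median_fri")], 3)
#>   species proportion_burned median_fri
#> 1   sp001         0.4416667   9.937984
#> 2   sp002         0.7666667  10.827961
#> 3   sp003         0.4416667   8.810845
print(res$fits$strategy_fri)
#> <phylo_glm> n = 116, alpha = 7.779
#>             estimate     se      z        p ci_lower ci_upper
#> (Intercept)  -1.0131 0.4998 -2.027 0.042700 -3.41041    0.227
#> log_fri       0.7230 0.2115  3.419 0.000629  0.09522    1.696
#> mean_fdi      0.7273 0.6829  1.065 0.287000 -1.64933    2.820
```

The `log_fri` row says resprouters are associated with longer fire return
intervals (less frequent fire) than seeders — the fitted slope is per
natural-log year, and its bootstrap interval excludes zero — while the
drought association is positive but not resolved at this sample size. A
converged Weibull fit for one species looks like:

```r
iv <- species_interval_sets(bundle$histories, bundle$mapping)[["sp001"]]
fit_weibull_censored(iv)
#> <weibull_fri_fit> b = 13.472, c = 1.205, median FRI = 9.94 yr
#>   (45 complete, 106 censored)
```

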