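# intersim

Simulation benchmark for **intersection-specific prevalence estimation of
binary health outcomes**.

Descriptive intersectional epidemiology estimates how often a binary
outcome (hypertension, depression, ...) occurs within *intersections* —
subgroups formed by crossing social position variables such as gender,
race/ethnicity, age group and income. With five or six crossed variables
the design has hundreds of cells, most of them small, and the standard
options all break somewhere: raw cell proportions (cross-classification)
are extremely noisy, saturated regressions stop converging, and
main-effects regression is biased because it assumes away exactly the
interactions that motivate the analysis. `intersim` generates
individual-level data over 192 intersections with *known* true
per-intersection prevalences and benchmarks nine estimators against that
truth:

| method | idea |
|---|---|
| `cross_classification` | raw within-cell event proportion |
| `main_effects` | modified Poisson (log link + robust sandwich variance), main effects only |
| `correct_spec` | modified Poisson with exactly the generating interactions |
| `saturated` | modified Poisson with all interactions |
| `maihda` | multilevel logistic: fixed main effects + random intercept per intersection (partial pooling) |
| `cart` | Gini classification tree, cost-complexity pruned by 10-fold CV |
| `ctree` | per-node association tests with Bonferroni-adjusted stopping (alpha 0.05) |
| `chaid` | chi-square category merging + Bonferroni multiway splits (alpha 0.05) |
| `random_forest` | 500 probability trees, `mtry` tuned by out-of-bag Brier score |

Accuracy is scored by the prevalence-scaled mean absolute deviation

```
MAD = (1/n) * sum_i |Phat_i - P_i| / p
```

(mean over intersections, each weighted equally, of the absolute error in
the estimated prevalence, divided by the overall sample prevalence `p`),
plus per-intersection bias/variance decompositions, convergence
proportions for the saturated fits, and variable-selection summaries
(splitting percentages, impurity and permutation variable importance with
Altmann p-values) in which the built-in null variable `x6` should rank
last.

## A worked example

```r
library(intersim)

sc <- scenario_config("categorical", "rare", n_individuals = 2000)
res <- run_grid(sc,
                methods = c("cross_classification", "main_effects",
                            "maihda", "ctree"),
                reps = 50, master_seed = 4001)
aggregate(mad ~ method, res$mad, median)
#>                 method       mad
#> 1 cross_classification 1.1456910
#> 2                ctree 0.4695408
#> 3               maihda 0.3244323
#> 4         main_effects 0.3260650
```

Read: at N = 2000 (about 10 observations per intersection, outcome
prevalence ~3%) the raw cell proportions are off by ~115% of the overall
prevalence on a typical iteration; a significance-gated tree more than
halves that; and MAIHDA's partially pooled estimates are tied with the
(biased but low-variance) main-effects regression at ~33%. That tie is the
small-sample story of the benchmark: MAIHDA's random intercepts are
almost fully shrunk away at this cell size, protecting it from the noise
that ruins cross-classification. At larger N the intersectional methods
pull ahead; a single fit is one line:

```r
ds  <- generate_dataset(scenario_config("categorical", "common", 50000),
                        rng_seed = 1)
fit <- fit_prevalence(ds, "maihda")
head(predict(fit))          # per-intersection estimated prevalence
#>   intersection_id   n  estimate
#> 1               0 714 0.2032646
#> 2               1 745 0.2245321
#> 3               2 766 0.2164738
#> 4               3 265 0.1573995
#> 5               4 246 0.1571669
#> 6               5 240 0.1603031
compute_mad(predict(fit), true_intersection_prevalence(ds),
            ds$sample_prevalence)$mad
#> [1] 0.08543721
```

A real-data style demonstration (60 intersections of sex x
race/ethnicity x age x poverty, high blood pressure defined as mean
systolic >= 130 and/or mean diastolic >= 80 mmHg over up to three
readings) runs on the bundled synthetic NHANES-like fixture:

```r
tab <- generate_nhanes_like_fixture(9576, seed = 3)
out <- run_real_data(tab)
head(out$estimates)
out$random_forest_vim
```

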