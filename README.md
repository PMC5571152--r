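# ricemeta

Comparing alternative rice tillage and crop-establishment (CE) options
against conventional puddled-transplanted rice across many independent
field studies.

Worldwide, rice is mostly established by wet tillage (puddling) followed by
manual transplanting — `CT-TPR(wet)`. Five alternatives (direct seeding
under conventional, reduced or zero tillage; unpuddled transplanting) are
evaluated in hundreds of paired trials that report arm means and replicate
counts but rarely variances. `ricemeta` is for agronomists and
meta-analysts who need to pool such corpora reproducibly. It implements two
parallel inference tracks:

**Meta-analysis track.** Effect sizes are log response ratios,
`lnR = ln(X_T / X_C)`, weighted by replication
`w = n_T n_C / (n_T + n_C)` with within-study weight division (a study
contributing *m* pairs to a category has each weight divided by *m*), a
single-pass 3-SD outlier screen per category, categorical random-effects
pooling with a generalized DerSimonian–Laird between-study variance
`tau² = max(0, (Q − (k−1)) / (Σw − Σw²/Σw))`, bias-corrected percentile
bootstrap 95% CIs (4999 iterations), and back-transformation to percent
change `(e^lnR − 1)·100`. An effect is significant when its CI excludes
zero; two categories differ when their CIs are disjoint.

**Mixed-model track.** Arm-level values on the original scale are fitted
by REML as `value ~ option (fixed) + study (random intercept)`, with
least-squares means, all-pairwise t comparisons, and a compact letter
display computed by the insert-and-absorb algorithm for unbalanced data.

A synthetic multi-study generator (`sim_truth()`, `generate_corpus()`,
`preset_paper_shape()`) draws corpora from exactly the model the pooling
assumes, with serialized ground truth, so every stage is testable without
any external data.

## Worked example

Generate a 60-study synthetic corpus and run both tracks:

```r
library(ricemeta)

truth  <- sim_truth(n_studies = 60, pairs_per_study_mean = 6, seed = 101)
trials <- generate_corpus(truth)   # 338 validated pairs

summary <- run_meta_analysis(trials, "grain_yield",
                             iterations = 4999, seed = 101)
dplyr::select(tibble::as_tibble(summary), group_label, k, percent_change,
              percent_ci_low, percent_ci_high, significant)
#> # A tibble: 5 × 6
#>   group_label       k percent_change percent_ci_low percent_ci_high significant
#>   <chr>         <int>          <dbl>          <dbl>           <dbl> <lgl>
#> 1 CT-DSR(dry)      98         -1.19          -2.97            0.570 FALSE
#> 2 CT-DSR(wet)     121          0.838         -0.732           2.44  FALSE
#> 3 RT-DSR(dry)      33         -7.22          -9.74           -4.90  TRUE
#> 4 RT-UPTPR(wet)    36         -7.96         -10.6            -5.08  TRUE
#> 5 ZT-DSR(dry)      50         -6.50          -8.34           -4.71  TRUE
```

Each row is one option pooled against the control: `k` effect records
survived screening, `percent_change` is the back-transformed pooled lnR,
and the reduced/zero-tillage options show significant yield losses of
6.5–8% (their bootstrap CIs exclude zero) while the two
conventional-tillage direct-seeding options do not differ detectably from
puddled transplanting — consistent with the generator's true effects
(+1.4%, −0.7%, −7.4%, −7.0%, −6.9%).

The mixed-model track on the same corpus:

```r
fit <- fit_reml(unpivot_to_arms(trials))
tidy(fit)
#> # A tibble: 6 × 5
#>   option        ls_mean    se n_arms letters
#>   <chr>           <dbl> <dbl>  <int> <chr>
#> 1 CT-DSR(dry)      4.99 0.175     98 a
#> 2 CT-DSR(wet)      5.10 0.175    121 b
#> 3 CT-TPR(wet)      5.03 0.177     60 ab
#> 4 RT-DSR(dry)      4.73 0.182     33 c
#> 5 RT-UPTPR(wet)    4.68 0.180     36 c
#> 6 ZT-DSR(dry)      4.66 0.178     50 c
```

LS means are in Mg/ha; options sharing a letter do not differ at p < 0.05.
The three reduced/zero-tillage options group together (`c`) below the
control, mirroring the meta-analysis verdicts. `glance(fit)` returns the
variance components, and `autoplot()` draws a forest-style figure for a
`meta_summary` or an LS-means figure for a fit.

Pipeline commands (`cmd_simulate()`, `cmd_meta()`, `cmd_mixed()`,
`cmd_report()`, and the thin CLI in `inst/cli/ricemeta.R`) write CSV
tables, SVG figures, run logs and a YAML manifest for fully reproducible
runs; see the methods vignette (`vignettes/ricemeta-methods.Rmd`) for the
model details and design choices.

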