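---
title: "Methods: replicate-weighted meta-analysis and the study-random mixed model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: replicate-weighted meta-analysis and the study-random mixed model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ricemeta)
```

## The problem

Rice grown by conventional wet tillage (puddling) and manual transplanting —
`CT-TPR(wet)` — is the reference practice across most of the rice-growing
world. Five alternative tillage / crop-establishment (CE) options are
candidates to replace it: direct seeding under conventional wet or dry
tillage (`CT-DSR(wet)`, `CT-DSR(dry)`), unpuddled transplanting under reduced
tillage (`RT-UPTPR(wet)`), and direct seeding under reduced or zero tillage
(`RT-DSR(dry)`, `ZT-DSR(dry)`). Evidence comes from hundreds of independent
field studies, each reporting treatment and control arm means (grain yield,
water input, CH~4~ and N~2~O emissions, cost, net return) with replicate
counts but usually **without variances**. `ricemeta` implements the two
inference tracks appropriate to such a corpus — a ratio-based categorical
meta-analysis and an arm-level linear mixed model — and a synthetic corpus
generator that makes both tracks testable end to end.

## The meta-analysis track

For a pair $(X_T, X_C)$ of treatment and control means, the effect size is
the log response ratio

$$\ln R = \ln(X_T / X_C),$$

and, because study variances are unavailable, each pair is weighted by its
replication,

$$w = \frac{n_T \, n_C}{n_T + n_C},$$

half the harmonic mean of the two replicate counts. If a study contributes
$m$ pairs to the same analysis category, each of its weights is divided by
$m$, so no single study can dominate a category. The category is the
combination of response, option (or contrast group), and at most one
moderator level (venue, season, or soil texture group).

**Outlier screen.** Within each category, records lying more than 3 SD from
the weighted mean effect size are removed in a single pass. The dispersion
is deliberately the *unweighted* sample SD centred on the *weighted* mean:
the source convention does not pin down the SD, and the single-pass
unweighted reading is the simplest one — an iterated screen would keep
shaving the tails, which is not what a one-shot rule describes. Categories
with fewer than two records or zero dispersion pass through unchanged
(identical values cannot be outliers, and a zero SD would make the rule
divide by zero); both cases are logged.

**Pooling.** Within a category, true study effects are modelled as randomly
varying around the category mean (differences between categories are fixed).
With the replicate weights taken as working precisions, the between-study
variance is the generalized DerSimonian–Laird moment estimator

$$\hat\tau^2 = \max\!\left(0,\; \frac{Q - (k-1)}{\sum w_i - \sum w_i^2 / \sum w_i}\right),
\qquad Q = \sum_i w_i (\ln R_i - \overline{\ln R}_w)^2,$$

and the pooled effect is the mean under adjusted weights
$w_i^* = 1/(1/w_i + \hat\tau^2)$. This estimator degrades gracefully: when
$Q \le k - 1$ it returns the plain weighted mean. It is scoped per category,
matching "random variation among studies within a group". The weights here
are not inverse variances, so $\hat\tau^2$ is a working-model quantity; the
tests therefore check it against an independent moment-estimator route
(`metafor`, method `"DL"`, with $v_i = 1/w_i$) rather than against any
published value.

**Bootstrap confidence intervals.** 95% CIs come from resampling the
category's records with replacement (4999 iterations by default), re-running
the *entire* pooling — including $\hat\tau^2$ re-estimation — on each
resample, and taking bias-corrected percentile bounds. Design choices that
had to be pinned for determinism:

* *Resampling unit*: effect records, the conventional unit for categorical
  meta-analysis bootstraps. A study-level block bootstrap is available
  (`unit = "study"`) but is not the default; which unit the original
  tooling used is not documentable from the method description.
* *CI type*: bias-corrected (BC) percentile. The acceleration constant of
  BCa is unspecified in the tradition this follows, so the simpler BC
  variant is the default and plain percentile is selectable. When the
  bootstrap distribution is entirely on one side of the point estimate the
  bias correction is undefined; the code falls back to plain percentile
  bounds and logs it.
* *Percentile rule*: linear interpolation between order statistics
  (`quantile(type = 7)`), so identical seed and iteration count give
  bit-identical bounds.
* *Seeding*: one root seed per run; each category derives a child seed by
  hashing its label into the root ([`derive_seed()`]), so a category's CI
  does not depend on which other categories are present or on iteration
  order.

A pooled effect is *significant* when its CI excludes zero; two categories
*differ* when their CIs are disjoint. Results are back-transformed to
percent change, $(e^{\ln R} - 1) \times 100$.

**Contrast schemes.** The tillage question (CT vs RT/ZT) pools
`CT-DSR(wet)` + `CT-DSR(dry)` against `RT-DSR(dry)` + `ZT-DSR(dry)`,
excluding `RT-UPTPR(wet)` so the establishment method is held at direct
seeding. The establishment question (TPR vs DSR) is the genuinely open
design point: control arms have $\ln R \equiv 0$ by construction, so they
cannot contribute ratio records to a TPR group. This implementation builds
the TPR group from `RT-UPTPR(wet)` records only and frames the verdict as a
difference of pooled DSR and TPR effects; synthesizing reciprocal pairs
from control arms was rejected because it would double-count every control.

## The mixed-model track

The confirmatory analysis works on arm means on the original measurement
scale (Mg/ha etc.), not on ratios: each pair contributes its treatment arm,
and each (study, response) context contributes one shared control arm. The
model is

$$y_{so} = \mu + \alpha_o + u_s + \varepsilon_{so}, \qquad
u_s \sim N(0, \sigma^2_{\text{study}}), \quad
\varepsilon \sim N(0, \sigma^2_e),$$

with option fixed and study random, fitted by REML (`lme4`, cell-means
coding, a tightened optimizer stopping rule so that balanced designs
reproduce the closed-form ANOVA estimators to ~1e-9). Least-squares means
are the fixed cell means; with equal replication they equal raw option
means. Arms are unweighted by replicates, as the arm-level analysis
tradition here specifies none.

Pairwise comparisons use a t statistic on each LS-mean difference with its
model standard error and a simple, deterministic residual df:
$N - (\text{fixed rank}) - (\text{number of studies}) + 1$, floored at 1.
Satterthwaite and Kenward–Roger corrections are intentionally not used —
the original df convention is unknowable, and a documented simple rule is
preferable to an approximation chosen post hoc. P-values are unadjusted by
default (matching unadjusted $p < 0.05$ reporting); Bonferroni is available.

The letter display uses the insert-and-absorb algorithm for unbalanced
all-pairwise comparisons: start with one letter column holding all options;
for each significant pair sharing a column, duplicate the column and delete
one member from each copy; absorb any column contained in another. Both
display conditions are guaranteed and are verified exhaustively in the test
suite: no significant pair shares a letter, and every non-significant pair
shares at least one.

## The synthetic corpus generator

No multi-study corpus of this kind is publicly deposited, so the generator
*is* the test bed. It draws noise on the log-ratio scale — exactly the
model under which lnR pooling is unbiased — which separates correctness
tests from robustness tests:

$$\ln R = \delta_o + s_{\text{season}} + t_{\text{texture}} + u_s +
\varepsilon, \qquad u_s \sim N(0, \sigma^2_{\text{study}}), \quad
\varepsilon \sim N(0, \sigma^2_e / w).$$

Control means are log-normal per response and drawn once per
(study, response): a study's pairs share their control arm, which is what
makes the arm-level unpivot exact and gives the mixed model a realistic
error structure. Replicate counts are uniform on 3–6, the typical range of
replicated field trials. Contaminated pairs (a configurable fraction) have
$|\ln R|$ inflated by a fixed magnitude to exercise the outlier screen.

`preset_paper_shape()` documents the scale the pipeline is designed for:
332 studies (9 on-farm), ~3878 pairs in expectation, true effects
$\delta_o$ spanning roughly −8% to +5% with the two conventional-tillage
DSR options dominating sampling, $\sigma_{\text{study}} = 0.05$,
$\sigma_e = 0.08$, 0.5% contamination of magnitude 0.5. The modifiers
(±0.01–0.02 on the log scale) are small relative to the option effects, as
moderator analyses of such corpora report.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: publication bias, correlated responses within a
study, heteroscedastic replicate quality, non-lognormal control means,
reporting errors other than the injected symmetric contamination, and any
dependence of effect size on study size. Parameter recovery on this
generator demonstrates that the machinery is correct under its own model,
not that the model is right for any particular literature.

## Numerical conventions and degenerate inputs

* Nonpositive means, missing or nonpositive replicate counts, and unknown
  codes are rejected row-wise at ingest with named reasons; a missing
  column is a schema error. Pairs with missing replicate counts are
  rejected rather than imputed — an imputation default could not be
  justified from the method description.
* `"unknown"` season/texture levels are permitted in the data but excluded
  (with a logged count) from moderator-stratified analyses.
* Multiplicity for weight division is computed *before* the outlier screen
  and not recomputed afterwards; no re-weighting step follows removal.
* Single-record categories: pooled effect is the record, $\tau^2 = 0$,
  degenerate CI equal to the point estimate, flagged.
* The screen is single-pass by design; it is *not* idempotent in general
  (re-screening the kept set could remove more), and no test asserts
  otherwise.
* All randomness flows from one root seed through `derive_seed()` child
  seeds (a modular rolling hash of the category label, exact in double
  precision below $2^{31}$).

## Problem sizes used in the test suite

The statistical checks run at sizes chosen to give stable verdicts while
keeping a full run in the low minutes: bootstrap calibration uses 1000 null
categories of $k = 30$ at 999 iterations (the reduced iteration count is
the documented option for calibration work; analysis defaults stay at
4999); planted-effect recovery uses 100 replicates with ~50 records per
option; REML recovery uses 200 balanced replicates of 12 studies × 6
options. The planted-effect criterion is evaluated per option — the
true-effect option must be detected in ≥90% of replicates and each null
option must stay non-significant in ≥90% — because the joint event "all
four nulls simultaneously quiet" is bounded near $0.95^4 \approx 0.81$ for
*any* correctly calibrated 95% procedure and is therefore not a meaningful
acceptance bar.

## Known limitations

* $\hat\tau^2$ under replicate weights is a working-model quantity; no
  external value exists to validate it against, only the independent
  moment-estimator route.
* BC bootstrap intervals undercover slightly at $k \approx 30$ (empirically
  ~0.93–0.95 under the generator); this is a property of the interval type,
  shared with the tooling tradition the default follows.
* The establishment contrast's TPR group is thinner than a re-paired
  arm-level analysis would be; the mixed-model track is the better
  instrument for that question and is reported alongside.
* The mixed model assumes a single homoscedastic residual; no
  repeated-measures or spatial covariance structures are offered.
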