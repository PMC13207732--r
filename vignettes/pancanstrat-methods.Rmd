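---
title: "Methods: focal-gene stratification of multi-cohort tumour data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: focal-gene stratification of multi-cohort tumour data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pancanstrat)
```

## The analysis in one paragraph

Many cancer genes are rarely mutated or amplified yet show strongly variable
mRNA expression across tumours of the same type. `pancanstrat` implements a
gene-centric pan-cancer workflow for such genes: tumours in each cohort are
split into high- and low-expression quartile groups on a user-chosen *focal
gene*, and the two groups are compared across five layers — co-expression
(which genes track the focal gene in most cohorts?), driver-mutation rates
(which drivers are preferentially mutated in high-expression tumours?),
genomic-instability metrics (mutation count, fraction of genome altered,
HRD and hypoxia scores), proliferation-adjusted regression (does the
instability association survive adjustment for a mitotic-activity proxy?),
and clinical endpoints (stage, grade, progression-free and overall
survival). A seeded simulator generates multi-cohort datasets with this
exact causal structure so every stage is testable without any external
download.

## Stratification

High/low groups use linear-interpolation empirical quantiles (the type-7
default of mainstream statistical software) at the 75th/25th percentiles,
with inclusive membership (`>= q75`, `<= q25`). The source conventions
conflict between inclusive and strict phrasing; we adopt the inclusive rule
because it is robust to ties and matches the stratification used for the
mutation analysis, and expose `strict = TRUE` for the exclusive reading.
Samples in the middle half are discarded from all two-group analyses. A
constant (or near-constant) expression vector makes the two thresholds
coincide; this raises a degenerate-stratification error rather than
returning empty groups.

Because quantile membership depends only on ranks, stratification is
invariant under any strictly monotone transform of the expression values —
so it does not matter whether a cohort ships RSEM, TPM or any other
non-negative linear-scale abundance, a property the tests assert.

## Co-expression consistency voting

Within each cohort, every gene is correlated with the focal gene by
mid-rank Spearman correlation (Pearson correlation of mid-ranks, which is
the tie-corrected estimator). Two-sided p-values use the t approximation
for n ≥ 10 and the exact method for small untied samples; the
approximation is documented as approximate under heavy ties. q-values are
Benjamini–Hochberg, computed within each cohort across its full gene list.

A gene is counted "positive" in a cohort when ρ ≥ 0.3 and q ≤ 0.05 (both
boundaries inclusive), and labelled `consistent_positive` when it passes in
at least `floor(0.8 × n_datasets)` cohorts — the floor reproduces the
42-of-53 vote of the motivating analysis. The default significance field is
the q-value; `sig_field = "p"` with `sig_thresh = 0.01` reproduces the
alternative p-based reading. Only genes present in every cohort enter the
vote. For display, consistent genes are split into group 1 (raw ρ > 0 in
every cohort) and group 2 (ρ < 0 somewhere) and ordered by descending mean
correlation; cells keep raw ρ values including non-significant ones.
Hierarchical clustering of the heatmap is deliberately out of scope — the
matrix is emitted in a form any clustering tool can consume.

## Mutation-rate delta enrichment

Within each tumour type, each gene's mutation rate is computed in the high
and low groups and differenced (Δ = high − low). Because both rates are
ratios of integer counts, the positive/negative/unchanged status is decided
by integer cross-multiplication (`count_high·n_low` vs `count_low·n_high`),
so Δ = 0 is exact and no floating-point tolerance is involved. Genes absent
from a cohort's mutation universe are `unknown` there: excluded from the
ratio but kept in the encoded heatmap (code 4).

Across tumour types the pos/neg ratio classifies genes as `enriched`
(ratio > 2, strict), `depleted` (ratio ≤ 0.8, inclusive) or `neither`. Both
boundary comparisons are done on integers (`n_pos > 2·n_neg`;
`5·n_pos ≤ 4·n_neg`). Two cases the source conventions never state are
fixed here as package policy: `n_neg = 0` with `n_pos > 0` yields +Inf and
classifies enriched (consistent with the strict "> 2"), and
`n_pos = n_neg = 0` has an undefined ratio and classifies neither. The
status matrix uses the documented numeric codes (positive = 1, negative =
2, unchanged = 3, unknown = 4) with rows ordered by the count of positive
tumour types.

## Proliferation adjustment

The proliferation score is the per-sample mean of per-gene z-scores of
log2-transformed expression over a G2/M-checkpoint gene set, with MKI67
excluded so the single-gene and multi-gene proxies stay non-redundant.
Choices the source leaves open, fixed here: the z-score uses the sample
standard deviation (n − 1); expression gets a +1 pseudocount before log2
(cBioPortal-style matrices can contain zeros; exposed as `pseudocount`);
zero-variance genes are dropped with a warning rather than producing NaN.

Three OLS models per outcome (FGA; natural-log1p mutation count) are
fitted per cohort and on the pooled pan-cancer table: unadjusted,
MKI67-adjusted, G2M-adjusted — separate models per proliferation proxy to
avoid collinearity. Confidence intervals are `β ± t(0.975, n−k)·SE`. For
pooling, scores and transforms are computed within cohort before
concatenation to avoid cohort-size artefacts; `pool_raw = TRUE` gives the
single-table global-standardisation reading. Pan-cancer models carry no
tumour-type fixed effects, matching the per-stratum-OLS design.
Attenuation is summarised as `1 − β_adj/β_unadj` for the focal term; a zero
unadjusted coefficient flags the statistic undefined instead of erroring.

## Clinical comparisons

Rank-sum comparisons of molecular metrics treat "Mann–Whitney" and
"Wilcoxon" as aliases of the same unpaired two-sample rank-sum test (the
groups are independent tumours in every analysis). Small untied samples use
the exact enumeration; otherwise the tie-corrected normal approximation
without continuity correction, so identical groups return p = 1. Stage and
grade use the Pearson chi-square without continuity correction after
dropping zero-marginal categories. Kaplan–Meier curves use the product-limit
estimator with events preceding censorings at tied times; the two-group
log-rank test accumulates observed minus expected events with the
hypergeometric variance, and a `stratify_by_cohort` option accumulates
within cohort for the stratified variant (default: pooled unstratified).
Survival times pass through in their input units (days assumed); no
administrative-censoring cutoff is applied. Zero total events makes the
log-rank undefined (flagged, not an error).

## What the simulator emulates — and what it does not

Each sample draws a latent proliferation factor `P ~ N(0,1)`. Gene
log-expression is `baseline + λ·factor + √(1−λ²)·ε`, exponentiated into
positive skewed linear-scale values. Loadings: focal gene 0.6 on P; G2M
genes 0.7 on P; MKI67 0.45 on P (a deliberately weaker proxy, so
G2M-adjustment attenuates more than MKI67-adjustment, mirroring the target
pattern structurally); planted co-expressed genes load 0.93 on a factor C
that loads 0.93 on P, giving a latent Pearson correlation of
0.93² × 0.6 ≈ 0.52 with the focal gene and hence a population Spearman ρ of
(6/π)·asin(r/2) ≈ 0.50 — the calibration was fixed analytically, once,
before any test was run. Null genes are independent noise.

Driver genes mutate at `base + Δ·1[top focal quartile]` (defaults 0.05 and
0.25); FGA is a logistic transform of `−1.5 + 0.5·P + c_direct·focal_z +
0.3·ε` so pure mediation (`c_direct = 0`) and direct-effect
(`c_direct = 0.4`) regimes are both reachable; mutation count is log-normal
with location shifted by 0.7·P; survival is exponential with log-hazard
0.5 per SD of focal expression and a fixed fraction (default 20%) of
subjects censored uniformly before their event time; stage and grade come
from an ordinal-logit latent shifted by 0.8 per SD of focal expression with
roughly uniform marginal categories. One root seed spawns per-cohort
substreams, so any cohort can be regenerated individually.

The simulator emulates structure, not marginals: it makes no attempt to
match real TCGA sample sizes, gene counts, mutation spectra, batch effects,
or platform differences. A green test therefore establishes that the
pipeline recovers planted structure under its own stated assumptions — it
says nothing about robustness to the messiness of real cBioPortal exports.

## Numerical and design notes

* The CI-coverage property for the regression module is tested on directly
  constructed linear data with a known coefficient. Under the simulator the
  OLS estimand for the focal term has no closed form (logistic link,
  imperfect proliferation proxy), so "coverage of the truth" would conflate
  CI machinery with link misspecification.
* The null-gene specificity property of the enrichment classifier is tested
  at 53 cohorts: for a null gene the pos/neg tallies are a symmetric
  binomial over non-tied tumour types, so the false-"enriched" rate is
  ~7% at 20 cohorts and ~1% at 53 — the 95% specificity bound can only
  hold at the larger scale.
* The pipeline configuration file uses R's native DCF format rather than
  YAML, to stay inside guaranteed base-R parsing; it carries the same
  content (per-cohort file paths plus the focal gene).
* Result tables are written with 15 significant digits so that write/read
  round-trips are exact for decimal-representable values, and the full
  pipeline is byte-deterministic for a fixed seed (asserted by the
  acceptance suite).

## Known limitations

Gene identifiers are opaque case-sensitive strings — no symbol aliasing or
ID mapping. The mutation reader parses only the three columns it needs, not
the full MAF specification. HRD and hypoxia scores are consumed as
precomputed inputs; their derivation is out of scope, as are pathway
enrichment services and dendrogram rendering. No multiple-testing
correction is applied across metric comparisons, matching the raw-p
reporting convention of the motivating analysis.
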