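---
title: "Detecting and scoring global aging signatures in multi-tissue expression atlases"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and scoring global aging signatures in multi-tissue expression atlases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gagatlas)
```

## The problem

Multi-organ single-cell atlases of aging mice sample many tissues, each
annotated into cell types, at a few chronological ages (here 3, 18 and
24 months) in both sexes. Two questions drive the analysis this package
implements:

1. **Which genes change expression with age, and where?** Expression
   change is assessed per *tissue-cell type* — a (tissue, annotated cell
   type) pair treated as one unit — so that a gene can age differently
   in, say, lung immune cells and liver hepatocytes.
2. **Is there a shared, organism-wide aging signature?** Genes that are
   age-dependent in most tissue-cell types, with a consistent direction,
   form a compact signature whose per-cell summary behaves like a
   transcriptomic aging score.

## The model at each stage

### Differential expression against age

Within one tissue-cell type, each gene's log-normalized expression
(counts scaled to 10,000 per cell, then `log(x + 1)` with the natural
log) is regressed on age as a continuous covariate, controlling for sex:

    expression ~ intercept + beta_age * age_months + beta_sex * male

`beta_age` is therefore a natural-log fold change per month; the default
effect-size threshold of 0.005/month corresponds to roughly a 10% change
over the 3-to-24-month span. A gene is called age-dependent in a group
when its Benjamini–Hochberg adjusted p-value (adjusted within the group,
over the genes tested there) is below 0.01 **and** |beta_age| >= 0.005.
The cellular detection rate (number of expressed genes per cell) is
deliberately not a covariate: it correlates positively with age, so
adjusting for it can absorb genuine aging signal. We fit a Gaussian
linear model with Wald t-tests rather than a hurdle likelihood; the
reported quantity — a single age coefficient in log-fold-change units —
is the same, and zero inflation matters little at the coverage this
package's generator emulates.

Only groups with at least 100 cells on each side of the young (3 m) /
old (18 m, 24 m) split are tested (500 for the shallower droplet
regime); cell number affects power, not bias, so no further balancing is
done.

### Global aging genes

Tissues contribute different numbers of cell types, so unweighted
proportions would over-represent cell-type-rich tissues. Each eligible
group gets weight 1/(number of eligible cell types in its tissue);
weights within a tissue sum to 1. A gene is a *global aging gene* (GAG)
when it is significant in **more than 50%** of the weighted groups.
Among GAGs, direction consistency is measured as the weighted proportion
of *significant* groups where the gene moves up; above 80% is
consistently up, below 20% consistently down, in between mixed. The
up-proportion conditions on significance because it asks "among the
contexts where this gene ages, how consistently does it rise?" — the
choice is exposed (`direction_denominator`) since the alternative
(denominator = all groups) is also defensible.

### The GAG score

For a cell with log-normalized expression `x`, up-GAG set `U` and
down-GAG set `D` (after intersection with the dataset's genes):

    raw   = mean(x[U]) - mean(x[D])
    score = raw / (sd(x) * sqrt(1/|U| + 1/|D|))

The denominator is the standard deviation of `raw` under the null that
`U` and `D` are random gene sets of the same sizes drawn from this cell:
a difference of two means of random sets has expectation 0 and variance
`sd(x)^2 (1/|U| + 1/|D|)`. `sd(x)` is the population-denominator
standard deviation over **all** genes (configurable to expressed genes
only), matching that random-background rationale. No mean is subtracted
because the null expectation is exactly 0. Cells with zero expression
variance get a missing score and are excluded from downstream fits with
a logged count. A variant weighting each gene by its expression range is
provided for robustness checks; on simulated data the two versions
correlate above 0.9.

### Score effects and meta-analysis

Score effects are estimated from the no-intercept linear model

    score ~ age + sex + (one indicator per tissue-cell type)

after centering the response and every column. The centered indicators
sum to the zero vector, so the design is exactly rank-deficient by one;
we take the minimum-norm least-squares solution (SVD pseudo-inverse),
under which the tissue-cell effects sum to zero and read as deviations
from the grand mean. This identification is a convention of this
package: any solution shifted along the null vector fits equally well,
and standard errors for the group effects are conditional on the choice.
The age and sex effects themselves are identified and unaffected.

Effects are pooled over tissue-cell types within a functional category
(or lifespan label) by DerSimonian–Laird random-effects meta-analysis:
fixed weights `w = 1/se^2`, heterogeneity `Q`, moment estimator
`tau2 = max(0, (Q - (K-1)) / (sum w - sum w^2 / sum w))`, pooled
estimate with re-weights `1/(se^2 + tau2)`. Categories are compared
pairwise with normal z-tests on the pooled estimates. DL was chosen as
the standard non-iterative estimator; the implementation is vectorized
across genes because the category-specific stage runs two meta-analyses
per gene, and it is cross-checked against `metafor` in the test suite.

### Category-specific aging genes

For a set of tissue-cell types (a functional category, a cell type
pooled across tissues, a tissue, or a single group), a gene is
*set-specific* when (i) its within-set and outside-set pooled age
coefficients differ significantly (normal z-test on the difference,
BH-adjusted over all genes, q < 0.01), (ii) the within-set coefficient
exceeds 0.005 in magnitude, and (iii) the outside-set coefficient is
not significantly non-zero (BH-adjusted q > 0.01). The two adjustments
run independently, each across all genes; criterion (iii) is applied to
the adjusted value. Genes absent from some groups contribute only their
available estimates — no imputation.

## What the synthetic generator emulates — and what it does not

`simulate_atlas()` draws negative-binomial counts with log mean

    baseline_g + beta_gc * age_i + gamma_g * male_i + log(depth_i)

over a 3-tissue layout with {2, 2, 1} cell types (tissue weights 0.5,
0.5, 0.5, 0.5, 1), ages {3, 18, 24} months, balanced sexes, and planted
gene classes: global up/down (beta = ±0.01/month everywhere),
category-specific (beta = 0.01/month only in one functional category,
whose weighted share never exceeds half, so these genes cannot leak into
the GAG set), and null. Defaults: 2000 genes, 150 cells per cell type
per age, per-gene baselines uniform on [2.5, 4.5] natural-log counts
(about 12–90 expected counts per gene per cell, roughly 78,000 counts
per cell), NB dispersion 0.05, log-normal depth with sigma 0.25, sex
effects N(0, 0.05). These emulate a deep-coverage plate-sorted regime
restricted to well-measured genes: a power analysis of the per-group
design (450 cells, age SD 8.8 months) shows the planted 0.01/month
effect is detectable at the 0.005 threshold only when the
log-normalization attenuation (a gene's scaled mean divided by itself
plus one) stays above ~0.6, which the chosen baseline window guarantees.

The generator deliberately does **not** reproduce: the heavy zero
inflation of shallow droplet data (zeros occur but are rare), empirical
mouse gene-level expression distributions, library-size confounding with
age, batch structure, or the non-linear and sex-specific trends in
detected-gene counts reported for real atlases (the generator is
strictly log-linear in age). Passing tests therefore demonstrate that
the estimators and selection rules are correct and calibrated under the
stated generative model — not that the pipeline is robust to every
pathology of real single-cell data.

## Numerical choices and degenerate inputs

- Filters run once, in the order gene filter → cell filters →
  normalization; the gene filter is not iterated after cells drop.
- "More than 100 cells" is implemented as `>= min_cells` with the
  threshold configurable; at the synthetic scales used here the
  boundary case never decides an analysis.
- Selection thresholds are strict inequalities: `prop_sig` exactly 0.5
  is not a GAG, `prop_up` exactly 0.8 is mixed.
- BH ties are handled by the standard step-up with cumulative-minimum
  monotonicity (via `p.adjust`).
- Zero-variance genes within a group are skipped and counted, not
  errored; zero-variance cells get missing scores.
- The effect-model SVD discards singular values below `1e-8` times the
  largest; residual degrees of freedom are `n - rank - 1` (centering
  absorbs one).
- The trajectory classifier treats mean differences within ±0.01 log
  units as flat.
- Hypergeometric overlap tests are one-sided (enrichment); the overlap
  universe defaults to the genes tested in at least one group and is
  configurable, since no single universe is canonical.

## Problem sizes used in validation

The bundled tests and the acceptance script run entirely on simulated
data at desk scale, chosen to keep each stage's Monte-Carlo error well
inside its assertion margins: the default 2000-gene, 2250-cell atlas for
recovery checks; twenty 2000-gene all-null atlases for p-value
uniformity (pooled KS against the 1% critical value) and empirical FDR;
2010 cells with i.i.d. genes for score calibration; 200 replicates for
confidence-interval coverage; 1000 random instances per closed-form
oracle comparison. Headline numbers from the real mouse atlases (e.g.
how many GAGs exist in 76 tissue-cell types) depend on those datasets
and are out of scope here.

## Known limitations

- The Gaussian model ignores the discrete, zero-inflated nature of
  shallow data; on droplet-depth data a hurdle or count model would be
  more faithful.
- Minimum-norm identification of group effects is one convention among
  many; comparing group-effect magnitudes across models fitted on
  different group sets requires care.
- DerSimonian–Laird can underestimate `tau2` for very small K; pooled
  intervals for two-group categories are accordingly optimistic.
- The pipeline assumes cell-type annotations are given and correct;
  mis-annotation propagates to every downstream stage.

## A worked run

```{r pipeline, eval = FALSE}
cfg <- pipeline_config(simulation = simulation_config(seed = 1),
                       preset = "facs", out_dir = "run1")
res <- run_pipeline(cfg)
length(res$gags$gags)        # selected global aging genes
print(res$effects)           # centered score-effect model
res$contrasts$meta           # pooled effects per functional category
```

The same stages are exposed individually (`simulate_atlas`,
`preprocess`, `eligible_groups`, `run_dge`, `weighted_proportions`,
`select_gags`, `compute_gag_score`, `fit_score_effects`,
`group_contrast`, `find_specific_genes`) for interactive use, and
`scripts/acceptance.R` re-derives the validation quantities from a fresh
seed.
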