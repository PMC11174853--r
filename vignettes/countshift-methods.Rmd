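---
title: "countshift: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{countshift: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(countshift)
```

# The problem

`countshift` compares the diurnal transcriptome of two genotype lines — a
parent (reference, "CS") and a chromosome-substitution derivative ("DS") —
sampled at four photoperiod timepoints with three biological replicates
each. At that replication depth, per-gene variance estimates are hopeless
and whole-distribution comparisons are more informative than gene lists
alone, so the pipeline is built around three ideas: a *pooled dispersion
trend*, an *outlier-trimmed mean estimator* with honest degrees-of-freedom
bookkeeping, and an *ECDF cumulative-shift statistic* with exact
permutation p-values.

# The count model

Counts are modeled as NB2: mean $\mu$, shape $\theta$, variance
$\sigma^2 = \mu + \mu^2/\theta$ (`nb2_variance()`). $\theta$ is never
estimated per gene. Instead, replicate vectors ("cells": one gene in one
line x timepoint group) with rounded method-of-moments mean $\ge 8$ are
pooled into abundance bins of at least 30 members (`pool_bins()`; sparse
bins merge upward, a convention — the direction is not prescribed — with
the last bin merging downward). Per bin, $\theta$ is the maximum-likelihood
estimate with each pooled count keeping its own cell mean
(`fit_theta_mle()`, via `MASS::theta.ml`), which avoids assuming that
genes of similar abundance share an expression rate. Under-dispersed bins
return the ceiling $10^6$ rather than diverging: numerically
Poisson-like, no infinities.

The per-bin estimates are smoothed by a gamma log-linear regression of
$\theta$ on $\log \mu$ (`fit_theta_trend()`), giving
$\theta(\mu) = \exp(a + b \log \mu)$, clamped to the observed mean range
at the boundaries. Everything downstream takes $\theta$ from this trend at
whatever mean it is currently considering.

# Outlier-trimmed mean estimation

For the replicates $x_1,\dots,x_r$ of one cell, `estimate_mean_trimmed()`
maximizes over $m$ the *lowest* two-sided tail probability

$$\min_i \ \min\{F(x_i; m, \theta(m)),\ 1 - F(x_i - 1; m, \theta(m))\},$$

i.e. it seeks the mean under which even the most discordant replicate is
least surprising. The search is a coarse log-grid (64 points over
$[\min x, \max x]$) refined by golden-section optimization at relative
tolerance $10^{-4}$; the optimizer is not prescribed by the method, only
the objective. A replicate whose tail probability at the optimum stays
below $\alpha = 0.05$ (outside the central 95% of the mass function) is
an outlier. Because the max–min optimum *equalizes* the extreme tails, the
smallest tail alone cannot tell which replicate is the outlier — with
counts (10, 12, 400) the equalized optimum leaves 10 with the smallest
tail. Removal is therefore greedy: among flagged replicates, the one whose
removal best restores the objective is dropped, and the mean re-estimated.
Trimming never goes below two retained replicates; with three replicates
at most one outlier can ever be removed, and a gene needing more is
excluded. The retained count is the estimate's degrees of freedom: for
regression the estimated mean enters repeated once per retained replicate.

# Differential expression

`wald_test()` tests $H_0$: zero log fold change between two trimmed
estimates, with $\theta$ from the trend at the average of the tested
(replicated) values. With $\theta$ fixed, the two-group NB GLM with log
link solves in closed form — the group means are the MLEs and the IRLS
weight $w = \mu/(1+\mu/\theta)$ gives
$\mathrm{Var}(\log \hat\mu_j) = 1/(n_j w_j)$ — so the package uses the
closed form and keeps the `stats::glm` +
`MASS::negative.binomial(theta)` route (the original analysis's
implementation) as an independent oracle in the tests. Means below 8 are
raised to 8 before both the fit and the fold change, so genes expressed
in only one line are testable without overestimating the fold change; a
consequence is that two means both at or under the floor give exactly
log2FC = 0.

DEG status requires all three filters (`call_degs()`): BH-adjusted p
(per-timepoint family) below 0.05, $|\log_2 FC| \ge 0.9$, and a mean of
at least 8 in one line. `timepoint_association()` reuses the same Wald
machinery to cluster genes with a sharp ($\ge$ 2-fold vs *each* other
timepoint, all three BH-adjusted p < 0.05) excursion at one timepoint;
$\theta$ is fixed at the trend value for the gene's mean across all
points. `classify_activity_change()` compares each line's log2 expression
at the DE timepoint with its own mean diurnal expression (arithmetic mean
of the four floored log2 values — the averaging scale is a convention):
opposite sides give *inversion*, same side farther *enhancement*, same
side closer *weakening*, with ties (including sitting exactly on the
mean) conservatively called weakening.

# Cumulative shift and permutation p-values

`cumulative_shift(a, b)` sums $F_a(x) - F_b(x)$ over the pooled sorted
distinct observed values (the evaluation grid is a convention; the signed
KS D statistic is deliberately *not* used, as a single largest local
difference cannot summarize an overall activity change). The statistic is
positive when `b` is stochastically larger and exactly antisymmetric.

Significance comes from relabeling the pooled observations
(`permutation_test()`, default 10,000 permutations). Two-sided tests
compare unsigned shifts; one-sided tests take the tail *in the direction
of the observed sign* — the literal "proportion of resampled signed
shifts exceeding the observed" would assign p near 1 to any strongly
negative observed shift, which is plainly not the intended test for
underexpression. "Exceeding" is strict with no pseudo-count, and the
reported p is floored at 1/n_permutations ($10^{-4}$ at the default).

`set_activity()` contrasts a gene set's expression at one timepoint with
its pooled values at the other three (pooling all values of the three
other points equally weighted — the alternative, averaging per point,
was rejected as it discards within-point spread); `differential_set_activity()`
contrasts the two lines at one timepoint. Sets need at least 100 members
expressed at $\ge 8$ in some timepoint; permutation p-values are one-sided
and deliberately not FDR-corrected (they are discrete with a hard floor).

# Simulated-count correlation

With only four mean estimates per gene, a direct Pearson correlation of
profiles is nearly meaningless. `pair_correlation()` instead simulates 30
NB2 counts per timepoint mean ($\theta$ from the trend), log2-transforms
with the $\ge 8$ floor (applied here too, for consistency with the
activity analyses), and aggregates the Pearson coefficients of the 16
cross pairings of 4 independent simulations per gene. The geometric mean
is undefined for mixed signs, so: all-same-sign sets aggregate as the
signed geometric mean of absolute values, mixed-sign sets fall back to
the arithmetic mean. Self-pairings are kept — the simulations are
independent, so they carry no shared noise. The seed is assigned to the
lexicographically smaller profile, making the aggregate exactly symmetric
in gene order. Coexpression is $r \ge 0.7$ (about half shared variance);
coregulation is preserved coexpression while both members' own diurnal
patterns transform drastically between lines ($r < 0.5$ cross-line).
Asymptotic p-values for $r$ use the t transform with $n-2$ degrees of
freedom.

# Enrichment

`fisher_overrep()` is the exact hypergeometric tail of the 2x2 table,
one-tailed per direction (under-representation calls need the `less`
tail, so the two-tailed variant is not used). BH families are per
(hit set, term class) — the family structure is a convention.
`paralog_enrichment()` reports mean paralog partners per gene and repeats
the comparison restricted to the paralog-bearing universe, the adjustment
used when paralogy itself biases a set. The default universe is the
expressed quantified genes (estimated mean $\ge 8$ somewhere).

# The synthetic generator: what it emulates, what it does not

`generate_dataset()` draws NB2 counts for 2 lines x 4 timepoints x 3
replicates with: log2-normal base means (default mean 5, sd 1.5 on the
log2 scale — a realistic bulk RNA-seq abundance spread), per-gene
sinusoidal diurnal modulation (amplitude uniform on [0, 1] log2 units,
random phase), an increasing dispersion trend
$\theta(\mu) = e^{0.5 + 0.4\log\mu}$ (so counts are overdispersed at all
abundances but more stable when high), a housekeeping gene with identical
true mean (1000) in every cell and near-Poisson dispersion — a gene whose
replicate noise followed the trend would not be "stably expressed", and
normalizing to it would inject that noise into every library — injected
signed DEG effects (default |log2FC| = 2 on 10% of genes, mostly at one
random timepoint, 5% of them at all timepoints, matching the observation
that most differential expression is timepoint-specific), multiplicative
replicate outliers (1% at 8x), homoeolog-triplet paralog clusters, uniform
chromosome assignment, and one BP and one pathway label per gene.
`ds_global_log2_shift` applies a per-timepoint shift to every DS gene —
the "down at dawn, up at night" world of the end-to-end acceptance run.

The generator does *not* emulate: correlated gene modules (genes are
independent given their profiles), library-size artifacts, mapping
ambiguity beyond the flagged decoy reads of `make_read_alignments()`,
isoform structure, or annotation hierarchies. A green end-to-end test
therefore establishes that the machinery recovers *injected* structure of
the assumed form — not that real wheat data would behave this way.

`make_read_alignments()` realizes each transcript copy as non-overlapping
tiled fragments, so the greatest coverage depth equals the stored count
exactly and quantification round-trips; flagged non-unique/incomplete
decoys must be removed by the filters. Coordinates are 0-based half-open
throughout. `qc_trim()` trims each end until the terminal 10 bases pass
quality > 3 (the window-vs-trim-until phrasing of the underlying rule is
ambiguous; the trim-until reading is implemented) and discards reads
under 30 bp.

# Numerical conventions, in one place

* theta ceiling $10^6$; trend clamped outside the fitted mean range.
* mean search: 64-point log grid + golden section, relative tol $10^{-4}$,
  lower bound 0.001 for all-zero cells.
* permutation p floored at 1/n_permutations; strict "exceeding".
* expression floor 8 before every log2; log base 2 everywhere.
* zero-variance standardized profiles are all-zero; ties in activity
  classification are weakening; UP/DOWN ratio is NA at 0/0 and Inf at
  UP/0.
* housekeeping reference level = geometric mean across samples
  (symmetric, idempotent).
* MAD curves use the unscaled median absolute deviation.

# Known limitations

* The trim-then-test scheme is anticonservative on the minority of genes
  where a replicate was trimmed: conditioning on removing the most
  extreme draw makes the survivors artificially concordant, and the
  degrees-of-freedom bookkeeping cannot repair that selection effect. The
  Wald machinery itself is well calibrated (the acceptance suite checks
  type-I error in [0.03, 0.07] and uniformity of null p-values on plain
  group means). Interpret single-gene p-values of trimmed genes with
  care.
* The max–min mean estimator is not the sample mean; for symmetric
  replicate sets the two nearly coincide, but for skewed NB tails the
  estimator sits slightly above the midpoint (this is intended — it
  maximizes the plausibility of the worst replicate).
* Correlation aggregation by geometric mean biases |r| slightly upward
  relative to a plain average when pairings vary; the mixed-sign fallback
  is a pragmatic convention.
* All-vs-all pair enumeration at transcriptome scale (~10^9 pairs) is out
  of scope; the engine is correct, not exhaustive.

# A worked micro-run

```{r, eval = FALSE}
cfg <- pipeline_config(
  synthetic = simulation_config(n_genes = 1200, deg_fraction = 0.1,
                                ds_global_log2_shift = c(-1.5, -0.5, 0.5, 1),
                                seed = 99),
  stages = c("normalize", "model", "estimate", "de", "activity"),
  n_permutations = 2000, seed = 99)
res <- run_pipeline(cfg)
res$report$shift         # DS-CS cumulative shift per timepoint
res$report$updown_ratio  # rising across the day in this world
```
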