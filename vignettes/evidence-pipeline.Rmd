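---
title: "From expression compendia to calibrated association evidence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From expression compendia to calibrated association evidence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evinet)
```

# The problem

Functional-association networks connect genes or proteins that work
together, whether or not they touch physically. One of the strongest
genome-wide signals for such associations is co-expression: genes under
shared regulation rise and fall together across conditions. Public
microarray compendia contain thousands of heterogeneous experiments per
organism, but turning them into a single, comparable evidence channel
requires solving four problems in sequence: uneven data quality,
incompatible measurement scales between platform types, massive
redundancy among deposited arrays, and the fact that a raw correlation
coefficient is not a probability. `evinet` implements that pipeline,
plus the machinery that typically surrounds it in a cross-species
association resource: orthology-based transfer of scored edges between
organisms, and term-enrichment statistics for the resulting gene sets.

# The co-expression model, stage by stage

## Inclusion filters

Not every deposited sample is usable. Three thresholds, applied in a
fixed order, gate the analysis:

* a *sample* must cover at least 100 distinct genes with a non-missing
  value after probe-to-gene mapping (`min_mappable_genes_per_sample`);
* an *experiment* must retain at least 3 samples after the sample
  filter (`min_samples_per_experiment`);
* an *organism* must retain at least 50 experiments
  (`min_experiments_per_organism`).

"Mappable genes" counts distinct gene identifiers, not probes, because
the quantity of interest is gene coverage. The sample filter runs
first and experiments are re-checked afterwards: an experiment that
only reaches three samples by counting an unusable one should not
survive. Filtering is idempotent and purely subtractive; every removal
is written to a structured exclusion log (`level`, `id`, `reason`).
The order sample → experiment → organism is a design choice — the
interaction of the thresholds when a removal cascades is otherwise
underdetermined — and we chose the conservative reading that re-checks
each level after the one below it.

## Per-channel normalization

Dual-channel arrays already measure log-ratios (fold changes), so each
sample column is only z-normalized. Single-channel arrays measure
absolute intensities; they are made fold-change-like by taking `log2`
(non-positive intensities are treated as missing rather than producing
`-Inf`), subtracting each probe's mean across the experiment's samples
(so a value becomes "log-fold relative to this probe's average
condition"), and then z-normalizing each sample column. The ordering
matters: z-scores contain negative values, so the log transform must
come first; and the per-*probe* (not per-sample) mean subtraction is
what makes the single-channel values comparable with dual-channel
log-ratios. Z-normalization uses the population (1/n) standard
deviation, which makes the step exactly idempotent; zero-variance
columns map to all zeros rather than NaN.

Genes measured by several probes are averaged per sample after
normalization, missing-aware. Missing values are tolerated throughout
(pairwise-complete handling downstream) rather than imputed; imputation
would manufacture correlation where the data have none.

## Redundancy pruning (Hobohm-2)

Compendia contain near-duplicate arrays — resubmissions, replicate
uploads, dye swaps — which silently multiply the weight of single
experiments. All arrays of one organism and channel are pooled,
pairwise Spearman rank correlations are computed over shared genes, and
the Hobohm-2 algorithm prunes the set: build a graph with an edge
wherever similarity exceeds the threshold (0.7 for single-channel,
0.95 for dual-channel), then repeatedly delete the currently
most-connected array until no edges remain. Equal degrees are broken
by deleting the lexicographically larger array ID, which makes the
output deterministic; the original algorithm leaves this open.
Similarity is signed — strongly anti-correlated arrays carry
independent information and are not redundant — and a pair's
similarity is only defined when the arrays share at least
`min_overlap` (default 20) non-missing genes, since rank correlations
over a handful of genes are noise.

## Correlation and calibration

Gene-by-gene Pearson correlations over the retained arrays
(pairwise-complete, with the same overlap guard) are the raw
co-expression signal. To convert a correlation into evidence, it is
benchmarked against pathway co-membership: a gene pair is a positive
when both genes share an annotated pathway, a negative when both are
annotated but share none, and unbenchmarkable otherwise. Pairs are
ranked by signed correlation (negative co-expression is not rewarded),
a sliding window of 500 pairs estimates local precision along the
ranking, and isotonic regression (pool-adjacent-violators) makes the
precision profile monotone in the raw score. The resulting curve maps
any correlation to a posterior association probability by linear
interpolation, clamped at the extreme knots. The window width trades
resolution against variance — at 500, the binomial standard error of a
window is about 2 percentage points at a precision of 0.1. The
estimator itself (window + isotonic fit) is our choice; any monotone
smoother would serve, and isotonic regression adds no tuning
parameters beyond the window.

## Probabilistic combination

Single- and dual-channel scores are calibrated separately — the two
platform families have different noise structure — and then combined.
The combination is a prior-corrected noisy-OR: each channel score `s`
is mapped to `(s - prior) / (1 - prior)` (scores below the prior are
floored at the prior: a channel that says less than the base rate
contributes nothing, it does not subtract), the corrected scores are
combined as `1 - prod(1 - s')`, and the prior is restored. The prior
defaults to the measured positive fraction of the benchmarkable pairs.
The operation is commutative, associative, monotone in each argument,
and never returns less than its largest input — exactly the algebra
one wants from independent evidence channels.

## Benchmarking

`roc_benchmark()` ranks pairs by combined score and reports a ROC
curve with tied scores grouped into single steps and the AUC computed
by the trapezoid rule, which equals the tie-corrected Mann–Whitney
statistic; the test suite asserts that equality against an independent
rank-based computation to 1e-9.

# Orthology: self-consistency and transfer

Interolog transfer propagates a scored interaction from a well-studied
organism to orthologs in another. It requires hierarchical
orthologous groups over a clade tree, and those groups should be
*self-consistent*: proteins grouped together at a clade must be
co-grouped at every ancestor clade. Independently computed per-clade
assignments routinely violate this. `enforce_consistency()` repairs a
group set by iterating split/merge passes until a fixpoint, under one
of two strategies:

* `merge_up` walks leaves-to-root and union-merges any ancestor groups
  that share proteins of one descendant group. Nothing is ever
  separated; ancestor groups only grow. This is the default because
  it preserves every stated grouping.
* `split_down` walks root-to-leaves and splits each group by its
  members' group at the nearest ancestor clade where they are
  assigned. Groups only shrink. Proteins unassigned at every
  ancestor carry no constraint; rather than being split off they stay
  with the largest fragment (ties broken by fragment label), keeping
  the repair minimal and deterministic.

The two strategies bracket the space of consistent repairs (coarsest
vs. finest); which intermediate state an iterative repair should
prefer is not determined by the consistency requirement itself, so we
expose the choice instead of hard-coding one.

Transfer maps each edge through the lowest clade covering both
species. With `n_a` and `n_b` target-species proteins in the two
groups, every target pair receives the source score times
`(n_a * n_b)^(-gamma)` (default `gamma = 0.5`). This penalty is our
own plumbing: fanning an edge out to `n_a * n_b` paralog pairs dilutes
the evidence per pair, and the square-root form conserves the *total*
transferred evidence in a rough sense while remaining configurable
(`gamma = 0` conserves each score exactly). It is documented as
non-canonical; resources differ in how they weight paralogy.
Multiple transfers landing on one target pair are merged with the same
noisy-OR used for channels (prior 0, since transferred fragments of
one edge share no benchmark prior), weak edges are dropped below
`min_transferred_score` (default 0.15), and untransferable edges are
written to a skip log rather than silently vanishing.

# Enrichment

The enrichment engine is a catalog-shaped hypergeometric test: for a
query gene set and each term, `P(X >= k)` under drawing the query from
the catalog background without replacement, computed through the
stable log-space tail of `phyper`, with Benjamini–Hochberg FDR across
all tested terms of the catalog. The background defaults to the
catalog's annotated universe rather than a whole proteome — a
conservative choice that never inflates significance for genes the
catalog cannot speak about. The test statistic itself is a design
decision; the annotation shapes (pathway, tissue, disease) all reduce
to the same term→gene table.

# What the synthetic generator emulates — and what it does not

`simulate_expression()` exists so that every stage of the pipeline can
be validated against planted truth. It draws, per sample, one latent
activity per module from Normal(0, 1); a member gene's signal is that
activity plus Normal(0, `noise_sd`) gene noise, and each probe adds
independent probe noise of the same magnitude. This latent-factor
construction is the minimal model under which "co-expression reflects
co-regulation" is literally true, which is precisely the assumption
the pipeline relies on. Single-channel experiments exponentiate the
signal (`2^x`) into positive intensities so the log2/mean-subtraction
path is exercised nontrivially; duplicate arrays are emitted with
probability `duplicate_array_rate` so pruning has real work to do; the
planted modules double as the gold-standard pathways.

The defaults describe the corpus used throughout the package's own
validation: 200 genes in 20 modules of 10, 12 experiments of 8 samples
(roughly 100 arrays after duplication, an even single/dual mix),
noise_sd 0.5, duplicate rate 0.1. These sizes give every stage
non-degenerate work — around 50 arrays per channel, comfortably above
the 20-array overlap guard, and ~20,000 gene pairs against a 500-pair
calibration window — while keeping a full run in seconds.

What the generator does **not** emulate: platform-specific artifacts
(dye bias, spatial effects, background correction), heavy-tailed
intensity distributions, batch effects correlated with biology,
RNA-seq counts, and modules that overlap or couple to each other. A
passing benchmark on this fixture therefore demonstrates that the
pipeline's machinery is correct — filters fire at their thresholds,
redundancy is removed, calibration recovers planted precision, ranking
discriminates planted modules — not that real-compendium AUC values
will be as high. On real data the separation between within- and
between-module correlation is far smaller; the near-perfect fixture
AUC is a property of the fixture, and is asserted only as `> 0.9`.

Likewise `simulate_orthology()` builds a balanced species tree with
nested groups that are consistent by construction, then corrupts a
configurable fraction of below-root assignments to emulate
independently computed clades; real orthology errors are not uniform
random reassignments, so the repair benchmark shows convergence and
monotonicity, not accuracy against evolutionary truth.

# Numerical choices and degenerate inputs

* Z-normalization uses the population standard deviation (exact
  idempotence); constant columns map to zeros, all-missing columns
  stay missing.
* Correlations are clamped to [−1, 1] against floating-point overshoot.
* Undefined similarities (overlap below `min_overlap`, zero variance)
  are `NA` and never create a redundancy edge.
* Calibration requires at least `window_size` benchmarkable pairs and
  a window of at least 50; an all-positive (or all-negative) labeling
  yields a constant curve rather than an error.
* Curve evaluation outside the knot range clamps to the end knots.
* ROC computation refuses single-class inputs; fully tied scores give
  the single-step diagonal (AUC 0.5).
* Hobohm-2 and the repair strategies break all ties lexicographically,
  so every pipeline output is reproducible byte for byte.
* The hypergeometric tail is evaluated in log space; `k = 0` returns
  exactly 1.

# Known limitations

* Calibration and benchmarking may share a gold standard in casual
  use; the package's own validation calibrates and evaluates on
  planted truth where the contamination is harmless (monotone
  recalibration does not change rank order, hence not the AUC), but
  real evaluations should split the standard.
* The paralogy penalty exponent is a free parameter with no
  gold-standard calibration of its own.
* Only two co-expression channels are built in; additional evidence
  channels enter only as pre-scored columns through the combination
  step.
* The enrichment test ignores network topology.

# A worked example

```{r example}
ds <- simulate_expression(simulation_config(seed = 1))
cfg <- pipeline_config(filter = filter_config(min_experiments_per_organism = 1))
res <- run_coexpression_pipeline(ds, config = cfg)
res$org1
head(res$org1$network, 3)
```

The per-channel calibration curves and the ROC are part of the result:

```{r curves}
res$org1$curves$single
res$org1$roc
```
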