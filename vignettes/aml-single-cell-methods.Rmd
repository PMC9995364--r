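---
title: "Methods: single-cell AML genotyping, monosomy scoring and risk stratification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-cell AML genotyping, monosomy scoring and risk stratification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amltk)
```

# Scope

`amltk` packages the bespoke computational steps needed to follow acute
myeloid leukemia (AML) through chemotherapy in single-cell RNA-seq data:
deciding, cell by cell, which droplets are leukemic (by direct mutation
detection or by chromosome-7 dosage), distilling an expression signature to
its informative genes, transferring that signature into survival cohorts,
and a set of smaller estimators (hashtag demultiplexing refinement,
limiting-dilution frequencies, gene-set similarity). Upstream alignment,
clustering, embedding and differential expression are deliberately out of
scope: cluster labels, embeddings and DE tables are *inputs* here, produced
by whatever standard toolchain the user prefers.

Every analysis function has a matching seeded generator (`sim_*`) that
plants known ground truth, so all recovery claims in the test suite are
statements about (data, truth) pairs produced by the package itself.

# NPM1 mutation genotyping

The NPM1 type-A mutation is a TCTG tandem duplication at
chr5:171410540-171410543, close enough to the gene's 3' end to appear in 3'
scRNA-seq reads. The genotyper rests on one asymmetric assumption: a single
mutant transcript proves a cell leukemic, while absence of mutant
transcripts proves nothing by itself.

**Motif matching.** `npm1_patterns()` holds ten literal motifs: one
unanchored core, four suffix-anchored and five prefix-anchored truncations,
so a duplication clipped at either read boundary is still recognized.
Matching is exact — the motifs are literal, and tolerating mismatches would
trade a known false-negative mode for an unquantified false-positive one.
Characters outside A/C/G/T never match (one warning per session).

**UMI collapsing.** Reads sharing a (cell barcode, UMI) pair are one
molecule. A molecule is `MUT` if *any* read matches a motif; otherwise it is
`WT` evidence only when some read's aligned interval fully contains the
4-nt locus — full containment is the minimal condition under which *not*
seeing the duplication is informative. Partial overlap is `uninformative`.
Conflicting reads within a UMI resolve to `MUT` (one mutant transcript is
enough).

**Cell classes.** `MUT`: ≥ 1 mutant UMI. `WT`: no mutant UMI and > 5
wild-type UMIs. `ND` (not detected): no mutant UMI, ≤ 5 wild-type UMIs,
but coverage over the locus. `NoCall`: no read overlapping the locus at
all. Cells with locus-overlapping reads but no classifiable molecule are
`ND`, reserving `NoCall` strictly for zero overlap.

**Cluster extension.** Because mutant and wild-type cells rarely co-cluster,
per-cluster class fractions support five sequential criteria
(`assign_clusters`): (1) MUT ≥ 40% extends the AML label to the whole
cluster; (2) 20–40% MUT with WT < 5% extends; (3) 10–20% MUT with WT < 5%
extends only for myeloid clusters whose majority is NoCall; (4) 5–10% MUT
with WT = 0% likewise; (5) below 5% MUT only the MUT cells themselves are
AML. WT cells are excluded everywhere. Fractions are computed over all
cluster cells (not only covered ones); compositions matching no criterion —
possible, e.g. 25% MUT with 6% WT — conservatively fall back to
criterion-5 behavior. The myeloid flag is an explicit per-cluster input
(`myeloid_flag()` offers a marker-score helper), mirroring the fact that
lineage assignment is an annotation judgement, not something this module
should decide silently.

# Module scores and monosomy 7

`module_score()` is a control-matched gene-set score: counts are scaled to
10,000 per cell and log1p-transformed; genes are ranked into 24
average-expression bins; each target gene draws 100 control genes from its
bin; the score is the per-cell mean over targets minus the mean over the
pooled (unique) controls. Two conventions matter:

* bins are ranked with ties broken by gene name, so scores are invariant
  under row/column reordering;
* when a bin holds no more genes than `n_ctrl`, the whole bin serves as the
  control set (with a warning) rather than resampling with replacement.
  This is the deterministic limit of resampling and makes two useful
  identities exact: a constant matrix scores 0, and a gene set spanning all
  genes scores 0.

The defaults (24 bins, 100 controls) are this package's choices, exposed in
the call; per-cell totals and bin counts are the only tunables that
materially move scores.

Loss of one chromosome-7 copy halves the aggregate expression of chr7
genes, so the chr7 gene-set score of leukemic cells shifts down by roughly
a constant, producing a bimodal score distribution. `classify_monosomy()`
splits it with an *exact* two-group 1-D k-means (the sorted split
minimizing within-group sum of squares) — equivalent to converged Lloyd
iterations but with no initialization randomness — and labels the
low-score group AML.

Two diagnostics accompany the split. The mean silhouette width is reported
descriptively, but it has no useful cutoff in one dimension: the optimal
two-way split of even a *single* Gaussian has mean silhouette ≈ 0.55
(≈ 0.67 for the centroid-based variant), a property of 1-D silhouettes,
not of the data. The `weak_bimodality` flag therefore comes from a BIC
comparison of one- versus two-component unequal-variance Gaussian mixtures
(`mclust::mclustBIC`): the flag fires when one component explains the
scores at least as well as two. On simulated data this separates null
(monosomy factor 1) from planted (factor 0.5) configurations cleanly. The
flag is a reporting aid; it never gates the classification.

# Signature scoring and item-test reduction

`score_signature()` applies the same module score to an expression
signature; a cell is *positive* when its score is strictly above zero (the
control-matched baseline), and percent-positive is summarized per sample.

`reduce_signature()` distills a signature to informative genes by item-test
correlation, as in reliability analysis: each gene's expression is
correlated (Spearman) with the full-signature score across cells; genes
with rho > 0.3 and Bonferroni-corrected p < 0.05 are kept. Conventions:
average ranks for ties; the t approximation for p when n > 30 and the exact
small-sample distribution below; the Bonferroni factor is the *full*
supplied signature length (the conservative reading when the tested subset
is ambiguous); zero-variance and absent genes are dropped with explicit
reason codes, never silently. Setting `rho_min = -1, alpha = 1` disables
both gates and keeps every finite-rho gene. At least 10 cells are required
— below that, rank correlations are too granular to mean anything.

`filter_markers()` and `eligible_comparison()` encode the marker-gating
conventions used around differential expression: |logFC| ≥ 0.25,
expressing fraction > 25% in at least one compared group, Wilcoxon
p < 1e-5; and intra-cluster group comparisons require at least 5 cells on
both sides.

# Survival risk stratification

Cross-platform transfer (microarray training, RNA-seq testing) motivates a
rank-based representation: `quartile_categorize()` maps each patient's
expression values to -1/0/+1 using that patient's *own* quartiles (strict
inequalities; boundary values are 0; linear-interpolation quartiles, the
common default, since the convention is otherwise arbitrary — exposed via
`qtype`). The categorization is invariant under any monotone per-patient
transformation, which is the point: platform and unit differences drop out.
The quartile universe defaults to the patient's full profile, with a
signature-only mode available.

`fit_risk_model()` fits an L1-penalized Cox model (glmnet), choosing the
penalty by 10-fold cross-validated partial-likelihood deviance; folds are
seeded and stratified by event status for stability with few events. The
linear predictor's training median becomes the frozen cutoff.
`apply_risk_model()` transfers coefficients and cutoff unchanged (strictly
greater than the cutoff is high risk; missing genes are an error, never
imputed), and `evaluate_groups()` reports Kaplan-Meier curves, the
log-rank test and the high-vs-low hazard ratio with Wald 95% CI. When the
selected penalty zeroes every coefficient the model is flagged degenerate
and refuses to stratify — on null data this is the *expected* outcome (the
lasso shrinks noise away in well over half of null simulations), and the
type-I error of the full train/test procedure stays within the nominal
band precisely because degenerate fits decline to test.

# Auxiliary estimators

**HTO refinement** (`refine_hto`). Hashtag demultiplexing leaves background
noise: cells called Negative inside an obvious hashtag cloud, and
hashtag-labeled cells far from it. For each hashtag in input order, the
medoid of its labeled cells on the 2-D embedding is found, the 0.98
quantile *r* of their distances to the medoid is taken, and an axis-aligned
box of half-width *r* around the medoid becomes the boundary: labeled cells
outside are discarded (to Negative), Negative cells inside are rescued.
Because the box contains the distance-quantile disc, at least 98% of a
hashtag's own cells always remain inside. A disc-shaped boundary is
available (`shape = "disc"`); rescued cells are never relabeled by later
hashtags; rescuing other hashtags' singlets is off by default because it
can oscillate. Two caveats are inherent to the procedure: it assumes false
positive hashtag labels are rarer than the quantile allowance (strays above
~2% of a hashtag drag the quantile into the stray cloud — the `sim_hto`
default stray fraction is 1% for this reason), and it is only *nearly*
idempotent: a second pass recomputes the boundary from the refined set and
can churn isolated cells at the 2% distance tail (measured ≈ 0.7% of cells
on the default simulation).

**Limiting dilution** (`estimate_frequency`). Under the single-hit model a
mouse transplanted with *d* cells fails to engraft with probability
exp(-f·d). The MLE of *f* is obtained from a binomial GLM with
complementary log-log link and log-dose offset — the same model the
classical limiting-dilution estimator fits — with a Wald CI on log f. A
single dose reduces to the closed form f = -log(k/n)/d. Experiments with
no engrafters return 0 with a one-sided upper bound; experiments where
every mouse engrafted failed to reach a limiting dose and return a
one-sided lower bound obtained from the likelihood directly.

**Gene-set kappa** (`kappa_score`). Cohen's kappa on the binary membership
vectors of two gene sets over a DEG universe — observed minus chance
agreement, normalized — which weights similarity for unequal set sizes.
Disjoint sets covering the universe reach -1, identical sets 1, random
sets ≈ 0.

# Synthetic data: what it emulates, and what it does not

`synth_config()` fixes the study conditions once; each generator derives
its own RNG stream from the master seed plus its name, so outputs are
byte-identical under a fixed seed and adding a generator never perturbs
the others.

* `sim_reads` plants mutant/wild-type transcript molecules (Poisson counts
  per cell, defaults 2 and 3) and emits reads as random windows of the
  transcript, so boundary-truncated motifs genuinely occur; 20% of cells
  receive no reads (ground-truth NoCall). Flanking sequence is checked to
  be motif-free. Mutant reads ending inside the duplicated TCTG can look
  locus-covering without a matchable motif — the same truncation blind
  spot the real method has, which is why cell-level recovery is ~99%, not
  100%.
* `sim_counts` draws negative-binomial counts with log-normal per-gene
  dispersion — the standard scRNA-seq noise model, sufficient for
  module-score bimodality. Chr7 genes of AML cells are scaled by 0.5;
  the first 50 of 200 signature genes are log-linearly coupled
  (strength 0.8) to a latent per-cell stemness score, giving planted
  informative genes a gene-latent Spearman rho around 0.55 — comfortably
  inside the "informative" regime their definition demands. It does *not*
  simulate splicing, ambient RNA, empty droplets, doublet expression
  profiles or read qualities; recovery results say nothing about those
  failure modes.
* `sim_survival` draws exponential event times with log-hazard equal to
  the planted coefficients applied to the *categorized* expression (+1/-1
  on the first two genes by default, n = 300 patients), with independent
  exponential censoring calibrated to 30%.
* `sim_hto` places isotropic Gaussian hashtag clouds (3 × 400 cells,
  spread 1, centers 10 apart), relabels 10% of each cloud Negative in
  place, plants 1% strays and 5% doublets.
* `sim_lda` draws engraftment outcomes from the single-hit model at
  f = 1/500 over doses 100/500/2000 with 12 mice each.

# Problem sizes and numerical choices

The shipped test suite runs the recovery experiments at the sizes the
claims refer to: monosomy recovery at 2,000 cells × 100 chr7 genes
(accuracy ≥ 0.95), reduction recovery at 2,000 cells with 50 informative +
150 null genes (recall ≥ 0.9) plus 200 null replicates at 300 cells × 60
genes for the family-wise false-keep rate, survival null calibration over
100 seeds at 160 patients × 12 genes and power over 30 seeds at 300
patients, limiting-dilution coverage over 200 seeded experiments, and
motif-matching equivalence against an independent per-motif regex oracle
on 10,000 random sequences.

Numerical conventions worth knowing: exact 1-D k-means removes clustering
randomness entirely; Spearman ties use average ranks; quartiles
interpolate linearly; the GLM behind the limiting-dilution estimator is
exactly scale-consistent in the dose unit; and every stochastic step
(control-gene draws, CV folds, train/test splits, generators) takes an
explicit seed.
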