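# amltk

Tools for tracking acute myeloid leukemia (AML) through chemotherapy in
single-cell RNA-seq data, for analysts who already have aligned count
matrices, cluster labels and embeddings and need the decision rules on top:

* **NPM1 mutation genotyping** — the NPM1 type-A mutation (a TCTG tandem
  duplication at chr5:171410540-171410543) sits near the 3' end of the gene
  and is directly visible in 3' scRNA-seq reads. `match_read()` screens
  reads against ten literal motifs (one internal, four suffix-anchored,
  five prefix-anchored, catching duplications clipped at read boundaries),
  `collapse_molecules()` reduces reads to UMI-level allele calls,
  `genotype_cells()` classifies cells (MUT: ≥ 1 mutant UMI; WT: > 5
  wild-type UMIs and none mutant; ND: ≤ 5 wild-type UMIs with coverage;
  NoCall: no coverage), and `assign_clusters()` extends the leukemia label
  cluster-wise through five sequential abundance criteria.
* **Chromosome-7 monosomy calling** — `module_score()` computes a
  control-matched gene-set score (per-cell mean of targets minus
  expression-matched controls, 24 bins × 100 controls); a chr7 gene-set
  score is bimodal under loss of one chromosome copy, and
  `classify_monosomy()` splits it with an exact 1-D 2-means, labelling the
  low mode AML.
* **Signature reduction and positivity** — `score_signature()` calls
  per-cell positivity (score > 0); `reduce_signature()` performs item-test
  reduction, keeping genes whose Spearman correlation with the
  full-signature score is > 0.3 with Bonferroni-corrected p < 0.05.
* **Survival risk stratification** — `quartile_categorize()` maps each
  patient's expression to −1/0/+1 by the patient's own quartiles (platform
  independent), `fit_risk_model()` fits a lasso-penalized Cox model with
  seeded 10-fold cross-validation and freezes the training-median cutoff
  of the linear predictor, `apply_risk_model()` transfers it unchanged to
  a test cohort, `evaluate_groups()` reports Kaplan–Meier curves, the
  log-rank test and the hazard ratio.
* **Auxiliary estimators** — `refine_hto()` (hashtag-demultiplexing rescue
  via a 0.98-distance-quantile box around each hashtag's medoid),
  `estimate_frequency()` (single-hit limiting-dilution MLE with Wald CI),
  `kappa_score()` (Cohen's kappa between gene sets over a DEG universe).
* **Seeded synthetic data** — `synth_config()` plus `sim_reads()`,
  `sim_counts()`, `sim_hto()`, `sim_survival()`, `sim_lda()` generate
  every input with planted ground truth; `run_end_to_end()` chains
  simulation and analysis and reports recovery metrics.

See the vignette (`vignettes/aml-single-cell-methods.Rmd`) for the models,
conventions and limitations.

## Worked example

```r
library(amltk)
cfg <- synth_config(seed = 42)       # 2000 cells, planted mutation/monosomy,
                                     # 50 informative signature genes,
                                     # 300-patient survival cohort
bundle <- run_end_to_end(cfg)
print(bundle)
#> pipeline_bundle (config 1fc5ea19 , seed 42 )
#>                    stage        value
#>               genotyping 9.950000e-01
#>                 monosomy 9.685000e-01
#>         signature_recall 9.600000e-01
#>     signature_false_keep 0.000000e+00
#>  survival_test_logrank_p 4.999302e-10
#>       hto_label_accuracy 9.933333e-01
#>            lda_frequency 1.360634e-03
```

Reading the metrics: 99.5% of cells get the correct leukemic/non-leukemic
label from NPM1 genotyping plus cluster extension; monosomy-7
classification recovers 96.9% of planted labels; item-test reduction finds
96% of the 50 planted informative genes and keeps none of the 150 null
genes; the risk model trained on half the simulated cohort separates the
test half at log-rank p ≈ 5e-10; hashtag refinement restores 99.3% of
true labels; and the limiting-dilution estimate is f ≈ 1/735 against a
planted 1/500 (the 95% CI covers the truth):

```r
print(bundle$survival$risk$eval_test)
#> survival_eval: log-rank chi-sq 38.678 (p = 4.999e-10), HR (high vs low) 4.270 [2.607, 6.993], 89 events
print(bundle$auxiliary$lda)
#> stem-cell frequency: 1 in 735.0 (f = 0.00136, 95% CI [0.000798, 0.00232])
print(bundle$signature$reduction)
#> reduction_result: 48 / 200 genes kept (rho > 0.30, Bonferroni p < 0.05)
```

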