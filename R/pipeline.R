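# End-to-end orchestration on synthetic data: generate every input with
# known truth, run each analysis stage, and report truth-vs-inferred
# recovery metrics together with a reproducibility manifest.

#' Run the full synthetic pipeline
#'
#' Executes, from one seeded configuration: read simulation and NPM1
#' genotyping with cluster-based leukemia assignment; count-matrix
#' simulation with chromosome-7 module scoring and monosomy
#' classification; signature scoring and item-test reduction; survival
#' simulation with train/test risk stratification; HTO refinement and
#' limiting-dilution estimation. Each stage consumes only the generated
#' data and the generator's truth, and contributes a recovery metric.
#'
#' @param config A \code{\link{synth_config}}.
#' @return List of class \code{"pipeline_bundle"} with per-stage results
#'   (\code{genotyping}, \code{monosomy}, \code{signature},
#'   \code{survival}, \code{hto}, \code{lda}), a \code{metrics} summary
#'   data frame and a \code{manifest} (config hash, seed, package
#'   version); identical configs reproduce identical bundles.
#' @export
run_end_to_end <- function(config) {
  validate_synth_config(config)
  warnings_seen <- character(0)
  collect <- function(expr) {
    withCallingHandlers(expr, warning = function(w) {
      warnings_seen <<- c(warnings_seen, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  }

  # --- stage 1: NPM1 genotyping -------------------------------------------
  rd <- sim_reads(config)
  mol <- collapse_molecules(rd$reads)
  cov <- locus_coverage(rd$reads, cells = rd$truth$cell_barcode)
  geno <- genotype_cells(mol, cov)
  clusters <- setNames(rd$truth$cluster, rd$truth$cell_barcode)
  myeloid <- tapply(rd$truth$myeloid, rd$truth$cluster, any)
  asg <- collect(assign_clusters(geno, clusters, myeloid))
  truth_aml <- setNames(rd$truth$is_aml, rd$truth$cell_barcode)
  geno_acc <- mean(asg$aml[names(truth_aml)] == truth_aml)
  genotyping <- list(genotypes = geno, assignment = asg,
                     n_mut_cells = sum(geno$call == "MUT"),
                     accuracy = geno_acc)

  # --- stage 2: chr7 monosomy ---------------------------------------------
  cnt <- sim_counts(config)
  chr7_scores <- collect(module_score(cnt$matrix, cnt$truth$chr7_genes,
                                      seed = config$seed))
  mono <- collect(classify_monosomy(chr7_scores))
  mono_acc <- mean((mono$labels == "AML") == cnt$truth$is_aml)
  monosomy <- list(scores = chr7_scores, classification = mono,
                   accuracy = mono_acc)

  # --- stage 3: signature scoring and reduction ---------------------------
  sig <- signature_definition("stemness", cnt$truth$signature_genes)
  sc <- collect(score_signature(cnt$matrix, sig, seed = config$seed))
  red <- collect(reduce_signature(cnt$matrix, sig, sc$scores))
  kept <- red$stats$gene[red$stats$kept]
  recall <- if (length(cnt$truth$informative_genes) > 0) {
    mean(cnt$truth$informative_genes %in% kept)
  } else NA_real_
  null_genes <- setdiff(cnt$truth$signature_genes,
                        cnt$truth$informative_genes)
  false_keep <- if (length(null_genes) > 0) {
    mean(null_genes %in% kept)
  } else NA_real_
  sig_kappa <- if (length(kept) > 0 &&
                   length(cnt$truth$informative_genes) > 0) {
    kappa_score(kept, cnt$truth$informative_genes,
                cnt$truth$signature_genes)
  } else NA_real_
  signature <- list(scores = sc, reduction = red, recall = recall,
                    false_keep = false_keep, kappa_vs_truth = sig_kappa)

  # --- stage 4: survival risk stratification ------------------------------
  sv <- sim_survival(config)
  risk <- collect(risk_pipeline(sv$expression, sv$survival,
                                seed = config$seed))
  survival_stage <- list(
    risk = risk,
    degenerate = risk$model$degenerate,
    test_logrank_p = if (!is.null(risk$eval_test))
      risk$eval_test$logrank_p else NA_real_,
    test_hr = if (!is.null(risk$eval_test)) risk$eval_test$hr else NA_real_)

  # --- stage 5: HTO refinement + limiting dilution ------------------------
  hto <- sim_hto(config)
  refined <- collect(refine_hto(hto$embedding, hto$labels))
  hto_acc <- mean((refined$labels == hto$truth)[
    hto$truth != "Background"])
  lda_tab <- sim_lda(config)
  lda_est <- collect(estimate_frequency(lda_tab))
  covered <- lda_est$status == "ok" &&
    lda_est$lower <= config$lda_frequency &&
    lda_est$upper >= config$lda_frequency
  auxiliary <- list(hto = refined, hto_accuracy = hto_acc,
                    lda = lda_est, lda_ci_covers_truth = covered)

  metrics <- data.frame(
    stage = c("genotyping", "monosomy", "signature_recall",
              "signature_false_keep", "survival_test_logrank_p",
              "hto_label_accuracy", "lda_frequency"),
    value = c(geno_acc, mono_acc, recall, false_keep,
              survival_stage$test_logrank_p, hto_acc,
              lda_est$frequency))

  manifest <- list(
    config_hash = rlang::hash(unclass(config)),
    seed = config$seed,
    package_version = as.character(utils::packageVersion("amltk")),
    warnings = warnings_seen)

  structure(list(genotyping = genotyping, monosomy = monosomy,
                 signature = signature, survival = survival_stage,
                 auxiliary = auxiliary, metrics = metrics,
                 manifest = manifest),
            class = "pipeline_bundle")
}

#' @export
#' @method print pipeline_bundle
print.pipeline_bundle <- function(x, ...) {
  cat("pipeline_bundle (config", substr(x$manifest$config_hash, 1, 8),
      ", seed", x$manifest$seed, ")\n")
  print(x$metrics, row.names = FALSE)
  invisible(x)
}
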