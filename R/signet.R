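# Signature scoring, positivity, item-test reduction to informative genes,
# and the marker/DE gating rules.

#' Define a directional gene signature
#'
#' @param name Signature name.
#' @param genes Ordered character vector of unique gene ids.
#' @param direction \code{"up"} or \code{"down"}.
#' @return List of class \code{"signature_definition"}.
#' @export
signature_definition <- function(name, genes, direction = c("up", "down")) {
  direction <- match.arg(direction)
  genes <- as.character(genes)
  if (length(genes) == 0) stop("signature must contain genes", call. = FALSE)
  if (anyDuplicated(genes) > 0) {
    stop("signature genes must be unique", call. = FALSE)
  }
  structure(list(name = name, genes = genes, direction = direction),
            class = "signature_definition")
}

as_signature <- function(x, name = "signature") {
  if (inherits(x, "signature_definition")) x
  else signature_definition(name, x)
}

#' Score a signature and call per-cell positivity
#'
#' Scoring delegates to \code{\link{module_score}}; a cell is positive when
#' its score is strictly greater than 0 (e.g. "percent of cells with
#' 126High score > 0"). If \code{samples} is given, percent-positive is also
#' summarized per sample.
#'
#' @param x A \code{\link{count_matrix}} or genes x cells matrix.
#' @param signature A \code{\link{signature_definition}} or gene id vector.
#' @param samples Optional per-cell sample labels (defaults to the
#'   \code{sample} metadata column of a \code{count_matrix}).
#' @param ... Passed to \code{\link{module_score}}.
#' @return List with \code{scores} (a \code{score_vector}),
#'   \code{positive} (named logical), \code{pct_positive} (overall percent)
#'   and \code{pct_positive_by_sample} (or NULL).
#' @export
score_signature <- function(x, signature, samples = NULL, ...) {
  sig <- as_signature(signature)
  if (is.null(samples) && inherits(x, "count_matrix") &&
      !is.null(x$cell_meta$sample)) {
    samples <- setNames(x$cell_meta$sample, x$cell_ids)
  }
  sc <- module_score(x, sig$genes, ...)
  positive <- sc$score > 0
  by_sample <- NULL
  if (!is.null(samples)) {
    samples <- samples[names(sc$score)]
    by_sample <- 100 * tapply(positive, samples, mean)
  }
  list(scores = sc, positive = positive,
       pct_positive = 100 * mean(positive),
       pct_positive_by_sample = by_sample)
}

# Spearman correlation with p-value: t approximation for n > 30, exact
# (permutation-distribution) p below; ties use average ranks.
spearman_test <- function(x, y, exact_max_n = 30L) {
  n <- length(x)
  rho <- suppressWarnings(cor(x, y, method = "spearman"))
  if (is.na(rho)) return(c(rho = NA_real_, p = NA_real_))
  if (n <= exact_max_n) {
    p <- suppressWarnings(
      cor.test(x, y, method = "spearman", exact = TRUE)$p.value)
  } else {
    tt <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- 2 * pt(-abs(tt), df = n - 2)
  }
  c(rho = rho, p = min(p, 1))
}

#' Item-test reduction of a signature to its informative genes
#'
#' For every signature gene, computes the Spearman correlation between the
#' gene's expression (z-scored values; rank-based, so any per-gene monotone
#' scaling gives the same result) and the module score of the full signature
#' across cells. Genes with a positive, non-negligible (\code{rho >
#' rho_min}) and significant (Bonferroni-corrected p < \code{alpha})
#' correlation are retained; the Bonferroni factor is the full length of the
#' supplied signature.
#'
#' @param x A \code{\link{count_matrix}} or genes x cells matrix.
#' @param signature A \code{\link{signature_definition}} or gene id vector.
#' @param scores A \code{\link{module_score}} result or per-cell numeric
#'   vector computed on the same cells.
#' @param rho_min Correlation threshold (strict; default 0.3).
#' @param alpha Family-wise significance level (default 0.05).
#' @return List of class \code{"reduction_result"}: \code{stats} (per-gene
#'   data frame: \code{gene}, \code{rho}, \code{p}, \code{p_adj},
#'   \code{kept}, \code{reason}) and \code{reduced} (a
#'   \code{signature_definition} of the kept genes).
#' @export
reduce_signature <- function(x, signature, scores, rho_min = 0.3,
                             alpha = 0.05) {
  sig <- as_signature(signature)
  m <- as_gene_matrix(x)
  s <- if (inherits(scores, "score_vector")) scores$score else scores
  if (ncol(m) != length(s)) {
    stop("scores must be computed on the same cells as the matrix",
         call. = FALSE)
  }
  if (ncol(m) < 10) {
    stop("at least 10 cells are required for item-test reduction",
         call. = FALSE)
  }
  n_sig <- length(sig$genes)
  stats <- data.frame(gene = sig$genes, rho = NA_real_, p = NA_real_,
                      p_adj = NA_real_, kept = FALSE, reason = "",
                      stringsAsFactors = FALSE)
  present <- sig$genes %in% rownames(m)
  stats$reason[!present] <- "absent"
  for (i in which(present)) {
    g <- as.numeric(m[sig$genes[i], ])
    if (sd(g) == 0) { stats$reason[i] <- "zero_variance"; next }
    st <- spearman_test(g, s)
    stats$rho[i] <- st[["rho"]]
    stats$p[i] <- st[["p"]]
    stats$p_adj[i] <- min(1, st[["p"]] * n_sig)
    # alpha >= 1 disables the significance gate (p_adj is capped at 1)
    stats$kept[i] <- is.finite(st[["rho"]]) && st[["rho"]] > rho_min &&
      (stats$p_adj[i] < alpha || alpha >= 1)
  }
  reduced_genes <- stats$gene[stats$kept]
  reduced <- if (length(reduced_genes) > 0) {
    signature_definition(paste0(sig$name, "_reduced"), reduced_genes,
                         sig$direction)
  } else NULL
  structure(list(stats = stats, reduced = reduced,
                 params = list(rho_min = rho_min, alpha = alpha,
                               n_signature_genes = n_sig)),
            class = "reduction_result")
}

#' @export
#' @method print reduction_result
print.reduction_result <- function(x, ...) {
  cat(sprintf(
    "reduction_result: %d / %d genes kept (rho > %.2f, Bonferroni p < %.2f)\n",
    sum(x$stats$kept), nrow(x$stats), x$params$rho_min, x$params$alpha))
  invisible(x)
}

# Empirically locate the correlation threshold of the item-test reduction:
# construct genes whose rank correlation with a fixed score vector spans a
# coarse 0.05..0.60 grid plus a dense band around the retention boundary,
# run reduce_signature (large n, so the Bonferroni p gate always passes near
# the boundary) and return the midpoint between the largest dropped and
# smallest kept empirical correlation.
rho_threshold_sweep <- function(seed = 1L, n_cells = 10000L,
                                targets = c(seq(0.05, 0.60, by = 0.05),
                                            seq(0.25, 0.35, by = 0.0025))) {
  with_seed(seed, {
    s <- rnorm(n_cells)
    z <- as.numeric(scale(s))
    m <- t(vapply(targets, function(r) {
      r * z + sqrt(1 - r^2) * rnorm(n_cells)
    }, numeric(n_cells)))
    rownames(m) <- sprintf("G%03d", seq_along(targets))
    colnames(m) <- sprintf("C%05d", seq_len(n_cells))
    red <- reduce_signature(m, rownames(m), s)
    kept <- red$stats$kept
    (max(red$stats$rho[!kept]) + min(red$stats$rho[kept])) / 2
  })
}

#' Filter a differential-expression table to marker genes
#'
#' Keeps genes with \code{|logFC| >= logfc_min}, expressed in more than
#' \code{pct_min} of the cells of at least one of the two compared groups,
#' and Wilcoxon p-value below \code{p_max}.
#'
#' @param de_table Data frame with columns \code{gene}, \code{logFC},
#'   \code{pct_in}, \code{pct_out}, \code{p}.
#' @param logfc_min Absolute log-fold-change threshold (default 0.25).
#' @param pct_min Minimum expressing fraction, strict (default 0.25).
#' @param p_max P-value bound, strict (default 1e-5).
#' @return Character vector of marker gene ids.
#' @export
filter_markers <- function(de_table, logfc_min = 0.25, pct_min = 0.25,
                           p_max = 1e-5) {
  stop_if_missing_cols(de_table, c("gene", "logFC", "pct_in", "pct_out", "p"),
                       "DE table")
  if (nrow(de_table) == 0) return(character(0))
  keep <- abs(de_table$logFC) >= logfc_min &
    pmax(de_table$pct_in, de_table$pct_out) > pct_min &
    de_table$p < p_max
  de_table$gene[keep]
}

#' Is an intra-cluster group comparison eligible?
#'
#' A differential-expression comparison between two cell groups is eligible
#' only if both groups contain at least \code{min_cells} cells.
#'
#' @param n_group_a,n_group_b Cell counts of the two groups.
#' @param min_cells Minimum per-group size (default 5).
#' @return Logical.
#' @export
eligible_comparison <- function(n_group_a, n_group_b, min_cells = 5L) {
  n_group_a >= min_cells & n_group_b >= min_cells
}
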