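# NPM1 Mutation Finder: motif matching, UMI collapsing, per-cell genotyping
# and sequential cluster-based leukemia assignment.
#
# The type-A mutation is a TCTG tandem duplication at chr5:171410540-171410543
# near the 3' end of NPM1, directly visible in 3' scRNA-seq reads. Because
# the duplication can sit at a read boundary, the motif set contains, besides
# the core duplication motif, every informative suffix/prefix truncation.

#' Default NPM1 type-A mutation locus (1-based inclusive, chr5)
#' @export
npm1_locus <- function() c(start = 171410540L, end = 171410543L)

#' Mutant-allele motif set for the NPM1 type-A duplication
#'
#' Ten motifs: one unanchored core motif, four suffix-anchored motifs (the
#' read must end with the motif) and five prefix-anchored motifs (the read
#' must begin with the motif), capturing duplication evidence truncated at
#' either read boundary.
#'
#' @param locus 1-based inclusive mutation interval, default
#'   \code{\link{npm1_locus}}.
#' @return List of class \code{"pattern_set"} with elements
#'   \code{unanchored}, \code{suffix_anchored}, \code{prefix_anchored},
#'   \code{locus}.
#' @export
npm1_patterns <- function(locus = npm1_locus()) {
  ps <- list(
    unanchored = "TCTCTGTCTGGC",
    suffix_anchored = c("GATCTCTGTCTGG", "GATCTCTGTCTG", "GATCTCTGTCT",
                        "GATCTCTGTC"),
    prefix_anchored = c("CTCTGTCTGGCAG", "TCTGTCTGGCAG", "CTGTCTGGCAG",
                        "TGTCTGGCAG", "GTCTGGCAG"),
    locus = locus
  )
  class(ps) <- "pattern_set"
  ps
}

# one-shot warning flag for non-ACGT characters, reset per R session
.npm1_env <- new.env(parent = emptyenv())

#' Does a read sequence support the mutant allele?
#'
#' TRUE iff any unanchored motif occurs anywhere in the sequence, any
#' suffix-anchored motif is a suffix, or any prefix-anchored motif is a
#' prefix. Matching is exact (no mismatches); characters outside A/C/G/T
#' never match and trigger a single warning per session.
#'
#' @param sequence Character vector of uppercase DNA sequences.
#' @param patterns A \code{\link{npm1_patterns}} set.
#' @return Logical vector, one element per sequence.
#' @export
match_read <- function(sequence, patterns = npm1_patterns()) {
  if (length(sequence) == 0) return(logical(0))
  if (any(grepl("[^ACGT]", sequence)) &&
      !isTRUE(.npm1_env$warned_non_acgt)) {
    warning("sequences contain non-ACGT characters; they never match")
    .npm1_env$warned_non_acgt <- TRUE
  }
  hit <- rep(FALSE, length(sequence))
  for (m in patterns$unanchored) {
    hit <- hit | grepl(m, sequence, fixed = TRUE)
  }
  for (m in patterns$suffix_anchored) {
    hit <- hit | endsWith(sequence, m)
  }
  for (m in patterns$prefix_anchored) {
    hit <- hit | startsWith(sequence, m)
  }
  hit
}

#' Collapse reads into per-molecule (UMI) allele calls
#'
#' One call per distinct (cell barcode, UMI) pair. A molecule is \code{MUT}
#' if any of its reads matches a mutant motif ("a single mutant transcript is
#' enough"); otherwise \code{WT} if at least one read's aligned interval
#' fully contains the mutation locus (absence of the duplication is then
#' informative); otherwise \code{uninformative}.
#'
#' @param reads Data frame of read records (see \code{\link{read_reads}}).
#' @param patterns A \code{\link{npm1_patterns}} set (carries the locus).
#' @return Data frame with columns \code{cell_barcode}, \code{umi},
#'   \code{allele} (\code{MUT}/\code{WT}/\code{uninformative}),
#'   \code{n_reads}.
#' @export
collapse_molecules <- function(reads, patterns = npm1_patterns()) {
  stop_if_missing_cols(reads, c("cell_barcode", "umi", "ref_start",
                                "ref_end", "sequence"), "read table")
  if (nrow(reads) == 0) {
    return(data.frame(cell_barcode = character(), umi = character(),
                      allele = character(), n_reads = integer(),
                      stringsAsFactors = FALSE))
  }
  loc <- patterns$locus
  mut_hit <- match_read(reads$sequence, patterns)
  contains <- reads$ref_start <= loc[["start"]] &
    reads$ref_end >= loc[["end"]]
  key <- paste(reads$cell_barcode, reads$umi, sep = "\r")
  any_mut <- tapply(mut_hit, key, any)
  any_contain <- tapply(contains, key, any)
  n_reads <- tapply(mut_hit, key, length)
  keys <- names(any_mut)
  split_keys <- strsplit(keys, "\r", fixed = TRUE)
  allele <- ifelse(any_mut, "MUT",
                   ifelse(any_contain[keys], "WT", "uninformative"))
  out <- data.frame(
    cell_barcode = vapply(split_keys, `[[`, character(1), 1),
    umi = vapply(split_keys, `[[`, character(1), 2),
    allele = as.character(allele),
    n_reads = as.integer(n_reads),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out[order(out$cell_barcode, out$umi), , drop = FALSE]
}

#' Coverage over the mutation locus, per cell
#'
#' A cell has coverage if any of its reads overlaps the locus interval by at
#' least one base.
#'
#' @param reads Data frame of read records.
#' @param cells Character vector of all cell barcodes to report (cells
#'   without reads get \code{FALSE}).
#' @param locus 1-based inclusive interval.
#' @return Named logical vector over \code{cells}.
#' @export
locus_coverage <- function(reads, cells = NULL, locus = npm1_locus()) {
  overlaps <- reads$ref_start <= locus[["end"]] &
    reads$ref_end >= locus[["start"]]
  covered <- unique(reads$cell_barcode[overlaps])
  if (is.null(cells)) cells <- unique(reads$cell_barcode)
  setNames(cells %in% covered, cells)
}

#' Genotype cells from molecule calls
#'
#' Classification: \code{MUT} if at least 1 mutant UMI; \code{WT} if no
#' mutant UMI and more than 5 wild-type UMIs; \code{ND} (not detected) if no
#' mutant UMI, at most 5 wild-type UMIs and coverage over the mutation
#' region; \code{NoCall} if the cell has no coverage over the region.
#'
#' @param molecules Data frame from \code{\link{collapse_molecules}}.
#' @param coverage Named logical vector per cell (from
#'   \code{\link{locus_coverage}}); its names define the cell universe.
#' @param wt_min Wild-type UMI count that must be exceeded for a WT call
#'   (default 5).
#' @return Data frame with columns \code{cell_barcode}, \code{n_mut_umi},
#'   \code{n_wt_umi}, \code{has_coverage}, \code{call}.
#' @export
genotype_cells <- function(molecules, coverage, wt_min = 5L) {
  stopifnot(is.logical(coverage), !is.null(names(coverage)))
  cells <- names(coverage)
  bad <- setdiff(unique(molecules$cell_barcode), cells)
  if (length(bad) > 0) {
    stop("cells with molecules but missing from coverage vector: ",
         paste(head(bad, 3), collapse = ", "), call. = FALSE)
  }
  informative <- molecules$allele != "uninformative"
  n_mut <- table(factor(molecules$cell_barcode[molecules$allele == "MUT"],
                        levels = cells))
  n_wt <- table(factor(molecules$cell_barcode[molecules$allele == "WT"],
                       levels = cells))
  n_mut <- as.integer(n_mut)
  n_wt <- as.integer(n_wt)
  has_mol <- cells %in% molecules$cell_barcode[informative]
  if (any(has_mol & !coverage)) {
    stop("internal inconsistency: cell has classified molecules but no ",
         "coverage over the mutation region", call. = FALSE)
  }
  call <- ifelse(!coverage, "NoCall",
          ifelse(n_mut >= 1L, "MUT",
          ifelse(n_wt > wt_min, "WT", "ND")))
  data.frame(cell_barcode = cells, n_mut_umi = n_mut, n_wt_umi = n_wt,
             has_coverage = unname(coverage), call = unname(call),
             stringsAsFactors = FALSE)
}

#' Sequential cluster-based leukemia assignment
#'
#' Evaluates, strictly in order, the five criteria on each cluster's
#' genotype-class fractions (computed over all cells of the cluster):
#' \enumerate{
#'   \item MUT >= 40\%: extend the AML definition to the whole cluster.
#'   \item 20\% <= MUT < 40\% and WT < 5\%: extend to the whole cluster.
#'   \item 10\% <= MUT < 20\% and WT < 5\%: extend to the whole cluster if
#'     the cluster is myeloid and the majority of cells are NoCall.
#'   \item 5\% <= MUT < 10\% and WT = 0\%: extend to the whole cluster if
#'     the cluster is myeloid and the majority of cells are NoCall.
#'   \item MUT < 5\%: only MUT cells are AML.
#' }
#' Whole-cluster extension marks every non-WT cell as AML; WT cells are
#' always excluded. Configurations matching no criterion (e.g. MUT 25\%, WT
#' 6\%) conservatively fall back to criterion-5 behavior (only MUT cells are
#' AML).
#'
#' @param genotypes Data frame from \code{\link{genotype_cells}}.
#' @param clusters Named character vector: cluster label per cell barcode.
#' @param myeloid Named logical vector: myeloid flag per cluster (from user
#'   annotation or \code{\link{myeloid_flag}}); clusters absent from it are
#'   treated as non-myeloid.
#' @return List with \code{clusters} (one row per cluster: fractions,
#'   \code{criterion_fired}, \code{whole_cluster}, \code{n_aml}) and
#'   \code{aml} (named logical per cell).
#' @export
assign_clusters <- function(genotypes, clusters, myeloid = NULL) {
  stopifnot(!is.null(names(clusters)))
  miss <- setdiff(genotypes$cell_barcode, names(clusters))
  if (length(miss) > 0) {
    stop("cells without a cluster label: ",
         paste(head(miss, 3), collapse = ", "), call. = FALSE)
  }
  cl <- clusters[genotypes$cell_barcode]
  aml <- setNames(rep(FALSE, nrow(genotypes)), genotypes$cell_barcode)
  rows <- list()
  for (k in unique(cl)) {
    idx <- which(cl == k)
    n <- length(idx)
    if (n == 0) { warning("empty cluster skipped: ", k); next }
    calls <- genotypes$call[idx]
    f <- c(MUT = mean(calls == "MUT"), WT = mean(calls == "WT"),
           ND = mean(calls == "ND"), NoCall = mean(calls == "NoCall"))
    myl <- isTRUE(myeloid[[k]])
    majority_nocall <- f[["NoCall"]] > 0.5
    crit <- if (f[["MUT"]] >= 0.40) 1L
      else if (f[["MUT"]] >= 0.20 && f[["WT"]] < 0.05) 2L
      else if (f[["MUT"]] >= 0.10 && f[["WT"]] < 0.05 && myl &&
               majority_nocall) 3L
      else if (f[["MUT"]] >= 0.05 && f[["MUT"]] < 0.10 && f[["WT"]] == 0 &&
               myl && majority_nocall) 4L
      else 5L # includes the rule gap (e.g. MUT 25%, WT >= 5%): MUT cells only
    whole <- crit <= 4L
    if (whole) {
      aml[idx[calls != "WT"]] <- TRUE
    } else {
      aml[idx[calls == "MUT"]] <- TRUE
    }
    rows[[k]] <- data.frame(
      cluster = k, n = n, frac_mut = f[["MUT"]], frac_wt = f[["WT"]],
      frac_nd = f[["ND"]], frac_nocall = f[["NoCall"]], myeloid = myl,
      criterion_fired = crit, whole_cluster = whole,
      n_aml = sum(aml[idx]), stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  list(clusters = out, aml = aml)
}

#' Myeloid flag per cluster from a marker module score
#'
#' Convenience helper: scores a myeloid marker gene list with
#' \code{\link{module_score}} and flags a cluster myeloid when the mean
#' score of its cells is above 0. The flag can equally be supplied from
#' manual annotation.
#'
#' @param cm A \code{\link{count_matrix}} with a \code{cluster} metadata
#'   column.
#' @param marker_genes Character vector of myeloid marker gene ids.
#' @param ... Passed to \code{\link{module_score}}.
#' @return Named logical vector per cluster.
#' @export
myeloid_flag <- function(cm, marker_genes, ...) {
  stopifnot(inherits(cm, "count_matrix"), !is.null(cm$cell_meta$cluster))
  sc <- module_score(cm, marker_genes, ...)
  means <- tapply(sc$score, cm$cell_meta$cluster, mean)
  setNames(as.vector(means) > 0, names(means))
}
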