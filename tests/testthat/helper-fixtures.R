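# Shared fixture builders; everything is generated in code.

# Independent per-motif regex oracle for mutant-pattern matching: each motif
# tested on its own with explicit regex anchoring.
oracle_match <- function(sequences, patterns = npm1_patterns()) {
  hit <- rep(FALSE, length(sequences))
  for (m in patterns$unanchored) {
    hit <- hit | grepl(m, sequences)
  }
  for (m in patterns$suffix_anchored) {
    hit <- hit | grepl(paste0(m, "$"), sequences)
  }
  for (m in patterns$prefix_anchored) {
    hit <- hit | grepl(paste0("^", m), sequences)
  }
  hit
}

# Tiny deterministic count matrix with named genes/cells.
toy_counts <- function(n_genes = 20, n_cells = 12, seed = 1, constant = NULL) {
  withr_seed <- function(expr) { set.seed(seed); expr }
  m <- if (is.null(constant)) {
    withr_seed(matrix(rpois(n_genes * n_cells, 5), nrow = n_genes))
  } else {
    matrix(constant, nrow = n_genes, ncol = n_cells)
  }
  dimnames(m) <- list(sprintf("G%02d", seq_len(n_genes)),
                      sprintf("CELL%03d", seq_len(n_cells)))
  m
}

# One read record row.
read_row <- function(cell, umi, start, end, seq) {
  data.frame(cell_barcode = cell, umi = umi, ref_start = start,
             ref_end = end, sequence = seq, stringsAsFactors = FALSE)
}

# Genotype table with prescribed class composition for one cluster.
geno_fixture <- function(n_mut, n_wt, n_nd, n_nocall, cluster = "K1") {
  n <- n_mut + n_wt + n_nd + n_nocall
  cells <- sprintf("%s-CELL%03d", cluster, seq_len(n))
  call <- rep(c("MUT", "WT", "ND", "NoCall"),
              times = c(n_mut, n_wt, n_nd, n_nocall))
  geno <- data.frame(
    cell_barcode = cells,
    n_mut_umi = ifelse(call == "MUT", 1L, 0L),
    n_wt_umi = ifelse(call == "WT", 6L, ifelse(call == "ND", 1L, 0L)),
    has_coverage = call != "NoCall",
    call = call, stringsAsFactors = FALSE)
  list(genotypes = geno, clusters = setNames(rep(cluster, n), cells))
}
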