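test_that("the default motif set holds the ten published patterns", {
  ps <- npm1_patterns()
  expect_length(c(ps$unanchored, ps$suffix_anchored, ps$prefix_anchored), 10)
  expect_true(all(grepl("^[ACGT]+$",
                        c(ps$unanchored, ps$suffix_anchored,
                          ps$prefix_anchored))))
  expect_equal(unname(ps$locus), c(171410540L, 171410543L))
})

test_that("match_read detects internal, suffix- and prefix-truncated motifs", {
  expect_true(match_read("AGGATCTCTGTCTGGCAGTG"))  # internal duplication
  expect_true(match_read("AGGATCTCTGTC"))          # read ends mid-duplication
  expect_true(match_read("GTCTGGCAGTTT"))          # read starts mid-duplication
  expect_false(match_read("AGGATCTCTGGCAGTG"))     # wild-type core
  # anchoring matters: the suffix motif inside a longer read must not match
  expect_false(match_read("AGGATCTCTGTCAAAAAA"))
  expect_false(match_read("AAAGTCTGGCAGTTT"))
})

test_that("match_read agrees with an independent per-motif regex oracle", {
  set.seed(42)
  n <- 2000
  lens <- sample(8:150, n, replace = TRUE)
  seqs <- vapply(lens, function(l)
    paste0(sample(c("A", "C", "G", "T"), l, replace = TRUE), collapse = ""),
    character(1))
  # enrich with motif-bearing sequences so both branches are exercised
  ps <- npm1_patterns()
  motifs <- c(ps$unanchored, ps$suffix_anchored, ps$prefix_anchored)
  planted <- vapply(seq_len(500), function(i) {
    m <- sample(motifs, 1)
    pre <- paste0(sample(c("A", "C", "G", "T"), sample(0:20, 1),
                         replace = TRUE), collapse = "")
    post <- paste0(sample(c("A", "C", "G", "T"), sample(0:20, 1),
                          replace = TRUE), collapse = "")
    paste0(pre, m, post)
  }, character(1))
  all_seqs <- c(seqs, planted)
  expect_identical(match_read(all_seqs), oracle_match(all_seqs))
})

test_that("non-ACGT characters never match and warn once", {
  assign("warned_non_acgt", FALSE, envir = amltk:::.npm1_env)
  expect_warning(r1 <- match_read("NNNNNNNNNNNNNN"), "non-ACGT")
  expect_false(r1)
  expect_silent(match_read("NNNNNNNNNNNNNN")) # second call: no new warning
  assign("warned_non_acgt", FALSE, envir = amltk:::.npm1_env)
})

test_that("UMI collapsing follows single-mutant-transcript and containment rules", {
  loc <- npm1_locus()
  reads <- rbind(
    # UMI m1: one mutant-matching read + one plain read -> MUT
    read_row("A", "m1", 171410500, 171410559, "AGGATCTCTGTCTGGCAGTG"),
    read_row("A", "m1", 171410500, 171410519, "ACGTACGTACGTACGTACGT"),
    # UMI w1: spans the locus without the duplication -> WT
    read_row("A", "w1", 171410500, 171410600, "ACGTACGTACGTACGTACGT"),
    # UMI u1: ends inside the locus (partial overlap) -> uninformative
    read_row("A", "u1", 171410500, 171410541, "ACGTACGTACGTACGTACGT"))
  mol <- collapse_molecules(reads)
  expect_equal(nrow(mol), 3)
  got <- setNames(mol$allele, mol$umi)
  expect_equal(got[["m1"]], "MUT")
  expect_equal(got[["w1"]], "WT")
  expect_equal(got[["u1"]], "uninformative")
  # containment boundary: interval touching only the locus start
  r <- read_row("B", "x", loc[["start"]] - 10, loc[["start"]],
                "ACGTACGTACG")
  expect_equal(collapse_molecules(r)$allele, "uninformative")
})

test_that("cell genotype classes implement the UMI-count rules", {
  mk <- function(n_mut, n_wt) {
    rows <- list()
    if (n_mut > 0) rows <- c(rows, lapply(seq_len(n_mut), function(i)
      data.frame(cell_barcode = "A", umi = paste0("m", i), allele = "MUT",
                 n_reads = 1L)))
    if (n_wt > 0) rows <- c(rows, lapply(seq_len(n_wt), function(i)
      data.frame(cell_barcode = "A", umi = paste0("w", i), allele = "WT",
                 n_reads = 1L)))
    do.call(rbind, rows)
  }
  cov <- c(A = TRUE)
  expect_equal(genotype_cells(mk(1, 10), cov)$call, "MUT")
  expect_equal(genotype_cells(mk(0, 6), cov)$call, "WT")
  expect_equal(genotype_cells(mk(0, 5), cov)$call, "ND")
  empty <- data.frame(cell_barcode = character(), umi = character(),
                      allele = character(), n_reads = integer())
  g <- genotype_cells(empty, c(A = FALSE))
  expect_equal(g$call, "NoCall")
  # molecules without coverage are an internal inconsistency
  expect_error(genotype_cells(mk(1, 0), c(A = FALSE)), "inconsistency")
})

test_that("genotype classes partition every cell exactly once", {
  cfg <- synth_config(seed = 21, n_cells = 300)
  rd <- sim_reads(cfg)
  mol <- collapse_molecules(rd$reads)
  cov <- locus_coverage(rd$reads, cells = rd$truth$cell_barcode)
  g <- genotype_cells(mol, cov)
  expect_equal(nrow(g), cfg$n_cells)
  expect_true(all(g$call %in% c("MUT", "WT", "ND", "NoCall")))
  expect_equal(anyDuplicated(g$cell_barcode), 0)
  # every cell with a planted, motif-visible mutant molecule is called MUT
  mut_called <- g$cell_barcode[g$call == "MUT"]
  mut_mol_cells <- unique(mol$cell_barcode[mol$allele == "MUT"])
  expect_setequal(mut_called, mut_mol_cells)
})

test_that("adding evidence is monotone for MUT calls", {
  base <- data.frame(cell_barcode = "A", umi = "w1", allele = "WT",
                     n_reads = 1L)
  mut <- data.frame(cell_barcode = "A", umi = "m1", allele = "MUT",
                    n_reads = 1L)
  cov <- c(A = TRUE)
  expect_equal(genotype_cells(rbind(base, mut), cov)$call, "MUT")
  # extra WT molecules never revert a MUT call
  more_wt <- do.call(rbind, lapply(1:20, function(i)
    data.frame(cell_barcode = "A", umi = paste0("w", i), allele = "WT",
               n_reads = 1L)))
  expect_equal(genotype_cells(rbind(more_wt, mut), cov)$call, "MUT")
})

test_that("sequential cluster criteria fire in order with WT exclusion", {
  # criterion 1: 40 MUT / 10 WT / 50 NoCall -> whole cluster, 90 AML
  fx <- geno_fixture(40, 10, 0, 50)
  out <- assign_clusters(fx$genotypes, fx$clusters)
  expect_equal(out$clusters$criterion_fired, 1L)
  expect_true(out$clusters$whole_cluster)
  expect_equal(sum(out$aml), 90)
  expect_true(all(!out$aml[fx$genotypes$cell_barcode[
    fx$genotypes$call == "WT"]]))

  # rule gap: 25% MUT, 5% WT -> criteria 1-4 fail, criterion-5 behavior
  fx <- geno_fixture(25, 5, 0, 70)
  out <- assign_clusters(fx$genotypes, fx$clusters)
  expect_equal(out$clusters$criterion_fired, 5L)
  expect_false(out$clusters$whole_cluster)
  expect_equal(sum(out$aml), 25)

  # criterion 4 needs myeloid + majority NoCall + WT = 0
  fx <- geno_fixture(7, 0, 33, 60)
  out <- assign_clusters(fx$genotypes, fx$clusters,
                         myeloid = c(K1 = TRUE))
  expect_equal(out$clusters$criterion_fired, 4L)
  expect_equal(sum(out$aml), 100)
  out_nm <- assign_clusters(fx$genotypes, fx$clusters,
                            myeloid = c(K1 = FALSE))
  expect_equal(out_nm$clusters$criterion_fired, 5L)
  expect_equal(sum(out_nm$aml), 7)

  # criterion 5: 2% MUT, 30% WT -> only MUT cells
  fx <- geno_fixture(2, 30, 28, 40)
  out <- assign_clusters(fx$genotypes, fx$clusters)
  expect_equal(out$clusters$criterion_fired, 5L)
  expect_equal(sum(out$aml), 2)

  # criterion 3: 15% MUT, 0% WT, 60% NoCall, myeloid
  fx <- geno_fixture(15, 0, 25, 60)
  out <- assign_clusters(fx$genotypes, fx$clusters,
                         myeloid = c(K1 = TRUE))
  expect_equal(out$clusters$criterion_fired, 3L)
  expect_equal(sum(out$aml), 100)
})

test_that("cells lacking a cluster label are rejected", {
  fx <- geno_fixture(5, 0, 0, 5)
  expect_error(assign_clusters(fx$genotypes, fx$clusters[-1]),
               "without a cluster")
})
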