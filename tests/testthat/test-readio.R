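test_that("read tables round-trip through TSV", {
  cfg <- synth_config(seed = 9, n_cells = 60)
  rd <- sim_reads(cfg)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_read_table(rd$reads, path)
  back <- read_reads(path)
  expect_equal(back$records, rd$reads)
  expect_equal(back$n_skipped, 0L)
})

test_that("empty read files give an empty stream with zero skips", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(character(0), path)
  out <- read_reads(path)
  expect_equal(nrow(out$records), 0)
  expect_equal(out$n_skipped, 0L)
})

test_that("records missing barcode or UMI are counted and skipped", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("cell_barcode\tumi\tref_start\tref_end\tsequence",
               "CELLA\tUMI1\t10\t20\tACGTACGTACG",
               "CELLB\t\t10\t20\tACGTACGTACG"), path)
  out <- read_reads(path)
  expect_equal(nrow(out$records), 1)
  expect_equal(out$n_skipped, 1L)
})

test_that("unparsable lines error with their line number", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("cell_barcode\tumi\tref_start\tref_end\tsequence",
               "CELLA\tUMI1\t10\t20\tACGT",
               "CELLB\tUMI2\tten\t20\tACGT"), path)
  expect_error(read_reads(path), "line 3")
  writeLines(c("cell_barcode\tumi\tref_start\tref_end\tsequence",
               "CELLA\tUMI1\t10"), path)
  expect_error(read_reads(path), "line 2")
})

test_that("SAM records carry CB/UB tags and CIGAR-derived intervals", {
  skip_if_not_installed("Rsamtools")
  sam <- withr::local_tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6\tSO:unsorted",
    "@SQ\tSN:chr5\tLN:181538259",
    paste("r1", "0", "chr5", "171410500", "60", "20M", "*", "0", "0",
          "ACGTACGTACGTACGTACGT", "*", "CB:Z:CELLA", "UB:Z:UMI1",
          sep = "\t"),
    paste("r2", "0", "chr5", "171410520", "60", "10M5D10M", "*", "0", "0",
          "ACGTACGTACGTACGTACGT", "*", "CB:Z:CELLA", "UB:Z:UMI2",
          sep = "\t"),
    paste("r3", "0", "chr5", "171410530", "60", "20M", "*", "0", "0",
          "ACGTACGTACGTACGTACGT", "*", "CB:Z:CELLB",
          sep = "\t")), sam)
  out <- read_reads(sam, format = "sam")
  expect_equal(nrow(out$records), 2)
  expect_equal(out$n_skipped, 1L) # r3 has no UMI tag
  expect_equal(out$records$ref_start, c(171410500L, 171410520L))
  # 10M5D10M consumes 25 reference bases
  expect_equal(out$records$ref_end, c(171410519L, 171410544L))
})

test_that("count matrices round-trip through MatrixMarket", {
  m <- Matrix::sparseMatrix(i = c(1, 2), j = c(1, 2), x = c(3, 4),
                            dims = c(2, 2),
                            dimnames = list(c("G1", "G2"), c("C1", "C2")))
  cm <- count_matrix(m, cell_meta = data.frame(cluster = c("K1", "K2"),
                                               row.names = c("C1", "C2")))
  dir <- withr::local_tempdir()
  write_mtx(cm, dir)
  back <- read_mtx(dir)
  expect_equal(as.matrix(back$counts), as.matrix(cm$counts))
  expect_equal(back$gene_ids, cm$gene_ids)
  expect_equal(back$cell_ids, cm$cell_ids)
  expect_equal(back$cell_meta$cluster, cm$cell_meta$cluster)
})

test_that("explicit zeros are dropped on write but values preserved", {
  m <- Matrix::sparseMatrix(i = c(1, 1, 2), j = c(1, 2, 2), x = c(5, 0, 7),
                            dims = c(2, 2),
                            dimnames = list(c("G1", "G2"), c("C1", "C2")))
  cm <- count_matrix(m)
  dir <- withr::local_tempdir()
  write_mtx(cm, dir)
  back <- read_mtx(dir)
  expect_equal(as.matrix(back$counts), as.matrix(Matrix::drop0(m)))
  expect_equal(length(back$counts@x), 2) # stored entries only
})

test_that("sidecar/matrix dimension mismatches error", {
  cfg <- synth_config(seed = 1, n_cells = 20, n_genes = 30,
                      n_chr7_genes = 5, n_signature_genes = 5,
                      n_informative = 2)
  cm <- sim_counts(cfg)$matrix
  dir <- withr::local_tempdir()
  write_mtx(cm, dir)
  writeLines(cm$cell_ids[-1], file.path(dir, "barcodes.tsv")) # truncate
  expect_error(read_mtx(dir), "barcodes")
})

test_that("gene lists deduplicate preserving first occurrence", {
  path <- withr::local_tempfile()
  writeLines(c("TSPAN13", "CD34", "TSPAN13", "NPM1"), path)
  expect_warning(genes <- read_gene_list(path), "duplicated")
  expect_equal(genes, c("TSPAN13", "CD34", "NPM1"))
})

test_that("survival tables are validated", {
  path <- withr::local_tempfile()
  writeLines(c("time\tevent", "5.5\t1", "-1\t0"), path)
  expect_error(read_survival(path), "non-negative")
  writeLines(c("time\tevent", "5.5\t2"), path)
  expect_error(read_survival(path), "event")
  writeLines(c("time\tevent", "5.5\t1", "3.2\t0"), path)
  df <- read_survival(path)
  expect_equal(df$event, c(1L, 0L))
})

test_that("random count matrices survive write-read fuzzing", {
  for (seed in 1:3) {
    set.seed(seed)
    g <- sample(3:15, 1); n <- sample(3:15, 1)
    m <- matrix(rpois(g * n, 2), nrow = g,
                dimnames = list(sprintf("G%d", 1:g), sprintf("C%d", 1:n)))
    cm <- count_matrix(m)
    dir <- withr::local_tempdir()
    write_mtx(cm, dir)
    expect_equal(as.matrix(read_mtx(dir)$counts), as.matrix(cm$counts))
  }
})
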