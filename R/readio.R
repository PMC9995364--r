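# Readers/writers for the plain-text formats the pipeline touches.
# Coordinates are 1-based inclusive throughout.

#' Construct a genes x cells count matrix container
#'
#' @param counts Sparse (\code{dgCMatrix}) or dense non-negative integer
#'   matrix, genes in rows, cells in columns, with dimnames.
#' @param cell_meta Optional data frame of per-cell metadata (e.g.
#'   \code{cluster}, \code{sample}, \code{timepoint}), rownames = cell ids.
#' @return An object of class \code{"count_matrix"}: list with
#'   \code{counts}, \code{gene_ids}, \code{cell_ids}, \code{cell_meta}.
#' @export
count_matrix <- function(counts, cell_meta = NULL) {
  if (is.matrix(counts)) {
    counts <- as(as(counts, "CsparseMatrix"), "generalMatrix")
  }
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must carry gene (row) and cell (column) names",
         call. = FALSE)
  }
  if (any(counts@x < 0)) stop("counts must be non-negative", call. = FALSE)
  if (!is.null(cell_meta)) {
    if (nrow(cell_meta) != ncol(counts)) {
      stop("cell_meta rows must match the number of cells", call. = FALSE)
    }
    if (!identical(rownames(cell_meta), colnames(counts))) {
      cell_meta <- cell_meta[colnames(counts), , drop = FALSE]
    }
  }
  structure(list(counts = Matrix::drop0(counts),
                 gene_ids = rownames(counts),
                 cell_ids = colnames(counts),
                 cell_meta = cell_meta),
            class = "count_matrix")
}

#' @export
#' @method print count_matrix
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d cells (%s metadata)\n",
              length(x$gene_ids), length(x$cell_ids),
              if (is.null(x$cell_meta)) "no"
              else paste(colnames(x$cell_meta), collapse = ", ")))
  invisible(x)
}

#' Write a read table as TSV
#'
#' Columns: \code{cell_barcode}, \code{umi}, \code{ref_start},
#' \code{ref_end} (1-based inclusive), \code{sequence}.
#'
#' @param reads Data frame of read records.
#' @param path Output file.
#' @export
write_read_table <- function(reads, path) {
  stop_if_missing_cols(reads, c("cell_barcode", "umi", "ref_start",
                                "ref_end", "sequence"), "read table")
  write.table(reads, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read barcoded reads from TSV or SAM/BAM
#'
#' For SAM/BAM input, cell barcode and UMI are taken from the conventional
#' \code{CB}/\code{UB} tags; the reference interval is derived from the
#' alignment position and CIGAR (reference-consuming operations). Reads
#' missing a barcode or UMI are counted and skipped.
#'
#' @param path Input file.
#' @param format One of \code{"tsv"}, \code{"sam"}, \code{"bam"}; default
#'   guessed from the file extension.
#' @return List with \code{records} (data frame of read records in file
#'   order) and \code{n_skipped}.
#' @export
read_reads <- function(path, format = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(format)) {
    format <- tolower(tools::file_ext(path))
    if (!format %in% c("tsv", "sam", "bam")) format <- "tsv"
  }
  format <- match.arg(format, c("tsv", "sam", "bam"))
  if (format == "tsv") read_reads_tsv(path) else read_reads_sam(path, format)
}

read_reads_tsv <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0) {
    return(list(records = empty_read_table(), n_skipped = 0L))
  }
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  need <- c("cell_barcode", "umi", "ref_start", "ref_end", "sequence")
  if (!all(need %in% header)) {
    stop("read table header must contain: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  body <- lines[-1]
  if (length(body) == 0) {
    return(list(records = empty_read_table(), n_skipped = 0L))
  }
  parts <- strsplit(body, "\t", fixed = TRUE)
  n_fields <- lengths(parts)
  bad <- which(n_fields != length(header))
  if (length(bad) > 0) {
    stop(sprintf("unparsable read record at line %d", bad[1] + 1L),
         call. = FALSE)
  }
  m <- do.call(rbind, parts)
  colnames(m) <- header
  rs <- suppressWarnings(as.integer(m[, "ref_start"]))
  re <- suppressWarnings(as.integer(m[, "ref_end"]))
  bad_num <- which(is.na(rs) | is.na(re))
  if (length(bad_num) > 0) {
    stop(sprintf("unparsable coordinates at line %d", bad_num[1] + 1L),
         call. = FALSE)
  }
  rec <- data.frame(cell_barcode = m[, "cell_barcode"], umi = m[, "umi"],
                    ref_start = rs, ref_end = re,
                    sequence = m[, "sequence"], stringsAsFactors = FALSE)
  keep <- nzchar(rec$cell_barcode) & nzchar(rec$umi) &
    !rec$cell_barcode %in% c("NA", "-") & !rec$umi %in% c("NA", "-")
  n_skipped <- sum(!keep)
  rec <- rec[keep, , drop = FALSE]
  if (any(rec$ref_start > rec$ref_end)) {
    stop("read record with ref_start > ref_end", call. = FALSE)
  }
  rownames(rec) <- NULL
  list(records = rec, n_skipped = as.integer(n_skipped))
}

read_reads_sam <- function(path, format) {
  if (!requireNamespace("Rsamtools", quietly = TRUE)) {
    stop("SAM/BAM input requires the Rsamtools package", call. = FALSE)
  }
  bam <- path
  if (format == "sam") {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  }
  res <- Rsamtools::scanBam(
    bam, param = Rsamtools::ScanBamParam(
      what = c("pos", "cigar", "seq"), tag = c("CB", "UB")))[[1]]
  n <- length(res$pos)
  if (n == 0) return(list(records = empty_read_table(), n_skipped = 0L))
  cb <- res$tag$CB
  ub <- res$tag$UB
  if (is.null(cb)) cb <- rep(NA_character_, n)
  if (is.null(ub)) ub <- rep(NA_character_, n)
  keep <- !is.na(cb) & !is.na(ub) & !is.na(res$pos)
  ref_width <- cigar_ref_width(res$cigar)
  rec <- data.frame(
    cell_barcode = cb, umi = ub, ref_start = res$pos,
    ref_end = res$pos + ref_width - 1L,
    sequence = as.character(res$seq), stringsAsFactors = FALSE
  )[keep, , drop = FALSE]
  rownames(rec) <- NULL
  list(records = rec, n_skipped = as.integer(sum(!keep)))
}

# Reference-space width of CIGAR strings (M, D, N, =, X consume reference).
cigar_ref_width <- function(cigar) {
  vapply(cigar, function(cg) {
    if (is.na(cg)) return(NA_integer_)
    lens <- as.integer(regmatches(cg, gregexpr("[0-9]+", cg))[[1]])
    ops <- regmatches(cg, gregexpr("[MIDNSHP=X]", cg))[[1]]
    as.integer(sum(lens[ops %in% c("M", "D", "N", "=", "X")]))
  }, integer(1), USE.NAMES = FALSE)
}

empty_read_table <- function() {
  data.frame(cell_barcode = character(), umi = character(),
             ref_start = integer(), ref_end = integer(),
             sequence = character(), stringsAsFactors = FALSE)
}

#' Write / read a count matrix in MatrixMarket triplet format
#'
#' \code{write_mtx} writes \code{matrix.mtx} with sidecar \code{barcodes.tsv}
#' (cell ids), \code{features.tsv} (gene ids) and, if metadata is present,
#' \code{cell_meta.tsv}. Explicit zeros are dropped on write.
#'
#' @param cm A \code{\link{count_matrix}}.
#' @param dir Directory to write into / read from.
#' @return \code{read_mtx} returns a \code{\link{count_matrix}}.
#' @export
write_mtx <- function(cm, dir) {
  stopifnot(inherits(cm, "count_matrix"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(Matrix::drop0(cm$counts), file.path(dir, "matrix.mtx"))
  writeLines(cm$cell_ids, file.path(dir, "barcodes.tsv"))
  writeLines(cm$gene_ids, file.path(dir, "features.tsv"))
  if (!is.null(cm$cell_meta)) {
    write.table(cbind(cell_id = rownames(cm$cell_meta), cm$cell_meta),
                file.path(dir, "cell_meta.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(dir)
}

#' @rdname write_mtx
#' @export
read_mtx <- function(dir) {
  mtx_path <- file.path(dir, "matrix.mtx")
  if (!file.exists(mtx_path)) stop("matrix.mtx not found in ", dir,
                                   call. = FALSE)
  m <- as(as(Matrix::readMM(mtx_path), "CsparseMatrix"), "generalMatrix")
  barcodes <- readLines(file.path(dir, "barcodes.tsv"))
  features <- readLines(file.path(dir, "features.tsv"))
  if (length(barcodes) != ncol(m)) {
    stop(sprintf("barcodes.tsv has %d entries but matrix has %d columns",
                 length(barcodes), ncol(m)), call. = FALSE)
  }
  if (length(features) != nrow(m)) {
    stop(sprintf("features.tsv has %d entries but matrix has %d rows",
                 length(features), nrow(m)), call. = FALSE)
  }
  dimnames(m) <- list(features, barcodes)
  meta_path <- file.path(dir, "cell_meta.tsv")
  meta <- NULL
  if (file.exists(meta_path)) {
    meta <- read.delim(meta_path, stringsAsFactors = FALSE)
    rownames(meta) <- meta$cell_id
    meta$cell_id <- NULL
    meta <- meta[barcodes, , drop = FALSE]
  }
  count_matrix(m, cell_meta = meta)
}

#' Read a gene list (one id per line)
#'
#' Duplicates are removed preserving first occurrence, with a warning.
#'
#' @param path Input file.
#' @return Character vector of unique gene ids in file order.
#' @export
read_gene_list <- function(path) {
  x <- trimws(readLines(path))
  x <- x[nzchar(x)]
  if (anyDuplicated(x) > 0) {
    warning(sprintf("%d duplicated gene id(s) removed", sum(duplicated(x))))
    x <- x[!duplicated(x)]
  }
  x
}

#' Read a survival table (TSV with columns time, event)
#'
#' @param path Input file.
#' @return Data frame with numeric \code{time} and integer \code{event}
#'   in \{0, 1\}.
#' @export
read_survival <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  stop_if_missing_cols(df, c("time", "event"), "survival table")
  if (any(!is.finite(df$time)) || any(df$time < 0)) {
    stop("survival times must be finite and non-negative", call. = FALSE)
  }
  if (!all(df$event %in% c(0, 1))) {
    stop("event column must be 0 (censored) or 1 (event)", call. = FALSE)
  }
  df$event <- as.integer(df$event)
  df
}
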