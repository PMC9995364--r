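# Synthetic-data generators. Every generator is deterministic given the
# configuration (one derived RNG stream per generator) and returns the planted
# ground truth alongside the data, so downstream recovery tests consume only
# (data, truth) pairs.

#' Configuration for the synthetic-data generators
#'
#' Bundles and validates every parameter used by the \code{sim_*} generators.
#' Defaults describe the study conditions the recovery experiments assume:
#' a 2,000-cell sample, half leukemic, a planted 2-fold loss of chromosome-7
#' gene expression in leukemic cells (monosomy 7), a 200-gene signature of
#' which 50 genes are truly coupled to a latent per-cell stemness score, and
#' a 300-patient survival cohort whose hazard depends on two categorized
#' signature genes.
#'
#' @param seed Integer master seed. Each generator derives its own stream
#'   from it, so adding a generator never perturbs the others.
#' @param n_cells Number of cells.
#' @param frac_aml Fraction of cells that are leukemic (carry the planted
#'   NPM1 mutation / monosomy).
#' @param mut_expression_rate Mean number of mutant-allele transcripts per
#'   leukemic cell (Poisson).
#' @param wt_expression_rate Mean number of wild-type-allele transcripts per
#'   cell (Poisson).
#' @param frac_nocall Fraction of cells receiving zero reads over the
#'   mutation region (ground-truth NoCall).
#' @param read_length Read length in bases for simulated reads.
#' @param n_genes Total genes in the simulated count matrix.
#' @param n_chr7_genes Number of chromosome-7 genes (first block of genes).
#' @param monosomy_factor Multiplicative expression loss applied to
#'   chromosome-7 genes of leukemic cells; 0.5 emulates loss of one copy.
#' @param n_signature_genes Number of signature genes (second block).
#' @param n_informative Number of signature genes truly coupled to the latent
#'   stemness score; the remainder are independent noise.
#' @param informative_strength Log-scale coupling of informative genes to the
#'   latent score (per-cell log-mean shift per latent s.d.).
#' @param sample_latent_means Numeric vector; one simulated sample per entry,
#'   cells split evenly, with the latent score centered at the entry's value.
#' @param n_patients Patients in the simulated survival cohort.
#' @param n_survival_genes Genes in the simulated survival expression matrix.
#' @param hazard_coefficients Numeric vector (length \code{n_survival_genes})
#'   of log-hazard coefficients applied to the quartile-categorized
#'   expression values. Default: first gene +1, second gene -1, rest 0.
#' @param baseline_hazard Baseline event rate (exponential model).
#' @param censoring_rate Target fraction of censored patients in [0, 1].
#' @param hto_layout List of hashtag populations, each a list with elements
#'   \code{id}, \code{n}, \code{center} (length-2 numeric) and \code{spread}.
#' @param hto_negative_frac Fraction of each hashtag's cells mislabeled
#'   \code{"Negative"} while sitting inside the cluster (rescuable).
#' @param hto_stray_frac Fraction of each hashtag's labels attached to cells
#'   placed far from the cluster (discardable).
#' @param hto_doublet_frac Doublet cells (labeled \code{"Doublet"}) added
#'   between cluster centers, as a fraction of total hashtag cells.
#' @param lda_frequency True stem-cell frequency per transplanted cell.
#' @param lda_doses Data frame with columns \code{dose} and \code{n_tested}
#'   describing the limiting-dilution design.
#'
#' @return A validated list of class \code{"synth_config"}.
#' @export
synth_config <- function(seed = 1L,
                         n_cells = 2000L,
                         frac_aml = 0.5,
                         mut_expression_rate = 2,
                         wt_expression_rate = 3,
                         frac_nocall = 0.2,
                         read_length = 60L,
                         n_genes = 500L,
                         n_chr7_genes = 100L,
                         monosomy_factor = 0.5,
                         n_signature_genes = 200L,
                         n_informative = 50L,
                         informative_strength = 0.8,
                         sample_latent_means = 0,
                         n_patients = 300L,
                         n_survival_genes = 24L,
                         hazard_coefficients = NULL,
                         baseline_hazard = 0.1,
                         censoring_rate = 0.3,
                         hto_layout = NULL,
                         hto_negative_frac = 0.10,
                         hto_stray_frac = 0.01,
                         hto_doublet_frac = 0.05,
                         lda_frequency = 1 / 500,
                         lda_doses = data.frame(dose = c(100, 500, 2000),
                                                n_tested = c(12L, 12L, 12L))) {
  if (is.null(hazard_coefficients)) {
    hazard_coefficients <- c(1, -1, rep(0, max(0, n_survival_genes - 2)))
  }
  if (is.null(hto_layout)) {
    hto_layout <- list(
      list(id = "HTO1", n = 400L, center = c(0, 0), spread = 1),
      list(id = "HTO2", n = 400L, center = c(10, 0), spread = 1),
      list(id = "HTO3", n = 400L, center = c(0, 10), spread = 1)
    )
  }
  cfg <- list(
    seed = as.integer(seed), n_cells = as.integer(n_cells),
    frac_aml = frac_aml, mut_expression_rate = mut_expression_rate,
    wt_expression_rate = wt_expression_rate, frac_nocall = frac_nocall,
    read_length = as.integer(read_length), n_genes = as.integer(n_genes),
    n_chr7_genes = as.integer(n_chr7_genes),
    monosomy_factor = monosomy_factor,
    n_signature_genes = as.integer(n_signature_genes),
    n_informative = as.integer(n_informative),
    informative_strength = informative_strength,
    sample_latent_means = sample_latent_means,
    n_patients = as.integer(n_patients),
    n_survival_genes = as.integer(n_survival_genes),
    hazard_coefficients = hazard_coefficients,
    baseline_hazard = baseline_hazard, censoring_rate = censoring_rate,
    hto_layout = hto_layout, hto_negative_frac = hto_negative_frac,
    hto_stray_frac = hto_stray_frac, hto_doublet_frac = hto_doublet_frac,
    lda_frequency = lda_frequency, lda_doses = lda_doses
  )
  validate_synth_config(cfg)
  structure(cfg, class = "synth_config")
}

validate_synth_config <- function(cfg) {
  stopifnot(is_count(cfg$n_cells), is_count(cfg$n_genes),
            is_count(cfg$n_patients), is_count(cfg$read_length))
  tr_len <- TRANSCRIPT_END - TRANSCRIPT_START + 1L
  if (cfg$read_length < 1 || cfg$read_length > tr_len) {
    stop(sprintf(
      "configuration error: read_length must be in [1, %d] (transcript span)",
      tr_len), call. = FALSE)
  }
  for (f in c("frac_aml", "frac_nocall", "censoring_rate",
              "hto_negative_frac", "hto_stray_frac", "hto_doublet_frac")) {
    if (!is_fraction(cfg[[f]])) {
      stop(sprintf("configuration error: '%s' must be a fraction in [0, 1]", f),
           call. = FALSE)
    }
  }
  if (cfg$monosomy_factor <= 0) {
    stop("configuration error: monosomy_factor must be > 0", call. = FALSE)
  }
  if (cfg$mut_expression_rate < 0 || cfg$wt_expression_rate < 0) {
    stop("configuration error: expression rates must be >= 0", call. = FALSE)
  }
  if (cfg$n_chr7_genes + cfg$n_signature_genes > cfg$n_genes) {
    stop("configuration error: n_chr7_genes + n_signature_genes > n_genes",
         call. = FALSE)
  }
  if (cfg$n_informative > cfg$n_signature_genes) {
    stop("configuration error: n_informative > n_signature_genes",
         call. = FALSE)
  }
  if (length(cfg$hazard_coefficients) != cfg$n_survival_genes) {
    stop("configuration error: hazard_coefficients length != n_survival_genes",
         call. = FALSE)
  }
  if (length(cfg$hto_layout) < 1) {
    stop("configuration error: at least one hashtag population required",
         call. = FALSE)
  }
  stop_if_missing_cols(cfg$lda_doses, c("dose", "n_tested"), "lda_doses")
  if (any(cfg$lda_doses$dose <= 0)) {
    stop("configuration error: limiting-dilution doses must be > 0",
         call. = FALSE)
  }
  if (cfg$lda_frequency < 0) {
    stop("configuration error: lda_frequency must be >= 0", call. = FALSE)
  }
  invisible(cfg)
}

# Mutation-region geometry. The type-A mutation is a TCTG tandem duplication
# at chr5:171410540-171410543; the wild-type core GATCTCTGGCAG occupies
# 171410536-171410547 and the mutant transcript carries GATCTCTGTCTGGCAG (the
# duplicated TCTG inserted after position 171410543).
TRANSCRIPT_START <- 171410480L
TRANSCRIPT_END <- 171410600L
WT_CORE <- "GATCTCTGGCAG"
MUT_CORE <- "GATCTCTGTCTGGCAG"
CORE_REF_START <- 171410536L

# Build wild-type / mutant transcript sequences whose flanks are random but
# guaranteed free of incidental mutant motifs.
build_transcripts <- function() {
  core_off <- CORE_REF_START - TRANSCRIPT_START + 1L # 1-based within window
  len <- TRANSCRIPT_END - TRANSCRIPT_START + 1L
  pats <- npm1_patterns()
  all_motifs <- c(pats$unanchored, pats$suffix_anchored, pats$prefix_anchored)
  repeat {
    left <- paste0(sample(c("A", "C", "G", "T"), core_off - 1L, replace = TRUE),
                   collapse = "")
    right_len <- len - (core_off - 1L) - nchar(WT_CORE)
    right <- paste0(sample(c("A", "C", "G", "T"), right_len, replace = TRUE),
                    collapse = "")
    wt <- paste0(left, WT_CORE, right)
    mut <- paste0(left, MUT_CORE, right)
    # flanks must not create spurious mutant motifs in the WT transcript
    if (!any(vapply(all_motifs, grepl, logical(1), x = wt, fixed = TRUE))) {
      return(list(wt = wt, mut = mut, core_offset = core_off))
    }
  }
}

#' Simulate barcoded reads over the NPM1 mutation region
#'
#' Plants mutant (duplication-bearing) and wild-type transcript molecules in
#' each cell and emits reads as random windows of the transcript, so that
#' boundary-truncated mutant motifs occur. Each molecule is one unique
#' (barcode, UMI) pair; molecules may be sequenced by several reads. A
#' configurable fraction of cells receives zero reads (ground-truth NoCall).
#'
#' @param config A \code{\link{synth_config}}.
#' @return A list with \code{reads} (data frame with columns
#'   \code{cell_barcode}, \code{umi}, \code{ref_start}, \code{ref_end}
#'   (1-based inclusive) and \code{sequence}) and \code{truth} (per-cell data
#'   frame: \code{cell_barcode}, \code{is_aml}, \code{nocall},
#'   \code{n_mut_molecules}, \code{n_wt_molecules}, \code{cluster},
#'   \code{myeloid}).
#' @export
sim_reads <- function(config) {
  validate_synth_config(config)
  with_seed(op_seed(config$seed, "reads"), {
    tx <- build_transcripts()
    n <- config$n_cells
    barcodes <- sprintf("CELL%05d", seq_len(n))
    is_aml <- rep(FALSE, n)
    is_aml[sample.int(n, round(config$frac_aml * n))] <- TRUE
    nocall <- rep(FALSE, n)
    nocall[sample.int(n, round(config$frac_nocall * n))] <- TRUE

    n_mut <- ifelse(is_aml & !nocall, rpois(n, config$mut_expression_rate), 0L)
    n_wt <- ifelse(!nocall, rpois(n, config$wt_expression_rate), 0L)

    emit_molecule <- function(cell, mutant) {
      umi <- random_strings(1, 10L)
      n_reads <- 1L + rpois(1, 0.5)
      template <- if (mutant) tx$mut else tx$wt
      tlen <- nchar(template)
      starts <- sample.int(tlen - config$read_length + 1L, n_reads,
                           replace = TRUE)
      ends <- starts + config$read_length - 1L
      seqs <- substring(template, starts, ends)
      if (mutant) {
        ref_start <- mut_pos_to_ref(starts, tx$core_offset)
        ref_end <- mut_pos_to_ref(ends, tx$core_offset)
      } else {
        ref_start <- TRANSCRIPT_START + starts - 1L
        ref_end <- TRANSCRIPT_START + ends - 1L
      }
      data.frame(cell_barcode = cell, umi = umi, ref_start = ref_start,
                 ref_end = ref_end, sequence = seqs,
                 stringsAsFactors = FALSE)
    }

    chunks <- vector("list", n)
    for (i in seq_len(n)) {
      mols <- list()
      if (n_mut[i] > 0) {
        mols <- c(mols, lapply(seq_len(n_mut[i]), function(j)
          emit_molecule(barcodes[i], TRUE)))
      }
      if (n_wt[i] > 0) {
        mols <- c(mols, lapply(seq_len(n_wt[i]), function(j)
          emit_molecule(barcodes[i], FALSE)))
      }
      if (length(mols) > 0) chunks[[i]] <- do.call(rbind, mols)
    }
    reads <- do.call(rbind, chunks[!vapply(chunks, is.null, logical(1))])
    if (is.null(reads)) {
      reads <- data.frame(cell_barcode = character(), umi = character(),
                          ref_start = integer(), ref_end = integer(),
                          sequence = character(), stringsAsFactors = FALSE)
    } else {
      reads <- reads[sample.int(nrow(reads)), , drop = FALSE]
      rownames(reads) <- NULL
    }

    cluster <- ifelse(is_aml,
                      sample(c("C1", "C2"), n, replace = TRUE),
                      sample(c("C3", "C4"), n, replace = TRUE))
    truth <- data.frame(
      cell_barcode = barcodes, is_aml = is_aml, nocall = nocall,
      n_mut_molecules = as.integer(n_mut), n_wt_molecules = as.integer(n_wt),
      cluster = cluster, myeloid = cluster %in% c("C1", "C2"),
      stringsAsFactors = FALSE
    )
    list(reads = reads, truth = truth)
  })
}

# Map positions within the mutant transcript window to reference coordinates.
# The 4 inserted bases (the duplicated TCTG, transcript offsets core+8..core+11)
# have no reference position and are clamped to the right edge of the locus.
mut_pos_to_ref <- function(pos, core_offset) {
  ins_start <- core_offset + 8L # first inserted base (1-based in transcript)
  ref <- integer(length(pos))
  before <- pos < ins_start
  inside <- pos >= ins_start & pos < ins_start + 4L
  after <- pos >= ins_start + 4L
  ref[before] <- TRANSCRIPT_START + pos[before] - 1L
  ref[inside] <- TRANSCRIPT_START + ins_start - 1L + 3L # clamp to 171410543
  ref[after] <- TRANSCRIPT_START + pos[after] - 1L - 4L
  ref
}

#' Simulate a clustered UMI count matrix with planted structure
#'
#' Generates negative-binomial counts (per-gene dispersion drawn
#' log-normally) for three gene blocks: chromosome-7 genes whose means are
#' multiplied by \code{monosomy_factor} in leukemic cells, signature genes of
#' which the first \code{n_informative} are log-linearly coupled to a latent
#' per-cell stemness score, and independent filler genes.
#'
#' @param config A \code{\link{synth_config}}.
#' @return A list with \code{matrix} (a \code{\link{count_matrix}}) and
#'   \code{truth} (list: \code{is_aml}, \code{latent}, gene-block id vectors).
#' @export
sim_counts <- function(config) {
  validate_synth_config(config)
  with_seed(op_seed(config$seed, "counts"), {
    n <- config$n_cells
    g <- config$n_genes
    chr7 <- sprintf("CHR7-%03d", seq_len(config$n_chr7_genes))
    sig <- sprintf("SIG-%03d", seq_len(config$n_signature_genes))
    filler_n <- g - length(chr7) - length(sig)
    filler <- if (filler_n > 0) sprintf("GENE-%03d", seq_len(filler_n))
              else character()
    genes <- c(chr7, sig, filler)
    informative <- head(sig, config$n_informative)

    cells <- sprintf("CELL%05d", seq_len(n))
    is_aml <- rep(FALSE, n)
    is_aml[sample.int(n, round(config$frac_aml * n))] <- TRUE
    n_samples <- length(config$sample_latent_means)
    sample_id <- sprintf("S%d", rep_len(seq_len(n_samples), n))
    latent <- rnorm(n, mean = config$sample_latent_means[
      rep_len(seq_len(n_samples), n)], sd = 1)

    base_mu <- exp(rnorm(g, mean = 0, sd = 0.5)) # median ~1 UMI per gene
    dispersion <- exp(rnorm(g, mean = log(0.3), sd = 0.5))
    size <- 1 / dispersion

    counts <- matrix(0L, nrow = g, ncol = n, dimnames = list(genes, cells))
    is_chr7 <- genes %in% chr7
    is_inf <- genes %in% informative
    for (j in seq_len(g)) {
      mu <- rep(base_mu[j], n)
      if (is_chr7[j]) mu[is_aml] <- mu[is_aml] * config$monosomy_factor
      if (is_inf[j]) mu <- mu * exp(config$informative_strength * latent)
      counts[j, ] <- rnbinom(n, mu = mu, size = size[j])
    }

    cluster <- ifelse(is_aml,
                      sample(c("C1", "C2"), n, replace = TRUE),
                      sample(c("C3", "C4"), n, replace = TRUE))
    cm <- count_matrix(
      counts = as(as(counts, "CsparseMatrix"), "generalMatrix"),
      cell_meta = data.frame(cluster = cluster, sample = sample_id,
                             timepoint = "DX", row.names = cells,
                             stringsAsFactors = FALSE)
    )
    truth <- list(is_aml = setNames(is_aml, cells),
                  latent = setNames(latent, cells),
                  chr7_genes = chr7, signature_genes = sig,
                  informative_genes = informative)
    list(matrix = cm, truth = truth)
  })
}

#' Simulate a 2-D embedding of hashtag-labeled cell populations
#'
#' Each hashtag population is an isotropic Gaussian cluster. A fraction of
#' each cluster's cells is mislabeled \code{"Negative"} in place (rescuable by
#' \code{\link{refine_hto}}), a fraction of labels is attached to stray cells
#' placed far from the cluster (discardable), and doublet cells are placed
#' between cluster centers.
#'
#' @param config A \code{\link{synth_config}}.
#' @return A list with \code{embedding} (n x 2 matrix), \code{labels}
#'   (initial labels: hashtag id, \code{"Negative"} or \code{"Doublet"}) and
#'   \code{truth} (generating population per cell; \code{"Background"} for
#'   strays and doublets).
#' @export
sim_hto <- function(config) {
  validate_synth_config(config)
  layout <- config$hto_layout
  with_seed(op_seed(config$seed, "hto"), {
    centers <- do.call(rbind, lapply(layout, `[[`, "center"))
    spreads <- vapply(layout, `[[`, numeric(1), "spread")
    if (any(spreads == 0) && anyDuplicated(centers) > 0) {
      warning("hashtag populations with identical centers and zero spread")
    }
    emb <- list(); lab <- list(); tru <- list()
    for (k in seq_along(layout)) {
      h <- layout[[k]]
      pts <- cbind(rnorm(h$n, h$center[1], h$spread),
                   rnorm(h$n, h$center[2], h$spread))
      labels <- rep(h$id, h$n)
      n_neg <- round(config$hto_negative_frac * h$n)
      if (n_neg > 0) labels[sample.int(h$n, n_neg)] <- "Negative"
      emb[[k]] <- pts; lab[[k]] <- labels; tru[[k]] <- rep(h$id, h$n)
      # stray cells: carry the hashtag label but sit far from the cluster
      n_stray <- round(config$hto_stray_frac * h$n)
      if (n_stray > 0) {
        ang <- runif(n_stray, 0, 2 * pi)
        rad <- runif(n_stray, 15, 25) * max(h$spread, 1)
        stray <- cbind(h$center[1] + rad * cos(ang),
                       h$center[2] + rad * sin(ang))
        emb[[k]] <- rbind(emb[[k]], stray)
        lab[[k]] <- c(lab[[k]], rep(h$id, n_stray))
        tru[[k]] <- c(tru[[k]], rep("Background", n_stray))
      }
    }
    embedding <- do.call(rbind, emb)
    labels <- unlist(lab)
    truth <- unlist(tru)
    n_total <- sum(vapply(layout, `[[`, numeric(1), "n"))
    n_dbl <- round(config$hto_doublet_frac * n_total)
    if (n_dbl > 0 && length(layout) >= 2) {
      pair <- matrix(
        vapply(seq_len(n_dbl),
               function(i) sample.int(length(layout), 2), integer(2)),
        ncol = 2, byrow = TRUE)
      mid <- (centers[pair[, 1], , drop = FALSE] +
              centers[pair[, 2], , drop = FALSE]) / 2
      dbl <- mid + matrix(rnorm(2 * n_dbl, 0, mean(spreads)), ncol = 2)
      embedding <- rbind(embedding, dbl)
      labels <- c(labels, rep("Doublet", n_dbl))
      truth <- c(truth, rep("Background", n_dbl))
    }
    rownames(embedding) <- sprintf("CELL%05d", seq_len(nrow(embedding)))
    colnames(embedding) <- c("x", "y")
    list(embedding = embedding, labels = setNames(labels, rownames(embedding)),
         truth = setNames(truth, rownames(embedding)))
  })
}

#' Simulate a patient cohort with expression-dependent survival
#'
#' Expression values are standard normal; the log hazard of the exponential
#' event-time model is the inner product of \code{hazard_coefficients} with
#' the patient's quartile-categorized expression values (the same -1/0/+1
#' categorization \code{\link{quartile_categorize}} applies). Censoring is
#' independent exponential, calibrated to \code{censoring_rate}.
#'
#' @param config A \code{\link{synth_config}}.
#' @return A list with \code{expression} (patients x genes matrix),
#'   \code{survival} (data frame: \code{time}, \code{event}) and \code{truth}
#'   (list: \code{coefficients}, \code{linear_predictor}).
#' @export
sim_survival <- function(config) {
  validate_synth_config(config)
  with_seed(op_seed(config$seed, "survival"), {
    n <- config$n_patients
    g <- config$n_survival_genes
    genes <- sprintf("SURV-%03d", seq_len(g))
    patients <- sprintf("PT%04d", seq_len(n))
    expr <- matrix(rnorm(n * g), nrow = n, dimnames = list(patients, genes))
    xc <- quartile_categorize(expr)
    lp <- drop(unclass(xc) %*% config$hazard_coefficients)
    event_time <- rexp(n, rate = config$baseline_hazard * exp(lp))
    if (config$censoring_rate >= 1) {
      time <- rexp(n, rate = config$baseline_hazard)
      event <- rep(0L, n)
    } else if (config$censoring_rate <= 0) {
      time <- event_time
      event <- rep(1L, n)
    } else {
      cens_rate <- config$baseline_hazard * mean(exp(lp)) *
        config$censoring_rate / (1 - config$censoring_rate)
      cens_time <- rexp(n, rate = cens_rate)
      time <- pmin(event_time, cens_time)
      event <- as.integer(event_time <= cens_time)
    }
    list(expression = expr,
         survival = data.frame(time = time, event = event,
                               row.names = patients),
         truth = list(coefficients = setNames(config$hazard_coefficients,
                                              genes),
                      linear_predictor = setNames(lp, patients)))
  })
}

#' Simulate a limiting-dilution engraftment table
#'
#' Under the single-hit model each transplanted mouse engrafts with
#' probability \eqn{1 - \exp(-f \cdot dose)}, where \eqn{f} is the true
#' stem-cell frequency per cell.
#'
#' @param config A \code{\link{synth_config}}.
#' @return A data frame with columns \code{dose}, \code{n_tested},
#'   \code{n_negative}.
#' @export
sim_lda <- function(config) {
  validate_synth_config(config)
  with_seed(op_seed(config$seed, "lda"), {
    d <- config$lda_doses
    p_engraft <- 1 - exp(-config$lda_frequency * d$dose)
    engrafted <- rbinom(nrow(d), size = d$n_tested, prob = p_engraft)
    data.frame(dose = d$dose, n_tested = as.integer(d$n_tested),
               n_negative = as.integer(d$n_tested - engrafted))
  })
}
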