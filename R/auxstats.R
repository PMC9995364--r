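# Auxiliary statistics: HTO label refinement on 2-D embeddings, single-hit
# limiting-dilution frequency estimation, and Cohen's kappa similarity
# between gene sets.

# Medoid (index) of a 2-D point set: the member minimizing summed Euclidean
# distance to the others. Chunked so that large populations never
# materialize a full pairwise distance matrix.
medoid_index <- function(pts, chunk = 512L) {
  n <- nrow(pts)
  if (n == 1) return(1L)
  sums <- numeric(n)
  for (s in seq(1, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    dx <- outer(pts[s:e, 1], pts[, 1], "-")
    dy <- outer(pts[s:e, 2], pts[, 2], "-")
    sums[s:e] <- rowSums(sqrt(dx^2 + dy^2))
  }
  which.min(sums)
}

#' Refine hashtag (HTO) demultiplexing labels on a 2-D embedding
#'
#' For each hashtag in input order: find the medoid of the currently
#' hashtag-labeled cells on the embedding, take the \code{quantile}-level
#' quantile r of those cells' Euclidean distances to the medoid, and draw
#' the rescue boundary \code{[mx - r, mx + r] x [my - r, my + r]} (an
#' axis-aligned box of half-width r around the medoid; \code{shape =
#' "disc"} uses the disc of radius r instead). Hashtag-labeled cells
#' outside the boundary are discarded (relabeled \code{"Negative"},
#' provenance \code{"discarded"}); \code{"Negative"} cells inside it are
#' rescued (relabeled with the hashtag, provenance \code{"rescued"}). Cells
#' rescued by an earlier hashtag are never relabeled by a later one;
#' because the box contains the distance-quantile disc, at least the
#' quantile fraction of a hashtag's own cells always lies inside its
#' boundary.
#'
#' @param embedding n x 2 numeric matrix of embedding coordinates (e.g.
#'   tSNE).
#' @param labels Character vector (hashtag id, \code{"Negative"} or
#'   \code{"Doublet"}), one per row of \code{embedding}.
#' @param quantile Distance quantile defining the boundary (default 0.98).
#' @param shape \code{"box"} (default) or \code{"disc"}.
#' @param rescue_other_singlets If TRUE, singlets of other hashtags inside
#'   the boundary are also relabeled (off by default; can oscillate).
#' @param hashtags Processing order; default: order of first appearance.
#' @param min_cells Hashtags with fewer labeled cells are skipped with a
#'   warning (default 3).
#' @return List of class \code{"hto_state"}: \code{labels},
#'   \code{provenance} (\code{original}/\code{rescued}/\code{discarded}),
#'   \code{boundaries} (one row per processed hashtag: medoid coordinates,
#'   radius, counts), \code{embedding}.
#' @export
refine_hto <- function(embedding, labels, quantile = 0.98,
                       shape = c("box", "disc"),
                       rescue_other_singlets = FALSE, hashtags = NULL,
                       min_cells = 3L) {
  shape <- match.arg(shape)
  embedding <- as.matrix(embedding)
  stopifnot(ncol(embedding) == 2, nrow(embedding) == length(labels))
  labels <- as.character(labels)
  specials <- c("Negative", "Doublet")
  if (is.null(hashtags)) {
    hashtags <- setdiff(unique(labels), specials)
  }
  if (length(hashtags) == 0) {
    stop("at least one hashtag population is required", call. = FALSE)
  }
  provenance <- rep("original", length(labels))
  rows <- list()
  for (h in hashtags) {
    own <- which(labels == h)
    if (length(own) < min_cells) {
      warning(sprintf("hashtag %s has %d < %d cells: skipped", h,
                      length(own), min_cells))
      next
    }
    med <- own[medoid_index(embedding[own, , drop = FALSE])]
    mx <- embedding[med, 1]; my <- embedding[med, 2]
    d_own <- sqrt((embedding[own, 1] - mx)^2 + (embedding[own, 2] - my)^2)
    r <- stats::quantile(d_own, quantile, names = FALSE)
    inside <- if (shape == "box") {
      abs(embedding[, 1] - mx) <= r & abs(embedding[, 2] - my) <= r
    } else {
      (embedding[, 1] - mx)^2 + (embedding[, 2] - my)^2 <= r^2
    }
    discard <- which(labels == h & !inside)
    labels[discard] <- "Negative"
    provenance[discard] <- "discarded"
    rescue <- which(labels == "Negative" & inside &
                      provenance == "original")
    if (rescue_other_singlets) {
      extra <- which(labels %in% setdiff(hashtags, h) & inside &
                       provenance == "original")
      rescue <- union(rescue, extra)
    }
    labels[rescue] <- h
    provenance[rescue] <- "rescued"
    rows[[h]] <- data.frame(
      hashtag = h, medoid_x = mx, medoid_y = my, radius = r,
      n_own = length(own), n_discarded = length(discard),
      n_rescued = length(rescue), stringsAsFactors = FALSE)
  }
  boundaries <- if (length(rows) > 0) do.call(rbind, rows) else NULL
  if (!is.null(boundaries)) rownames(boundaries) <- NULL
  structure(list(labels = labels, provenance = provenance,
                 boundaries = boundaries, embedding = embedding,
                 quantile = quantile, shape = shape),
            class = "hto_state")
}

#' Estimate stem-cell frequency from a limiting-dilution experiment
#'
#' Single-hit Poisson model: the probability that a mouse transplanted with
#' dose d cells does NOT engraft is exp(-f d). The frequency f is the
#' maximum-likelihood estimate from a binomial generalized linear model
#' with complementary log-log link and log-dose offset; the confidence
#' interval is the Wald interval on log f, back-transformed.
#'
#' Boundary cases: with no engrafted mouse at any dose the estimate is 0
#' with a one-sided upper bound; with every mouse engrafted the dose range
#' failed to reach a limiting dose and only a one-sided lower bound is
#' reported.
#'
#' @param experiment Data frame with columns \code{dose} (cells
#'   transplanted), \code{n_tested} (mice), \code{n_negative} (non-engrafted
#'   mice).
#' @param confidence Confidence level (default 0.95).
#' @return List of class \code{"lda_estimate"}: \code{frequency},
#'   \code{lower}, \code{upper} (CI on f), \code{one_in} (1/f),
#'   \code{status} (\code{"ok"}, \code{"all_negative"} or
#'   \code{"all_engrafted"}), \code{confidence}.
#' @export
estimate_frequency <- function(experiment, confidence = 0.95) {
  stop_if_missing_cols(experiment, c("dose", "n_tested", "n_negative"),
                       "limiting-dilution table")
  d <- experiment
  if (any(d$dose <= 0) || any(d$n_tested <= 0) ||
      any(d$n_negative < 0 | d$n_negative > d$n_tested)) {
    stop("invalid limiting-dilution table", call. = FALSE)
  }
  alpha <- 1 - confidence
  total_neg <- sum(d$n_negative)
  total_pos <- sum(d$n_tested - d$n_negative)
  if (total_pos == 0) { # no engrafter anywhere: f = 0, one-sided upper bound
    upper <- -log(alpha) / sum(d$dose * d$n_tested)
    return(structure(list(frequency = 0, lower = 0, upper = upper,
                          one_in = Inf, status = "all_negative",
                          confidence = confidence),
                     class = "lda_estimate"))
  }
  if (total_neg == 0) { # every mouse engrafted: no limiting dose reached
    loglik_zero_neg <- function(f) {
      sum(d$n_tested * log1p(-exp(-f * d$dose)))
    }
    lower <- stats::uniroot(function(f) loglik_zero_neg(f) - log(alpha),
                            lower = 1e-12, upper = 1,
                            extendInt = "upX", tol = 1e-12)$root
    return(structure(list(frequency = Inf, lower = lower, upper = Inf,
                          one_in = 0, status = "all_engrafted",
                          confidence = confidence),
                     class = "lda_estimate"))
  }
  engrafted <- d$n_tested - d$n_negative
  fit <- stats::glm(cbind(engrafted, d$n_negative) ~ 1,
                    offset = log(d$dose),
                    family = stats::binomial(link = "cloglog"))
  logf <- unname(coef(fit)[1])
  se <- sqrt(stats::vcov(fit)[1, 1])
  z <- qnorm(1 - alpha / 2)
  f <- exp(logf)
  structure(list(frequency = f, lower = exp(logf - z * se),
                 upper = exp(logf + z * se), one_in = 1 / f,
                 status = "ok", confidence = confidence),
            class = "lda_estimate")
}

#' @export
#' @method print lda_estimate
print.lda_estimate <- function(x, ...) {
  if (x$status == "ok") {
    cat(sprintf(
      "stem-cell frequency: 1 in %.1f (f = %.3g, %g%% CI [%.3g, %.3g])\n",
      x$one_in, x$frequency, 100 * x$confidence, x$lower, x$upper))
  } else {
    cat(sprintf("stem-cell frequency: %s (bound %.3g at %g%% confidence)\n",
                x$status,
                if (x$status == "all_negative") x$upper else x$lower,
                100 * x$confidence))
  }
  invisible(x)
}

#' Cohen's kappa similarity between two gene sets
#'
#' The two sets are encoded as binary membership vectors over the gene
#' universe (e.g. the DEG list); kappa = (p_o - p_e) / (1 - p_e) with p_o
#' the observed agreement and p_e the chance agreement from the marginals,
#' weighting the similarity for the different sizes of the compared sets.
#'
#' @param set_a,set_b Character vectors of gene ids; must be subsets of
#'   \code{universe}.
#' @param universe Character vector of all genes under consideration.
#' @return Kappa in [-1, 1].
#' @export
kappa_score <- function(set_a, set_b, universe) {
  if (length(universe) == 0) stop("universe must be non-empty",
                                  call. = FALSE)
  universe <- unique(universe)
  if (!all(set_a %in% universe) || !all(set_b %in% universe)) {
    stop("gene sets must be subsets of the universe", call. = FALSE)
  }
  a <- universe %in% set_a
  b <- universe %in% set_b
  p_o <- mean(a == b)
  p_a <- mean(a); p_b <- mean(b)
  p_e <- p_a * p_b + (1 - p_a) * (1 - p_b)
  if (1 - p_e < .Machine$double.eps) {
    if (all(a == b)) return(1)
    stop("chance agreement is 1 but vectors differ: kappa undefined",
         call. = FALSE)
  }
  (p_o - p_e) / (1 - p_e)
}
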