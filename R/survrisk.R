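# Cross-platform survival risk stratification: per-patient quartile
# categorization, lasso-penalized Cox training with seeded 10-fold CV,
# median split of the linear predictor, transfer of the frozen model to a
# test cohort, and log-rank / hazard-ratio evaluation.

#' Quartile-categorize expression per patient
#'
#' For each patient (row), values below that patient's own 1st quartile
#' become -1 (downregulated), values above the 3rd quartile become +1
#' (upregulated), and values in between (boundaries included) become 0.
#' Inequalities are strict, so a value exactly at a quartile maps to 0.
#' Quartiles use linear interpolation (\code{quantile} type 7) and are
#' computed over the chosen gene universe; because the categorization is
#' rank-based it is invariant under any monotone per-patient transformation
#' of the expression values.
#'
#' @param expr Numeric matrix, patients in rows, genes in columns.
#' @param universe \code{"all_genes"} (default: each patient's quartiles
#'   come from their full profile) or \code{"signature_genes"}.
#' @param signature Gene ids defining the universe when
#'   \code{universe = "signature_genes"}.
#' @param qtype \code{\link[stats]{quantile}} type (default 7, linear
#'   interpolation).
#' @return Matrix of the same shape with values in \{-1, 0, 1\}, class
#'   \code{"categorized_matrix"}, with attribute \code{"universe"}.
#' @export
quartile_categorize <- function(expr, universe = c("all_genes",
                                                   "signature_genes"),
                                signature = NULL, qtype = 7) {
  universe <- match.arg(universe)
  stopifnot(is.matrix(expr), is.numeric(expr))
  ucols <- if (universe == "signature_genes") {
    if (is.null(signature)) {
      stop("signature required when universe = 'signature_genes'",
           call. = FALSE)
    }
    intersect(signature, colnames(expr))
  } else colnames(expr)
  if (length(ucols) < 4) {
    stop("at least 4 universe values per patient are required",
         call. = FALSE)
  }
  out <- matrix(0L, nrow = nrow(expr), ncol = ncol(expr),
                dimnames = dimnames(expr))
  constant <- FALSE
  for (i in seq_len(nrow(expr))) {
    vals <- expr[i, ucols]
    q <- quantile(vals, c(0.25, 0.75), type = qtype, names = FALSE)
    if (q[1] == q[2] && sd(vals) == 0) constant <- TRUE
    out[i, ] <- ifelse(expr[i, ] < q[1], -1L,
                ifelse(expr[i, ] > q[2], 1L, 0L))
  }
  if (constant) warning("constant expression for at least one patient: ",
                        "all categories 0")
  structure(out, universe = universe, class = c("categorized_matrix",
                                                class(out)))
}

#' Fit a lasso-penalized Cox risk model with cross-validated penalty
#'
#' L1-penalized proportional-hazards fit (glmnet); the penalty is chosen as
#' the one minimizing the partial-likelihood deviance in a seeded
#' \code{n_folds}-fold cross-validation with folds stratified by event
#' status. The linear predictor of the training data is computed and its
#' median becomes the risk-group cutoff, frozen for later application to
#' test cohorts.
#'
#' @param X Numeric matrix, patients x genes (categorized -1/0/1 values or
#'   standardized expression).
#' @param surv Data frame with columns \code{time}, \code{event} aligned
#'   with the rows of \code{X}.
#' @param n_folds Number of CV folds (default 10).
#' @param seed Seed for fold assignment.
#' @param standardize Passed to glmnet (default FALSE: categorized inputs
#'   are already on a common scale).
#' @return List of class \code{"risk_model"}: \code{genes},
#'   \code{coefficients}, \code{lambda}, \code{cutoff} (training median of
#'   the linear predictor; \code{NA} when degenerate),
#'   \code{degenerate} (TRUE when the selected penalty zeroes every
#'   coefficient), \code{linear_predictor} (training values).
#' @export
fit_risk_model <- function(X, surv, n_folds = 10L, seed = 1L,
                           standardize = FALSE) {
  stop_if_missing_cols(surv, c("time", "event"), "survival table")
  X <- unclass(X)
  stopifnot(is.matrix(X), nrow(X) == nrow(surv))
  if (sum(surv$event) < 2) {
    stop("at least 2 events are required to fit a risk model",
         call. = FALSE)
  }
  if (n_folds > nrow(X)) {
    stop("n_folds must not exceed the number of patients", call. = FALSE)
  }
  y <- survival::Surv(surv$time, surv$event)
  foldid <- with_seed(op_seed(seed, "cvfolds"), {
    f <- integer(nrow(X))
    for (ev in unique(surv$event)) { # stratify folds by event status
      idx <- which(surv$event == ev)
      f[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
    }
    f
  })
  cv <- glmnet::cv.glmnet(X, y, family = "cox", alpha = 1,
                          foldid = foldid, type.measure = "deviance",
                          standardize = standardize)
  beta <- as.numeric(coef(cv, s = "lambda.min"))
  names(beta) <- rownames(coef(cv, s = "lambda.min"))
  degenerate <- all(beta == 0)
  lp <- drop(X %*% beta)
  model <- list(genes = colnames(X), coefficients = beta,
                lambda = cv$lambda.min,
                cutoff = if (degenerate) NA_real_ else median(lp),
                degenerate = degenerate,
                linear_predictor = lp,
                cv_criterion = "partial-likelihood deviance",
                n_folds = n_folds, seed = seed)
  class(model) <- "risk_model"
  model
}

#' @export
#' @method print risk_model
print.risk_model <- function(x, ...) {
  nz <- sum(x$coefficients != 0)
  cat(sprintf("risk_model: %d / %d genes selected, lambda = %.4g, %s\n",
              nz, length(x$genes), x$lambda,
              if (x$degenerate) "DEGENERATE (no genes selected)"
              else sprintf("cutoff = %.4g", x$cutoff)))
  invisible(x)
}

#' Apply a frozen risk model to a cohort
#'
#' Computes the linear predictor with the trained coefficients and assigns
#' \code{"high"} to patients strictly above the training cutoff,
#' \code{"low"} otherwise (a predictor exactly at the cutoff is low). All
#' model genes must be present; absent genes are an error, never silently
#' imputed.
#'
#' @param model A \code{\link{fit_risk_model}} result.
#' @param X_test Numeric matrix, patients x genes (same categorization /
#'   standardization as used for training).
#' @return Factor of risk groups with levels \code{c("low", "high")}.
#' @export
apply_risk_model <- function(model, X_test) {
  stopifnot(inherits(model, "risk_model"))
  if (model$degenerate) {
    stop("degenerate model (no selected genes): cutoff undefined",
         call. = FALSE)
  }
  X_test <- unclass(X_test)
  miss <- setdiff(model$genes, colnames(X_test))
  if (length(miss) > 0) {
    stop("genes absent from test data: ", paste(head(miss, 5),
                                                collapse = ", "),
         call. = FALSE)
  }
  lp <- drop(X_test[, model$genes, drop = FALSE] %*% model$coefficients)
  factor(ifelse(lp > model$cutoff, "high", "low"),
         levels = c("low", "high"))
}

#' Compare the survival of two risk groups
#'
#' Kaplan-Meier estimates per group, the log-rank test for their
#' difference, and the high-vs-low hazard ratio with Wald 95\% CI from a
#' Cox proportional-hazards fit on the group indicator.
#'
#' @param groups Factor with levels \code{c("low", "high")} (or coercible).
#' @param surv Data frame with columns \code{time}, \code{event}.
#' @return List of class \code{"survival_eval"}: \code{logrank_stat},
#'   \code{logrank_p}, \code{hr}, \code{hr_ci} (length 2), \code{km}
#'   (a \code{survfit} object), \code{n_events}.
#' @export
evaluate_groups <- function(groups, surv) {
  stop_if_missing_cols(surv, c("time", "event"), "survival table")
  groups <- factor(groups, levels = c("low", "high"))
  if (any(table(groups) == 0) || anyNA(groups)) {
    stop("both risk groups must be non-empty", call. = FALSE)
  }
  if (sum(surv$event) < 1) {
    stop("no events observed: log-rank test and hazard ratio undefined",
         call. = FALSE)
  }
  df <- data.frame(time = surv$time, event = surv$event, group = groups)
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ group, data = df)
  logrank_stat <- sd_$chisq
  logrank_p <- pchisq(sd_$chisq, df = 1, lower.tail = FALSE)
  cx <- survival::coxph(survival::Surv(time, event) ~ group, data = df)
  hr <- unname(exp(coef(cx)))
  ci <- unname(exp(stats::confint(cx)))
  km <- survival::survfit(survival::Surv(time, event) ~ group, data = df)
  structure(list(logrank_stat = logrank_stat, logrank_p = logrank_p,
                 hr = hr, hr_ci = c(lower = ci[1], upper = ci[2]),
                 km = km, n_events = sum(surv$event),
                 n_per_group = table(groups)),
            class = "survival_eval")
}

#' @export
#' @method print survival_eval
print.survival_eval <- function(x, ...) {
  cat(sprintf(
    "survival_eval: log-rank chi-sq %.3f (p = %.4g), HR (high vs low) %.3f [%.3f, %.3f], %d events\n",
    x$logrank_stat, x$logrank_p, x$hr, x$hr_ci[1], x$hr_ci[2], x$n_events))
  invisible(x)
}

#' Train/test risk stratification in one call
#'
#' Splits patients into training and test halves (seeded, stratified by
#' event status), quartile-categorizes each cohort per patient (so no test
#' statistic can leak into training), fits the penalized model on the
#' training half, transfers the frozen linear combination and cutoff to the
#' test half and evaluates the resulting groups.
#'
#' @param expr Patients x genes expression matrix.
#' @param surv Survival data frame (\code{time}, \code{event}).
#' @param train_frac Fraction of patients used for training (default 0.5).
#' @param seed Seed for the split and CV folds.
#' @param categorize If TRUE (default) apply
#'   \code{\link{quartile_categorize}} per cohort.
#' @param ... Passed to \code{\link{fit_risk_model}}.
#' @return List with \code{model}, \code{train_idx}, \code{groups_test},
#'   \code{eval_test} (NULL when the model is degenerate).
#' @export
risk_pipeline <- function(expr, surv, train_frac = 0.5, seed = 1L,
                          categorize = TRUE, ...) {
  n <- nrow(expr)
  train_idx <- with_seed(op_seed(seed, "traintest"), {
    idx <- logical(n)
    for (ev in unique(surv$event)) {
      w <- which(surv$event == ev)
      idx[sample(w, round(train_frac * length(w)))] <- TRUE
    }
    which(idx)
  })
  prep <- function(m) if (categorize) quartile_categorize(m) else m
  X_train <- prep(expr[train_idx, , drop = FALSE])
  X_test <- prep(expr[-train_idx, , drop = FALSE])
  model <- fit_risk_model(X_train, surv[train_idx, , drop = FALSE],
                          seed = seed, ...)
  if (model$degenerate) {
    return(list(model = model, train_idx = train_idx,
                groups_test = NULL, eval_test = NULL))
  }
  groups_test <- apply_risk_model(model, X_test)
  eval_test <- tryCatch(
    evaluate_groups(groups_test, surv[-train_idx, , drop = FALSE]),
    error = function(e) NULL)
  list(model = model, train_idx = train_idx, groups_test = groups_test,
       eval_test = eval_test)
}
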