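test_that("per-patient quartile categorization matches hand computation", {
  # {1,2,3,4,100}: Q1 = 2, Q3 = 4 under linear interpolation;
  # strict inequalities put the boundary values at 0
  expr <- matrix(c(1, 2, 3, 4, 100), nrow = 1,
                 dimnames = list("P1", paste0("g", 1:5)))
  out <- quartile_categorize(expr)
  expect_equal(as.integer(out), c(-1L, 0L, 0L, 0L, 1L))
})

test_that("constant patient profiles categorize to all zero with a warning", {
  expr <- matrix(5, nrow = 1, ncol = 6,
                 dimnames = list("P1", paste0("g", 1:6)))
  expect_warning(out <- quartile_categorize(expr), "constant")
  expect_true(all(out == 0))
})

test_that("categorization is invariant under monotone per-patient transforms", {
  set.seed(2)
  expr <- matrix(rnorm(10 * 20), nrow = 10,
                 dimnames = list(paste0("P", 1:10), paste0("g", 1:20)))
  a <- quartile_categorize(expr)
  b <- quartile_categorize(exp(expr)) # monotone transform, same ranks
  expect_equal(unclass(a), unclass(b))
})

test_that("risk-model fitting validates inputs", {
  set.seed(4)
  X <- matrix(rnorm(40 * 6), nrow = 40,
              dimnames = list(NULL, paste0("g", 1:6)))
  surv <- data.frame(time = rexp(40), event = rep(0L, 40))
  expect_error(fit_risk_model(X, surv), "2 events")
  surv$event <- rep(1L, 40)
  expect_error(fit_risk_model(X, surv, n_folds = 50), "n_folds")
})

test_that("a strong planted gene is selected with the correct sign", {
  hits <- vapply(1:10, function(sd) {
    cfg <- synth_config(seed = 100 + sd, n_patients = 200,
                        n_survival_genes = 12,
                        hazard_coefficients = c(1.2, rep(0, 11)))
    sv <- sim_survival(cfg)
    X <- quartile_categorize(sv$expression)
    m <- fit_risk_model(X, sv$survival, seed = sd)
    m$coefficients[["SURV-001"]] > 0
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("applying the model to its training data reproduces the split", {
  cfg <- synth_config(seed = 55, n_patients = 150)
  sv <- sim_survival(cfg)
  X <- quartile_categorize(sv$expression)
  m <- fit_risk_model(X, sv$survival, seed = 2)
  skip_if(m$degenerate)
  g <- apply_risk_model(m, X)
  expect_equal(g == "high", unname(m$linear_predictor > m$cutoff),
               ignore_attr = TRUE)
})

test_that("a predictor exactly at the cutoff goes to the low group", {
  m <- structure(list(genes = c("a", "b"), coefficients = c(a = 1, b = 1),
                      cutoff = 2, degenerate = FALSE),
                 class = "risk_model")
  X <- matrix(c(1, 1, 2, 1), nrow = 2, byrow = TRUE,
              dimnames = list(NULL, c("a", "b")))
  g <- apply_risk_model(m, X)
  expect_equal(as.character(g), c("low", "high")) # 2 is not > 2
})

test_that("test data missing model genes is an error, never imputed", {
  m <- structure(list(genes = c("a", "b"), coefficients = c(a = 1, b = 1),
                      cutoff = 0, degenerate = FALSE),
                 class = "risk_model")
  X <- matrix(1, nrow = 2, ncol = 1, dimnames = list(NULL, "a"))
  expect_error(apply_risk_model(m, X), "absent")
})

test_that("degenerate models refuse application", {
  m <- structure(list(genes = "a", coefficients = c(a = 0),
                      cutoff = NA_real_, degenerate = TRUE),
                 class = "risk_model")
  expect_error(apply_risk_model(m, matrix(1, 1, 1,
                                          dimnames = list(NULL, "a"))),
               "degenerate")
})

test_that("identical survival in both groups gives HR 1 and log-rank 0", {
  surv1 <- data.frame(time = c(1, 2, 3, 4, 5, 6),
                      event = c(1L, 0L, 1L, 1L, 0L, 1L))
  groups <- factor(rep(c("low", "high"), each = 6),
                   levels = c("low", "high"))
  ev <- evaluate_groups(groups, rbind(surv1, surv1))
  expect_equal(ev$hr, 1, tolerance = 1e-6)
  expect_equal(ev$logrank_stat, 0, tolerance = 1e-9)
})

test_that("group evaluation rejects empty groups and event-free data", {
  surv <- data.frame(time = 1:4, event = c(1L, 1L, 0L, 1L))
  expect_error(evaluate_groups(factor(rep("high", 4),
                                      levels = c("low", "high")), surv),
               "non-empty")
  surv$event <- 0L
  expect_error(evaluate_groups(factor(rep(c("low", "high"), 2),
                                      levels = c("low", "high")), surv),
               "no events")
})

test_that("planted hazard ratios are recovered by group evaluation", {
  ok <- vapply(1:20, function(sd) {
    set.seed(sd)
    g <- factor(rep(c("low", "high"), each = 150), levels = c("low", "high"))
    ev_t <- rexp(300, rate = ifelse(g == "high", 0.3, 0.1)) # HR = 3
    cens <- rexp(300, rate = 0.08) # ~30% censoring
    surv <- data.frame(time = pmin(ev_t, cens),
                       event = as.integer(ev_t <= cens))
    e <- evaluate_groups(g, surv)
    e$hr >= 2 && e$hr <= 4.5
  }, logical(1))
  expect_gte(mean(ok), 0.8)
})

test_that("the fitted model is untouched by applying it to test data", {
  cfg <- synth_config(seed = 77, n_patients = 160)
  sv <- sim_survival(cfg)
  rp <- risk_pipeline(sv$expression, sv$survival, seed = 7)
  skip_if(rp$model$degenerate)
  before <- rlang::hash(rp$model)
  invisible(apply_risk_model(
    rp$model, quartile_categorize(sv$expression[-rp$train_idx, ])))
  expect_identical(rlang::hash(rp$model), before)
})
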