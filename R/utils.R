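# Internal helpers shared across modules.

# Derive a per-operation RNG seed from a master seed so that adding a new
# generator never perturbs the streams of existing ones. Kept below 2^31.
op_seed <- function(seed, op) {
  codes <- utf8ToInt(op)
  h <- sum(codes * seq_along(codes))
  as.integer((as.double(seed) %% 1e6) * 2039 + h) %% 2147483647L
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG state is restored afterwards.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# Random fixed-length DNA / barcode strings.
random_strings <- function(n, len, alphabet = c("A", "C", "G", "T")) {
  m <- matrix(sample(alphabet, n * len, replace = TRUE), nrow = len)
  apply(m, 2, paste0, collapse = "")
}

is_count <- function(x) length(x) == 1 && is.numeric(x) && !is.na(x) &&
  x == round(x) && x > 0

is_fraction <- function(x) length(x) == 1 && is.numeric(x) && !is.na(x) &&
  x >= 0 && x <= 1

stop_if_missing_cols <- function(df, cols, what = "table") {
  miss <- setdiff(cols, colnames(df))
  if (length(miss) > 0) {
    stop(sprintf("%s is missing required column(s): %s", what,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  invisible(TRUE)
}
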