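# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @importFrom withr with_seed
NULL

# Spawn deterministic child seeds from a root seed without disturbing the
# caller's RNG state. Values stay below 2^31 - 1 (R integers are 32-bit).
derive_seeds <- function(seed, n, stream = 0L) {
  withr::with_seed(as.integer(seed) + as.integer(stream), {
    sample.int(2147483646L, n)
  })
}

# Row-wise z-score; constant rows are mapped to all-zero rows rather than
# NaN so downstream correlation/distance code can treat them as uninformative.
standardize_rows <- function(m) {
  mu <- rowMeans(m)
  centered <- m - mu
  s <- sqrt(rowSums(centered^2) / (ncol(m) - 1))
  s[s == 0] <- Inf
  centered / s
}

assert_expression_matrix <- function(expr, arg = "expr") {
  if (!is.matrix(expr) || !is.numeric(expr)) {
    stop(sprintf("`%s` must be a numeric matrix (genes x samples)", arg), call. = FALSE)
  }
  if (nrow(expr) < 2 || ncol(expr) < 2) {
    stop(sprintf("`%s` needs at least 2 genes and 2 samples", arg), call. = FALSE)
  }
  if (is.null(rownames(expr)) || is.null(colnames(expr))) {
    stop(sprintf("`%s` must carry gene rownames and sample colnames", arg), call. = FALSE)
  }
  if (anyDuplicated(rownames(expr))) stop("duplicate gene ids", call. = FALSE)
  if (anyDuplicated(colnames(expr))) stop("duplicate sample ids", call. = FALSE)
  if (anyNA(expr)) stop(sprintf("`%s` contains missing values", arg), call. = FALSE)
  invisible(expr)
}

# Pearson correlation that tolerates zero-variance vectors (returns 0):
# used for coherence where standardized constant genes are all-zero rows.
safe_cor <- function(x, y) {
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(0)
  stats::cor(x, y)
}
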