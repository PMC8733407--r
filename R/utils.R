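## internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

## evaluate expr with a fixed RNG state, restoring the caller's stream
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed) || seed < 0)
    stopf("`seed` must be a single nonnegative integer")
  withr::with_seed(as.integer(seed), expr)
}

## derive a distinct child seed from a base seed; kept below 2^31
child_seed <- function(seed, k) {
  (as.integer(seed) * 7919L + as.integer(k) * 104729L) %% 2147483647L
}

is_count <- function(x, min = 1) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= min && x == round(x)
}

## strict 0/1 integer labels from anything reasonable
as_label01 <- function(y) {
  if (is.factor(y)) y <- as.character(y)
  y <- as.integer(as.numeric(y))
  if (any(is.na(y)) || !all(y %in% c(0L, 1L)))
    stopf("labels must be coded 0 (non-AD) and 1 (AD)")
  y
}

## column standardization used by LDA/BP/SVM-style learners
standardize_fit <- function(x) {
  ctr <- colMeans(x)
  scl <- apply(x, 2L, stats::sd)
  scl[!is.finite(scl) | scl == 0] <- 1
  list(center = ctr, scale = scl)
}

standardize_apply <- function(x, std) {
  scale(x, center = std$center, scale = std$scale)[, , drop = FALSE]
}

as_feature_matrix <- function(x) {
  if (is.data.frame(x)) {
    drop <- intersect(c("label", "stratum"), names(x))
    if (length(drop)) x <- x[setdiff(names(x), drop)]
    x <- as.matrix(x)
  }
  if (!is.matrix(x)) x <- as.matrix(x)
  storage.mode(x) <- "double"
  x
}
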