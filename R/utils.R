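#' @keywords internal
"_PACKAGE"

# Row-wise softmax with max-subtraction; rows sum to 1 exactly up to fp error.
softmax_rows <- function(M) {
  M <- M - apply(M, 1L, max)
  E <- exp(M)
  E / rowSums(E)
}

relu <- function(M) {
  M[M < 0] <- 0
  M
}

# Derive a child seed from a base seed and a stage label, staying inside the
# 32-bit integer range required by set.seed().
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}

# Canonical numeric formatting (9 significant digits) used for every file the
# package writes, so that output hashes are reproducible across platforms.
format_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "" else sprintf("%.9g", v)
  }, character(1))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop(sprintf("`%s` must be a single value in [0, 1]", name), call. = FALSE)
  }
  invisible(x)
}
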