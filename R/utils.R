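# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

.assert_scalar_num <- function(x, name, lo = -Inf, hi = Inf, integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  if (x < lo || x > hi)
    stop(sprintf("'%s' must be in [%s, %s], got %s", name, lo, hi, x), call. = FALSE)
  if (integer && x != round(x))
    stop(sprintf("'%s' must be an integer", name), call. = FALSE)
  invisible(TRUE)
}

# derive a stage sub-seed from a global seed; stays below 2^31
.derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1009 + offset * 9973) %% 2147483647)
}

# dense numeric matrix from possibly-sparse input
.as_dense <- function(x) {
  if (methods::is(x, "sparseMatrix")) as.matrix(x) else as.matrix(x)
}

# Benjamini-Hochberg step-up, thin wrapper kept for clarity at call sites
.bh_adjust <- function(p) stats::p.adjust(p, method = "BH")
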