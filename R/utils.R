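# Internal helpers shared across modules.

# Derive a reproducible 32-bit child seed from a parent seed and an index.
# Used so that subject i of a synthetic cohort is identical whether the
# cohort is generated whole or subset.
child_seed <- function(seed, index) {
  # Linear congruential mix; kept strictly below 2^31 - 1.
  as.integer((as.double(seed) * 69069 + as.double(index) * 104729 + 1) %%
               2147483647)
}

# Stable short hash of a (config) object, recorded in artifacts so that a
# report can be matched to the exact configuration that produced it.
config_hash <- function(x) {
  rlang::hash(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Drop S3 classes recursively so nested configs serialize as plain JSON.
strip_classes <- function(x) {
  if (is.list(x)) lapply(unclass(x), strip_classes) else x
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper) {
    stop(sprintf("`%s` must be a scalar in [%g, %g]", name, lower, upper),
         call. = FALSE)
  }
  invisible(x)
}
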