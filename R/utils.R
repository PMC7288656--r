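#' @keywords internal
"_PACKAGE"

# Derive a reproducible 32-bit substream seed from a master seed.
# Distinct streams (frequencies, genotypes, admixed cohort, depths, EM
# restarts...) must not share a seed or they would reuse the same draws.
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  (abs(as.double(seed)) * 7919 + 104729 * stream) %% 2147483629
}

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_aisnp <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_that <- function(cond, fmt, ...) {
  if (!isTRUE(cond)) stop_aisnp(fmt, ...)
  invisible(TRUE)
}
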