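# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Two-sided normal quantile for a coverage level (exact, not 1.96).
z_level <- function(level = 0.95) {
  stopifnot(is.numeric(level), length(level) == 1L, level > 0, level < 1)
  stats::qnorm(1 - (1 - level) / 2)
}

# Deterministic sub-seed derivation; keeps results < 2^31 so set.seed() is safe.
derive_seed <- function(seed, k) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  as.integer((abs(seed) %% 1000003) * 1009 + k) %% 2147483647L
}

# Strand complement of allele strings (vectors of "A"/"C"/"G"/"T").
complement_allele <- function(a) chartr("ACGT", "TGCA", a)

is_palindromic <- function(ea, oa) oa == complement_allele(ea)

two_sided_p <- function(z) 2 * stats::pnorm(-abs(z))

stop_medimr <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "medimr_error")))
}
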