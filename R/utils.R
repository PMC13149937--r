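# Internal helpers shared across modules.

# Two-sided normal p-value from a z-score, safe for large |z|.
z_to_p <- function(z) 2 * stats::pnorm(-abs(z))

# Minor allele frequency from an effect-allele frequency.
maf_of <- function(eaf) pmin(eaf, 1 - eaf)

# Effective sample size for a binary trait (harmonic case/control form).
effective_n <- function(n_case, n_ctrl) 4 / (1 / n_case + 1 / n_ctrl)

# Collapse a character set to a canonical comma-joined key.
set_key <- function(x) paste(sort(unique(x)), collapse = ",")

split_key <- function(x) {
  if (is.na(x) || !nzchar(x)) character(0) else strsplit(x, ",", fixed = TRUE)[[1]]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_prob <- function(x, name) {
  if (any(!is.finite(x)) || any(x <= 0) || any(x > 1)) {
    stop(sprintf("%s must lie in (0, 1]", name), call. = FALSE)
  }
}
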