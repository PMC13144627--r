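#' @keywords internal
"_PACKAGE"

# Canonical chromosome naming: "chr" prefixes stripped, names "1".."22","X".
normalize_chrom <- function(x) {
  sub("^[Cc]hr", "", as.character(x))
}

# Reverse complement of an ACGT string vector (no ambiguity codes).
revcomp <- function(x) {
  chartr("ACGT", "TGCA", vapply(strsplit(x, ""), function(s)
    paste(rev(s), collapse = ""), character(1)))
}

complement_base <- function(x) chartr("ACGT", "TGCA", x)

#' Derive a per-sample seed from a master seed
#'
#' Mixing function for reproducible per-sample streams: the i-th sample's
#' seed is `(master + i * 1103515245) mod (2^31 - 1)`, computed in double
#' precision (exact below 2^53) so cohorts are order-independent.
#'
#' @param master_seed integer master seed.
#' @param index 1-based sample index.
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
mix_seed <- function(master_seed, index) {
  as.integer((as.numeric(master_seed) + as.numeric(index) * 1103515245) %%
               2147483647)
}

# stop() wrapper with sprintf formatting
abort <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

cosine_sim <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(0)
  sum(a * b) / (na * nb)
}
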