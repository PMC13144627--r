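# Canonical channel orderings for the three signature feature encodings.
# SBS96 follows the conventional pyrimidine-strand scheme: six substitution
# classes (C>A, C>G, C>T, T>A, T>C, T>G), within each the 5' base (A,C,G,T)
# varies slowest and the 3' base fastest.

BASES <- c("A", "C", "G", "T")
SBS6_CLASSES <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")

#' SBS96 channel labels
#'
#' The 96 trinucleotide substitution channels in canonical order, labelled
#' `"A[C>A]A"` style: substitution class major, then 5' base, then 3' base.
#'
#' @return character vector of length 96.
#' @export
sbs96_labels <- function() {
  unlist(lapply(SBS6_CLASSES, function(sub) {
    ref <- substr(sub, 1, 1)
    unlist(lapply(BASES, function(p5)
      paste0(p5, "[", sub, "]", BASES)))
  }), use.names = FALSE)
}

CN_LEN_BINS <- c("0-100kb", "100kb-1Mb", "1Mb-10Mb", "10Mb-40Mb", ">40Mb")
CN_HOMDEL_LEN_BINS <- c("0-100kb", "100kb-1Mb", ">1Mb")
CN_LOH_TOTALS <- c("1", "2", "3-4", "5-8", "9+")
CN_HET_TOTALS <- c("2", "3-4", "5-8", "9+")

#' CN48 channel labels
#'
#' The 48-channel copy-number encoding: 3 homozygous-deletion length classes,
#' 25 LOH (total copy number x length) classes and 20 heterozygous classes.
#'
#' @return character vector of length 48.
#' @export
cn48_labels <- function() {
  c(paste0("0:homdel:", CN_HOMDEL_LEN_BINS),
    unlist(lapply(CN_LOH_TOTALS, function(t) paste0(t, ":LOH:", CN_LEN_BINS))),
    unlist(lapply(CN_HET_TOTALS, function(t) paste0(t, ":het:", CN_LEN_BINS))))
}

SV_SIZE_BINS <- c("0-10kb", "10kb-100kb", "100kb-1Mb", "1Mb-10Mb", ">10Mb")
SV_TYPES_SIZED <- c("DEL", "DUP", "INV")

#' SV32 channel labels
#'
#' The 32-channel structural-variant encoding: deletions, duplications and
#' inversions in 5 size bins, each split clustered / non-clustered, plus
#' translocations split clustered / non-clustered.
#'
#' @return character vector of length 32.
#' @export
sv32_labels <- function() {
  c(unlist(lapply(SV_TYPES_SIZED, function(ty)
    c(paste0(ty, ":", SV_SIZE_BINS, ":non-clustered"),
      paste0(ty, ":", SV_SIZE_BINS, ":clustered")))),
    "TRA:non-clustered", "TRA:clustered")
}

# Length class for CN48 LOH/het states, boundaries (0,0.1], (0.1,1], (1,10],
# (10,40], (40, Inf] in Mb.
cn_len_bin <- function(len_bp) {
  CN_LEN_BINS[findInterval(len_bp, c(0, 1e5, 1e6, 1e7, 4e7), left.open = TRUE,
                           rightmost.closed = FALSE)]
}

cn_homdel_len_bin <- function(len_bp) {
  CN_HOMDEL_LEN_BINS[findInterval(len_bp, c(0, 1e5, 1e6), left.open = TRUE)]
}

cn_total_bin <- function(total, loh) {
  if (loh) {
    if (total == 1) "1"
    else if (total == 2) "2"
    else if (total <= 4) "3-4"
    else if (total <= 8) "5-8"
    else "9+"
  } else {
    if (total <= 2) "2"
    else if (total <= 4) "3-4"
    else if (total <= 8) "5-8"
    else "9+"
  }
}

sv_size_bin <- function(size_bp) {
  SV_SIZE_BINS[findInterval(size_bp, c(0, 1e4, 1e5, 1e6, 1e7), left.open = TRUE)]
}
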