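#' Read a COSMIC-style SBS96 signature matrix
#'
#' First column: the 96 trinucleotide channel labels (`"A[C>A]A"` style);
#' remaining columns: one probability vector per signature. Rows are
#' reordered to the canonical channel order ([sbs96_labels()]) so files may
#' list channels in any order. Columns must be non-negative and sum to 1;
#' sums within `1e-3` of 1 are renormalized, anything further off is an
#' error.
#'
#' @param path TSV path.
#' @return numeric matrix, 96 rows (canonical channel order) by signatures.
#' @export
read_signature_matrix <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (nrow(tab) != 96)
    abort("expected 96 features, got %d rows in '%s'", nrow(tab), path)
  labels <- as.character(tab[[1]])
  canon <- sbs96_labels()
  i <- match(canon, labels)
  if (anyNA(i))
    abort("signature matrix '%s' is missing channel '%s'", path,
          canon[which(is.na(i))[1]])
  m <- as.matrix(tab[i, -1, drop = FALSE])
  rownames(m) <- canon
  storage.mode(m) <- "numeric"
  validate_signature_matrix(m)
}

#' Validate and normalize a signature matrix
#'
#' @param m numeric matrix, 96 rows in canonical channel order.
#' @param tol column sums within `tol` of 1 are renormalized.
#' @return the validated matrix with unit column sums.
#' @export
validate_signature_matrix <- function(m, tol = 1e-3) {
  if (nrow(m) != 96) abort("expected 96 features, got %d", nrow(m))
  if (any(m < 0)) abort("signature probabilities must be non-negative")
  s <- colSums(m)
  off <- abs(s - 1) > tol
  if (any(off))
    abort("signature column '%s' sums to %.4f, not 1",
          colnames(m)[off][1], s[off][1])
  sweep(m, 2, s, "/")
}
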