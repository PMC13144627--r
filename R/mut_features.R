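# SBS96 class of a record: purine-reference records are mapped to the
# reverse-complement pyrimidine representation before binning.
sbs96_class <- function(ref, alt, context) {
  pur <- ref %in% c("A", "G")
  ref2 <- ifelse(pur, complement_base(ref), ref)
  alt2 <- ifelse(pur, complement_base(alt), alt)
  ctx2 <- context
  ctx2[pur] <- revcomp(context[pur])
  paste0(substr(ctx2, 1, 1), "[", ref2, ">", alt2, "]", substr(ctx2, 3, 3))
}

#' Build the SBS96 mutation catalog of a sample
#'
#' Counts SNVs in the 96 trinucleotide substitution channels
#' ([sbs96_labels()]). Records with a purine reference are mapped to the
#' reverse-complement pyrimidine channel; records without a context are
#' excluded and counted in the `n_excluded` attribute, so that
#' `sum(v) + n_excluded` equals the input SNV count.
#'
#' @param snvs SNV data frame (`chrom`, `pos`, `ref`, `alt`, `context`).
#' @return named integer vector of length 96 with attribute `n_excluded`.
#' @export
sbs96_vector <- function(snvs) {
  labels <- sbs96_labels()
  v <- stats::setNames(integer(96), labels)
  has <- !is.na(snvs$context) & nchar(snvs$context) == 3
  if (any(has)) {
    cls <- sbs96_class(snvs$ref[has], snvs$alt[has], snvs$context[has])
    tab <- table(factor(cls, levels = labels))
    if (sum(tab) != sum(has))
      abort("unclassifiable SNV record (non-ACGT context?)")
    v[] <- as.integer(tab)
  }
  attr(v, "n_excluded") <- sum(!has)
  v
}

#' Tumor mutational burden
#'
#' Somatic mutations per megabase: `(n_snvs + n_indels) / genome_mb`. The
#' default denominator of 2,800 Mb approximates the non-N hg19 genome;
#' set `n_indels = 0` to exclude indels.
#'
#' @param n_snvs,n_indels mutation counts.
#' @param genome_mb denominator in Mb.
#' @return mutations per Mb.
#' @export
tmb <- function(n_snvs, n_indels = 0, genome_mb = 2800) {
  if (genome_mb <= 0) abort("genome_mb must be positive")
  (n_snvs + n_indels) / genome_mb
}

APOBEC_TCW_BINS <- c("T[C>G]A", "T[C>G]T", "T[C>T]A", "T[C>T]T")

#' APOBEC TCW fraction of an SBS96 catalog
#'
#' Fraction of context-bearing SNVs in the four APOBEC-characteristic TpCpW
#' channels: T\[C>G\]A, T\[C>G\]T, T\[C>T\]A and T\[C>T\]T.
#'
#' @param v an SBS96 count vector ([sbs96_vector()]).
#' @return fraction in \[0, 1\].
#' @export
apobec_fraction <- function(v) {
  tot <- sum(v)
  if (tot == 0) abort("undefined fraction: empty SBS96 vector")
  sum(v[APOBEC_TCW_BINS]) / tot
}

#' Detect kataegis clusters
#'
#' A kataegis event is a maximal run of at least `min_run` consecutive SNVs
#' on one chromosome in which every inter-mutation distance is strictly
#' below `max_imd`. The default 100 bp criterion is the per-case definition;
#' a looser value (e.g. 2 kb, rainfall-style) may be passed instead.
#' Duplicate positions are collapsed before run-finding.
#'
#' @param snvs SNV data frame.
#' @param min_run minimum SNVs per event (default 6).
#' @param max_imd inter-mutation distance bound, bp, exclusive (default 100).
#' @return data frame `chrom`, `start`, `end`, `n_snvs`, `max_imd` plus six
#'   columns `C>A` .. `T>G` with the substitution-class breakdown of each
#'   event (`sum == n_snvs`).
#' @export
detect_kataegis <- function(snvs, min_run = 6, max_imd = 100) {
  empty <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                      n_snvs = integer(), max_imd = numeric(),
                      stringsAsFactors = FALSE)
  for (cl in SBS6_CLASSES) empty[[cl]] <- integer()
  if (nrow(snvs) == 0) return(empty)
  snvs <- snvs[order(match(snvs$chrom, unique(snvs$chrom)), snvs$pos), ,
               drop = FALSE]
  snvs <- snvs[!duplicated(paste(snvs$chrom, snvs$pos)), , drop = FALSE]
  events <- list()
  for (ch in unique(snvs$chrom)) {
    s <- snvs[snvs$chrom == ch, , drop = FALSE]
    if (nrow(s) < min_run) next
    gap_ok <- diff(s$pos) < max_imd
    r <- rle(gap_ok)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (k in which(r$values & r$lengths >= min_run - 1)) {
      idx <- starts[k]:(ends[k] + 1)  # gaps i..j cover SNVs i..j+1
      sub <- s[idx, , drop = FALSE]
      pur <- sub$ref %in% c("A", "G")
      cls <- paste0(ifelse(pur, complement_base(sub$ref), sub$ref), ">",
                    ifelse(pur, complement_base(sub$alt), sub$alt))
      counts <- table(factor(cls, levels = SBS6_CLASSES))
      ev <- data.frame(chrom = ch, start = min(sub$pos), end = max(sub$pos),
                       n_snvs = nrow(sub), max_imd = max(diff(sub$pos)),
                       stringsAsFactors = FALSE)
      for (cl in SBS6_CLASSES) ev[[cl]] <- as.integer(counts[[cl]])
      events[[length(events) + 1]] <- ev
    }
  }
  if (length(events) == 0) return(empty)
  do.call(rbind, c(events, list(make.row.names = FALSE)))
}

#' Refit signature exposures by non-negative least squares
#'
#' Solves `min || p - S h ||_2` with `h >= 0`, where `p` is the normalized
#' SBS96 profile and `S` the signature matrix; signatures whose normalized
#' weight falls below `prune` are zeroed and the system re-solved on the
#' surviving set (the convention of established refitting tools). Reports
#' normalized weights, the L2 residual of the final fit, and the cosine
#' similarity between the profile and its reconstruction.
#'
#' @param v SBS96 count vector (non-empty).
#' @param sigs 96-row signature matrix, canonical channel order.
#' @param prune minimum normalized weight retained, in \[0, 1).
#' @return list with `weights` (named, sums to 1), `residual`,
#'   `reconstruction_cosine`.
#' @export
refit_exposures <- function(v, sigs, prune = 0.06) {
  if (sum(v) == 0) abort("cannot refit an empty catalog")
  if (prune < 0 || prune >= 1) abort("prune must be in [0, 1)")
  if (nrow(sigs) != 96) abort("signature matrix must have 96 rows")
  p <- as.numeric(v) / sum(v)
  solve_set <- function(active) {
    fit <- pracma::lsqnonneg(sigs[, active, drop = FALSE], p)
    h <- stats::setNames(numeric(ncol(sigs)), colnames(sigs))
    h[active] <- fit$x
    h
  }
  h <- solve_set(colnames(sigs))
  if (sum(h) > 0) {
    w <- h / sum(h)
    keep <- names(w)[w >= prune]
    if (length(keep) > 0 && length(keep) < ncol(sigs)) h <- solve_set(keep)
  }
  recon <- as.numeric(sigs %*% h)
  total <- sum(h)
  weights <- if (total > 0) h / total else h
  list(weights = weights,
       residual = sqrt(sum((p - recon)^2)),
       reconstruction_cosine = cosine_sim(p, recon))
}

#' Cosine similarity profile against a signature matrix
#'
#' Cosine similarity between a sample's SBS96 catalog and each signature
#' column, with a flag for signatures above `floor` (the convention used
#' when displaying only signatures with similarity > 0.6).
#'
#' @param v SBS96 count vector (non-empty).
#' @param sigs 96-row signature matrix.
#' @param floor similarity threshold for the `above_floor` flag.
#' @return data frame `signature`, `cosine`, `above_floor`.
#' @export
cosine_profile <- function(v, sigs, floor = 0.6) {
  if (sum(v) == 0) abort("undefined similarity: empty SBS96 vector")
  if (nrow(sigs) != 96) abort("signature matrix must have 96 rows")
  cs <- apply(sigs, 2, cosine_sim, a = as.numeric(v))
  data.frame(signature = colnames(sigs), cosine = as.numeric(cs),
             above_floor = as.numeric(cs) > floor, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' CN48 copy-number feature vector
#'
#' Assigns every segment of a profile to one of the 48 copy-number channels
#' ([cn48_labels()]): homozygous deletions (total CN 0) by 3 length
#' classes; LOH segments by total CN (1, 2, 3-4, 5-8, 9+) and 5 length
#' classes; heterozygous segments by total CN (2, 3-4, 5-8, 9+) and the
#' same 5 length classes. The vector sums to the segment count.
#'
#' @param profile an `ascn_profile`.
#' @return named integer vector of length 48.
#' @export
cn48_vector <- function(profile) {
  labels <- cn48_labels()
  v <- stats::setNames(integer(48), labels)
  seg <- profile$segments
  if (nrow(seg) == 0) return(v)
  len <- seg_length(seg)
  total <- seg_total(seg)
  cls <- character(nrow(seg))
  for (i in seq_len(nrow(seg))) {
    if (total[i] == 0) {
      cls[i] <- paste0("0:homdel:", cn_homdel_len_bin(len[i]))
    } else if (seg$minor[i] == 0) {
      cls[i] <- paste0(cn_total_bin(total[i], TRUE), ":LOH:", cn_len_bin(len[i]))
    } else {
      cls[i] <- paste0(cn_total_bin(total[i], FALSE), ":het:", cn_len_bin(len[i]))
    }
  }
  tab <- table(factor(cls, levels = labels))
  v[] <- as.integer(tab)
  v
}

#' SV32 structural-variant feature vector
#'
#' Classifies SVs into the 32 channels of [sv32_labels()]: deletions,
#' duplications and inversions by 5 size bins, translocations separately,
#' each split clustered / non-clustered. An SV is *clustered* when either
#' of its breakpoints lies, together with at least `cluster_min - 1` other
#' breakpoints (all SV breakpoints genome-wide), inside some window of
#' `cluster_window` bp — a deterministic fixed-window density criterion.
#'
#' @param svs SV data frame.
#' @param cluster_window window size, bp (default 1 Mb).
#' @param cluster_min minimum breakpoints per window (default 3).
#' @return named integer vector of length 32 summing to `nrow(svs)`.
#' @export
sv32_vector <- function(svs, cluster_window = 1e6, cluster_min = 3) {
  labels <- sv32_labels()
  v <- stats::setNames(integer(32), labels)
  if (nrow(svs) == 0) return(v)
  bp <- data.frame(
    chrom = c(svs$chrom1, svs$chrom2),
    pos = c(svs$pos1, svs$pos2),
    sv = rep(seq_len(nrow(svs)), 2), stringsAsFactors = FALSE)
  bp$clustered <- FALSE
  for (ch in unique(bp$chrom)) {
    idx <- which(bp$chrom == ch)
    pos <- bp$pos[idx]
    ord <- order(pos)
    pos_s <- pos[ord]
    n <- length(pos_s)
    clus <- logical(n)
    if (n >= cluster_min) {
      # window of cluster_min consecutive breakpoints spanning <= window
      for (i in seq_len(n - cluster_min + 1)) {
        j <- i + cluster_min - 1
        if (pos_s[j] - pos_s[i] <= cluster_window) clus[i:j] <- TRUE
      }
    }
    bp$clustered[idx[ord]] <- clus
  }
  sv_clustered <- tapply(bp$clustered, bp$sv, any)
  state <- ifelse(sv_clustered[as.character(seq_len(nrow(svs)))],
                  "clustered", "non-clustered")
  cls <- ifelse(svs$svtype == "TRA",
                paste0("TRA:", state),
                paste0(svs$svtype, ":", sv_size_bin(svs$size), ":", state))
  tab <- table(factor(cls, levels = labels))
  if (sum(tab) != nrow(svs)) abort("unclassifiable SV record")
  v[] <- as.integer(tab)
  v
}
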