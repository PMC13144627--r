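#' HRD chromosomal scar scores
#'
#' Computes the three homologous-recombination-deficiency scar indices from
#' an allele-specific copy-number profile and sums them:
#'
#' * **NtAI** — allelically imbalanced segments (`major != minor`) that
#'   reach a telomere without crossing the centromere ([count_ntai()]);
#' * **LST** — large-scale state transitions: breakpoints between adjacent
#'   blocks of at least 10 Mb after 3 Mb small-segment smoothing, counted
#'   per chromosome arm ([count_lst()]);
#' * **HRD-LOH** — loss-of-heterozygosity segments longer than 15 Mb that
#'   do not span a whole chromosome ([count_hrd_loh()]).
#'
#' The HRD score is the unweighted sum of the three. Whole-genome
#' duplication is flagged when ploidy exceeds 3.5 ([call_wgd()]).
#'
#' @param profile an [ascn_profile()].
#' @param build a `genome_build` (defaults to the profile's bound build,
#'   else the bundled hg19 table).
#' @param include_x include chromosome X (default TRUE).
#' @return a one-row data frame: `sample`, `ntai`, `lst`, `hrd_loh`,
#'   `hrd_score`, `ploidy`, `purity`, `wgd`.
#' @examples
#' build <- read_genome_build()
#' prof <- ascn_profile("s1", data.frame(
#'   chrom = "1", start = 1, end = 4e7, major = 2, minor = 1),
#'   purity = 0.8, ploidy = 2.1)
#' scar_scores(prof, build)
#' @export
scar_scores <- function(profile, build = NULL, include_x = TRUE) {
  build <- resolve_build(profile, build)
  prof <- restrict_chroms(profile, build, include_x)
  ntai <- count_ntai(prof, build)
  lst <- count_lst(prof, build)
  loh <- count_hrd_loh(prof, build)
  data.frame(sample = profile$sample_id, ntai = ntai, lst = lst,
             hrd_loh = loh, hrd_score = hrd_score(ntai, lst, loh),
             ploidy = profile$ploidy, purity = profile$purity,
             wgd = call_wgd(profile$ploidy), stringsAsFactors = FALSE)
}

resolve_build <- function(profile, build) {
  if (!is.null(build)) return(build)
  if (!is.null(profile$build)) return(profile$build)
  read_genome_build()
}

restrict_chroms <- function(profile, build, include_x) {
  keep <- build$chrom
  if (!include_x) keep <- setdiff(keep, "X")
  profile$segments <- profile$segments[profile$segments$chrom %in% keep, ,
                                       drop = FALSE]
  profile
}

#' Remove small segments and merge equal neighbours
#'
#' The smoothing pre-step of the LST convention: repeatedly drop the
#' shortest segment below `min_len`, close the resulting gap by extending
#' the flanking segments to its midpoint (or the single neighbour over the
#' whole gap), and merge adjacent segments with identical (major, minor)
#' states. Idempotent; never increases the segment count.
#'
#' @param profile an `ascn_profile`.
#' @param min_len minimum segment length kept, bp (default 3 Mb).
#' @return the smoothed `ascn_profile`.
#' @export
smooth_segments <- function(profile, min_len = 3e6) {
  seg <- profile$segments
  out <- lapply(split(seg, factor(seg$chrom, levels = unique(seg$chrom))),
                smooth_chrom, min_len = min_len)
  profile$segments <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  if (is.null(profile$segments)) profile$segments <- seg[0, , drop = FALSE]
  rownames(profile$segments) <- NULL
  profile
}

smooth_chrom <- function(s, min_len) {
  chrom <- s$chrom[1]
  start <- s$start; end <- s$end; major <- s$major; minor <- s$minor
  repeat {
    # merge adjacent equal (major, minor) runs
    if (length(start) > 1) {
      changed <- c(TRUE, diff(major) != 0 | diff(minor) != 0)
      if (!all(changed)) {
        last <- c(which(changed)[-1] - 1, length(end))
        start <- start[changed]
        major <- major[changed]
        minor <- minor[changed]
        end <- end[last]
      }
    }
    len <- end - start + 1
    short <- which(len < min_len)
    if (length(short) == 0) break
    i <- short[which.min(len[short])]
    n <- length(start)
    if (n == 1) {
      start <- numeric(0); end <- numeric(0)
      major <- numeric(0); minor <- numeric(0)
      break
    }
    if (i == 1) {
      start[2] <- start[1]
    } else if (i == n) {
      end[i - 1] <- end[i]
    } else {
      mid <- floor((start[i] + end[i]) / 2)
      end[i - 1] <- mid
      start[i + 1] <- mid + 1
    }
    start <- start[-i]; end <- end[-i]; major <- major[-i]; minor <- minor[-i]
  }
  data.frame(chrom = rep(chrom, length(start)), start = start, end = end,
             major = major, minor = minor, stringsAsFactors = FALSE)
}

#' Count HRD-LOH segments
#'
#' Loss-of-heterozygosity segments (`minor == 0`, `major >= 1`) longer than
#' `min_len` that do not span the entire chromosome (touch both telomeres,
#' within `tol`).
#'
#' @param profile an `ascn_profile`.
#' @param build a `genome_build`.
#' @param min_len minimum LOH length, exclusive (default 15 Mb).
#' @param tol telomere tolerance in bp (default 1 kb).
#' @return integer count.
#' @export
count_hrd_loh <- function(profile, build = NULL, min_len = 15e6, tol = 1000) {
  build <- resolve_build(profile, build)
  seg <- profile$segments
  if (nrow(seg) == 0) return(0L)
  chrlen <- build$length[build_lookup(build, seg$chrom)]
  whole <- seg$start <= 1 + tol & seg$end >= chrlen - tol
  sum(seg_is_loh(seg) & seg_length(seg) > min_len & !whole)
}

#' Count telomeric allelic imbalances (NtAI)
#'
#' Allelically imbalanced segments (`major != minor`) that reach a telomere
#' (start within `tol` of position 1, or end within `tol` of the chromosome
#' end) and do not cross the centromere interval (extend strictly into both
#' arms). No minimum size by default.
#'
#' @param profile an `ascn_profile`.
#' @param build a `genome_build`.
#' @param min_size minimum segment length, bp (default 0).
#' @param tol telomere tolerance in bp (default 1 kb).
#' @return integer count.
#' @export
count_ntai <- function(profile, build = NULL, min_size = 0, tol = 1000) {
  build <- resolve_build(profile, build)
  seg <- profile$segments
  if (nrow(seg) == 0) return(0L)
  i <- build_lookup(build, seg$chrom)
  telomeric <- seg$start <= 1 + tol | seg$end >= build$length[i] - tol
  crosses_cen <- seg$start < build$cen_start[i] & seg$end > build$cen_end[i]
  sum(seg$major != seg$minor & telomeric & !crosses_cen &
        seg_length(seg) >= min_size)
}

#' Count large-scale state transitions (LST)
#'
#' After smoothing away segments below `smooth_len` ([smooth_segments()]),
#' segments are split at the centromere into arm portions and, per arm,
#' each breakpoint between consecutive segments is counted when both flanks
#' are at least `min_seg` long, their allele-specific states differ, and
#' the gap between them does not exceed `smooth_len`.
#'
#' @param profile an `ascn_profile`.
#' @param build a `genome_build`.
#' @param min_seg minimum flank length, bp (default 10 Mb).
#' @param smooth_len smoothing scale, bp (default 3 Mb).
#' @return integer count.
#' @export
count_lst <- function(profile, build = NULL, min_seg = 10e6, smooth_len = 3e6) {
  build <- resolve_build(profile, build)
  prof <- smooth_segments(profile, smooth_len)
  seg <- prof$segments
  if (nrow(seg) < 2) return(0L)
  i <- build_lookup(build, seg$chrom)
  arms <- split_at_centromere(seg, build$cen_start[i], build$cen_end[i],
                              build$length[i])
  n <- 0L
  for (key in unique(paste(arms$chrom, arms$arm))) {
    a <- arms[paste(arms$chrom, arms$arm) == key, , drop = FALSE]
    if (nrow(a) < 2) next
    len <- a$end - a$start + 1
    for (k in 2:nrow(a)) {
      gap <- a$start[k] - a$end[k - 1] - 1
      if (len[k] >= min_seg && len[k - 1] >= min_seg && gap <= smooth_len &&
          (a$major[k] != a$major[k - 1] || a$minor[k] != a$minor[k - 1]))
        n <- n + 1L
    }
  }
  n
}

# Split segments into p-arm ([1, cen_start]) and q-arm ([cen_end, length])
# portions; portions falling wholly inside the centromere are dropped.
split_at_centromere <- function(seg, cen_start, cen_end, chrlen) {
  p <- seg; p$end <- pmin(p$end, cen_start); p$arm <- "p"
  q <- seg; q$start <- pmax(q$start, cen_end); q$arm <- "q"
  out <- rbind(p[p$start <= p$end & p$start <= cen_start, , drop = FALSE],
               q[q$start <= q$end & q$end >= cen_end, , drop = FALSE])
  out[order(match(out$chrom, unique(seg$chrom)), out$arm, out$start), ,
      drop = FALSE]
}

#' Sum the three scar indices into an HRD score
#'
#' @param ntai,lst,hrd_loh non-negative counts.
#' @return `ntai + lst + hrd_loh`.
#' @export
hrd_score <- function(ntai, lst, hrd_loh) {
  if (any(c(ntai, lst, hrd_loh) < 0)) abort("scar counts must be non-negative")
  ntai + lst + hrd_loh
}

#' Call whole-genome duplication
#'
#' WGD is called when the estimated tumor ploidy strictly exceeds 3.5.
#'
#' @param ploidy positive average ploidy.
#' @return logical.
#' @export
call_wgd <- function(ploidy) {
  if (!is.numeric(ploidy) || any(ploidy <= 0))
    abort("ploidy must be positive")
  ploidy > 3.5
}
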