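#' Count somatic copy-number-altered segments
#'
#' Number of segments whose allele-specific state differs from the baseline
#' pair (default heterozygous diploid, `(1, 1)`).
#'
#' @param profile an `ascn_profile`.
#' @param baseline length-2 vector `(major, minor)`.
#' @return integer count.
#' @export
scna_count <- function(profile, baseline = c(1, 1)) {
  seg <- profile$segments
  if (nrow(seg) == 0) return(0L)
  sum(seg$major != baseline[1] | seg$minor != baseline[2])
}

#' Size-stratified copy-number burden
#'
#' Splits copy-number events by length (small: `<= cut`, default 10 Mb;
#' large: `> cut`) and direction relative to the rounded sample ploidy:
#' total CN above `round(ploidy)` is an amplification, below is a deletion,
#' and ploidy-neutral LOH segments count as deletions (of the minor
#' allele). Segments at the rounded ploidy without LOH are baseline and not
#' counted.
#'
#' @param profile an `ascn_profile` (its `ploidy` field is used).
#' @param cut small/large boundary in bp, inclusive on the small side.
#' @return named integer vector `small_amp`, `small_del`, `large_amp`,
#'   `large_del`.
#' @export
size_stratified_counts <- function(profile, cut = 10e6) {
  seg <- profile$segments
  out <- c(small_amp = 0L, small_del = 0L, large_amp = 0L, large_del = 0L)
  if (nrow(seg) == 0) return(out)
  base_total <- round(profile$ploidy)
  total <- seg_total(seg)
  dir <- ifelse(total > base_total, "amp",
                ifelse(total < base_total, "del",
                       ifelse(seg_is_loh(seg), "del", NA)))
  size <- ifelse(seg_length(seg) <= cut, "small", "large")
  keep <- !is.na(dir)
  tab <- table(factor(paste0(size[keep], "_", dir[keep]), levels = names(out)))
  out[] <- as.integer(tab)
  out
}

#' Subtype classification thresholds
#'
#' The classifier's cut-offs. `fixed` mode returns the published values
#' (HRD score >= 58; TMB > 2.2 mut/Mb; segment count > 2,269); `cohort_mean`
#' mode keeps the HRD cut at 58 and replaces the TMB and segment cuts by
#' the cohort means, the rule used to derive the published values.
#'
#' @param cohort data frame of per-sample metrics (needs `tmb` and
#'   `scna_count` in `cohort_mean` mode).
#' @param mode `"fixed"` or `"cohort_mean"`.
#' @param hrd_cut HRD score cut-off (inclusive).
#' @return list of class `subtype_thresholds`: `hrd_cut`, `tmb_cut`,
#'   `seg_cut`, `provenance`.
#' @export
derive_thresholds <- function(cohort = NULL, mode = c("fixed", "cohort_mean"),
                              hrd_cut = 58) {
  mode <- match.arg(mode)
  if (mode == "fixed") {
    t <- list(hrd_cut = hrd_cut, tmb_cut = 2.2, seg_cut = 2269,
              provenance = "fixed")
  } else {
    if (is.null(cohort) || nrow(cohort) == 0)
      abort("cohort_mean mode needs a non-empty cohort")
    t <- list(hrd_cut = hrd_cut, tmb_cut = mean(cohort$tmb),
              seg_cut = mean(cohort$scna_count), provenance = "cohort_mean")
  }
  if (any(unlist(t[1:3]) <= 0)) abort("thresholds must be positive")
  class(t) <- "subtype_thresholds"
  t
}

#' @export
print.subtype_thresholds <- function(x, ...) {
  cat(sprintf("<subtype_thresholds (%s)> HRD >= %g, TMB > %g mut/Mb, seg > %g\n",
              x$provenance, x$hrd_cut, x$tmb_cut, x$seg_cut))
  invisible(x)
}

#' Classify samples into the four instability subtypes
#'
#' Decision rule, in order of precedence: **HRD** if the HRD score is at or
#' above `hrd_cut` (inclusive); otherwise **MUT** if TMB strictly exceeds
#' `tmb_cut`; otherwise **CN** if the SCNA segment count strictly exceeds
#' `seg_cut`; otherwise **GS** (genome stable). A `dual_flag` marks samples
#' exceeding more than one cut-off.
#'
#' @param metrics data frame with columns `hrd_score`, `tmb`, `scna_count`
#'   (one row per sample; no missing values).
#' @param thresholds a [derive_thresholds()] object.
#' @return `metrics` with `subtype` (factor HRD/MUT/CN/GS) and `dual_flag`
#'   columns appended.
#' @export
classify_samples <- function(metrics, thresholds = derive_thresholds()) {
  need <- c("hrd_score", "tmb", "scna_count")
  miss <- setdiff(need, names(metrics))
  if (length(miss) > 0)
    abort("missing metric columns: %s", paste(miss, collapse = ", "))
  if (anyNA(metrics[need])) abort("metrics contain unset (NA) fields")
  hi_hrd <- metrics$hrd_score >= thresholds$hrd_cut
  hi_tmb <- metrics$tmb > thresholds$tmb_cut
  hi_seg <- metrics$scna_count > thresholds$seg_cut
  metrics$subtype <- factor(
    ifelse(hi_hrd, "HRD", ifelse(hi_tmb, "MUT", ifelse(hi_seg, "CN", "GS"))),
    levels = c("HRD", "MUT", "CN", "GS"))
  metrics$dual_flag <- (hi_hrd + hi_tmb + hi_seg) > 1
  metrics
}

#' Association statistics for a 2x2 contingency table
#'
#' For a 2x2 table (rows: groups; columns: e.g. mutated / wild-type)
#' reports row proportions of the first column, the odds ratio `ad/bc`,
#' the uncorrected chi-square statistic by the closed form
#' `N (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))` with its p-value, the
#' Yates-corrected chi-square, and the two-sided Fisher exact p
#' (point-probability method).
#'
#' @param tbl 2x2 matrix of non-negative integer counts.
#' @return list: `row_prop` (fractions), `odds_ratio`, `chisq`, `chisq_p`,
#'   `chisq_yates`, `chisq_yates_p`, `fisher_p`.
#' @export
contingency_stats <- function(tbl) {
  tbl <- as.matrix(tbl)
  if (!all(dim(tbl) == c(2, 2))) abort("need a 2x2 table")
  if (any(tbl < 0) || sum(tbl) == 0) abort("invalid contingency table")
  if (any(rowSums(tbl) == 0)) abort("zero row total: proportions undefined")
  a <- tbl[1, 1]; b <- tbl[1, 2]; c <- tbl[2, 1]; d <- tbl[2, 2]
  n <- sum(tbl)
  chisq <- n * (a * d - b * c)^2 /
    ((a + b) * (c + d) * (a + c) * (b + d))
  yates <- suppressWarnings(stats::chisq.test(tbl, correct = TRUE))
  fisher <- stats::fisher.test(tbl)
  list(row_prop = as.numeric(tbl[, 1] / rowSums(tbl)),
       odds_ratio = (a * d) / (b * c),
       chisq = as.numeric(chisq),
       chisq_p = stats::pchisq(chisq, df = 1, lower.tail = FALSE),
       chisq_yates = as.numeric(yates$statistic),
       chisq_yates_p = yates$p.value,
       fisher_p = fisher$p.value)
}

#' Welch two-sample comparison
#'
#' Welch's unequal-variance t-test between two groups of a per-sample
#' measure. When both groups are constant with equal means the degenerate
#' result `t = 0, p = 1` is returned; constant groups with unequal means
#' give `|t| = Inf, p = 0`.
#'
#' @param values numeric vector.
#' @param labels grouping vector with exactly two levels, each with at
#'   least two observations.
#' @return list `t`, `p`.
#' @export
compare_groups <- function(values, labels) {
  labels <- as.character(labels)
  lev <- unique(labels)
  if (length(lev) != 2) abort("need exactly two groups, got %d", length(lev))
  g1 <- values[labels == lev[1]]
  g2 <- values[labels == lev[2]]
  if (length(g1) < 2 || length(g2) < 2)
    abort("each group needs at least 2 values")
  if (stats::var(g1) == 0 && stats::var(g2) == 0) {
    if (mean(g1) == mean(g2)) return(list(t = 0, p = 1))
    return(list(t = sign(mean(g1) - mean(g2)) * Inf, p = 0))
  }
  fit <- stats::t.test(g1, g2, var.equal = FALSE)
  list(t = as.numeric(fit$statistic), p = fit$p.value)
}

#' Germline-variant inclusion filter
#'
#' Retains, with a reason code:
#' * variants classified pathogenic or likely pathogenic (`P`, `LP`) —
#'   reason `"pathogenic"`;
#' * VUS with a truncating consequence (nonsense, splice, frameshift),
#'   treated as likely pathogenic — reason `"truncating_vus"`;
#' * missense VUS called damaging by both SIFT and PolyPhen — reason
#'   `"damaging_missense_vus"`.
#'
#' Benign / likely benign variants and everything else are dropped. The
#' filter is idempotent and invariant to input order.
#'
#' @param variants data frame with columns `gene`, `class` (P/LP/VUS/LB/B),
#'   `consequence` (nonsense/splice/frameshift/missense/other), `sift`
#'   (damaging/tolerated/absent), `polyphen` (damaging/benign/absent).
#' @return the retained rows with a `reason` column appended.
#' @export
filter_germline <- function(variants) {
  v <- as.data.frame(variants, stringsAsFactors = FALSE)
  v$reason <- NULL
  need <- c("gene", "class", "consequence", "sift", "polyphen")
  if (!all(need %in% names(v)))
    abort("germline table needs columns %s", paste(need, collapse = ", "))
  ok_enum <- function(x, allowed, what) {
    bad <- setdiff(unique(x), allowed)
    if (length(bad) > 0) abort("invalid %s value '%s'", what, bad[1])
  }
  ok_enum(v$class, c("P", "LP", "VUS", "LB", "B"), "class")
  ok_enum(v$consequence, c("nonsense", "splice", "frameshift", "missense",
                           "other"), "consequence")
  ok_enum(v$sift, c("damaging", "tolerated", "absent"), "sift")
  ok_enum(v$polyphen, c("damaging", "benign", "absent"), "polyphen")
  reason <- rep(NA_character_, nrow(v))
  reason[v$class %in% c("P", "LP")] <- "pathogenic"
  trunc <- v$class == "VUS" &
    v$consequence %in% c("nonsense", "splice", "frameshift")
  reason[trunc] <- "truncating_vus"
  dam <- v$class == "VUS" & v$consequence == "missense" &
    v$sift == "damaging" & v$polyphen == "damaging"
  reason[dam & is.na(reason)] <- "damaging_missense_vus"
  out <- v[!is.na(reason), , drop = FALSE]
  out$reason <- reason[!is.na(reason)]
  rownames(out) <- NULL
  out
}
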