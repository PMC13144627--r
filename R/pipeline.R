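#' Per-sample instability summary
#'
#' Computes the quadruple the subtype classifier consumes — HRD scar score,
#' tumor mutational burden, SCNA segment count and SV count — plus the
#' size-stratified copy-number burden, from one sample's inputs.
#'
#' @param profile an `ascn_profile`.
#' @param snvs SNV data frame (may be empty).
#' @param svs SV data frame (may be empty).
#' @param indels indel data frame (counted into TMB; default none).
#' @param build a `genome_build`.
#' @param tmb_mb TMB denominator in Mb (default 2,800).
#' @param include_indels count indels into TMB (default TRUE).
#' @return one-row data frame: `sample`, `ntai`, `lst`, `hrd_loh`,
#'   `hrd_score`, `tmb`, `scna_count`, `small_cn`, `large_cn`, `sv_count`,
#'   `ploidy`, `purity`, `wgd`.
#' @export
sample_instability <- function(profile, snvs = empty_snvs(),
                               svs = empty_svs(), indels = empty_indels(),
                               build = NULL, tmb_mb = 2800,
                               include_indels = TRUE) {
  build <- resolve_build(profile, build)
  scars <- scar_scores(profile, build)
  strat <- size_stratified_counts(profile)
  data.frame(
    scars[c("sample", "ntai", "lst", "hrd_loh", "hrd_score")],
    tmb = tmb(nrow(snvs), if (include_indels) nrow(indels) else 0, tmb_mb),
    scna_count = scna_count(profile),
    small_cn = unname(strat["small_amp"] + strat["small_del"]),
    large_cn = unname(strat["large_amp"] + strat["large_del"]),
    sv_count = nrow(svs),
    scars[c("ploidy", "purity", "wgd")],
    stringsAsFactors = FALSE)
}

#' Score every sample of a cohort
#'
#' Runs the scar metrics and mutation features over a cohort (a
#' [simulate_cohort()] result or any list of samples with `profile`,
#' `snvs`, `svs` elements) and returns the per-sample instability table
#' plus the SBS96, CN48 and SV32 feature matrices.
#'
#' @param cohort a `synthetic_cohort` or compatible list.
#' @param build a `genome_build` (default: the cohort's).
#' @param tmb_mb TMB denominator in Mb.
#' @return list: `metrics` (data frame), `sbs96`, `cn48`, `sv32` (feature
#'   x sample matrices), `kataegis` (per-sample event counts).
#' @export
run_score <- function(cohort, build = NULL, tmb_mb = 2800) {
  samples <- if (inherits(cohort, "synthetic_cohort")) cohort$samples
             else cohort
  if (is.null(build) && inherits(cohort, "synthetic_cohort"))
    build <- cohort$build
  metrics <- list(); sbs <- list(); cn <- list(); sv <- list()
  kat <- integer(length(samples))
  for (i in seq_along(samples)) {
    s <- samples[[i]]
    metrics[[i]] <- sample_instability(s$profile, s$snvs, s$svs,
                                       build = build, tmb_mb = tmb_mb)
    sbs[[i]] <- sbs96_vector(s$snvs)
    cn[[i]] <- cn48_vector(s$profile)
    sv[[i]] <- sv32_vector(s$svs)
    kat[i] <- nrow(detect_kataegis(s$snvs))
  }
  ids <- vapply(metrics, `[[`, character(1), "sample")
  list(metrics = do.call(rbind, c(metrics, list(make.row.names = FALSE))),
       sbs96 = matrix(unlist(sbs), nrow = 96,
                      dimnames = list(sbs96_labels(), ids)),
       cn48 = matrix(unlist(cn), nrow = 48,
                     dimnames = list(cn48_labels(), ids)),
       sv32 = matrix(unlist(sv), nrow = 32,
                     dimnames = list(sv32_labels(), ids)),
       kataegis = stats::setNames(kat, ids))
}

#' Classify a scored cohort and record the run manifest
#'
#' @param scored a [run_score()] result (or a bare metrics data frame).
#' @param thresholds a [derive_thresholds()] object, or `"fixed"` /
#'   `"cohort_mean"` to derive them here.
#' @param manifest_path optional path for a JSON manifest recording the
#'   thresholds and their provenance.
#' @return the metrics data frame with `subtype` and `dual_flag` columns.
#' @export
run_classify <- function(scored, thresholds = "fixed", manifest_path = NULL) {
  metrics <- if (is.data.frame(scored)) scored else scored$metrics
  if (is.null(metrics) || nrow(metrics) == 0) abort("empty cohort")
  if (is.character(thresholds))
    thresholds <- derive_thresholds(metrics, mode = thresholds)
  out <- classify_samples(metrics, thresholds)
  if (!is.null(manifest_path)) {
    jsonlite::write_json(
      list(thresholds = thresholds[c("hrd_cut", "tmb_cut", "seg_cut",
                                     "provenance")],
           n_samples = nrow(out),
           subtype_counts = as.list(table(out$subtype))),
      manifest_path, auto_unbox = TRUE, digits = NA)
  }
  out
}

#' Cohort summary report
#'
#' Text report with per-subtype medians of the four instability measures
#' and, when a binary annotation is supplied, its 2x2 contingency analysis
#' against HRD vs non-HRD subtype ([contingency_stats()]).
#'
#' @param classified a [run_classify()] result.
#' @param annotation optional named logical/character vector (per sample)
#'   of a binary status, e.g. TP53 mutation.
#' @return the report as a character vector (one line per element),
#'   invisibly; printed to the console.
#' @export
run_report <- function(classified, annotation = NULL) {
  lines <- c("Genomic instability cohort report",
             sprintf("%d samples", nrow(classified)), "")
  for (st in levels(classified$subtype)) {
    sub <- classified[classified$subtype == st, , drop = FALSE]
    lines <- c(lines, sprintf(
      "%-3s n=%-3d median HRD score %.0f | TMB %.2f mut/Mb | SCNA %.0f | SV %.0f",
      st, nrow(sub),
      if (nrow(sub)) stats::median(sub$hrd_score) else NA,
      if (nrow(sub)) stats::median(sub$tmb) else NA,
      if (nrow(sub)) stats::median(sub$scna_count) else NA,
      if (nrow(sub)) stats::median(sub$sv_count) else NA))
  }
  if (!is.null(annotation)) {
    ann <- annotation[classified$sample]
    if (anyNA(ann)) abort("annotation missing for some samples")
    if (length(unique(ann)) != 2)
      abort("annotation must be binary (two levels)")
    pos <- ann == sort(unique(ann), decreasing = TRUE)[1]
    is_hrd <- classified$subtype == "HRD"
    tbl <- rbind(c(sum(is_hrd & pos), sum(is_hrd & !pos)),
                 c(sum(!is_hrd & pos), sum(!is_hrd & !pos)))
    st <- contingency_stats(tbl)
    lines <- c(lines, "",
               sprintf("Annotation vs HRD subtype: %.1f%% (%d of %d) vs %.1f%% (%d of %d)",
                       100 * st$row_prop[1], tbl[1, 1], sum(tbl[1, ]),
                       100 * st$row_prop[2], tbl[2, 1], sum(tbl[2, ])),
               sprintf("chi-square %.2f (P = %.3g); Yates %.2f (P = %.3g); Fisher P = %.3g",
                       st$chisq, st$chisq_p, st$chisq_yates, st$chisq_yates_p,
                       st$fisher_p))
  }
  cat(paste(lines, collapse = "\n"), "\n")
  invisible(lines)
}
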