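#' Allele-specific copy-number profiles
#'
#' An `ascn_profile` holds one sample's allele-specific copy-number segments
#' together with tumor purity and ploidy. Segments are 1-based inclusive
#' intervals with integer major/minor allele copies (`minor <= major`);
#' per chromosome they are kept sorted and non-overlapping. Derived per
#' segment: total copy number (`major + minor`), length
#' (`end - start + 1`), and the class flags LOH (`minor == 0, major >= 1`)
#' and homozygous deletion (`major == 0`).
#'
#' @param sample_id sample label.
#' @param segments data frame with columns `chrom`, `start`, `end`, `major`,
#'   `minor`.
#' @param purity tumor cell fraction in (0, 1].
#' @param ploidy average tumor ploidy (> 0).
#' @param build optional `genome_build`; when given, segment chromosomes are
#'   checked against it and it is stored with the profile.
#' @return an object of class `ascn_profile`.
#' @export
ascn_profile <- function(sample_id, segments, purity, ploidy, build = NULL) {
  stopifnot(is.character(sample_id), length(sample_id) == 1)
  if (!is.numeric(purity) || length(purity) != 1 || is.na(purity) ||
      purity <= 0 || purity > 1)
    abort("purity must be in (0, 1], got %s", format(purity))
  if (!is.numeric(ploidy) || length(ploidy) != 1 || is.na(ploidy) || ploidy <= 0)
    abort("ploidy must be positive, got %s", format(ploidy))
  seg <- as.data.frame(segments, stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "major", "minor")
  if (!all(need %in% names(seg)))
    abort("segments need columns %s", paste(need, collapse = ", "))
  seg <- seg[need]
  seg$chrom <- normalize_chrom(seg$chrom)
  for (col in c("start", "end", "major", "minor")) seg[[col]] <- as.numeric(seg[[col]])
  if (nrow(seg) > 0) {
    if (anyNA(seg)) abort("segments contain missing values")
    if (any(seg$start > seg$end)) abort("segment with start > end")
    if (any(seg$major < 0 | seg$minor < 0)) abort("negative allele copies")
    if (any(seg$minor > seg$major)) abort("segment with minor > major")
    if (any(seg$major != round(seg$major) | seg$minor != round(seg$minor)))
      abort("allele copies must be integers")
    if (!is.null(build)) build_lookup(build, seg$chrom)
    ord <- order(match(seg$chrom, unique(seg$chrom)), seg$start)
    seg <- seg[ord, , drop = FALSE]
    rownames(seg) <- NULL
    for (ch in unique(seg$chrom)) {
      s <- seg[seg$chrom == ch, , drop = FALSE]
      if (nrow(s) > 1 && any(s$start[-1] <= s$end[-nrow(s)]))
        abort("overlapping segments on chromosome %s", ch)
    }
  }
  structure(list(sample_id = sample_id, purity = purity, ploidy = ploidy,
                 segments = seg, build = build),
            class = "ascn_profile")
}

#' @export
print.ascn_profile <- function(x, ...) {
  cat(sprintf("<ascn_profile '%s'> %d segments, purity %.2f, ploidy %.2f\n",
              x$sample_id, nrow(x$segments), x$purity, x$ploidy))
  invisible(x)
}

# Segment-level derived quantities
seg_length <- function(seg) seg$end - seg$start + 1
seg_total <- function(seg) seg$major + seg$minor
seg_is_loh <- function(seg) seg$minor == 0 & seg$major >= 1
seg_is_homdel <- function(seg) seg$major == 0

#' Read allele-specific copy-number segments
#'
#' Reads a tab-separated segment file with columns `sample`, `chrom`,
#' `start`, `end`, `nMajor`, `nMinor` into an [ascn_profile()]. Purity and
#' ploidy are taken, in order of precedence, from `purity`/`ploidy` columns
#' in the file, from `##purity=` / `##ploidy=` header lines, or from a
#' sidecar table (columns `sample`, `purity`, `ploidy`). Rows with
#' `nMinor > nMajor` are swapped with a warning (allele labels are
#' symmetric); overlapping segments and unknown chromosomes are errors.
#'
#' @param path segment TSV path.
#' @param build a `genome_build` the segments must live on.
#' @param sidecar optional path to a purity/ploidy TSV.
#' @return a single `ascn_profile` (the file must contain one sample; use
#'   [read_ascn_cohort()] for multi-sample files).
#' @export
read_segments <- function(path, build = read_genome_build(), sidecar = NULL) {
  profiles <- read_ascn_cohort(path, build, sidecar)
  if (length(profiles) != 1)
    abort("'%s' contains %d samples; read_ascn_cohort() reads multi-sample files",
          path, length(profiles))
  profiles[[1]]
}

#' Read a multi-sample segment file
#'
#' @inheritParams read_segments
#' @return named list of `ascn_profile` objects.
#' @export
read_ascn_cohort <- function(path, build = read_genome_build(), sidecar = NULL) {
  lines <- readLines(path)
  hdr <- grep("^##", lines, value = TRUE)
  meta <- list()
  for (h in hdr) {
    kv <- sub("^##", "", h)
    key <- sub("=.*", "", kv)
    meta[[key]] <- as.numeric(sub(".*=", "", kv))
  }
  tab <- tryCatch(
    utils::read.table(text = lines[!grepl("^##", lines)], header = TRUE,
                      sep = "\t", stringsAsFactors = FALSE),
    error = function(e) abort("cannot parse segment file '%s': %s", path,
                              conditionMessage(e)))
  need <- c("sample", "chrom", "start", "end", "nMajor", "nMinor")
  if (!all(need %in% names(tab)))
    abort("segment file '%s' must have columns %s", path,
          paste(need, collapse = ", "))
  swap <- tab$nMinor > tab$nMajor
  if (any(swap)) {
    warning(sprintf("%d segment(s) with nMinor > nMajor: allele labels swapped",
                    sum(swap)), call. = FALSE)
    tmp <- tab$nMajor[swap]
    tab$nMajor[swap] <- tab$nMinor[swap]
    tab$nMinor[swap] <- tmp
  }
  side <- NULL
  if (!is.null(sidecar)) {
    side <- utils::read.table(sidecar, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE)
    if (!all(c("sample", "purity", "ploidy") %in% names(side)))
      abort("sidecar '%s' must have columns sample, purity, ploidy", sidecar)
  }
  out <- list()
  for (sid in unique(tab$sample)) {
    rows <- tab[tab$sample == sid, , drop = FALSE]
    if (all(c("purity", "ploidy") %in% names(rows))) {
      purity <- rows$purity[1]; ploidy <- rows$ploidy[1]
    } else if (!is.null(side) && sid %in% side$sample) {
      i <- match(sid, side$sample)
      purity <- side$purity[i]; ploidy <- side$ploidy[i]
    } else if (!is.null(meta$purity) && !is.null(meta$ploidy)) {
      purity <- meta$purity; ploidy <- meta$ploidy
    } else {
      abort("no purity/ploidy for sample '%s' (columns, ## header, or sidecar)",
            sid)
    }
    out[[sid]] <- ascn_profile(
      sid,
      data.frame(chrom = rows$chrom, start = rows$start, end = rows$end,
                 major = rows$nMajor, minor = rows$nMinor,
                 stringsAsFactors = FALSE),
      purity = purity, ploidy = ploidy, build = build)
  }
  out
}

#' Write segment profiles to a TSV
#'
#' Inverse of [read_segments()] / [read_ascn_cohort()]: writes `sample`,
#' `chrom`, `start`, `end`, `nMajor`, `nMinor`, `purity`, `ploidy` columns.
#'
#' @param profiles an `ascn_profile` or list of them.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_segments <- function(profiles, path) {
  if (inherits(profiles, "ascn_profile")) profiles <- list(profiles)
  tabs <- lapply(profiles, function(p) {
    if (nrow(p$segments) == 0) return(NULL)
    data.frame(sample = p$sample_id, chrom = p$segments$chrom,
               start = p$segments$start, end = p$segments$end,
               nMajor = p$segments$major, nMinor = p$segments$minor,
               purity = p$purity, ploidy = p$ploidy,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, tabs)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
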