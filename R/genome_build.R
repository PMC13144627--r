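#' Genome build tables
#'
#' A genome build is a data frame with one row per chromosome and columns
#' `chrom`, `length`, `cen_start`, `cen_end` (1-based bp). A table for the
#' hg19 autosomes plus X is bundled and used when `path` is omitted. The
#' Y chromosome and the mitochondrion are excluded by default; supply your
#' own table to change that.
#'
#' @param path path to a tab-separated file with columns `chrom`, `length`,
#'   `cen_start`, `cen_end`. If `NULL`, the bundled hg19 table is used.
#' @param name label for the build (default `"hg19"` for the bundled table,
#'   otherwise the file name).
#' @return an object of class `genome_build`.
#' @examples
#' build <- read_genome_build()
#' nrow(build)  # 23 chromosomes: 1-22, X
#' @export
read_genome_build <- function(path = NULL, name = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "hg19_build.tsv", package = "gitax")
    if (is.null(name)) name <- "hg19"
  }
  if (is.null(name)) name <- basename(path)
  tab <- tryCatch(
    utils::read.table(path, header = TRUE, sep = "\t",
                      colClasses = c("character", "numeric", "numeric",
                                     "numeric"),
                      stringsAsFactors = FALSE),
    error = function(e) abort("cannot parse genome build table '%s': %s",
                              path, conditionMessage(e)))
  need <- c("chrom", "length", "cen_start", "cen_end")
  if (!all(need %in% names(tab)))
    abort("genome build table must have columns %s", paste(need, collapse = ", "))
  if (anyNA(tab[need]))
    abort("genome build table '%s' has malformed rows (NA after parsing)", path)
  genome_build(tab$chrom, tab$length, tab$cen_start, tab$cen_end, name = name)
}

#' Construct a genome build
#'
#' @param chrom chromosome names (unique; `chr` prefixes are stripped).
#' @param length chromosome lengths in bp.
#' @param cen_start,cen_end centromere interval, 1-based bp, strictly inside
#'   the chromosome.
#' @param name build label.
#' @return an object of class `genome_build`.
#' @export
genome_build <- function(chrom, length, cen_start, cen_end, name = "custom") {
  chrom <- normalize_chrom(chrom)
  if (anyDuplicated(chrom))
    abort("duplicate chromosome names in genome build")
  bad <- which(!(length > 0 & cen_start > 0 & cen_start < cen_end &
                   cen_end < length))
  if (length(bad) > 0)
    abort("invalid chromosome row %d ('%s'): need 0 < cen_start < cen_end < length",
          bad[1], chrom[bad[1]])
  out <- data.frame(chrom = chrom, length = as.numeric(length),
                    cen_start = as.numeric(cen_start),
                    cen_end = as.numeric(cen_end),
                    stringsAsFactors = FALSE)
  attr(out, "build_name") <- name
  class(out) <- c("genome_build", "data.frame")
  out
}

#' @export
print.genome_build <- function(x, ...) {
  cat(sprintf("<genome_build '%s'> %d chromosomes, %.2f Gb\n",
              attr(x, "build_name"), nrow(x), sum(x$length) / 1e9))
  invisible(x)
}

#' Total genome size in megabases
#'
#' @param build a `genome_build`.
#' @return total chromosome length in Mb.
#' @export
genome_mb <- function(build) sum(build$length) / 1e6

# Chromosome arms: p = [1, cen_start], q = [cen_end, length].
genome_arms <- function(build) {
  data.frame(
    chrom = rep(build$chrom, 2),
    arm = rep(c("p", "q"), each = nrow(build)),
    start = c(rep(1, nrow(build)), build$cen_end),
    end = c(build$cen_start, build$length),
    stringsAsFactors = FALSE)
}

build_lookup <- function(build, chrom) {
  i <- match(normalize_chrom(chrom), build$chrom)
  if (anyNA(i))
    abort("chromosome '%s' not in genome build",
          normalize_chrom(chrom)[which(is.na(i))[1]])
  i
}
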