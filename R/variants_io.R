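#' Read SNVs and indels from a VCF
#'
#' Parses a VCF 4.x file, splits multi-allelic records, and partitions
#' records into SNVs (both alleles single bases) and indels (allele lengths
#' differ). A trinucleotide context may be carried in an INFO key (default
#' `TNC`); when present its middle base must equal the reference allele.
#'
#' @param path VCF path (plain or bgzipped).
#' @param context_key INFO key holding the reference-strand 3-mer context.
#' @return a list with data frames `snvs` (`chrom`, `pos`, `ref`, `alt`,
#'   `context`) and `indels` (`chrom`, `pos`, `ref`, `alt`).
#' @export
read_snvs_vcf <- function(path, context_key = "TNC") {
  v <- suppressWarnings(vcfR::read.vcfR(path, verbose = FALSE))
  fix <- as.data.frame(vcfR::getFIX(v, getINFO = TRUE),
                       stringsAsFactors = FALSE)
  if (nrow(fix) == 0)
    return(list(snvs = empty_snvs(), indels = empty_indels()))
  info <- fix$INFO
  if (is.null(info)) info <- rep(NA_character_, nrow(fix))
  # split multi-allelic ALT
  alts <- strsplit(fix$ALT, ",", fixed = TRUE)
  n <- lengths(alts)
  idx <- rep(seq_len(nrow(fix)), n)
  rec <- data.frame(chrom = normalize_chrom(fix$CHROM[idx]),
                    pos = as.numeric(fix$POS[idx]),
                    ref = toupper(fix$REF[idx]),
                    alt = toupper(unlist(alts)),
                    info = info[idx],
                    stringsAsFactors = FALSE)
  ctx <- rep(NA_character_, nrow(rec))
  if (!is.null(context_key)) {
    pat <- paste0("(^|;)", context_key, "=([^;]+)")
    hit <- regexpr(pat, rec$info)
    has <- !is.na(hit) & hit > 0
    ctx[has] <- sub(paste0(".*(^|;)", context_key, "=([^;]+).*"), "\\2",
                    rec$info[has])
    ctx <- toupper(ctx)
  }
  is_snv <- nchar(rec$ref) == 1 & nchar(rec$alt) == 1 &
    rec$ref %in% BASES & rec$alt %in% BASES & rec$ref != rec$alt
  is_indel <- nchar(rec$ref) != nchar(rec$alt)
  bad_ctx <- is_snv & !is.na(ctx) &
    (nchar(ctx) != 3 | substr(ctx, 2, 2) != rec$ref)
  if (any(bad_ctx))
    abort("context '%s' at %s:%d does not match ref allele %s",
          ctx[bad_ctx][1], rec$chrom[bad_ctx][1], rec$pos[bad_ctx][1],
          rec$ref[bad_ctx][1])
  ctx[grepl("N", ctx, fixed = TRUE)] <- NA_character_
  snvs <- data.frame(chrom = rec$chrom[is_snv], pos = rec$pos[is_snv],
                     ref = rec$ref[is_snv], alt = rec$alt[is_snv],
                     context = ctx[is_snv], stringsAsFactors = FALSE)
  indels <- data.frame(chrom = rec$chrom[is_indel], pos = rec$pos[is_indel],
                       ref = rec$ref[is_indel], alt = rec$alt[is_indel],
                       stringsAsFactors = FALSE)
  list(snvs = snvs, indels = indels)
}

empty_snvs <- function() {
  data.frame(chrom = character(), pos = numeric(), ref = character(),
             alt = character(), context = character(), stringsAsFactors = FALSE)
}
empty_indels <- function() {
  data.frame(chrom = character(), pos = numeric(), ref = character(),
             alt = character(), stringsAsFactors = FALSE)
}

#' Write SNVs to a minimal VCF
#'
#' Emits a minimal VCF 4.2 with the trinucleotide context (when present) in
#' the `TNC` INFO key, so files round-trip through [read_snvs_vcf()].
#'
#' @param snvs SNV data frame (`chrom`, `pos`, `ref`, `alt`, `context`).
#' @param path output path.
#' @param sample_id sample name recorded in the header.
#' @return `path`, invisibly.
#' @export
write_snvs_vcf <- function(snvs, path, sample_id = "sample") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               sprintf("##source=gitax; sample=%s", sample_id),
               "##INFO=<ID=TNC,Number=1,Type=String,Description=\"Trinucleotide context, reference strand\">",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  if (nrow(snvs) > 0) {
    info <- ifelse(is.na(snvs$context) | !nzchar(snvs$context), ".",
                   paste0("TNC=", snvs$context))
    writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t%s",
                       snvs$chrom, as.integer(snvs$pos), snvs$ref, snvs$alt,
                       info), con)
  }
  invisible(path)
}

#' Read structural variants from BEDPE
#'
#' Standard 10+ column BEDPE; breakpoint positions are converted from
#' 0-based starts to 1-based (`pos = start + 1`). The SV type (DEL, DUP,
#' INV, TRA) is taken from `svtype_col` (default column 11). Interchromosomal
#' records must be typed TRA and get an undefined (`NA`) size; intrachromosomal
#' records must not be TRA and get `size = |pos2 - pos1|`.
#'
#' @param path BEDPE path.
#' @param svtype_col column index holding the SV type.
#' @return data frame `chrom1`, `pos1`, `chrom2`, `pos2`, `svtype`, `size`.
#' @export
read_svs_bedpe <- function(path, svtype_col = 11) {
  tab <- tryCatch(
    utils::read.table(path, header = FALSE, sep = "\t",
                      stringsAsFactors = FALSE),
    error = function(e) {
      if (grepl("no lines available", conditionMessage(e)))
        return(NULL)
      abort("cannot parse BEDPE '%s': %s", path, conditionMessage(e))
    })
  if (is.null(tab) || nrow(tab) == 0) return(empty_svs())
  if (ncol(tab) < svtype_col)
    abort("BEDPE '%s' has %d columns; svtype expected in column %d", path,
          ncol(tab), svtype_col)
  svs <- data.frame(chrom1 = normalize_chrom(tab[[1]]),
                    pos1 = as.numeric(tab[[2]]) + 1,
                    chrom2 = normalize_chrom(tab[[4]]),
                    pos2 = as.numeric(tab[[5]]) + 1,
                    svtype = toupper(as.character(tab[[svtype_col]])),
                    stringsAsFactors = FALSE)
  validate_svs(svs)
}

validate_svs <- function(svs) {
  if (!all(svs$svtype %in% c("DEL", "DUP", "INV", "TRA")))
    abort("unknown svtype '%s'",
          setdiff(svs$svtype, c("DEL", "DUP", "INV", "TRA"))[1])
  inter <- svs$chrom1 != svs$chrom2
  if (any(inter & svs$svtype != "TRA"))
    abort("interchromosomal record typed %s; must be TRA",
          svs$svtype[inter & svs$svtype != "TRA"][1])
  if (any(!inter & svs$svtype == "TRA"))
    abort("intrachromosomal record typed TRA")
  svs$size <- ifelse(inter, NA_real_, abs(svs$pos2 - svs$pos1))
  svs
}

empty_svs <- function() {
  data.frame(chrom1 = character(), pos1 = numeric(), chrom2 = character(),
             pos2 = numeric(), svtype = character(), size = numeric(),
             stringsAsFactors = FALSE)
}

#' Write structural variants to BEDPE
#'
#' Inverse of [read_svs_bedpe()]: 1-based breakpoints become 0-based
#' single-bp intervals, svtype in column 11.
#'
#' @param svs SV data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_svs_bedpe <- function(svs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(svs) > 0)
    writeLines(sprintf("%s\t%d\t%d\t%s\t%d\t%d\t.\t.\t+\t+\t%s",
                       svs$chrom1, as.integer(svs$pos1) - 1L,
                       as.integer(svs$pos1), svs$chrom2,
                       as.integer(svs$pos2) - 1L, as.integer(svs$pos2),
                       svs$svtype), con)
  invisible(path)
}

#' Fill trinucleotide contexts from a reference FASTA
#'
#' Looks up the reference-strand 3-mer centred on each SNV position. The
#' reference base at the position must equal the record's ref allele;
#' contexts containing N are left absent and the record retained.
#'
#' @param snvs SNV data frame.
#' @param reference path to a FASTA file covering the SNV chromosomes.
#' @param only_missing fill only records whose context is absent.
#' @return the SNV data frame with `context` filled.
#' @export
fetch_context <- function(snvs, reference, only_missing = TRUE) {
  if (nrow(snvs) == 0) return(snvs)
  fa <- Biostrings::readDNAStringSet(reference)
  names(fa) <- normalize_chrom(sub("\\s.*", "", names(fa)))
  todo <- if (only_missing) which(is.na(snvs$context)) else seq_len(nrow(snvs))
  for (i in todo) {
    ch <- snvs$chrom[i]
    if (!ch %in% names(fa)) abort("chromosome '%s' not in reference", ch)
    len <- length(fa[[ch]])
    p <- snvs$pos[i]
    if (p < 2 || p > len - 1)
      abort("position %s:%d too close to the contig edge for a 3-mer", ch, p)
    ctx <- toupper(as.character(Biostrings::subseq(fa[[ch]], p - 1, p + 1)))
    if (substr(ctx, 2, 2) == "N") next  # context-less, record retained
    if (substr(ctx, 2, 2) != snvs$ref[i])
      abort("reference base %s at %s:%d does not match ref allele %s",
            substr(ctx, 2, 2), ch, p, snvs$ref[i])
    if (!grepl("N", ctx, fixed = TRUE)) snvs$context[i] <- ctx
  }
  snvs
}
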