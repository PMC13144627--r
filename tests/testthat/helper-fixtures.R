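# Shared fixtures: a small 3-chromosome toy build, random profile/catalog
# generators, and synthetic signature matrices. Everything is built in code.

toy_build <- function() {
  genome_build(chrom = c("1", "2", "3"),
               length = c(200e6, 150e6, 100e6),
               cen_start = c(80e6, 60e6, 40e6),
               cen_end = c(85e6, 64e6, 44e6),
               name = "toy3")
}

# Random valid profile on the toy build: up to max_seg segments per
# chromosome, random states (possibly equal neighbours), random gaps.
random_profile <- function(build = toy_build(), max_seg = 10,
                           sample_id = "rand") {
  segs <- list()
  for (ci in seq_len(nrow(build))) {
    n <- sample(0:max_seg, 1)
    if (n == 0) next
    # 2n sorted breakpoints -> n candidate intervals, some dropped as gaps
    bp <- sort(sample.int(build$length[ci], 2 * n))
    starts <- bp[seq(1, 2 * n, 2)]
    ends <- pmax(bp[seq(2, 2 * n, 2)], starts)
    keep <- stats::runif(n) < 0.8
    if (!any(keep)) next
    major <- sample(0:3, sum(keep), replace = TRUE)
    minor <- vapply(major, function(m) sample(0:m, 1), integer(1))
    segs[[ci]] <- data.frame(chrom = build$chrom[ci],
                             start = starts[keep], end = ends[keep],
                             major = major, minor = minor,
                             stringsAsFactors = FALSE)
  }
  seg <- if (length(segs)) do.call(rbind, segs)
  else data.frame(chrom = character(), start = numeric(), end = numeric(),
                  major = numeric(), minor = numeric())
  ascn_profile(sample_id, seg, purity = 0.8, ploidy = 2, build = build)
}

# Two synthetic signatures with disjoint support (first/last 48 channels).
disjoint_signatures <- function() {
  m <- cbind(sigA = c(rep(1 / 48, 48), rep(0, 48)),
             sigB = c(rep(0, 48), rep(1 / 48, 48)))
  rownames(m) <- sbs96_labels()
  m
}

# Random SNV catalog with valid contexts (a fraction context-less).
random_snvs <- function(n, p_missing = 0.2) {
  if (n == 0) return(gitax:::empty_snvs())
  cls <- sample(sbs96_labels(), n, replace = TRUE)
  ref <- substr(cls, 3, 3)
  alt <- substr(cls, 5, 5)
  ctx <- paste0(substr(cls, 1, 1), ref, substr(cls, 7, 7))
  # randomly present some records on the purine strand
  flip <- stats::runif(n) < 0.5
  ref[flip] <- chartr("CT", "GA", ref[flip])
  alt[flip] <- chartr("ACGT", "TGCA", alt[flip])
  ctx[flip] <- vapply(strsplit(chartr("ACGT", "TGCA", ctx[flip]), ""),
                      function(s) paste(rev(s), collapse = ""), character(1))
  ctx[stats::runif(n) < p_missing] <- NA_character_
  data.frame(chrom = "1", pos = sort(sample.int(1e8, n)), ref = ref,
             alt = alt, context = ctx, stringsAsFactors = FALSE)
}

# Random SV list on the toy build.
random_svs <- function(n, build = toy_build()) {
  out <- list()
  for (i in seq_len(n)) {
    ty <- sample(c("DEL", "DUP", "INV", "TRA"), 1)
    if (ty == "TRA") {
      cc <- sample(build$chrom, 2)
      out[[i]] <- data.frame(chrom1 = cc[1],
                             pos1 = sample.int(90e6, 1),
                             chrom2 = cc[2],
                             pos2 = sample.int(90e6, 1),
                             svtype = "TRA", size = NA_real_)
    } else {
      ch <- sample(build$chrom, 1)
      p1 <- sample.int(50e6, 1)
      size <- round(exp(stats::runif(1, log(1e3), log(2e7))))
      out[[i]] <- data.frame(chrom1 = ch, pos1 = p1, chrom2 = ch,
                             pos2 = p1 + size, svtype = ty, size = size)
    }
  }
  if (n == 0) return(gitax:::empty_svs())
  do.call(rbind, out)
}
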