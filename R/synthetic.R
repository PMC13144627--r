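# Approximate genome-wide trinucleotide background for context simulation:
# independent base frequencies (A/T 0.295, C/G 0.205) with CpG dinucleotides
# depleted 4-fold, collapsed to the 32 pyrimidine-centred 3-mers. A coarse
# model of hg19 composition; see the methods vignette for what it does and
# does not emulate.
trinuc_background <- function() {
  f <- c(A = 0.295, C = 0.205, G = 0.205, T = 0.295)
  grid <- expand.grid(p5 = BASES, mid = c("C", "T"), p3 = BASES,
                      stringsAsFactors = FALSE)
  w <- f[grid$p5] * f[grid$mid] * f[grid$p3]
  cpg <- (grid$mid == "C" & grid$p3 == "G") | (grid$p5 == "C" & grid$mid == "G")
  w[cpg] <- w[cpg] * 0.25
  stats::setNames(w / sum(w), paste0(grid$p5, grid$mid, grid$p3))
}

#' Archetype parameters for the synthetic-cohort generator
#'
#' Default event rates for the four genomic-instability archetypes the
#' generator emulates:
#' * `HRD` — high ploidy (mean 3.2), 25 large-scale transitions, 15
#'   telomeric allelic imbalances, 20 large (>15 Mb) LOH segments;
#' * `MUT` — hypermutated: 4 mut/Mb, 30% APOBEC TCW weight, 8 kataegis foci;
#' * `CN` — near-diploid with 3,000 small focal LOH segments;
#' * `GS` — quiet genome, all event counts low.
#'
#' @param archetype one of `"HRD"`, `"MUT"`, `"CN"`, `"GS"`.
#' @param ... named overrides of individual fields.
#' @return list of class `archetype_params`.
#' @export
archetype_params <- function(archetype = c("HRD", "MUT", "CN", "GS"), ...) {
  archetype <- match.arg(archetype)
  p <- switch(archetype,
    HRD = list(ploidy_mean = 3.2, ploidy_sd = 0.3, n_large_transitions = 25,
               n_telomeric_ai = 15, n_loh_large = 20, n_loh_small = 0,
               loh_small_len_range = c(1e5, 1e7), snv_rate = 1.5,
               apobec_weight = 0.05, n_kataegis_foci = 0,
               n_sv = c(DEL = 80, DUP = 30, INV = 25, TRA = 15),
               sv_clustered_frac = 0.1),
    MUT = list(ploidy_mean = 2.0, ploidy_sd = 0.1, n_large_transitions = 2,
               n_telomeric_ai = 2, n_loh_large = 1, n_loh_small = 20,
               loh_small_len_range = c(1e5, 1e7), snv_rate = 4,
               apobec_weight = 0.3, n_kataegis_foci = 8,
               n_sv = c(DEL = 15, DUP = 10, INV = 8, TRA = 7),
               sv_clustered_frac = 0.3),
    CN = list(ploidy_mean = 2.0, ploidy_sd = 0.1, n_large_transitions = 2,
              n_telomeric_ai = 1, n_loh_large = 2, n_loh_small = 3000,
              loh_small_len_range = c(1e5, 1e6), snv_rate = 1.0,
              apobec_weight = 0.05, n_kataegis_foci = 0,
              n_sv = c(DEL = 10, DUP = 8, INV = 6, TRA = 6),
              sv_clustered_frac = 0),
    GS = list(ploidy_mean = 2.0, ploidy_sd = 0.1, n_large_transitions = 1,
              n_telomeric_ai = 1, n_loh_large = 1, n_loh_small = 10,
              loh_small_len_range = c(1e5, 1e6), snv_rate = 0.5,
              apobec_weight = 0.05, n_kataegis_foci = 0,
              n_sv = c(DEL = 4, DUP = 3, INV = 2, TRA = 1),
              sv_clustered_frac = 0))
  p$archetype <- archetype
  over <- list(...)
  bad <- setdiff(names(over), names(p))
  if (length(bad) > 0) abort("unknown archetype parameter '%s'", bad[1])
  p[names(over)] <- over
  counts <- c(p$n_large_transitions, p$n_telomeric_ai, p$n_loh_large,
              p$n_loh_small, p$n_kataegis_foci, p$n_sv)
  if (any(counts < 0)) abort("event counts must be non-negative")
  if (p$apobec_weight < 0 || p$apobec_weight > 1 ||
      p$sv_clustered_frac < 0 || p$sv_clustered_frac > 1)
    abort("fractions must be in [0, 1]")
  class(p) <- "archetype_params"
  p
}

# Overlap check against occupied intervals expanded by `buffer`.
interval_free <- function(start, end, occupied, buffer) {
  if (length(occupied) == 0) return(TRUE)
  !any(vapply(occupied, function(o)
    start <= o[2] + buffer && end >= o[1] - buffer, logical(1)))
}

#' Simulate an allele-specific copy-number profile
#'
#' Places the requested numbers of large-scale transitions (a >= 10 Mb
#' altered block abutting the centromere, producing exactly one arm-level
#' state change against the background), telomeric allelic-imbalance
#' blocks, large interstitial LOH segments (> 15 Mb), and small focal LOH
#' segments (lengths log-uniform over `loh_small_len_range`, kept clear of
#' telomeres) on randomly chosen arms without overlap. The background is
#' the heterozygous state nearest the drawn ploidy, tiled over everything
#' not occupied by an event. Placement is rejection sampling with a
#' 1,000-attempt cap per event; exceeding genome capacity is an error
#' naming the binding constraint. Deterministic given `seed`.
#'
#' @param params an [archetype_params()] object.
#' @param build a `genome_build`.
#' @param seed integer seed.
#' @param sample_id sample label.
#' @return an [ascn_profile()].
#' @export
simulate_profile <- function(params, build, seed, sample_id = "synthetic") {
  withr::with_seed(seed, sim_profile_impl(params, build, sample_id))
}

sim_profile_impl <- function(params, build, sample_id) {
  buffer <- 10.5e6   # background flank preserved around large events
  tel_margin <- 2e6  # keep small focal events away from telomeres
  min_gap <- 1e5
  ploidy <- max(1.6, stats::rnorm(1, params$ploidy_mean, params$ploidy_sd))
  bg_total <- round(ploidy)
  bg <- c(ceiling(bg_total / 2), floor(bg_total / 2))
  arms <- genome_arms(build)
  arms$len <- arms$end - arms$start + 1
  occ <- vector("list", nrow(arms))          # occupied intervals per arm
  slot <- matrix(FALSE, nrow(arms), 2,
                 dimnames = list(NULL, c("tel", "cen")))
  events <- list()

  place_anchored <- function(n, len_range, state, anchor, what) {
    for (e in seq_len(n)) {
      L <- round(stats::runif(1, len_range[1], len_range[2]))
      done <- FALSE
      for (attempt in seq_len(1000)) {
        a <- sample.int(nrow(arms), 1)
        if (slot[a, anchor]) next
        tel_side <- (arms$arm[a] == "p") == (anchor == "tel")
        blk <- if (tel_side) c(arms$start[a], arms$start[a] + L - 1)
               else c(arms$end[a] - L + 1, arms$end[a])
        if (blk[1] < arms$start[a] || blk[2] > arms$end[a]) next
        # keep a full background flank between the block and the far arm end
        room <- if (tel_side) arms$end[a] - blk[2] else blk[1] - arms$start[a]
        if (room < buffer) next
        if (!interval_free(blk[1], blk[2], occ[[a]], buffer)) next
        occ[[a]][[length(occ[[a]]) + 1]] <<- blk
        slot[a, anchor] <<- TRUE
        events[[length(events) + 1]] <<- data.frame(
          chrom = arms$chrom[a], start = blk[1], end = blk[2],
          major = state[1], minor = state[2], stringsAsFactors = FALSE)
        done <- TRUE
        break
      }
      if (!done)
        abort("genome capacity exceeded placing %s event %d of %d", what, e, n)
    }
  }

  place_interstitial <- function(n, len_range, state, what) {
    for (e in seq_len(n)) {
      L <- round(stats::runif(1, len_range[1], len_range[2]))
      done <- FALSE
      for (attempt in seq_len(1000)) {
        a <- sample.int(nrow(arms), 1, prob = arms$len)
        lo <- arms$start[a] + buffer
        hi <- arms$end[a] - buffer - L
        if (hi <= lo) next
        s <- round(stats::runif(1, lo, hi))
        if (!interval_free(s, s + L - 1, occ[[a]], buffer)) next
        occ[[a]][[length(occ[[a]]) + 1]] <<- c(s, s + L - 1)
        events[[length(events) + 1]] <<- data.frame(
          chrom = arms$chrom[a], start = s, end = s + L - 1,
          major = state[1], minor = state[2], stringsAsFactors = FALSE)
        done <- TRUE
        break
      }
      if (!done)
        abort("genome capacity exceeded placing %s event %d of %d", what, e, n)
    }
  }

  trans_state <- c(bg[1] + 1, bg[2])
  place_anchored(params$n_large_transitions, c(10e6, 14e6), trans_state,
                 "cen", "large-transition")
  place_anchored(params$n_telomeric_ai, c(12e6, 18e6), trans_state,
                 "tel", "telomeric-AI")
  place_interstitial(params$n_loh_large, c(16e6, 24e6), c(max(bg[1], 1), 0),
                     "large-LOH")

  # small focal LOH: capacity-weighted assignment to free intervals, then
  # order-statistics placement inside each interval
  if (params$n_loh_small > 0) {
    free <- list()
    free_chrom <- character()
    add_free <- function(ch, lo, hi) {
      free[[length(free) + 1]] <<- c(lo, hi)
      free_chrom[length(free_chrom) + 1] <<- ch
    }
    for (a in seq_len(nrow(arms))) {
      lo <- arms$start[a] + if (arms$arm[a] == "p") tel_margin else min_gap
      hi <- arms$end[a] - if (arms$arm[a] == "q") tel_margin else min_gap
      pts <- occ[[a]]
      pts <- pts[order(vapply(pts, `[`, numeric(1), 1))]
      cur <- lo
      for (o in pts) {
        if (o[1] - min_gap - 1 >= cur)
          add_free(arms$chrom[a], cur, o[1] - min_gap - 1)
        cur <- max(cur, o[2] + min_gap + 1)
      }
      if (hi >= cur) add_free(arms$chrom[a], cur, hi)
    }
    wide <- vapply(free, function(x) x[2] - x[1] + 1, numeric(1)) > 2 * min_gap
    free <- free[wide]
    free_chrom <- free_chrom[wide]
    cap <- vapply(free, function(x) x[2] - x[1] + 1, numeric(1))
    lr <- params$loh_small_len_range
    lens <- round(exp(stats::runif(params$n_loh_small, log(lr[1]), log(lr[2]))))
    assign_iv <- integer(params$n_loh_small)
    remaining <- cap
    for (k in seq_len(params$n_loh_small)) {
      ok <- remaining >= lens[k] + min_gap
      if (!any(ok))
        abort("genome capacity exceeded placing small-LOH event %d of %d",
              k, params$n_loh_small)
      iv <- sample.int(length(free), 1, prob = remaining * ok)
      if (!ok[iv]) iv <- which(ok)[sample.int(sum(ok), 1)]
      assign_iv[k] <- iv
      remaining[iv] <- remaining[iv] - lens[k] - min_gap
    }
    for (iv in unique(assign_iv)) {
      ks <- which(assign_iv == iv)
      li <- lens[ks]
      k <- length(ks)
      span <- cap[iv]
      slack <- span - sum(li) - (k - 1) * min_gap
      u <- sort(stats::runif(k, 0, slack))
      starts <- free[[iv]][1] + round(u) +
        c(0, cumsum(li[-k] + min_gap))
      events[[length(events) + 1]] <- data.frame(
        chrom = free_chrom[iv], start = starts, end = starts + li - 1,
        major = 1, minor = 0, stringsAsFactors = FALSE)
    }
  }

  ev <- if (length(events) > 0)
    do.call(rbind, c(events, list(make.row.names = FALSE)))
  else data.frame(chrom = character(), start = numeric(), end = numeric(),
                  major = numeric(), minor = numeric(), stringsAsFactors = FALSE)

  # background tiling: complement of events on every chromosome (vectorized)
  seg <- list()
  for (ci in seq_len(nrow(build))) {
    ch <- build$chrom[ci]
    e <- ev[ev$chrom == ch, , drop = FALSE]
    e <- e[order(e$start), , drop = FALSE]
    gap_start <- c(1, e$end + 1)
    gap_end <- c(e$start - 1, build$length[ci])
    ok <- gap_start <= gap_end
    chrom_seg <- data.frame(
      chrom = ch,
      start = c(e$start, gap_start[ok]),
      end = c(e$end, gap_end[ok]),
      major = c(e$major, rep(bg[1], sum(ok))),
      minor = c(e$minor, rep(bg[2], sum(ok))),
      stringsAsFactors = FALSE)
    seg[[ci]] <- chrom_seg[order(chrom_seg$start), , drop = FALSE]
  }
  segments <- do.call(rbind, c(seg, list(make.row.names = FALSE)))
  ascn_profile(sample_id, segments, purity = stats::runif(1, 0.4, 0.95),
               ploidy = ploidy, build = build)
}

#' Simulate a somatic SNV catalog
#'
#' Draws `snv_rate x genome Mb` SNVs uniformly over the genome. With
#' probability `apobec_weight` a record is forced into one of the four
#' APOBEC TCW classes (T\[C>G\]A, T\[C>G\]T, T\[C>T\]A, T\[C>T\]T, equal
#' mass); otherwise its context is drawn from an approximate genome
#' trinucleotide background with a uniformly chosen alternate allele.
#' Kataegis foci are planted as runs of 6-20 TCW-class SNVs with
#' consecutive spacing uniform on \[10, 80\] bp. Contexts are attached at
#' generation, so no reference FASTA is needed downstream.
#'
#' @param params an [archetype_params()] object.
#' @param build a `genome_build`.
#' @param seed integer seed.
#' @return SNV data frame (`chrom`, `pos`, `ref`, `alt`, `context`).
#' @export
simulate_snvs <- function(params, build, seed) {
  withr::with_seed(seed, sim_snvs_impl(params, build))
}

apobec_classes <- function() {
  data.frame(ref = "C", alt = c("G", "G", "T", "T"),
             context = c("TCA", "TCT", "TCA", "TCT"), stringsAsFactors = FALSE)
}

sim_snvs_impl <- function(params, build) {
  n <- round(params$snv_rate * genome_mb(build))
  bgw <- trinuc_background()
  recs <- list()
  if (n > 0) {
    ci <- sample.int(nrow(build), n, replace = TRUE, prob = build$length)
    pos <- floor(stats::runif(n, 2, build$length[ci] - 1))
    is_ap <- stats::runif(n) < params$apobec_weight
    ctx <- character(n); ref <- character(n); alt <- character(n)
    n_ap <- sum(is_ap)
    if (n_ap > 0) {
      cl <- apobec_classes()[sample.int(4, n_ap, replace = TRUE), ]
      ctx[is_ap] <- cl$context; ref[is_ap] <- cl$ref; alt[is_ap] <- cl$alt
    }
    n_bg <- sum(!is_ap)
    if (n_bg > 0) {
      tri <- names(bgw)[sample.int(length(bgw), n_bg, replace = TRUE,
                                   prob = bgw)]
      mid <- substr(tri, 2, 2)
      alt_bg <- vapply(mid, function(r)
        sample(setdiff(BASES, r), 1), character(1))
      # keep the background out of the four TCW channels so apobec_weight
      # is the TCW fraction of the catalog, not just a lower bound
      tcw <- tri %in% c("TCA", "TCT") & alt_bg %in% c("G", "T")
      alt_bg[tcw] <- "A"
      ctx[!is_ap] <- tri; ref[!is_ap] <- mid; alt[!is_ap] <- alt_bg
    }
    recs[[1]] <- data.frame(chrom = build$chrom[ci], pos = pos, ref = ref,
                            alt = alt, context = ctx, stringsAsFactors = FALSE)
  }
  if (params$n_kataegis_foci > 0) {
    for (f in seq_len(params$n_kataegis_foci)) {
      k <- sample(6:20, 1)
      ci <- sample.int(nrow(build), 1, prob = build$length)
      start <- floor(stats::runif(1, 2, build$length[ci] - 100 * k))
      pos <- start + c(0, cumsum(sample(10:80, k - 1, replace = TRUE)))
      cl <- apobec_classes()[sample.int(4, k, replace = TRUE), ]
      recs[[length(recs) + 1]] <- data.frame(
        chrom = build$chrom[ci], pos = pos, ref = cl$ref, alt = cl$alt,
        context = cl$context, stringsAsFactors = FALSE)
    }
  }
  if (length(recs) == 0) return(empty_snvs())
  snvs <- do.call(rbind, c(recs, list(make.row.names = FALSE)))
  snvs <- snvs[!duplicated(paste(snvs$chrom, snvs$pos)), , drop = FALSE]
  snvs <- snvs[order(match(snvs$chrom, build$chrom), snvs$pos), , drop = FALSE]
  rownames(snvs) <- NULL
  snvs
}

#' Simulate structural variants
#'
#' Generates the requested counts per SV type. Deletion, duplication and
#' inversion sizes are log-uniform on \[1 kb, 50 Mb\]; translocations join
#' random chromosome pairs. A `sv_clustered_frac` fraction of events is
#' placed with one breakpoint inside shared 500 kb windows (groups of up
#' to 10); the rest are kept mutually isolated (breakpoints > 1 Mb apart)
#' so the fixed-window density rule classifies them as non-clustered.
#'
#' @param params an [archetype_params()] object.
#' @param build a `genome_build`.
#' @param seed integer seed.
#' @return SV data frame (`chrom1`, `pos1`, `chrom2`, `pos2`, `svtype`,
#'   `size`).
#' @export
simulate_svs <- function(params, build, seed) {
  withr::with_seed(seed, sim_svs_impl(params, build))
}

sim_svs_impl <- function(params, build) {
  types <- rep(names(params$n_sv), params$n_sv)
  if (length(types) == 0) return(empty_svs())
  types <- sample(types)
  n_cl <- round(params$sv_clustered_frac * length(types))
  placed <- list()  # per-chrom breakpoint positions for isolation checks
  bp_far <- function(ch, p, dist) {
    is.null(placed[[ch]]) || all(abs(placed[[ch]] - p) > dist)
  }
  note_bp <- function(ch, p) placed[[ch]] <<- c(placed[[ch]], p)
  svs <- list()
  draw_size <- function() round(exp(stats::runif(1, log(1e3), log(5e7))))

  make_sv <- function(ty, ch1 = NULL, p1 = NULL, isolated = TRUE) {
    for (attempt in seq_len(1000)) {
      if (ty == "TRA") {
        pair <- sample.int(nrow(build), 2, prob = build$length)
        c1 <- if (is.null(ch1)) build$chrom[pair[1]] else ch1
        c2 <- build$chrom[pair[2]]
        if (c1 == c2) next
        q1 <- if (is.null(p1))
          floor(stats::runif(1, 1, build$length[match(c1, build$chrom)]))
          else p1
        q2 <- floor(stats::runif(1, 1, build$length[pair[2]]))
        if (isolated && !(bp_far(c1, q1, 1.1e6) && bp_far(c2, q2, 1.1e6))) next
        note_bp(c1, q1); note_bp(c2, q2)
        return(data.frame(chrom1 = c1, pos1 = q1, chrom2 = c2, pos2 = q2,
                          svtype = "TRA", size = NA_real_,
                          stringsAsFactors = FALSE))
      }
      size <- draw_size()
      ci <- if (is.null(ch1)) {
        j <- sample.int(nrow(build), 1, prob = build$length)
        build$chrom[j]
      } else ch1
      len <- build$length[match(ci, build$chrom)]
      if (size >= len - 2) next
      q1 <- if (is.null(p1)) floor(stats::runif(1, 1, len - size)) else p1
      if (q1 + size > len) next
      q2 <- q1 + size
      if (isolated && !(bp_far(ci, q1, 1.1e6) && bp_far(ci, q2, 1.1e6))) next
      note_bp(ci, q1); note_bp(ci, q2)
      return(data.frame(chrom1 = ci, pos1 = q1, chrom2 = ci, pos2 = q2,
                        svtype = ty, size = size, stringsAsFactors = FALSE))
    }
    abort("genome capacity exceeded placing %s structural variant", ty)
  }

  if (n_cl > 0) {
    cl_types <- types[seq_len(n_cl)]
    g <- 0
    while (length(cl_types) > 0) {
      g <- g + 1
      take <- min(10, length(cl_types))
      grp <- cl_types[seq_len(take)]
      cl_types <- cl_types[-seq_len(take)]
      big <- which(build$length > 6e7)
      ci <- big[sample.int(length(big), 1)]
      wch <- build$chrom[ci]
      wstart <- floor(stats::runif(1, 1, build$length[ci] - 5.1e7))
      for (ty in grp) {
        p1 <- floor(stats::runif(1, wstart, wstart + 5e5))
        svs[[length(svs) + 1]] <- make_sv(ty, ch1 = wch, p1 = p1,
                                          isolated = FALSE)
      }
    }
  }
  for (ty in types[setdiff(seq_along(types), seq_len(n_cl))])
    svs[[length(svs) + 1]] <- make_sv(ty)
  out <- do.call(rbind, c(svs, list(make.row.names = FALSE)))
  validate_svs(out)
}

#' Configure a synthetic cohort
#'
#' @param n_per_archetype samples per archetype (>= 1).
#' @param seed master seed; per-sample seeds are derived with [mix_seed()].
#' @param build a `genome_build`.
#' @param archetypes named list of [archetype_params()]; defaults to the
#'   four standard archetypes.
#' @return list of class `cohort_config`.
#' @export
cohort_config <- function(n_per_archetype = 10, seed = 1,
                          build = read_genome_build(), archetypes = NULL) {
  if (n_per_archetype < 1) abort("n_per_archetype must be >= 1")
  if (is.null(archetypes))
    archetypes <- lapply(stats::setNames(nm = c("HRD", "MUT", "CN", "GS")),
                         archetype_params)
  structure(list(n_per_archetype = n_per_archetype, seed = seed,
                 build = build, archetypes = archetypes),
            class = "cohort_config")
}

#' Simulate a cohort with ground-truth archetype labels
#'
#' Generates, per archetype and sample, an allele-specific copy-number
#' profile, an SNV catalog and an SV list, each from a per-sample seed
#' derived from the master seed, so identical configurations give
#' identical cohorts regardless of generation order.
#'
#' @param config a [cohort_config()].
#' @return list of class `synthetic_cohort` with elements `samples` (each
#'   a list `sample_id`, `archetype`, `profile`, `snvs`, `svs`), `build`
#'   and `truth` (data frame `sample`, `archetype`).
#' @export
simulate_cohort <- function(config = cohort_config()) {
  samples <- list()
  i <- 0
  for (arch in names(config$archetypes)) {
    for (k in seq_len(config$n_per_archetype)) {
      i <- i + 1
      sid <- sprintf("%s_%02d", arch, k)
      base <- mix_seed(config$seed, i)
      samples[[sid]] <- list(
        sample_id = sid, archetype = arch,
        profile = simulate_profile(config$archetypes[[arch]], config$build,
                                   seed = base, sample_id = sid),
        snvs = simulate_snvs(config$archetypes[[arch]], config$build,
                             seed = mix_seed(base, 1)),
        svs = simulate_svs(config$archetypes[[arch]], config$build,
                           seed = mix_seed(base, 2)))
    }
  }
  structure(list(samples = samples, build = config$build, config = config,
                 truth = data.frame(
                   sample = names(samples),
                   archetype = vapply(samples, `[[`, character(1), "archetype"),
                   stringsAsFactors = FALSE, row.names = NULL)),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d samples (%s)\n", length(x$samples),
              paste(sprintf("%s: %d", names(table(x$truth$archetype)),
                            table(x$truth$archetype)), collapse = ", ")))
  invisible(x)
}

#' Write a synthetic cohort to disk
#'
#' Emits the formats the readers consume: a combined `segments.tsv` (with
#' purity/ploidy columns), one VCF and one BEDPE per sample, and
#' `truth.tsv` with the ground-truth archetype labels.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_segments(lapply(cohort$samples, `[[`, "profile"),
                 file.path(dir, "segments.tsv"))
  for (s in cohort$samples) {
    write_snvs_vcf(s$snvs, file.path(dir, paste0(s$sample_id, ".vcf")),
                   sample_id = s$sample_id)
    write_svs_bedpe(s$svs, file.path(dir, paste0(s$sample_id, ".bedpe")))
  }
  utils::write.table(cohort$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
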