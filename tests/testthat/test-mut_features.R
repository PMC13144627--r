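test_that("SBS96 binning maps purine records to the pyrimidine strand", {
  snvs <- data.frame(chrom = "1", pos = c(100, 200, 300),
                     ref = c("C", "G", "A"), alt = c("T", "A", "C"),
                     context = c("ACA", "TGT", "CAG"),
                     stringsAsFactors = FALSE)
  v <- sbs96_vector(snvs)
  expect_equal(unname(v["A[C>T]A"]), 2)  # G>A at TGT == C>T at ACA
  expect_equal(unname(v["C[T>G]G"]), 1)  # A>C at CAG == T>G at CTG
  expect_equal(sum(v), 3)
  expect_equal(attr(v, "n_excluded"), 0)

  # empty catalog gives the zero vector
  v0 <- sbs96_vector(gitax:::empty_snvs())
  expect_equal(sum(v0), 0)
  expect_length(v0, 96)
})

test_that("SBS96 is invariant under reverse-complementing every record", {
  set.seed(7)
  snvs <- random_snvs(500, p_missing = 0)
  rc <- snvs
  rc$ref <- chartr("ACGT", "TGCA", snvs$ref)
  rc$alt <- chartr("ACGT", "TGCA", snvs$alt)
  rc$context <- vapply(strsplit(chartr("ACGT", "TGCA", snvs$context), ""),
                       function(s) paste(rev(s), collapse = ""), character(1))
  expect_equal(sbs96_vector(rc), sbs96_vector(snvs))
})

test_that("conservation: catalog sums equal their input counts", {
  set.seed(8)
  for (i in 1:25) {
    snvs <- random_snvs(sample(0:300, 1))
    v <- sbs96_vector(snvs)
    expect_equal(sum(v) + attr(v, "n_excluded"), nrow(snvs))

    p <- random_profile()
    expect_equal(sum(cn48_vector(p)), nrow(p$segments))

    svs <- random_svs(sample(0:40, 1))
    expect_equal(sum(sv32_vector(svs)), nrow(svs))
  }
})

test_that("TMB divides mutation counts by the genome size", {
  expect_equal(tmb(6160, 0, 2800), 2.2)
  expect_equal(tmb(0, 0, 2800), 0)
  expect_equal(tmb(2800, 2800, 2800), 2)
  expect_error(tmb(100, 0, 0), "positive")
})

test_that("APOBEC fraction sums the four TCW channels", {
  v <- stats::setNames(integer(96), sbs96_labels())
  v[c("T[C>G]A", "T[C>G]T", "T[C>T]A", "T[C>T]T")] <- 1
  v["A[C>A]A"] <- 6
  expect_equal(apobec_fraction(v), 0.4)
  v2 <- stats::setNames(integer(96), sbs96_labels())
  v2["A[C>A]A"] <- 10
  expect_equal(apobec_fraction(v2), 0)
  v3 <- stats::setNames(integer(96), sbs96_labels())
  v3["T[C>T]A"] <- 5
  expect_equal(apobec_fraction(v3), 1)
  expect_error(apobec_fraction(stats::setNames(integer(96), sbs96_labels())),
               "undefined")
})

test_that("kataegis calls maximal runs of >=6 SNVs under 100 bp spacing", {
  mk <- function(pos) data.frame(chrom = "1", pos = pos, ref = "C", alt = "T",
                                 context = "TCA", stringsAsFactors = FALSE)
  ev <- detect_kataegis(mk(seq(1000, 1250, by = 50)))
  expect_equal(nrow(ev), 1)
  expect_equal(ev$n_snvs, 6)
  expect_equal(ev$start, 1000)
  expect_equal(ev$end, 1250)
  expect_equal(ev[["C>T"]], 6)

  expect_equal(nrow(detect_kataegis(mk(seq(1000, 1200, by = 50)))), 0)

  # a 150 bp gap breaks the run; neither side reaches 6
  pos <- 1000 + cumsum(c(0, 50, 50, 150, 50, 50, 50))
  expect_equal(nrow(detect_kataegis(mk(pos))), 0)

  # the looser rainfall criterion can be requested explicitly
  expect_equal(nrow(detect_kataegis(mk(pos), max_imd = 2000)), 1)
})

test_that("kataegis null: uniform genome-wide SNVs yield no events", {
  zero_runs <- 0
  for (s in 1:100) {
    set.seed(s)
    pos <- sort(sample.int(2.8e9, 3000))
    snvs <- data.frame(chrom = "1", pos = pos, ref = "C", alt = "T",
                       context = "TCA", stringsAsFactors = FALSE)
    if (nrow(detect_kataegis(snvs)) == 0) zero_runs <- zero_runs + 1
  }
  expect_gte(zero_runs, 99)
})

test_that("exposure refitting recovers planted mixtures", {
  S <- disjoint_signatures()
  # identity case: catalog exactly proportional to one signature
  v <- stats::setNames(round(S[, "sigA"] * 4800), sbs96_labels())
  fit <- refit_exposures(v, S)
  expect_equal(unname(fit$weights["sigA"]), 1)
  expect_lt(fit$residual, 1e-9)

  # 0.6 / 0.4 multinomial mixture
  set.seed(42)
  cnt <- as.vector(stats::rmultinom(1, 5000, 0.6 * S[, 1] + 0.4 * S[, 2]))
  names(cnt) <- sbs96_labels()
  fit2 <- refit_exposures(cnt, S)
  expect_equal(unname(fit2$weights["sigA"]), 0.6, tolerance = 0.05 / 0.6)
  expect_gt(fit2$reconstruction_cosine, 0.95)

  # aggressive pruning keeps only the dominant signature
  fit3 <- refit_exposures(cnt, S, prune = 0.5)
  expect_equal(sum(fit3$weights > 0), 1)
  expect_equal(unname(fit3$weights["sigA"]), 1)

  # reconstruction cosine is non-decreasing as pruning loosens
  cos_by_prune <- vapply(c(0.5, 0.06, 0),
                         function(pr) refit_exposures(cnt, S, pr)$reconstruction_cosine,
                         numeric(1))
  expect_true(all(diff(cos_by_prune) >= -1e-12))

  expect_error(refit_exposures(stats::setNames(integer(96), sbs96_labels()), S),
               "empty")
  expect_error(refit_exposures(cnt, S, prune = 1), "prune")
})

test_that("cosine profiling is scale invariant with the documented floor", {
  S <- disjoint_signatures()
  v <- stats::setNames(S[, "sigA"] * 1000, sbs96_labels())
  cp <- cosine_profile(v, S)
  expect_equal(cp$cosine[cp$signature == "sigA"], 1)
  expect_equal(cp$cosine[cp$signature == "sigB"], 0)
  expect_equal(cp$above_floor, c(TRUE, FALSE))

  # balanced mix of two disjoint-support signatures: 1/sqrt(2) to each
  mix <- stats::setNames(500 * (S[, 1] + S[, 2]), sbs96_labels())
  cp2 <- cosine_profile(mix, S)
  expect_equal(cp2$cosine, rep(1 / sqrt(2), 2), tolerance = 1e-12)
})

test_that("CN48 classifies segments by state, total copies and length", {
  p <- ascn_profile("t", data.frame(
    chrom = c("1", "1", "2"),
    start = c(1, 1e6, 1),
    end = c(5e5, 1e6 + 5e4 - 1, 3e7),
    major = c(1, 0, 2), minor = c(0, 0, 2)), 0.9, 2, toy_build())
  v <- cn48_vector(p)
  expect_equal(unname(v["1:LOH:100kb-1Mb"]), 1)   # focal CN=1 LOH, 500 kb
  expect_equal(unname(v["0:homdel:0-100kb"]), 1)  # 50 kb homozygous deletion
  expect_equal(unname(v["3-4:het:10Mb-40Mb"]), 1)
  expect_equal(sum(v), 3)
  expect_equal(sum(cn48_vector(ascn_profile("e", data.frame(
    chrom = character(), start = numeric(), end = numeric(),
    major = numeric(), minor = numeric()), 0.9, 2))), 0)
})

test_that("SV32 separates clustered from dispersed events by window density", {
  # a single small deletion is non-clustered
  one <- data.frame(chrom1 = "1", pos1 = 1000, chrom2 = "1", pos2 = 6000,
                    svtype = "DEL", size = 5000, stringsAsFactors = FALSE)
  v <- sv32_vector(one)
  expect_equal(unname(v["DEL:0-10kb:non-clustered"]), 1)
  expect_equal(sum(v), 1)

  # ten translocations with breakpoints inside one 500 kb region
  tra <- data.frame(chrom1 = "1", pos1 = seq(10e6, 10e6 + 4.5e5, length.out = 10),
                    chrom2 = as.character(2:11 %% 3 + 2),
                    pos2 = seq(5e6, 50e6, length.out = 10),
                    svtype = "TRA", size = NA_real_, stringsAsFactors = FALSE)
  v2 <- sv32_vector(tra)
  expect_equal(unname(v2["TRA:clustered"]), 10)
  expect_equal(sum(sv32_vector(gitax:::empty_svs())), 0)
})
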