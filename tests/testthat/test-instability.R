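test_that("SCNA counting measures deviation from the baseline state", {
  p <- ascn_profile("t", data.frame(
    chrom = "1", start = c(1, 50e6, 100e6), end = c(50e6 - 1, 100e6 - 1, 150e6),
    major = c(2, 1, 1), minor = c(1, 0, 1)), 0.9, 2, toy_build())
  expect_equal(scna_count(p), 2)
  expect_equal(scna_count(p, baseline = c(2, 2)), 3)
  all11 <- ascn_profile("t", data.frame(chrom = "1", start = 1, end = 1e8,
                                        major = 1, minor = 1), 0.9, 2)
  expect_equal(scna_count(all11), 0)
})

test_that("size stratification splits by 10 Mb and ploidy direction", {
  p <- ascn_profile("t", data.frame(
    chrom = "1",
    start = c(1, 10e6, 70e6, 120e6),
    end = c(5e6, 60e6, 80e6 - 1, 160e6),
    major = c(2, 1, 1, 1), minor = c(1, 0, 1, 1)), 0.9, 2, toy_build())
  # 5 Mb total 3 -> small_amp; 50 Mb total 1 -> large_del; 10 Mb exactly is small
  s <- size_stratified_counts(p)
  expect_equal(unname(s["small_amp"]), 1)
  expect_equal(unname(s["large_del"]), 1)

  exact10 <- ascn_profile("t", data.frame(chrom = "1", start = 1, end = 10e6,
                                          major = 2, minor = 1), 0.9, 2)
  expect_equal(unname(size_stratified_counts(exact10)["small_amp"]), 1)

  # ploidy-neutral LOH counts as a deletion of the minor allele
  loh <- ascn_profile("t", data.frame(chrom = "1", start = 1, end = 5e6,
                                      major = 2, minor = 0), 0.9, 2)
  expect_equal(unname(size_stratified_counts(loh)["small_del"]), 1)
})

test_that("thresholds come out fixed or as cohort means", {
  t1 <- derive_thresholds(mode = "fixed")
  expect_equal(c(t1$hrd_cut, t1$tmb_cut, t1$seg_cut), c(58, 2.2, 2269))
  expect_equal(t1$provenance, "fixed")

  cohort <- data.frame(tmb = c(1, 2, 3), scna_count = c(10, 20, 30))
  t2 <- derive_thresholds(cohort, mode = "cohort_mean")
  expect_equal(t2$tmb_cut, 2)
  expect_equal(t2$seg_cut, 20)

  one <- data.frame(tmb = 1.5, scna_count = 7)
  t3 <- derive_thresholds(one, mode = "cohort_mean")
  expect_equal(c(t3$tmb_cut, t3$seg_cut), c(1.5, 7))

  expect_error(derive_thresholds(data.frame(), mode = "cohort_mean"),
               "non-empty")
})

test_that("classification follows HRD > MUT > CN precedence with GS fallback", {
  m <- data.frame(sample = letters[1:4],
                  hrd_score = c(60, 10, 10, 10),
                  tmb = c(0.5, 3.0, 1.0, 2.2),
                  scna_count = c(100, 5000, 5000, 2269))
  cls <- classify_samples(m)
  expect_equal(as.character(cls$subtype), c("HRD", "MUT", "CN", "GS"))
  expect_true(cls$dual_flag[2])  # exceeds both TMB and seg cuts
  expect_error(classify_samples(m[, 1:2]), "missing metric columns")
  m$tmb[1] <- NA
  expect_error(classify_samples(m), "unset")
})

test_that("every sample gets exactly one label and HRD counts are monotone in the cut", {
  set.seed(30)
  m <- data.frame(sample = sprintf("s%03d", 1:200),
                  hrd_score = rpois(200, 40),
                  tmb = rexp(200, 1 / 2),
                  scna_count = rpois(200, 2000))
  cls <- classify_samples(m)
  expect_false(anyNA(cls$subtype))
  expect_equal(sum(table(cls$subtype)), 200)
  n_hrd <- vapply(c(20, 40, 58, 80), function(cut)
    sum(classify_samples(m, derive_thresholds(hrd_cut = cut))$subtype == "HRD"),
    numeric(1))
  expect_true(all(diff(n_hrd) <= 0))
})

test_that("contingency statistics reproduce closed forms", {
  st <- contingency_stats(rbind(c(24, 9), c(20, 76)))
  expect_equal(round(100 * st$row_prop, 1), c(72.7, 20.8))
  expect_equal(st$chisq, 29.43, tolerance = 0.01 / 29.43)
  expect_equal(st$odds_ratio, 24 * 76 / (9 * 20))

  sym <- contingency_stats(rbind(c(5, 5), c(5, 5)))
  expect_equal(sym$odds_ratio, 1)
  expect_equal(sym$chisq, 0)
  expect_equal(sym$fisher_p, 1)

  # closed form N(ad-bc)^2 / product of margins on random positive tables
  set.seed(31)
  for (i in 1:20) {
    tbl <- matrix(sample(1:50, 4, replace = TRUE), 2)
    st <- contingency_stats(tbl)
    a <- tbl[1, 1]; b <- tbl[1, 2]; c <- tbl[2, 1]; d <- tbl[2, 2]
    expect_equal(st$chisq, sum(tbl) * (a * d - b * c)^2 /
                   ((a + b) * (c + d) * (a + c) * (b + d)))
  }
  expect_error(contingency_stats(rbind(c(0, 0), c(1, 1))), "zero row")
})

test_that("group comparison is a Welch t-test with degenerate handling", {
  expect_equal(compare_groups(c(1, 1, 1, 1), c("a", "a", "b", "b")),
               list(t = 0, p = 1))
  set.seed(32)
  x <- c(rnorm(4, 0, 1e-4), rnorm(4, 1, 1e-4))
  res <- compare_groups(x, rep(c("lo", "hi"), each = 4))
  expect_gt(abs(res$t), 100)
  expect_lt(res$p, 0.001)
  expect_error(compare_groups(c(1, 2, 3), c("a", "b", "b")), "at least 2")
})

test_that("germline filter keeps P/LP, truncating VUS and doubly damaging missense", {
  g <- data.frame(
    gene = c("BRCA1", "BARD1", "BLM", "ATM", "TP53", "CHEK2"),
    class = c("P", "VUS", "VUS", "VUS", "B", "LP"),
    consequence = c("missense", "nonsense", "missense", "missense",
                    "missense", "frameshift"),
    sift = c("absent", "absent", "damaging", "tolerated", "damaging", "absent"),
    polyphen = c("absent", "absent", "damaging", "damaging", "damaging",
                 "absent"),
    stringsAsFactors = FALSE)
  kept <- filter_germline(g)
  expect_setequal(kept$gene, c("BRCA1", "BARD1", "BLM", "CHEK2"))
  expect_equal(kept$reason[kept$gene == "BARD1"], "truncating_vus")
  expect_equal(kept$reason[kept$gene == "BLM"], "damaging_missense_vus")

  # order invariance and idempotence
  perm <- g[sample(nrow(g)), ]
  kept2 <- filter_germline(perm)
  expect_setequal(kept2$gene, kept$gene)
  expect_equal(filter_germline(kept)[names(kept)], kept)

  bad <- g; bad$class[1] <- "weird"
  expect_error(filter_germline(bad), "invalid class")
})
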