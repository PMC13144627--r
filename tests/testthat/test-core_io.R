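test_that("bundled genome build has the expected autosomes plus X", {
  build <- read_genome_build()
  expect_s3_class(build, "genome_build")
  expect_equal(nrow(build), 23)
  expect_setequal(build$chrom, c(as.character(1:22), "X"))
  expect_equal(build$length[build$chrom == "1"], 249250621)
  expect_equal(build$cen_start[build$chrom == "1"], 121535434)
})

test_that("genome build tables are validated on read", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chrom\tlength\tcen_start\tcen_end",
               "chr1\t249250621\t121535434\t124535434"), f)
  b <- read_genome_build(f)
  expect_equal(b$chrom, "1")  # chr prefix stripped
  expect_equal(b$length, 249250621)

  writeLines(c("chrom\tlength\tcen_start\tcen_end",
               "chr1\t1000\t900\t2000"), f)  # centromere beyond chromosome
  expect_error(read_genome_build(f), "cen_start < cen_end < length")

  writeLines(c("chrom\tlength\tcen_start\tcen_end",
               "chr1\tnot_a_number\t1\t2"), f)
  expect_error(read_genome_build(f), "malformed|parse")
})

test_that("segment files round-trip and dialect quirks are handled", {
  build <- toy_build()
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample\tchrom\tstart\tend\tnMajor\tnMinor",
               "s1\tchr1\t1\t50000000\t2\t1",
               "s1\tchr2\t100\t20000000\t1\t1"), f)
  expect_error(read_segments(f, build), "purity")
  writeLines(c("##purity=0.7", "##ploidy=2.4",
               "sample\tchrom\tstart\tend\tnMajor\tnMinor",
               "s1\tchr1\t1\t50000000\t2\t1",
               "s1\tchr2\t100\t20000000\t1\t1"), f)
  prof <- read_segments(f, build)
  expect_equal(nrow(prof$segments), 2)
  expect_equal(prof$purity, 0.7)
  expect_equal(prof$ploidy, 2.4)

  # round trip through the writer
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_segments(prof, f2)
  prof2 <- read_segments(f2, build)
  expect_equal(prof2$segments, prof$segments)
  expect_equal(prof2$purity, prof$purity)

  # allele-label swap tolerance
  writeLines(c("##purity=0.7", "##ploidy=2",
               "sample\tchrom\tstart\tend\tnMajor\tnMinor",
               "s1\t1\t1\t50000000\t1\t2"), f)
  expect_warning(prof3 <- read_segments(f, build), "swap")
  expect_equal(prof3$segments$major, 2)
  expect_equal(prof3$segments$minor, 1)

  # overlapping segments rejected
  writeLines(c("##purity=0.7", "##ploidy=2",
               "sample\tchrom\tstart\tend\tnMajor\tnMinor",
               "s1\t1\t1\t50000000\t2\t1",
               "s1\t1\t40000000\t60000000\t1\t1"), f)
  expect_error(read_segments(f, build), "overlap")

  # unknown chromosome rejected
  writeLines(c("##purity=0.7", "##ploidy=2",
               "sample\tchrom\tstart\tend\tnMajor\tnMinor",
               "s1\tchr99\t1\t50000000\t2\t1"), f)
  expect_error(read_segments(f, build), "not in genome build")
})

test_that("VCF records are split and partitioned into SNVs and indels", {
  f <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=TNC,Number=1,Type=String,Description=\"context\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    "1\t100\t.\tC\tT\t.\tPASS\tTNC=ACA",
    "1\t200\t.\tCT\tC\t.\tPASS\t.",
    "1\t300\t.\tC\tT,G\t.\tPASS\tTNC=TCT",
    "2\t400\t.\tG\tA\t.\tPASS\t."), f)
  out <- read_snvs_vcf(f)
  expect_equal(nrow(out$snvs), 4)  # 1 + 2 (multi-allelic split) + 1
  expect_equal(nrow(out$indels), 1)
  expect_equal(out$snvs$context[1], "ACA")
  expect_true(is.na(out$snvs$context[4]))
  expect_equal(out$snvs$alt[out$snvs$pos == 300], c("T", "G"))
})

test_that("BEDPE coordinates convert to 1-based and back", {
  f <- withr::local_tempfile(fileext = ".bedpe")
  writeLines("chr1\t999\t1000\tchr1\t5999\t6000\t.\t.\t+\t+\tDEL", f)
  svs <- read_svs_bedpe(f)
  expect_equal(svs$pos1, 1000)
  expect_equal(svs$pos2, 6000)
  expect_equal(svs$size, 5000)

  # interchromosomal record is a TRA with undefined size
  writeLines("chr1\t999\t1000\tchr2\t5999\t6000\t.\t.\t+\t+\tTRA", f)
  tra <- read_svs_bedpe(f)
  expect_equal(tra$svtype, "TRA")
  expect_true(is.na(tra$size))

  # intrachromosomal TRA is invalid
  writeLines("chr1\t999\t1000\tchr1\t5999\t6000\t.\t.\t+\t+\tTRA", f)
  expect_error(read_svs_bedpe(f), "intrachromosomal")

  # empty file -> empty list
  file.create(f)
  expect_equal(nrow(read_svs_bedpe(f)), 0)

  # write/read is its own inverse
  set.seed(5)
  svs <- random_svs(20)
  f2 <- withr::local_tempfile(fileext = ".bedpe")
  write_svs_bedpe(svs, f2)
  back <- read_svs_bedpe(f2)
  expect_equal(back[c("chrom1", "pos1", "chrom2", "pos2", "svtype", "size")],
               svs[c("chrom1", "pos1", "chrom2", "pos2", "svtype", "size")],
               ignore_attr = TRUE)
})

test_that("fetch_context fills 3-mers from a reference and validates them", {
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">1", "AACATTNGG"), fa)
  snvs <- data.frame(chrom = "1", pos = 4, ref = "A", alt = "G",
                     context = NA_character_, stringsAsFactors = FALSE)
  out <- fetch_context(snvs, fa)
  expect_equal(out$context, "CAT")

  # middle base mismatch is an error naming the position
  bad <- data.frame(chrom = "1", pos = 4, ref = "C", alt = "G",
                    context = NA_character_)
  expect_error(fetch_context(bad, fa), "1:4")

  # N in the context leaves the record retained but context-less
  nn <- data.frame(chrom = "1", pos = 6, ref = "T", alt = "G",
                   context = NA_character_)
  out2 <- fetch_context(nn, fa)
  expect_equal(nrow(out2), 1)
  expect_true(is.na(out2$context))
})

test_that("signature matrices read, reorder and renormalize", {
  labels <- sbs96_labels()
  f <- withr::local_tempfile(fileext = ".tsv")
  # shuffled row order, one column slightly off unit sum (within 1e-3)
  set.seed(3)
  ord <- sample(96)
  s1 <- rep(1 / 96, 96)
  s2 <- (1:96) / sum(1:96) * 1.0005
  tab <- data.frame(Type = labels[ord], U = s1[ord], R = s2[ord])
  utils::write.table(tab, f, sep = "\t", quote = FALSE, row.names = FALSE)
  m <- read_signature_matrix(f)
  expect_equal(dim(m), c(96, 2))
  expect_equal(rownames(m), labels)
  expect_equal(unname(colSums(m)), c(1, 1))
  expect_equal(unname(m["A[C>A]A", "U"]), 1 / 96, tolerance = 1e-9)

  # column summing to 0.9 is rejected
  tab$U <- tab$U * 0.9
  utils::write.table(tab, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_signature_matrix(f), "sums to")

  # wrong number of rows is rejected
  utils::write.table(tab[1:90, ], f, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  expect_error(read_signature_matrix(f), "expected 96 features")
})
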