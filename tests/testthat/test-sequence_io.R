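test_that("FASTA reading parses, validates and preserves order", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">c1", "ACGT", ">c2 extra description", "acgtn", ">c3",
               "AAAA", "CCCC"), f)
  ct <- read_fasta(f, genotype = "A")
  expect_equal(ct$id, c("c1", "c2", "c3"))
  expect_equal(ct$sequence, c("ACGT", "ACGTN", "AAAACCCC"))
  expect_equal(ct$length, c(4L, 5L, 8L))
  expect_equal(unique(ct$genotype), "A")

  empty <- withr::local_tempfile(fileext = ".fa")
  writeLines(character(0), empty)
  expect_equal(nrow(read_fasta(empty)), 0L)

  bad <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">c1", "ACGU"), bad)
  expect_error(read_fasta(bad), "non-DNA")

  noseq <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">c1", "", ">c2", "ACGT"), noseq)
  expect_error(read_fasta(noseq), "empty sequence")
})

test_that("contig sets round-trip through FASTA exactly", {
  set.seed(31)
  ct <- contig_set(sprintf("ctg%02d", 1:10),
                   replicate(10, random_seq(sample(50:200, 1))), "B")
  f <- withr::local_tempfile(fileext = ".fa")
  write_fasta(ct, f)
  back <- read_fasta(f, genotype = "B")
  expect_identical(back, ct)
})

test_that("variant tables parse, type and validate records", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(paste(radmarker:::VARIANT_COLS, collapse = "\t"),
               "c1\t101\tG\tT\t30\t45\t1\t80\t18\t12",
               "c1\t150\tGA\tG\t40\t60\t0\t90\t20\t15",
               "c2\t7\tA\tATT\t25\t58\t0\t70\t10\t12"), f)
  v <- read_variant_table(f)
  expect_equal(v$vtype, c("SNP", "DEL", "INS"))
  expect_equal(v$DP[1], 30L)

  g <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("contig_id\tpos\tref\talt\tDP\tMQ\tMQ0\tad_ref\tad_alt",
               "c1\t1\tA\tT\t10\t60\t0\t5\t5"), g)
  expect_error(read_variant_table(g), "QUAL")

  h <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(paste(radmarker:::VARIANT_COLS, collapse = "\t"),
               "c1\t101\tG\tT\t10\t45\t1\t80\t18\t12"), h)
  expect_error(read_variant_table(h), "line 1")
})

test_that("variant tables round-trip through TSV", {
  f <- withr::local_tempfile(fileext = ".tsv")
  tab <- radmarker:::variant_records(data.frame(
    contig_id = c("c1", "c2"), pos = c(5L, 9L), ref = c("A", "TG"),
    alt = c("G", "T"), DP = c(30L, 22L), MQ = c(60, 59.5), MQ0 = c(0L, 1L),
    QUAL = c(200, 88), ad_ref = c(2L, 11L), ad_alt = c(28L, 11L),
    stringsAsFactors = FALSE))
  write_variant_table(tab, f)
  expect_identical(read_variant_table(f), tab)
})

test_that("marker reports are deterministic and carry summary fields", {
  mk <- data.frame(marker_id = c("m2", "m1"), genotype = c("B", "A"),
                   contig_id = c("c9", "c1"), start = c(5L, 10L),
                   stringsAsFactors = FALSE)
  stats <- list(ssr_total = 2L,
                ssr_frequency = frequency_label(marker_frequency(5158,
                                                                 55270)))
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_marker_report(mk, stats, f1)
  write_marker_report(mk[2:1, ], stats, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_true(any(grepl("1/10.72 kb", readLines(f1), fixed = TRUE)))

  f3 <- withr::local_tempfile()
  write_marker_report(mk[0, ], list(ssr_total = 0L), f3)
  expect_true(any(grepl("ssr_total\t0", readLines(f3), fixed = TRUE)))
})

test_that("YAML configuration overrides merge into validated defaults", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("flank_min: 25", "evalue_cutoff: 1.0e-4",
               "primer:", "  product_max: 400"), f)
  cfg <- read_config(f)
  expect_equal(cfg$flank_min, 25)
  expect_equal(cfg$evalue_cutoff, 1e-4)
  expect_equal(cfg$primer$product_max, 400)
  expect_equal(cfg$primer$len_opt, 20L) # untouched default survives
  expect_error(pipeline_config(maf_hom = 0.3, maf_het = 0.2), "below")
  expect_error(pipeline_config(nonsense = 1), "unknown config")
})
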