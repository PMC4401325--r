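test_that("marker clustering applies the strict distance rule", {
  mk <- function(pos) data.frame(marker_id = sprintf("m%d", pos),
                                 start = pos, end = pos,
                                 stringsAsFactors = FALSE)
  two <- rbind(mk(100), mk(550))   # gap 450 < 500
  cl <- cluster_markers(two, 500L)
  expect_equal(nrow(cl), 1L)
  expect_true(cl$clustered)
  expect_equal(cl$span_start, 100L)
  expect_equal(cl$span_end, 550L)
  apart <- rbind(mk(100), mk(600)) # gap 500, strict <
  cl2 <- cluster_markers(apart, 500L)
  expect_equal(nrow(cl2), 2L)
  expect_false(any(cl2$clustered))
})

test_that("clustering partitions the input and respects the product bound", {
  set.seed(81)
  pos <- sort(sample(1:4000, 15))
  mk <- data.frame(marker_id = sprintf("m%02d", seq_along(pos)),
                   start = pos, end = pos + 10L, stringsAsFactors = FALSE)
  cl <- cluster_markers(mk, 500L)
  members <- unlist(strsplit(cl$members, ",", fixed = TRUE))
  expect_setequal(members, mk$marker_id)
  expect_equal(length(members), nrow(mk))
  # spans never exceed what a sub-800 bp product can cover
  expect_true(all(cl$span_end - cl$span_start + 1L <= 799L - 2L * 18L))
  # shrinking the threshold never merges clusters
  cl_small <- cluster_markers(mk, 200L)
  expect_gte(nrow(cl_small), nrow(cl))
})

test_that("designed primer pairs satisfy every hard constraint", {
  set.seed(82)
  cfg <- pipeline_config()
  n_ok <- 0
  for (i in 1:15) {
    cseq <- random_seq(1000, gc = 0.45)
    region <- data.frame(span_start = 480L, span_end = 520L,
                         clustered = FALSE)
    pp <- design_primers(region, cseq, cfg)
    if (is.null(pp)) next
    n_ok <- n_ok + 1
    for (side in c("left", "right")) {
      s <- pp[[paste0(side, "_seq")]]
      expect_gte(nchar(s), 18L); expect_lte(nchar(s), 24L)
      expect_gte(pp[[paste0("gc_", side)]], 40)
      expect_lte(pp[[paste0("gc_", side)]], 60)
    }
    expect_gte(pp$product_size, 100L)
    expect_lte(pp$product_size, 500L)
    expect_lt(pp$left_end, region$span_start)
    expect_gt(pp$right_start, region$span_end)
    expect_equal(pp$product_size, pp$right_end - pp$left_start + 1L)
    # sequences really come from the contig (right primer reverse strand)
    expect_equal(pp$left_seq, substr(cseq, pp$left_start, pp$left_end))
    expect_equal(pp$right_seq,
                 revcomp(substr(cseq, pp$right_start, pp$right_end)))
  }
  expect_gt(n_ok, 10)
})

test_that("primer design is deterministic and fails cleanly at contig
           edges", {
  set.seed(83)
  cseq <- random_seq(800, gc = 0.5)
  region <- data.frame(span_start = 380L, span_end = 420L,
                       clustered = FALSE)
  p1 <- design_primers(region, cseq)
  p2 <- design_primers(region, cseq)
  expect_identical(p1, p2)
  edge <- data.frame(span_start = 3L, span_end = 30L, clustered = FALSE)
  expect_null(design_primers(edge, substr(cseq, 1, 60)))
})

test_that("clustered regions may use the extended product bound", {
  set.seed(84)
  cseq <- random_seq(1200, gc = 0.5)
  region <- data.frame(span_start = 300L, span_end = 900L, clustered = TRUE)
  pp <- design_primers(region, cseq)
  expect_false(is.null(pp))
  expect_lt(pp$product_size, 800L)
  expect_gt(pp$product_size, 500L) # must exceed the singleton maximum here
})

test_that("melting temperature and GC follow the standard formulas", {
  expect_equal(gc_percent("GGCC"), 100)
  expect_equal(gc_percent("ATAT"), 0)
  expect_equal(primer_tm(strrep("AT", 10)), 64.9 + 41 * (0 - 16.4) / 20)
  expect_equal(primer_tm(paste0(strrep("GC", 5), strrep("AT", 5))),
               64.9 + 41 * (10 - 16.4) / 20)
})
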