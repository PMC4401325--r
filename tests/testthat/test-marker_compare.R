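test_that("flank extraction does exact coordinate arithmetic", {
  set.seed(41)
  seq <- random_seq(300)
  ct <- contig_set("c1", seq, "A")
  mk <- data.frame(marker_id = "m1", contig_id = "c1", start = 50L,
                   end = 63L, stringsAsFactors = FALSE)
  fm <- extract_flanks(mk, ct, flank_min = 20L, flank_max = 20L)
  expect_equal(fm$left_flank, substr(seq, 30, 49))
  expect_equal(fm$right_flank, substr(seq, 64, 83))
  expect_equal(fm$anchor_status, "ok")
  # a 1-base SNP locus at 150
  snp <- data.frame(marker_id = "s1", contig_id = "c1", start = 150L,
                    end = 150L, stringsAsFactors = FALSE)
  fs <- extract_flanks(snp, ct, 20L, 20L)
  expect_equal(fs$left_flank, substr(seq, 130, 149))
  expect_equal(fs$right_flank, substr(seq, 151, 170))
  # too close to the contig start
  near <- data.frame(marker_id = "m2", contig_id = "c1", start = 10L,
                     end = 20L, stringsAsFactors = FALSE)
  expect_equal(extract_flanks(near, ct, 20L)$anchor_status, "UNANCHORABLE")
  expect_error(extract_flanks(data.frame(marker_id = "m3",
                                         contig_id = "nope", start = 5L,
                                         end = 6L), ct), "unknown contig")
  # N in a flank blocks anchoring but keeps the flanks
  seqn <- paste0(substr(seq, 1, 44), "N", substr(seq, 46, 300))
  fmn <- extract_flanks(mk, contig_set("c1", seqn, "A"), 20L, 20L)
  expect_true(fmn$flank_has_n)
  expect_equal(fmn$anchor_status, "ok")
})

test_that("flank matching requires both flanks, the E-value cutoff and
           consistent geometry", {
  set.seed(55)
  lf <- random_seq(40); rf <- random_seq(40)
  mkA <- data.frame(marker_id = "a1", start = 100L, end = 115L,
                    left_flank = lf, right_flank = rf,
                    anchor_status = "ok", flank_has_n = FALSE,
                    stringsAsFactors = FALSE)
  mkB <- mkA; mkB$marker_id <- "b1"
  m <- match_flanks(mkA, mkB)
  expect_equal(m$partner_id, "b1")
  # unrelated flanks: no partner
  mkR <- mkB; mkR$left_flank <- random_seq(40); mkR$right_flank <- random_seq(40)
  expect_true(is.na(match_flanks(mkA, mkR)$partner_id))
  # one flank degraded beyond the cutoff: no partner
  deg <- strsplit(rf, "")[[1]]
  deg[seq(1, 40, by = 2)] <- sample(c("A", "C", "G", "T"), 20, TRUE)
  mkD <- mkB; mkD$right_flank <- paste(deg, collapse = "")
  res <- match_flanks(mkA, mkD)
  expect_true(is.na(res$partner_id))
  # incompatible geometry (span difference beyond the window): no partner
  mkG <- mkB; mkG$end <- mkG$start + 400L
  expect_true(is.na(match_flanks(mkA, mkG)$partner_id))
})

test_that("shared SSR pairs are polymorphic exactly on repeat-count
           difference", {
  a <- data.frame(repeats = 8L, canonical_class = "AT/AT")
  b10 <- data.frame(repeats = 10L, canonical_class = "AT/AT")
  b8 <- data.frame(repeats = 8L, canonical_class = "AT/AT")
  bag <- data.frame(repeats = 8L, canonical_class = "AG/CT")
  expect_true(classify_ssr_pair(a, b10)$polymorphic)
  expect_false(classify_ssr_pair(a, b8)$polymorphic)
  cl <- classify_ssr_pair(a, bag)
  expect_false(cl$polymorphic)
  expect_true(cl$inconsistent)
})

test_that("shared variant sites are polymorphic only when both parents are
           homozygous for different alleles", {
  expect_true(classify_variant_pair("G", "T", "HOM", "HOM"))
  expect_false(classify_variant_pair("G", "T", "HOM", "HET"))
  expect_false(classify_variant_pair("G", "G", "HOM", "HOM"))
  expect_false(classify_variant_pair("G", "T", "UNKNOWN", "HOM"))
})

test_that("marker partition is exhaustive and the counts identity holds", {
  fix <- pipeline_fixture()
  for (part_name in c("ssr", "variants")) {
    part <- fix$res[[part_name]]$partition
    st <- part$status
    expect_true(all(st$status %in% c("SHARED", "A_ONLY", "B_ONLY",
                                     "UNANCHORABLE")))
    n_sh <- unname(part$counts["shared"])
    expect_equal(sum(st$status == "SHARED"), 2L * n_sh)
    # every marker in exactly one status
    expect_equal(anyDuplicated(st$marker_id), 0L)
    # SHARED <=> partner set; polymorphic => SHARED
    expect_equal(!is.na(st$partner_id), st$status == "SHARED")
    expect_true(all(st$status[st$insilico_polymorphic] == "SHARED"))
    # candidates = insilico_poly + a_only + b_only
    expect_equal(unname(part$counts["candidates"]),
                 unname(part$counts["insilico_poly"] +
                          part$counts["a_only"] + part$counts["b_only"]))
  }
})

test_that("anchoring is symmetric on noiseless synthetic parents", {
  fix <- pipeline_fixture()
  rev_anchors <- anchor_markers(fix$res$ssr$flanked_b,
                                fix$res$ssr$flanked_a, pipeline_config())
  fwd <- fix$res$ssr$anchors
  expect_equal(nrow(rev_anchors), nrow(fwd))
  key_f <- sort(paste(fwd$marker_a, fwd$marker_b))
  key_r <- sort(paste(rev_anchors$marker_b, rev_anchors$marker_a))
  expect_equal(key_f, key_r)
})

test_that("screening-set arithmetic reproduces published category sums", {
  expect_equal(screening_candidates(67, 598, 658), 1323)
  expect_equal(screening_candidates(0, 0, 0), 0)
  expect_equal(screening_candidates(0, 41, 59), 100)
})

test_that("disjoint marker sets yield only parent-specific candidates", {
  set.seed(61)
  mk <- function(id, genotype) {
    data.frame(marker_id = id, genotype = genotype, start = 60L, end = 75L,
               left_flank = random_seq(40), right_flank = random_seq(40),
               anchor_status = "ok", flank_has_n = FALSE,
               stringsAsFactors = FALSE)
  }
  fmA <- do.call(rbind, lapply(sprintf("a%d", 1:4), mk, genotype = "A"))
  fmB <- do.call(rbind, lapply(sprintf("b%d", 1:3), mk, genotype = "B"))
  anchors <- anchor_markers(fmA, fmB, pipeline_config())
  expect_equal(nrow(anchors), 0L)
  part <- partition_markers(fmA, fmB, anchors)
  expect_equal(unname(part$counts["candidates"]), 7L)
  expect_equal(unname(part$counts["shared"]), 0L)
})
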