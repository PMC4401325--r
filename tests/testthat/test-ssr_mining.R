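test_that("canonical motif classes match the marker-catalogue convention", {
  expect_equal(canonical_motif("TA"), "AT/AT")
  expect_equal(canonical_motif("TTC"), "AAG/CTT")
  expect_equal(canonical_motif("TGA"), "ATC/ATG")
  expect_equal(canonical_motif("GAAAA"), "AAAAG/CTTTT")
  expect_error(canonical_motif("ATAT"), "tandem repetition")
  expect_error(canonical_motif("AXT"), "A/C/G/T")
})

test_that("canonical_motif is invariant under rotation and reverse
           complement (exhaustive over short motifs)", {
  for (k in 2:4) {
    motifs <- apply(expand.grid(rep(list(c("A", "C", "G", "T")), k)), 1,
                    paste, collapse = "")
    motifs <- motifs[vapply(motifs, radmarker:::is_primitive_motif,
                            logical(1))]
    for (m in motifs) {
      cls <- canonical_motif(m)
      for (rot in radmarker:::rotations(m)) {
        expect_equal(canonical_motif(rot), cls)
        expect_equal(canonical_motif(revcomp(rot)), cls)
      }
    }
  }
})

test_that("find_ssrs applies the published repeat minima", {
  flank <- "GGCATCCGGTTACGGCAATGCCGG"
  hit <- find_ssrs(paste0(flank, strrep("AT", 7), flank), "c1")
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$unit_len, 2L)
  expect_equal(hit$repeats, 7L)
  expect_equal(hit$start, nchar(flank) + 1L)
  expect_equal(hit$canonical_class, "AT/AT")
  # one repeat below the dinucleotide minimum: nothing
  expect_equal(nrow(find_ssrs(paste0(flank, strrep("AT", 6), flank))), 0L)
  # locus invariants: span = unit_len * repeats and exact tiling
  seqs <- paste0(flank, strrep("CTG", 5), flank, strrep("ACGTG", 3), flank)
  loci <- find_ssrs(seqs, "c2")
  expect_equal(loci$end - loci$start + 1L, loci$unit_len * loci$repeats)
  for (i in seq_len(nrow(loci)))
    expect_equal(substr(seqs, loci$start[i], loci$end[i]),
                 strrep(loci$motif[i], loci$repeats[i]))
  expect_equal(nrow(find_ssrs("")), 0L)
})

test_that("nearby loci form compound SSRs under the interruption limit", {
  set.seed(5)
  spacer100 <- random_seq(100)
  spacer600 <- random_seq(600)
  flank <- random_seq(40)
  s <- paste0(flank, strrep("AAT", 5), spacer100, strrep("AG", 8), flank)
  loci <- find_ssrs(s, "c1")
  # brute-force oracle confirms both runs before the compound rule
  oracle <- brute_force_ssrs(s)
  expect_equal(loci[, c("start", "end", "motif", "unit_len", "repeats")],
               oracle, ignore_attr = TRUE)
  expect_equal(nrow(loci), 2L)
  expect_false(any(is.na(loci$compound_id)))
  expect_equal(loci$compound_id[1], loci$compound_id[2])
  # beyond the 500 bp interruption limit: two solitary loci
  s2 <- paste0(flank, strrep("AAT", 5), spacer600, strrep("AG", 8), flank)
  loci2 <- find_ssrs(s2, "c1")
  expect_equal(nrow(loci2), 2L)
  expect_true(all(is.na(loci2$compound_id)))
})

test_that("miner agrees exactly with the brute-force oracle on random and
           repeat-salted sequences", {
  set.seed(1234)
  for (i in 1:40) {
    s <- random_seq(sample(300:1200, 1), gc = 0.34)
    if (i %% 2 == 0) {
      # salt with a random planted repeat to exercise non-empty cases
      k <- sample(2:8, 1)
      m <- random_seq(k)
      at <- sample(nchar(s) %/% 2, 1)
      s <- paste0(substr(s, 1, at), strrep(m, sample(3:9, 1)),
                  substr(s, at + 1, nchar(s)))
    }
    got <- find_ssrs(s, "x")[, c("start", "end", "motif", "unit_len",
                                 "repeats")]
    expect_equal(got, brute_force_ssrs(s), ignore_attr = TRUE)
  }
})

test_that("SSR summaries reproduce catalogue-style frequencies", {
  expect_equal(marker_frequency(5158, 55270), 10.72)
  expect_lt(abs(marker_frequency(5461, 57060) - 10.44), 0.011)
  loci <- find_ssrs(paste0(random_seq(50), strrep("AT", 8), random_seq(50)),
                    "c1")
  sm <- ssr_summary(loci, 10)
  expect_equal(sm$frequency_kb, 10)
  expect_equal(sm$frequency, "1/10.00 kb")
  expect_equal(sum(sm$by_unit_len), 100)
  empty <- ssr_summary(loci[0, ], 100)
  expect_equal(empty$frequency, "NA")
})

test_that("per-unit-length percentages sum to 100 within rounding", {
  fix <- pipeline_fixture()
  sm <- fix$res$ssr$summary_a
  expect_lt(abs(sum(sm$by_unit_len) - 100), 0.05)
  expect_lt(abs(sum(sm$by_class) - 100), 0.5)
})
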