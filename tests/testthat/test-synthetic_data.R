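test_that("an all-zero configuration yields empty parents and truth", {
  cfg <- simulation_config(seed = 3, n_ssr_shared_equal = 0,
                           n_ssr_shared_divergent = 0, n_ssr_a_only = 0,
                           n_ssr_b_only = 0, n_snp = 0, n_indel = 0)
  sim <- generate_parents(cfg)
  expect_equal(nrow(sim$contigs_a), 0L)
  expect_equal(nrow(sim$contigs_b), 0L)
  expect_null(sim$truth)
})

test_that("generation is deterministic for a fixed seed", {
  cfg <- simulation_config(seed = 19, n_ssr_shared_equal = 4,
                           n_ssr_shared_divergent = 3, n_ssr_a_only = 2,
                           n_ssr_b_only = 2, n_snp = 20, n_indel = 8)
  s1 <- generate_parents(cfg)
  s2 <- generate_parents(cfg)
  expect_identical(s1, s2)
  c1 <- emit_variant_calls(s1$truth, cfg)
  c2 <- emit_variant_calls(s2$truth, cfg)
  expect_identical(c1, c2)
  s3 <- generate_parents(simulation_config(seed = 20,
                                           n_ssr_shared_equal = 4,
                                           n_ssr_shared_divergent = 3,
                                           n_ssr_a_only = 2,
                                           n_ssr_b_only = 2, n_snp = 20,
                                           n_indel = 8))
  expect_false(identical(s1$contigs_a$sequence, s3$contigs_a$sequence))
})

test_that("planted features carry exactly one truth row with valid
           coordinates", {
  fix <- pipeline_fixture()
  tr <- fix$sim$truth
  expect_equal(anyDuplicated(tr$feature_id), 0L)
  ina <- !is.na(tr$contig_a)
  la <- fix$sim$contigs_a$length[match(tr$contig_a[ina],
                                       fix$sim$contigs_a$id)]
  expect_true(all(tr$start_a[ina] >= 1 & tr$end_a[ina] <= la))
  inb <- !is.na(tr$contig_b)
  lb <- fix$sim$contigs_b$length[match(tr$contig_b[inb],
                                       fix$sim$contigs_b$id)]
  expect_true(all(tr$start_b[inb] >= 1 & tr$end_b[inb] <= lb))
  # divergent SSRs differ in repeats only; equal SSRs do not
  div <- tr[tr$category == "shared_divergent", ]
  expect_true(all(div$repeats_a != div$repeats_b))
  eq <- tr[tr$category == "shared_equal", ]
  expect_true(all(eq$repeats_a == eq$repeats_b))
})

test_that("generated background matches the target GC composition", {
  set.seed(29)
  s <- radmarker:::random_dna(1e6, 0.34)
  gc <- nchar(gsub("[AT]", "", s)) / 1e6
  expect_lt(abs(gc - 0.34), 0.01)
})

test_that("emitted allele depths recover the planted zygosity", {
  fix <- pipeline_fixture()
  for (dir in c("ab", "ba")) {
    tab <- fix$calls[[dir]]
    tr <- fix$sim$truth
    v <- if (dir == "ab") tr[tr$kind != "SSR" & !is.na(tr$contig_b), ]
         else tr[tr$kind != "SSR" & !is.na(tr$contig_a), ]
    key <- if (dir == "ab") paste(v$contig_b, v$start_b)
           else paste(v$contig_a, v$start_a)
    zyg <- if (dir == "ab") v$zyg_a else v$zyg_b
    m <- match(key, paste(tab$contig_id, tab$pos))
    expect_false(any(is.na(m)))
    calls <- vapply(m, function(i)
      zygosity(tab[i, , drop = FALSE])$call, character(1))
    expect_equal(calls, zyg)
  }
})

test_that("reciprocal tables swap ref and alt at shared SNP sites", {
  fix <- pipeline_fixture()
  tr <- fix$sim$truth
  sh <- tr[tr$category == "shared" & tr$kind == "SNP", ]
  ab <- fix$calls$ab; ba <- fix$calls$ba
  ma <- match(paste(sh$contig_b, sh$start_b), paste(ab$contig_id, ab$pos))
  mb <- match(paste(sh$contig_a, sh$start_a), paste(ba$contig_id, ba$pos))
  expect_equal(ab$ref[ma], ba$alt[mb])
  expect_equal(ab$alt[ma], ba$ref[mb])
})

test_that("noise fractions force the requested filter failures", {
  cfg <- simulation_config(seed = 23, n_ssr_shared_equal = 0,
                           n_ssr_shared_divergent = 0, n_ssr_a_only = 0,
                           n_ssr_b_only = 0, n_snp = 40, n_indel = 40,
                           noise = list(frac_fail_dp = 0.25))
  sim <- generate_parents(cfg)
  calls <- emit_variant_calls(sim$truth, cfg)
  exp_rm <- calls$expected[calls$expected$decision == "REMOVE", ]
  expect_gt(nrow(exp_rm), 0L)
  expect_true(all(exp_rm$reason == "DP<5"))
  for (dir in c("ab", "ba")) {
    scr <- screen_variants(calls[[dir]])
    exp_dir <- calls$expected[calls$expected$direction == dir, ]
    m <- match(paste(scr$audit$contig_id, scr$audit$pos),
               paste(exp_dir$contig_id, exp_dir$pos))
    expect_equal(scr$audit$decision, exp_dir$decision[m])
  }
})

test_that("substitution sampling concentrates on the target ts/tv ratio", {
  set.seed(37)
  subs <- sample_substitutions(10000, tstv = 1.76)
  expect_lt(abs(tstv_ratio(subs) - 1.76), 0.1)
})

test_that("known-DB overlap fractions of 0 and 1 are honoured end to end", {
  fix <- pipeline_fixture()
  sim <- fix$sim
  db0 <- known_db_fixture(sim$truth, sim$contigs_a, sim$contigs_b,
                          overlap_fraction = 0, seed = 7, fix$cfg)
  expect_equal(length(db0$redundant_features), 0L)
  db1 <- known_db_fixture(sim$truth, sim$contigs_a, sim$contigs_b,
                          overlap_fraction = 1, seed = 7, fix$cfg)
  cand_feats <- sim$truth$feature_id[sim$truth$kind == "SSR" &
                                       sim$truth$category != "shared_equal"]
  expect_true(all(db1$redundant_features %in% cand_feats))
  # almost every candidate amplicon supplies an alignable stretch
  expect_gte(length(db1$redundant_features), 0.9 * length(cand_feats))
})
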