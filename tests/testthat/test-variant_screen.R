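mk_rec <- function(vtype = "INS", DP = 30L, MQ = 60, MQ0 = 0L, QUAL = 200,
                   ad_ref = 2L, ad_alt = 28L) {
  data.frame(contig_id = "c1", pos = 10L,
             ref = if (vtype == "SNP") "A" else "A",
             alt = switch(vtype, SNP = "G", INS = "AT", DEL = "A"),
             vtype = vtype, DP = DP, MQ = MQ, MQ0 = MQ0, QUAL = QUAL,
             ad_ref = ad_ref, ad_alt = ad_alt, stringsAsFactors = FALSE)
}

test_that("InDel hard-filter clauses fire at their exact boundaries", {
  # depth clause, boundary inclusive at 5
  expect_equal(indel_hard_filter(mk_rec(DP = 4L, ad_alt = 2L))$reason,
               "DP<5")
  expect_equal(indel_hard_filter(mk_rec(DP = 5L, ad_alt = 3L))$decision,
               "KEEP")
  # mapping-quality clause at 30.0
  expect_equal(indel_hard_filter(mk_rec(MQ = 29.9))$reason, "MQ<30")
  expect_equal(indel_hard_filter(mk_rec(MQ = 30))$decision, "KEEP")
  # call-quality clause at 50
  expect_equal(indel_hard_filter(mk_rec(QUAL = 49))$reason, "QUAL<50")
  expect_equal(indel_hard_filter(mk_rec(QUAL = 50))$decision, "KEEP")
  # MQ0 conjunction: needs both MQ0 >= 4 AND ratio > 0.1
  expect_equal(indel_hard_filter(mk_rec(MQ0 = 5L, DP = 40L))$reason,
               "MQ0_ratio") # 5/40 = 0.125
  expect_equal(indel_hard_filter(mk_rec(MQ0 = 5L, DP = 60L))$decision,
               "KEEP")      # 5/60 = 0.083
  expect_equal(indel_hard_filter(mk_rec(MQ0 = 3L, DP = 20L))$decision,
               "KEEP")      # ratio 0.15 but MQ0 < 4
  expect_equal(indel_hard_filter(mk_rec(MQ0 = 4L, DP = 40L))$decision,
               "KEEP")      # ratio exactly 0.1, not > 0.1
  # DP = 0 removed as the depth clause without touching the ratio
  expect_equal(indel_hard_filter(mk_rec(DP = 0L, ad_ref = 0L,
                                        ad_alt = 0L))$reason, "DP<5")
})

test_that("SNP depth screen is inclusive at the minimum", {
  expect_equal(snp_depth_filter(mk_rec("SNP", DP = 8L, ad_alt = 6L)), "KEEP")
  expect_equal(snp_depth_filter(mk_rec("SNP", DP = 7L, ad_alt = 5L)),
               "REMOVE")
  expect_equal(snp_depth_filter(mk_rec("SNP", DP = 100L, ad_alt = 90L)),
               "KEEP")
})

test_that("zygosity calls follow the MAF thresholds with boundaries to
           UNKNOWN", {
  z <- function(r, a) zygosity(mk_rec("SNP", DP = r + a, ad_ref = r,
                                      ad_alt = a))
  expect_equal(z(1L, 19L)$call, "HOM")     # maf 0.05
  expect_equal(z(6L, 14L)$call, "HET")     # maf 0.30
  expect_equal(z(3L, 17L)$call, "UNKNOWN") # maf 0.15
  expect_equal(z(2L, 18L)$call, "UNKNOWN") # maf exactly 0.10
  expect_equal(z(5L, 15L)$call, "UNKNOWN") # maf exactly 0.25
  expect_error(z(0L, 0L), "zero")
})

test_that("zygosity is invariant under depth scaling", {
  set.seed(3)
  for (i in 1:50) {
    r <- sample(0:12, 1); a <- sample(1:30, 1)
    k <- sample(2:20, 1)
    c1 <- zygosity(mk_rec("SNP", DP = r + a, ad_ref = r, ad_alt = a))$call
    c2 <- zygosity(mk_rec("SNP", DP = k * (r + a), ad_ref = k * r,
                          ad_alt = k * a))$call
    expect_equal(c1, c2)
  }
})

test_that("ts/tv ratio counts purine-purine and pyrimidine-pyrimidine
           substitutions as transitions", {
  snps <- data.frame(ref = c("A", "C", "A"), alt = c("G", "T", "C"))
  expect_equal(tstv_ratio(snps), 2)
  expect_true(is.na(tstv_ratio(data.frame(ref = "A", alt = "G"))))
  expect_true(is.na(tstv_ratio(snps[0, ])))
})

test_that("screening is idempotent and removal reasons are accounted", {
  fix <- pipeline_fixture()
  tab <- fix$calls$ab
  scr <- screen_variants(tab)
  again <- screen_variants(scr$kept[, colnames(tab)])
  expect_equal(nrow(again$kept), nrow(scr$kept))
  expect_true(all(again$audit$decision == "KEEP"))
  removed <- scr$audit[scr$audit$decision == "REMOVE", ]
  expect_equal(sum(!is.na(removed$reason)), nrow(removed))
  expect_equal(sum(table(removed$reason)), nrow(removed))
})
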