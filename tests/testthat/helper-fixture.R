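# One mid-sized noiseless simulation + pipeline run shared by several test
# files (built lazily, cached for the session).
pipeline_fixture <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    cfg <- simulation_config(seed = 7, n_ssr_shared_equal = 15,
                             n_ssr_shared_divergent = 10, n_ssr_a_only = 8,
                             n_ssr_b_only = 8, n_snp = 80, n_indel = 30)
    sim <- generate_parents(cfg)
    calls <- emit_variant_calls(sim$truth, cfg)
    db <- known_db_fixture(sim$truth, sim$contigs_a, sim$contigs_b,
                           overlap_fraction = 0.5, seed = 7, cfg)
    res <- run_pipeline(pipeline_config(), sim$contigs_a, sim$contigs_b,
                        calls$ab, calls$ba, db$db)
    cache <<- list(cfg = cfg, sim = sim, calls = calls, db = db, res = res)
    cache
  }
})

# map truth rows to the pipeline's marker ids
truth_marker_ids <- function(truth) {
  ifelse(truth$kind == "SSR",
         ifelse(!is.na(truth$contig_a),
                sprintf("A|SSR|%s|%d", truth$contig_a, truth$start_a),
                sprintf("B|SSR|%s|%d", truth$contig_b, truth$start_b)),
         ifelse(!is.na(truth$contig_b),
                sprintf("AB|%s|%s|%d", truth$kind, truth$contig_b,
                        truth$start_b),
                sprintf("BA|%s|%s|%d", truth$kind, truth$contig_a,
                        truth$start_a)))
}

# candidate-side marker id for planted SSR features (A side preferred, as
# the pipeline lists polymorphic pairs under the A member)
truth_ssr_candidate_ids <- function(truth) {
  ssr <- truth[truth$kind == "SSR", , drop = FALSE]
  ifelse(is.na(ssr$contig_a),
         sprintf("B|SSR|%s|%d", ssr$contig_b, ssr$start_b),
         sprintf("A|SSR|%s|%d", ssr$contig_a, ssr$start_a))
}

# full recovery comparison: returns character vector of mismatch messages
compare_to_truth <- function(res, sim, db) {
  msgs <- character(0)
  st <- rbind(res$ssr$partition$status, res$variants$partition$status)
  tr <- sim$truth
  m <- match(truth_marker_ids(tr), st$marker_id)
  if (any(is.na(m)))
    msgs <- c(msgs, sprintf("%d planted features missing from pipeline",
                            sum(is.na(m))))
  ok <- !is.na(m)
  bad <- sum(st$status[m[ok]] != tr$expected_status[ok])
  if (bad) msgs <- c(msgs, sprintf("%d status mismatches", bad))
  bad <- sum(st$insilico_polymorphic[m[ok]] != tr$expected_poly[ok])
  if (bad) msgs <- c(msgs, sprintf("%d polymorphism-call mismatches", bad))
  # zygosity in both directions
  for (dir in c("ab", "ba")) {
    kept <- if (dir == "ab") res$variants$kept_ab else res$variants$kept_ba
    v <- if (dir == "ab") tr[tr$kind != "SSR" & !is.na(tr$contig_b), ]
         else tr[tr$kind != "SSR" & !is.na(tr$contig_a), ]
    key_t <- if (dir == "ab") paste(v$contig_b, v$start_b)
             else paste(v$contig_a, v$start_a)
    zyg_t <- if (dir == "ab") v$zyg_a else v$zyg_b
    mm <- match(key_t, paste(kept$contig_id, kept$pos))
    bad <- sum(is.na(mm)) + sum(kept$call[mm] != zyg_t, na.rm = TRUE)
    if (bad) msgs <- c(msgs, sprintf("%d zygosity mismatches (%s)", bad, dir))
  }
  # redundancy flags over candidate SSRs
  ssr <- tr[tr$kind == "SSR" & tr$category != "shared_equal", , drop = FALSE]
  cand_mid <- ifelse(ssr$category == "b_only",
                     sprintf("B|SSR|%s|%d", ssr$contig_b, ssr$start_b),
                     sprintf("A|SSR|%s|%d", ssr$contig_a, ssr$start_a))
  expected <- setNames(ssr$feature_id %in% db$redundant_features, cand_mid)
  got <- setNames(res$redundancy$redundant, res$redundancy$marker_id)
  common <- intersect(names(expected), names(got))
  # markers whose region admitted no primer pair have no amplicon to
  # screen; the fixture never marks such markers redundant, so every
  # expected-redundant marker must have a call and all calls must agree
  if (!all(names(expected)[expected] %in% common))
    msgs <- c(msgs, "expected-redundant marker missing a redundancy call")
  bad <- sum(expected[common] != got[common])
  if (bad) msgs <- c(msgs, sprintf("%d redundancy-flag mismatches", bad))
  msgs
}
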