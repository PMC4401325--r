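#' Simulation configuration for the synthetic dual-parent generator
#'
#' Defaults emulate the statistical structure of a parental RAD-seq contig
#' pair from a low-GC plant genome: ~34% GC contigs of 200-800 bp (SSR
#' contigs use 500-800 bp so primer and redundancy windows always fit),
#' motif-length frequencies matching a cotton-like SSR catalogue
#' (pentanucleotides most abundant), SNP substitutions at a
#' transition/transversion ratio of 1.76, and short InDels with geometric
#' lengths of mean 1.4 bp. Variant sites are split into shared
#' (discoverable in both mapping directions) and direction-only sets at
#' catalogue-like proportions, with the homozygous-homozygous fraction of
#' shared sites matching the same source (SNP 441/1216, InDel 121/675).
#'
#' @param ... named overrides of the defaults.
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(...) {
  cfg <- list(
    seed = 1L,
    n_ssr_shared_equal = 100L,
    n_ssr_shared_divergent = 50L,
    n_ssr_a_only = 60L,
    n_ssr_b_only = 60L,
    n_snp = 500L,
    n_indel = 200L,
    contig_len = c(200L, 800L),
    ssr_contig_len = c(500L, 800L),
    gc_target = 0.34,
    motif_len_weights = c(`2` = 18.96, `3` = 17.82, `4` = 12.39,
                          `5` = 33.29, `6` = 13.90, `7` = 3.16,
                          `8` = 0.48),
    tstv_target = 1.76,
    indel_mean_len = 1.4,
    snp_shared_frac = 1216 / 9366,
    indel_shared_frac = 675 / 3838,
    snp_homhom_frac = 441 / 1216,
    indel_homhom_frac = 121 / 675,
    dironly_hom_frac = 0.7,
    unknown_frac = 0,
    site_margin = 100L,
    site_spacing = 220L,
    depth_mean = 30,
    noise = list(frac_fail_mq0 = 0, frac_fail_mq = 0, frac_fail_qual = 0,
                 frac_fail_dp = 0, frac_snp_lowdp = 0),
    db_overlap = 0.5,
    db_record_flank = 120L,
    db_n_random = 20L
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown simulation field(s): ",
                        paste(bad, collapse = ", "))
  for (nm in names(over)) {
    if (is.list(cfg[[nm]]) && is.list(over[[nm]])) {
      cfg[[nm]][names(over[[nm]])] <- over[[nm]]
    } else {
      cfg[[nm]] <- over[[nm]]
    }
  }
  stopifnot(cfg$gc_target > 0, cfg$gc_target < 1, cfg$tstv_target > 0,
            all(unlist(cfg[startsWith(names(cfg), "n_")]) >= 0))
  class(cfg) <- "simulation_config"
  cfg
}

# iid background sequence at the target GC
random_dna <- function(n, gc) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# background contig guaranteed free of detectable SSRs (rejection sampling)
ssr_free_background <- function(len, gc, minima, tries = 50L) {
  for (i in seq_len(tries)) {
    s <- random_dna(len, gc)
    if (nrow(find_ssrs(s, minima = minima)) == 0) return(s)
  }
  stop("could not generate an SSR-free background of length ", len)
}

random_primitive_motif <- function(k, gc) {
  for (i in 1:100) {
    m <- random_dna(k, gc)
    if (is_primitive_motif(m)) return(m)
  }
  stop("no primitive motif found for length ", k)
}

# insert an SSR block centred in an SSR-free background; verify the miner
# sees exactly the planted locus
plant_ssr_contig <- function(len, gc, motif, reps, minima, tries = 25L) {
  k <- nchar(motif)
  block <- strrep(motif, reps)
  for (i in seq_len(tries)) {
    bg <- ssr_free_background(len, gc, minima)
    at <- (len - nchar(block)) %/% 2L + 1L
    seq <- paste0(substr(bg, 1L, at - 1L), block, substr(bg, at, len))
    loci <- find_ssrs(seq, minima = minima)
    if (nrow(loci) == 1 && loci$unit_len == k && loci$repeats == reps &&
        loci$start == at)
      return(list(sequence = seq, start = at,
                  end = at + nchar(block) - 1L, background = bg))
  }
  stop("could not plant SSR (", motif, " x ", reps, ") cleanly")
}

# plant two parental versions over one background differing only in repeats
plant_ssr_pair <- function(len, gc, motif, reps_a, reps_b, minima,
                           tries = 25L) {
  k <- nchar(motif)
  for (i in seq_len(tries)) {
    bg <- ssr_free_background(len, gc, minima)
    build <- function(reps) {
      block <- strrep(motif, reps)
      at <- (len - nchar(block)) %/% 2L + 1L
      seq <- paste0(substr(bg, 1L, at - 1L), block, substr(bg, at, len))
      loci <- find_ssrs(seq, minima = minima)
      if (nrow(loci) == 1 && loci$unit_len == k && loci$repeats == reps &&
          loci$start == at)
        list(sequence = seq, start = at, end = at + nchar(block) - 1L)
      else NULL
    }
    a <- build(reps_a); b <- build(reps_b)
    if (!is.null(a) && !is.null(b)) return(list(a = a, b = b))
  }
  stop("could not plant SSR pair (", motif, ")")
}

# draw an alternative base at the target ts/tv ratio
substitute_base <- function(ref, tstv) {
  ts_map <- c(A = "G", G = "A", C = "T", T = "C")
  tv_map <- list(A = c("C", "T"), G = c("C", "T"),
                 C = c("A", "G"), T = c("A", "G"))
  if (runif(1) < tstv / (1 + tstv)) unname(ts_map[ref])
  else sample(tv_map[[ref]], 1)
}

#' Sample SNP substitution pairs at a target ts/tv ratio
#'
#' The substitution sampler used by the generator, exposed so the realised
#' transition/transversion ratio can be checked at any sample size.
#'
#' @param n number of substitutions.
#' @param tstv target transition/transversion ratio.
#' @param gc GC fraction used to draw reference bases.
#' @return data.frame with `ref` and `alt` single-base columns.
#' @export
sample_substitutions <- function(n, tstv = 1.76, gc = 0.34) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  ref <- sample(names(p), n, replace = TRUE, prob = p)
  alt <- vapply(ref, substitute_base, character(1), tstv = tstv,
                USE.NAMES = FALSE)
  data.frame(ref = ref, alt = alt, stringsAsFactors = FALSE)
}

#' Generate two synthetic parental contig sets with a planted truth table
#'
#' Builds ancestral contigs at the target GC and derives the two parents by
#' planting: shared SSR loci with equal repeat counts, shared SSR loci
#' diverging only in repeat count inside identical flanks, parent-only SSR
#' contigs, and SNP/InDel sites that are either shared (discoverable in
#' both mapping directions: the parents' assemblies carry different
#' alleles) or direction-only (their contig exists in only one parent's
#' assembly). Every planted feature has exactly one truth row recording its
#' coordinates in each parent, parental states, zygosities and the status
#' the pipeline is expected to recover. Deterministic for a fixed seed.
#'
#' @param config [simulation_config()].
#' @return list with `contigs_a`, `contigs_b` (contig data.frames) and
#'   `truth` (data.frame; see Details in the package vignette).
#' @export
generate_parents <- function(config = simulation_config()) {
  set.seed(config$seed)
  minima <- pipeline_config()$ssr_minima
  gc <- config$gc_target
  ids_a <- character(0); seq_a <- character(0)
  ids_b <- character(0); seq_b <- character(0)
  truth <- list()
  add_truth <- function(...) {
    truth[[length(truth) + 1L]] <<- data.frame(..., stringsAsFactors = FALSE)
  }
  draw_motif <- function() {
    k <- as.integer(sample(names(config$motif_len_weights), 1,
                           prob = config$motif_len_weights))
    random_primitive_motif(k, gc)
  }
  ssr_len <- function() {
    if (config$ssr_contig_len[1] > config$ssr_contig_len[2])
      stop("infeasible SSR contig length range")
    sample(config$ssr_contig_len[1]:config$ssr_contig_len[2], 1)
  }
  # --- SSR features ---------------------------------------------------
  ssr_plan <- rep(c("shared_equal", "shared_divergent", "a_only", "b_only"),
                  c(config$n_ssr_shared_equal, config$n_ssr_shared_divergent,
                    config$n_ssr_a_only, config$n_ssr_b_only))
  for (i in seq_along(ssr_plan)) {
    cat_i <- ssr_plan[i]
    motif <- draw_motif()
    k <- nchar(motif)
    r_a <- minima[[as.character(k)]] + sample(0:3, 1)
    len <- ssr_len()
    if (len < nchar(motif) * (r_a + 4L) + 2L * config$site_margin)
      stop("infeasible packing: SSR contigs too short for planted loci")
    fid <- sprintf("ssr_%04d", i)
    if (cat_i %in% c("shared_equal", "shared_divergent")) {
      r_b <- if (cat_i == "shared_equal") r_a else r_a + sample(1:3, 1)
      pl <- plant_ssr_pair(len, gc, motif, r_a, r_b, minima)
      ca <- sprintf("A_%s", fid); cb <- sprintf("B_%s", fid)
      ids_a <- c(ids_a, ca); seq_a <- c(seq_a, pl$a$sequence)
      ids_b <- c(ids_b, cb); seq_b <- c(seq_b, pl$b$sequence)
      add_truth(feature_id = fid, kind = "SSR", category = cat_i,
                contig_a = ca, contig_b = cb,
                start_a = pl$a$start, end_a = pl$a$end,
                start_b = pl$b$start, end_b = pl$b$end,
                motif = motif, canonical_class = canonical_motif(motif),
                repeats_a = r_a, repeats_b = r_b,
                allele_a = NA, allele_b = NA,
                zyg_a = NA, zyg_b = NA,
                expected_status = "SHARED",
                expected_poly = (cat_i == "shared_divergent"))
    } else {
      pl <- plant_ssr_contig(len, gc, motif, r_a, minima)
      if (cat_i == "a_only") {
        ca <- sprintf("A_%s", fid)
        ids_a <- c(ids_a, ca); seq_a <- c(seq_a, pl$sequence)
        add_truth(feature_id = fid, kind = "SSR", category = cat_i,
                  contig_a = ca, contig_b = NA,
                  start_a = pl$start, end_a = pl$end,
                  start_b = NA, end_b = NA,
                  motif = motif, canonical_class = canonical_motif(motif),
                  repeats_a = r_a, repeats_b = NA,
                  allele_a = NA, allele_b = NA, zyg_a = NA, zyg_b = NA,
                  expected_status = "A_ONLY", expected_poly = FALSE)
      } else {
        cb <- sprintf("B_%s", fid)
        ids_b <- c(ids_b, cb); seq_b <- c(seq_b, pl$sequence)
        add_truth(feature_id = fid, kind = "SSR", category = cat_i,
                  contig_a = NA, contig_b = cb,
                  start_a = NA, end_a = NA,
                  start_b = pl$start, end_b = pl$end,
                  motif = motif, canonical_class = canonical_motif(motif),
                  repeats_a = NA, repeats_b = r_a,
                  allele_a = NA, allele_b = NA, zyg_a = NA, zyg_b = NA,
                  expected_status = "B_ONLY", expected_poly = FALSE)
      }
    }
  }
  # --- variant features ------------------------------------------------
  n_snp_sh <- round(config$n_snp * config$snp_shared_frac)
  n_ind_sh <- round(config$n_indel * config$indel_shared_frac)
  n_snp_ab <- (config$n_snp - n_snp_sh) %/% 2L
  n_snp_ba <- config$n_snp - n_snp_sh - n_snp_ab
  n_ind_ab <- (config$n_indel - n_ind_sh) %/% 2L
  n_ind_ba <- config$n_indel - n_ind_sh - n_ind_ab
  draw_zyg <- function(homhom_frac) {
    u <- runif(1)
    if (config$unknown_frac > 0 && runif(1) < config$unknown_frac)
      return(c("UNKNOWN", sample(c("HOM", "HET"), 1)))
    if (u < homhom_frac) c("HOM", "HOM")
    else if (runif(1) < 0.5) c("HET", "HOM") else c("HOM", "HET")
  }
  indel_len <- function() rgeom(1, 1 / config$indel_mean_len) + 1L
  vcount <- 0L
  plant_variant_contigs <- function(direction, sites) {
    # sites: data.frame(kind); direction "shared", "ab_only", "ba_only"
    rows <- list()
    idx <- 1L
    while (idx <= nrow(sites)) {
      len <- sample(max(config$contig_len[1], 400L):config$contig_len[2], 1)
      cap <- max(1L, (len - 2L * config$site_margin) %/%
                   config$site_spacing + 1L)
      take <- min(cap, nrow(sites) - idx + 1L)
      anc <- ssr_free_background(len, gc, minima)
      pos <- config$site_margin + config$site_spacing * (seq_len(take) - 1L)
      cid <- sprintf("%s_var_%04d", toupper(substr(direction, 1, 2)),
                     vcount + 1L)
      vcount <<- vcount + 1L
      edits <- list()
      for (s in seq_len(take)) {
        kind <- sites$kind[idx + s - 1L]
        p <- pos[s]
        anchor <- substr(anc, p, p)
        if (kind == "SNP") {
          alt <- substitute_base(anchor, config$tstv_target)
          edits[[s]] <- list(kind = "SNP", pos = p, ref = anchor, alt = alt)
        } else {
          d <- indel_len()
          if (runif(1) < 0.5) { # sampled/alternate parent carries insertion
            ins <- random_dna(d, gc)
            edits[[s]] <- list(kind = "INS", pos = p, ref = anchor,
                               alt = paste0(anchor, ins))
          } else {             # alternate parent carries a deletion
            del <- substr(anc, p, p + d)
            edits[[s]] <- list(kind = "DEL", pos = p, ref = del,
                               alt = anchor)
          }
        }
      }
      # reference parent's contig is the ancestor; the alternate parent's
      # contig (shared sites only) applies the alt alleles with offsets
      if (direction == "shared") {
        alt_seq <- anc
        offset <- 0L
        pos_alt <- integer(take)
        for (s in seq_len(take)) {
          e <- edits[[s]]
          p_alt <- e$pos + offset
          pos_alt[s] <- p_alt
          alt_seq <- paste0(substr(alt_seq, 1L, p_alt - 1L), e$alt,
                            substr(alt_seq, p_alt + nchar(e$ref),
                                   nchar(alt_seq)))
          offset <- offset + nchar(e$alt) - nchar(e$ref)
        }
        ca <- paste0("A_", cid); cb <- paste0("B_", cid)
        ids_a <<- c(ids_a, ca); seq_a <<- c(seq_a, alt_seq)
        ids_b <<- c(ids_b, cb); seq_b <<- c(seq_b, anc)
        for (s in seq_len(take)) {
          e <- edits[[s]]
          homhom <- if (e$kind == "SNP") config$snp_homhom_frac
                    else config$indel_homhom_frac
          z <- draw_zyg(homhom)
          rows[[length(rows) + 1L]] <- data.frame(
            feature_id = sprintf("var_%05d", vcount * 100L + s),
            kind = e$kind, category = "shared",
            contig_a = ca, contig_b = cb,
            start_a = pos_alt[s],
            end_a = pos_alt[s] + nchar(e$alt) - 1L,
            start_b = e$pos, end_b = e$pos + nchar(e$ref) - 1L,
            motif = NA, canonical_class = NA,
            repeats_a = NA, repeats_b = NA,
            allele_a = e$alt, allele_b = e$ref,
            zyg_a = z[1], zyg_b = z[2],
            expected_status = "SHARED",
            expected_poly = all(z == "HOM"),
            stringsAsFactors = FALSE)
        }
      } else {
        # contig exists only in the mapped-to parent's assembly
        if (direction == "ab_only") {
          cb <- paste0("B_", cid)
          ids_b <<- c(ids_b, cb); seq_b <<- c(seq_b, anc)
        } else {
          ca <- paste0("A_", cid)
          ids_a <<- c(ids_a, ca); seq_a <<- c(seq_a, anc)
        }
        for (s in seq_len(take)) {
          e <- edits[[s]]
          zyg <- if (runif(1) < config$dironly_hom_frac) "HOM" else "HET"
          rows[[length(rows) + 1L]] <- data.frame(
            feature_id = sprintf("var_%05d", vcount * 100L + s),
            kind = e$kind, category = direction,
            contig_a = if (direction == "ba_only") paste0("A_", cid)
                       else NA_character_,
            contig_b = if (direction == "ab_only") paste0("B_", cid)
                       else NA_character_,
            start_a = if (direction == "ba_only") e$pos else NA,
            end_a = if (direction == "ba_only")
                      e$pos + nchar(e$ref) - 1L else NA,
            start_b = if (direction == "ab_only") e$pos else NA,
            end_b = if (direction == "ab_only")
                      e$pos + nchar(e$ref) - 1L else NA,
            motif = NA, canonical_class = NA,
            repeats_a = NA, repeats_b = NA,
            allele_a = if (direction == "ab_only") e$alt else e$ref,
            allele_b = if (direction == "ba_only") e$alt else e$ref,
            zyg_a = if (direction == "ab_only") zyg else NA,
            zyg_b = if (direction == "ba_only") zyg else NA,
            expected_status = if (direction == "ab_only") "A_ONLY"
                              else "B_ONLY",
            expected_poly = FALSE,
            stringsAsFactors = FALSE)
        }
      }
      idx <- idx + take
    }
    rows
  }
  mk_sites <- function(n_snp, n_indel) {
    kinds <- c(rep("SNP", n_snp), rep("INDEL", n_indel))
    data.frame(kind = sample(kinds), stringsAsFactors = FALSE)
  }
  truth <- c(truth,
             plant_variant_contigs("shared", mk_sites(n_snp_sh, n_ind_sh)),
             plant_variant_contigs("ab_only", mk_sites(n_snp_ab, n_ind_ab)),
             plant_variant_contigs("ba_only", mk_sites(n_snp_ba, n_ind_ba)))
  truth_df <- if (length(truth)) do.call(rbind, truth) else NULL
  list(contigs_a = contig_set(ids_a, seq_a, "A"),
       contigs_b = contig_set(ids_b, seq_b, "B"),
       truth = truth_df)
}

# allele depths consistent with a planted zygosity call
draw_allele_depths <- function(zyg, dp) {
  minor <- switch(zyg,
    HOM = min(floor(0.08 * dp), max(0L, round(dp * runif(1, 0, 0.08)))),
    HET = min(dp %/% 2L, max(floor(0.25 * dp) + 1L,
                             round(dp * runif(1, 0.30, 0.50)))),
    UNKNOWN = min(floor(0.25 * dp),
                  max(ceiling(0.10 * dp), round(dp * runif(1, 0.12, 0.22)))))
  c(minor = as.integer(minor), major = as.integer(dp - minor))
}

#' Emit caller-style variant tables from a planted truth table
#'
#' Produces the two reciprocal variant tables (A reads mapped to B contigs,
#' and the reverse), with one record per planted site reachable in each
#' direction: depth drawn from the depth model, allele depths consistent
#' with the planted zygosity, and clean mapping metrics by default. Noise
#' fractions in the simulation config force chosen records to fail each
#' hard-filter clause (or the SNP depth screen); the expected decision per
#' record is returned alongside.
#'
#' @param truth truth table from [generate_parents()].
#' @param config the same [simulation_config()].
#' @return list with `ab`, `ba` (variant record data.frames) and
#'   `expected` (direction, contig_id, pos, decision, reason).
#' @export
emit_variant_calls <- function(truth, config = simulation_config()) {
  set.seed(config$seed + 1000L)
  vt <- truth[truth$kind %in% c("SNP", "INS", "DEL"), , drop = FALSE]
  build <- function(direction) {
    rows <- vt[if (direction == "ab") !is.na(vt$contig_b)
               else !is.na(vt$contig_a), , drop = FALSE]
    if (nrow(rows) == 0) {
      return(variant_records(data.frame(
        contig_id = character(), pos = integer(), ref = character(),
        alt = character(), DP = integer(), MQ = numeric(),
        MQ0 = integer(), QUAL = numeric(), ad_ref = integer(),
        ad_alt = integer(), stringsAsFactors = FALSE)))
    }
    n <- nrow(rows)
    dp <- pmax(10L, as.integer(round(rnorm(n, config$depth_mean, 4))))
    if (direction == "ab") {
      contig <- rows$contig_b; pos <- rows$start_b
      ref <- rows$allele_b; alt <- rows$allele_a
      zyg <- rows$zyg_a
    } else {
      contig <- rows$contig_a; pos <- rows$start_a
      ref <- rows$allele_a; alt <- rows$allele_b
      zyg <- rows$zyg_b
    }
    ad_ref <- integer(n); ad_alt <- integer(n)
    for (i in seq_len(n)) {
      ad <- draw_allele_depths(zyg[i], dp[i])
      # the sampled parent's own allele (alt) is the major allele when HOM
      ad_alt[i] <- ad[["major"]]; ad_ref[i] <- ad[["minor"]]
    }
    variant_records(data.frame(
      contig_id = contig, pos = as.integer(pos), ref = ref, alt = alt,
      DP = dp, MQ = 60, MQ0 = 0L, QUAL = 200, ad_ref = ad_ref,
      ad_alt = ad_alt, stringsAsFactors = FALSE))
  }
  ab <- build("ab"); ba <- build("ba")
  expected <- list()
  apply_noise <- function(tab, direction) {
    n <- nrow(tab)
    decision <- rep("KEEP", n); reason <- rep(NA_character_, n)
    indels <- which(tab$vtype != "SNP")
    snps <- which(tab$vtype == "SNP")
    pool <- indels
    grab <- function(frac, from) {
      k <- round(frac * length(from))
      if (k == 0) return(integer(0))
      take <- from[seq_len(k)]
      take
    }
    nz <- config$noise
    i_mq0 <- grab(nz$frac_fail_mq0, pool); pool <- setdiff(pool, i_mq0)
    i_mq <- grab(nz$frac_fail_mq, pool); pool <- setdiff(pool, i_mq)
    i_qual <- grab(nz$frac_fail_qual, pool); pool <- setdiff(pool, i_qual)
    i_dp <- grab(nz$frac_fail_dp, pool)
    i_snp <- grab(nz$frac_snp_lowdp, snps)
    if (length(i_mq0)) {
      tab$MQ0[i_mq0] <- pmax(4L, ceiling(0.12 * tab$DP[i_mq0]))
      decision[i_mq0] <- "REMOVE"; reason[i_mq0] <- "MQ0_ratio"
    }
    if (length(i_mq)) {
      tab$MQ[i_mq] <- 25
      decision[i_mq] <- "REMOVE"; reason[i_mq] <- "MQ<30"
    }
    if (length(i_qual)) {
      tab$QUAL[i_qual] <- 30
      decision[i_qual] <- "REMOVE"; reason[i_qual] <- "QUAL<50"
    }
    if (length(i_dp)) {
      tab$DP[i_dp] <- 4L
      tab$ad_ref[i_dp] <- pmin(tab$ad_ref[i_dp], 1L)
      tab$ad_alt[i_dp] <- 3L
      decision[i_dp] <- "REMOVE"; reason[i_dp] <- "DP<5"
    }
    if (length(i_snp)) {
      tab$DP[i_snp] <- 7L
      tab$ad_ref[i_snp] <- pmin(tab$ad_ref[i_snp], 1L)
      tab$ad_alt[i_snp] <- 6L
      decision[i_snp] <- "REMOVE"; reason[i_snp] <- "DP<min"
    }
    expected[[direction]] <<- data.frame(
      direction = direction, contig_id = tab$contig_id, pos = tab$pos,
      decision = decision, reason = reason, stringsAsFactors = FALSE)
    tab
  }
  ab <- apply_noise(ab, "ab")
  ba <- apply_noise(ba, "ba")
  list(ab = ab, ba = ba, expected = do.call(rbind, expected))
}

#' Build a known-marker database fixture
#'
#' For a chosen fraction of the candidate (in-silico polymorphic or
#' parent-only) planted SSR markers, the database receives a record that
#' shares at least the matched-bases threshold of identical non-repeat
#' bases with the marker's inter-primer sequence. Because the primer picker
#' is deterministic, the fixture designs the same singleton primer pair the
#' pipeline will, masks the repeat out of the amplicon, and copies the
#' longest contiguous non-repeat stretch into the record (padded with
#' random sequence so it reads like a published marker). Candidates whose
#' amplicon cannot supply such a stretch are skipped (they could never be
#' recognised as redundant by a masked-alignment rule). All remaining
#' records are unrelated random sequence.
#'
#' @param truth truth table from [generate_parents()].
#' @param contigs_a,contigs_b the generated parental contig sets.
#' @param overlap_fraction fraction of candidate SSR markers to cover.
#' @param seed RNG seed for record selection and random records.
#' @param config [simulation_config()] (random-record count, GC).
#' @param pconfig [pipeline_config()] used for the deterministic primer
#'   design and the matched-bases threshold; must match the config the
#'   pipeline is run with.
#' @return list with `db` (contig data.frame usable as the known-marker
#'   database) and `redundant_features` (feature ids expected to be flagged
#'   redundant).
#' @export
known_db_fixture <- function(truth, contigs_a, contigs_b,
                             overlap_fraction = 0.5, seed = 1L,
                             config = simulation_config(),
                             pconfig = pipeline_config()) {
  stopifnot(overlap_fraction >= 0, overlap_fraction <= 1)
  # offset so the fixture's RNG stream never replays the contig generator's
  # stream when both are handed the same base seed
  set.seed(seed + 77777L)
  cand <- truth[truth$kind == "SSR" &
                  (truth$expected_poly |
                     truth$expected_status %in% c("A_ONLY", "B_ONLY")), ,
                drop = FALSE]
  n_over <- round(overlap_fraction * nrow(cand))
  ord <- if (nrow(cand)) sample(nrow(cand)) else integer(0)
  ids <- character(0); seqs <- character(0); chosen <- character(0)
  for (i in ord) {
    if (length(chosen) >= n_over) break
    r <- cand[i, ]
    if (!is.na(r$contig_a)) {
      src <- contigs_a$sequence[match(r$contig_a, contigs_a$id)]
      st <- r$start_a; en <- r$end_a
    } else {
      src <- contigs_b$sequence[match(r$contig_b, contigs_b$id)]
      st <- r$start_b; en <- r$end_b
    }
    region <- data.frame(span_start = st, span_end = en, clustered = FALSE)
    pp <- design_primers(region, src, pconfig)
    if (is.null(pp)) next
    amplicon <- interprimer_sequence(pp, src)
    rel <- data.frame(start = st - pp$left_start + 1L,
                      end = en - pp$left_start + 1L)
    masked <- mask_ssr(amplicon, rel)
    # longest contiguous non-masked stretch of the amplicon
    runs <- gregexpr("[^N]+", masked)[[1]]
    if (runs[1] == -1L) next
    lens <- attr(runs, "match.length")
    k <- which.max(lens)
    if (lens[k] < pconfig$redundancy_matched_min) next
    stretch <- substr(masked, runs[k], runs[k] + lens[k] - 1L)
    rec <- paste0(random_dna(30, config$gc_target), stretch,
                  random_dna(30, config$gc_target))
    ids <- c(ids, sprintf("KDB_%s", r$feature_id))
    seqs <- c(seqs, rec)
    chosen <- c(chosen, r$feature_id)
  }
  for (j in seq_len(config$db_n_random)) {
    ids <- c(ids, sprintf("KDB_rand_%03d", j))
    seqs <- c(seqs, random_dna(sample(200:400, 1), config$gc_target))
  }
  list(db = contig_set(ids, seqs, "DB"),
       redundant_features = chosen)
}
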