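#' Run the whole marker-development pipeline
#'
#' Executes the workflow end to end: SSR mining per parent, flank
#' extraction, cross-parent anchoring and partition of SSR markers,
#' hard-filtering and zygosity classification of the two reciprocal
#' variant tables, anchoring and classification of shared variant sites,
#' primer-region clustering and primer design for the candidate screening
#' set, known-marker redundancy screening of candidate SSRs, and the
#' summary statistics block. Deterministic given config and inputs; count
#' identities (partition completeness) are self-checked before returning.
#'
#' @param config [pipeline_config()].
#' @param contigs_a,contigs_b parental contig sets ([read_fasta()]).
#' @param variants_ab variant records of parent A's reads mapped to parent
#'   B's contigs ([read_variant_table()]); sites live on B contigs.
#' @param variants_ba the reciprocal table; sites live on A contigs.
#' @param known_db known-marker database contig data.frame, or `NULL` to
#'   skip redundancy screening.
#' @return `pipeline_result` list: `ssr` (loci, flanked markers, anchors,
#'   partition, summaries), `variants` (audits, kept records, anchors,
#'   partition, classification), `candidates`, `regions`, `primers`,
#'   `redundancy`, `stats`.
#' @export
run_pipeline <- function(config, contigs_a, contigs_b, variants_ab,
                         variants_ba, known_db = NULL) {
  validate_config(config)
  ## 1. SSR mining per parent
  loci_a <- mine_ssrs(contigs_a, config)
  loci_b <- mine_ssrs(contigs_b, config)
  ssr_markers <- function(loci, genotype) {
    if (nrow(loci) == 0) {
      return(data.frame(marker_id = character(), genotype = character(),
                        kind = character(), contig_id = character(),
                        start = integer(), end = integer(),
                        repeats = integer(), canonical_class = character(),
                        stringsAsFactors = FALSE))
    }
    data.frame(marker_id = sprintf("%s|SSR|%s|%d", genotype,
                                   loci$contig_id, loci$start),
               genotype = genotype, kind = "SSR",
               contig_id = loci$contig_id, start = loci$start,
               end = loci$end, repeats = loci$repeats,
               canonical_class = loci$canonical_class,
               stringsAsFactors = FALSE)
  }
  ma <- ssr_markers(loci_a, "A")
  mb <- ssr_markers(loci_b, "B")
  ## 2. flank extraction
  fma <- extract_flanks_all(ma, contigs_a, config$flank_min,
                            config$flank_max)
  fmb <- extract_flanks_all(mb, contigs_b, config$flank_min,
                            config$flank_max)
  ## 3. anchoring + in-silico SSR polymorphism
  ssr_anchors <- anchor_markers(fma, fmb, config)
  ssr_poly <- character(0); ssr_inconsistent <- character(0)
  for (i in seq_len(nrow(ssr_anchors))) {
    a <- fma[match(ssr_anchors$marker_a[i], fma$marker_id), , drop = FALSE]
    b <- fmb[match(ssr_anchors$marker_b[i], fmb$marker_id), , drop = FALSE]
    cl <- classify_ssr_pair(a, b)
    if (cl$inconsistent)
      ssr_inconsistent <- c(ssr_inconsistent, a$marker_id)
    else if (cl$polymorphic) ssr_poly <- c(ssr_poly, a$marker_id)
  }
  ssr_partition <- partition_markers(fma, fmb, ssr_anchors, ssr_poly)
  ## 4. variant hard filters + zygosity
  scr_ab <- screen_variants(variants_ab, config)
  scr_ba <- screen_variants(variants_ba, config)
  var_markers <- function(kept, genotype) {
    if (nrow(kept) == 0) {
      return(data.frame(marker_id = character(), genotype = character(),
                        kind = character(), contig_id = character(),
                        start = integer(), end = integer(),
                        allele = character(), call = character(),
                        stringsAsFactors = FALSE))
    }
    data.frame(marker_id = sprintf("%s|%s|%s|%d", genotype, kept$vtype,
                                   kept$contig_id, kept$pos),
               genotype = genotype, kind = kept$vtype,
               contig_id = kept$contig_id, start = kept$pos,
               end = kept$pos + nchar(kept$ref) - 1L,
               allele = kept$alt, call = kept$call,
               stringsAsFactors = FALSE)
  }
  vab <- var_markers(scr_ab$kept, "AB")
  vba <- var_markers(scr_ba$kept, "BA")
  ## 5. anchor shared variant sites (AB markers live on B contigs)
  fvab <- extract_flanks_all(vab, contigs_b, config$flank_min,
                             config$flank_max)
  fvba <- extract_flanks_all(vba, contigs_a, config$flank_min,
                             config$flank_max)
  var_anchors <- anchor_markers(fvab, fvba, config)
  var_poly <- character(0)
  for (i in seq_len(nrow(var_anchors))) {
    a <- fvab[match(var_anchors$marker_a[i], fvab$marker_id), ,
              drop = FALSE]
    b <- fvba[match(var_anchors$marker_b[i], fvba$marker_id), ,
              drop = FALSE]
    if (classify_variant_pair(a$allele, b$allele, a$call, b$call))
      var_poly <- c(var_poly, a$marker_id)
  }
  var_partition <- partition_markers(fvab, fvba, var_anchors, var_poly)
  ## 6. candidate screening set
  all_flanked <- rbind(
    fma[, c("marker_id", "genotype", "kind", "contig_id", "start", "end")],
    fmb[, c("marker_id", "genotype", "kind", "contig_id", "start", "end")],
    fvab[, c("marker_id", "genotype", "kind", "contig_id", "start", "end")],
    fvba[, c("marker_id", "genotype", "kind", "contig_id", "start", "end")])
  candidates <- c(ssr_partition$candidates, var_partition$candidates)
  cand_tab <- all_flanked[all_flanked$marker_id %in% candidates, ,
                          drop = FALSE]
  ## 7. primer-region clustering and design
  contig_of <- function(genotype) {
    if (genotype %in% c("A", "BA")) contigs_a else contigs_b
  }
  regions <- list(); primers <- list(); failures <- list()
  for (grp in split(cand_tab, paste(cand_tab$genotype,
                                    cand_tab$contig_id))) {
    contigs <- contig_of(grp$genotype[1])
    cseq <- contigs$sequence[match(grp$contig_id[1], contigs$id)]
    regs <- cluster_markers(grp, config$cluster_dist, config = config)
    regs$genotype <- grp$genotype[1]
    regs$contig_id <- grp$contig_id[1]
    regs$region_id <- sprintf("%s|%s|%s", grp$genotype[1],
                              grp$contig_id[1], regs$region_id)
    for (i in seq_len(nrow(regs))) {
      pp <- design_primers(regs[i, , drop = FALSE], cseq, config)
      if (is.null(pp)) {
        failures[[length(failures) + 1L]] <- data.frame(
          region_id = regs$region_id[i], members = regs$members[i],
          reason = "no acceptable primer pair", stringsAsFactors = FALSE)
      } else {
        pp$region_id <- regs$region_id[i]
        pp$members <- regs$members[i]
        primers[[length(primers) + 1L]] <- pp
      }
    }
    regions[[length(regions) + 1L]] <- regs
  }
  regions <- if (length(regions)) do.call(rbind, regions) else NULL
  primer_tab <- if (length(primers)) do.call(rbind, primers) else NULL
  failure_tab <- if (length(failures)) do.call(rbind, failures) else NULL
  ## 8. known-marker redundancy screening of candidate SSRs
  redundancy <- NULL
  if (!is.null(known_db) && !is.null(primer_tab)) {
    red_rows <- list()
    ssr_cand <- cand_tab[cand_tab$kind == "SSR", , drop = FALSE]
    loci_all <- rbind(cbind(loci_a, genotype = "A"),
                      cbind(loci_b, genotype = "B"))
    member_lists <- strsplit(regions$members, ",", fixed = TRUE)
    region_of <- rep(seq_len(nrow(regions)), lengths(member_lists))
    names(region_of) <- unlist(member_lists)
    for (i in seq_len(nrow(ssr_cand))) {
      mk <- ssr_cand[i, ]
      reg_i <- unname(region_of[mk$marker_id])
      if (is.na(reg_i)) next
      pp <- primer_tab[primer_tab$region_id ==
                         regions$region_id[reg_i], , drop = FALSE]
      if (nrow(pp) == 0) next # design failed; no amplicon to screen
      contigs <- contig_of(mk$genotype)
      cseq <- contigs$sequence[match(mk$contig_id, contigs$id)]
      amplicon <- interprimer_sequence(pp[1, ], cseq)
      spans <- loci_all[loci_all$genotype == mk$genotype &
                          loci_all$contig_id == mk$contig_id, , drop = FALSE]
      spans <- spans[spans$end >= pp$left_start[1] &
                       spans$start <= pp$right_end[1], , drop = FALSE]
      rel <- data.frame(start = pmax(spans$start - pp$left_start[1] + 1L, 1L),
                        end = pmin(spans$end - pp$left_start[1] + 1L,
                                   nchar(amplicon)))
      masked <- mask_ssr(amplicon, rel)
      res <- is_redundant(masked, known_db, config$redundancy_matched_min,
                          config)
      red_rows[[length(red_rows) + 1L]] <- data.frame(
        marker_id = mk$marker_id, redundant = res$redundant,
        matched_bases = res$matched_bases,
        db_hit = if (is.null(res$best)) NA_character_
                 else res$best$subject_id,
        stringsAsFactors = FALSE)
    }
    redundancy <- if (length(red_rows)) do.call(rbind, red_rows) else NULL
  }
  ## 9. statistics block + self-checks
  kb_a <- sum(contigs_a$length) / 1000
  kb_b <- sum(contigs_b$length) / 1000
  sum_a <- ssr_summary(loci_a, max(kb_a, 1e-9))
  sum_b <- ssr_summary(loci_b, max(kb_b, 1e-9))
  kept_snps <- rbind(scr_ab$kept[scr_ab$kept$vtype == "SNP", , drop = FALSE],
                     scr_ba$kept[scr_ba$kept$vtype == "SNP", , drop = FALSE])
  stats <- list(
    contigs_a = nrow(contigs_a), contigs_b = nrow(contigs_b),
    total_kb_a = round_half_up(kb_a, 2), total_kb_b = round_half_up(kb_b, 2),
    ssr_total_a = sum_a$total, ssr_total_b = sum_b$total,
    ssr_compound_a = sum_a$n_compound, ssr_compound_b = sum_b$n_compound,
    ssr_frequency_a = sum_a$frequency, ssr_frequency_b = sum_b$frequency,
    ssr_shared = unname(ssr_partition$counts["shared"]),
    ssr_insilico_poly = unname(ssr_partition$counts["insilico_poly"]),
    ssr_a_only = unname(ssr_partition$counts["a_only"]),
    ssr_b_only = unname(ssr_partition$counts["b_only"]),
    ssr_candidates = unname(ssr_partition$counts["candidates"]),
    ssr_ambiguous = sum(ssr_anchors$ambiguity > 1),
    ssr_inconsistent = length(ssr_inconsistent),
    var_kept_ab = nrow(scr_ab$kept), var_kept_ba = nrow(scr_ba$kept),
    var_removed_ab = sum(scr_ab$audit$decision == "REMOVE"),
    var_removed_ba = sum(scr_ba$audit$decision == "REMOVE"),
    var_shared = unname(var_partition$counts["shared"]),
    var_homhom_poly = unname(var_partition$counts["insilico_poly"]),
    var_ab_only = unname(var_partition$counts["a_only"]),
    var_ba_only = unname(var_partition$counts["b_only"]),
    var_candidates = unname(var_partition$counts["candidates"]),
    tstv_kept = if (nrow(kept_snps)) round_half_up(tstv_ratio(kept_snps), 2)
                else NA_real_,
    candidates_total = length(candidates),
    primers_designed = if (is.null(primer_tab)) 0L else nrow(primer_tab),
    primer_failures = if (is.null(failure_tab)) 0L else nrow(failure_tab),
    redundant_ssrs = if (is.null(redundancy)) NA_integer_
                     else sum(redundancy$redundant)
  )
  ## partition completeness self-checks
  chk <- function(part, fmx, fmy) {
    tab <- table(factor(part$status$status,
                        levels = c("SHARED", "A_ONLY", "B_ONLY",
                                   "UNANCHORABLE")))
    n_sh <- unname(part$counts["shared"])
    if (2L * n_sh != unname(tab["SHARED"]))
      stop("partition self-check failed: shared pairing inconsistent")
    total <- unname(tab["SHARED"]) + unname(tab["A_ONLY"]) +
      unname(tab["B_ONLY"]) + unname(tab["UNANCHORABLE"])
    if (total != nrow(fmx) + nrow(fmy))
      stop("partition self-check failed: statuses not exhaustive")
  }
  chk(ssr_partition, fma, fmb)
  chk(var_partition, fvab, fvba)
  structure(list(
    config = config,
    ssr = list(loci_a = loci_a, loci_b = loci_b, flanked_a = fma,
               flanked_b = fmb, anchors = ssr_anchors,
               polymorphic = ssr_poly, inconsistent = ssr_inconsistent,
               partition = ssr_partition, summary_a = sum_a,
               summary_b = sum_b),
    variants = list(audit_ab = scr_ab$audit, audit_ba = scr_ba$audit,
                    kept_ab = scr_ab$kept, kept_ba = scr_ba$kept,
                    flanked_ab = fvab, flanked_ba = fvba,
                    anchors = var_anchors, polymorphic = var_poly,
                    partition = var_partition),
    candidates = cand_tab, regions = regions, primers = primer_tab,
    primer_failures = failure_tab, redundancy = redundancy,
    stats = stats), class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  s <- x$stats
  cat("<pipeline_result>\n")
  cat(sprintf("  contigs: %d (A) / %d (B); %s / %s kb\n", s$contigs_a,
              s$contigs_b, s$total_kb_a, s$total_kb_b))
  cat(sprintf("  SSRs: %d (A) / %d (B); shared %d, in-silico poly %d,\n",
              s$ssr_total_a, s$ssr_total_b, s$ssr_shared,
              s$ssr_insilico_poly))
  cat(sprintf("    A-only %d, B-only %d -> %d SSR candidates\n",
              s$ssr_a_only, s$ssr_b_only, s$ssr_candidates))
  cat(sprintf("  variants kept: %d (A/B) / %d (B/A); shared %d,",
              s$var_kept_ab, s$var_kept_ba, s$var_shared))
  cat(sprintf(" hom-hom poly %d\n", s$var_homhom_poly))
  cat(sprintf("  candidates %d; primers %d designed, %d failed\n",
              s$candidates_total, s$primers_designed, s$primer_failures))
  invisible(x)
}

#' Write the pipeline's report
#'
#' @param result `pipeline_result` from [run_pipeline()].
#' @param path output TSV path.
#' @export
write_pipeline_report <- function(result, path) {
  status <- rbind(result$ssr$partition$status,
                  result$variants$partition$status)
  fl <- rbind(result$ssr$flanked_a, result$ssr$flanked_b)[,
    c("marker_id", "contig_id", "start")]
  flv <- rbind(result$variants$flanked_ab, result$variants$flanked_ba)[,
    c("marker_id", "contig_id", "start")]
  markers <- merge(status, rbind(fl, flv), by = "marker_id", sort = FALSE)
  write_marker_report(markers, result$stats, path)
}
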