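#' Hard-filter an InDel record
#'
#' An InDel call is removed when it conforms to any one of the four
#' conditions `{(MQ0 >= 4 AND MQ0/DP > 0.1); MQ < 30.0; QUAL < 50; DP < 5}`.
#' The bracketed pair is the standard conjunction of the hard-filter idiom:
#' at least four mapping-quality-zero reads AND those reads exceeding 10% of
#' the total depth. The reason reported is the first failing clause in the
#' order above; a record with `DP = 0` is removed as `DP<5` without
#' evaluating the ratio.
#'
#' @param record one-row variant data.frame (INS or DEL) with `DP`, `MQ`,
#'   `MQ0`, `QUAL`.
#' @return list with `decision` (`"KEEP"`/`"REMOVE"`) and `reason`
#'   (`NA` when kept).
#' @export
indel_hard_filter <- function(record) {
  stopifnot(record$vtype %in% c("INS", "DEL"))
  if (record$DP == 0) return(list(decision = "REMOVE", reason = "DP<5"))
  if (record$MQ0 >= 4 && record$MQ0 / (1.0 * record$DP) > 0.1)
    return(list(decision = "REMOVE", reason = "MQ0_ratio"))
  if (record$MQ < 30.0) return(list(decision = "REMOVE", reason = "MQ<30"))
  if (record$QUAL < 50) return(list(decision = "REMOVE", reason = "QUAL<50"))
  if (record$DP < 5) return(list(decision = "REMOVE", reason = "DP<5"))
  list(decision = "KEEP", reason = NA_character_)
}

#' Depth-screen a SNP record
#'
#' @param record one-row SNP variant data.frame.
#' @param min_depth minimum coverage depth (inclusive), default 8.
#' @return `"KEEP"` when `DP >= min_depth`, else `"REMOVE"`.
#' @export
snp_depth_filter <- function(record, min_depth = 8L) {
  stopifnot(record$vtype == "SNP")
  if (record$DP >= min_depth) "KEEP" else "REMOVE"
}

#' Classify site zygosity from allele depths
#'
#' The minor-allele frequency is `min(ad_ref, ad_alt) / (ad_ref + ad_alt)`.
#' A site is called homozygous when MAF is strictly below `hom_thr`
#' (default 0.10), heterozygous when strictly above `het_thr` (default
#' 0.25), and unknown in between (boundary values inclusive to unknown).
#'
#' @param record one-row variant data.frame with `ad_ref`, `ad_alt`.
#' @param hom_thr,het_thr MAF thresholds, `hom_thr < het_thr`.
#' @return list with `maf` and `call` (`"HOM"`/`"HET"`/`"UNKNOWN"`).
#' @export
zygosity <- function(record, hom_thr = 0.10, het_thr = 0.25) {
  tot <- record$ad_ref + record$ad_alt
  if (tot <= 0) stop("zygosity undefined: zero summed allele depth")
  maf <- min(record$ad_ref, record$ad_alt) / tot
  call <- if (maf < hom_thr) "HOM" else if (maf > het_thr) "HET" else "UNKNOWN"
  list(maf = maf, call = call)
}

#' Transition/transversion ratio of a SNP set
#'
#' Transitions are the purine-purine (A<->G) and pyrimidine-pyrimidine
#' (C<->T) substitutions; all other substitutions are transversions.
#'
#' @param snps variant data.frame restricted to SNPs (`ref`, `alt` single
#'   bases).
#' @return ratio, or `NA` when there are no transversions (or no SNPs).
#' @export
tstv_ratio <- function(snps) {
  if (is.null(snps) || nrow(snps) == 0) return(NA_real_)
  pair <- paste0(pmin(snps$ref, snps$alt), pmax(snps$ref, snps$alt))
  ts <- sum(pair %in% c("AG", "CT"))
  tv <- nrow(snps) - ts
  if (tv == 0) return(NA_real_)
  ts / tv
}

#' Screen a variant table: hard filters plus zygosity calls
#'
#' Applies [indel_hard_filter()] to INS/DEL records and
#' [snp_depth_filter()] to SNP records, then calls zygosity on every kept
#' record. Sites whose summed allele depth is zero are flagged and
#' excluded. Filtering is idempotent: screening the kept set again changes
#' nothing.
#'
#' @param records variant data.frame ([read_variant_table()]).
#' @param config [pipeline_config()].
#' @return list with `audit` (one row per input record: `decision`,
#'   `reason`, `maf`, `call`) and `kept` (the surviving records with `maf`
#'   and `call` columns).
#' @export
screen_variants <- function(records, config = pipeline_config()) {
  n <- nrow(records)
  decision <- character(n); reason <- rep(NA_character_, n)
  maf <- rep(NA_real_, n); call <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    rec <- records[i, , drop = FALSE]
    if (rec$vtype == "SNP") {
      decision[i] <- snp_depth_filter(rec, config$snp_min_depth)
      if (decision[i] == "REMOVE") reason[i] <- "DP<min"
    } else {
      f <- indel_hard_filter(rec)
      decision[i] <- f$decision
      reason[i] <- f$reason
    }
    if (decision[i] == "KEEP") {
      if (rec$ad_ref + rec$ad_alt <= 0) {
        decision[i] <- "REMOVE"
        reason[i] <- "no_allele_depth"
      } else {
        z <- zygosity(rec, config$maf_hom, config$maf_het)
        maf[i] <- z$maf
        call[i] <- z$call
      }
    }
  }
  audit <- cbind(records[, c("contig_id", "pos", "ref", "alt", "vtype")],
                 data.frame(decision = decision, reason = reason, maf = maf,
                            call = call, stringsAsFactors = FALSE))
  kept <- cbind(records, data.frame(maf = maf, call = call))[
    decision == "KEEP", , drop = FALSE]
  rownames(kept) <- NULL
  list(audit = audit, kept = kept)
}
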