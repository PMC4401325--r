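#!/usr/bin/env Rscript
# Step 4 — variant screening.
#
# Applies the hard filters to the two reciprocal variant tables — InDels
# removed when (MQ0 >= 4 AND MQ0/DP > 0.1) OR MQ < 30 OR QUAL < 50 OR
# DP < 5; SNPs kept at coverage depth >= 8 — then classifies each kept
# site's zygosity from its minor-allele frequency (< 0.10 homozygous,
# > 0.25 heterozygous, boundaries unknown) and reports the ts/tv ratio of
# the kept SNPs.

suppressPackageStartupMessages(library(radmarker))
cfg <- pipeline_config()

kept_snps <- list()
for (dir in c("AB", "BA")) {
  tab <- read_variant_table(sprintf("results/sim/variants_%s.tsv", dir))
  scr <- screen_variants(tab, cfg)
  write.table(scr$audit, sprintf("results/variant_audit_%s.tsv", dir),
              sep = "\t", quote = FALSE, row.names = FALSE)
  rm_tab <- table(scr$audit$reason[scr$audit$decision == "REMOVE"])
  message(sprintf("%s: %d records, %d kept, %d removed (%s)", dir,
                  nrow(tab), nrow(scr$kept),
                  sum(scr$audit$decision == "REMOVE"),
                  if (length(rm_tab)) paste(names(rm_tab), rm_tab,
                                            sep = "=", collapse = ", ")
                  else "none"))
  zt <- table(scr$kept$call)
  message(sprintf("  zygosity: %s",
                  paste(names(zt), zt, sep = "=", collapse = ", ")))
  kept_snps[[dir]] <- scr$kept[scr$kept$vtype == "SNP", ]
}
snps <- do.call(rbind, kept_snps)
message(sprintf("ts/tv of %d kept SNPs: %.3f", nrow(snps),
                tstv_ratio(snps)))
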