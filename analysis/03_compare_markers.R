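#!/usr/bin/env Rscript
# Step 3 — cross-genotype SSR comparison.
#
# Extracts >= 20 bp flanks around every mined SSR, anchors markers between
# the parents by seeded local alignment of both flanks (E <= 1e-5,
# consistent orientation and geometry), and partitions markers into
# shared / in-silico polymorphic (repeat-count difference) / parent-only.
# The candidate screening set is the union of the polymorphic and
# parent-only markers — the arithmetic behind totals like 67 + 598 + 658.

suppressPackageStartupMessages(library(radmarker))
cfg <- pipeline_config()

contigs_a <- read_fasta("results/sim/parent_A.fa", "A")
contigs_b <- read_fasta("results/sim/parent_B.fa", "B")
mk <- function(parent, contigs) {
  loci <- read.delim(sprintf("results/ssr_loci_%s.tsv", parent))
  m <- data.frame(marker_id = sprintf("%s|SSR|%s|%d", parent,
                                      loci$contig_id, loci$start),
                  genotype = parent, kind = "SSR",
                  contig_id = loci$contig_id, start = loci$start,
                  end = loci$end, repeats = loci$repeats,
                  canonical_class = loci$canonical_class)
  radmarker:::extract_flanks_all(m, contigs, cfg$flank_min, cfg$flank_max)
}
fma <- mk("A", contigs_a)
fmb <- mk("B", contigs_b)
anchors <- anchor_markers(fma, fmb, cfg)
poly <- character(0)
for (i in seq_len(nrow(anchors))) {
  a <- fma[match(anchors$marker_a[i], fma$marker_id), ]
  b <- fmb[match(anchors$marker_b[i], fmb$marker_id), ]
  if (classify_ssr_pair(a, b)$polymorphic) poly <- c(poly, a$marker_id)
}
part <- partition_markers(fma, fmb, anchors, poly)
write.table(part$status, "results/ssr_partition.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cnt <- part$counts
message(sprintf(
  "shared %d (in-silico polymorphic %d), A-only %d, B-only %d",
  cnt["shared"], cnt["insilico_poly"], cnt["a_only"], cnt["b_only"]))
message(sprintf("candidate screening set: %d + %d + %d = %d SSRs",
                cnt["insilico_poly"], cnt["a_only"], cnt["b_only"],
                screening_candidates(cnt["insilico_poly"], cnt["a_only"],
                                     cnt["b_only"])))
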