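#!/usr/bin/env Rscript
# Step 1 — simulate the study conditions.
#
# Generates the two synthetic parental contig sets with planted,
# truth-tracked divergence (shared-equal, repeat-divergent and parent-only
# SSRs; shared and direction-only SNP/InDel sites at catalogue-like
# proportions), the two reciprocal caller-style variant tables, and the
# known-marker database fixture. Everything downstream reads these files,
# so the whole analysis is reproducible from one seed.

suppressPackageStartupMessages(library(radmarker))
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 2 && args[1] == "--seed") as.integer(args[2]) else 1L

dir.create("results/sim", recursive = TRUE, showWarnings = FALSE)

cfg <- simulation_config(seed = seed)
message("simulating parents (seed ", seed, ") ...")
sim <- generate_parents(cfg)
calls <- emit_variant_calls(sim$truth, cfg)
db <- known_db_fixture(sim$truth, sim$contigs_a, sim$contigs_b,
                       overlap_fraction = cfg$db_overlap, seed = seed, cfg)

write_fasta(sim$contigs_a, "results/sim/parent_A.fa")
write_fasta(sim$contigs_b, "results/sim/parent_B.fa")
write_variant_table(calls$ab, "results/sim/variants_AB.tsv")
write_variant_table(calls$ba, "results/sim/variants_BA.tsv")
write_fasta(db$db, "results/sim/known_markers.fa")
write.table(sim$truth, "results/sim/truth.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
writeLines(db$redundant_features, "results/sim/expected_redundant.txt")

message(sprintf(
  "wrote %d A contigs (%.1f kb), %d B contigs (%.1f kb), %d truth rows,",
  nrow(sim$contigs_a), sum(sim$contigs_a$length) / 1000,
  nrow(sim$contigs_b), sum(sim$contigs_b$length) / 1000, nrow(sim$truth)))
message(sprintf("  %d + %d variant records, %d known-marker records",
                nrow(calls$ab), nrow(calls$ba), nrow(db$db)))
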