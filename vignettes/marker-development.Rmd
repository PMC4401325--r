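---
title: "In-silico marker development from two parental RAD-seq assemblies"
author: "radmarker"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{In-silico marker development from two parental RAD-seq assemblies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radmarker)
```

## The problem

Intraspecific crops with narrow genetic bases — upland cotton is the
archetype — show very low marker polymorphism between mapping parents, so
enriching a genetic map requires mining markers directly from the parents'
own genome sequence. Reduced-representation (RAD) sequencing of the two
parents yields two de-novo contig sets of a few tens of Mb each. From
those, three marker classes can be predicted *in silico*:

* **SSRs** whose repeat count differs between the parents,
* **SNP sites** at which both parents are homozygous for different
  alleles, and
* **InDel sites** with the same homozygous-polymorphic configuration,

plus the parent-specific markers (present in only one assembly) that are
worth screening because the other parent may simply lack the locus from
its reduced representation. radmarker implements this comparison pipeline
end to end, together with a synthetic dual-parent generator so that every
stage can be verified against a planted truth table without any external
download.

## The procedure

1. **SSR mining.** Each contig is scanned for maximal perfect tandem
   repeats of primitive 2–8 bp motifs. The complete-unit minima are the
   classical microsatellite-search settings: 7 units for dinucleotides, 5
   for tri-, 4 for tetra-, and 3 for penta- through octanucleotides.
   Mononucleotide runs are not searched. Runs separated by at most 500
   interrupting bases form a *compound* SSR. Motifs are reported by their
   canonical class — the lexicographically smallest string over all cyclic
   rotations of the motif and of its reverse complement, printed as
   `AT/AT`, `AAG/CTT`, and so on.
2. **Flank anchoring.** A marker in one parent is declared the *same
   locus* as a marker in the other when both of its immediate flanking
   sequences (≥ 20 bp, up to 200 bp) align to the flanks of a single
   partner marker with E ≤ 1e−5, consistent orientation (left–left /
   right–right on the plus strand, swapped on minus) and compatible
   geometry (the spans implied by the two flank pairs must agree within
   50 bp). Alignment is a seeded local alignment: an exact shared 11-mer
   is required, after which the optimal affine-gap local alignment is
   computed by dynamic programming (match +1, mismatch −2, gap of length
   L costing 5 + 2(L−1)). E-values use the standard extreme-value
   expectation `E = K·m·n·exp(−λS)` with ungapped nucleotide constants
   K = 0.711, λ = 1.37, applied to gapped scores as an approximation; m is
   the query flank length and n the total flank collection length of the
   partner set, recomputed per search.
3. **Partition and classification.** Every marker lands in exactly one
   status: SHARED (anchored), parent-only, or UNANCHORABLE (a flank
   shorter than 20 bp). A shared SSR pair is in-silico polymorphic exactly
   when the repeat counts differ (a pair anchored across different
   canonical classes is flagged as an inconsistency instead). A shared
   variant site is polymorphic when both parents' calls are homozygous and
   the alleles differ.
4. **Variant screening.** InDel records are removed when any of four
   conditions holds: (MQ0 ≥ 4 AND MQ0/DP > 0.1), MQ < 30.0, QUAL < 50, or
   DP < 5 — the bracketed pair is the usual hard-filter conjunction. SNPs
   are kept at coverage depth ≥ 8. Zygosity is called from the
   minor-allele frequency of the two most-supported alleles:
   homozygous below 0.10, heterozygous above 0.25, unknown in between
   (both boundary values land in unknown, because the defining wording is
   strictly "below"/"above").
5. **Primer regions.** Candidate markers closer than 500 bp on one contig
   share one primer region (single linkage, strict `<`); chains too long
   for any product under 800 bp are split at their largest gaps. The
   deterministic primer picker scans 18–24-mers within a 150 bp window on
   each side, rejects candidates with GC outside 40–60 %, any N, or a
   reverse-complement-palindromic 3′ terminal 4-mer, and minimises
   `|len − 20| + |Tm − 57| + 0.2·|GC − 50|` summed over the pair, plus
   `0.01·|product − 300|` for singleton regions (product 100–500 bp for
   singletons, < 800 bp for clustered regions). Ties break by smaller
   left-primer position, then smaller product, so reruns are
   byte-identical. Tm is the basic formula `64.9 + 41·(GC_count −
   16.4)/len`.
6. **Known-marker redundancy.** For each candidate SSR the inter-primer
   (amplicon) sequence is extracted, its SSR spans are masked to N, and
   the remainder is aligned against the known-marker database; the marker
   is *redundant* when the single best local alignment carries ≥ 50
   identities. N positions can never count as matches, so the repeat
   itself cannot drive redundancy.
7. **Statistics.** Polymorphism rates (percent, two decimals), marker
   frequencies (kb of assembly per marker, printed `1/X kb`), mean
   adjacent map distance (total cM / mapped loci), the
   transition/transversion ratio, and a per-locus segregation χ² screen
   against 1:2:1 (df 2) or 3:1 (df 1) with distortion flagged at
   P ≤ 0.05 (Pearson statistic via `stats::chisq.test`, no
   multiple-testing correction).

### Ordering decisions

Two orderings were genuinely open and are fixed as follows. First,
cross-parent anchoring runs **before** known-marker redundancy screening,
so the novelty check applies to the candidate screening set; the
alternative (novelty first) changes only which markers are aligned against
the database, not any individual decision. Second, the redundancy rule is
defined on the inter-primer sequence, so primers are designed **before**
redundancy screening even though redundancy conceptually precedes primer
synthesis; a candidate whose region admits no acceptable primer pair gets
a recorded design failure and is excluded from redundancy screening
(there is no amplicon to compare).

### Corner-case policies

* Overlapping maximal repeat runs: the longer run wins; ties break by
  smaller start, then shorter motif. The same policy is applied by the
  independent brute-force oracle in the tests, so miner/oracle agreement
  is exact.
* A marker whose flanks reach 20 bp but contain N cannot be anchored
  (N never matches) yet keeps its flanks; it is treated as parent-specific
  so it can still enter the primer pool. Markers with a flank shorter than
  20 bp are UNANCHORABLE and are dropped from the candidate pool.
* A marker whose flanks accept two partners above the cutoff takes the
  best by smallest worst-flank E-value, then most identities, then
  lexicographic partner id; the ambiguity count is reported. Pairing is
  made one-to-one greedily in the same order.
* All printed statistics round half-up at two decimals. The catalogue
  frequency convention can differ from recomputation by one cent
  (e.g. 10.44 vs 10.45 kb); comparisons therefore allow ±0.01.

## The synthetic generator

`generate_parents()` builds ancestral contigs as i.i.d. sequence at 34 %
GC — the composition of the cotton RAD assemblies this design targets —
with contig lengths of 200–800 bp (SSR-bearing contigs use 500–800 bp so
primer and redundancy windows always fit). Backgrounds are rejection
sampled to be free of detectable SSRs, and each planted SSR is verified to
be re-detected exactly as planted. Defaults follow the study conditions:

* 100 shared-equal SSRs, 50 repeat-divergent SSRs (identical flanks,
  repeat counts differing by 1–3 units), 60 + 60 parent-only SSR contigs;
  motif lengths drawn at catalogue frequencies (pentanucleotides most
  common at ~33 %).
* 500 SNPs at a transition/transversion target of 1.76 and 200 InDels
  with geometric lengths of mean 1.4 bp. Sites are split into shared
  (discoverable in both mapping directions; the two assemblies carry
  different alleles) and direction-only (the site's contig exists in only
  one assembly, emulating reduced-representation dropout) at
  catalogue-like proportions (SNP 1216/9366 shared, InDel 675/3838), with
  the homozygous–homozygous fraction of shared sites likewise matched
  (441/1216 and 121/675).
* Variant sites are spaced ≥ 220 bp so each marker's flanks are unique;
  allele depths are drawn to realise the planted zygosity (homozygous
  MAF < 0.08, heterozygous 0.30–0.50) at mean depth 30; mapping metrics
  are clean unless a noise fraction forces a chosen hard-filter clause to
  fire. Noise layers (per-clause failures, SNP low depth) are
  independently switchable so each stage's failure mode is testable in
  isolation.
* `known_db_fixture()` selects a fraction of the candidate SSR markers
  and, for each, stores a record sharing the longest contiguous
  non-repeat stretch of the marker's deterministic amplicon (well above
  the 50-base rule), padded with random sequence; remaining records are
  unrelated random sequence. Because the primer picker is deterministic,
  the fixture and the pipeline see the same amplicon.

What passing recovery tests show — and what they do not: on noiseless
synthetic parents the pipeline recovers every planted status, zygosity,
filter decision and redundancy flag exactly. This validates the decision
logic and coordinate bookkeeping, not performance on real assemblies:
the generator plants unique flanks (no paralogy or repeat families), no
assembly errors or chimeric contigs, no allele-balance skew beyond the
planted zygosity, and clean site metrics. Real RAD assemblies of a
polyploid will violate all of these, so real-data counts should be read
as candidate pools, not confirmed polymorphisms — the reason wet-lab
validation rates of in-silico candidates are far below 100 %.

## Problem sizes

The shipped test-suite fixture uses a 46-feature SSR plan plus 110
variant sites; the acceptance-scale run uses the full study conditions
above (970 planted features over ~760 contigs, ~480 kb of synthetic
assembly), which completes in well under a minute for generation and
about 40 s for the pipeline. Oracle-equivalence checks run the miner
against a brute-force scanner on 500 random 2-kb sequences and the
seeded aligner against exact dynamic programming on 500 random flank
pairs.

## Limitations

* The aligner's E-values use ungapped Karlin–Altschul constants on gapped
  scores; they are meant for thresholding short high-identity flank hits,
  not as calibrated significance values.
* The primer picker checks only a 3′ self-complementarity heuristic, not
  full dimer/hairpin thermodynamics, and uses the basic Tm formula.
* Read mapping and variant calling are out of scope: the pipeline starts
  from caller-style variant tables, and its filters assume those fields
  (DP, MQ, MQ0, QUAL, allele depths) are present and meaningful.
* Linkage-map construction and QTL scanning are out of scope; only the
  scalar map statistics and the per-locus segregation screen are
  provided.
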