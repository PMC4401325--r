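#' Canonical motif class of an SSR repeat unit
#'
#' The canonical representative of a motif is the lexicographically smallest
#' string among all cyclic rotations of the motif and of its reverse
#' complement, so that e.g. TA, AT, and their complements all fall into one
#' class. The class is rendered `"canonical/revcomp(canonical)"`, the form
#' used in marker catalogues (AT/AT, AAG/CTT, ...).
#'
#' @param motif repeat unit over A/C/G/T, length 2-8, primitive (not itself
#'   a tandem repetition of a shorter unit).
#' @return class label string.
#' @examples
#' canonical_motif("TA")   # "AT/AT"
#' canonical_motif("TTC")  # "AAG/CTT"
#' @export
canonical_motif <- function(motif) {
  motif <- toupper(motif)
  k <- nchar(motif)
  if (k < 2 || k > 8 || grepl("[^ACGT]", motif))
    stop("motif must be over A/C/G/T with length 2-8: ", motif)
  if (!is_primitive_motif(motif))
    stop("motif is a tandem repetition of a shorter unit: ", motif)
  canon <- min(c(rotations(motif), rotations(revcomp(motif))))
  # the class's second member is the smallest rotation of the reverse
  # complement, the form marker catalogues print (ATC/ATG, AAG/CTT)
  paste0(canon, "/", min(rotations(revcomp(canon))))
}

rotations <- function(m) {
  k <- nchar(m)
  d <- paste0(m, m)
  vapply(seq_len(k), function(i) substr(d, i, i + k - 1L), character(1))
}

# a motif is primitive if it is not a whole-number power of a shorter unit
is_primitive_motif <- function(motif) {
  k <- nchar(motif)
  for (d in seq_len(k - 1)) {
    if (k %% d == 0L &&
        motif == strrep(substr(motif, 1L, d), k / d)) return(FALSE)
  }
  TRUE
}

#' Find microsatellites (SSRs) in a contig
#'
#' Detects maximal perfect tandem repeats of primitive 2-8 bp motifs whose
#' complete-unit count reaches the configured minimum for the motif length
#' (defaults: 7 for dinucleotides, 5 for tri-, 4 for tetra-, 3 for penta-
#' through octanucleotides). Mononucleotide runs are not searched. Where two
#' maximal runs overlap, the longer run wins; ties go to the smaller start,
#' then the shorter motif. Candidate runs containing N are discarded.
#' Consecutive reported loci separated by at most `compound_gap` interrupting
#' bases share a `compound_id` (compound SSR).
#'
#' @param sequence contig DNA string (or a one-row contig data.frame).
#' @param contig_id id recorded on the loci; taken from the data.frame when
#'   one is supplied.
#' @param minima named integer vector of minimum complete-unit counts for
#'   motif lengths `"2"`..`"8"`.
#' @param compound_gap maximum interrupting bases within a compound SSR.
#' @return data.frame of SSR loci: `contig_id`, `start`, `end` (1-based
#'   inclusive), `motif` (as observed on the forward strand), `unit_len`,
#'   `repeats`, `canonical_class`, `compound_id` (NA for solitary loci),
#'   sorted by start.
#' @export
find_ssrs <- function(sequence, contig_id = "",
                      minima = pipeline_config()$ssr_minima,
                      compound_gap = 500L) {
  if (is.data.frame(sequence)) {
    stopifnot(nrow(sequence) == 1)
    contig_id <- sequence$id
    sequence <- sequence$sequence
  }
  sequence <- toupper(sequence)
  cand <- ssr_candidates(sequence, minima)
  loci <- resolve_overlaps(cand)
  empty <- data.frame(contig_id = character(), start = integer(),
                      end = integer(), motif = character(),
                      unit_len = integer(), repeats = integer(),
                      canonical_class = character(),
                      compound_id = character(), stringsAsFactors = FALSE)
  if (nrow(loci) == 0) return(empty)
  loci <- loci[order(loci$start, loci$unit_len), , drop = FALSE]
  loci$contig_id <- contig_id
  loci$canonical_class <- vapply(loci$motif, canonical_motif, character(1),
                                 USE.NAMES = FALSE)
  loci$compound_id <- assign_compounds(loci, contig_id, compound_gap)
  rownames(loci) <- NULL
  loci[, names(empty)]
}

# maximal perfect runs per motif length via backreference regex; greedy
# leftmost matching yields maximal complete-unit runs
ssr_candidates <- function(sequence, minima) {
  out <- list()
  for (k in as.integer(names(minima))) {
    minrep <- minima[[as.character(k)]]
    pat <- sprintf("([ACGT]{%d})\\1{%d,}", k, minrep - 1L)
    m <- gregexpr(pat, sequence, perl = TRUE)[[1]]
    if (m[1] == -1L) next
    starts <- as.integer(m)
    lens <- attr(m, "match.length")
    motifs <- substr(rep(sequence, length(starts)), starts, starts + k - 1L)
    keep <- vapply(motifs, is_primitive_motif, logical(1), USE.NAMES = FALSE)
    if (!any(keep)) next
    out[[length(out) + 1L]] <- data.frame(
      start = starts[keep], end = starts[keep] + lens[keep] - 1L,
      motif = motifs[keep], unit_len = k,
      repeats = as.integer(lens[keep] / k), stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    return(data.frame(start = integer(), end = integer(), motif = character(),
                      unit_len = integer(), repeats = integer(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

# overlap policy: longer run first, then smaller start, then shorter unit
resolve_overlaps <- function(cand) {
  if (nrow(cand) <= 1) return(cand)
  len <- cand$end - cand$start + 1L
  ord <- order(-len, cand$start, cand$unit_len)
  cand <- cand[ord, , drop = FALSE]
  kept <- logical(nrow(cand))
  ks <- integer(0); ke <- integer(0)
  for (i in seq_len(nrow(cand))) {
    if (!any(cand$start[i] <= ke & cand$end[i] >= ks)) {
      kept[i] <- TRUE
      ks <- c(ks, cand$start[i]); ke <- c(ke, cand$end[i])
    }
  }
  cand[kept, , drop = FALSE]
}

assign_compounds <- function(loci, contig_id, compound_gap) {
  n <- nrow(loci)
  gap_prev <- c(Inf, loci$start[-1] - loci$end[-n] - 1L)
  grp <- cumsum(gap_prev > compound_gap)
  sizes <- table(grp)
  ids <- rep(NA_character_, n)
  multi <- names(sizes)[sizes >= 2]
  if (length(multi)) {
    lab <- setNames(sprintf("%s_comp%d", contig_id, seq_along(multi)), multi)
    sel <- as.character(grp) %in% multi
    ids[sel] <- lab[as.character(grp)[sel]]
  }
  ids
}

#' Mine SSRs across a whole contig set
#'
#' @param contigs contig data.frame ([read_fasta()]).
#' @param config [pipeline_config()].
#' @return combined SSR locus data.frame over all contigs.
#' @export
mine_ssrs <- function(contigs, config = pipeline_config()) {
  if (nrow(contigs) == 0) return(find_ssrs(""))
  res <- lapply(seq_len(nrow(contigs)), function(i) {
    find_ssrs(contigs$sequence[i], contigs$id[i], config$ssr_minima,
              config$compound_gap)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Summarise a set of SSR loci
#'
#' Produces the catalogue-style summary: total loci, loci in compound
#' formation, SSR-containing contigs, percentage breakdown by motif length
#' and by canonical class, and the average frequency in kb of sequence per
#' SSR (reported as `1/X kb`, X to two decimals, half-up).
#'
#' @param loci SSR locus data.frame.
#' @param total_len_kb total assembled length in kb.
#' @return list with `total`, `n_compound`, `n_contigs`, `by_unit_len`
#'   (percent, named by motif length), `by_class` (percent, named by class,
#'   descending), `frequency_kb` (NA when no loci) and `frequency` label.
#' @export
ssr_summary <- function(loci, total_len_kb) {
  stopifnot(total_len_kb > 0)
  total <- nrow(loci)
  if (total == 0) {
    return(list(total = 0L, n_compound = 0L, n_contigs = 0L,
                by_unit_len = numeric(0), by_class = numeric(0),
                frequency_kb = NA_real_, frequency = "NA"))
  }
  by_len <- table(loci$unit_len)
  by_len <- round_half_up(100 * as.numeric(by_len) / total, 2) |>
    setNames(names(by_len))
  by_class <- sort(table(loci$canonical_class), decreasing = TRUE)
  by_class <- round_half_up(100 * as.numeric(by_class) / total, 2) |>
    setNames(names(by_class))
  freq <- round_half_up(total_len_kb / total, 2)
  list(total = total,
       n_compound = sum(!is.na(loci$compound_id)),
       n_contigs = length(unique(loci$contig_id)),
       by_unit_len = by_len, by_class = by_class,
       frequency_kb = freq, frequency = frequency_label(freq))
}
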