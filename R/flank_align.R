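#' Seeded local alignment of two short sequences
#'
#' A nucleotide-BLAST-like search specialised for short, high-identity
#' marker flanks: an exact shared word (default 11-mer) is required as a
#' seed; when one exists the optimal affine-gap local alignment is computed
#' by dynamic programming (so the score equals the Smith-Waterman optimum
#' whenever a seed exists, and no hit is reported otherwise). Both strands
#' of the subject are searched; subject coordinates are always reported on
#' the forward strand.
#'
#' Scoring defaults to match +1, mismatch -2, and affine gaps costing 5 for
#' the first base and 2 for each additional base. `N` never matches.
#'
#' @param query,subject DNA strings over A/C/G/T/N.
#' @param scoring list with `match`, `mismatch`, `gap_open`, `gap_ext`.
#' @param word_size exact-seed word length.
#' @return one-row data.frame (`q_start`, `q_end`, `s_start`, `s_end`,
#'   `strand`, `score`, `identities`, `matched_bases`, `aln_len`) or `NULL`
#'   when no seed exists on either strand.
#' @export
local_align <- function(query, subject,
                        scoring = pipeline_config()$scoring,
                        word_size = 11L) {
  h <- align_pair(query, subject, scoring, word_size)
  if (is.null(h)) return(NULL)
  as.data.frame(h, stringsAsFactors = FALSE)
}

# list-returning core of local_align (hot path; no data.frame overhead)
align_pair <- function(query, subject, scoring, word_size = 11L) {
  if (!nzchar(query) || !nzchar(subject))
    stop("local_align requires non-empty sequences")
  query <- toupper(query); subject <- toupper(subject)
  best <- NULL
  for (strand in c("+", "-")) {
    subj <- if (strand == "+") subject else revcomp(subject)
    if (!has_shared_word_cpp(query, subj, as.integer(word_size))) next
    h <- sw_align_cpp(query, subj, scoring$match, scoring$mismatch,
                      scoring$gap_open, scoring$gap_ext)
    if (h$score <= 0) next
    s_start <- h$s_start; s_end <- h$s_end
    if (strand == "-") {
      n <- nchar(subject)
      tmp <- s_start
      s_start <- n - s_end + 1L
      s_end <- n - tmp + 1L
    }
    hit <- list(q_start = h$q_start, q_end = h$q_end,
                s_start = s_start, s_end = s_end, strand = strand,
                score = h$score, identities = h$identities,
                matched_bases = h$identities, aln_len = h$aln_len)
    if (is.null(best) || hit$score > best$score) best <- hit
  }
  best
}

#' Extreme-value expectation (E-value) of an alignment score
#'
#' Standard Karlin-Altschul expectation `E = K * m * n * exp(-lambda * S)`
#' with ungapped nucleotide constants (K = 0.711, lambda = 1.37) applied to
#' gapped scores as an approximation. Monotonically decreasing in the score
#' and linear in the search-space product.
#'
#' @param score alignment score (>= 0).
#' @param q_len query length.
#' @param db_len total subject collection length.
#' @param K,lambda Karlin-Altschul constants.
#' @return expectation value (>= 0).
#' @export
evalue <- function(score, q_len, db_len, K = 0.711, lambda = 1.37) {
  stopifnot(score >= 0, q_len >= 1, db_len >= 1)
  K * q_len * db_len * exp(-lambda * score)
}

#' Search a query against a collection of subjects
#'
#' Runs [local_align()] of the query against every subject and returns all
#' hits with E-values computed against the total collection length, ordered
#' by the anchoring tie-break: smallest E-value, then most identities, then
#' lexicographic subject id.
#'
#' @param query DNA string.
#' @param subjects named character vector of subject sequences.
#' @param scoring,word_size as in [local_align()].
#' @param K,lambda E-value constants.
#' @param db_len search-space size; defaults to the summed subject lengths.
#' @return data.frame of hits with `subject_id` and `evalue` columns
#'   (zero rows when nothing seeds).
#' @export
align_to_set <- function(query, subjects,
                         scoring = pipeline_config()$scoring,
                         word_size = 11L, K = 0.711, lambda = 1.37,
                         db_len = NULL) {
  if (is.null(db_len)) db_len <- sum(nchar(subjects))
  hits <- list()
  for (id in names(subjects)) {
    h <- local_align(query, subjects[[id]], scoring, word_size)
    if (is.null(h)) next
    h$subject_id <- id
    h$evalue <- evalue(h$score, nchar(query), db_len, K, lambda)
    hits[[length(hits) + 1L]] <- h
  }
  if (!length(hits)) {
    return(data.frame(q_start = integer(), q_end = integer(),
                      s_start = integer(), s_end = integer(),
                      strand = character(), score = integer(),
                      identities = integer(), matched_bases = integer(),
                      aln_len = integer(), subject_id = character(),
                      evalue = numeric(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, hits)
  out[order(out$evalue, -out$identities, out$subject_id), , drop = FALSE]
}
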