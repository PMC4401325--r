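#' Extract the inter-primer (amplicon) sequence of a marker
#'
#' @param primer_pair one-row primer data.frame with `left_start` and
#'   `right_end` (1-based, inclusive of the primer sites).
#' @param contig_seq contig DNA string.
#' @return the amplicon sub-sequence spanned by the primer pair.
#' @export
interprimer_sequence <- function(primer_pair, contig_seq) {
  ls <- primer_pair$left_start; re <- primer_pair$right_end
  if (ls < 1 || re > nchar(contig_seq))
    stop("primer positions fall outside the contig")
  if (re < ls) stop("right primer lies before left primer")
  substr(contig_seq, ls, re)
}

#' Mask SSR spans within a sequence
#'
#' Replaces every base inside the given spans by N, preserving length, so
#' the repeat itself can never contribute matched bases to a redundancy
#' alignment.
#'
#' @param sequence DNA string.
#' @param ssr_spans data.frame with `start`, `end` (1-based, relative to
#'   `sequence`); zero rows leave the sequence unchanged.
#' @return masked sequence.
#' @export
mask_ssr <- function(sequence, ssr_spans) {
  if (is.null(ssr_spans) || nrow(ssr_spans) == 0) return(sequence)
  n <- nchar(sequence)
  if (any(ssr_spans$start < 1 | ssr_spans$end > n |
            ssr_spans$end < ssr_spans$start))
    stop("SSR span outside sequence")
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  for (i in seq_len(nrow(ssr_spans)))
    chars[ssr_spans$start[i]:ssr_spans$end[i]] <- "N"
  paste(chars, collapse = "")
}

#' Is a masked marker sequence redundant with a known-marker database?
#'
#' The marker is redundant when the single best local alignment against any
#' database record carries at least `matched_min` identities (matched
#' bases). Masked (N) positions never count as matches. The database search
#' itself is permissive (any seeded hit is considered); only the
#' matched-bases rule decides.
#'
#' @param masked_seq SSR-masked amplicon sequence.
#' @param db known-marker database: a contig data.frame ([read_fasta()]) or
#'   named character vector of sequences.
#' @param matched_min matched-bases threshold (default 50).
#' @param config [pipeline_config()] (scoring, word size).
#' @return list with `redundant` logical, `best` hit row (or `NULL`) and
#'   `matched_bases` of the best hit (0 when nothing seeds).
#' @export
is_redundant <- function(masked_seq, db, matched_min = 50L,
                         config = pipeline_config()) {
  seqs <- if (is.data.frame(db)) setNames(db$sequence, db$id) else db
  if (!length(seqs) || !nzchar(gsub("N", "", masked_seq, fixed = TRUE)))
    return(list(redundant = FALSE, best = NULL, matched_bases = 0L))
  best <- NULL
  for (id in names(seqs)) {
    h <- align_pair(masked_seq, seqs[[id]], config$scoring,
                     config$word_size)
    if (is.null(h)) next
    h$subject_id <- id
    if (is.null(best) || h$identities > best$identities ||
        (h$identities == best$identities && h$subject_id < best$subject_id))
      best <- h
  }
  if (is.null(best))
    return(list(redundant = FALSE, best = NULL, matched_bases = 0L))
  list(redundant = best$identities >= matched_min, best = best,
       matched_bases = best$identities)
}
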