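# Independent oracles used across the suite. These deliberately take
# different routes than the package implementation: the SSR oracle tests
# every (start, unit_len) pair by direct base comparison instead of regex
# matching, and the alignment oracle is Biostrings' exact Smith-Waterman.

# brute-force microsatellite scan: for every motif length k, compare each
# base with the base k ahead, then read maximal complete-unit runs off the
# equality vector; apply the same published overlap policy (longer run
# first, then smaller start, then shorter unit) implemented independently.
brute_force_ssrs <- function(sequence, minima = c(`2` = 7L, `3` = 5L,
                                                  `4` = 4L, `5` = 3L,
                                                  `6` = 3L, `7` = 3L,
                                                  `8` = 3L)) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  n <- length(chars)
  runs <- list()
  for (k in as.integer(names(minima))) {
    minrep <- minima[[as.character(k)]]
    if (n < k * minrep) next
    for (p in seq_len(n - k * minrep + 1L)) {
      motif <- paste(chars[p:(p + k - 1L)], collapse = "")
      if (grepl("[^ACGT]", motif)) next
      # primitive?
      prim <- TRUE
      for (d in seq_len(k - 1L)) {
        if (k %% d == 0L &&
            motif == strrep(substr(motif, 1L, d), k / d)) prim <- FALSE
      }
      if (!prim) next
      # not extendable left by a whole unit (leftmost complete start)
      if (p > k &&
          paste(chars[(p - k):(p - 1L)], collapse = "") == motif) next
      reps <- 1L
      while (p + (reps + 1L) * k - 1L <= n &&
             paste(chars[(p + reps * k):(p + (reps + 1L) * k - 1L)],
                   collapse = "") == motif) reps <- reps + 1L
      if (reps >= minrep) {
        runs[[length(runs) + 1L]] <- data.frame(
          start = p, end = p + reps * k - 1L, motif = motif,
          unit_len = k, repeats = reps, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(runs)) {
    return(data.frame(start = integer(), end = integer(),
                      motif = character(), unit_len = integer(),
                      repeats = integer(), stringsAsFactors = FALSE))
  }
  cand <- do.call(rbind, runs)
  len <- cand$end - cand$start + 1L
  cand <- cand[order(-len, cand$start, cand$unit_len), , drop = FALSE]
  sel <- rep(FALSE, nrow(cand))
  occ_s <- integer(0); occ_e <- integer(0)
  for (i in seq_len(nrow(cand))) {
    if (!any(cand$start[i] <= occ_e & cand$end[i] >= occ_s)) {
      sel[i] <- TRUE
      occ_s <- c(occ_s, cand$start[i]); occ_e <- c(occ_e, cand$end[i])
    }
  }
  out <- cand[sel, , drop = FALSE]
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# exact local-alignment score oracle (Smith-Waterman via Biostrings), with
# the package's gap convention: a gap of length L costs 5 + 2*(L-1)
sw_oracle_score <- function(a, b) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2,
                                                  baseOnly = TRUE)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b), type = "local",
    substitutionMatrix = mat, gapOpening = 3, gapExtension = 2)
  max(0, Biostrings::score(pa))
}

random_seq <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# does an exact shared 11-mer exist on either strand?
shared_seed_exists <- function(a, b, w = 11L) {
  radmarker:::has_shared_word_cpp(a, b, w) ||
    radmarker:::has_shared_word_cpp(a, revcomp(b), w)
}
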