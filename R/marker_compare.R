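#' Extract anchoring flanks for a marker
#'
#' Takes up to `flank_max` bases (default 200) immediately adjacent to the
#' marker span on each side, requiring at least `flank_min` (default 20).
#' A marker with a too-short flank on either side is UNANCHORABLE and is
#' dropped from the comparison. A marker whose flanks reach `flank_min` but
#' contain N cannot be anchored either (N never matches), but keeps its
#' flanks so it can still enter the parent-specific primer pool; it is
#' flagged `flank_has_n`.
#'
#' @param marker one-row data.frame with `contig_id`, `start`, `end`.
#' @param contigs contig data.frame of the marker's genotype.
#' @param flank_min,flank_max flank length bounds (bp).
#' @return the marker row with `left_flank`, `right_flank`, `anchor_status`
#'   (`"ok"`/`"UNANCHORABLE"`) and `flank_has_n` columns.
#' @export
extract_flanks <- function(marker, contigs, flank_min = 20L,
                           flank_max = 200L) {
  i <- match(marker$contig_id, contigs$id)
  if (is.na(i)) stop("unknown contig: ", marker$contig_id)
  seq <- contigs$sequence[i]
  len <- contigs$length[i]
  lf_start <- max(1L, marker$start - flank_max)
  lf <- if (marker$start > 1) substr(seq, lf_start, marker$start - 1L) else ""
  rf_end <- min(len, marker$end + flank_max)
  rf <- if (marker$end < len) substr(seq, marker$end + 1L, rf_end) else ""
  marker$left_flank <- lf
  marker$right_flank <- rf
  short <- nchar(lf) < flank_min || nchar(rf) < flank_min
  marker$anchor_status <- if (short) "UNANCHORABLE" else "ok"
  marker$flank_has_n <- grepl("N", lf, fixed = TRUE) ||
    grepl("N", rf, fixed = TRUE)
  marker
}

# vectorised flank extraction over a marker table
extract_flanks_all <- function(markers, contigs, flank_min = 20L,
                               flank_max = 200L) {
  if (nrow(markers) == 0) {
    markers$left_flank <- character(0)
    markers$right_flank <- character(0)
    markers$anchor_status <- character(0)
    markers$flank_has_n <- logical(0)
    return(markers)
  }
  out <- lapply(seq_len(nrow(markers)), function(i) {
    extract_flanks(markers[i, , drop = FALSE], contigs, flank_min, flank_max)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# index every word of the B flanks -> which B markers carry it
build_flank_index <- function(fmB, word_size) {
  km <- list(); ow <- list()
  for (side in c("left_flank", "right_flank")) {
    seqs <- fmB[[side]]
    for (i in seq_along(seqs)) {
      s <- seqs[i]
      n <- nchar(s)
      if (n < word_size) next
      st <- seq_len(n - word_size + 1L)
      km[[length(km) + 1L]] <- substring(s, st, st + word_size - 1L)
      ow[[length(ow) + 1L]] <- rep.int(i, length(st))
    }
  }
  kmers <- unlist(km, use.names = FALSE)
  owners <- unlist(ow, use.names = FALSE)
  keep <- !grepl("N", kmers, fixed = TRUE)
  split(owners[keep], kmers[keep])
}

query_flank_index <- function(index, flank, word_size) {
  n <- nchar(flank)
  if (n < word_size) return(integer(0))
  st <- seq_len(n - word_size + 1L)
  words <- substring(flank, st, st + word_size - 1L)
  words <- unique(c(words, substring(revcomp(flank),
                                     st, st + word_size - 1L)))
  unique(unlist(index[words], use.names = FALSE))
}

#' Match one marker's flanks against candidate partners
#'
#' A partner is accepted when BOTH flanks of the query marker hit flanks of
#' the SAME candidate marker with E-value at or below the cutoff, with
#' consistent orientation (left-left and right-right on the plus strand;
#' left-right swapped and reversed on minus) and compatible geometry: the
#' implied inter-flank span must agree within the geometry window. Among
#' acceptable partners the best is chosen by smallest worst-flank E-value,
#' then most summed identities, then lexicographic partner id.
#'
#' @param markerA one-row flanked-marker data.frame.
#' @param candidatesB flanked-marker data.frame of potential partners.
#' @param e_cutoff anchoring E-value cutoff (default 1e-5).
#' @param config [pipeline_config()] (scoring, word size, geometry window).
#' @param db_len total flank-collection length used for E-values; defaults
#'   to the summed candidate flank lengths.
#' @return list with `partner_id` (or `NA`), `n_acceptable` (ambiguity
#'   count) and the best pair's `evalue`/`identities`, or `NULL` when no
#'   candidate is acceptable.
#' @export
match_flanks <- function(markerA, candidatesB, e_cutoff = 1e-5,
                         config = pipeline_config(), db_len = NULL) {
  if (nrow(candidatesB) == 0 || markerA$anchor_status != "ok" ||
      isTRUE(markerA$flank_has_n))
    return(list(partner_id = NA_character_, n_acceptable = 0L))
  if (is.null(db_len))
    db_len <- sum(nchar(candidatesB$left_flank)) +
      sum(nchar(candidatesB$right_flank))
  spanA <- markerA$end - markerA$start + 1L
  acc <- list()
  for (j in seq_len(nrow(candidatesB))) {
    cand <- candidatesB[j, , drop = FALSE]
    if (cand$anchor_status != "ok" || isTRUE(cand$flank_has_n)) next
    spanB <- cand$end - cand$start + 1L
    if (abs(spanA - spanB) > config$geometry_window) next
    best <- NULL
    # plus orientation: left-left, right-right, both on plus strand
    hl <- align_pair(markerA$left_flank, cand$left_flank, config$scoring,
                      config$word_size)
    hr <- align_pair(markerA$right_flank, cand$right_flank, config$scoring,
                      config$word_size)
    if (!is.null(hl) && !is.null(hr) && hl$strand == "+" &&
        hr$strand == "+") {
      best <- list(orient = "+", hl = hl, hr = hr)
    }
    if (is.null(best)) {
      # minus orientation: A-left vs B-right (reverse), A-right vs B-left
      hl <- align_pair(markerA$left_flank, cand$right_flank,
                        config$scoring, config$word_size)
      hr <- align_pair(markerA$right_flank, cand$left_flank,
                        config$scoring, config$word_size)
      if (!is.null(hl) && !is.null(hr) && hl$strand == "-" &&
          hr$strand == "-") {
        best <- list(orient = "-", hl = hl, hr = hr)
      }
    }
    if (is.null(best)) next
    el <- evalue(best$hl$score, nchar(markerA$left_flank), db_len,
                 config$karlin_K, config$karlin_lambda)
    er <- evalue(best$hr$score, nchar(markerA$right_flank), db_len,
                 config$karlin_K, config$karlin_lambda)
    if (el > e_cutoff || er > e_cutoff) next
    acc[[length(acc) + 1L]] <- data.frame(
      partner_id = cand$marker_id, evalue = max(el, er),
      identities = best$hl$identities + best$hr$identities,
      orient = best$orient, stringsAsFactors = FALSE)
  }
  if (!length(acc)) return(list(partner_id = NA_character_,
                                n_acceptable = 0L))
  tab <- do.call(rbind, acc)
  tab <- tab[order(tab$evalue, -tab$identities, tab$partner_id), ,
             drop = FALSE]
  list(partner_id = tab$partner_id[1], n_acceptable = nrow(tab),
       evalue = tab$evalue[1], identities = tab$identities[1],
       orient = tab$orient[1])
}

#' Anchor two flanked marker sets
#'
#' Seeds candidate partners through a shared-word index over the B flanks,
#' applies [match_flanks()] per A marker, and resolves to a one-to-one
#' pairing greedily in tie-break order (each B marker is used at most
#' once).
#'
#' @param fmA,fmB flanked marker data.frames (see [extract_flanks()]) with
#'   `marker_id` columns.
#' @param config [pipeline_config()].
#' @return data.frame with one row per anchored pair: `marker_a`,
#'   `marker_b`, `evalue`, `identities`, `orient`, `ambiguity` (number of
#'   acceptable partners seen by the A marker).
#' @export
anchor_markers <- function(fmA, fmB, config = pipeline_config()) {
  empty <- data.frame(marker_a = character(), marker_b = character(),
                      evalue = numeric(), identities = integer(),
                      orient = character(), ambiguity = integer(),
                      stringsAsFactors = FALSE)
  okB <- fmB[fmB$anchor_status == "ok" & !fmB$flank_has_n, , drop = FALSE]
  if (nrow(fmA) == 0 || nrow(okB) == 0) return(empty)
  index <- build_flank_index(okB, config$word_size)
  db_len <- sum(nchar(okB$left_flank)) + sum(nchar(okB$right_flank))
  rows <- list()
  for (i in seq_len(nrow(fmA))) {
    a <- fmA[i, , drop = FALSE]
    if (a$anchor_status != "ok" || isTRUE(a$flank_has_n)) next
    cand_idx <- sort(unique(c(
      query_flank_index(index, a$left_flank, config$word_size),
      query_flank_index(index, a$right_flank, config$word_size))))
    if (!length(cand_idx)) next
    m <- match_flanks(a, okB[cand_idx, , drop = FALSE],
                      config$evalue_cutoff, config, db_len)
    if (is.na(m$partner_id)) next
    rows[[length(rows) + 1L]] <- data.frame(
      marker_a = a$marker_id, marker_b = m$partner_id, evalue = m$evalue,
      identities = m$identities, orient = m$orient,
      ambiguity = m$n_acceptable, stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(empty)
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$evalue, -tab$identities, tab$marker_b, tab$marker_a),
             , drop = FALSE]
  used_b <- character(0); keep <- logical(nrow(tab))
  for (i in seq_len(nrow(tab))) {
    if (!(tab$marker_b[i] %in% used_b)) {
      keep[i] <- TRUE
      used_b <- c(used_b, tab$marker_b[i])
    }
  }
  out <- tab[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Is a shared SSR pair polymorphic in silico?
#'
#' A shared SSR locus is in-silico polymorphic when the two parents carry
#' different numbers of complete motif units. A shared pair whose motifs
#' fall in different canonical classes is flagged inconsistent (a suspect
#' anchoring), not polymorphic.
#'
#' @param a,b one-row SSR locus data.frames with `repeats` and
#'   `canonical_class`.
#' @return list with `polymorphic` and `inconsistent` logicals.
#' @export
classify_ssr_pair <- function(a, b) {
  if (a$canonical_class != b$canonical_class)
    return(list(polymorphic = FALSE, inconsistent = TRUE))
  list(polymorphic = a$repeats != b$repeats, inconsistent = FALSE)
}

#' Is a shared variant site polymorphic in silico?
#'
#' True exactly when both parents' zygosity calls are homozygous and their
#' alleles differ.
#'
#' @param a_allele,b_allele each parent's allele at the site.
#' @param zygA,zygB zygosity calls (`"HOM"`/`"HET"`/`"UNKNOWN"`).
#' @return logical.
#' @export
classify_variant_pair <- function(a_allele, b_allele, zygA, zygB) {
  zygA == "HOM" && zygB == "HOM" && a_allele != b_allele
}

#' Partition two marker sets by anchoring status
#'
#' Every marker lands in exactly one status: SHARED (anchored to a partner;
#' counted once per pair), A_ONLY / B_ONLY (anchorable but unpartnered, or
#' N-flanked and hence unalignable but still primer-designable), or
#' UNANCHORABLE (flanks below the minimum; dropped from the candidate
#' pool). The candidate screening list is the union of in-silico
#' polymorphic shared markers and the parent-specific markers, mirroring
#' the screening-set arithmetic of the workflow.
#'
#' @param fmA,fmB flanked marker data.frames.
#' @param anchors pairing table from [anchor_markers()].
#' @param polymorphic character vector of `marker_a` ids of pairs judged
#'   in-silico polymorphic.
#' @return list with `status` (data.frame: marker_id, genotype, status,
#'   partner_id, insilico_polymorphic), `counts` (shared, insilico_poly,
#'   a_only, b_only, unanchorable, candidates) and `candidates` (marker id
#'   vector).
#' @export
partition_markers <- function(fmA, fmB, anchors,
                              polymorphic = character(0)) {
  mk_status <- function(fm, side) {
    if (nrow(fm) == 0) {
      return(data.frame(marker_id = character(), genotype = character(),
                        status = character(), partner_id = character(),
                        insilico_polymorphic = logical(),
                        stringsAsFactors = FALSE))
    }
    partner <- if (side == "A") {
      anchors$marker_b[match(fm$marker_id, anchors$marker_a)]
    } else {
      anchors$marker_a[match(fm$marker_id, anchors$marker_b)]
    }
    status <- ifelse(!is.na(partner), "SHARED",
                     ifelse(fm$anchor_status == "UNANCHORABLE",
                            "UNANCHORABLE",
                            if (side == "A") "A_ONLY" else "B_ONLY"))
    poly_ids <- c(polymorphic,
                  anchors$marker_b[anchors$marker_a %in% polymorphic])
    data.frame(marker_id = fm$marker_id, genotype = fm$genotype,
               status = status, partner_id = partner,
               insilico_polymorphic = fm$marker_id %in% poly_ids &
                 status == "SHARED",
               stringsAsFactors = FALSE)
  }
  sa <- mk_status(fmA, "A")
  sb <- mk_status(fmB, "B")
  status <- rbind(sa, sb)
  n_shared <- nrow(anchors)
  counts <- c(shared = n_shared,
              insilico_poly = length(unique(
                intersect(polymorphic, anchors$marker_a))),
              a_only = sum(sa$status == "A_ONLY"),
              b_only = sum(sb$status == "B_ONLY"),
              unanchorable = sum(status$status == "UNANCHORABLE"))
  candidates <- c(anchors$marker_a[anchors$marker_a %in% polymorphic],
                  sa$marker_id[sa$status == "A_ONLY"],
                  sb$marker_id[sb$status == "B_ONLY"])
  counts <- c(counts, candidates = length(candidates))
  list(status = status, counts = counts, candidates = candidates)
}

#' Candidate screening-set size from category counts
#'
#' The screening set a marker-development run sends to the wet lab is the
#' union of the in-silico polymorphic shared markers and the two
#' parent-specific sets; its size is the plain sum of the three category
#' counts.
#'
#' @param insilico_poly,a_only,b_only category counts.
#' @return total candidate count.
#' @export
screening_candidates <- function(insilico_poly, a_only, b_only) {
  stopifnot(insilico_poly >= 0, a_only >= 0, b_only >= 0)
  insilico_poly + a_only + b_only
}
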