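#' GC content of a primer (percent)
#' @param seq primer sequence.
#' @return percent G+C.
#' @export
gc_percent <- function(seq) {
  n <- nchar(seq)
  gc <- n - nchar(gsub("[GC]", "", seq))
  100 * gc / n
}

#' Basic melting temperature (Wallace/Marmur-Doty extended formula)
#'
#' `Tm = 64.9 + 41 * (GC_count - 16.4) / length`, the standard quick
#' estimate used by primer pickers for 18-24 bp oligos.
#'
#' @param seq primer sequence.
#' @return Tm in degrees C.
#' @export
primer_tm <- function(seq) {
  n <- nchar(seq)
  gc <- n - nchar(gsub("[GC]", "", seq))
  64.9 + 41 * (gc - 16.4) / n
}

# reject primers whose 3'-terminal >= 4 bases are self reverse-complementary
# (3' dimer/hairpin propensity); vectorised
has_3prime_selfcomp <- function(seq, k = 4L) {
  tail <- substr(seq, nchar(seq) - k + 1L, nchar(seq))
  tail == revcomp(tail)
}

#' Cluster nearby markers into shared primer regions
#'
#' Single-linkage chaining: consecutive markers on a contig whose
#' inter-marker distance is strictly below `dist_thr` (default 500 bp) join
#' one region, so one primer pair can serve the whole group. Chains too
#' long for any product below the clustered-product bound are split
#' greedily at their largest internal gaps.
#'
#' @param markers data.frame with `marker_id`, `start`, `end` for one
#'   contig, sorted by position (sorted internally if not).
#' @param dist_thr clustering distance threshold (bp).
#' @param max_span widest region span still amplifiable (defaults to the
#'   clustered product bound minus room for two minimal primers).
#' @param config [pipeline_config()].
#' @return data.frame of regions: `region_id`, `span_start`, `span_end`,
#'   `n_members`, `clustered`, `members` (comma-joined marker ids).
#' @export
cluster_markers <- function(markers, dist_thr = 500L, max_span = NULL,
                            config = pipeline_config()) {
  if (is.null(max_span))
    max_span <- config$primer$clustered_product_max -
      2L * config$primer$len_min
  if (nrow(markers) == 0) {
    return(data.frame(region_id = character(), span_start = integer(),
                      span_end = integer(), n_members = integer(),
                      clustered = logical(), members = character(),
                      stringsAsFactors = FALSE))
  }
  markers <- markers[order(markers$start, markers$end), , drop = FALSE]
  n <- nrow(markers)
  gap <- c(Inf, pmax(markers$start[-1] - markers$end[-n], 0L))
  grp <- cumsum(gap >= dist_thr)
  pieces <- split(seq_len(n), grp)
  # split over-long chains at their largest internal gaps
  split_chain <- function(idx) {
    span <- markers$end[idx[length(idx)]] - markers$start[idx[1]] + 1L
    if (span <= max_span || length(idx) == 1L) return(list(idx))
    gaps <- markers$start[idx[-1]] - markers$end[idx[-length(idx)]]
    cut <- which.max(gaps)
    c(split_chain(idx[seq_len(cut)]),
      split_chain(idx[(cut + 1L):length(idx)]))
  }
  pieces <- unlist(lapply(pieces, split_chain), recursive = FALSE)
  out <- lapply(seq_along(pieces), function(k) {
    idx <- pieces[[k]]
    data.frame(region_id = sprintf("region_%03d", k),
               span_start = markers$start[idx[1]],
               span_end = markers$end[idx[length(idx)]],
               n_members = length(idx),
               clustered = length(idx) >= 2L,
               members = paste(markers$marker_id[idx], collapse = ","),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Design a primer pair for a marker region
#'
#' Scans candidate primers outward from the region within a window,
#' enforcing the hard constraints (length 18-24 bp, GC 40-60%, no N, no
#' 3'-terminal self-complementarity of 4+, product 100-500 bp for
#' singleton regions or up to the clustered bound for clustered regions)
#' and choosing the pair with the minimal penalty
#' `|len-20| + |Tm-57| + 0.2*|GC-50|` summed over both primers, plus
#' `0.01*|product-300|` for singleton regions. Ties break deterministically
#' by smaller left position, then smaller product.
#'
#' @param region one-row data.frame with `span_start`, `span_end`,
#'   `clustered`.
#' @param contig_seq DNA string of the region's contig.
#' @param config [pipeline_config()].
#' @return one-row data.frame (`left_seq`, `right_seq`, `left_start`,
#'   `left_end`, `right_start`, `right_end`, `tm_left`, `tm_right`,
#'   `gc_left`, `gc_right`, `product_size`, `penalty`) or `NULL` when no
#'   acceptable pair exists.
#' @export
design_primers <- function(region, contig_seq, config = pipeline_config()) {
  p <- config$primer
  n <- nchar(contig_seq)
  rs <- region$span_start; re <- region$span_end
  clustered <- isTRUE(region$clustered)
  prod_max <- if (clustered) p$clustered_product_max else p$product_max
  cand <- function(side) {
    # enumerate candidate primers within the scan window on one side
    v_st <- list(); v_en <- list(); v_seq <- list(); v_gc <- list()
    v_tm <- list(); v_pen <- list()
    if (side == "left") {
      lo <- max(1L, rs - p$scan_window)
      starts <- seq.int(lo, max(lo, rs - p$len_min))
    } else {
      hi <- min(n, re + p$scan_window)
      starts <- seq.int(min(hi, re + p$len_min), hi)
    }
    for (len in p$len_min:p$len_max) {
      if (side == "left") {
        st <- starts; en <- st + len - 1L
        ok <- en < rs
      } else {
        en <- starts; st <- en - len + 1L
        ok <- st > re
      }
      st <- st[ok]; en <- en[ok]
      if (!length(st)) next
      seqs <- substring(contig_seq, st, en)
      if (side == "right") seqs <- revcomp(seqs)
      keep <- !grepl("N", seqs, fixed = TRUE)
      gc <- gc_percent(seqs)
      keep <- keep & gc >= p$gc_min & gc <= p$gc_max
      keep <- keep & !has_3prime_selfcomp(seqs)
      if (!any(keep)) next
      tm <- primer_tm(seqs[keep])
      k <- length(v_st) + 1L
      v_st[[k]] <- st[keep]; v_en[[k]] <- en[keep]
      v_seq[[k]] <- seqs[keep]; v_gc[[k]] <- gc[keep]; v_tm[[k]] <- tm
      v_pen[[k]] <- abs(len - p$len_opt) + abs(tm - p$tm_opt) +
        0.2 * abs(gc[keep] - p$gc_opt)
    }
    if (!length(v_st)) return(NULL)
    list(start = unlist(v_st), end = unlist(v_en), seq = unlist(v_seq),
         gc = unlist(v_gc), tm = unlist(v_tm), pen = unlist(v_pen))
  }
  L <- cand("left"); R <- cand("right")
  if (is.null(L) || is.null(R)) return(NULL)
  # all pairs, vectorised over the candidate grid
  nl <- length(L$start); nr <- length(R$start)
  li <- rep(seq_len(nl), times = nr)
  ri <- rep(seq_len(nr), each = nl)
  product <- R$end[ri] - L$start[li] + 1L
  ok <- product >= p$product_min & product <= prod_max
  if (!any(ok)) return(NULL)
  li <- li[ok]; ri <- ri[ok]; product <- product[ok]
  pen <- L$pen[li] + R$pen[ri]
  if (!clustered) pen <- pen + 0.01 * abs(product - 300)
  ties <- which(pen == min(pen))
  ord <- ties[order(L$start[li[ties]], product[ties])[1]]
  i <- li[ord]; j <- ri[ord]
  data.frame(left_seq = L$seq[i], right_seq = R$seq[j],
             left_start = L$start[i], left_end = L$end[i],
             right_start = R$start[j], right_end = R$end[j],
             tm_left = L$tm[i], tm_right = R$tm[j],
             gc_left = L$gc[i], gc_right = R$gc[j],
             product_size = product[ord], penalty = pen[ord],
             stringsAsFactors = FALSE)
}
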