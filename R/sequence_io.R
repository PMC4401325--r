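#' Read a parental contig set from FASTA
#'
#' Sequences are uppercased and validated as DNA over A/C/G/T/N; RNA (U) and
#' any other characters are rejected. Record order is preserved.
#'
#' @param path FASTA file path.
#' @param genotype label attached to every contig (e.g. `"A"` or `"B"` for
#'   the two mapping parents).
#' @return data.frame with columns `id`, `sequence`, `genotype`, `length`;
#'   one row per FASTA record.
#' @export
read_fasta <- function(path, genotype = NA_character_) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  ids <- names(set)
  seqs <- toupper(as.character(set))
  if (length(seqs) == 0) {
    return(data.frame(id = character(), sequence = character(),
                      genotype = character(), length = integer(),
                      stringsAsFactors = FALSE))
  }
  ids <- sub("\\s.*$", "", ids)
  if (any(!nzchar(ids)))
    stop("FASTA record ", which(!nzchar(ids))[1], " has an empty header")
  empty <- !nzchar(seqs)
  if (any(empty))
    stop("FASTA record '", ids[which(empty)[1]], "' has an empty sequence")
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad))
    stop("FASTA record '", ids[which(bad)[1]],
         "' contains non-DNA characters (only A/C/G/T/N allowed)")
  if (anyDuplicated(ids))
    stop("duplicate contig id: ", ids[anyDuplicated(ids)])
  contig_set(ids, seqs, genotype)
}

#' Construct a contig set
#'
#' @param ids unique contig identifiers.
#' @param seqs uppercase DNA sequences, same length as `ids`.
#' @param genotype parent label.
#' @return contig data.frame (see [read_fasta()]).
#' @export
contig_set <- function(ids, seqs, genotype = NA_character_) {
  stopifnot(length(ids) == length(seqs), !anyDuplicated(ids),
            all(nchar(seqs) > 0))
  out <- data.frame(id = unname(as.character(ids)),
                    sequence = unname(as.character(seqs)),
                    genotype = rep_len(genotype, length(ids)),
                    length = unname(nchar(seqs)),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Write a contig set to FASTA
#'
#' @param contigs contig data.frame from [read_fasta()] or [contig_set()].
#' @param path output path.
#' @export
write_fasta <- function(contigs, path) {
  set <- Biostrings::DNAStringSet(contigs$sequence)
  names(set) <- contigs$id
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

VARIANT_COLS <- c("contig_id", "pos", "ref", "alt", "DP", "MQ", "MQ0",
                  "QUAL", "ad_ref", "ad_alt")

#' Read a caller-style variant table
#'
#' The table is a fixed tab-separated dialect with a header line and columns
#' `contig_id pos ref alt DP MQ MQ0 QUAL ad_ref ad_alt` (a restricted
#' VCF-like record: position is 1-based, `DP` total depth, `MQ` RMS mapping
#' quality, `MQ0` mapping-quality-zero reads, `QUAL` call quality, allele
#' depths for ref and alt). The variant type is inferred from allele
#' lengths: equal length 1 is a SNP, a longer alt an insertion, a longer
#' ref a deletion.
#'
#' @param path TSV path.
#' @return data.frame of variant records with an added `vtype` column
#'   (`"SNP"`, `"INS"` or `"DEL"`).
#' @export
read_variant_table <- function(path) {
  if (!file.exists(path)) stop("variant table not found: ", path)
  tab <- read.delim(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(VARIANT_COLS, names(tab))
  if (length(missing))
    stop("variant table missing column(s): ", paste(missing, collapse = ", "))
  tab <- tab[, VARIANT_COLS]
  for (cl in c("pos", "DP", "MQ0", "ad_ref", "ad_alt"))
    tab[[cl]] <- as.integer(tab[[cl]])
  for (cl in c("MQ", "QUAL")) tab[[cl]] <- as.numeric(tab[[cl]])
  variant_records(tab, src = path)
}

# validate and type a variant record table
variant_records <- function(tab, src = "variant table") {
  tab$ref <- toupper(as.character(tab$ref))
  tab$alt <- toupper(as.character(tab$alt))
  bad <- which(tab$pos < 1)
  if (length(bad)) stop(src, " line ", bad[1], ": pos < 1")
  bad <- which(tab$DP < tab$ad_ref + tab$ad_alt | tab$ad_ref < 0 |
                 tab$ad_alt < 0)
  if (length(bad))
    stop(src, " line ", bad[1], ": DP must be >= ad_ref + ad_alt >= 0")
  rl <- nchar(tab$ref); al <- nchar(tab$alt)
  tab$vtype <- ifelse(rl == al & rl == 1L, "SNP",
                      ifelse(al > rl, "INS", "DEL"))
  bad <- which(rl == al & rl != 1L)
  if (length(bad))
    stop(src, " line ", bad[1], ": equal-length multi-base alleles are not",
         " a supported variant type")
  tab
}

#' Write a variant table
#'
#' Inverse of [read_variant_table()]; the `vtype` column is recomputed on
#' read and not written.
#'
#' @param records variant record data.frame.
#' @param path output TSV path.
#' @export
write_variant_table <- function(records, path) {
  write.table(records[, VARIANT_COLS], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Write the marker report
#'
#' Deterministic TSV: a `#`-prefixed summary block (counts, frequencies and
#' rate statistics mirroring the pipeline's bookkeeping) followed by the
#' marker table sorted by genotype, contig and position. Two runs on the
#' same inputs produce byte-identical files.
#'
#' @param markers data.frame with at least `marker_id`, `genotype`,
#'   `contig_id`, `start` columns (extra columns are carried through).
#' @param stats named list of summary fields; scalar entries are printed
#'   `# name<TAB>value`. Frequencies supplied as kb-per-marker are formatted
#'   `1/X kb`.
#' @param path output path.
#' @export
write_marker_report <- function(markers, stats, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("# radmarker marker report", con)
  for (nm in names(stats)) {
    v <- stats[[nm]]
    if (length(v) != 1) v <- paste(v, collapse = ",")
    if (is.numeric(v)) v <- format(v, scientific = FALSE, trim = TRUE)
    writeLines(sprintf("# %s\t%s", nm, v), con)
  }
  if (is.null(markers) || nrow(markers) == 0) {
    writeLines("marker_id\tgenotype\tcontig_id\tstart", con)
    return(invisible(path))
  }
  ord <- order(markers$genotype, markers$contig_id, markers$start,
               markers$marker_id, method = "radix")
  markers <- markers[ord, , drop = FALSE]
  suppressWarnings(write.table(markers, con, sep = "\t", quote = FALSE,
                               row.names = FALSE))
  invisible(path)
}

#' Format a marker frequency as the conventional "1/X kb" label
#'
#' @param freq_kb kilobases per marker (2-decimal scale).
#' @return character label, `"NA"` when the frequency is undefined.
#' @export
frequency_label <- function(freq_kb) {
  if (is.null(freq_kb) || length(freq_kb) == 0 || is.na(freq_kb)) return("NA")
  sprintf("1/%.2f kb", freq_kb)
}
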