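#' Pipeline configuration
#'
#' Assembles the full set of tunable parameters of the marker-development
#' pipeline, with defaults matching the published protocol the package
#' implements: SSR repeat minima of 7/5/4/3/3/3/3 for motif lengths 2-8,
#' compound-SSR interruption limit 500 bp, flank minimum 20 bp, anchoring
#' E-value cutoff 1e-5, known-marker redundancy threshold of 50 matched
#' bases, marker-cluster distance 500 bp, primer length 18-24 bp (optimum
#' 20), optimum Tm 57 C, GC 40-60% (optimum 50), product size 100-500 bp
#' (singleton) and < 800 bp (clustered region), minor-allele-frequency
#' thresholds 0.10 (homozygous) / 0.25 (heterozygous), and SNP depth
#' minimum 8.
#'
#' @param ... named overrides of any default listed above (see
#'   `pipeline_config()` for names).
#' @return a list of class `pipeline_config`.
#' @examples
#' cfg <- pipeline_config(flank_min = 25)
#' cfg$ssr_minima
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    ssr_minima = c(`2` = 7L, `3` = 5L, `4` = 4L, `5` = 3L, `6` = 3L,
                   `7` = 3L, `8` = 3L),
    compound_gap = 500L,
    flank_min = 20L,
    flank_max = 200L,
    evalue_cutoff = 1e-5,
    redundancy_matched_min = 50L,
    redundancy_evalue = 10,
    cluster_dist = 500L,
    geometry_window = 50L,
    word_size = 11L,
    scoring = list(match = 1L, mismatch = -2L, gap_open = 5L, gap_ext = 2L),
    karlin_K = 0.711,
    karlin_lambda = 1.37,
    primer = list(len_min = 18L, len_opt = 20L, len_max = 24L,
                  tm_opt = 57, gc_min = 40, gc_opt = 50, gc_max = 60,
                  product_min = 100L, product_max = 500L,
                  clustered_product_max = 799L, scan_window = 150L),
    maf_hom = 0.10,
    maf_het = 0.25,
    snp_min_depth = 8L,
    seed = 1L
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config field(s): ", paste(bad, collapse = ", "))
  for (nm in names(over)) {
    if (is.list(cfg[[nm]]) && is.list(over[[nm]])) {
      cfg[[nm]][names(over[[nm]])] <- over[[nm]]
    } else {
      cfg[[nm]] <- over[[nm]]
    }
  }
  validate_config(cfg)
  class(cfg) <- "pipeline_config"
  cfg
}

validate_config <- function(cfg) {
  stopifnot(all(cfg$ssr_minima >= 1), cfg$compound_gap > 0,
            cfg$flank_min > 0, cfg$flank_max >= cfg$flank_min,
            cfg$evalue_cutoff > 0, cfg$redundancy_matched_min > 0,
            cfg$cluster_dist > 0, cfg$snp_min_depth > 0)
  if (!(cfg$maf_hom < cfg$maf_het))
    stop("hom MAF threshold must be below het MAF threshold")
  invisible(cfg)
}

#' Read a pipeline configuration from a YAML file
#'
#' Flat keys override the defaults of [pipeline_config()]; nested keys
#' (`scoring`, `primer`) merge field-wise.
#'
#' @param path path to a YAML file.
#' @return a `pipeline_config` list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  do.call(pipeline_config, vals)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  str(unclass(x), max.level = 2, give.attr = FALSE)
  invisible(x)
}
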