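#' Marker polymorphism rate (percent)
#'
#' @param n_poly polymorphic marker count.
#' @param n_screened markers screened (> 0).
#' @return percent, rounded half-up to 2 decimals.
#' @examples
#' polymorphism_rate(83, 1323) # 6.27
#' @export
polymorphism_rate <- function(n_poly, n_screened) {
  if (n_screened <= 0) stop("n_screened must be > 0")
  stopifnot(n_poly >= 0, n_poly <= n_screened)
  round_half_up(100 * n_poly / n_screened, 2)
}

#' Average marker frequency (kb of sequence per marker)
#'
#' @param count marker count.
#' @param total_len_kb assembled length in kb.
#' @return kb per marker to 2 decimals (half-up), `NA` for zero markers.
#' @examples
#' marker_frequency(10619, 112330) # 10.58, i.e. one SSR per 10.58 kb
#' @export
marker_frequency <- function(count, total_len_kb) {
  stopifnot(total_len_kb > 0)
  if (count == 0) return(NA_real_)
  round_half_up(total_len_kb / count, 2)
}

#' Mean distance between adjacent mapped loci
#'
#' Total map length divided by the number of mapped loci (the convention
#' used when a map's mean adjacent distance is quoted).
#'
#' @param total_cM summed linkage-map length in centiMorgans.
#' @param n_loci mapped locus count (> 0).
#' @return cM, 2 decimals (half-up).
#' @export
mean_map_distance <- function(total_cM, n_loci) {
  if (n_loci <= 0) stop("n_loci must be > 0")
  round_half_up(total_cM / n_loci, 2)
}

#' Segregation chi-square screen for one locus
#'
#' Pearson chi-square of observed F2 genotype counts against the Mendelian
#' expectation: 1:2:1 for codominant loci (counts AA, Aa, aa; df = 2) or
#' 3:1 for dominant loci (counts dominant, recessive; df = 1). A locus is
#' flagged distorted at P <= 0.05. The model ratio may be given scaled
#' (25:50:25 is the same model as 1:2:1).
#'
#' @param observed integer counts, length 3 (`"1:2:1"`) or 2 (`"3:1"`).
#' @param model `"1:2:1"` or `"3:1"`, or a numeric ratio vector matching
#'   `observed` in length.
#' @param alpha distortion threshold on the p-value.
#' @return list: `chi2`, `df`, `pvalue`, `distorted`.
#' @export
segregation_chisq <- function(observed, model = c("1:2:1", "3:1"),
                              alpha = 0.05) {
  if (is.character(model)) {
    model <- match.arg(model)
    ratio <- if (model == "1:2:1") c(1, 2, 1) else c(3, 1)
  } else {
    ratio <- model
  }
  if (length(observed) != length(ratio))
    stop("observed counts do not match the model arity")
  stopifnot(all(observed >= 0), sum(observed) > 0, all(ratio > 0))
  ct <- suppressWarnings(
    chisq.test(observed, p = ratio / sum(ratio), correct = FALSE))
  chi2 <- unname(ct$statistic)
  df <- unname(ct$parameter)
  p <- pchisq(chi2, df, lower.tail = FALSE)
  list(chi2 = chi2, df = df, pvalue = p, distorted = p <= alpha)
}

#' Segregation screen over a locus table
#'
#' @param loci data.frame with `locus_id`, count columns `n_AA`, `n_Aa`,
#'   `n_aa` (codominant) or `n_dom`, `n_rec` (dominant), and a `model`
#'   column (`"1:2:1"`/`"3:1"`).
#' @param alpha distortion threshold.
#' @return input with `chi2`, `df`, `pvalue`, `distorted` columns added.
#' @export
segregation_screen <- function(loci, alpha = 0.05) {
  res <- lapply(seq_len(nrow(loci)), function(i) {
    obs <- if (loci$model[i] == "1:2:1") {
      c(loci$n_AA[i], loci$n_Aa[i], loci$n_aa[i])
    } else {
      c(loci$n_dom[i], loci$n_rec[i])
    }
    segregation_chisq(obs, loci$model[i], alpha)
  })
  loci$chi2 <- vapply(res, `[[`, numeric(1), "chi2")
  loci$df <- vapply(res, `[[`, numeric(1), "df")
  loci$pvalue <- vapply(res, `[[`, numeric(1), "pvalue")
  loci$distorted <- vapply(res, `[[`, logical(1), "distorted")
  loci
}
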