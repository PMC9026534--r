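#' Diversity summary: polymorphic ratio and heterozygosity
#'
#' Computes three population-diversity statistics over the markers of the
#' dataset as given (the caller chooses whether that is pre- or post-QC):
#'
#' * `P_N = M / N` — proportion of polymorphic markers, where a marker is
#'   polymorphic when both alleles are observed among genotyped individuals
#'   (MAF > 0), and `N` is the total marker count of the dataset.
#' * `Ho` — observed heterozygosity: mean over markers of the fraction of
#'   heterozygous calls among non-missing calls.
#' * `He` — expected heterozygosity: mean over markers of `2 p (1 - p)` with
#'   `p` estimated from the sample. With `unbiased = TRUE` each term is
#'   multiplied by `2n_j / (2n_j - 1)` (small-sample correction); the default
#'   is the plain plug-in ratio.
#'
#' @param ds a [genotype_dataset()] with at least one marker and sample.
#' @param unbiased apply the small-sample correction to `He`.
#' @return A list of class `diversity_summary` with fields `P_N`,
#'   `n_polymorphic`, `n_total`, `He`, `Ho`.
#' @export
diversity_summary <- function(ds, unbiased = FALSE) {
  if (nrow(ds$markers) == 0L || nrow(ds$samples) == 0L)
    stop("diversity summary requires a non-empty dataset")
  nn <- colSums(!is.na(ds$calls))
  genotyped <- nn > 0L
  p <- allele_freq(ds)
  maf <- pmin(p, 1 - p)
  n_poly <- sum(maf > 0, na.rm = TRUE)
  n_total <- nrow(ds$markers)

  n_het <- colSums(ds$calls == 1L, na.rm = TRUE)
  ho <- mean(n_het[genotyped] / nn[genotyped])
  he_j <- 2 * p[genotyped] * (1 - p[genotyped])
  if (unbiased)
    he_j <- he_j * (2 * nn[genotyped]) / (2 * nn[genotyped] - 1)
  he <- mean(he_j)

  structure(list(P_N = n_poly / n_total, n_polymorphic = n_poly,
                 n_total = n_total, He = he, Ho = ho),
            class = "diversity_summary")
}

#' @export
print.diversity_summary <- function(x, ...) {
  cat(sprintf("P_N = %.4f (%d / %d polymorphic)\n",
              x$P_N, x$n_polymorphic, x$n_total))
  cat(sprintf("He  = %.4f\nHo  = %.4f\n", x$He, x$Ho))
  invisible(x)
}
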