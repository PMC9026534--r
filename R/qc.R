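#' Per-marker call rate
#'
#' Fraction of samples with a non-missing call at each marker.
#'
#' @param ds a [genotype_dataset()].
#' @return Numeric vector, one value per marker.
#' @export
marker_call_rate <- function(ds) {
  if (nrow(ds$samples) == 0L) stop("call rate undefined for zero samples")
  colMeans(!is.na(ds$calls))
}

#' Per-marker allele frequency and minor allele frequency
#'
#' `allele_freq` returns the frequency `p` of the second allele (`a2`, the
#' allele dosages count); `minor_allele_freq` returns `min(p, 1 - p)`.
#' Markers with no non-missing call get `NA`.
#'
#' @param ds a [genotype_dataset()].
#' @return Numeric vector, one value per marker.
#' @export
allele_freq <- function(ds) {
  nn <- colSums(!is.na(ds$calls))
  p <- colSums(ds$calls, na.rm = TRUE) / (2 * nn)
  p[nn == 0L] <- NA_real_
  p
}

#' @rdname allele_freq
#' @export
minor_allele_freq <- function(ds) {
  p <- allele_freq(ds)
  pmin(p, 1 - p)
}

#' Exact Hardy-Weinberg test for one biallelic marker
#'
#' Two-sided exact test on observed genotype counts: conditioning on the
#' allele counts, the p-value is the summed probability of every heterozygote
#' count whose conditional probability does not exceed that of the observed
#' count. Probabilities follow the standard conditional distribution
#' `P(n_het | n, n_minor)`, evaluated by recurrence for numerical stability.
#' Not a mid-p variant.
#'
#' @param n_hom1,n_het,n_hom2 non-negative genotype counts (hom for one
#'   allele, het, hom for the other); at least one individual in total.
#' @return p-value in `(0, 1]`.
#' @export
hwe_exact_p <- function(n_hom1, n_het, n_hom2) {
  if (any(c(n_hom1, n_het, n_hom2) < 0)) stop("genotype counts must be >= 0")
  n <- n_hom1 + n_het + n_hom2
  if (n < 1) stop("at least one genotyped individual required")
  n_rare <- 2L * min(n_hom1, n_hom2) + n_het
  hets <- seq.int(n_rare %% 2L, n_rare, by = 2L)  # feasible het counts
  # unnormalized probabilities by recurrence:
  # P(h+2)/P(h) = 4*hom1(h)*hom2(h) / ((h+2)*(h+1)),
  # where hom_rare(h) = (n_rare - h)/2, hom_common(h) = n - (n_rare + h)/2...
  lp <- numeric(length(hets))
  for (k in seq_along(hets)[-1]) {
    h <- hets[k - 1L]
    hr <- (n_rare - h) / 2
    hc <- n - (n_rare + h) / 2
    lp[k] <- lp[k - 1L] + log(4 * hr * hc) - log((h + 2) * (h + 1))
  }
  pr <- exp(lp - max(lp))
  pr <- pr / sum(pr)
  obs <- which(hets == n_het)
  if (length(obs) != 1L)
    stop("observed het count ", n_het,
         " impossible given the allele counts")
  p <- sum(pr[pr <= pr[obs] * (1 + 1e-12)])
  min(1, p)
}

#' QC thresholds
#'
#' Container for the marker-filter thresholds: minimum call rate, minimum
#' minor allele frequency, minimum exact Hardy-Weinberg p-value, and whether
#' to keep autosomes only.
#'
#' @param min_call_rate,min_maf fractions in `[0, 1]`.
#' @param min_hwe_p probability in `[0, 1]`.
#' @param autosomes_only drop markers on chromosomes outside `autosomes`.
#' @param autosomes integer labels treated as autosomes.
#' @return A list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_call_rate = 0.90, min_maf = 0.01,
                          min_hwe_p = 1e-6, autosomes_only = TRUE,
                          autosomes = 1:18) {
  for (v in c(min_call_rate, min_maf, min_hwe_p))
    if (is.na(v) || v < 0 || v > 1)
      stop("QC thresholds must lie in [0, 1]")
  structure(list(min_call_rate = min_call_rate, min_maf = min_maf,
                 min_hwe_p = min_hwe_p, autosomes_only = autosomes_only,
                 autosomes = as.integer(autosomes)),
            class = "qc_thresholds")
}

#' Sequential marker quality control
#'
#' Applies the four marker filters sequentially — call rate, then minor
#' allele frequency, then the exact Hardy-Weinberg test, then the autosome
#' restriction — so each stage's removal count refers to the survivors of the
#' previous stage and `n_retained = n_input - sum(removals)`. Markers keep
#' their original order. Individuals are never removed.
#'
#' @param ds a [genotype_dataset()].
#' @param thresholds a [qc_thresholds()].
#' @return List with elements `dataset` (filtered [genotype_dataset()]) and
#'   `report` (a `qc_report` with per-stage removal counts).
#' @export
apply_qc <- function(ds, thresholds = qc_thresholds()) {
  stopifnot(inherits(thresholds, "qc_thresholds"))
  validate_genotype_dataset(ds)
  m0 <- nrow(ds$markers)
  cur <- ds

  cr <- marker_call_rate(cur)
  keep <- cr >= thresholds$min_call_rate
  removed_call_rate <- sum(!keep)
  cur <- subset_dataset(cur, markers = which(keep))

  maf <- minor_allele_freq(cur)
  keep <- !is.na(maf) & maf >= thresholds$min_maf
  removed_maf <- sum(!keep)
  cur <- subset_dataset(cur, markers = which(keep))

  hwe <- hwe_p_per_marker(cur)
  keep <- is.na(hwe) | hwe >= thresholds$min_hwe_p
  removed_hwe <- sum(!keep)
  cur <- subset_dataset(cur, markers = which(keep))

  if (thresholds$autosomes_only) {
    keep <- cur$markers$chromosome %in% thresholds$autosomes
    removed_sex <- sum(!keep)
    cur <- subset_dataset(cur, markers = which(keep))
  } else removed_sex <- 0L

  report <- qc_report(n_input_snps = m0,
                      removed_call_rate = removed_call_rate,
                      removed_maf = removed_maf,
                      removed_hwe = removed_hwe,
                      removed_sex_chrom = removed_sex,
                      n_samples = nrow(ds$samples))
  list(dataset = cur, report = report)
}

#' QC report
#'
#' Records the input marker count and each sequential filter's removal count;
#' `n_retained` is derived as the input count minus the summed removals.
#'
#' @param n_input_snps,removed_call_rate,removed_maf,removed_hwe,removed_sex_chrom
#'   counts from the sequential filter stages.
#' @param n_samples number of individuals (all retained).
#' @return A list of class `qc_report` with computed `n_retained`.
#' @export
qc_report <- function(n_input_snps, removed_call_rate, removed_maf,
                      removed_hwe, removed_sex_chrom, n_samples) {
  counts <- c(n_input_snps, removed_call_rate, removed_maf, removed_hwe,
              removed_sex_chrom)
  if (any(counts < 0)) stop("counts must be non-negative")
  n_retained <- n_input_snps - (removed_call_rate + removed_maf +
                                removed_hwe + removed_sex_chrom)
  if (n_retained < 0) stop("removals exceed input marker count")
  structure(list(n_input_snps = n_input_snps,
                 removed_call_rate = removed_call_rate,
                 removed_maf = removed_maf,
                 removed_hwe = removed_hwe,
                 removed_sex_chrom = removed_sex_chrom,
                 n_retained = n_retained,
                 n_samples = n_samples),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("Marker QC (sequential filters)\n")
  cat(sprintf("  input SNPs:           %8d\n", x$n_input_snps))
  cat(sprintf("  - low call rate:      %8d\n", x$removed_call_rate))
  cat(sprintf("  - low MAF:            %8d\n", x$removed_maf))
  cat(sprintf("  - HWE failure:        %8d\n", x$removed_hwe))
  cat(sprintf("  - sex chromosomes:    %8d\n", x$removed_sex_chrom))
  cat(sprintf("  retained:             %8d\n", x$n_retained))
  cat(sprintf("  individuals:          %8d\n", x$n_samples))
  invisible(x)
}

#' Exact Hardy-Weinberg p-value for every marker
#'
#' Computed on complete genotypes only; markers with no non-missing call get
#' `NA`.
#'
#' @param ds a [genotype_dataset()].
#' @return Numeric vector of p-values.
#' @export
hwe_p_per_marker <- function(ds) {
  vapply(seq_len(nrow(ds$markers)), function(j) {
    x <- ds$calls[, j]
    x <- x[!is.na(x)]
    if (!length(x)) return(NA_real_)
    hwe_exact_p(sum(x == 0L), sum(x == 1L), sum(x == 2L))
  }, numeric(1))
}
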