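#' VanRaden genomic relationship matrix
#'
#' Method-1 GRM: `G = Z Z' / (2 * sum_j p_j (1 - p_j))`, where `Z` holds the
#' dosages centred by twice the allele frequency estimated from this sample.
#' Missing dosages are mean-imputed (zero after centring); monomorphic
#' markers contribute nothing and are skipped. Off-diagonal entries
#' approximate twice the kinship coefficient; the construction is invariant
#' to which allele is labelled `a1`/`a2` at any marker.
#'
#' @param ds a post-QC [genotype_dataset()] with at least one polymorphic
#'   marker.
#' @return A `relationship_matrix` (list with `sample_ids`, `values`,
#'   `kind = "G"`, and `n_markers_used`).
#' @export
vanraden_g <- function(ds) {
  validate_genotype_dataset(ds)
  p <- allele_freq(ds)
  poly <- !is.na(p) & p > 0 & p < 1
  if (!any(poly))
    stop("all markers monomorphic: VanRaden denominator is zero")
  x <- ds$calls[, poly, drop = FALSE]
  p <- p[poly]
  z <- sweep(x, 2L, 2 * p)
  z[is.na(z)] <- 0
  denom <- 2 * sum(p * (1 - p))
  g <- tcrossprod(z) / denom
  dimnames(g) <- list(ds$samples$sample_id, ds$samples$sample_id)
  structure(list(sample_ids = ds$samples$sample_id, values = g, kind = "G",
                 n_markers_used = sum(poly)),
            class = "relationship_matrix")
}

#' Identity-by-state distance matrix
#'
#' `D_ij = 1 - (shared alleles) / (2 m_ij)` over pairwise-complete markers,
#' where a marker contributes `2 - |dosage_i - dosage_j|` shared alleles and
#' `m_ij` is the count of markers genotyped in both individuals. Identical
#' genotypes give 0, opposite homozygotes at every marker give 1.
#'
#' @param ds a [genotype_dataset()]; every pair must share at least one
#'   genotyped marker.
#' @return A `relationship_matrix` with `kind = "IBS_distance"`.
#' @export
ibs_distance <- function(ds) {
  validate_genotype_dataset(ds)
  x <- ds$calls
  a0 <- (!is.na(x) & x == 0L) * 1
  a1 <- (!is.na(x) & x == 1L) * 1
  a2 <- (!is.na(x) & x == 2L) * 1
  nonmiss <- a0 + a1 + a2
  m_ij <- tcrossprod(nonmiss)
  if (any(m_ij == 0)) {
    bad <- which(m_ij == 0, arr.ind = TRUE)[1, ]
    stop("no shared genotyped marker for pair ",
         ds$samples$sample_id[bad[1]], " / ", ds$samples$sample_id[bad[2]])
  }
  # sum over complete markers of |d_i - d_j|
  absdiff <- 2 * (tcrossprod(a0, a2) + tcrossprod(a2, a0)) +
    tcrossprod(a1, a0 + a2) + tcrossprod(a0 + a2, a1)
  d <- absdiff / (2 * m_ij)
  diag(d) <- 0
  dimnames(d) <- list(ds$samples$sample_id, ds$samples$sample_id)
  structure(list(sample_ids = ds$samples$sample_id, values = d,
                 kind = "IBS_distance"),
            class = "relationship_matrix")
}

#' @export
print.relationship_matrix <- function(x, ...) {
  cat(x$kind, "matrix,", length(x$sample_ids), "individuals\n")
  off <- x$values[upper.tri(x$values)]
  if (length(off))
    cat(sprintf("  off-diagonal range: [%.4f, %.4f]\n", min(off), max(off)))
  invisible(x)
}

#' Write a relationship matrix as tab-separated text
#'
#' Square layout with a header row and first column of sample ids; the kind
#' is recorded on a comment line.
#'
#' @param rm a `relationship_matrix`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_relationship_matrix <- function(rm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# kind=", rm$kind), con)
  writeLines(paste(c("sample_id", rm$sample_ids), collapse = "\t"), con)
  apply_rows <- vapply(seq_along(rm$sample_ids), function(i)
    paste(c(rm$sample_ids[i],
            formatC(rm$values[i, ], format = "g", digits = 10)),
          collapse = "\t"), character(1))
  writeLines(apply_rows, con)
  invisible(path)
}
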