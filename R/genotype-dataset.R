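#' In-memory SNP genotype dataset
#'
#' Bundles a sample table, a marker map, and an allele-dosage call matrix into
#' a validated container used by every analysis stage. Calls are coded as the
#' number of copies of the second allele (`a2`): `0` = homozygous `a1/a1`,
#' `1` = heterozygous, `2` = homozygous `a2/a2`, `NA` = missing.
#'
#' @param samples data.frame with columns `sample_id` (unique character),
#'   `sex` (`"male"`, `"female"` or `"unknown"`) and optionally `group_label`.
#' @param markers data.frame with columns `marker_id`, `chromosome` (integer
#'   label), `position_bp` (1-based physical position), `allele_a1`,
#'   `allele_a2`.
#' @param calls integer matrix, `nrow(samples)` x `nrow(markers)`, values in
#'   `{0, 1, 2, NA}`.
#' @param sort_markers if `TRUE` (default), markers are re-sorted by
#'   `(chromosome, position_bp)` and the call matrix columns permuted to
#'   match.
#'
#' @return An object of class `genotype_dataset`.
#' @export
genotype_dataset <- function(samples, markers, calls, sort_markers = TRUE) {
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  markers <- as.data.frame(markers, stringsAsFactors = FALSE)
  if (!"sex" %in% names(samples))
    samples$sex <- rep("unknown", nrow(samples))
  if (!"group_label" %in% names(samples))
    samples$group_label <- rep(NA_character_, nrow(samples))
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (sort_markers && nrow(markers) > 1L) {
    ord <- order(markers$chromosome, markers$position_bp)
    markers <- markers[ord, , drop = FALSE]
    calls <- calls[, ord, drop = FALSE]
    rownames(markers) <- NULL
  }
  ds <- structure(
    list(samples = samples, markers = markers, calls = calls),
    class = "genotype_dataset"
  )
  validate_genotype_dataset(ds)
  dimnames(ds$calls) <- list(samples$sample_id, markers$marker_id)
  ds
}

#' Validate a genotype dataset
#'
#' Checks the container invariants: matching dimensions, unique sample ids,
#' legal call codes, positive 1-based positions, and per-chromosome position
#' sorting.
#'
#' @param ds a `genotype_dataset`.
#' @return `ds`, invisibly; stops with a descriptive error on violation.
#' @export
validate_genotype_dataset <- function(ds) {
  stopifnot(inherits(ds, "genotype_dataset"))
  n <- nrow(ds$samples)
  m <- nrow(ds$markers)
  if (!identical(dim(ds$calls), c(n, m)))
    stop("call matrix is ", nrow(ds$calls), "x", ncol(ds$calls),
         " but dataset declares ", n, " samples x ", m, " markers")
  if (anyDuplicated(ds$samples$sample_id))
    stop("duplicate sample_id: ",
         paste(unique(ds$samples$sample_id[duplicated(ds$samples$sample_id)]),
               collapse = ", "))
  bad <- ds$calls[!is.na(ds$calls)]
  if (length(bad) && (min(bad) < 0L || max(bad) > 2L))
    stop("call codes must be 0, 1, 2 or NA")
  if (m > 0L) {
    if (any(ds$markers$position_bp < 1L))
      stop("position_bp must be >= 1 (1-based coordinates)")
    for (chr in unique(ds$markers$chromosome)) {
      pos <- ds$markers$position_bp[ds$markers$chromosome == chr]
      if (is.unsorted(pos))
        stop("markers on chromosome ", chr, " are not sorted by position")
    }
  }
  invisible(ds)
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat("genotype_dataset:", nrow(x$samples), "samples x",
      nrow(x$markers), "markers\n")
  if (nrow(x$markers))
    cat("  chromosomes:", paste(sort(unique(x$markers$chromosome)),
                                collapse = " "), "\n")
  miss <- mean(is.na(x$calls))
  cat(sprintf("  missing call rate: %.4f\n", if (length(x$calls)) miss else 0))
  invisible(x)
}

#' @export
dim.genotype_dataset <- function(x) dim(x$calls)

#' Subset a genotype dataset by samples and/or markers
#'
#' @param ds a `genotype_dataset`.
#' @param samples,markers logical, integer or character index into the sample
#'   and marker tables; `NULL` keeps everything.
#' @return A new `genotype_dataset`.
#' @export
subset_dataset <- function(ds, samples = NULL, markers = NULL) {
  si <- if (is.null(samples)) seq_len(nrow(ds$samples)) else samples
  if (is.character(si)) si <- match(si, ds$samples$sample_id)
  mi <- if (is.null(markers)) seq_len(nrow(ds$markers)) else markers
  if (is.character(mi)) mi <- match(mi, ds$markers$marker_id)
  smp <- ds$samples[si, , drop = FALSE]
  mk <- ds$markers[mi, , drop = FALSE]
  rownames(smp) <- NULL
  rownames(mk) <- NULL
  genotype_dataset(smp, mk, ds$calls[si, mi, drop = FALSE],
                   sort_markers = FALSE)
}
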