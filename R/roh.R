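#' ROH detection parameters
#'
#' The seven sliding-window criteria used to call a run of homozygosity:
#' a minimum of `min_snps_in_roh` consecutive SNPs; a scanning window of
#' `window_snps` SNPs moved one SNP at a time; a minimum density of one SNP
#' per `min_density_bp_per_snp` bp; at most `max_het_in_roh` heterozygous and
#' `max_missing_in_roh` missing calls; a per-SNP good-window proportion of at
#' least `window_threshold`; a minimum length of `min_length_bp`; and a
#' maximum gap between consecutive SNPs of `max_gap_bp`.
#'
#' @param min_snps_in_roh minimum SNP count in an emitted segment (30).
#' @param window_snps scanning-window size in SNPs (50).
#' @param min_density_bp_per_snp maximum bp per SNP inside a segment (1 Mb,
#'   i.e. one SNP per 1000 kb).
#' @param max_het_in_roh,max_missing_in_roh heterozygous / missing call caps,
#'   applied both per window and per final segment (1 and 1).
#' @param window_threshold minimum proportion of good windows covering a SNP
#'   for it to be eligible (0.05).
#' @param min_length_bp minimum segment length (1 Mb).
#' @param max_gap_bp maximum gap between consecutive SNPs in a segment (1 Mb).
#' @return A list of class `roh_params`.
#' @export
roh_params <- function(min_snps_in_roh = 30L, window_snps = 50L,
                       min_density_bp_per_snp = 1e6L, max_het_in_roh = 1L,
                       max_missing_in_roh = 1L, window_threshold = 0.05,
                       min_length_bp = 1e6L, max_gap_bp = 1e6L) {
  p <- list(min_snps_in_roh = as.integer(min_snps_in_roh),
            window_snps = as.integer(window_snps),
            min_density_bp_per_snp = as.numeric(min_density_bp_per_snp),
            max_het_in_roh = as.integer(max_het_in_roh),
            max_missing_in_roh = as.integer(max_missing_in_roh),
            window_threshold = window_threshold,
            min_length_bp = as.numeric(min_length_bp),
            max_gap_bp = as.numeric(max_gap_bp))
  if (any(unlist(p) <= 0)) stop("all ROH parameters must be positive")
  if (p$window_threshold > 1) stop("window_threshold must lie in (0, 1]")
  structure(p, class = "roh_params")
}

# Candidate-run splitter: greedy left-to-right; when adding a SNP would push
# the segment past the het or missing cap, the candidate closes just before
# it and a new candidate starts at that SNP. Guarantees emitted segments are
# disjoint and never contain more than the capped number of het/missing calls.
.split_by_caps <- function(het, miss, max_het, max_missing) {
  n <- length(het)
  out <- list()
  s <- 1L
  ch <- 0L
  cm <- 0L
  for (i in seq_len(n)) {
    nh <- ch + het[i]
    nm <- cm + miss[i]
    if (nh > max_het || nm > max_missing) {
      if (i > s) out[[length(out) + 1L]] <- c(s, i - 1L)
      s <- i
      ch <- het[i]
      cm <- miss[i]
    } else {
      ch <- nh
      cm <- nm
    }
  }
  if (n >= s) out[[length(out) + 1L]] <- c(s, n)
  out
}

# indices (relative) after trimming both ends to homozygous non-missing calls
.trim_to_hom <- function(het, miss, from, to) {
  while (from <= to && (het[from] || miss[from])) from <- from + 1L
  while (to >= from && (het[to] || miss[to])) to <- to - 1L
  if (from > to) NULL else c(from, to)
}

#' Detect runs of homozygosity
#'
#' Scans each sample and chromosome with a sliding window of
#' `window_snps` SNPs moved one SNP at a time. A window is *good* when it
#' holds at most `max_het_in_roh` heterozygous and `max_missing_in_roh`
#' missing calls; a SNP is *eligible* when the proportion of good windows
#' covering it is at least `window_threshold`. Maximal runs of eligible SNPs
#' are split wherever adjacent SNPs lie more than `max_gap_bp` apart, split
#' again so no candidate exceeds the het/missing caps (greedy left-to-right;
#' see Details), trimmed so both ends are homozygous non-missing calls, and
#' emitted only if they satisfy every segment criterion: SNP count, length,
#' density, and the het/missing caps. Chromosomes with fewer SNPs than
#' `window_snps` are scanned with a single window spanning the whole
#' chromosome.
#'
#' Segment length is `end_bp - start_bp` (the span between the first and last
#' SNP), matching the kb convention of the common command-line tools.
#'
#' @param ds a post-QC autosomal [genotype_dataset()].
#' @param params a [roh_params()].
#' @param segment_caps enforce the het/missing caps on final segments (the
#'   default) in addition to the window level; `FALSE` restricts them to the
#'   window level.
#' @return data.frame with one row per segment: `sample_id`, `chromosome`,
#'   `start_bp`, `end_bp`, `n_snps`, `length_bp`, `n_het`, `n_missing`.
#' @export
detect_roh <- function(ds, params = roh_params(), segment_caps = TRUE) {
  validate_genotype_dataset(ds)
  res <- list()
  nres <- 0L
  for (chr in unique(ds$markers$chromosome)) {
    mi <- which(ds$markers$chromosome == chr)
    pos <- ds$markers$position_bp[mi]
    m <- length(mi)
    w <- min(params$window_snps, m)
    n_win <- m - w + 1L
    # number of windows covering SNP i
    cover <- pmin(seq_len(m), n_win, w, m - seq_len(m) + 1L)
    for (s in seq_len(nrow(ds$samples))) {
      calls <- ds$calls[s, mi]
      het <- !is.na(calls) & calls == 1L
      miss <- is.na(calls)
      # good windows via running sums
      ch <- cumsum(c(0L, het))
      cm <- cumsum(c(0L, miss))
      starts <- seq_len(n_win)
      good <- (ch[starts + w] - ch[starts]) <= params$max_het_in_roh &
        (cm[starts + w] - cm[starts]) <= params$max_missing_in_roh
      cg <- cumsum(c(0L, good))
      lo <- pmax(seq_len(m) - w + 1L, 1L)
      hi <- pmin(seq_len(m), n_win)
      n_good <- cg[hi + 1L] - cg[lo]
      eligible <- hi >= lo & (n_good / cover) >= params$window_threshold

      # maximal eligible runs, split at large gaps
      r <- rle(eligible)
      ends <- cumsum(r$lengths)
      starts_r <- ends - r$lengths + 1L
      for (k in which(r$values)) {
        a <- starts_r[k]
        b <- ends[k]
        gap_break <- which(diff(pos[a:b]) > params$max_gap_bp)
        piece_start <- a + c(0L, gap_break)
        piece_end <- c(a + gap_break - 1L, b)
        for (pc in seq_along(piece_start)) {
          pa <- piece_start[pc]
          pb <- piece_end[pc]
          cand <- if (segment_caps)
            lapply(.split_by_caps(het[pa:pb], miss[pa:pb],
                                  params$max_het_in_roh,
                                  params$max_missing_in_roh),
                   function(z) z + pa - 1L)
          else list(c(pa, pb))
          for (cd in cand) {
            tr <- .trim_to_hom(het, miss, cd[1], cd[2])
            if (is.null(tr)) next
            n_snps <- tr[2] - tr[1] + 1L
            len <- pos[tr[2]] - pos[tr[1]]
            if (n_snps < params$min_snps_in_roh) next
            if (len < params$min_length_bp) next
            if (len / n_snps > params$min_density_bp_per_snp) next
            nh <- sum(het[tr[1]:tr[2]])
            nm <- sum(miss[tr[1]:tr[2]])
            if (segment_caps &&
                (nh > params$max_het_in_roh ||
                 nm > params$max_missing_in_roh)) next
            nres <- nres + 1L
            res[[nres]] <- data.frame(
              sample_id = ds$samples$sample_id[s], chromosome = chr,
              start_bp = pos[tr[1]], end_bp = pos[tr[2]],
              n_snps = n_snps, length_bp = len, n_het = nh, n_missing = nm,
              stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  if (!nres)
    return(data.frame(sample_id = character(0), chromosome = integer(0),
                      start_bp = numeric(0), end_bp = numeric(0),
                      n_snps = integer(0), length_bp = numeric(0),
                      n_het = integer(0), n_missing = integer(0)))
  out <- do.call(rbind, res)
  out[order(out$sample_id, out$chromosome, out$start_bp), , drop = FALSE]
}

#' Length-class summary of ROH segments
#'
#' Splits segments into half-open length classes (default 1–5, 5–10 and
#' > 10 Mb, with 5 Mb in the middle class and 10 Mb in the long class) and
#' tabulates count, share of all segments, mean and SD of lengths, total
#' length, and share of the summed length — all lengths in Mb.
#'
#' @param segments a segment table from [detect_roh()] (or any data.frame
#'   with a `length_bp` column).
#' @param breaks_mb lower class edges in Mb; the last class is open-ended.
#' @return data.frame with columns `class`, `count`, `number_pct`, `mean_mb`,
#'   `sd_mb`, `total_mb`, `length_pct`.
#' @export
classify_roh <- function(segments, breaks_mb = c(1, 5, 10)) {
  lab <- c(paste0(breaks_mb[-length(breaks_mb)], "-",
                  breaks_mb[-1], "Mb"),
           paste0(">", breaks_mb[length(breaks_mb)], "Mb"))
  len_mb <- segments$length_bp / 1e6
  cls <- findInterval(len_mb, breaks_mb)
  cls[cls == 0L] <- NA_integer_  # below the first edge: not classified
  n_all <- sum(!is.na(cls))
  tot_all <- sum(len_mb[!is.na(cls)])
  out <- do.call(rbind, lapply(seq_along(lab), function(k) {
    v <- len_mb[!is.na(cls) & cls == k]
    data.frame(class = lab[k], count = length(v),
               number_pct = if (n_all) 100 * length(v) / n_all else 0,
               mean_mb = if (length(v)) mean(v) else 0,
               sd_mb = if (length(v) > 1) stats::sd(v) else 0,
               total_mb = sum(v),
               length_pct = if (tot_all > 0) 100 * sum(v) / tot_all else 0,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Per-chromosome and per-individual ROH summaries
#'
#' @param segments a segment table from [detect_roh()].
#' @param ds the [genotype_dataset()] the segments came from; supplies the
#'   full sample and chromosome lists so zero-count rows appear.
#' @return List with `per_chromosome` (chromosome, n_roh), `per_individual`
#'   (sample_id, n_roh, total_length_bp) and `mean_per_individual`.
#' @export
roh_summaries <- function(segments, ds) {
  chroms <- sort(unique(ds$markers$chromosome))
  per_chr <- data.frame(
    chromosome = chroms,
    n_roh = vapply(chroms, function(c) sum(segments$chromosome == c),
                   integer(1)))
  ids <- ds$samples$sample_id
  per_ind <- data.frame(
    sample_id = ids,
    n_roh = vapply(ids, function(i) sum(segments$sample_id == i),
                   integer(1)),
    total_length_bp = vapply(ids, function(i)
      sum(segments$length_bp[segments$sample_id == i]), numeric(1)))
  rownames(per_ind) <- NULL
  list(per_chromosome = per_chr, per_individual = per_ind,
       mean_per_individual = nrow(segments) / length(ids))
}

#' Genomic inbreeding coefficient from ROHs
#'
#' `F_ROH` for an individual is the summed length of its ROH segments
#' divided by the autosomal genome length. Individuals listed in
#' `sample_ids` but carrying no segment get `F_ROH = 0`.
#'
#' @param segments a segment table from [detect_roh()].
#' @param autosome_length_kb total autosomal length in kb. The default,
#'   2,450,713 kb, is the pig (Sscrofa 10.2) autosomal genome length.
#' @param sample_ids individuals to report; defaults to those present in
#'   `segments`.
#' @return A list of class `inbreeding_result`: `f_roh` (named per-sample
#'   vector), `population_mean`, `autosome_length_kb`.
#' @export
f_roh <- function(segments, autosome_length_kb = 2450713,
                  sample_ids = NULL) {
  if (autosome_length_kb <= 0) stop("autosome_length_kb must be > 0")
  if (is.null(sample_ids)) sample_ids <- unique(segments$sample_id)
  tot_kb <- vapply(sample_ids, function(i)
    sum(segments$length_bp[segments$sample_id == i]) / 1000, numeric(1))
  if (any(tot_kb > autosome_length_kb))
    stop("summed ROH length exceeds the autosome length for: ",
         paste(sample_ids[tot_kb > autosome_length_kb], collapse = ", "))
  f <- tot_kb / autosome_length_kb
  names(f) <- sample_ids
  structure(list(f_roh = f,
                 population_mean = if (length(f)) mean(f) else 0,
                 autosome_length_kb = autosome_length_kb),
            class = "inbreeding_result")
}

#' @export
print.inbreeding_result <- function(x, ...) {
  cat(sprintf("F_ROH over %d individuals (L_auto = %s kb)\n",
              length(x$f_roh), format(x$autosome_length_kb, big.mark = ",")))
  cat(sprintf("  mean %.4f, range [%.4f, %.4f]\n", x$population_mean,
              if (length(x$f_roh)) min(x$f_roh) else 0,
              if (length(x$f_roh)) max(x$f_roh) else 0))
  invisible(x)
}
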