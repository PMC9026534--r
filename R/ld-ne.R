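# LD decay and effective population size. r^2 is the squared Pearson
# correlation of allele dosages (composite, unphased LD); Ne comes from the
# Sved relation E[r^2] = 1 / (1 + 4 Ne c), inverted per distance bin.

#' Squared dosage correlation between two markers
#'
#' Composite (genotype-based, unphased) LD: the squared Pearson correlation
#' of the two dosage vectors over pairwise-complete individuals.
#'
#' @param x_calls,y_calls integer dosage vectors (`0/1/2/NA`), same length.
#' @return `r^2` in `[0, 1]`, or `NA` if fewer than two complete pairs remain
#'   or either marker is monomorphic in the complete subset.
#' @export
genotype_r2 <- function(x_calls, y_calls) {
  ok <- !is.na(x_calls) & !is.na(y_calls)
  x <- x_calls[ok]
  y <- y_calls[ok]
  if (length(x) < 2L || stats::var(x) == 0 || stats::var(y) == 0)
    return(NA_real_)
  stats::cor(x, y)^2
}

#' Mean r-squared by physical-distance bin
#'
#' For every same-chromosome marker pair whose distance falls in a half-open
#' bin `[min, max)`, accumulates the squared dosage correlation. Pairs where
#' either marker is monomorphic in the pairwise-complete subset are excluded
#' and counted. Bins holding more than `max_pairs_per_bin` eligible pairs are
#' downsampled uniformly under the given seed.
#'
#' @param ds a post-QC [genotype_dataset()] (markers sorted by position).
#' @param bin_edges_bp strictly increasing vector of bin edges in bp;
#'   `length(bin_edges_bp) - 1` bins.
#' @param max_pairs_per_bin cap on pairs used per bin (`Inf` disables).
#' @param seed integer seed for the downsampling.
#' @param map_rate_morgan_per_bp physical-to-genetic map rate; the default
#'   1e-8 is the conventional 1 cM/Mb.
#' @return data.frame with one row per bin: `min_dist_bp`, `max_dist_bp`,
#'   `n_pairs`, `n_excluded`, `mean_r2`, `mean_c_morgans`.
#' @export
binned_r2 <- function(ds, bin_edges_bp = default_ld_bins(),
                      max_pairs_per_bin = 50000L, seed = 1L,
                      map_rate_morgan_per_bp = 1e-8) {
  validate_genotype_dataset(ds)
  if (any(diff(bin_edges_bp) <= 0))
    stop("bin edges must be strictly increasing")
  n_bins <- length(bin_edges_bp) - 1L
  lo <- bin_edges_bp[-length(bin_edges_bp)]
  hi <- bin_edges_bp[-1L]
  max_d <- max(bin_edges_bp)
  min_d <- min(bin_edges_bp)

  acc_i <- list(); acc_j <- list(); acc_d <- list(); na <- 0L
  for (chr in unique(ds$markers$chromosome)) {
    idx <- which(ds$markers$chromosome == chr)
    pos <- ds$markers$position_bp[idx]
    for (a in seq_along(idx)) {
      # downstream markers with distance in [min_d, max_d)
      b <- which(pos - pos[a] >= min_d & pos - pos[a] < max_d)
      b <- b[b > a]
      if (!length(b)) next
      na <- na + 1L
      acc_i[[na]] <- rep(idx[a], length(b))
      acc_j[[na]] <- idx[b]
      acc_d[[na]] <- pos[b] - pos[a]
    }
  }
  pair_i <- unlist(acc_i); pair_j <- unlist(acc_j); pair_d <- unlist(acc_d)
  if (is.null(pair_i)) pair_i <- integer(0)

  bin_of <- findInterval(pair_d, bin_edges_bp, left.open = FALSE)
  out <- data.frame(min_dist_bp = lo, max_dist_bp = hi, n_pairs = 0L,
                    n_excluded = 0L, mean_r2 = NA_real_,
                    mean_c_morgans = NA_real_)
  if (!length(pair_i)) return(out)

  withr_seed <- function(expr) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    expr
  }
  for (k in seq_len(n_bins)) {
    sel <- which(bin_of == k)
    if (!length(sel)) next
    if (length(sel) > max_pairs_per_bin)
      sel <- withr_seed(sort(sample(sel, max_pairs_per_bin)))
    r2 <- vapply(sel, function(s)
      genotype_r2(ds$calls[, pair_i[s]], ds$calls[, pair_j[s]]), numeric(1))
    usable <- !is.na(r2)
    out$n_pairs[k] <- sum(usable)
    out$n_excluded[k] <- sum(!usable)
    if (any(usable)) {
      out$mean_r2[k] <- mean(r2[usable])
      out$mean_c_morgans[k] <- mean(pair_d[sel][usable]) *
        map_rate_morgan_per_bp
    }
  }
  out
}

#' Default LD distance bins
#'
#' Ten log-spaced half-open bins from 50 kb to 5 Mb.
#' @return Numeric vector of 11 bin edges in bp.
#' @export
default_ld_bins <- function() {
  round(exp(seq(log(5e4), log(5e6), length.out = 11L)))
}

#' Effective population size from the Sved relation
#'
#' Inverts `E[r^2] = 1 / (1 + 4 Ne c)` to `Ne = (1 / (4 c)) (1 / r^2 - 1)`.
#' When a sample size is supplied, the expected sampling inflation `1/(2n)`
#' for unphased genotype data on `n` individuals is subtracted from `r^2`
#' first, floored at `eps`.
#'
#' @param r2 mean squared correlation, in `(0, 1]`.
#' @param c_morgans recombination distance in Morgans, `> 0`.
#' @param n_individuals sample size for the correction, or `NULL` to skip it.
#' @param eps floor for the corrected `r^2`.
#' @return List with `ne`, `r2_adjusted` and `floored` (`TRUE` when the
#'   correction hit the floor, i.e. the estimate is effectively unbounded).
#' @export
sved_ne <- function(r2, c_morgans, n_individuals = NULL, eps = 1e-6) {
  if (is.na(r2) || r2 <= 0 || r2 > 1) stop("r2 must lie in (0, 1]")
  if (c_morgans <= 0) stop("c_morgans must be > 0")
  r2_adj <- if (is.null(n_individuals)) r2 else r2 - 1 / (2 * n_individuals)
  floored <- r2_adj <= eps
  r2_adj <- max(r2_adj, eps)
  list(ne = (1 / (4 * c_morgans)) * (1 / r2_adj - 1),
       r2_adjusted = r2_adj, floored = floored)
}

#' Ne trajectory over LD distance bins
#'
#' One Sved-equation estimate per usable distance bin, with the generation
#' horizon `t = 1 / (2 c)`: long distances inform recent generations, short
#' distances ancient ones. The headline estimate is the bin with the smallest
#' `t` (most recent generations, largest distances), configurable via
#' `headline`.
#'
#' @param ds a post-QC [genotype_dataset()].
#' @param bin_edges_bp,max_pairs_per_bin,seed,map_rate_morgan_per_bp passed
#'   to [binned_r2()].
#' @param correct_sample_size apply the `1/(2n)` correction.
#' @param min_pairs bins with fewer usable pairs are dropped.
#' @param headline `"most_recent"` (default) or `"most_ancient"`.
#' @return List with `trajectory` (data.frame: bin columns plus
#'   `r2_adjusted`, `t_generations`, `ne`, `floored`) and `ne_headline`.
#' @export
ne_trajectory <- function(ds, bin_edges_bp = default_ld_bins(),
                          max_pairs_per_bin = 50000L, seed = 1L,
                          map_rate_morgan_per_bp = 1e-8,
                          correct_sample_size = TRUE,
                          min_pairs = 10L,
                          headline = c("most_recent", "most_ancient")) {
  headline <- match.arg(headline)
  bins <- binned_r2(ds, bin_edges_bp, max_pairs_per_bin, seed,
                    map_rate_morgan_per_bp)
  usable <- !is.na(bins$mean_r2) & bins$n_pairs >= min_pairs &
    bins$mean_r2 > 0
  bins <- bins[usable, , drop = FALSE]
  if (!nrow(bins)) stop("no usable LD bins (too few pairs everywhere)")
  n_ind <- if (correct_sample_size) nrow(ds$samples) else NULL
  est <- lapply(seq_len(nrow(bins)), function(k)
    sved_ne(bins$mean_r2[k], bins$mean_c_morgans[k], n_ind))
  bins$r2_adjusted <- vapply(est, `[[`, numeric(1), "r2_adjusted")
  bins$t_generations <- 1 / (2 * bins$mean_c_morgans)
  bins$ne <- vapply(est, `[[`, numeric(1), "ne")
  bins$floored <- vapply(est, `[[`, logical(1), "floored")
  pick <- if (headline == "most_recent") which.min(bins$t_generations)
          else which.max(bins$t_generations)
  list(trajectory = bins, ne_headline = bins$ne[pick])
}
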