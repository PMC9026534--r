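#' Simulate founder haplotypes
#'
#' Draws a pool of `2 * n_founders` haplotypes per chromosome at biallelic
#' markers with positions uniform on `[1, chrom_length_bp]` and allele
#' frequencies from `maf_distribution`. Optionally the founders are split
#' into `n_groups` diverged source groups: group frequencies are drawn
#' around the ancestral frequency with a Balding-Nichols Beta model at the
#' given `divergence` (an Fst-like parameter), planting between-group
#' differentiation that downstream family-structure methods should recover.
#'
#' @param n_founders number of founder individuals in the pool.
#' @param n_markers_per_chrom markers per chromosome.
#' @param n_chroms number of chromosomes.
#' @param maf_distribution function of one argument `m` returning `m` allele
#'   frequencies in `(0, 0.5]`; the default draws Uniform(0.05, 0.5).
#' @param seed integer seed; the pool is bit-reproducible given the seed.
#' @param chrom_length_bp chromosome length in bp (all chromosomes equal).
#' @param n_groups number of diverged founder groups (1 = panmictic pool).
#' @param divergence Balding-Nichols divergence in `[0, 1)`; ignored when
#'   `n_groups = 1`.
#' @return A list of class `founder_pool`: `positions` (per chromosome),
#'   `haplotypes` (per chromosome, `2 n_founders` x markers 0/1 matrix),
#'   `founder_group`, `chrom_length_bp`, `config`.
#' @export
simulate_founder_haplotypes <- function(n_founders, n_markers_per_chrom,
                                        n_chroms,
                                        maf_distribution = function(m)
                                          stats::runif(m, 0.05, 0.5),
                                        seed = 1L,
                                        chrom_length_bp = 1e8,
                                        n_groups = 1L,
                                        divergence = 0) {
  stopifnot(n_founders >= 1, n_markers_per_chrom >= 1, n_chroms >= 1)
  if (n_groups > 1 && n_founders %% n_groups != 0)
    stop("n_founders must be divisible by n_groups")
  set.seed(seed)
  founder_group <- rep(seq_len(n_groups), each = n_founders / n_groups)
  positions <- vector("list", n_chroms)
  haplotypes <- vector("list", n_chroms)
  for (chr in seq_len(n_chroms)) {
    pos <- sort(sample.int(chrom_length_bp, n_markers_per_chrom))
    p <- maf_distribution(n_markers_per_chrom)
    if (any(is.na(p)) || any(p <= 0) || any(p > 0.5))
      stop("maf_distribution must return frequencies in (0, 0.5]")
    h <- matrix(0L, 2L * n_founders, n_markers_per_chrom)
    for (g in seq_len(n_groups)) {
      pg <- if (n_groups > 1 && divergence > 0) {
        shp <- (1 - divergence) / divergence
        pmin(pmax(stats::rbeta(length(p), p * shp, (1 - p) * shp),
                  1e-4), 1 - 1e-4)
      } else p
      rows <- which(rep(founder_group, each = 2L) == g)
      h[rows, ] <- matrix(
        stats::rbinom(length(rows) * length(p), 1L,
                      rep(pg, each = length(rows))),
        length(rows))
    }
    positions[[chr]] <- pos
    haplotypes[[chr]] <- h
  }
  structure(list(positions = positions, haplotypes = haplotypes,
                 founder_group = founder_group,
                 chrom_length_bp = chrom_length_bp,
                 config = list(n_founders = n_founders,
                               n_markers_per_chrom = n_markers_per_chrom,
                               n_chroms = n_chroms, seed = seed,
                               n_groups = n_groups,
                               divergence = divergence)),
            class = "founder_pool")
}
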