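# Independent oracles and small fixture builders shared across tests.

# --- exact HWE oracle: direct factorial formula, no recurrence ------------
# P(n_het | n, n_rare) = n! / (n_hom_rare! n_het! n_hom_common!) *
#                        2^n_het * n_rare! n_common! / (2n)!
hwe_oracle_p <- function(n_hom1, n_het, n_hom2) {
  n <- n_hom1 + n_het + n_hom2
  n_rare <- 2 * min(n_hom1, n_hom2) + n_het
  n_common <- 2 * n - n_rare
  hets <- seq(n_rare %% 2, n_rare, by = 2)
  logp <- vapply(hets, function(h) {
    hr <- (n_rare - h) / 2
    hc <- (n_common - h) / 2
    lfactorial(n) - lfactorial(hr) - lfactorial(h) - lfactorial(hc) +
      h * log(2) + lfactorial(n_rare) + lfactorial(n_common) -
      lfactorial(2 * n)
  }, numeric(1))
  p <- exp(logp)
  obs <- p[hets == n_het]
  min(1, sum(p[p <= obs * (1 + 1e-12)]))
}

# --- brute-force ROH oracle: the window rules applied literally -----------
# One sample, one chromosome. pos sorted; calls in {0,1,2,NA}. Enumerates
# every window with explicit loops, derives SNP eligibility, forms runs,
# splits at gaps and at the het/missing caps (greedy left-to-right), trims
# ends to homozygous calls, then filters on every segment criterion.
roh_oracle <- function(pos, calls, params) {
  m <- length(pos)
  het <- !is.na(calls) & calls == 1L
  miss <- is.na(calls)
  w <- min(params$window_snps, m)
  n_win <- m - w + 1L
  good <- logical(n_win)
  for (s in seq_len(n_win))
    good[s] <- sum(het[s:(s + w - 1)]) <= params$max_het_in_roh &&
      sum(miss[s:(s + w - 1)]) <= params$max_missing_in_roh
  eligible <- logical(m)
  for (i in seq_len(m)) {
    covering <- which(seq_len(n_win) <= i & seq_len(n_win) + w - 1 >= i)
    eligible[i] <- mean(good[covering]) >= params$window_threshold
  }

  runs <- list()
  i <- 1L
  while (i <= m) {
    if (!eligible[i]) { i <- i + 1L; next }
    j <- i
    while (j < m && eligible[j + 1L]) j <- j + 1L
    runs[[length(runs) + 1L]] <- c(i, j)
    i <- j + 1L
  }

  pieces <- list()
  for (r in runs) {
    a <- r[1]
    for (i in seq(r[1], r[2])) {
      if (i < r[2] && pos[i + 1] - pos[i] > params$max_gap_bp) {
        pieces[[length(pieces) + 1L]] <- c(a, i)
        a <- i + 1L
      }
    }
    pieces[[length(pieces) + 1L]] <- c(a, r[2])
  }

  cands <- list()
  for (p in pieces) {
    s <- p[1]; nh <- 0L; nm <- 0L
    for (i in seq(p[1], p[2])) {
      if (nh + het[i] > params$max_het_in_roh ||
          nm + miss[i] > params$max_missing_in_roh) {
        if (i > s) cands[[length(cands) + 1L]] <- c(s, i - 1L)
        s <- i; nh <- as.integer(het[i]); nm <- as.integer(miss[i])
      } else {
        nh <- nh + het[i]; nm <- nm + miss[i]
      }
    }
    cands[[length(cands) + 1L]] <- c(s, p[2])
  }

  out <- list()
  for (cd in cands) {
    a <- cd[1]; b <- cd[2]
    while (a <= b && (het[a] || miss[a])) a <- a + 1L
    while (b >= a && (het[b] || miss[b])) b <- b - 1L
    if (a > b) next
    n_snps <- b - a + 1L
    len <- pos[b] - pos[a]
    if (n_snps < params$min_snps_in_roh) next
    if (len < params$min_length_bp) next
    if (len / n_snps > params$min_density_bp_per_snp) next
    if (sum(het[a:b]) > params$max_het_in_roh) next
    if (sum(miss[a:b]) > params$max_missing_in_roh) next
    out[[length(out) + 1L]] <- data.frame(start_bp = pos[a], end_bp = pos[b],
                                          n_snps = n_snps, length_bp = len)
  }
  if (!length(out))
    return(data.frame(start_bp = numeric(0), end_bp = numeric(0),
                      n_snps = integer(0), length_bp = numeric(0)))
  do.call(rbind, out)
}

# --- small dataset builders ----------------------------------------------
make_ds <- function(calls, positions = NULL, chromosome = NULL,
                    sex = NULL) {
  n <- nrow(calls)
  m <- ncol(calls)
  if (is.null(positions)) positions <- seq_len(m) * 1000L
  if (is.null(chromosome)) chromosome <- rep(1L, m)
  if (is.null(sex)) sex <- rep("unknown", n)
  genotype_dataset(
    data.frame(sample_id = sprintf("s%d", seq_len(n)), sex = sex,
               stringsAsFactors = FALSE),
    data.frame(marker_id = sprintf("m%d", seq_len(m)), chromosome = chromosome,
               position_bp = positions, allele_a1 = rep("A", m),
               allele_a2 = rep("B", m), stringsAsFactors = FALSE),
    calls)
}

random_ds <- function(n, m, miss_rate = 0.05, seed = 1, n_chroms = 2) {
  set.seed(seed)
  p <- runif(m, 0.1, 0.9)
  calls <- matrix(rbinom(n * m, 2, rep(p, each = n)), n, m)
  calls[runif(n * m) < miss_rate] <- NA_integer_
  chrom <- sort(rep_len(seq_len(n_chroms), m))
  pos <- as.integer(unlist(lapply(split(seq_len(m), chrom), function(ix)
    sort(sample.int(5e7, length(ix))))))
  make_ds(calls, positions = pos, chromosome = chrom)
}

expect_dataset_equal <- function(a, b) {
  expect_equal(a$samples$sample_id, b$samples$sample_id)
  expect_equal(a$samples$sex, b$samples$sex)
  expect_equal(a$markers$marker_id, b$markers$marker_id)
  expect_equal(a$markers$chromosome, b$markers$chromosome)
  expect_equal(a$markers$position_bp, b$markers$position_bp)
  expect_equal(a$markers$allele_a1, b$markers$allele_a1)
  expect_equal(a$markers$allele_a2, b$markers$allele_a2)
  expect_equal(unname(a$calls), unname(b$calls))
}

adjusted_rand <- function(x, y) {
  tab <- table(x, y)
  comb2 <- function(v) sum(choose(v, 2))
  a <- comb2(tab)
  b <- comb2(rowSums(tab))
  c_ <- comb2(colSums(tab))
  n2 <- choose(sum(tab), 2)
  exp_ <- b * c_ / n2
  (a - exp_) / ((b + c_) / 2 - exp_)
}
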