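roh_case_ds <- function(calls, pos) {
  make_ds(matrix(calls, nrow = 1), positions = pos)
}

test_that("a clean homozygous stretch becomes exactly one ROH", {
  pos <- round(seq(1e6, 3e6, length.out = 100))
  ds <- roh_case_ds(rep(0L, 100), pos)
  seg <- detect_roh(ds)
  expect_equal(nrow(seg), 1L)
  expect_equal(seg$n_snps, 100L)
  expect_equal(seg$length_bp, 2e6)
  expect_equal(seg$start_bp, 1e6)
  expect_equal(seg$end_bp, 3e6)
})

test_that("runs below the SNP, length, or density criteria are dropped", {
  # 29 homozygous SNPs over 2 Mb: below the 30-SNP minimum
  expect_equal(nrow(detect_roh(roh_case_ds(
    rep(2L, 29), round(seq(1e6, 3e6, length.out = 29))))), 0L)
  # 40 SNPs spanning 0.8 Mb: below the 1 Mb minimum length
  expect_equal(nrow(detect_roh(roh_case_ds(
    rep(0L, 40), round(seq(1e6, 1.8e6, length.out = 40))))), 0L)
  # 35 SNPs spread over 40 Mb: density worse than one SNP per Mb
  expect_equal(nrow(detect_roh(roh_case_ds(
    rep(0L, 35), round(seq(1e6, 41e6, length.out = 35))))), 0L)
})

test_that("no emitted segment contains two heterozygous calls", {
  calls <- rep(0L, 120)
  calls[c(40, 80)] <- 1L
  pos <- round(seq(1e6, 7e6, length.out = 120))
  seg <- detect_roh(roh_case_ds(calls, pos))
  expect_gt(nrow(seg), 0L)
  expect_true(all(seg$n_het <= 1L))
  # verify against the literal rule oracle
  orc <- roh_oracle(pos, calls, roh_params())
  expect_equal(seg[, c("start_bp", "end_bp", "n_snps", "length_bp")],
               orc, ignore_attr = TRUE)
})

test_that("a gap larger than 1 Mb splits a run", {
  pos <- c(round(seq(1e6, 3e6, length.out = 60)),
           round(seq(5e6, 7e6, length.out = 60)))
  seg <- detect_roh(roh_case_ds(rep(0L, 120), pos))
  expect_equal(nrow(seg), 2L)
  expect_equal(seg$start_bp, c(1e6, 5e6))
})

test_that("detection equals the brute-force oracle on random chromosomes", {
  params <- roh_params(min_snps_in_roh = 10, window_snps = 15,
                       min_length_bp = 3e5, max_gap_bp = 4e5,
                       min_density_bp_per_snp = 2e5)
  for (seed in 1:40) {
    set.seed(seed)
    m <- sample(30:200, 1)
    pos <- sort(sample.int(6e6, m))
    hom_block <- runif(1) < 0.7
    calls <- if (hom_block) {
      # mostly homozygous with sparse het/missing contamination
      x <- sample(c(0L, 2L), m, replace = TRUE, prob = c(0.5, 0.5))
      x[runif(m) < 0.05] <- 1L
      x[runif(m) < 0.04] <- NA_integer_
      x
    } else sample(c(0L, 1L, 2L, NA), m, replace = TRUE)
    seg <- detect_roh(roh_case_ds(calls, pos), params)
    orc <- roh_oracle(pos, calls, params)
    expect_equal(nrow(seg), nrow(orc), info = paste("seed", seed))
    if (nrow(orc))
      expect_equal(seg[, c("start_bp", "end_bp", "n_snps", "length_bp")],
                   orc, ignore_attr = TRUE, info = paste("seed", seed))
  }
})

test_that("segments never overlap within a sample-chromosome", {
  ped <- make_conservation_pedigree(n_families = 2, boars_per_family = 2,
                                    sows_per_family = 4,
                                    n_generations = 3,
                                    inbred_loop_fraction = 0.6, seed = 41)
  pool <- simulate_founder_haplotypes(sum(is.na(ped$sire_id)), 400, 4,
                                      seed = 42, chrom_length_bp = 4e7)
  gd <- gene_drop(ped, pool, seed = 43)
  seg <- detect_roh(gd$dataset)
  expect_gt(nrow(seg), 0L)
  for (key in split(seg, paste(seg$sample_id, seg$chromosome))) {
    if (nrow(key) < 2) next
    key <- key[order(key$start_bp), ]
    expect_true(all(key$start_bp[-1] > key$end_bp[-nrow(key)]))
  }
})

test_that("relaxing length or SNP thresholds only adds segments", {
  ped <- make_conservation_pedigree(n_families = 1, boars_per_family = 2,
                                    sows_per_family = 3,
                                    n_generations = 3,
                                    inbred_loop_fraction = 0.8, seed = 44)
  pool <- simulate_founder_haplotypes(sum(is.na(ped$sire_id)), 500, 3,
                                      seed = 45, chrom_length_bp = 4e7)
  ds <- gene_drop(ped, pool, seed = 46)$dataset
  strict <- detect_roh(ds, roh_params())
  relaxed <- detect_roh(ds, roh_params(min_length_bp = 5e5,
                                       min_snps_in_roh = 15))
  key <- function(s) paste(s$sample_id, s$chromosome, s$start_bp, s$end_bp)
  expect_true(all(key(strict) %in% key(relaxed)))
})

test_that("planted autozygous segments are recovered nearly base-for-base", {
  # dense map: 500 SNPs on a 15 Mb chromosome (~33 SNPs per Mb)
  ped <- data.frame(
    individual_id = c("f1", "f2", "c1", "c2", "x1", "x2", "x3", "x4"),
    sire_id = c(NA, NA, "f1", "f1", "c1", "c1", "c1", "c1"),
    dam_id = c(NA, NA, "f2", "f2", "c2", "c2", "c2", "c2"),
    sex = c("male", "female", "male", "female", rep("female", 4)))
  pool <- simulate_founder_haplotypes(2, 500, 6, seed = 51,
                                      chrom_length_bp = 1.5e7)
  gd <- gene_drop(ped, pool, seed = 52, missing_rate = 0)
  seg <- detect_roh(gd$dataset)
  truth <- gd$truth$true_ibd_segments
  truth <- truth[truth$end_bp - truth$start_bp >= 2e6, ]
  overlap <- 0
  total <- 0
  for (r in seq_len(nrow(truth))) {
    t <- truth[r, ]
    total <- total + (t$end_bp - t$start_bp)
    s <- seg[seg$sample_id == t$individual_id &
               seg$chromosome == t$chromosome, ]
    if (!nrow(s)) next
    overlap <- overlap + sum(pmax(0, pmin(s$end_bp, t$end_bp) -
                                    pmax(s$start_bp, t$start_bp)))
  }
  expect_gt(nrow(truth), 5)
  expect_gte(overlap / total, 0.95)
})

test_that("classification tabulates counts, means and shares per class", {
  seg <- data.frame(length_bp = c(2e6, 3e6, 6e6, 12e6))
  tab <- classify_roh(seg)
  expect_equal(tab$count, c(2L, 1L, 1L))
  expect_equal(tab$number_pct, c(50, 25, 25))
  expect_equal(tab$mean_mb, c(2.5, 6, 12))
  expect_equal(tab$total_mb, c(5, 6, 12))
  expect_equal(tab$length_pct, 100 * c(5, 6, 12) / 23)
  # half-open edges: 5 Mb belongs to the middle class, 10 Mb to the long one
  tab2 <- classify_roh(data.frame(length_bp = c(5e6, 1e7)))
  expect_equal(tab2$count, c(0L, 1L, 1L))
  empty <- classify_roh(data.frame(length_bp = numeric(0)))
  expect_equal(empty$count, c(0L, 0L, 0L))
  expect_equal(empty$total_mb, c(0, 0, 0))
})

test_that("summaries count per chromosome and per individual", {
  ds <- random_ds(3, 40, seed = 61, n_chroms = 2)
  seg <- data.frame(sample_id = c("s1", "s1", "s2"),
                    chromosome = c(1L, 2L, 1L),
                    start_bp = 1, end_bp = 2e6,
                    length_bp = c(2e6, 3e6, 4e6))
  s <- roh_summaries(seg, ds)
  expect_equal(s$per_chromosome$n_roh, c(2L, 1L))
  expect_equal(s$per_individual$n_roh, c(2L, 1L, 0L))
  expect_equal(s$per_individual$total_length_bp, c(5e6, 4e6, 0))
  expect_equal(s$mean_per_individual, 1)
  none <- roh_summaries(seg[0, ], ds)
  expect_equal(sum(none$per_chromosome$n_roh), 0L)
})

test_that("F_ROH divides summed segment length by the genome length", {
  seg <- data.frame(sample_id = "s1", length_bp = c(1e8, 1.450713e8))
  res <- f_roh(seg, autosome_length_kb = 2450713)
  expect_equal(unname(res$f_roh), 0.1)
  expect_equal(f_roh(seg[0, ], sample_ids = "s1")$f_roh[["s1"]], 0)
  expect_equal(f_roh(seg[0, ], sample_ids = character(0))$population_mean, 0)
  too_long <- data.frame(sample_id = "s1", length_bp = 3e12)
  expect_error(f_roh(too_long), "exceeds")
})
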