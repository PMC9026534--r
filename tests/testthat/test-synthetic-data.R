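test_that("generators are bit-reproducible for a fixed seed", {
  p1 <- simulate_founder_haplotypes(6, 50, 2, seed = 9)
  p2 <- simulate_founder_haplotypes(6, 50, 2, seed = 9)
  expect_identical(p1, p2)
  ped1 <- make_conservation_pedigree(seed = 9)
  ped2 <- make_conservation_pedigree(seed = 9)
  expect_identical(ped1, ped2)
  small <- make_conservation_pedigree(n_families = 2, boars_per_family = 2,
                                      sows_per_family = 3, seed = 10)
  g1 <- gene_drop(small, simulate_founder_haplotypes(10, 40, 2, seed = 11),
                  seed = 12)
  g2 <- gene_drop(small, simulate_founder_haplotypes(10, 40, 2, seed = 11),
                  seed = 12)
  expect_identical(g1$dataset$calls, g2$dataset$calls)
  expect_identical(g1$truth$true_ibd_segments, g2$truth$true_ibd_segments)
  w1 <- simulate_wright_fisher(10, n_generations = 5, n_markers = 60,
                               seed = 13, n_chroms = 2)
  w2 <- simulate_wright_fisher(10, n_generations = 5, n_markers = 60,
                               seed = 13, n_chroms = 2)
  expect_identical(w1$calls, w2$calls)
})

test_that("founder allele frequencies follow the requested distribution", {
  pool <- simulate_founder_haplotypes(
    200, 300, 1, maf_distribution = function(m) rep(0.5, m), seed = 15)
  emp <- colMeans(pool$haplotypes[[1]])
  # binomial SE for 400 haplotypes at p = 0.5 is 0.025
  expect_lt(abs(mean(emp) - 0.5), 3 * 0.025 / sqrt(300))
  expect_lt(max(abs(emp - 0.5)), 5 * 0.025)
  expect_error(simulate_founder_haplotypes(
    4, 10, 1, maf_distribution = function(m) rep(0.7, m)),
    "\\(0, 0.5\\]")
})

test_that("founders carry no IBD and zero-recombination transmits intact", {
  ped <- data.frame(individual_id = c("f1", "f2", "k1"),
                    sire_id = c(NA, NA, "f1"), dam_id = c(NA, NA, "f2"),
                    sex = c("male", "female", "female"))
  pool <- simulate_founder_haplotypes(2, 100, 2, seed = 16)
  gd <- gene_drop(ped, pool, cm_per_mb = 0, seed = 17, missing_rate = 0)
  segs <- gd$truth$true_ibd_segments
  expect_equal(nrow(segs), 0L)  # outbred child, non-inbred founders
  # with no recombination each transmitted haplotype is one founder segment,
  # so the child is everywhere hom or het according to two intact haplotypes
  h1 <- pool$haplotypes[[1]]
  child <- gd$dataset$calls[3, gd$dataset$markers$chromosome == 1]
  possible <- vapply(1:2, function(a) vapply(3:4, function(b)
    all(child == h1[a, ] + h1[b, ]), logical(1)), logical(2))
  expect_true(any(possible))
})

test_that("selfing and sib matings reproduce path-counting inbreeding", {
  ped_self <- data.frame(individual_id = c("f", "k"), sire_id = c(NA, "f"),
                         dam_id = c(NA, "f"), sex = "unknown")
  expect_equal(unname(pedigree_inbreeding(ped_self)["k"]), 0.5)
  ped_full <- data.frame(
    individual_id = c("a", "b", "c", "d", "k"),
    sire_id = c(NA, NA, "a", "a", "c"), dam_id = c(NA, NA, "b", "b", "d"),
    sex = "unknown")
  expect_equal(unname(pedigree_inbreeding(ped_full)["k"]), 0.25)
  ped_half <- data.frame(
    individual_id = c("a", "b", "b2", "c", "d", "k"),
    sire_id = c(NA, NA, NA, "a", "a", "c"),
    dam_id = c(NA, NA, NA, "b", "b2", "d"), sex = "unknown")
  expect_equal(unname(pedigree_inbreeding(ped_half)["k"]), 0.125)

  # Monte-Carlo: realized IBD fraction matches the expectation for selfing
  pool <- simulate_founder_haplotypes(1, 50, 2, seed = 18)
  fr <- vapply(1:120, function(s)
    true_ibd_fraction(gene_drop(ped_self, pool, seed = s,
                                missing_rate = 0)$truth)[["k"]],
    numeric(1))
  se <- sd(fr) / sqrt(length(fr))
  expect_lt(abs(mean(fr) - 0.5), 3 * se + 1e-9)

  # and for half sibs
  pool6 <- simulate_founder_haplotypes(3, 50, 2, seed = 19)
  fr2 <- vapply(1:120, function(s)
    true_ibd_fraction(gene_drop(ped_half, pool6, seed = 1000 + s,
                                missing_rate = 0)$truth)[["k"]],
    numeric(1))
  se2 <- sd(fr2) / sqrt(length(fr2))
  expect_lt(abs(mean(fr2) - 0.125), 3 * se2 + 1e-9)
})

test_that("gene-drop errors on unknown parents and misordered pedigrees", {
  bad <- data.frame(individual_id = c("k", "f"), sire_id = c("f", NA),
                    dam_id = c("f", NA), sex = "unknown")
  pool <- simulate_founder_haplotypes(2, 20, 1, seed = 20)
  expect_error(gene_drop(bad, pool), "not defined earlier")
  lone <- data.frame(individual_id = "k", sire_id = "f", dam_id = NA,
                     sex = "unknown")
  expect_error(validate_pedigree(lone), "exactly one known parent")
})

test_that("conservation pedigrees are sized and structured as configured", {
  ped <- make_conservation_pedigree(n_families = 8, boars_per_family = 4,
                                    sows_per_family = 22,
                                    n_generations = 2, seed = 22)
  last <- ped[ped$generation == 2, ]
  expect_equal(nrow(last), 8 * 26)
  expect_equal(sum(last$sex == "male"), 32)
  expect_equal(length(unique(ped$family_label)), 8)
  # parents always belong to the offspring's family
  idx <- setNames(ped$family_label, ped$individual_id)
  kids <- ped[!is.na(ped$sire_id), ]
  expect_true(all(idx[kids$sire_id] == kids$family_label))
  # no inbreeding loops and a single generation means F = 0 everywhere
  flat <- make_conservation_pedigree(n_families = 2, boars_per_family = 2,
                                     sows_per_family = 3,
                                     n_generations = 1,
                                     inbred_loop_fraction = 0, seed = 23)
  expect_equal(max(pedigree_inbreeding(flat)), 0)
  expect_error(make_conservation_pedigree(sows_per_family = 0), "at least")
})

test_that("smaller populations accumulate more long-range LD", {
  mean_far_r2 <- function(ne, seed) {
    ds <- simulate_wright_fisher(ne, n_generations = 40,
                                 n_sample = min(15, ne),
                                 n_markers = 200, chrom_length_bp = 5e7,
                                 seed = seed, n_chroms = 2)
    qc <- apply_qc(ds, qc_thresholds(min_maf = 0.1,
                                     autosomes_only = FALSE))$dataset
    b <- binned_r2(qc, bin_edges_bp = c(1e6, 5e6))
    b$mean_r2
  }
  paired <- vapply(1:3, function(s)
    mean_far_r2(15, 200 + s) - mean_far_r2(200, 200 + s), numeric(1))
  expect_true(all(paired > 0))
})

test_that("simulated datasets pass validation and survive a PLINK round trip", {
  ped <- make_conservation_pedigree(n_families = 2, boars_per_family = 2,
                                    sows_per_family = 4, seed = 24)
  pool <- simulate_founder_haplotypes(sum(is.na(ped$sire_id)), 100, 3,
                                      seed = 25)
  gd <- gene_drop(ped, pool, seed = 26)
  expect_silent(validate_genotype_dataset(gd$dataset))
  prefix <- file.path(withr::local_tempdir(), "sim")
  write_plink_binary(gd$dataset, prefix)
  back <- read_plink_binary(paste0(prefix, ".bed"), paste0(prefix, ".bim"),
                            paste0(prefix, ".fam"))
  expect_equal(unname(back$calls), unname(gd$dataset$calls))
  # IBD truth segments never overlap within an individual-chromosome
  segs <- gd$truth$true_ibd_segments
  for (grp in split(segs, paste(segs$individual_id, segs$chromosome))) {
    if (nrow(grp) < 2) next
    grp <- grp[order(grp$start_bp), ]
    expect_true(all(grp$start_bp[-1] > grp$end_bp[-nrow(grp)]))
  }
})
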