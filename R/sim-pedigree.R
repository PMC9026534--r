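#' Build a closed-nucleus conservation pedigree
#'
#' Emulates a boar-anchored closed herd: `n_families` independent founder
#' families, each with `boars_per_family` founder boars and
#' `sows_per_family` founder sows, bred within-family for `n_generations`
#' discrete generations. Each offspring takes a random sire from the
#' previous generation's boars of its family; with probability
#' `inbred_loop_fraction` the dam is drawn from sows sharing a parent with
#' the sire (a full- or half-sib mating, planting nonzero inbreeding), and
#' otherwise uniformly from the family's sows. Family labels propagate to
#' all descendants. The defaults size the final generation like a
#' conservation herd of about 30 boars and 180 sows in 8 families.
#'
#' @param n_families number of independent families.
#' @param boars_per_family,sows_per_family males/females bred per family per
#'   generation (also the founder counts).
#' @param n_generations generations bred after the founders.
#' @param inbred_loop_fraction probability a mating is between close
#'   relatives, in `[0, 1]`.
#' @param seed integer seed.
#' @return A pedigree data.frame (`individual_id`, `sire_id`, `dam_id`,
#'   `sex`, `family_label`, `generation`) accepted by [gene_drop()].
#' @export
make_conservation_pedigree <- function(n_families = 8L,
                                       boars_per_family = 4L,
                                       sows_per_family = 22L,
                                       n_generations = 2L,
                                       inbred_loop_fraction = 0.3,
                                       seed = 1L) {
  if (n_families < 1L || boars_per_family < 1L || sows_per_family < 1L)
    stop("families need at least one boar and one sow each")
  if (inbred_loop_fraction < 0 || inbred_loop_fraction > 1)
    stop("inbred_loop_fraction must lie in [0, 1]")
  set.seed(seed)
  rows <- list()
  add <- function(id, sire, dam, sex, fam, gen)
    rows[[length(rows) + 1L]] <<- data.frame(
      individual_id = id, sire_id = sire, dam_id = dam, sex = sex,
      family_label = fam, generation = gen, stringsAsFactors = FALSE)

  for (f in seq_len(n_families)) {
    fam <- paste0("fam", f)
    boars <- paste0(fam, "_g0_b", seq_len(boars_per_family))
    sows <- paste0(fam, "_g0_s", seq_len(sows_per_family))
    for (b in boars) add(b, NA, NA, "male", fam, 0L)
    for (s in sows) add(s, NA, NA, "female", fam, 0L)
    parent_of <- list()  # id -> c(sire, dam) for relative-mating lookups
    for (g in seq_len(n_generations)) {
      nb <- paste0(fam, "_g", g, "_b", seq_len(boars_per_family))
      ns <- paste0(fam, "_g", g, "_s", seq_len(sows_per_family))
      kids <- c(nb, ns)
      sexes <- rep(c("male", "female"), c(boars_per_family, sows_per_family))
      for (k in seq_along(kids)) {
        sire <- sample(boars, 1L)
        dam <- sample(sows, 1L)
        if (stats::runif(1) < inbred_loop_fraction && g > 1L) {
          sp <- parent_of[[sire]]
          sibs <- sows[vapply(sows, function(s)
            any(parent_of[[s]] %in% sp), logical(1))]
          if (length(sibs)) dam <- sample(sibs, 1L)
        }
        add(kids[k], sire, dam, sexes[k], fam, g)
        parent_of[[kids[k]]] <- c(sire, dam)
      }
      boars <- nb
      sows <- ns
      parent_of <- parent_of[c(nb, ns)]
    }
  }
  do.call(rbind, rows)
}

#' Simulate a constant-size Wright-Fisher population
#'
#' Evolves a monoecious random-mating population of constant size `ne_true`
#' for `n_generations` discrete generations with Haldane recombination, from
#' unrelated founders in linkage equilibrium, then genotypes a sample of the
#' final generation. The LD that accumulates reflects drift at `ne_true`, so
#' LD-based effective-size estimators can be checked against the truth.
#'
#' @param ne_true population size per generation (>= 2).
#' @param n_generations generations evolved (enough for LD at the distances
#'   of interest to approach drift-recombination equilibrium).
#' @param n_sample individuals genotyped from the final generation
#'   (`<= ne_true`).
#' @param n_markers total markers, split evenly over `n_chroms`.
#' @param chrom_length_bp chromosome length in bp.
#' @param seed integer seed.
#' @param n_chroms number of chromosomes.
#' @param cm_per_mb genetic map rate.
#' @return A [genotype_dataset()] of the sampled individuals (no missing
#'   calls).
#' @export
simulate_wright_fisher <- function(ne_true, n_generations = 100L,
                                   n_sample = ne_true, n_markers = 600L,
                                   chrom_length_bp = 1e8, seed = 1L,
                                   n_chroms = 3L, cm_per_mb = 1) {
  if (ne_true < 2L) stop("ne_true must be >= 2")
  if (n_sample > ne_true) stop("n_sample cannot exceed ne_true")
  m_per <- n_markers %/% n_chroms
  pool <- simulate_founder_haplotypes(ne_true, m_per, n_chroms,
                                      seed = seed,
                                      chrom_length_bp = chrom_length_bp)
  set.seed(seed + 1L)
  morgan_per_bp <- cm_per_mb * 1e-8
  L <- chrom_length_bp
  # pop[[chrom]][[ind]] = list(pat, mat)
  pop <- lapply(seq_len(n_chroms), function(chr)
    lapply(seq_len(ne_true), .founder_haps))
  for (g in seq_len(n_generations)) {
    sires <- sample.int(ne_true, ne_true, replace = TRUE)
    dams <- sample.int(ne_true, ne_true, replace = TRUE)
    clash <- which(dams == sires)
    for (i in clash) dams[i] <- if (sires[i] == ne_true) 1L else sires[i] + 1L
    for (chr in seq_len(n_chroms)) {
      prev <- pop[[chr]]
      pop[[chr]] <- lapply(seq_len(ne_true), function(i) {
        sp <- prev[[sires[i]]]
        dp <- prev[[dams[i]]]
        list(pat = .meiosis(sp$pat, sp$mat, L, morgan_per_bp),
             mat = .meiosis(dp$pat, dp$mat, L, morgan_per_bp))
      })
    }
  }
  take <- sort(sample.int(ne_true, n_sample))
  calls <- matrix(NA_integer_, n_sample, n_chroms * m_per)
  for (chr in seq_len(n_chroms)) {
    cols <- (chr - 1L) * m_per + seq_len(m_per)
    H <- pool$haplotypes[[chr]]
    pos <- pool$positions[[chr]]
    for (r in seq_along(take)) {
      h <- pop[[chr]][[take[r]]]
      calls[r, cols] <- .mosaic_alleles(h$pat, pos, H) +
        .mosaic_alleles(h$mat, pos, H)
    }
  }
  markers <- data.frame(
    marker_id = paste0("snp", rep(seq_len(n_chroms), each = m_per), "_",
                       unlist(pool$positions)),
    chromosome = rep(seq_len(n_chroms), each = m_per),
    position_bp = unlist(pool$positions),
    allele_a1 = "A", allele_a2 = "B", stringsAsFactors = FALSE)
  samples <- data.frame(sample_id = paste0("wf", take), sex = "unknown",
                        group_label = NA_character_,
                        stringsAsFactors = FALSE)
  genotype_dataset(samples, markers, calls, sort_markers = FALSE)
}
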