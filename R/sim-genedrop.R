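# Gene dropping: founder haplotypes are transmitted down a pedigree with
# Haldane recombination (Poisson crossover counts, uniform breakpoints, no
# interference). Each transmitted haplotype is a mosaic of founder-haplotype
# segments, kept as (breakpoint, founder-haplotype-id) run-length lists, so
# identity by descent is tracked exactly rather than inferred.

# one meiosis: recombine the two parental haplotype mosaics
.meiosis <- function(h1, h2, chrom_length_bp, morgan_per_bp) {
  n_x <- stats::rpois(1L, chrom_length_bp * morgan_per_bp)
  cur <- sample.int(2L, 1L)
  if (n_x == 0L) return(if (cur == 1L) h1 else h2)
  x <- sort(stats::runif(n_x, min = 1, max = chrom_length_bp))
  bounds <- c(1, x, chrom_length_bp + 1)
  bp <- vector("list", length(bounds) - 1L)
  id <- vector("list", length(bounds) - 1L)
  for (t in seq_len(length(bounds) - 1L)) {
    h <- if (cur == 1L) h1 else h2
    s <- bounds[t]
    e <- bounds[t + 1L]
    k0 <- findInterval(s, h$bp)
    k1 <- findInterval(e, h$bp, left.open = TRUE)
    bp[[t]] <- c(s, h$bp[k0:k1][-1L])
    id[[t]] <- h$id[k0:k1]
    cur <- 3L - cur
  }
  bp <- unlist(bp)
  id <- unlist(id)
  keep <- c(TRUE, id[-1L] != id[-length(id)])
  list(bp = bp[keep], id = id[keep])
}

# founder haplotype mosaics: one intact segment each
.founder_haps <- function(founder_slot) {
  list(pat = list(bp = 1, id = 2L * founder_slot - 1L),
       mat = list(bp = 1, id = 2L * founder_slot))
}

# alleles of a mosaic at marker positions, from the founder haplotype matrix
.mosaic_alleles <- function(h, positions, founder_hap_matrix) {
  seg <- findInterval(positions, h$bp)
  founder_hap_matrix[cbind(h$id[seg], seq_along(positions))]
}

# IBD intervals of one individual on one chromosome: stretches where the two
# mosaics carry the same founder haplotype
.ibd_intervals <- function(pat, mat, chrom_length_bp) {
  bp <- sort(unique(c(pat$bp, mat$bp)))
  idp <- pat$id[findInterval(bp, pat$bp)]
  idm <- mat$id[findInterval(bp, mat$bp)]
  ibd <- idp == idm
  ends <- c(bp[-1L] - 1, chrom_length_bp)
  r <- rle(ibd)
  stop_i <- cumsum(r$lengths)
  start_i <- stop_i - r$lengths + 1L
  keep <- which(r$values)
  if (!length(keep))
    return(data.frame(start_bp = numeric(0), end_bp = numeric(0)))
  data.frame(start_bp = bp[start_i[keep]], end_bp = ends[stop_i[keep]])
}

#' Validate and normalize a pedigree table
#'
#' @param pedigree data.frame with columns `individual_id`, `sire_id`,
#'   `dam_id` (`NA` for founders), `sex`, and optionally `family_label`.
#' @return The pedigree with parents verified to precede offspring.
#' @export
validate_pedigree <- function(pedigree) {
  pedigree <- as.data.frame(pedigree, stringsAsFactors = FALSE)
  need <- c("individual_id", "sire_id", "dam_id", "sex")
  if (!all(need %in% names(pedigree)))
    stop("pedigree needs columns: ", paste(need, collapse = ", "))
  if (!"family_label" %in% names(pedigree))
    pedigree$family_label <- NA_character_
  if (anyDuplicated(pedigree$individual_id))
    stop("duplicate individual_id in pedigree")
  seen <- character(0)
  for (i in seq_len(nrow(pedigree))) {
    if (xor(is.na(pedigree$sire_id[i]), is.na(pedigree$dam_id[i])))
      stop("individual ", pedigree$individual_id[i],
           " has exactly one known parent; founders must have neither")
    for (par in c(pedigree$sire_id[i], pedigree$dam_id[i])) {
      if (!is.na(par) && !par %in% seen)
        stop("parent ", par, " of ", pedigree$individual_id[i],
             " not defined earlier in the pedigree")
    }
    seen <- c(seen, pedigree$individual_id[i])
  }
  pedigree
}

#' Pedigree additive-relationship matrix (tabular method)
#'
#' Wright's numerator relationship matrix `A`: `A_ij` is twice the kinship
#' coefficient between `i` and `j`; `A_ii = 1 + F_i`.
#'
#' @param pedigree a pedigree accepted by [validate_pedigree()].
#' @return Symmetric matrix with individual ids as dimnames.
#' @export
pedigree_amatrix <- function(pedigree) {
  ped <- validate_pedigree(pedigree)
  n <- nrow(ped)
  idx <- stats::setNames(seq_len(n), ped$individual_id)
  a <- matrix(0, n, n, dimnames = list(ped$individual_id,
                                       ped$individual_id))
  for (i in seq_len(n)) {
    s <- ped$sire_id[i]
    d <- ped$dam_id[i]
    if (is.na(s)) {
      a[i, i] <- 1
      next
    }
    si <- idx[[s]]
    di <- idx[[d]]
    a[i, i] <- 1 + 0.5 * a[si, di]
    if (i > 1L) {
      j <- seq_len(i - 1L)
      a[i, j] <- 0.5 * (a[si, j] + a[di, j])
      a[j, i] <- a[i, j]
    }
  }
  a
}

#' Pedigree inbreeding coefficients by the tabular method
#'
#' Computes the additive-relationship matrix over the ordered pedigree and
#' returns `F_i = 0.5 * A(sire_i, dam_i)` (0 for founders), the path-counting
#' expectation of the autozygous genome fraction.
#'
#' @param pedigree a pedigree accepted by [validate_pedigree()].
#' @return Named numeric vector of inbreeding coefficients.
#' @export
pedigree_inbreeding <- function(pedigree) {
  diag(pedigree_amatrix(pedigree)) - 1
}

#' Drop founder haplotypes down a pedigree
#'
#' Simulates inheritance with Haldane recombination (`Poisson` crossover
#' count with mean `chrom_length_Mb * cm_per_mb / 100`, uniform breakpoints)
#' and emits both the genotypes and the exact simulation truth: every
#' individual's autozygous (within-pedigree IBD) segments, family labels,
#' and the pedigree itself. Founders take consecutive slots of the pool in
#' pedigree order, so group-structured pools align with family-blocked
#' pedigrees.
#'
#' @param pedigree a pedigree accepted by [validate_pedigree()].
#' @param pool a founder pool from [simulate_founder_haplotypes()] with at
#'   least as many founders as the pedigree has.
#' @param cm_per_mb genetic map rate (default 1 cM/Mb).
#' @param seed integer seed.
#' @param missing_rate fraction of calls set to missing (default 0.02).
#' @param error_rate fraction of calls replaced by a random genotype drawn
#'   from the marker's founder frequency (default 0).
#' @param keep logical/character/integer selection of pedigree individuals to
#'   genotype (default: all).
#' @return List with `dataset` (a [genotype_dataset()]) and `truth` (class
#'   `sim_truth`: `pedigree`, `true_ibd_segments`, `true_family`,
#'   `pedigree_f`, `sim_config`).
#' @export
gene_drop <- function(pedigree, pool, cm_per_mb = 1, seed = 1L,
                      missing_rate = 0.02, error_rate = 0, keep = NULL) {
  ped <- validate_pedigree(pedigree)
  stopifnot(inherits(pool, "founder_pool"))
  founders <- which(is.na(ped$sire_id))
  if (length(founders) > pool$config$n_founders)
    stop("pool has ", pool$config$n_founders, " founders but pedigree needs ",
         length(founders))
  set.seed(seed)
  n_chroms <- pool$config$n_chroms
  L <- pool$chrom_length_bp
  morgan_per_bp <- cm_per_mb * 1e-8
  idx <- stats::setNames(seq_len(nrow(ped)), ped$individual_id)
  founder_slot <- match(seq_len(nrow(ped)), founders)

  # haps[[chrom]][[individual]] = list(pat, mat)
  haps <- lapply(seq_len(n_chroms), function(chr) vector("list", nrow(ped)))
  for (i in seq_len(nrow(ped))) {
    if (is.na(ped$sire_id[i])) {
      fh <- .founder_haps(founder_slot[i])
      for (chr in seq_len(n_chroms)) haps[[chr]][[i]] <- fh
    } else {
      si <- idx[[ped$sire_id[i]]]
      di <- idx[[ped$dam_id[i]]]
      for (chr in seq_len(n_chroms)) {
        sp <- haps[[chr]][[si]]
        dp <- haps[[chr]][[di]]
        haps[[chr]][[i]] <- list(
          pat = .meiosis(sp$pat, sp$mat, L, morgan_per_bp),
          mat = .meiosis(dp$pat, dp$mat, L, morgan_per_bp))
      }
    }
  }

  keep_i <- if (is.null(keep)) seq_len(nrow(ped)) else {
    if (is.character(keep)) match(keep, ped$individual_id) else which(
      if (is.logical(keep)) keep else seq_len(nrow(ped)) %in% keep)
  }

  m_per <- pool$config$n_markers_per_chrom
  calls <- matrix(NA_integer_, length(keep_i), n_chroms * m_per)
  for (chr in seq_len(n_chroms)) {
    cols <- (chr - 1L) * m_per + seq_len(m_per)
    H <- pool$haplotypes[[chr]]
    pos <- pool$positions[[chr]]
    for (r in seq_along(keep_i)) {
      h <- haps[[chr]][[keep_i[r]]]
      calls[r, cols] <- .mosaic_alleles(h$pat, pos, H) +
        .mosaic_alleles(h$mat, pos, H)
    }
  }
  if (error_rate > 0) {
    hit <- which(stats::runif(length(calls)) < error_rate)
    calls[hit] <- sample(0:2, length(hit), replace = TRUE)
  }
  if (missing_rate > 0)
    calls[stats::runif(length(calls)) < missing_rate] <- NA_integer_

  markers <- data.frame(
    marker_id = paste0("snp", rep(seq_len(n_chroms), each = m_per), "_",
                       unlist(pool$positions)),
    chromosome = rep(seq_len(n_chroms), each = m_per),
    position_bp = unlist(pool$positions),
    allele_a1 = "A", allele_a2 = "B", stringsAsFactors = FALSE)
  samples <- data.frame(sample_id = ped$individual_id[keep_i],
                        sex = ped$sex[keep_i],
                        group_label = ped$family_label[keep_i],
                        stringsAsFactors = FALSE)
  ds <- genotype_dataset(samples, markers, calls, sort_markers = FALSE)

  ibd <- list()
  k <- 0L
  for (i in keep_i) for (chr in seq_len(n_chroms)) {
    h <- haps[[chr]][[i]]
    seg <- .ibd_intervals(h$pat, h$mat, L)
    if (nrow(seg)) {
      k <- k + 1L
      ibd[[k]] <- data.frame(individual_id = ped$individual_id[i],
                             chromosome = chr, seg,
                             stringsAsFactors = FALSE)
    }
  }
  ibd <- if (k) do.call(rbind, ibd) else
    data.frame(individual_id = character(0), chromosome = integer(0),
               start_bp = numeric(0), end_bp = numeric(0))

  truth <- structure(list(
    pedigree = ped,
    true_ibd_segments = ibd,
    true_family = stats::setNames(ped$family_label, ped$individual_id),
    pedigree_f = pedigree_inbreeding(ped),
    sim_config = list(cm_per_mb = cm_per_mb, seed = seed,
                      missing_rate = missing_rate, error_rate = error_rate,
                      chrom_length_bp = L, n_chroms = n_chroms,
                      n_markers_per_chrom = m_per)),
    class = "sim_truth")
  list(dataset = ds, truth = truth)
}

#' Genome fraction autozygous by simulation truth
#'
#' @param truth a `sim_truth` from [gene_drop()].
#' @return Named numeric vector: per pedigree individual, the summed length
#'   of true IBD segments over the simulated genome length.
#' @export
true_ibd_fraction <- function(truth) {
  total <- truth$sim_config$chrom_length_bp * truth$sim_config$n_chroms
  ids <- truth$pedigree$individual_id
  segs <- truth$true_ibd_segments
  out <- vapply(ids, function(i) {
    s <- segs[segs$individual_id == i, , drop = FALSE]
    sum(s$end_bp - s$start_bp + 1) / total
  }, numeric(1))
  stats::setNames(out, ids)
}
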