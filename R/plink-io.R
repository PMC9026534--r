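# PLINK 1 genotype file dialects. Binary .bed uses the SNP-major 2-bit
# encoding: 00 = hom a1/a1, 01 = missing, 10 = het, 11 = hom a2/a2, packed
# low-bits-first, one byte block per 4 samples, each marker padded to a whole
# byte. Only mode byte 0x01 (SNP-major) is accepted.

# read.table that tolerates zero-row files
.read_table_or_empty <- function(path, col_classes, col_names) {
  tab <- tryCatch(
    utils::read.table(path, header = FALSE, colClasses = col_classes),
    error = function(e) {
      if (length(readLines(path, n = 1L)) == 0L) {
        cols <- lapply(col_classes, function(cl) vector(cl, 0L))
        as.data.frame(cols, col.names = col_names)
      } else stop("cannot parse ", path, ": ", conditionMessage(e))
    })
  names(tab) <- col_names
  tab
}

.sex_from_plink <- function(code) {
  out <- rep("unknown", length(code))
  out[code == "1"] <- "male"
  out[code == "2"] <- "female"
  out
}

.sex_to_plink <- function(sex) {
  out <- rep("0", length(sex))
  out[sex == "male"] <- "1"
  out[sex == "female"] <- "2"
  out
}

#' Read PLINK text genotypes (.ped/.map)
#'
#' Parses the whitespace-separated PLINK 1 text dialect. Allele pairs `0 0`
#' become missing calls. For each marker the first allele (`a1`) is the minor
#' allele among observed calls (ties broken alphabetically); monomorphic
#' markers get `a1 = "0"`. Markers are re-sorted by `(chromosome, position)`
#' with calls permuted consistently.
#'
#' @param ped_path path to the .ped file (6 leading columns, then two allele
#'   columns per marker).
#' @param map_path path to the .map file (chromosome, marker id, genetic
#'   position, physical position).
#' @return A [genotype_dataset()].
#' @export
read_plink_text <- function(ped_path, map_path) {
  if (!file.exists(ped_path)) stop("no such file: ", ped_path)
  if (!file.exists(map_path)) stop("no such file: ", map_path)
  map <- .read_table_or_empty(map_path,
                              c("integer", "character", "numeric", "integer"),
                              c("chromosome", "marker_id", "cm",
                                "position_bp"))
  m <- nrow(map)

  lines <- readLines(ped_path)
  lines <- lines[nzchar(trimws(lines))]
  n <- length(lines)
  ids <- character(n)
  fid <- character(n)
  sex <- character(n)
  a_first <- matrix("0", n, m)  # first allele of each pair, per sample
  a_second <- matrix("0", n, m)
  for (i in seq_len(n)) {
    f <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
    if (length(f) != 6L + 2L * m)
      stop("malformed .ped line ", i, ": expected ", 6L + 2L * m,
           " fields, found ", length(f))
    fid[i] <- f[1]
    ids[i] <- f[2]
    sex[i] <- f[5]
    g <- f[-(1:6)]
    a_first[i, ] <- g[seq(1L, 2L * m, by = 2L)]
    a_second[i, ] <- g[seq(2L, 2L * m, by = 2L)]
  }
  if (anyDuplicated(ids))
    stop("duplicate sample_id in .ped: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))

  calls <- matrix(NA_integer_, n, m)
  allele_a1 <- character(m)
  allele_a2 <- character(m)
  for (j in seq_len(m)) {
    x <- c(a_first[, j], a_second[, j])
    obs <- x[x != "0"]
    if ((length(obs) %% 2L) != 0L || any(xor(a_first[, j] == "0",
                                             a_second[, j] == "0")))
      stop("half-missing allele pair at marker ", map$marker_id[j])
    tab <- sort(table(obs))  # ascending count; ties keep alphabetical order
    alleles <- names(tab)
    if (length(alleles) > 2L)
      stop("marker ", map$marker_id[j], " has >2 alleles: ",
           paste(alleles, collapse = ","))
    if (length(alleles) == 0L) {
      allele_a1[j] <- "0"; allele_a2[j] <- "0"
      next
    }
    if (length(alleles) == 1L) {
      allele_a1[j] <- "0"; allele_a2[j] <- alleles[1]
    } else {
      allele_a1[j] <- alleles[1]; allele_a2[j] <- alleles[2]
    }
    present <- a_first[, j] != "0"
    dose <- (a_first[, j] == allele_a2[j]) + (a_second[, j] == allele_a2[j])
    calls[present, j] <- as.integer(dose[present])
  }

  samples <- data.frame(sample_id = ids, sex = .sex_from_plink(sex),
                        group_label = ifelse(fid == ids, NA_character_, fid),
                        stringsAsFactors = FALSE)
  markers <- data.frame(marker_id = map$marker_id,
                        chromosome = map$chromosome,
                        position_bp = map$position_bp,
                        allele_a1 = allele_a1, allele_a2 = allele_a2,
                        stringsAsFactors = FALSE)
  genotype_dataset(samples, markers, calls)
}

# byte value (0..255) -> 4 dosage codes, low bit-pair first
.bed_decode_table <- function() {
  two_bit <- c(0L, NA_integer_, 1L, 2L)  # 00, 01, 10, 11
  b <- 0:255
  cbind(two_bit[b %% 4L + 1L],
        two_bit[(b %/% 4L) %% 4L + 1L],
        two_bit[(b %/% 16L) %% 4L + 1L],
        two_bit[(b %/% 64L) %% 4L + 1L])
}

#' Read PLINK binary genotypes (.bed/.bim/.fam)
#'
#' Decodes the PLINK 1 SNP-major binary format. The magic bytes `6c 1b` and
#' mode byte `01` are required; individual-major files (mode `00`) are
#' rejected rather than transposed.
#'
#' @param bed_path,bim_path,fam_path paths to the binary triple.
#' @return A [genotype_dataset()].
#' @export
read_plink_binary <- function(bed_path, bim_path, fam_path) {
  for (p in c(bed_path, bim_path, fam_path))
    if (!file.exists(p)) stop("no such file: ", p)
  bim <- .read_table_or_empty(bim_path,
                              c("integer", "character", "numeric", "integer",
                                "character", "character"),
                              c("chromosome", "marker_id", "cm",
                                "position_bp", "allele_a1", "allele_a2"))
  fam <- .read_table_or_empty(fam_path, rep("character", 6L),
                              c("fid", "sample_id", "pat", "mat", "sex",
                                "pheno"))
  n <- nrow(fam)
  m <- nrow(bim)
  if (anyDuplicated(fam$sample_id))
    stop("duplicate sample_id in .fam: ",
         paste(unique(fam$sample_id[duplicated(fam$sample_id)]),
               collapse = ", "))

  raw <- readBin(bed_path, "raw", n = file.size(bed_path))
  if (length(raw) < 3L || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b))
    stop("not a PLINK .bed file (bad magic bytes): ", bed_path)
  if (raw[3] == as.raw(0x00))
    stop("individual-major .bed (mode 0x00) is not supported")
  if (raw[3] != as.raw(0x01))
    stop("unknown .bed mode byte: ", as.integer(raw[3]))
  bpm <- if (n > 0L) (n + 3L) %/% 4L else 0L  # bytes per marker
  body <- as.integer(raw[-(1:3)])
  if (length(body) != bpm * m)
    stop("truncated or oversized .bed: expected ", bpm * m,
         " data bytes for ", n, " samples x ", m, " markers, found ",
         length(body))

  calls <- matrix(NA_integer_, n, m)
  if (n > 0L && m > 0L) {
    tab <- .bed_decode_table()
    codes <- matrix(t(tab[body + 1L, , drop = FALSE]), nrow = 4L * bpm)
    calls <- codes[seq_len(n), , drop = FALSE]
  }
  samples <- data.frame(sample_id = fam$sample_id,
                        sex = .sex_from_plink(fam$sex),
                        group_label = ifelse(fam$fid == fam$sample_id,
                                             NA_character_, fam$fid),
                        stringsAsFactors = FALSE)
  markers <- bim[, c("marker_id", "chromosome", "position_bp",
                     "allele_a1", "allele_a2")]
  genotype_dataset(samples, markers, calls)
}

#' Write PLINK binary genotypes (.bed/.bim/.fam)
#'
#' Emits a SNP-major PLINK 1 binary triple that [read_plink_binary()] reads
#' back to an identical dataset, missing calls included.
#'
#' @param ds a [genotype_dataset()].
#' @param prefix output path prefix; `prefix.bed`, `prefix.bim` and
#'   `prefix.fam` are written.
#' @return `prefix`, invisibly.
#' @export
write_plink_binary <- function(ds, prefix) {
  validate_genotype_dataset(ds)
  n <- nrow(ds$samples)
  m <- nrow(ds$markers)

  fam <- data.frame(
    fid = ifelse(is.na(ds$samples$group_label), ds$samples$sample_id,
                 ds$samples$group_label),
    iid = ds$samples$sample_id, pat = rep("0", n), mat = rep("0", n),
    sex = .sex_to_plink(ds$samples$sex), pheno = rep("-9", n)
  )
  utils::write.table(fam, paste0(prefix, ".fam"), quote = FALSE,
                     row.names = FALSE, col.names = FALSE, sep = " ")
  bim <- data.frame(
    chr = ds$markers$chromosome, id = ds$markers$marker_id,
    cm = rep(0, m), bp = ds$markers$position_bp,
    a1 = ds$markers$allele_a1, a2 = ds$markers$allele_a2
  )
  utils::write.table(bim, paste0(prefix, ".bim"), quote = FALSE,
                     row.names = FALSE, col.names = FALSE, sep = "\t")

  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  if (m > 0L && n > 0L) {
    bpm <- (n + 3L) %/% 4L
    code2bits <- c(0L, 2L, 3L)  # dosage 0,1,2 -> bit pairs 00,10,11
    v <- matrix(1L, 4L * bpm, m)  # pad + missing = 01
    x <- ds$calls
    v[seq_len(n), ] <- ifelse(is.na(x), 1L, code2bits[x + 1L])
    # rows beyond n are padding; PLINK pads with zero bits
    if (4L * bpm > n) v[(n + 1L):(4L * bpm), ] <- 0L
    shift <- c(1L, 4L, 16L, 64L)
    grp <- matrix(v * shift, nrow = 4L)
    bytes <- as.raw(colSums(grp))
    writeBin(bytes, con)
  }
  invisible(prefix)
}
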