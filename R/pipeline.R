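#' Pipeline configuration
#'
#' Bundles every stage's settings with defaults matching the standard herd
#' assessment: QC at call rate 0.90 / MAF 0.01 / HWE 1e-6 / autosomes only,
#' the seven-criterion ROH definition, 10 log-spaced LD bins from 50 kb to
#' 5 Mb at 1 cM/Mb with sample-size correction, and the 0.1 relationship
#' threshold for family assignment.
#'
#' @param qc a [qc_thresholds()].
#' @param roh a [roh_params()].
#' @param ld_bin_edges_bp LD bin edges in bp.
#' @param map_rate_morgan_per_bp physical-to-genetic map rate.
#' @param max_pairs_per_bin LD pair cap per bin.
#' @param k_lineages number of boar lineages to cut the tree into.
#' @param relationship_threshold below this maximum boar relationship an
#'   individual forms a separate family.
#' @param autosome_length_kb genome length for `F_ROH`; `NULL` uses the
#'   marker map extent (sum over chromosomes of the largest position).
#' @param seed integer seed for the LD pair downsampling.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(qc = qc_thresholds(), roh = roh_params(),
                            ld_bin_edges_bp = default_ld_bins(),
                            map_rate_morgan_per_bp = 1e-8,
                            max_pairs_per_bin = 50000L,
                            k_lineages = 8L,
                            relationship_threshold = 0.1,
                            autosome_length_kb = NULL,
                            seed = 1L) {
  structure(list(qc = qc, roh = roh, ld_bin_edges_bp = ld_bin_edges_bp,
                 map_rate_morgan_per_bp = map_rate_morgan_per_bp,
                 max_pairs_per_bin = max_pairs_per_bin,
                 k_lineages = k_lineages,
                 relationship_threshold = relationship_threshold,
                 autosome_length_kb = autosome_length_kb,
                 seed = seed),
            class = "pipeline_config")
}

.write_tsv <- function(df, path)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)

#' Run the full conservation-assessment pipeline
#'
#' Executes QC, diversity, LD-based Ne, relationship matrices, boar-lineage
#' family structure, and ROH-based inbreeding on one dataset, writing every
#' result table to `out_dir` as tab-separated text (plus newick trees and a
#' key=value run manifest).
#'
#' @param ds a [genotype_dataset()], e.g. from [read_plink_binary()].
#' @param config a [pipeline_config()].
#' @param out_dir output directory, created if needed; `NULL` skips writing.
#' @return List with `qc_report`, `dataset` (post-QC), `diversity`, `ne`,
#'   `g_matrix`, `ibs_matrix`, `boar_tree`, `all_tree`, `lineages`,
#'   `families`, `roh_segments`, `roh_classes`, `roh_summaries`,
#'   `inbreeding`.
#' @export
run_pipeline <- function(ds, config = pipeline_config(), out_dir = NULL) {
  t0 <- Sys.time()
  log_stage <- function(stage, detail)
    message(sprintf("[%s] %s (%.1fs elapsed)", stage, detail,
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))

  qc <- apply_qc(ds, config$qc)
  post <- qc$dataset
  log_stage("qc", sprintf("%d -> %d markers, %d samples",
                          qc$report$n_input_snps, qc$report$n_retained,
                          qc$report$n_samples))
  if (nrow(post$markers) == 0L) stop("qc: no markers survived")

  div <- diversity_summary(post)
  log_stage("diversity", sprintf("P_N=%.3f He=%.4f Ho=%.4f",
                                 div$P_N, div$He, div$Ho))

  ne <- ne_trajectory(post, bin_edges_bp = config$ld_bin_edges_bp,
                      max_pairs_per_bin = config$max_pairs_per_bin,
                      seed = config$seed,
                      map_rate_morgan_per_bp = config$map_rate_morgan_per_bp)
  log_stage("ld_ne", sprintf("headline Ne=%.1f over %d bins",
                             ne$ne_headline, nrow(ne$trajectory)))

  g <- vanraden_g(post)
  ibs <- ibs_distance(post)
  log_stage("relatedness", sprintf("G and IBS over %d individuals",
                                   length(g$sample_ids)))

  is_boar <- post$samples$sex == "male"
  if (sum(is_boar) < 2L) {
    warning("fewer than 2 males: lineage tree built on all individuals")
    is_boar <- rep(TRUE, nrow(post$samples))
  }
  boar_ids <- post$samples$sample_id[is_boar]
  boar_tree <- neighbor_joining(
    structure(list(sample_ids = boar_ids,
                   values = ibs$values[boar_ids, boar_ids],
                   kind = "IBS_distance"), class = "relationship_matrix"))
  all_tree <- neighbor_joining(ibs)
  k <- min(config$k_lineages, length(boar_ids))
  lineages <- cut_lineages(boar_tree, k)
  families <- assign_families(g, lineages,
                              threshold = config$relationship_threshold)
  families$group_label <- post$samples$group_label[
    match(families$sample_id, post$samples$sample_id)]
  log_stage("family_structure",
            sprintf("%d lineages -> %d families", k,
                    length(unique(families$family))))

  segments <- detect_roh(post, config$roh)
  classes <- classify_roh(segments)
  summaries <- roh_summaries(segments, post)
  l_auto <- config$autosome_length_kb
  if (is.null(l_auto))
    l_auto <- sum(vapply(split(post$markers$position_bp,
                               post$markers$chromosome), max,
                         numeric(1))) / 1000
  inbreeding <- f_roh(segments, autosome_length_kb = l_auto,
                      sample_ids = post$samples$sample_id)
  log_stage("roh_inbreeding",
            sprintf("%d segments, mean F_ROH=%.4f", nrow(segments),
                    inbreeding$population_mean))

  res <- list(qc_report = qc$report, dataset = post, diversity = div,
              ne = ne, g_matrix = g, ibs_matrix = ibs,
              boar_tree = boar_tree, all_tree = all_tree,
              lineages = lineages, families = families,
              roh_segments = segments, roh_classes = classes,
              roh_summaries = summaries, inbreeding = inbreeding)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    .write_tsv(as.data.frame(unclass(qc$report)),
               file.path(out_dir, "qc_report.tsv"))
    .write_tsv(data.frame(statistic = c("P_N", "n_polymorphic", "n_total",
                                        "He", "Ho"),
                          value = c(div$P_N, div$n_polymorphic, div$n_total,
                                    div$He, div$Ho)),
               file.path(out_dir, "diversity.tsv"))
    .write_tsv(ne$trajectory, file.path(out_dir, "ne_trajectory.tsv"))
    write_relationship_matrix(g, file.path(out_dir, "g_matrix.tsv"))
    write_relationship_matrix(ibs, file.path(out_dir, "ibs_matrix.tsv"))
    ape::write.tree(boar_tree, file.path(out_dir, "boar_tree.nwk"))
    ape::write.tree(all_tree, file.path(out_dir, "all_tree.nwk"))
    .write_tsv(families, file.path(out_dir, "families.tsv"))
    .write_tsv(segments, file.path(out_dir, "roh_segments.tsv"))
    .write_tsv(classes, file.path(out_dir, "roh_classes.tsv"))
    .write_tsv(summaries$per_chromosome,
               file.path(out_dir, "roh_per_chromosome.tsv"))
    .write_tsv(summaries$per_individual,
               file.path(out_dir, "roh_per_individual.tsv"))
    .write_tsv(data.frame(sample_id = names(inbreeding$f_roh),
                          f_roh = unname(inbreeding$f_roh)),
               file.path(out_dir, "f_roh.tsv"))
    manifest <- c(
      sprintf("package_version=%s",
              as.character(utils::packageVersion("herdgen"))),
      sprintf("seed=%d", config$seed),
      sprintf("k_lineages=%d", config$k_lineages),
      sprintf("relationship_threshold=%g", config$relationship_threshold),
      sprintf("autosome_length_kb=%g", l_auto),
      sprintf("qc_min_call_rate=%g", config$qc$min_call_rate),
      sprintf("qc_min_maf=%g", config$qc$min_maf),
      sprintf("qc_min_hwe_p=%g", config$qc$min_hwe_p),
      sprintf("qc_autosomes_only=%s", config$qc$autosomes_only),
      sprintf("map_rate_morgan_per_bp=%g", config$map_rate_morgan_per_bp),
      vapply(names(unclass(config$roh)), function(nm)
        sprintf("roh_%s=%g", nm, config$roh[[nm]]), character(1)))
    writeLines(manifest, file.path(out_dir, "manifest.txt"))
  }
  res
}
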