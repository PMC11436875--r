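#' Run the full synthetic-cohort pipeline
#'
#' Orchestrates the stages in dependency order on one simulated cohort:
#' simulation, candidate nomination (filters + inheritance + peak
#' restriction + cohort exclusion), multi-hit peak and gene aggregation,
#' permutation enrichment of the dominant candidates, peak-to-gene linking
#' with DORC scoring, and cluster-labeling metrics. All stage outputs plus
#' a provenance manifest (seed, package version, input hashes) are written
#' to `out_dir`; a rerun with the same config is byte-identical.
#'
#' @param config A [sim_config()] (drives every stage's inputs).
#' @param out_dir Output directory.
#' @param thresholds Threshold list, see [ccdd_defaults()].
#' @param dmap Disease map.
#' @param perm_n_iter Permutation iterations for the enrichment stage
#'   (kept configurable so demo runs stay fast).
#' @return Invisible list with every stage result (`cohort`, `candidates`,
#'   `multihit_peaks`, `multihit_genes`, `permutation`, `links`,
#'   `gene_ranks`, `dorc`, `vmeasure`, `manifest`).
#' @export
run_pipeline <- function(config, out_dir,
                         thresholds = ccdd_defaults(),
                         dmap = config$disease_map,
                         perm_n_iter = 500) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- simulate_cohort(config)
  paths <- write_cohort(cohort, file.path(out_dir, "inputs"))

  candidates <- nominate_candidates(cohort, cohort$atlas, dmap, thresholds)
  utils::write.table(candidates, file.path(out_dir, "candidates.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  mh_peaks <- find_multihit_peaks(candidates, thresholds)
  utils::write.table(mh_peaks, file.path(out_dir, "multihit_peaks.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # enrichment of dominant-broad candidates in the pooled disease peaks
  dom_idx <- candidates$var_idx[
    broad_mode_of(candidates$mode) == "dominant" &
      !is.na(candidates$var_idx)
  ]
  dom_vars <- cohort$vs$variants[unique(dom_idx), , drop = FALSE]
  all_peaks <- merge_intervals(do.call(rbind, lapply(
    cohort$atlas$sets, function(df) df[, c("chrom", "start", "end")]
  )))
  perm <- permutation_test(dom_vars, all_peaks, config$chrom_lengths,
                           mask = sim_mask(config), n_iter = perm_n_iter,
                           seed = config$seed + 404L)

  # peak-to-gene stage on the paired cell matrices
  mats <- simulate_cell_matrices(config)
  aggs <- make_cell_aggregates(mats$peak_counts, mats$gene_expr,
                               k_groups = min(100, config$n_cells),
                               seed = config$seed + 505L)
  links <- compute_links(aggs, mats$peaks, mats$genes,
                         window = thresholds$link_window,
                         r_min = thresholds$link_r_min,
                         fdr_max = thresholds$link_fdr_max)
  utils::write.table(links, file.path(out_dir, "peak_gene_links.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  gene_ranks <- rank_genes_by_links(links,
                                    window = thresholds$gene_rank_window)
  dorc <- dorc_scores(mats$peak_counts, mats$cell_meta$fragments, links,
                      mats$peaks, mats$genes,
                      window = thresholds$link_window)
  mh_genes <- find_multihit_genes(candidates, links)

  vm <- v_measure(contingency(mats$cell_meta$class,
                              mats$cell_meta$cluster))

  summary <- list(
    n_candidates = nrow(candidates),
    n_multihit_peaks = nrow(mh_peaks),
    n_multihit_genes = nrow(mh_genes),
    permutation = list(observed = perm$observed_count, z = perm$z,
                       p_empirical = perm$p_empirical),
    n_links = nrow(links),
    vmeasure = vm[c("h", "c", "v_beta")]
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  manifest <- list(
    package = "ncmendel",
    version = as.character(utils::packageVersion("ncmendel")),
    seed = config$seed,
    input_md5 = as.list(tools::md5sum(unname(paths[c("ped", "vcf", "sv",
                                                     "te")])))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(cohort = cohort, candidates = candidates,
                 multihit_peaks = mh_peaks, multihit_genes = mh_genes,
                 permutation = perm, links = links,
                 gene_ranks = gene_ranks, dorc = dorc, vmeasure = vm,
                 manifest = manifest))
}
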