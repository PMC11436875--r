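#' Default analysis thresholds
#'
#' Every numeric threshold used by the pipeline, defined exactly once.
#' Stage functions take their defaults from this list so that a single
#' config edit changes behaviour everywhere.
#'
#' @details
#' * `af_max_monoallelic` / `af_max_biallelic`: gnomAD and TOPMed allele
#'   frequency ceilings for dominant/de novo (1e-3) and recessive (1e-2)
#'   searches. Missing AF is treated as 0 (absent from reference panels).
#' * `sv_af_max`: cohort AF ceiling for structural variants (0.005).
#' * `te_af_max_inherited` / `te_af_max_denovo`: gnomAD AF ceilings for
#'   transposable-element insertions (0.01 inherited, 0 de novo).
#' * `gerp_min`: conservation floor (GERP > 2).
#' * `gq_min`: genotype quality floor (GQ > 20).
#' * `ab_min`: allele-balance floor for heterozygous calls (> 0.15).
#' * `link_window`: peak-to-gene testing window (+/- 500 kb of the TSS).
#' * `gene_rank_window`: per-gene link tabulation window (+/- 50 kb).
#' * `link_r_min`, `link_fdr_max`: correlation and FDR retention gates.
#' * `perm_n_iter`: permutation iterations (5000).
#' * `denovo_outlier_max`: per-individual de novo count above which the
#'   individual is dropped before permutation testing (> 75).
#' * `multihit_sv_max_bp`: SV size ceiling for multi-hit tabulation (100 kb).
#' * `te_padding`: peak padding for TE insertion-point overlap (+/- 15 bp).
#' * `sad_z_min`: absolute SAD Z-score called significant (> 2).
#' * `promoter_upstream` / `promoter_downstream`: strand-aware promoter
#'   window about the TSS (the analysis' own definition; configurable).
#'
#' @return Named list of thresholds.
#' @export
ccdd_defaults <- function() {
  list(
    af_max_monoallelic  = 1e-3,
    af_max_biallelic    = 1e-2,
    sv_af_max           = 5e-3,
    te_af_max_inherited = 1e-2,
    te_af_max_denovo    = 0,
    te_confidence_denovo    = "two_side_tprt_both",
    te_confidence_inherited = c("two_side_tprt_both", "two_side_tprt"),
    gerp_min            = 2,
    gq_min              = 20,
    ab_min              = 0.15,
    ab_symmetric        = FALSE,
    link_window         = 500000,
    gene_rank_window    = 50000,
    link_r_min          = 0.1,
    link_r_inclusive    = TRUE,
    link_fdr_max        = 1e-4,
    perm_n_iter         = 5000,
    denovo_outlier_max  = 75,
    multihit_min_families = 2,
    multihit_sv_max_bp  = 100000,
    te_padding          = 15,
    sad_z_min           = 2,
    promoter_upstream   = 2000,
    promoter_downstream = 200,
    family_blocklist    = character(0),
    known_gene_list     = character(0)
  )
}

#' Default disease-group to cell-type map
#'
#' Maps each congenital cranial dysinnervation disorder (CCDD) group to the
#' cranial motor neuron (cMN) population(s) whose accessible-chromatin peaks
#' define its non-coding search space: CFEOM to cMN3/4, ptosis phenotypes to
#' the superior branch of cMN3, fourth nerve palsy (FNP) to cMN4, Duane
#' retraction syndrome (DRS) to cMN6, congenital facial palsy (CFP) to cMN7,
#' and Moebius syndrome to cMN6 and cMN7.
#'
#' @return Named list: disease group -> character vector of cell types.
#' @export
disease_map_default <- function() {
  list(
    "CFEOM"        = "cMN3_4",
    "FNP"          = "cMN4",
    "DRS"          = "cMN6",
    "CFP"          = "cMN7",
    "Moebius"      = c("cMN6", "cMN7"),
    "Ptosis"       = "cMN3s",
    "Ptosis/MGJWS" = "cMN3s"
  )
}

#' Load a run configuration from YAML
#'
#' Reads a YAML file and overlays it on [ccdd_defaults()] (and, under the
#' `disease_map` key, on [disease_map_default()]). Keys absent from the file
#' keep their defaults; unknown keys are rejected.
#'
#' @param path Path to a YAML config file, or `NULL` for pure defaults.
#' @return List with elements `thresholds` and `disease_map`.
#' @export
load_config <- function(path = NULL) {
  thr <- ccdd_defaults()
  dmap <- disease_map_default()
  if (!is.null(path)) {
    raw <- yaml::read_yaml(path)
    user_thr <- raw[setdiff(names(raw), "disease_map")]
    bad <- setdiff(names(user_thr), names(thr))
    if (length(bad)) {
      stop("unknown config keys: ", paste(bad, collapse = ", "))
    }
    thr[names(user_thr)] <- user_thr
    if (!is.null(raw$disease_map)) {
      dmap[names(raw$disease_map)] <- raw$disease_map
    }
  }
  list(thresholds = thr, disease_map = dmap)
}
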