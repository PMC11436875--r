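`%||%` <- function(a, b) if (is.null(a)) b else a

#' Synthetic-cohort configuration
#'
#' Defines the desk-scale study conditions for the synthetic cohort: a small
#' assembly (default 3 chromosomes x 10 Mb) with a masked fraction, families
#' spanning the seven CCDD disease groups and four inheritance/phenotype
#' subgroups, planted candidate variants that satisfy every hard filter, and
#' background variants constructed to violate at least one. One seed
#' determines every output.
#'
#' @param seed Integer master seed.
#' @param n_chromosomes,chrom_length Assembly shape (bp per chromosome).
#' @param mask_fraction Fraction of each chromosome (its leading block)
#'   excluded from random placement.
#' @param disease_groups,subgroups Cohort strata; defaults are the seven
#'   CCDD groups and the four familial/sporadic x syndromic/isolated
#'   subgroups.
#' @param n_families_per_group Families simulated per (group, subgroup).
#' @param n_background_variants Background SNV/indel count.
#' @param af_spectrum Allele-frequency mixture: point mass at 0 (private),
#'   log-uniform rare component straddling the filter thresholds, and a
#'   common component.
#' @param genotype_error_rate Per-genotype probability of replacing a
#'   Mendelian-consistent call with a random other code.
#' @param background_violate Force every background variant to violate at
#'   least one hard filter (guarantees planted-only recovery downstream).
#' @param cell_types,n_peaks_per_celltype,peak_width_range Peak-atlas shape.
#' @param planted_modes_sporadic,planted_modes_familial Mode cycles used to
#'   auto-plant one candidate per family.
#' @param planted_multihit List of entries `list(cell_type=, peak_index=,
#'   families=, mode=)` planting one same-mode variant per listed family in
#'   one peak.
#' @param n_background_sv,n_background_te Background SV / TE counts.
#' @param planted_sv,planted_te Lists of planted SV / TE specs
#'   (`list(family=, mode=, cell_type=, peak_index=, type=, len=)` for SVs;
#'   `list(family=, mode=, cell_type=, peak_index=, te_family=)` for TEs).
#' @param n_cells,n_peaks,n_genes,nb_size,base_mean,depth_sdlog Cell-matrix
#'   shape and negative-binomial noise (per-cell depth factor is lognormal).
#' @param n_clusters,n_replicates,cluster_noise Cell-metadata structure.
#' @param planted_links List of `list(peak = j, gene = g, r = rho)` planted
#'   accessibility-expression correlations.
#' @param disease_map Disease-group to cell-type map.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       n_chromosomes = 3,
                       chrom_length = 1e7,
                       mask_fraction = 0.1,
                       disease_groups = c("CFEOM", "FNP", "DRS", "CFP",
                                          "Moebius", "Ptosis",
                                          "Ptosis/MGJWS"),
                       subgroups = c("familial/syndromic",
                                     "familial/isolated",
                                     "sporadic-trio/syndromic",
                                     "sporadic-trio/isolated"),
                       n_families_per_group = 1,
                       n_background_variants = 500,
                       af_spectrum = list(p_private = 0.3, p_rare = 0.5,
                                          rare_log10_min = -4,
                                          rare_log10_max = -1.5,
                                          common_min = 0.05,
                                          common_max = 0.5),
                       genotype_error_rate = 0.002,
                       background_violate = TRUE,
                       cell_types = c("cMN3_4", "cMN3s", "cMN4", "cMN6",
                                      "cMN7", "cMN12"),
                       n_peaks_per_celltype = 40,
                       peak_width_range = c(200, 1000),
                       planted_modes_sporadic = c("de_novo",
                                                  "homozygous_recessive",
                                                  "compound_het"),
                       planted_modes_familial = c("dominant",
                                                  "homozygous_recessive"),
                       planted_multihit = list(),
                       n_background_sv = 20,
                       n_background_te = 20,
                       planted_sv = list(),
                       planted_te = list(),
                       n_cells = 1000,
                       n_peaks = 200,
                       n_genes = 100,
                       nb_size = 10,
                       base_mean = 20,
                       depth_sdlog = 0.1,
                       n_clusters = 8,
                       n_replicates = 4,
                       cluster_noise = 0.05,
                       planted_links = list(),
                       disease_map = disease_map_default()) {
  stopifnot(chrom_length > 0, n_chromosomes >= 1,
            mask_fraction >= 0, mask_fraction < 1,
            genotype_error_rate >= 0, genotype_error_rate < 1)
  for (pl in planted_links) {
    if (abs(pl$r) > 1) stop("planted correlation outside [-1, 1]")
  }
  cl <- stats::setNames(rep(chrom_length, n_chromosomes),
                        paste0("chr", seq_len(n_chromosomes)))
  cfg <- as.list(environment())
  cfg$cl <- NULL
  cfg$chrom_lengths <- cl
  structure(cfg, class = "sim_config")
}

#' Placement mask of a simulated assembly
#'
#' The masked region is the leading `mask_fraction` block of every
#' chromosome (deterministic, so identical seeds give identical masks).
#'
#' @param config A [sim_config()].
#' @return data.frame of masked intervals (`chrom`, `start`, `end`).
#' @export
sim_mask <- function(config) {
  cl <- config$chrom_lengths
  data.frame(chrom = names(cl), start = 0,
             end = floor(config$mask_fraction * cl),
             stringsAsFactors = FALSE)
}

# uniform positions over the unmasked portion of the assembly (0-based)
sample_positions <- function(config, n) {
  cl <- config$chrom_lengths
  off <- floor(config$mask_fraction * cl)
  avail <- cl - off
  ch <- sample(names(cl), n, replace = TRUE, prob = avail)
  pos <- off[ch] + floor(stats::runif(n) * avail[ch])
  data.frame(chrom = ch, pos0 = as.numeric(pos), stringsAsFactors = FALSE)
}

#' Simulate a per-cell-type peak atlas
#'
#' Draws `n_peaks_per_celltype` intervals per cell type over the unmasked
#' assembly with widths uniform in `peak_width_range`; overlaps within and
#' across cell types arise by chance and exercise the merge semantics.
#'
#' @param config A [sim_config()].
#' @return A [peak_atlas()].
#' @export
simulate_peak_atlas <- function(config) {
  set.seed(config$seed + 101L)
  sets <- lapply(stats::setNames(nm = config$cell_types), function(ct) {
    n <- config$n_peaks_per_celltype
    p <- sample_positions(config, n)
    w <- floor(stats::runif(n, config$peak_width_range[1],
                            config$peak_width_range[2] + 1))
    end <- pmin(p$pos0 + w, config$chrom_lengths[p$chrom])
    data.frame(chrom = p$chrom, start = p$pos0, end = end,
               stringsAsFactors = FALSE)
  })
  peak_atlas(sets, provenance = sprintf("simulated(seed=%d)", config$seed))
}

random_base <- function(n, not = NULL) {
  bases <- c("A", "C", "G", "T")
  out <- sample(bases, n, replace = TRUE)
  if (!is.null(not)) {
    clash <- out == not
    while (any(clash)) {
      out[clash] <- sample(bases, sum(clash), replace = TRUE)
      clash <- out == not
    }
  }
  out
}

draw_af <- function(config, n) {
  sp <- config$af_spectrum
  comp <- stats::runif(n)
  af <- numeric(n)
  rare <- comp >= sp$p_private & comp < sp$p_private + sp$p_rare
  common <- comp >= sp$p_private + sp$p_rare
  af[rare] <- 10^stats::runif(sum(rare), sp$rare_log10_min,
                              sp$rare_log10_max)
  af[common] <- stats::runif(sum(common), sp$common_min, sp$common_max)
  af
}

build_pedigrees <- function(config) {
  ped <- list(); fams <- list()
  fi <- 0L
  for (g in config$disease_groups) {
    gslug <- gsub("[^A-Za-z0-9]", "", g)
    for (s in config$subgroups) {
      sporadic <- grepl("^sporadic", s)
      cycle <- if (sporadic) {
        config$planted_modes_sporadic
      } else {
        config$planted_modes_familial
      }
      for (k in seq_len(config$n_families_per_group)) {
        fi <- fi + 1L
        fam_id <- sprintf("F%03d_%s", fi, gslug)
        mode <- cycle[(fi - 1L) %% length(cycle) + 1L]
        fa <- paste0(fam_id, "_fa"); mo <- paste0(fam_id, "_mo")
        ch1 <- paste0(fam_id, "_p1")
        rows <- data.frame(
          family_id = fam_id,
          individual_id = c(fa, mo, ch1),
          father_id = c("0", "0", fa),
          mother_id = c("0", "0", mo),
          sex = c(1L, 2L, 1L),
          affected = c(!sporadic && mode == "dominant", FALSE, TRUE),
          stringsAsFactors = FALSE
        )
        if (!sporadic) {
          rows <- rbind(rows, data.frame(
            family_id = fam_id, individual_id = paste0(fam_id, "_s1"),
            father_id = fa, mother_id = mo, sex = 2L, affected = FALSE,
            stringsAsFactors = FALSE
          ))
        }
        ped[[fi]] <- rows
        fams[[fi]] <- data.frame(
          family_id = fam_id, disease_group = g, subgroup = s,
          incomplete_penetrance = FALSE, planted_mode = mode,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  list(ped = do.call(rbind, c(ped, list(make.row.names = FALSE))),
       families = do.call(rbind, c(fams, list(make.row.names = FALSE))))
}

# pick the planted peak for family number k within its disease group
planted_peak <- function(atlas, dmap, group, k) {
  ct <- dmap[[group]][1]
  peaks <- atlas$sets[[ct]]
  peaks[(k - 1L) %% nrow(peaks) + 1L, , drop = FALSE]
}

transmit <- function(parent_gt) {
  # one allele from a parent genotype code (0/1/2)
  if (parent_gt == 0L) 0L
  else if (parent_gt == 2L) 1L
  else stats::rbinom(1, 1, 0.5)
}

#' Simulate a pedigree cohort with planted candidate variants
#'
#' Generates pedigrees over the seven disease groups and four subgroups,
#' plants one quality-passing candidate variant per family (mode cycling
#' through the sporadic/familial mode lists) plus any configured multi-hit
#' peaks, and adds background variants whose genotypes are
#' Mendelian-consistent except at the configured genotype-error rate and
#' which (by default) each violate at least one hard filter. SV and TE call
#' tables are built the same way. The returned truth set lists every
#' planted item.
#'
#' @param config A [sim_config()].
#' @param atlas Optional [peak_atlas()]; defaults to
#'   [simulate_peak_atlas()] under the same seed.
#' @return Object of class `ccdd_cohort`: list with `ped`, `families`, `vs`
#'   (a [variant_set()]), `sv`, `te`, `truth`, `atlas`, `config`.
#' @export
simulate_cohort <- function(config, atlas = NULL) {
  atlas <- atlas %||% simulate_peak_atlas(config)
  set.seed(config$seed + 202L)
  pd <- build_pedigrees(config)
  ped <- pd$ped; fams <- pd$families
  samples <- ped$individual_id
  ns <- length(samples)
  dmap <- config$disease_map

  peaksets <- lapply(stats::setNames(nm = unique(fams$disease_group)),
                     function(g) build_disease_peakset(atlas, dmap, g))
  group_peak_id <- function(group, chrom, pos1) {
    hits <- overlap_variants(data.frame(chrom = chrom, pos = pos1),
                             peaksets[[group]], type = "point")
    if (nrow(hits)) hits$peak_id[1] else NA_character_
  }

  vrows <- list(); gts <- list()
  truth_cand <- list()
  fam_counter_in_group <- stats::setNames(rep(0L,
    length(unique(fams$disease_group))), unique(fams$disease_group))

  add_variant <- function(chrom, pos1, ref, alt, cohort_af, gnomad_af,
                          topmed_af, gerp, filt, gt) {
    vrows[[length(vrows) + 1]] <<- data.frame(
      var_id = paste(chrom, pos1, ref, alt, sep = ":"),
      chrom = chrom, pos = pos1, ref = ref, alt = alt,
      var_class = if (nchar(ref) == 1 && nchar(alt) == 1) "SNV" else "indel",
      cohort_af = cohort_af, gnomad_af = gnomad_af, topmed_af = topmed_af,
      gerp = gerp, filter_status = filt, stringsAsFactors = FALSE
    )
    gts[[length(gts) + 1]] <<- gt
  }

  plant_variant <- function(fam_id, mode, peak, group, offset = 0L) {
    pos1 <- floor((peak$start + peak$end) / 2) + 1L + offset  # 1-based
    ref <- random_base(1)
    alt <- random_base(1, not = ref)
    gt <- stats::setNames(rep(0L, ns), samples)
    fam <- ped[ped$family_id == fam_id, ]
    aff <- fam$individual_id[fam$affected]
    unaff <- fam$individual_id[!fam$affected]
    kids <- fam$individual_id[fam$father_id != "0"]
    parents <- setdiff(fam$individual_id, kids)
    if (mode == "de_novo") {
      gt[aff] <- 1L
    } else if (mode %in% c("dominant", "dominant_incomplete_penetrance")) {
      gt[aff] <- 1L
    } else if (mode == "homozygous_recessive") {
      gt[aff] <- 2L
      # unaffected parents are het carriers; an affected founder parent
      # stays homozygous (and transmits one allele)
      gt[setdiff(parents, aff)] <- 1L
    } else {
      stop("unknown planted mode: ", mode)
    }
    af_hi <- if (mode == "homozygous_recessive") 5e-3 else 5e-4
    af <- if (mode == "de_novo") 0 else stats::runif(1, 0, af_hi)
    add_variant(peak$chrom, pos1, ref, alt,
                cohort_af = sum(gt) / (2 * ns),
                gnomad_af = af, topmed_af = af,
                gerp = stats::runif(1, 3, 6), filt = "PASS", gt = gt)
    truth_cand[[length(truth_cand) + 1]] <<- data.frame(
      family_id = fam_id, var_id = vrows[[length(vrows)]]$var_id,
      mode = mode, peak_id = group_peak_id(group, peak$chrom, pos1),
      stringsAsFactors = FALSE
    )
  }

  plant_compound_het <- function(fam_id, peak, group) {
    fam <- ped[ped$family_id == fam_id, ]
    kid <- fam$individual_id[fam$affected][1]
    fa <- fam$father_id[fam$individual_id == kid]
    mo <- fam$mother_id[fam$individual_id == kid]
    mid <- floor((peak$start + peak$end) / 2)
    for (side in 1:2) {
      pos1 <- mid + c(-10L, 10L)[side] + 1L
      ref <- random_base(1); alt <- random_base(1, not = ref)
      gt <- stats::setNames(rep(0L, ns), samples)
      gt[kid] <- 1L
      gt[if (side == 1) fa else mo] <- 1L
      af <- stats::runif(1, 0, 5e-3)
      add_variant(peak$chrom, pos1, ref, alt,
                  cohort_af = sum(gt) / (2 * ns),
                  gnomad_af = af, topmed_af = af,
                  gerp = stats::runif(1, 3, 6), filt = "PASS", gt = gt)
      truth_cand[[length(truth_cand) + 1]] <<- data.frame(
        family_id = fam_id, var_id = vrows[[length(vrows)]]$var_id,
        mode = "compound_het",
        peak_id = group_peak_id(group, peak$chrom, pos1),
        stringsAsFactors = FALSE
      )
    }
  }

  # planted candidates: one per family, mode per the configured cycle
  for (i in seq_len(nrow(fams))) {
    g <- fams$disease_group[i]
    fam_counter_in_group[g] <- fam_counter_in_group[g] + 1L
    peak <- planted_peak(atlas, dmap, g, fam_counter_in_group[g])
    if (fams$planted_mode[i] == "compound_het") {
      plant_compound_het(fams$family_id[i], peak, g)
    } else {
      plant_variant(fams$family_id[i], fams$planted_mode[i], peak, g)
    }
  }

  # planted multi-hit peaks: one same-mode variant per listed family
  truth_multihit <- list()
  for (mh in config$planted_multihit) {
    ct <- mh$cell_type
    peak <- atlas$sets[[ct]][mh$peak_index, , drop = FALSE]
    offs <- seq(-20L, by = 7L, length.out = length(mh$families))
    for (j in seq_along(mh$families)) {
      fam_id <- mh$families[j]
      group <- fams$disease_group[fams$family_id == fam_id]
      plant_variant(fam_id, mh$mode, peak, group, offset = offs[j])
    }
    pos1 <- floor((peak$start + peak$end) / 2) + 1L
    group0 <- fams$disease_group[fams$family_id == mh$families[1]]
    truth_multihit[[length(truth_multihit) + 1]] <- data.frame(
      peak_id = group_peak_id(group0, peak$chrom, pos1),
      broad_mode = broad_mode_of(mh$mode),
      families = paste(sort(mh$families), collapse = ","),
      stringsAsFactors = FALSE
    )
  }

  # background variants: founder HWE genotypes, Mendelian transmission,
  # each (by default) violating >= 1 hard filter for both AF classes
  nb <- config$n_background_variants
  if (nb > 0) {
    p <- sample_positions(config, nb)
    founders <- ped$individual_id[ped$father_id == "0"]
    kids <- ped[ped$father_id != "0", ]
    for (i in seq_len(nb)) {
      ref <- random_base(1); alt <- random_base(1, not = ref)
      af <- draw_af(config, 1)
      gt <- stats::setNames(rep(0L, ns), samples)
      gt[founders] <- stats::rbinom(length(founders), 2, af)
      for (j in seq_len(nrow(kids))) {
        gt[kids$individual_id[j]] <-
          transmit(gt[[kids$father_id[j]]]) + transmit(gt[[kids$mother_id[j]]])
      }
      err <- stats::runif(ns) < config$genotype_error_rate
      if (any(err)) {
        gt[err] <- vapply(gt[err], function(x) {
          sample(setdiff(0:2, x), 1)
        }, integer(1))
      }
      gnomad <- af * stats::runif(1, 0.5, 1.5)
      topmed <- af * stats::runif(1, 0.5, 1.5)
      gerp <- stats::runif(1, -3, 6)
      filt <- if (stats::runif(1) < 0.9) "PASS" else "LowQual"
      if (config$background_violate &&
          gnomad < ccdd_defaults()$af_max_biallelic &&
          topmed < ccdd_defaults()$af_max_biallelic &&
          gerp > ccdd_defaults()$gerp_min && filt == "PASS") {
        # force a violation that blocks both AF classes
        pickv <- sample(3, 1)
        if (pickv == 1) gerp <- stats::runif(1, -3, 2)
        else if (pickv == 2) filt <- "LowQual"
        else gnomad <- stats::runif(1, 1e-2, 0.5)
      }
      add_variant(p$chrom[i], as.integer(p$pos0[i]) + 1L, ref, alt,
                  cohort_af = min(1, sum(gt) / (2 * ns)),
                  gnomad_af = gnomad, topmed_af = topmed,
                  gerp = gerp, filt = filt, gt = gt)
    }
  }

  variants <- do.call(rbind, c(vrows, list(make.row.names = FALSE)))
  gt <- do.call(rbind, gts)
  ord <- order(variants$chrom, variants$pos, variants$alt)
  variants <- variants[ord, , drop = FALSE]
  gt <- gt[ord, , drop = FALSE]
  rownames(variants) <- NULL
  n_var <- nrow(variants)
  gq <- matrix(60, n_var, ns)
  depth <- 40L
  ad_alt <- matrix(0L, n_var, ns)
  ad_alt[gt == 1L] <- depth %/% 2L
  ad_alt[gt == 2L] <- depth
  ad_ref <- depth - ad_alt
  ad_ref[is.na(gt)] <- 0L
  ad_alt[is.na(gt)] <- 0L
  vs <- variant_set(variants, gt, gq, ad_ref, ad_alt, samples)

  # SV and TE call tables
  sv <- simulate_sv_table(config, atlas, fams, peaksets)
  te <- simulate_te_table(config, atlas, fams, peaksets)

  truth <- list(
    candidates = if (length(truth_cand)) {
      do.call(rbind, c(truth_cand, list(make.row.names = FALSE)))
    } else {
      data.frame(family_id = character(0), var_id = character(0),
                 mode = character(0), peak_id = character(0))
    },
    multihit_peaks = if (length(truth_multihit)) {
      do.call(rbind, c(truth_multihit, list(make.row.names = FALSE)))
    } else {
      data.frame(peak_id = character(0), broad_mode = character(0),
                 families = character(0))
    },
    sv = sv$truth, te = te$truth
  )

  structure(
    list(ped = ped, families = fams, vs = vs, sv = sv$table, te = te$table,
         truth = truth, atlas = atlas, config = config),
    class = "ccdd_cohort"
  )
}

simulate_sv_table <- function(config, atlas, fams, peaksets) {
  rows <- list(); truth <- list()
  for (ps in config$planted_sv) {
    peak <- atlas$sets[[ps$cell_type]][ps$peak_index, , drop = FALSE]
    len <- ps$len %||% 5000
    start <- max(0, floor((peak$start + peak$end) / 2) - floor(len / 2))
    rows[[length(rows) + 1]] <- data.frame(
      chrom = peak$chrom, start = start, end = start + len,
      type = ps$type %||% "DEL",
      cohort_af = stats::runif(1, 0, 4e-3),
      family_id = ps$family, mode = ps$mode, stringsAsFactors = FALSE
    )
    truth[[length(truth) + 1]] <- data.frame(
      family_id = ps$family,
      var_id = sprintf("%s:%d-%d:%s", peak$chrom, start, start + len,
                       ps$type %||% "DEL"),
      mode = ps$mode, stringsAsFactors = FALSE
    )
  }
  n <- config$n_background_sv
  if (n > 0) {
    p <- sample_positions(config, n)
    len <- floor(stats::runif(n, 1e3, 5e4))
    rows[[length(rows) + 1]] <- data.frame(
      chrom = p$chrom, start = p$pos0, end = p$pos0 + len,
      type = sample(c("DEL", "DUP", "INV"), n, replace = TRUE),
      cohort_af = stats::runif(n, 5e-3, 0.5),  # violates the SV AF gate
      family_id = sample(fams$family_id, n, replace = TRUE),
      mode = sample(c("de_novo", "dominant"), n, replace = TRUE),
      stringsAsFactors = FALSE
    )
  }
  table <- if (length(rows)) {
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  } else {
    data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
               type = character(0), cohort_af = numeric(0),
               family_id = character(0), mode = character(0))
  }
  truth <- if (length(truth)) {
    do.call(rbind, c(truth, list(make.row.names = FALSE)))
  } else {
    data.frame(family_id = character(0), var_id = character(0),
               mode = character(0))
  }
  list(table = table, truth = truth)
}

simulate_te_table <- function(config, atlas, fams, peaksets) {
  rows <- list(); truth <- list()
  for (pt in config$planted_te) {
    peak <- atlas$sets[[pt$cell_type]][pt$peak_index, , drop = FALSE]
    pos0 <- floor((peak$start + peak$end) / 2)
    af <- if (pt$mode == "de_novo") 0 else stats::runif(1, 0, 9e-3)
    rows[[length(rows) + 1]] <- data.frame(
      chrom = peak$chrom, insertion_pos = pos0,
      te_family = pt$te_family %||% "L1",
      gnomad_af = af, confidence = "two_side_tprt_both",
      family_id = pt$family, mode = pt$mode, stringsAsFactors = FALSE
    )
    truth[[length(truth) + 1]] <- data.frame(
      family_id = pt$family,
      var_id = sprintf("%s:%d:%s", peak$chrom, pos0,
                       pt$te_family %||% "L1"),
      mode = pt$mode, stringsAsFactors = FALSE
    )
  }
  n <- config$n_background_te
  if (n > 0) {
    p <- sample_positions(config, n)
    # background TEs violate the AF gate or the confidence filter
    viol <- sample(c("af", "conf"), n, replace = TRUE)
    rows[[length(rows) + 1]] <- data.frame(
      chrom = p$chrom, insertion_pos = p$pos0,
      te_family = sample(c("L1", "Alu", "SVA"), n, replace = TRUE),
      gnomad_af = ifelse(viol == "af", stats::runif(n, 1e-2, 0.5), 0),
      confidence = ifelse(viol == "conf", "one_side_tprt",
                          "two_side_tprt_both"),
      family_id = sample(fams$family_id, n, replace = TRUE),
      mode = ifelse(viol == "af", "de_novo",
                    sample(c("de_novo", "dominant"), n, replace = TRUE)),
      stringsAsFactors = FALSE
    )
    # confidence-violating de novo rows with af 0 would pass the AF gate;
    # ensure the "conf" rows fail on the label alone, which they do
  }
  table <- if (length(rows)) {
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  } else {
    data.frame(chrom = character(0), insertion_pos = numeric(0),
               te_family = character(0), gnomad_af = numeric(0),
               confidence = character(0), family_id = character(0),
               mode = character(0))
  }
  truth <- if (length(truth)) {
    do.call(rbind, c(truth, list(make.row.names = FALSE)))
  } else {
    data.frame(family_id = character(0), var_id = character(0),
               mode = character(0))
  }
  list(table = table, truth = truth)
}

#' Mendelian-consistency rate of child genotypes
#'
#' Fraction of (variant, child) genotype calls consistent with the parents'
#' calls under biallelic Mendelian transmission; trios with any missing
#' genotype are skipped.
#'
#' @param vs A [variant_set()].
#' @param ped Pedigree data.frame.
#' @return Proportion in [0, 1].
#' @export
mendelian_consistency_rate <- function(vs, ped) {
  kids <- ped[ped$father_id != "0" & ped$mother_id != "0", ]
  kids <- kids[kids$individual_id %in% vs$samples &
                 kids$father_id %in% vs$samples &
                 kids$mother_id %in% vs$samples, , drop = FALSE]
  consistent <- 0L; total <- 0L
  for (j in seq_len(nrow(kids))) {
    gc <- vs$gt[, kids$individual_id[j]]
    gf <- vs$gt[, kids$father_id[j]]
    gm <- vs$gt[, kids$mother_id[j]]
    ok <- !is.na(gc) & !is.na(gf) & !is.na(gm)
    # child code must be writable as one allele from each parent
    lo <- (gf >= 1) + (gm >= 1)  # max transmissible alt alleles
    hi <- (gf == 2) + (gm == 2)  # min transmissible alt alleles
    cons <- ok & gc <= lo & gc >= hi
    consistent <- consistent + sum(cons, na.rm = TRUE)
    total <- total + sum(ok)
  }
  if (total == 0) return(NA_real_)
  consistent / total
}

#' Simulate paired single-cell accessibility and expression matrices
#'
#' Draws negative-binomial counts through a Gaussian copula with a
#' lognormal per-cell depth factor. Planted (peak, gene) pairs share a
#' latent normal with the target correlation; all other pairs are
#' independent. Cells carry cluster, class, and replicate labels, and
#' per-cell fragment counts (the peak-matrix row sums) for DORC
#' normalization. Peaks and genes receive assembly coordinates with every
#' planted peak placed within the linking window of its gene's TSS.
#'
#' @param config A [sim_config()].
#' @return List: `peak_counts` (cells x peaks), `gene_expr` (cells x
#'   genes), `cell_meta` (data.frame: `cell_id`, `class`, `cluster`,
#'   `replicate`, `fragments`), `peaks`, `genes` (coordinate data.frames),
#'   `truth_links` (planted pairs with target r).
#' @export
simulate_cell_matrices <- function(config) {
  set.seed(config$seed + 303L)
  nc <- config$n_cells; np <- config$n_peaks; ng <- config$n_genes
  for (pl in config$planted_links) {
    if (pl$peak > np || pl$gene > ng) {
      stop("planted link references a peak or gene beyond the matrix")
    }
  }
  peak_ids <- sprintf("peak_%03d", seq_len(np))
  gene_ids <- sprintf("gene_%03d", seq_len(ng))

  gp <- sample_positions(config, ng)
  genes <- data.frame(gene_id = gene_ids, chrom = gp$chrom,
                      tss = gp$pos0,
                      strand = sample(c("+", "-"), ng, replace = TRUE),
                      stringsAsFactors = FALSE)
  pp <- sample_positions(config, np)
  w <- floor(stats::runif(np, config$peak_width_range[1],
                          config$peak_width_range[2] + 1))
  peaks <- data.frame(peak_id = peak_ids, chrom = pp$chrom,
                      start = pp$pos0, end = pp$pos0 + w,
                      stringsAsFactors = FALSE)
  for (pl in config$planted_links) {
    # place the planted peak within the linking window of its gene
    g <- genes[pl$gene, ]
    s <- max(0, g$tss + round(stats::runif(1, -4e5, 4e5)))
    peaks$chrom[pl$peak] <- g$chrom
    peaks$start[pl$peak] <- s
    peaks$end[pl$peak] <- s + w[pl$peak]
  }

  zp <- matrix(stats::rnorm(nc * np), nc, np)
  zg <- matrix(stats::rnorm(nc * ng), nc, ng)
  for (pl in config$planted_links) {
    zg[, pl$gene] <- pl$r * zp[, pl$peak] +
      sqrt(1 - pl$r^2) * stats::rnorm(nc)
  }
  depth <- exp(stats::rnorm(nc, 0, config$depth_sdlog))
  mu_p <- outer(depth, rep(config$base_mean, np))
  mu_g <- outer(depth, rep(config$base_mean, ng))
  counts_from <- function(z, mu) {
    q <- stats::qnbinom(stats::pnorm(z), size = config$nb_size, mu = mu)
    dimnames(q) <- NULL
    q
  }
  peak_counts <- counts_from(zp, mu_p)
  gene_expr <- counts_from(zg, mu_g)
  colnames(peak_counts) <- peak_ids
  colnames(gene_expr) <- gene_ids
  cell_ids <- sprintf("cell_%04d", seq_len(nc))
  rownames(peak_counts) <- rownames(gene_expr) <- cell_ids

  classes <- sample(config$cell_types, nc, replace = TRUE)
  clusters <- paste0(classes, "_c",
                     sample(2, nc, replace = TRUE))
  scramble <- stats::runif(nc) < config$cluster_noise
  if (any(scramble)) {
    clusters[scramble] <- sample(unique(clusters), sum(scramble),
                                 replace = TRUE)
  }
  meta <- data.frame(
    cell_id = cell_ids, class = classes, cluster = clusters,
    replicate = sample(sprintf("rep%d", seq_len(config$n_replicates)),
                       nc, replace = TRUE),
    fragments = rowSums(peak_counts) + 1L,
    stringsAsFactors = FALSE
  )
  truth_links <- if (length(config$planted_links)) {
    do.call(rbind, lapply(config$planted_links, function(pl) {
      data.frame(peak_id = peak_ids[pl$peak], gene_id = gene_ids[pl$gene],
                 r_target = pl$r, stringsAsFactors = FALSE)
    }))
  } else {
    data.frame(peak_id = character(0), gene_id = character(0),
               r_target = numeric(0))
  }
  list(peak_counts = peak_counts, gene_expr = gene_expr, cell_meta = meta,
       peaks = peaks, genes = genes, truth_links = truth_links)
}

#' Simulate replicated allele counts
#'
#' Reference-allele counts per replicate are Binomial(n, p) draws with the
#' total coverage split as evenly as possible across replicates.
#'
#' @param true_ref_prob True reference-allele probability, in (0, 1)
#'   exclusive.
#' @param n_total Total informative coverage across replicates.
#' @param n_replicates Number of biological replicates.
#' @param seed Optional seed.
#' @return data.frame: `replicate`, `k`, `n`.
#' @export
simulate_allele_counts <- function(true_ref_prob, n_total,
                                   n_replicates = 2, seed = NULL) {
  if (!(true_ref_prob > 0 && true_ref_prob < 1)) {
    stop("true_ref_prob must lie strictly inside (0, 1)")
  }
  if (n_total <= 0) stop("n_total must be positive")
  if (!is.null(seed)) set.seed(seed)
  n <- rep(n_total %/% n_replicates, n_replicates)
  extra <- n_total - sum(n)
  if (extra > 0) n[seq_len(extra)] <- n[seq_len(extra)] + 1L
  data.frame(
    replicate = sprintf("rep%d", seq_len(n_replicates)),
    k = stats::rbinom(n_replicates, n, true_ref_prob),
    n = n
  )
}
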