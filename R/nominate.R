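empty_candidates <- function() {
  data.frame(
    family_id = character(0), var_id = character(0),
    var_class = character(0), mode = character(0), peak_id = character(0),
    partner_var_id = character(0), disease_group = character(0),
    var_idx = integer(0), sv_len = numeric(0), partner_idx = integer(0),
    stringsAsFactors = FALSE
  )
}

cand_row <- function(family_id, var_id, var_class, mode, peak_id,
                     partner_var_id = NA_character_,
                     disease_group = NA_character_, var_idx = NA_integer_,
                     sv_len = NA_real_, partner_idx = NA_integer_) {
  data.frame(family_id = family_id, var_id = var_id, var_class = var_class,
             mode = mode, peak_id = peak_id,
             partner_var_id = partner_var_id, disease_group = disease_group,
             var_idx = var_idx, sv_len = sv_len, partner_idx = partner_idx,
             stringsAsFactors = FALSE)
}

#' Nominate cell type-aware non-coding candidate variants
#'
#' The headline pipeline stage: hard filters, per-family inheritance
#' searches, restriction to the disease group's accessible-chromatin peaks,
#' and cohort-level exclusion, composed over SNVs/indels, SVs and TE
#' insertions.
#'
#' SNVs/indels must pass the variant-level hard filters at the search's AF
#' class (monoallelic 1e-3 for de novo/dominant, biallelic 1e-2 for
#' recessive and both compound-het members), match an inheritance
#' configuration in the family, and lie inside a disease-relevant peak
#' (point containment). SVs require cohort AF < 0.005 and any overlap of
#' their span with a peak. TE insertions require the class-specific gnomAD
#' AF gate (0.01 inherited, 0 de novo), a high-confidence call label, and
#' their insertion point inside a peak padded by +/-15 bp. Dominant/de novo
#' SNV/indel calls carried by any unaffected individual cohort-wide, and
#' recessive calls homozygous in any unaffected individual, are excluded.
#' Families on the blocklist (e.g. solved by coding variants) are dropped.
#'
#' @param cohort List with elements `ped` (pedigree data.frame), `families`
#'   (data.frame: `family_id`, `disease_group`, `subgroup`, logical
#'   `incomplete_penetrance`), `vs` (a [variant_set()]), and optionally `sv`
#'   and `te` call tables (see [simulate_cohort()] for their columns).
#' @param atlas A [peak_atlas()].
#' @param dmap Disease map (named list of cell types per group).
#' @param thresholds Threshold list, see [ccdd_defaults()].
#' @return Candidate data.frame: `family_id`, `var_id`, `var_class`,
#'   `mode`, `peak_id`, `partner_var_id`, `disease_group`, `var_idx`,
#'   `sv_len`.
#' @export
nominate_candidates <- function(cohort, atlas, dmap,
                                thresholds = ccdd_defaults()) {
  ped <- cohort$ped
  fams <- cohort$families
  vs <- cohort$vs
  mono_pass <- apply_hard_filters(vs, "monoallelic",
                                  thresholds = thresholds)$passed
  bi_pass <- apply_hard_filters(vs, "biallelic",
                                thresholds = thresholds)$passed
  peaksets <- lapply(
    stats::setNames(nm = unique(fams$disease_group)),
    function(g) build_disease_peakset(atlas, dmap, g)
  )
  out <- list()
  add <- function(df) if (nrow(df)) out[[length(out) + 1]] <<- df
  snv_hits_cache <- list()
  peak_of <- function(group) {
    if (is.null(snv_hits_cache[[group]])) {
      hits <- overlap_variants(vs$variants, peaksets[[group]], type = "point")
      po <- rep(NA_character_, nrow(vs$variants))
      po[hits$variant_idx] <- hits$peak_id
      snv_hits_cache[[group]] <<- po
    }
    snv_hits_cache[[group]]
  }
  for (i in seq_len(nrow(fams))) {
    fam_id <- fams$family_id[i]
    group <- fams$disease_group[i]
    fam <- ped[ped$family_id == fam_id, , drop = FALSE]
    if (!any(fam$individual_id %in% vs$samples)) next
    ip <- isTRUE(fams$incomplete_penetrance[i])
    po <- peak_of(group)
    in_peak <- !is.na(po)

    # de novo: every affected member with both parents genotyped
    kids <- fam[fam$affected & fam$father_id != "0" & fam$mother_id != "0", ]
    for (j in seq_len(nrow(kids))) {
      if (!all(c(kids$individual_id[j], kids$father_id[j],
                 kids$mother_id[j]) %in% vs$samples)) next
      dn <- call_de_novo(vs, kids$individual_id[j], kids$father_id[j],
                         kids$mother_id[j], thresholds)
      idx <- which(dn & mono_pass & in_peak)
      if (length(idx)) {
        add(cand_row(fam_id, vs$variants$var_id[idx], "SNV_indel",
                     "de_novo", po[idx], disease_group = group,
                     var_idx = idx))
      }
    }

    # dominant: familial subgroups, or a trio with an affected parent
    parent_affected <- any(fam$affected[fam$individual_id %in%
                                          c(fam$father_id, fam$mother_id)])
    if (grepl("^familial", fams$subgroup[i]) || parent_affected) {
      dom <- find_dominant(vs, ped, fam_id, incomplete_penetrance = ip,
                           thresholds = thresholds)
      dom <- dom[mono_pass[dom$var_idx] & in_peak[dom$var_idx], ,
                 drop = FALSE]
      if (nrow(dom)) {
        add(cand_row(fam_id, dom$var_id, "SNV_indel", dom$mode,
                     po[dom$var_idx], disease_group = group,
                     var_idx = dom$var_idx))
      }
    }

    # homozygous recessive
    rec <- find_homozygous_recessive(vs, ped, fam_id, thresholds)
    rec <- rec[bi_pass[rec$var_idx] & in_peak[rec$var_idx], , drop = FALSE]
    if (nrow(rec)) {
      add(cand_row(fam_id, rec$var_id, "SNV_indel", rec$mode,
                   po[rec$var_idx], disease_group = group,
                   var_idx = rec$var_idx))
    }

    # compound het: both members gated at the biallelic AF class
    ch <- find_compound_het(vs, ped, fam_id, peaksets[[group]], thresholds,
                            eligible = bi_pass)
    if (nrow(ch)) {
      add(cand_row(fam_id, ch$var_id, "SNV_indel", "compound_het",
                   ch$peak_id, partner_var_id = ch$partner_var_id,
                   disease_group = group, var_idx = ch$var_idx,
                   partner_idx = ch$partner_idx))
    }

    # structural variants: cohort AF gate + any-overlap
    sv <- cohort$sv
    if (!is.null(sv) && nrow(sv)) {
      svf <- sv[sv$family_id == fam_id &
                  sv$cohort_af < thresholds$sv_af_max, , drop = FALSE]
      if (nrow(svf)) {
        hits <- overlap_variants(svf, peaksets[[group]], type = "span")
        if (nrow(hits)) {
          h <- hits[!duplicated(hits$variant_idx), , drop = FALSE]
          add(cand_row(
            fam_id,
            sprintf("%s:%d-%d:%s", svf$chrom[h$variant_idx],
                    svf$start[h$variant_idx], svf$end[h$variant_idx],
                    svf$type[h$variant_idx]),
            "SV", svf$mode[h$variant_idx], h$peak_id,
            disease_group = group,
            sv_len = svf$end[h$variant_idx] - svf$start[h$variant_idx]
          ))
        }
      }
    }

    # transposable elements: class-specific AF + confidence + padded point
    te <- cohort$te
    if (!is.null(te) && nrow(te)) {
      tef <- te[te$family_id == fam_id, , drop = FALSE]
      af <- ifelse(is.na(tef$gnomad_af), 0, tef$gnomad_af)
      keep <- ifelse(
        tef$mode == "de_novo",
        af <= thresholds$te_af_max_denovo &
          tef$confidence %in% thresholds$te_confidence_denovo,
        af < thresholds$te_af_max_inherited &
          tef$confidence %in% thresholds$te_confidence_inherited
      )
      tef <- tef[keep, , drop = FALSE]
      if (nrow(tef)) {
        hits <- overlap_variants(tef, peaksets[[group]], type = "insertion",
                                 padding = thresholds$te_padding)
        if (nrow(hits)) {
          h <- hits[!duplicated(hits$variant_idx), , drop = FALSE]
          add(cand_row(
            fam_id,
            sprintf("%s:%d:%s", tef$chrom[h$variant_idx],
                    tef$insertion_pos[h$variant_idx],
                    tef$te_family[h$variant_idx]),
            "TE", tef$mode[h$variant_idx], h$peak_id,
            disease_group = group
          ))
        }
      }
    }
  }
  if (!length(out)) return(empty_candidates())
  cands <- do.call(rbind, c(out, list(make.row.names = FALSE)))

  # cohort-level exclusion applies to genotyped SNV/indel calls
  snv <- cands[cands$var_class == "SNV_indel", , drop = FALSE]
  other <- cands[cands$var_class != "SNV_indel", , drop = FALSE]
  ip_fams <- fams$family_id[fams$incomplete_penetrance %in% TRUE]
  snv <- apply_cohort_exclusion(snv, vs, ped, ip_families = ip_fams)
  cands <- rbind(snv, other)

  cands <- cands[!cands$family_id %in% thresholds$family_blocklist, ,
                 drop = FALSE]
  cands$partner_idx <- NULL
  rownames(cands) <- NULL
  cands
}

#' Aggregate candidates into multi-hit peaks
#'
#' A multi-hit peak harbors candidate variants from two or more families
#' under the same broad mode of inheritance (dominant = de novo, dominant,
#' dominant with incomplete penetrance; recessive = homozygous recessive,
#' compound het). SVs longer than the size ceiling (default 100 kb) are
#' excluded before tabulation; a peak qualifies only if at least
#' `min_families` families remain.
#'
#' @param candidates Candidate data.frame from [nominate_candidates()].
#' @param thresholds Threshold list.
#' @return data.frame: `peak_id`, `broad_mode`, `n_families`, `families`,
#'   `variants` (comma-joined).
#' @export
find_multihit_peaks <- function(candidates, thresholds = ccdd_defaults()) {
  x <- candidates
  if (nrow(x) && "sv_len" %in% names(x)) {
    drop <- x$var_class == "SV" & !is.na(x$sv_len) &
      x$sv_len > thresholds$multihit_sv_max_bp
    x <- x[!drop, , drop = FALSE]
  }
  if (!nrow(x)) {
    return(data.frame(peak_id = character(0), broad_mode = character(0),
                      n_families = integer(0), families = character(0),
                      variants = character(0), stringsAsFactors = FALSE))
  }
  x$broad_mode <- broad_mode_of(x$mode)
  key <- paste(x$peak_id, x$broad_mode, sep = "\r")
  grp <- split(x, key)
  rows <- lapply(grp, function(g) {
    fams <- unique(g$family_id)
    if (length(fams) < thresholds$multihit_min_families) return(NULL)
    data.frame(
      peak_id = g$peak_id[1], broad_mode = g$broad_mode[1],
      n_families = length(fams),
      families = paste(sort(fams), collapse = ","),
      variants = paste(sort(unique(g$var_id)), collapse = ","),
      stringsAsFactors = FALSE
    )
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    return(data.frame(peak_id = character(0), broad_mode = character(0),
                      n_families = integer(0), families = character(0),
                      variants = character(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out[order(-out$n_families, out$peak_id), , drop = FALSE]
}

#' Aggregate candidates into multi-hit genes
#'
#' A multi-hit gene has two or more distinct linked peaks, each containing
#' at least one dominant-broad-mode candidate variant. Candidate `peak_id`s
#' must share the peak universe of the link table.
#'
#' @param candidates Candidate data.frame from [nominate_candidates()].
#' @param links Link table from [compute_links()].
#' @return data.frame: `gene_id`, `n_peaks`, `n_variants`, `peaks`,
#'   `variants` (comma-joined).
#' @export
find_multihit_genes <- function(candidates, links) {
  dom <- candidates[broad_mode_of(candidates$mode) == "dominant", ,
                    drop = FALSE]
  out <- list()
  for (g in unique(links$gene_id)) {
    gpeaks <- unique(links$peak_id[links$gene_id == g])
    hit <- dom[dom$peak_id %in% gpeaks, , drop = FALSE]
    np <- length(unique(hit$peak_id))
    if (np >= 2) {
      out[[length(out) + 1]] <- data.frame(
        gene_id = g, n_peaks = np,
        n_variants = length(unique(hit$var_id)),
        peaks = paste(sort(unique(hit$peak_id)), collapse = ","),
        variants = paste(sort(unique(hit$var_id)), collapse = ","),
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(out)) {
    return(data.frame(gene_id = character(0), n_peaks = integer(0),
                      n_variants = integer(0), peaks = character(0),
                      variants = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p-value from the conditional hypergeometric distribution
#' (tables at fixed margins with probability at most the observed table's),
#' with the sample odds ratio (a d) / (b c); zero cells give 0, Inf or NaN
#' as the arithmetic dictates.
#'
#' @param tab 2x2 matrix of non-negative integer counts.
#' @return List with `odds_ratio` and `p_two_sided`.
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == c(2, 2)), all(tab >= 0),
            all(tab == round(tab)))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("degenerate 2x2 table: zero margin")
  }
  or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  p <- stats::fisher.test(tab)$p.value
  list(odds_ratio = or, p_two_sided = p)
}

#' Z-normalize predicted accessibility-difference (SAD) scores
#'
#' SNV raw scores define the null distribution; every score (SNVs and
#' indels alike) is standardized against the SNV mean and SD, and scores
#' with |Z| above the threshold (default 2) are flagged significant.
#'
#' @param scores data.frame with `var_id`, `var_class` (`"SNV"` or
#'   `"indel"`), `raw_sad`.
#' @param thresholds Threshold list.
#' @return Input data.frame with `sad_z` and `significant` columns.
#' @export
sad_zscores <- function(scores, thresholds = ccdd_defaults()) {
  stopifnot(all(c("var_class", "raw_sad") %in% names(scores)))
  snv <- scores$raw_sad[scores$var_class == "SNV"]
  if (length(snv) < 2) stop("need >= 2 SNV scores to define the null")
  s <- stats::sd(snv)
  if (s == 0) stop("SNV null distribution has zero variance")
  scores$sad_z <- (scores$raw_sad - mean(snv)) / s
  scores$significant <- abs(scores$sad_z) > thresholds$sad_z_min
  scores
}

#' Integer-percent validation summaries
#'
#' @param tallies data.frame with `label`, `positive`, `total`.
#' @return Input with `percent = round(100 * positive / total)`.
#' @export
summarize_validation <- function(tallies) {
  stopifnot(all(c("positive", "total") %in% names(tallies)),
            all(tallies$total > 0),
            all(tallies$positive <= tallies$total),
            all(tallies$positive >= 0))
  tallies$percent <- round(100 * tallies$positive / tallies$total)
  tallies
}
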