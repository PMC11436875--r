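#' Read / write 6-column PED files
#'
#' Standard PED: family, individual, father, mother, sex (1=male, 2=female,
#' 0=unknown), phenotype (2=affected, 1=unaffected). Founders have father
#' and mother `"0"`.
#'
#' @param path PED path.
#' @return data.frame with `family_id`, `individual_id`, `father_id`,
#'   `mother_id`, `sex`, `affected` (logical).
#' @export
read_ped <- function(path) {
  df <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                          col.names = c("family_id", "individual_id",
                                        "father_id", "mother_id",
                                        "sex", "pheno"),
                          colClasses = c(rep("character", 4),
                                         "integer", "integer"))
  df$affected <- df$pheno == 2L
  df$pheno <- NULL
  df
}

#' @rdname read_ped
#' @param ped Pedigree data.frame as returned by [read_ped()].
#' @export
write_ped <- function(ped, path) {
  out <- data.frame(ped$family_id, ped$individual_id, ped$father_id,
                    ped$mother_id, ped$sex,
                    ifelse(ped$affected, 2L, 1L))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

gt_of <- function(vs, sample) {
  if (!sample %in% vs$samples) return(rep(NA_integer_, nrow(vs$variants)))
  vs$gt[, sample]
}

sample_passes <- function(vs, sample, thresholds) {
  if (!sample %in% vs$samples) return(rep(FALSE, nrow(vs$variants)))
  genotype_passes(vs$gt[, sample], vs$gq[, sample],
                  vs$ad_ref[, sample], vs$ad_alt[, sample], thresholds)
}

is_carrier <- function(gt) !is.na(gt) & gt >= 1L

#' De novo caller for a trio
#'
#' A variant is called de novo when the child is a quality-passing
#' heterozygote (GQ and allele-balance gates) and both parents are
#' quality-passing homozygous reference. A missing genotype in any trio
#' member vetoes the call.
#'
#' @param vs A [variant_set()].
#' @param child,father,mother Sample ids.
#' @param thresholds Threshold list, see [ccdd_defaults()].
#' @return Logical vector over variants.
#' @export
call_de_novo <- function(vs, child, father, mother,
                         thresholds = ccdd_defaults()) {
  gc <- gt_of(vs, child); gf <- gt_of(vs, father); gm <- gt_of(vs, mother)
  !is.na(gc) & gc == 1L & sample_passes(vs, child, thresholds) &
    !is.na(gf) & gf == 0L & sample_passes(vs, father, thresholds) &
    !is.na(gm) & gm == 0L & sample_passes(vs, mother, thresholds)
}

fam_members <- function(ped, family_id) ped[ped$family_id == family_id, ]

#' Dominant segregation search in one family
#'
#' Nominates a variant when every affected member is a quality-passing
#' carrier (het or hom alt) and, in the standard mode, no unaffected member
#' of the family carries it. The incomplete-penetrance mode drops the
#' within-family unaffected exclusion. Unaffected members with missing
#' genotypes never block a call; affected members with missing genotypes
#' always do.
#'
#' @param vs A [variant_set()].
#' @param ped Pedigree data.frame (one or more families).
#' @param family_id Family to search.
#' @param incomplete_penetrance Drop the unaffected-carrier exclusion.
#' @param thresholds Threshold list.
#' @return data.frame of candidate calls: `family_id`, `var_idx`, `var_id`,
#'   `mode`.
#' @export
find_dominant <- function(vs, ped, family_id, incomplete_penetrance = FALSE,
                          thresholds = ccdd_defaults()) {
  fam <- fam_members(ped, family_id)
  affected <- fam$individual_id[fam$affected]
  unaffected <- fam$individual_id[!fam$affected]
  if (!length(affected)) stop("family has no affected member: ", family_id)
  ok <- rep(TRUE, nrow(vs$variants))
  for (s in affected) {
    ok <- ok & is_carrier(gt_of(vs, s)) & sample_passes(vs, s, thresholds)
  }
  if (!incomplete_penetrance) {
    for (s in unaffected) {
      ok <- ok & !is_carrier(gt_of(vs, s))
    }
  }
  idx <- which(ok)
  data.frame(
    family_id = rep(family_id, length(idx)),
    var_idx = idx,
    var_id = vs$variants$var_id[idx],
    mode = rep(if (incomplete_penetrance) {
      "dominant_incomplete_penetrance"
    } else {
      "dominant"
    }, length(idx)),
    stringsAsFactors = FALSE
  )
}

#' Homozygous-recessive search in one family
#'
#' Nominates a variant when every affected member is quality-passing
#' homozygous alternate, no unaffected member is homozygous alternate, and
#' every available parent of an affected member carries at least one
#' alternate allele (a homozygous-reference parent is
#' inheritance-inconsistent).
#'
#' @inheritParams find_dominant
#' @return data.frame of candidate calls.
#' @export
find_homozygous_recessive <- function(vs, ped, family_id,
                                      thresholds = ccdd_defaults()) {
  fam <- fam_members(ped, family_id)
  affected <- fam[fam$affected, ]
  unaffected <- fam$individual_id[!fam$affected]
  if (!nrow(affected)) stop("family has no affected member: ", family_id)
  ok <- rep(TRUE, nrow(vs$variants))
  for (i in seq_len(nrow(affected))) {
    s <- affected$individual_id[i]
    g <- gt_of(vs, s)
    ok <- ok & !is.na(g) & g == 2L & sample_passes(vs, s, thresholds)
    for (p in c(affected$father_id[i], affected$mother_id[i])) {
      if (p != "0" && p %in% vs$samples) {
        gp <- gt_of(vs, p)
        # available parent must be a carrier; missing genotype is tolerated
        ok <- ok & (is.na(gp) | gp >= 1L)
      }
    }
  }
  for (s in unaffected) {
    g <- gt_of(vs, s)
    ok <- ok & !(!is.na(g) & g == 2L)
  }
  idx <- which(ok)
  data.frame(
    family_id = rep(family_id, length(idx)),
    var_idx = idx,
    var_id = vs$variants$var_id[idx],
    mode = rep("homozygous_recessive", length(idx)),
    stringsAsFactors = FALSE
  )
}

#' Compound-heterozygous search in one family
#'
#' The accessible-chromatin peak is the unit of heredity: a pair of distinct
#' variants in the same disease-relevant peak qualifies when one was
#' transmitted by the unaffected father and the other by the unaffected
#' mother, with the affected child a quality-passing heterozygote at both
#' sites. Parental origin is inferred from trio genotypes: a variant is
#' paternal when the father carries it and the mother is homozygous
#' reference (and vice versa); variants carried by both parents are skipped
#' with a warning (origin ambiguous).
#'
#' @inheritParams find_dominant
#' @param disease_peaks Merged interval data.frame with `peak_id` (the
#'   disease group's peak set, see [build_disease_peakset()]).
#' @param eligible Optional logical vector over variants restricting the
#'   search (e.g. hard-filter survivors).
#' @return data.frame of paired calls: `family_id`, `var_idx`, `var_id`,
#'   `partner_idx`, `partner_var_id`, `peak_id`, `mode` (one row per pair,
#'   paternal member first).
#' @export
find_compound_het <- function(vs, ped, family_id, disease_peaks,
                              thresholds = ccdd_defaults(),
                              eligible = NULL) {
  fam <- fam_members(ped, family_id)
  out <- list()
  kids <- fam[fam$affected & fam$father_id != "0" & fam$mother_id != "0", ]
  hits <- overlap_variants(vs$variants, disease_peaks, type = "point")
  peak_of <- rep(NA_character_, nrow(vs$variants))
  peak_of[hits$variant_idx] <- hits$peak_id
  for (i in seq_len(nrow(kids))) {
    child <- kids$individual_id[i]
    fa <- kids$father_id[i]; mo <- kids$mother_id[i]
    par_rows <- fam[match(c(fa, mo), fam$individual_id), ]
    if (any(is.na(par_rows$individual_id)) || any(par_rows$affected)) next
    gc <- gt_of(vs, child); gf <- gt_of(vs, fa); gm <- gt_of(vs, mo)
    child_het <- !is.na(gc) & gc == 1L & sample_passes(vs, child, thresholds)
    in_peak <- !is.na(peak_of)
    cand <- child_het & in_peak
    if (!is.null(eligible)) cand <- cand & eligible
    paternal <- cand & is_carrier(gf) & !is.na(gm) & gm == 0L &
      sample_passes(vs, fa, thresholds)
    maternal <- cand & is_carrier(gm) & !is.na(gf) & gf == 0L &
      sample_passes(vs, mo, thresholds)
    ambiguous <- cand & is_carrier(gf) & is_carrier(gm)
    if (any(ambiguous)) {
      warning(sum(ambiguous), " candidate variant(s) with ambiguous ",
              "parental origin skipped in family ", family_id)
    }
    for (p in which(paternal)) {
      partners <- which(maternal & peak_of == peak_of[p])
      partners <- setdiff(partners, p)
      for (q in partners) {
        out[[length(out) + 1]] <- data.frame(
          family_id = family_id,
          var_idx = p, var_id = vs$variants$var_id[p],
          partner_idx = q, partner_var_id = vs$variants$var_id[q],
          peak_id = peak_of[p], mode = "compound_het",
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (!length(out)) {
    return(data.frame(family_id = character(0), var_idx = integer(0),
                      var_id = character(0), partner_idx = integer(0),
                      partner_var_id = character(0), peak_id = character(0),
                      mode = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

broad_mode_of <- function(mode) {
  ifelse(mode %in% c("de_novo", "dominant", "dominant_incomplete_penetrance"),
         "dominant", "recessive")
}

#' Cohort-level exclusion of candidate calls
#'
#' Removes dominant/de novo calls whose variant is carried by any unaffected
#' individual cohort-wide, and recessive calls (homozygous recessive and
#' compound het, either pair member) whose variant is homozygous alternate
#' in any unaffected individual. Families flagged as incomplete penetrance
#' are exempted from triggering exclusion of their own family's calls by
#' their own unaffected carriers.
#'
#' @param calls Candidate data.frame (columns `family_id`, `var_idx`,
#'   `mode`, optionally `partner_idx`).
#' @param vs A [variant_set()] carrying cohort-wide genotypes.
#' @param ped Cohort pedigree data.frame.
#' @param ip_families Character vector of incomplete-penetrance family ids.
#' @return Filtered calls data.frame.
#' @export
apply_cohort_exclusion <- function(calls, vs, ped,
                                   ip_families = character(0)) {
  if (!nrow(calls)) return(calls)
  unaff <- ped[!ped$affected, , drop = FALSE]
  unaff <- unaff[unaff$individual_id %in% vs$samples, , drop = FALSE]
  keep <- logical(nrow(calls))
  for (i in seq_len(nrow(calls))) {
    fam <- calls$family_id[i]
    blockers <- unaff
    if (fam %in% ip_families) {
      blockers <- blockers[blockers$family_id != fam, , drop = FALSE]
    }
    ids <- blockers$individual_id
    vidx <- calls$var_idx[i]
    if (!is.null(calls$partner_idx) && !is.na(calls$partner_idx[i])) {
      vidx <- c(vidx, calls$partner_idx[i])
    }
    g <- vs$gt[vidx, ids, drop = FALSE]
    hit <- if (broad_mode_of(calls$mode[i]) == "dominant") {
      any(!is.na(g) & g >= 1L)
    } else {
      any(!is.na(g) & g == 2L)
    }
    keep[i] <- !hit
  }
  calls[keep, , drop = FALSE]
}
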