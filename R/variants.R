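#' Construct a variant set
#'
#' Container for biallelic variant records with per-sample genotype calls.
#' Genotypes are coded 0 (hom ref), 1 (het), 2 (hom alt), `NA` (missing).
#'
#' @param variants data.frame with columns `var_id`, `chrom`, `pos` (1-based),
#'   `ref`, `alt`, `var_class` (`"SNV"` or `"indel"`), `cohort_af`,
#'   `gnomad_af`, `topmed_af`, `gerp`, `filter_status`.
#' @param gt Integer matrix, variants x samples.
#' @param gq Numeric matrix of genotype qualities (phred).
#' @param ad_ref,ad_alt Integer matrices of allelic depths.
#' @param samples Character vector of sample ids (column order of `gt`).
#' @return Object of class `variant_set`.
#' @export
variant_set <- function(variants, gt, gq, ad_ref, ad_alt, samples) {
  stopifnot(
    nrow(variants) == nrow(gt), ncol(gt) == length(samples),
    all(dim(gt) == dim(gq)), all(dim(gt) == dim(ad_ref)),
    all(dim(gt) == dim(ad_alt))
  )
  for (af in c("cohort_af", "gnomad_af", "topmed_af")) {
    v <- variants[[af]]
    if (any(!is.na(v) & (v < 0 | v > 1))) stop("AF outside [0,1]: ", af)
  }
  if (any(variants$pos < 1)) stop("variant pos must be >= 1")
  colnames(gt) <- colnames(gq) <- colnames(ad_ref) <- colnames(ad_alt) <- samples
  structure(
    list(variants = variants, gt = gt, gq = gq,
         ad_ref = ad_ref, ad_alt = ad_alt, samples = samples),
    class = "variant_set"
  )
}

#' @export
print.variant_set <- function(x, ...) {
  cat("variant_set:", nrow(x$variants), "variants x",
      length(x$samples), "samples\n")
  invisible(x)
}

#' Read a VCF into raw (possibly multi-allelic) records
#'
#' Parses a VCF v4.2 file (GT:GQ:AD FORMAT; INFO keys `COHORT_AF`,
#' `GNOMAD_AF`, `TOPMED_AF`, `GERP`) with vcfR. Multi-allelic sites are kept
#' as-is; use [split_multiallelic()] to obtain a biallelic [variant_set()].
#'
#' @param path VCF path.
#' @return List of class `vcf_records` with per-site fields and per-sample
#'   `gt` (allele strings like `"1/2"`), `gq`, and `ad` (comma strings).
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  info_num <- function(key) {
    x <- vcfR::extract.info(v, element = key)
    x[is.na(x) | x == "."] <- NA
    x
  }
  rec <- list(
    chrom = fix$CHROM,
    pos = as.integer(fix$POS),
    ref = fix$REF,
    alt = fix$ALT,
    filter_status = fix$FILTER,
    cohort_af = info_num("COHORT_AF"),
    gnomad_af = info_num("GNOMAD_AF"),
    topmed_af = info_num("TOPMED_AF"),
    gerp = suppressWarnings(as.numeric(info_num("GERP"))),
    gt = vcfR::extract.gt(v, element = "GT"),
    gq = suppressWarnings(
      apply(vcfR::extract.gt(v, element = "GQ"), 2, as.numeric)
    ),
    ad = vcfR::extract.gt(v, element = "AD"),
    samples = colnames(v@gt)[-1]
  )
  # extract.gt drops matrix dims for single-variant files
  n <- length(rec$chrom)
  for (f in c("gt", "gq", "ad")) {
    rec[[f]] <- matrix(rec[[f]], nrow = n,
                       dimnames = list(NULL, rec$samples))
  }
  class(rec) <- "vcf_records"
  rec
}

#' Split multi-allelic records into biallelic variants
#'
#' Each alternate allele becomes one biallelic record; spanning-deletion
#' alleles (`alt == "*"`) are dropped. Per-sample genotypes are recoded
#' against the single alternate: alleles other than the current alternate
#' count as reference, so a `1/2` genotype becomes het for each of the two
#' alternates. Per-alt INFO frequencies are taken positionally; allelic
#' depth for the reference side is the total depth minus the current
#' alternate's depth.
#'
#' @param records A `vcf_records` object from [read_vcf()].
#' @return A biallelic [variant_set()].
#' @export
split_multiallelic <- function(records) {
  stopifnot(inherits(records, "vcf_records"))
  n_sites <- length(records$chrom)
  if (n_sites == 0) stop("no variant records")
  rows <- list()
  gt_rows <- list(); gq_rows <- list()
  adr_rows <- list(); ada_rows <- list()
  pick <- function(x, a_idx) {
    # a_idx-th element of a comma-separated per-alt INFO value
    if (is.na(x)) return(NA_real_)
    parts <- strsplit(x, ",", fixed = TRUE)[[1]]
    val <- parts[min(a_idx, length(parts))]
    if (is.na(val) || val == ".") NA_real_ else as.numeric(val)
  }
  for (i in seq_len(n_sites)) {
    alts <- strsplit(records$alt[i], ",", fixed = TRUE)[[1]]
    if (!length(alts)) stop("record with no alternate allele")
    if (any(!grepl("^[ACGTN]+$|^\\*$", alts))) {
      stop("malformed alternate allele at ", records$chrom[i], ":",
           records$pos[i])
    }
    ad_parsed <- lapply(records$ad[i, ], function(s) {
      if (is.na(s)) return(NULL)
      suppressWarnings(as.integer(strsplit(s, ",", fixed = TRUE)[[1]]))
    })
    for (a in seq_along(alts)) {
      if (alts[a] == "*") next  # spanning deletions are not kept
      gt_codes <- vapply(records$gt[i, ], function(g) {
        if (is.na(g) || g %in% c(".", "./.", ".|.")) return(NA_integer_)
        al <- strsplit(g, "[/|]")[[1]]
        if (any(al == ".")) return(NA_integer_)
        sum(al == as.character(a))
      }, integer(1))
      adr <- vapply(seq_along(ad_parsed), function(s) {
        x <- ad_parsed[[s]]
        if (is.null(x) || length(x) < a + 1) return(NA_integer_)
        sum(x, na.rm = TRUE) - x[a + 1]
      }, integer(1))
      ada <- vapply(seq_along(ad_parsed), function(s) {
        x <- ad_parsed[[s]]
        if (is.null(x) || length(x) < a + 1) return(NA_integer_)
        x[a + 1]
      }, integer(1))
      rows[[length(rows) + 1]] <- data.frame(
        var_id = paste(records$chrom[i], records$pos[i],
                       records$ref[i], alts[a], sep = ":"),
        chrom = records$chrom[i], pos = records$pos[i],
        ref = records$ref[i], alt = alts[a],
        var_class = if (nchar(records$ref[i]) == 1L &&
                        nchar(alts[a]) == 1L) "SNV" else "indel",
        cohort_af = pick(records$cohort_af[i], a),
        gnomad_af = pick(records$gnomad_af[i], a),
        topmed_af = pick(records$topmed_af[i], a),
        gerp = records$gerp[i],
        filter_status = records$filter_status[i],
        stringsAsFactors = FALSE
      )
      gt_rows[[length(gt_rows) + 1]] <- gt_codes
      gq_rows[[length(gq_rows) + 1]] <- records$gq[i, ]
      adr_rows[[length(adr_rows) + 1]] <- adr
      ada_rows[[length(ada_rows) + 1]] <- ada
    }
  }
  variants <- do.call(rbind, rows)
  rownames(variants) <- NULL
  variant_set(
    variants,
    gt = do.call(rbind, gt_rows),
    gq = do.call(rbind, gq_rows),
    ad_ref = do.call(rbind, adr_rows),
    ad_alt = do.call(rbind, ada_rows),
    samples = records$samples
  )
}

#' Variant-level hard filters
#'
#' Applies the population-frequency, conservation and call-quality gates:
#' gnomAD AF and TOPMed AF below 1e-3 for monoallelic (dominant/de novo) or
#' 1e-2 for biallelic (recessive) searches, GERP > 2, and VCF FILTER equal
#' to PASS. Missing population AF counts as 0 (absent from the reference
#' panels). Genotype-level gates (GQ, het allele balance) are applied to the
#' genotypes an inheritance decision consumes, via [genotype_passes()];
#' supply `gq`/`ab` here to fold one genotype's gates into the decision.
#'
#' @param vs A [variant_set()] (or its `variants` data.frame).
#' @param mode_class `"monoallelic"` or `"biallelic"`.
#' @param gq,ab Optional scalar/vector genotype quality and het allele
#'   balance to gate alongside the variant-level rules.
#' @param thresholds Threshold list, see [ccdd_defaults()].
#' @return data.frame with `var_id`, `passed`, and `reasons` (comma-joined
#'   identifiers of every failed rule; empty string iff passed).
#' @export
apply_hard_filters <- function(vs, mode_class = c("monoallelic", "biallelic"),
                               gq = NULL, ab = NULL,
                               thresholds = ccdd_defaults()) {
  mode_class <- match.arg(mode_class)
  v <- if (inherits(vs, "variant_set")) vs$variants else vs
  af_max <- if (mode_class == "monoallelic") {
    thresholds$af_max_monoallelic
  } else {
    thresholds$af_max_biallelic
  }
  af0 <- function(x) ifelse(is.na(x), 0, as.numeric(x))
  n <- nrow(v)
  fails <- list(
    gnomad_af = af0(v$gnomad_af) >= af_max,
    topmed_af = af0(v$topmed_af) >= af_max,
    gerp = is.na(v$gerp) | v$gerp <= thresholds$gerp_min,
    filter_status = v$filter_status != "PASS"
  )
  if (!is.null(gq)) {
    fails$gq <- rep_len(gq, n) <= thresholds$gq_min
  }
  if (!is.null(ab)) {
    ab_ok <- if (isTRUE(thresholds$ab_symmetric)) {
      pmin(ab, 1 - ab) > thresholds$ab_min
    } else {
      ab > thresholds$ab_min
    }
    fails$allele_balance <- !rep_len(ab_ok, n)
  }
  fail_mat <- do.call(cbind, fails)
  reasons <- apply(fail_mat, 1, function(r) {
    paste(names(fails)[r], collapse = ",")
  })
  data.frame(
    var_id = v$var_id,
    passed = !apply(fail_mat, 1, any),
    reasons = reasons,
    stringsAsFactors = FALSE
  )
}

#' Per-genotype quality gates
#'
#' GQ must exceed the floor, and heterozygous calls must show allele
#' balance `alt / (ref + alt)` above the floor (optionally the symmetric
#' `min(AB, 1 - AB)` check). Missing genotypes never pass.
#'
#' @param gt,gq,ad_ref,ad_alt Vectors of genotype codes, qualities, depths.
#' @param thresholds Threshold list.
#' @return Logical vector.
#' @export
genotype_passes <- function(gt, gq, ad_ref, ad_alt,
                            thresholds = ccdd_defaults()) {
  ok <- !is.na(gt) & !is.na(gq) & gq > thresholds$gq_min
  het <- !is.na(gt) & gt == 1L
  if (any(het)) {
    tot <- ad_ref[het] + ad_alt[het]
    ab <- ifelse(tot > 0, ad_alt[het] / tot, NA_real_)
    ab_ok <- if (isTRUE(thresholds$ab_symmetric)) {
      !is.na(ab) & pmin(ab, 1 - ab) > thresholds$ab_min
    } else {
      !is.na(ab) & ab > thresholds$ab_min
    }
    ok[het] <- ok[het] & ab_ok
  }
  ok
}

#' Construct a gene model
#'
#' @param genes data.frame with `gene_id`, `chrom`, `start`, `end`
#'   (0-based half-open gene body), `strand` (`"+"`/`"-"`), `tss`
#'   (0-based position).
#' @param exons data.frame with `gene_id`, `chrom`, `start`, `end`, or NULL.
#' @return Object of class `gene_model`.
#' @export
gene_model <- function(genes, exons = NULL) {
  stopifnot(all(c("gene_id", "chrom", "start", "end", "strand", "tss")
                %in% names(genes)))
  if (is.null(exons)) {
    exons <- data.frame(gene_id = character(0), chrom = character(0),
                        start = integer(0), end = integer(0),
                        stringsAsFactors = FALSE)
  }
  structure(list(genes = genes, exons = exons), class = "gene_model")
}

promoter_windows <- function(gm, thresholds = ccdd_defaults()) {
  g <- gm$genes
  up <- thresholds$promoter_upstream
  down <- thresholds$promoter_downstream
  plus <- g$strand != "-"
  start <- ifelse(plus, g$tss - up, g$tss - down + 1L)
  end <- ifelse(plus, g$tss + down, g$tss + up + 1L)
  data.frame(chrom = g$chrom, start = pmax(0L, as.integer(start)),
             end = as.integer(end), gene_id = g$gene_id,
             stringsAsFactors = FALSE)
}

#' Classify genomic context of variants
#'
#' Assigns exactly one label per variant with precedence
#' exonic > promoter > intronic > intergenic. The promoter is a strand-aware
#' window about the TSS (defaults -2000/+200 bp). Variants on chromosomes
#' absent from the gene model are intergenic (with a warning).
#'
#' @param variants data.frame with `chrom` and 1-based `pos` (e.g. the
#'   `variants` slot of a [variant_set()]).
#' @param gm A [gene_model()].
#' @param thresholds Threshold list.
#' @return Character vector of labels.
#' @export
classify_context <- function(variants, gm, thresholds = ccdd_defaults()) {
  stopifnot(inherits(gm, "gene_model"))
  n <- nrow(variants)
  labels <- rep("intergenic", n)
  pts <- data.frame(chrom = variants$chrom, pos = variants$pos)
  in_any <- function(iv) {
    if (!nrow(iv)) return(rep(FALSE, n))
    hits <- overlap_variants(pts, iv[, c("chrom", "start", "end")],
                             type = "point")
    seq_len(n) %in% hits$variant_idx
  }
  gene_body <- gm$genes[, c("chrom", "start", "end")]
  labels[in_any(gene_body)] <- "intronic"
  labels[in_any(promoter_windows(gm, thresholds))] <- "promoter"
  labels[in_any(gm$exons)] <- "exonic"
  off_model <- !variants$chrom %in% unique(c(gm$genes$chrom, gm$exons$chrom))
  if (any(off_model)) {
    warning(sum(off_model),
            " variant(s) on chromosomes absent from the gene model")
    labels[off_model] <- "intergenic"
  }
  labels
}

#' Tabulate context-label fractions
#'
#' @param labels Character vector of context labels.
#' @return Named numeric vector over the four labels, summing to 1.
#' @export
tabulate_context_fractions <- function(labels) {
  if (!length(labels)) stop("no variants to tabulate")
  lv <- c("exonic", "promoter", "intronic", "intergenic")
  counts <- table(factor(labels, levels = lv))
  as.vector(counts / sum(counts)) |> stats::setNames(lv)
}
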