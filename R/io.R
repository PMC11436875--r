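gt_string <- function(code) {
  c("0/0", "0/1", "1/1")[code + 1L] |>
    (\(x) ifelse(is.na(x), "./.", x))()
}

fmt_af <- function(x) {
  ifelse(is.na(x), ".", sprintf("%.6g", x))
}

#' Write a variant set as VCF v4.2
#'
#' Serializes a biallelic [variant_set()] with `GT:GQ:AD` FORMAT and INFO
#' keys `COHORT_AF`, `GNOMAD_AF`, `TOPMED_AF`, `GERP`. Output is plain text
#' and byte-stable for identical inputs.
#'
#' @param vs A [variant_set()].
#' @param path Output path.
#' @param chrom_lengths Optional named vector for `##contig` headers.
#' @export
write_vcf <- function(vs, path, chrom_lengths = NULL) {
  v <- vs$variants
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=ncmendel",
    if (!is.null(chrom_lengths)) {
      sprintf("##contig=<ID=%s,length=%d>", names(chrom_lengths),
              as.integer(chrom_lengths))
    },
    "##INFO=<ID=COHORT_AF,Number=A,Type=Float,Description=\"Cohort allele frequency\">",
    "##INFO=<ID=GNOMAD_AF,Number=A,Type=Float,Description=\"gnomAD allele frequency\">",
    "##INFO=<ID=TOPMED_AF,Number=A,Type=Float,Description=\"TOPMed allele frequency\">",
    "##INFO=<ID=GERP,Number=1,Type=Float,Description=\"GERP conservation score\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", vs$samples), collapse = "\t")
  )
  info <- sprintf("COHORT_AF=%s;GNOMAD_AF=%s;TOPMED_AF=%s;GERP=%s",
                  fmt_af(v$cohort_af), fmt_af(v$gnomad_af),
                  fmt_af(v$topmed_af), fmt_af(v$gerp))
  sample_cols <- vapply(seq_along(vs$samples), function(s) {
    sprintf("%s:%d:%d,%d", gt_string(vs$gt[, s]),
            as.integer(vs$gq[, s]), as.integer(vs$ad_ref[, s]),
            as.integer(vs$ad_alt[, s]))
  }, character(nrow(v)))
  sample_cols <- matrix(sample_cols, nrow = nrow(v))
  body <- paste(
    v$chrom, v$pos, v$var_id, v$ref, v$alt, ".", v$filter_status, info,
    "GT:GQ:AD",
    apply(sample_cols, 1, paste, collapse = "\t"),
    sep = "\t"
  )
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write every file of a simulated cohort
#'
#' Emits the PED file, VCF, SV and TE TSV tables, per-cell-type atlas BEDs,
#' family metadata TSV, and the truth set as JSON into a directory.
#'
#' @param cohort A `ccdd_cohort` from [simulate_cohort()].
#' @param dir Output directory (created if absent).
#' @return Named vector of written paths.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    ped = file.path(dir, "cohort.ped"),
    vcf = file.path(dir, "cohort.vcf"),
    sv = file.path(dir, "sv_calls.tsv"),
    te = file.path(dir, "te_calls.tsv"),
    families = file.path(dir, "families.tsv"),
    truth = file.path(dir, "truth.json")
  )
  write_ped(cohort$ped, paths["ped"])
  write_vcf(cohort$vs, paths["vcf"],
            chrom_lengths = cohort$config$chrom_lengths)
  utils::write.table(cohort$sv, paths["sv"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(cohort$te, paths["te"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(cohort$families, paths["families"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  for (ct in names(cohort$atlas$sets)) {
    bp <- file.path(dir, sprintf("atlas_%s.bed", gsub("/", "_", ct)))
    write_bed(cohort$atlas$sets[[ct]], bp)
    paths[paste0("atlas_", ct)] <- bp
  }
  jsonlite::write_json(cohort$truth, paths["truth"], dataframe = "rows",
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  paths
}
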