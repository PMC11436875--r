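write_test_vcf <- function(lines) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=COHORT_AF,Number=A,Type=Float,Description=\"x\">",
    "##INFO=<ID=GNOMAD_AF,Number=A,Type=Float,Description=\"x\">",
    "##INFO=<ID=TOPMED_AF,Number=A,Type=Float,Description=\"x\">",
    "##INFO=<ID=GERP,Number=1,Type=Float,Description=\"x\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"x\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"x\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"x\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "s1", "s2"), collapse = "\t")
  )
  f <- tempfile(fileext = ".vcf")
  writeLines(c(hdr, lines), f)
  f
}

test_that("spanning-deletion alleles are dropped on splitting", {
  f <- write_test_vcf(paste(
    "chr1", 100, ".", "G", "A,*", ".", "PASS",
    "COHORT_AF=0.01,0.02;GNOMAD_AF=1e-4,2e-4;TOPMED_AF=1e-4,2e-4;GERP=3.5",
    "GT:GQ:AD", "0/1:50:10,8,0", "0/2:40:12,0,5", sep = "\t"))
  vs <- split_multiallelic(read_vcf(f))
  expect_equal(nrow(vs$variants), 1L)
  expect_equal(vs$variants$alt, "A")
  expect_equal(vs$variants$gnomad_af, 1e-4)
  # s2 carried only the spanning deletion: hom ref against the kept alt
  expect_equal(unname(vs$gt[1, ]), c(1L, 0L))
})

test_that("biallelic input round-trips through splitting unchanged", {
  f <- write_test_vcf(paste(
    "chr2", 500, ".", "T", "C", ".", "PASS",
    "COHORT_AF=0.001;GNOMAD_AF=5e-4;TOPMED_AF=0;GERP=2.5",
    "GT:GQ:AD", "1/1:60:0,20", "./.:.:.", sep = "\t"))
  vs <- split_multiallelic(read_vcf(f))
  expect_equal(nrow(vs$variants), 1L)
  expect_equal(unname(vs$gt[1, ]), c(2L, NA_integer_))
  expect_equal(unname(vs$ad_alt[1, 1]), 20L)
  expect_equal(vs$variants$var_class, "SNV")
})

test_that("multi-allelic genotype recoding matches the hand-worked table", {
  # alts A,T; every diploid combination of alleles 0,1,2
  gts <- c("0/0", "0/1", "0/2", "1/1", "1/2", "2/2")
  lines <- vapply(seq_along(gts), function(i) paste(
    "chr1", 100 * i, ".", "G", "A,T", ".", "PASS",
    "COHORT_AF=0.01,0.02;GNOMAD_AF=1e-4,2e-4;TOPMED_AF=0,0;GERP=3",
    "GT:GQ:AD", paste0(gts[i], ":50:10,5,3"), "0/0:60:18,0,0",
    sep = "\t"), character(1))
  vs <- split_multiallelic(read_vcf(write_test_vcf(lines)))
  expect_equal(nrow(vs$variants), 12L)
  # per input genotype: (code vs alt1, code vs alt2)
  expected <- rbind(c(0, 0), c(1, 0), c(0, 1), c(2, 0), c(1, 1), c(0, 2))
  got <- matrix(vs$gt[, "s1"], ncol = 2, byrow = TRUE)
  expect_equal(unname(got), unname(expected))
  # alt-specific AFs follow allele order
  expect_equal(unique(vs$variants$gnomad_af[vs$variants$alt == "A"]), 1e-4)
  expect_equal(unique(vs$variants$gnomad_af[vs$variants$alt == "T"]), 2e-4)
  # AD recoding: ref side is total minus the current alt's depth
  expect_equal(unname(vs$ad_alt[1:2, "s1"]), c(5L, 3L))
  expect_equal(unname(vs$ad_ref[1:2, "s1"]), c(13L, 15L))
  # splitting preserves the total number of non-spanning alternates
  expect_equal(nrow(vs$variants), length(gts) * 2L)
})

test_that("hard filters implement the AF/GERP/FILTER gates per mode class", {
  vs <- make_vs(list(c(s1 = 1L)), gnomad_af = 5e-4, topmed_af = 0,
                gerp = 3.1)
  d <- apply_hard_filters(vs, "monoallelic", gq = 45, ab = 0.42)
  expect_true(d$passed)
  expect_identical(d$reasons, "")

  vs2 <- make_vs(list(c(s1 = 1L)), gnomad_af = 2e-3)
  d2 <- apply_hard_filters(vs2, "monoallelic")
  expect_false(d2$passed)
  expect_match(d2$reasons, "gnomad_af")
  # the same variant passes the biallelic AF class
  expect_true(apply_hard_filters(vs2, "biallelic")$passed)

  # every failed rule is enumerated
  vs3 <- make_vs(list(c(s1 = 1L)), gnomad_af = 0.5, topmed_af = 0.5,
                 gerp = 0, filter_status = "LowQual")
  expect_setequal(
    strsplit(apply_hard_filters(vs3, "biallelic")$reasons, ",")[[1]],
    c("gnomad_af", "topmed_af", "gerp", "filter_status"))

  # missing AF counts as 0 (absent from the panels)
  vs4 <- make_vs(list(c(s1 = 1L)))
  vs4$variants$gnomad_af <- NA_real_
  expect_true(apply_hard_filters(vs4, "monoallelic")$passed)
})

test_that("relaxing any single threshold never removes a passing variant", {
  set.seed(21)
  n <- 200
  vs <- make_vs(lapply(seq_len(n), function(i) c(s1 = 1L)),
                gnomad_af = 10^runif(n, -5, -0.5),
                topmed_af = 10^runif(n, -5, -0.5),
                gerp = runif(n, -2, 6),
                filter_status = sample(c("PASS", "LowQual"), n,
                                       replace = TRUE, prob = c(.8, .2)))
  base <- ccdd_defaults()
  pass0 <- apply_hard_filters(vs, "monoallelic", thresholds = base)$passed
  for (knob in c("af_max_monoallelic", "gerp_min")) {
    relaxed <- base
    relaxed[[knob]] <- if (knob == "gerp_min") base[[knob]] - 1 else
      base[[knob]] * 10
    pass1 <- apply_hard_filters(vs, "monoallelic",
                                thresholds = relaxed)$passed
    expect_true(all(pass1[pass0]))
  }
})

test_that("genotype gates enforce GQ and het allele balance", {
  thr <- ccdd_defaults()
  expect_true(genotype_passes(1L, 50, 22, 18, thr))
  expect_false(genotype_passes(1L, 15, 22, 18, thr))     # GQ too low
  expect_false(genotype_passes(1L, 50, 36, 4, thr))      # AB 0.10
  expect_true(genotype_passes(0L, 50, 40, 0, thr))       # hom ref: no AB
  expect_false(genotype_passes(NA_integer_, 50, 20, 20, thr))
  thr$ab_symmetric <- TRUE
  expect_false(genotype_passes(1L, 50, 4, 36, thr))      # 1 - AB = 0.10
})

test_that("context classification follows the precedence order", {
  gm <- gene_model(
    genes = data.frame(
      gene_id = c("A", "B"), chrom = "chr1",
      start = c(10000, 14000), end = c(13000, 20000),
      strand = c("+", "+"), tss = c(10000, 14000)),
    exons = data.frame(gene_id = c("A", "B"), chrom = "chr1",
                       start = c(10000, 14000), end = c(10500, 14200))
  )
  # inside an exon
  expect_equal(classify_context(data.frame(chrom = "chr1", pos = 10101), gm),
               "exonic")
  # promoter window of B (TSS 14000, -2000) overlapping intron of A
  expect_equal(classify_context(data.frame(chrom = "chr1", pos = 12501), gm),
               "promoter")
  # intron of A outside both promoter windows... position 0-based 11000
  gm2 <- gene_model(genes = gm$genes[1, ], exons = gm$exons[1, ])
  expect_equal(classify_context(data.frame(chrom = "chr1", pos = 12901), gm2),
               "intronic")
  expect_equal(classify_context(data.frame(chrom = "chr1", pos = 999999), gm),
               "intergenic")
  expect_warning(
    lab <- classify_context(data.frame(chrom = "chr9", pos = 500), gm),
    "absent")
  expect_equal(lab, "intergenic")
})

test_that("context fractions partition the variant set", {
  expect_equal(
    unname(tabulate_context_fractions(
      c("exonic", "promoter", "intronic", "intergenic"))),
    rep(0.25, 4))
  expect_equal(
    tabulate_context_fractions(
      c("exonic", "exonic", "intronic", "intergenic"))[["exonic"]], 0.5)
  expect_error(tabulate_context_fractions(character(0)), "no variants")
  # random draw matches its probabilities within a binomial bound
  set.seed(5)
  probs <- c(exonic = 0.021, promoter = 0.007, intronic = 0.342,
             intergenic = 0.63)
  labs <- sample(names(probs), 10000, replace = TRUE, prob = probs)
  fr <- tabulate_context_fractions(labs)
  expect_true(all(abs(fr[names(probs)] - probs) < 0.02))
  expect_equal(sum(fr), 1)
})

test_that("a simulated cohort round-trips through VCF on disk", {
  co <- simulate_cohort(small_sim_config(seed = 9))
  f <- tempfile(fileext = ".vcf")
  write_vcf(co$vs, f, chrom_lengths = co$config$chrom_lengths)
  back <- split_multiallelic(read_vcf(f))
  expect_equal(back$variants$var_id, co$vs$variants$var_id)
  expect_equal(unname(back$gt), unname(co$vs$gt))
  expect_equal(back$variants$gnomad_af, co$vs$variants$gnomad_af,
               tolerance = 1e-5)
  expect_equal(back$variants$filter_status, co$vs$variants$filter_status)
})
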