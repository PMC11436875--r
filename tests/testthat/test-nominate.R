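test_that("planted candidates are recovered with precision = recall = 1", {
  for (seed in c(1, 7, 19)) {
    co <- simulate_cohort(small_sim_config(seed = seed))
    cand <- nominate_candidates(co, co$atlas, co$config$disease_map)
    tk <- truth_keys(co$truth$candidates)
    ck <- candidate_keys(cand[cand$var_class == "SNV_indel", ])
    expect_setequal(ck, tk)
    # planted SV/TE (none configured by default): no spurious calls
    expect_equal(nrow(cand[cand$var_class != "SNV_indel", ]), 0L)
  }
})

test_that("candidates are a subset of hard-filter survivors", {
  co <- simulate_cohort(small_sim_config(seed = 5))
  cand <- nominate_candidates(co, co$atlas, co$config$disease_map)
  snv <- cand[cand$var_class == "SNV_indel", ]
  bi <- apply_hard_filters(co$vs, "biallelic")$passed
  expect_true(all(bi[snv$var_idx]))
})

test_that("a candidate outside the disease peaks is never nominated", {
  co <- simulate_cohort(small_sim_config(seed = 4))
  # move one planted de novo far away from every peak
  tr <- co$truth$candidates[co$truth$candidates$mode == "de_novo", ][1, ]
  idx <- match(tr$var_id, co$vs$variants$var_id)
  all_iv <- do.call(rbind, lapply(co$atlas$sets, function(d) {
    d[, c("chrom", "start", "end")]
  }))
  co$vs$variants$pos[idx] <- max(all_iv$end) + 100000
  cand <- nominate_candidates(co, co$atlas, co$config$disease_map)
  expect_false(tr$var_id %in% cand$var_id)
})

test_that("blocklisted families are absent from the candidate set", {
  co <- simulate_cohort(small_sim_config(seed = 4))
  thr <- ccdd_defaults()
  fam <- co$truth$candidates$family_id[1]
  thr$family_blocklist <- fam
  cand <- nominate_candidates(co, co$atlas, co$config$disease_map, thr)
  expect_false(fam %in% cand$family_id)
})

test_that("planted SVs and TEs pass their class-specific gates", {
  cfg <- small_sim_config(
    seed = 10,
    planted_sv = list(list(family = "F001_DRS", mode = "dominant",
                           cell_type = "cMN6", peak_index = 2,
                           type = "DEL", len = 4000)),
    planted_te = list(list(family = "F002_DRS", mode = "de_novo",
                           cell_type = "cMN6", peak_index = 3,
                           te_family = "Alu")))
  co <- simulate_cohort(cfg)
  cand <- nominate_candidates(co, co$atlas, cfg$disease_map)
  expect_true(all(truth_keys(co$truth$sv) %in% candidate_keys(cand)))
  expect_true(all(truth_keys(co$truth$te) %in% candidate_keys(cand)))
  # a de novo TE with nonzero gnomAD AF is gated out (de novo gate is 0)
  co2 <- co
  co2$te$gnomad_af[co2$te$family_id == "F002_DRS" &
                     co2$te$mode == "de_novo"] <- 0.001
  cand2 <- nominate_candidates(co2, co2$atlas, cfg$disease_map)
  expect_false(any(truth_keys(co$truth$te) %in% candidate_keys(cand2)))
})

test_that("multi-hit peaks require two families sharing the broad mode", {
  base <- data.frame(
    family_id = c("F1", "F2"), var_id = c("v1", "v2"),
    var_class = "SNV_indel", mode = c("de_novo", "dominant"),
    peak_id = "pk1", partner_var_id = NA_character_,
    disease_group = "DRS", var_idx = 1:2, sv_len = NA_real_,
    partner_idx = NA_integer_, stringsAsFactors = FALSE)
  mh <- find_multihit_peaks(base)
  expect_equal(nrow(mh), 1L)
  expect_equal(mh$broad_mode, "dominant")
  expect_equal(mh$n_families, 2L)
  # dominant + recessive in the same peak do not aggregate
  mixed <- base; mixed$mode <- c("dominant", "homozygous_recessive")
  expect_equal(nrow(find_multihit_peaks(mixed)), 0L)
  # one family with two variants is not multi-hit
  dup <- base; dup$family_id <- c("F1", "F1")
  expect_equal(nrow(find_multihit_peaks(dup)), 0L)
  # an oversized SV is dropped before tabulation
  sv <- base
  sv$var_class <- c("SNV_indel", "SV")
  sv$sv_len <- c(NA, 250000)
  expect_equal(nrow(find_multihit_peaks(sv)), 0L)
  sv$sv_len <- c(NA, 50000)
  expect_equal(nrow(find_multihit_peaks(sv)), 1L)
})

test_that("planted multi-hit peaks are recovered and nothing else", {
  cfg <- small_sim_config(
    seed = 14,
    planted_multihit = list(
      list(cell_type = "cMN6", peak_index = 9,
           families = c("F001_DRS", "F002_DRS"), mode = "dominant")))
  co <- simulate_cohort(cfg)
  cand <- nominate_candidates(co, co$atlas, cfg$disease_map)
  mh <- find_multihit_peaks(cand)
  expect_true(all(co$truth$multihit_peaks$peak_id %in% mh$peak_id))
  got <- mh[mh$peak_id %in% co$truth$multihit_peaks$peak_id, ]
  expect_equal(got$families, co$truth$multihit_peaks$families)
  expect_equal(got$broad_mode, co$truth$multihit_peaks$broad_mode)
  # every reported peak has >= 2 families
  expect_true(all(mh$n_families >= 2))
})

test_that("multi-hit genes need two linked candidate-bearing peaks", {
  links <- data.frame(peak_id = c("pk1", "pk2", "pk3"),
                      gene_id = c("gA", "gA", "gB"),
                      r = 0.5, p = 1e-9, fdr = 1e-8, distance = 100)
  cand <- data.frame(
    family_id = c("F1", "F2", "F3"),
    var_id = c("v1", "v2", "v3"), var_class = "SNV_indel",
    mode = c("dominant", "de_novo", "dominant"),
    peak_id = c("pk1", "pk2", "pk3"),
    partner_var_id = NA_character_, disease_group = "DRS",
    var_idx = 1:3, sv_len = NA_real_, partner_idx = NA_integer_,
    stringsAsFactors = FALSE)
  mg <- find_multihit_genes(cand, links)
  expect_equal(mg$gene_id, "gA")
  expect_equal(mg$n_peaks, 2L)
  expect_equal(mg$n_variants, 2L)
  # one peak with several candidates is not multi-hit
  cand1 <- cand; cand1$peak_id <- "pk1"
  expect_equal(nrow(find_multihit_genes(cand1, links)), 0L)
  # a recessive candidate does not count toward the dominant definition
  cand2 <- cand; cand2$mode[2] <- "homozygous_recessive"
  expect_equal(nrow(find_multihit_genes(cand2, links)), 0L)
})

test_that("Fisher 2x2 matches hypergeometric enumeration", {
  res <- fisher_exact_2x2(rbind(c(10, 2), c(4, 8)))
  expect_equal(res$odds_ratio, 10)
  # independent enumeration over tables with fixed margins
  enum_p <- function(tab) {
    m <- rowSums(tab); k <- colSums(tab)
    pr <- function(a) {
      choose(m[1], a) * choose(m[2], k[1] - a) / choose(sum(m), k[1])
    }
    av <- max(0, k[1] - m[2]):min(m[1], k[1])
    probs <- vapply(av, pr, numeric(1))
    obs <- pr(tab[1, 1])
    sum(probs[probs <= obs * (1 + 1e-7)])
  }
  expect_equal(res$p_two_sided, enum_p(rbind(c(10, 2), c(4, 8))),
               tolerance = 1e-9)
  sym <- fisher_exact_2x2(rbind(c(5, 5), c(5, 5)))
  expect_equal(sym$odds_ratio, 1)
  expect_equal(sym$p_two_sided, 1)
  set.seed(9)
  for (rep in 1:60) {
    tab <- matrix(sample(0:10, 4, replace = TRUE), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(fisher_exact_2x2(tab)$p_two_sided, enum_p(tab),
                 tolerance = 1e-9)
  }
  expect_error(fisher_exact_2x2(rbind(c(0, 0), c(1, 2))), "margin")
})

test_that("SAD Z-scores use the SNV null and are affine-invariant", {
  sc <- data.frame(var_id = c("a", "b", "c", "d"),
                   var_class = c("SNV", "SNV", "SNV", "indel"),
                   raw_sad = c(-1, 0, 1, 3))
  z <- sad_zscores(sc)
  expect_equal(z$sad_z[2], 0)            # at the SNV mean
  expect_equal(z$sad_z[4], 3)            # indel scored on the SNV null
  expect_equal(z$significant, c(FALSE, FALSE, FALSE, TRUE))
  # affine transform of the raw scores leaves z unchanged
  sc2 <- sc; sc2$raw_sad <- 5 * sc$raw_sad + 7
  expect_equal(sad_zscores(sc2)$sad_z, z$sad_z)
  # normal tail mass beyond |z| > 2
  set.seed(15)
  big <- data.frame(var_id = as.character(1:4000), var_class = "SNV",
                    raw_sad = rnorm(4000))
  frac <- mean(sad_zscores(big)$significant)
  expect_lt(abs(frac - 0.0455), 0.02)
  expect_error(sad_zscores(data.frame(var_class = "SNV", raw_sad = 1)),
               ">= 2 SNV")
  expect_error(sad_zscores(data.frame(var_class = c("SNV", "SNV"),
                                      raw_sad = c(1, 1))), "zero variance")
})

test_that("validation summaries round to integer percents", {
  t <- summarize_validation(data.frame(
    label = c("reporter", "overall", "none"),
    positive = c(17, 44, 0), total = c(26, 59, 10)))
  expect_equal(t$percent, c(65, 75, 0))
  expect_error(summarize_validation(data.frame(positive = 2, total = 0)))
  expect_error(summarize_validation(data.frame(positive = 5, total = 3)))
})
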