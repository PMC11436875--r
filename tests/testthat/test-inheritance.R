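test_that("de novo caller matches the rule table over all trio genotypes", {
  codes <- c(0L, 1L, 2L, NA_integer_)
  combos <- expand.grid(child = codes, father = codes, mother = codes)
  for (i in seq_len(nrow(combos))) {
    gt <- c(F1_fa = combos$father[i], F1_mo = combos$mother[i],
            F1_ch = combos$child[i])
    vs <- make_vs(list(gt))
    got <- call_de_novo(vs, "F1_ch", "F1_fa", "F1_mo")
    # independent restatement: child het, both parents hom ref, no missing
    want <- !is.na(combos$child[i]) && combos$child[i] == 1L &&
      !is.na(combos$father[i]) && combos$father[i] == 0L &&
      !is.na(combos$mother[i]) && combos$mother[i] == 0L
    expect_identical(unname(got), want)
  }
})

test_that("de novo caller enforces the genotype quality gates", {
  gt <- c(F1_fa = 0L, F1_mo = 0L, F1_ch = 1L)
  expect_true(call_de_novo(make_vs(list(gt)), "F1_ch", "F1_fa", "F1_mo"))
  # low child GQ
  vs <- make_vs(list(gt), gq = 10)
  expect_false(call_de_novo(vs, "F1_ch", "F1_fa", "F1_mo"))
  # skewed child allele balance (alt depth 4/40 = 0.10)
  vs2 <- make_vs(list(gt))
  vs2$ad_alt[1, "F1_ch"] <- 4L
  vs2$ad_ref[1, "F1_ch"] <- 36L
  expect_false(call_de_novo(vs2, "F1_ch", "F1_fa", "F1_mo"))
})

test_that("dominant search handles penetrance modes", {
  ped <- rbind(
    trio_ped("F1", father_affected = TRUE),
    data.frame(family_id = "F1", individual_id = "F1_s1",
               father_id = "F1_fa", mother_id = "F1_mo", sex = 2L,
               affected = FALSE)
  )
  # 2 affecteds het, unaffecteds hom ref -> nominated
  vs <- make_vs(list(c(F1_fa = 1L, F1_mo = 0L, F1_ch = 1L, F1_s1 = 0L)))
  expect_equal(nrow(find_dominant(vs, ped, "F1")), 1L)
  # an unaffected het carrier blocks the standard mode only
  vs2 <- make_vs(list(c(F1_fa = 1L, F1_mo = 0L, F1_ch = 1L, F1_s1 = 1L)))
  expect_equal(nrow(find_dominant(vs2, ped, "F1")), 0L)
  ip <- find_dominant(vs2, ped, "F1", incomplete_penetrance = TRUE)
  expect_equal(nrow(ip), 1L)
  expect_equal(ip$mode, "dominant_incomplete_penetrance")
  # an affected non-carrier blocks both modes
  vs3 <- make_vs(list(c(F1_fa = 0L, F1_mo = 0L, F1_ch = 1L, F1_s1 = 0L)))
  expect_equal(nrow(find_dominant(vs3, ped, "F1")), 0L)
  expect_equal(nrow(find_dominant(vs3, ped, "F1",
                                  incomplete_penetrance = TRUE)), 0L)
})

test_that("homozygous-recessive search requires carrier parents", {
  ped <- trio_ped("F1")
  # proband 1/1, parents 0/1 x 0/1 -> nominated
  vs <- make_vs(list(c(F1_fa = 1L, F1_mo = 1L, F1_ch = 2L)))
  expect_equal(nrow(find_homozygous_recessive(vs, ped, "F1")), 1L)
  # hom-ref father is inheritance-inconsistent
  vs2 <- make_vs(list(c(F1_fa = 0L, F1_mo = 1L, F1_ch = 2L)))
  expect_equal(nrow(find_homozygous_recessive(vs2, ped, "F1")), 0L)
  # unaffected hom-alt sib blocks
  ped2 <- rbind(ped, data.frame(
    family_id = "F1", individual_id = "F1_s1", father_id = "F1_fa",
    mother_id = "F1_mo", sex = 2L, affected = FALSE))
  vs3 <- make_vs(list(c(F1_fa = 1L, F1_mo = 1L, F1_ch = 2L, F1_s1 = 2L)))
  expect_equal(nrow(find_homozygous_recessive(vs3, ped2, "F1")), 0L)
})

test_that("compound hets pair variants across parents within one peak", {
  ped <- trio_ped("F1")
  peaks <- data.frame(chrom = "chr1", start = c(0, 5000),
                      end = c(2000, 7000), peak_id = c("pkA", "pkB"))
  # v1 paternal, v2 maternal, same peak, child het at both
  vs <- make_vs(list(
    c(F1_fa = 1L, F1_mo = 0L, F1_ch = 1L),
    c(F1_fa = 0L, F1_mo = 1L, F1_ch = 1L)
  ), pos = c(100, 200))
  pairs <- find_compound_het(vs, ped, "F1", peaks)
  expect_equal(nrow(pairs), 1L)
  expect_equal(pairs$var_id, "v1")
  expect_equal(pairs$partner_var_id, "v2")
  expect_equal(pairs$peak_id, "pkA")
  # different peaks -> no pair
  vs2 <- make_vs(list(
    c(F1_fa = 1L, F1_mo = 0L, F1_ch = 1L),
    c(F1_fa = 0L, F1_mo = 1L, F1_ch = 1L)
  ), pos = c(100, 5200))
  expect_equal(nrow(find_compound_het(vs2, ped, "F1", peaks)), 0L)
  # both variants paternal -> no pair
  vs3 <- make_vs(list(
    c(F1_fa = 1L, F1_mo = 0L, F1_ch = 1L),
    c(F1_fa = 1L, F1_mo = 0L, F1_ch = 1L)
  ), pos = c(100, 200))
  expect_equal(nrow(find_compound_het(vs3, ped, "F1", peaks)), 0L)
  # ambiguous origin (both parents carriers) is skipped with a warning
  vs4 <- make_vs(list(
    c(F1_fa = 1L, F1_mo = 1L, F1_ch = 1L),
    c(F1_fa = 0L, F1_mo = 1L, F1_ch = 1L)
  ), pos = c(100, 200))
  expect_warning(pairs4 <- find_compound_het(vs4, ped, "F1", peaks),
                 "ambiguous")
  expect_equal(nrow(pairs4), 0L)
})

test_that("cohort exclusion distinguishes het and homozygous carriers", {
  ped <- rbind(trio_ped("F1"), trio_ped("F2", child_affected = FALSE))
  # unrelated unaffected het carrier F2_ch
  vs <- make_vs(list(c(F1_fa = 0L, F1_mo = 0L, F1_ch = 1L,
                       F2_fa = 0L, F2_mo = 0L, F2_ch = 1L)))
  dom_call <- data.frame(family_id = "F1", var_idx = 1L, var_id = "v1",
                         mode = "de_novo", stringsAsFactors = FALSE)
  expect_equal(nrow(apply_cohort_exclusion(dom_call, vs, ped)), 0L)
  rec_call <- dom_call; rec_call$mode <- "homozygous_recessive"
  # het carrier does not trigger the recessive exclusion
  expect_equal(nrow(apply_cohort_exclusion(rec_call, vs, ped)), 1L)
  # but a homozygous unaffected carrier does
  vs2 <- make_vs(list(c(F1_fa = 0L, F1_mo = 0L, F1_ch = 1L,
                        F2_fa = 0L, F2_mo = 0L, F2_ch = 2L)))
  expect_equal(nrow(apply_cohort_exclusion(rec_call, vs2, ped)), 0L)
  # incomplete-penetrance family's own unaffected carrier is exempt
  vs3 <- make_vs(list(c(F1_fa = 1L, F1_mo = 0L, F1_ch = 1L,
                        F2_fa = 0L, F2_mo = 0L, F2_ch = 0L)))
  ip_call <- dom_call; ip_call$mode <- "dominant_incomplete_penetrance"
  expect_equal(nrow(apply_cohort_exclusion(ip_call, vs3, ped,
                                           ip_families = "F1")), 1L)
  expect_equal(nrow(apply_cohort_exclusion(ip_call, vs3, ped)), 0L)
})

test_that("searches equal a brute-force oracle on random small pedigrees", {
  set.seed(99)
  for (rep in 1:300) {
    n_kids <- sample(1:4, 1)
    ids <- c("fa", "mo", paste0("k", seq_len(n_kids)))
    ped <- data.frame(
      family_id = "F1", individual_id = ids,
      father_id = c("0", "0", rep("fa", n_kids)),
      mother_id = c("0", "0", rep("mo", n_kids)),
      sex = c(1L, 2L, sample(1:2, n_kids, replace = TRUE)),
      affected = c(sample(c(TRUE, FALSE), 2, replace = TRUE),
                   sample(c(TRUE, FALSE), n_kids, replace = TRUE)),
      stringsAsFactors = FALSE
    )
    if (!any(ped$affected)) ped$affected[3] <- TRUE
    n_var <- sample(1:4, 1)
    gts <- lapply(seq_len(n_var), function(i) {
      stats::setNames(sample(0:2, length(ids), replace = TRUE), ids)
    })
    vs <- make_vs(gts)
    aff <- ped$individual_id[ped$affected]
    unaff <- ped$individual_id[!ped$affected]

    dom_oracle <- which(vapply(seq_len(n_var), function(v) {
      all(vs$gt[v, aff] >= 1) && all(vs$gt[v, unaff] == 0)
    }, logical(1)))
    expect_equal(find_dominant(vs, ped, "F1")$var_idx, dom_oracle)

    dom_ip_oracle <- which(vapply(seq_len(n_var), function(v) {
      all(vs$gt[v, aff] >= 1)
    }, logical(1)))
    expect_equal(
      find_dominant(vs, ped, "F1", incomplete_penetrance = TRUE)$var_idx,
      dom_ip_oracle)

    rec_oracle <- which(vapply(seq_len(n_var), function(v) {
      ok <- all(vs$gt[v, aff] == 2) && all(vs$gt[v, unaff] != 2)
      for (a in aff) {
        pa <- ped[ped$individual_id == a, ]
        if (pa$father_id != "0") {
          ok <- ok && vs$gt[v, pa$father_id] >= 1 &&
            vs$gt[v, pa$mother_id] >= 1
        }
      }
      ok
    }, logical(1)))
    expect_equal(find_homozygous_recessive(vs, ped, "F1")$var_idx,
                 rec_oracle)
  }
})

test_that("compound-het pairs match an exhaustive pair scan", {
  set.seed(123)
  peaks <- data.frame(chrom = "chr1", start = c(0, 3000),
                      end = c(2000, 6000), peak_id = c("pkA", "pkB"))
  ped <- trio_ped("F1")
  for (rep in 1:200) {
    n_var <- sample(2:5, 1)
    pos <- sample(c(100, 500, 900, 3500, 4200, 5100, 9000), n_var)
    gts <- lapply(seq_len(n_var), function(i) {
      c(F1_fa = sample(0:2, 1), F1_mo = sample(0:2, 1),
        F1_ch = sample(0:2, 1))
    })
    vs <- make_vs(gts, pos = pos)
    got <- suppressWarnings(find_compound_het(vs, ped, "F1", peaks))
    peak_at <- function(p) {
      j <- which(p - 1 >= peaks$start & p - 1 < peaks$end)
      if (length(j)) peaks$peak_id[j] else NA_character_
    }
    want <- list()
    for (a in seq_len(n_var)) for (b in seq_len(n_var)) {
      if (a == b) next
      pa <- peak_at(pos[a]); pb <- peak_at(pos[b])
      if (is.na(pa) || is.na(pb) || pa != pb) next
      g <- vs$gt
      if (g[a, "F1_ch"] == 1 && g[b, "F1_ch"] == 1 &&
          g[a, "F1_fa"] >= 1 && g[a, "F1_mo"] == 0 &&
          g[b, "F1_mo"] >= 1 && g[b, "F1_fa"] == 0) {
        want[[length(want) + 1]] <- c(a, b)
      }
    }
    want_keys <- vapply(want, paste, collapse = "-", FUN.VALUE = character(1))
    got_keys <- paste(got$var_idx, got$partner_idx, sep = "-")
    expect_setequal(got_keys, want_keys)
  }
})
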