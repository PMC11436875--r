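# Shared fixture builders and independent oracles.

# Compact variant_set builder: `gts` is a named list sample -> genotype
# vector (codes 0/1/2/NA), one entry per variant.
make_vs <- function(gts, chrom = "chr1", pos = NULL,
                    gnomad_af = 0, topmed_af = 0, gerp = 4,
                    filter_status = "PASS", gq = 60, ad_depth = 40) {
  samples <- names(gts[[1]])
  n <- length(gts)
  if (is.null(pos)) pos <- seq(1000, by = 1000, length.out = n)
  gt <- do.call(rbind, lapply(gts, function(x) unname(unlist(x))))
  variants <- data.frame(
    var_id = paste0("v", seq_len(n)),
    chrom = rep_len(chrom, n), pos = pos,
    ref = "A", alt = "T", var_class = "SNV",
    cohort_af = 0,
    gnomad_af = rep_len(gnomad_af, n),
    topmed_af = rep_len(topmed_af, n),
    gerp = rep_len(gerp, n),
    filter_status = rep_len(filter_status, n),
    stringsAsFactors = FALSE
  )
  gqm <- matrix(gq, n, length(samples))
  ad_alt <- matrix(0L, n, length(samples))
  ad_alt[gt == 1L] <- ad_depth %/% 2L
  ad_alt[gt == 2L] <- ad_depth
  ad_ref <- ad_depth - ad_alt
  variant_set(variants, gt, gqm, ad_ref, ad_alt, samples)
}

trio_ped <- function(family_id = "F1", child_affected = TRUE,
                     father_affected = FALSE, mother_affected = FALSE) {
  data.frame(
    family_id = family_id,
    individual_id = paste0(family_id, c("_fa", "_mo", "_ch")),
    father_id = c("0", "0", paste0(family_id, "_fa")),
    mother_id = c("0", "0", paste0(family_id, "_mo")),
    sex = c(1L, 2L, 1L),
    affected = c(father_affected, mother_affected, child_affected),
    stringsAsFactors = FALSE
  )
}

# Quadratic brute-force interval overlap (independent of GenomicRanges).
brute_point_overlap <- function(pts, iv) {
  hits <- list()
  for (i in seq_len(nrow(pts))) {
    p0 <- pts$pos[i] - 1  # 0-based
    for (j in seq_len(nrow(iv))) {
      if (pts$chrom[i] == iv$chrom[j] &&
          p0 >= iv$start[j] && p0 < iv$end[j]) {
        hits[[length(hits) + 1]] <- c(i, j)
      }
    }
  }
  if (!length(hits)) return(matrix(integer(0), ncol = 2))
  do.call(rbind, hits)
}

brute_span_overlap <- function(spans, iv) {
  hits <- list()
  for (i in seq_len(nrow(spans))) {
    for (j in seq_len(nrow(iv))) {
      if (spans$chrom[i] == iv$chrom[j] &&
          spans$start[i] < iv$end[j] && spans$end[i] > iv$start[j]) {
        hits[[length(hits) + 1]] <- c(i, j)
      }
    }
  }
  if (!length(hits)) return(matrix(integer(0), ncol = 2))
  do.call(rbind, hits)
}

# Entropy-identity oracle for homogeneity/completeness: conditional
# entropies via the joint entropy, H(C|K) = H(C,K) - H(K), a different
# route than the per-cluster expansion used by the implementation.
oracle_hc <- function(classes, clusters) {
  n <- length(classes)
  ent <- function(x) {
    p <- table(x) / n
    -sum(p * log(p))
  }
  h_c <- ent(classes); h_k <- ent(clusters)
  h_ck <- ent(paste(classes, clusters, sep = "\r"))
  h_c_given_k <- h_ck - h_k
  h_k_given_c <- h_ck - h_c
  h <- if (abs(h_c_given_k) < 1e-12) 1 else 1 - h_c_given_k / h_c
  cc <- if (abs(h_k_given_c) < 1e-12) 1 else 1 - h_k_given_c / h_k
  list(h = h, c = cc, v = if (h + cc == 0) 0 else 2 * h * cc / (h + cc))
}

# Direct pmf-enumeration oracle for the two-sided exact binomial p-value,
# built from choose() arithmetic rather than dbinom.
oracle_binom_p <- function(k, n, pi0 = 0.5) {
  pmf <- choose(n, 0:n) * pi0^(0:n) * (1 - pi0)^(n - (0:n))
  min(1, sum(pmf[pmf <= pmf[k + 1] * (1 + 1e-7)]))
}

# Tiny default sim config used across tests (2 disease groups, small
# genome) so each simulated cohort builds in well under a second.
small_sim_config <- function(seed = 1, ...) {
  args <- list(
    seed = seed,
    disease_groups = c("DRS", "CFP"),
    n_background_variants = 120,
    n_peaks_per_celltype = 15,
    n_background_sv = 6, n_background_te = 6,
    n_cells = 300, n_peaks = 40, n_genes = 20
  )
  user <- list(...)
  args[names(user)] <- user
  do.call(sim_config, args)
}

# Candidate/truth comparison keys; a compound-het candidate row covers its
# partner variant as well.
candidate_keys <- function(cand) {
  k <- paste(cand$family_id, cand$var_id, cand$mode)
  partner <- !is.na(cand$partner_var_id)
  c(k, paste(cand$family_id[partner], cand$partner_var_id[partner],
             cand$mode[partner]))
}

truth_keys <- function(truth) {
  paste(truth$family_id, truth$var_id, truth$mode)
}
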