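#' Aggregate cells into metacell profiles
#'
#' Sums the cell x peak and cell x gene matrices within cell groups to
#' obtain paired aggregate profiles, reducing single-cell sparsity before
#' correlation. Groups may be supplied directly, derived by k-means on an
#' embedding, or drawn at random.
#'
#' @param peak_mat Numeric matrix, cells x peaks.
#' @param gene_mat Numeric matrix, cells x genes (same cell order).
#' @param k_groups Number of aggregates.
#' @param grouping Optional factor/vector assigning each cell to a group
#'   (overrides `k_groups`).
#' @param embedding Optional cells x dims matrix; groups are k-means
#'   clusters on it.
#' @param seed Optional seed for the random/k-means grouping.
#' @return List with `peak_agg` (groups x peaks), `gene_agg` (groups x
#'   genes) and `groups` (assignment per cell).
#' @export
make_cell_aggregates <- function(peak_mat, gene_mat, k_groups = 100,
                                 grouping = NULL, embedding = NULL,
                                 seed = NULL) {
  stopifnot(nrow(peak_mat) == nrow(gene_mat))
  n_cells <- nrow(peak_mat)
  if (is.null(grouping)) {
    if (k_groups > n_cells) stop("k_groups exceeds the number of cells")
    if (!is.null(seed)) set.seed(seed)
    grouping <- if (!is.null(embedding)) {
      stats::kmeans(embedding, centers = k_groups, nstart = 3)$cluster
    } else {
      sample(rep_len(seq_len(k_groups), n_cells))
    }
  }
  grouping <- as.factor(grouping)
  agg <- function(m) {
    out <- rowsum(m, grouping)
    out[levels(grouping), , drop = FALSE]
  }
  list(peak_agg = agg(peak_mat), gene_agg = agg(gene_mat),
       groups = grouping)
}

peak_midpoints <- function(peaks) {
  floor((peaks$start + peaks$end) / 2)
}

#' Correlation-based peak-to-gene links
#'
#' For every (peak, gene) pair whose peak midpoint lies within `window` bp
#' of the gene's TSS, computes the Pearson correlation of accessibility and
#' expression across cell aggregates, a two-sided p-value via the
#' t-transform with n - 2 degrees of freedom, and Benjamini-Hochberg FDR
#' across all tested pairs in the run. Pairs are retained when the
#' correlation meets the minimum (one-sided positive by default, `r >=
#' r_min` when `r_inclusive`) at FDR below `fdr_max`. Zero-variance features
#' are skipped.
#'
#' @param aggregates Output of [make_cell_aggregates()].
#' @param peaks data.frame of peak coordinates (`peak_id`, `chrom`,
#'   `start`, `end`), rows matching `peak_agg` columns by `peak_id`.
#' @param genes data.frame of gene annotation (`gene_id`, `chrom`, `tss`
#'   0-based, `strand`), rows matching `gene_agg` columns by `gene_id`.
#' @param window TSS window in bp (default 500 kb).
#' @param r_min Minimum correlation (default 0.1).
#' @param fdr_max FDR ceiling (default 1e-4).
#' @param r_inclusive Retain at `r == r_min` (default TRUE).
#' @param two_sided_retention Retain on `|r|` instead of signed r.
#' @return data.frame of links: `peak_id`, `gene_id`, `r`, `p`, `fdr`,
#'   `distance` (signed peak midpoint minus TSS), plus attribute
#'   `n_tested`.
#' @export
compute_links <- function(aggregates, peaks, genes,
                          window = ccdd_defaults()$link_window,
                          r_min = ccdd_defaults()$link_r_min,
                          fdr_max = ccdd_defaults()$link_fdr_max,
                          r_inclusive = ccdd_defaults()$link_r_inclusive,
                          two_sided_retention = FALSE) {
  pa <- aggregates$peak_agg
  ga <- aggregates$gene_agg
  n <- nrow(pa)
  if (n < 3) stop("need at least 3 aggregates to correlate")
  stopifnot(all(peaks$peak_id %in% colnames(pa)),
            all(genes$gene_id %in% colnames(ga)))
  mid <- peak_midpoints(peaks)
  cand <- list()
  for (gi in seq_len(nrow(genes))) {
    same <- which(peaks$chrom == genes$chrom[gi])
    d <- mid[same] - genes$tss[gi]
    sel <- same[abs(d) <= window]
    if (length(sel)) {
      cand[[length(cand) + 1]] <- data.frame(
        peak_id = peaks$peak_id[sel],
        gene_id = genes$gene_id[gi],
        distance = mid[sel] - genes$tss[gi],
        stringsAsFactors = FALSE
      )
    }
  }
  empty <- data.frame(peak_id = character(0), gene_id = character(0),
                      r = numeric(0), p = numeric(0), fdr = numeric(0),
                      distance = numeric(0), stringsAsFactors = FALSE)
  if (!length(cand)) {
    attr(empty, "n_tested") <- 0L
    return(empty)
  }
  cand <- do.call(rbind, cand)
  x <- pa[, cand$peak_id, drop = FALSE]
  y <- ga[, cand$gene_id, drop = FALSE]
  sdx <- apply(x, 2, stats::sd)
  sdy <- apply(y, 2, stats::sd)
  testable <- sdx > 0 & sdy > 0
  cand <- cand[testable, , drop = FALSE]
  if (!nrow(cand)) {
    attr(empty, "n_tested") <- 0L
    return(empty)
  }
  x <- x[, testable, drop = FALSE]
  y <- y[, testable, drop = FALSE]
  r <- vapply(seq_len(nrow(cand)), function(i) {
    stats::cor(x[, i], y[, i])
  }, numeric(1))
  r_t <- pmin(pmax(r, -1 + 1e-15), 1 - 1e-15)
  tval <- r_t * sqrt((n - 2) / (1 - r_t^2))
  p <- 2 * stats::pt(-abs(tval), df = n - 2)
  fdr <- stats::p.adjust(p, method = "BH")
  links <- data.frame(cand[, c("peak_id", "gene_id")], r = r, p = p,
                      fdr = fdr, distance = cand$distance,
                      stringsAsFactors = FALSE)
  rg <- if (two_sided_retention) abs(links$r) else links$r
  pass_r <- if (r_inclusive) rg >= r_min else rg > r_min
  out <- links[pass_r & links$fdr < fdr_max, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_tested") <- nrow(links)
  out
}

#' Domain of regulatory chromatin (DORC) scores
#'
#' For every cell and gene, sums the cell's depth-normalized accessibility
#' (peak count divided by the cell's unique fragment count) over the gene's
#' linked peaks whose midpoint lies within `window` bp of the TSS. Genes
#' with no links score zero; the score is invariant to per-cell depth
#' rescaling.
#'
#' @param peak_mat Cells x peaks count matrix (columns named by peak id).
#' @param fragments Per-cell unique fragment counts (all > 0).
#' @param links Link table from [compute_links()].
#' @param peaks,genes Annotation data.frames as in [compute_links()].
#' @param window TSS window in bp (default 500 kb).
#' @return Cells x genes matrix of DORC scores.
#' @export
dorc_scores <- function(peak_mat, fragments, links, peaks, genes,
                        window = ccdd_defaults()$link_window) {
  if (any(fragments <= 0)) stop("all cells must have positive fragment counts")
  stopifnot(length(fragments) == nrow(peak_mat))
  norm <- peak_mat / fragments
  out <- matrix(0, nrow(peak_mat), nrow(genes),
                dimnames = list(rownames(peak_mat), genes$gene_id))
  if (!nrow(links)) return(out)
  mid <- stats::setNames(peak_midpoints(peaks), peaks$peak_id)
  pchrom <- stats::setNames(peaks$chrom, peaks$peak_id)
  for (gi in seq_len(nrow(genes))) {
    g <- genes$gene_id[gi]
    lp <- links$peak_id[links$gene_id == g]
    lp <- lp[pchrom[lp] == genes$chrom[gi] &
               abs(mid[lp] - genes$tss[gi]) <= window]
    if (length(lp)) {
      out[, g] <- rowSums(norm[, lp, drop = FALSE])
    }
  }
  out
}

#' Rank genes by their significant link count
#'
#' Tabulates significant links within a tight TSS window (default +/-50 kb).
#' A peak connected to multiple genes is counted once, for the link with the
#' lowest FDR (ties broken by larger absolute correlation, then
#' lexicographic gene id). Genes are ranked by descending link count, with a
#' top-percentile annotation.
#'
#' @param links Link table from [compute_links()].
#' @param window Tabulation window in bp (default 50 kb).
#' @param top_percent Percentile threshold for the `top_flag` column
#'   (default 1, i.e. top 1% of linked genes).
#' @return data.frame: `gene_id`, `n_links`, `rank`, `top_flag`, ordered by
#'   rank.
#' @export
rank_genes_by_links <- function(links,
                                window = ccdd_defaults()$gene_rank_window,
                                top_percent = 1) {
  lk <- links[abs(links$distance) <= window, , drop = FALSE]
  if (!nrow(lk)) {
    return(data.frame(gene_id = character(0), n_links = integer(0),
                      rank = integer(0), top_flag = logical(0)))
  }
  # one gene per peak: lowest FDR, then largest |r|, then gene id
  ord <- order(lk$peak_id, lk$fdr, -abs(lk$r), lk$gene_id)
  lk <- lk[ord, , drop = FALSE]
  lk <- lk[!duplicated(lk$peak_id), , drop = FALSE]
  counts <- sort(table(lk$gene_id), decreasing = TRUE)
  out <- data.frame(gene_id = names(counts),
                    n_links = as.integer(counts),
                    stringsAsFactors = FALSE)
  out$rank <- rank(-out$n_links, ties.method = "min")
  out$top_flag <- out$rank <= max(1, ceiling(nrow(out) * top_percent / 100))
  rownames(out) <- NULL
  out
}

#' Concordance of ABC predictions with peak-to-gene links
#'
#' Matched peak: the fraction of ABC enhancers whose interval overlaps any
#' linked peak, irrespective of the predicted cognate gene. Matched gene:
#' the fraction whose overlapping linked peak also shares the cognate gene.
#'
#' @param abc data.frame of ABC predictions: `chrom`, `start`, `end`,
#'   `gene_id`.
#' @param links Link table from [compute_links()].
#' @param peaks Peak coordinate data.frame (`peak_id`, `chrom`, `start`,
#'   `end`).
#' @return List with `matched_peak_fraction`, `matched_gene_fraction`,
#'   `n_abc`, `n_matched_peak`, `n_matched_gene`.
#' @export
abc_concordance <- function(abc, links, peaks) {
  if (!nrow(abc)) stop("empty ABC prediction list")
  linked <- peaks[peaks$peak_id %in% links$peak_id, , drop = FALSE]
  hits <- overlap_variants(abc, linked, type = "span")
  matched_peak <- unique(hits$variant_idx)
  matched_gene <- unique(hits$variant_idx[vapply(seq_len(nrow(hits)),
    function(i) {
      pid <- linked$peak_id[hits$interval_idx[i]]
      abc$gene_id[hits$variant_idx[i]] %in%
        links$gene_id[links$peak_id == pid]
    }, logical(1))])
  list(
    matched_peak_fraction = length(matched_peak) / nrow(abc),
    matched_gene_fraction = length(matched_gene) / nrow(abc),
    n_abc = nrow(abc),
    n_matched_peak = length(matched_peak),
    n_matched_gene = length(matched_gene)
  )
}
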