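#' Cross-tabulate class and cluster labels
#'
#' @param classes Vector of ground-truth class labels (e.g. dissection/FACS
#'   origin), one per cell.
#' @param clusters Vector of cluster labels, same length.
#' @return Object of class `cluster_labeling`: list with the contingency
#'   matrix `a` (classes x clusters) and total `n`.
#' @export
contingency <- function(classes, clusters) {
  if (length(classes) != length(clusters)) {
    stop("class and cluster label vectors differ in length")
  }
  if (!length(classes)) stop("empty labeling")
  a <- table(class = as.character(classes), cluster = as.character(clusters))
  structure(list(a = unclass(a), n = length(classes)),
            class = "cluster_labeling")
}

# entropy of a count vector, in nats; 0 log 0 := 0
entropy_nats <- function(counts, total = sum(counts)) {
  p <- counts[counts > 0] / total
  -sum(p * log(p))
}

#' Homogeneity, completeness and V-measure
#'
#' Homogeneity h is 1 when every cluster contains cells of a single class
#' (conditional entropy H(C|K) = 0), else 1 - H(C|K)/H(C); completeness c is
#' the symmetric quantity with classes and clusters swapped; the V-measure
#' is their beta-weighted harmonic mean (1 + beta) h c / (beta h + c).
#' Entropies are natural-log; h, c and V are entropy ratios and therefore
#' base-invariant.
#'
#' @param cl A [contingency()] labeling, or a contingency matrix.
#' @param beta Weight on completeness relative to homogeneity (default 1).
#' @return List with `h`, `c`, `v_beta`, `beta` and the raw entropies
#'   `H_C`, `H_K`, `H_C_given_K`, `H_K_given_C` (nats).
#' @export
v_measure <- function(cl, beta = 1) {
  a <- if (inherits(cl, "cluster_labeling")) cl$a else as.matrix(cl)
  n <- sum(a)
  stopifnot(n >= 1)
  h_c <- entropy_nats(rowSums(a), n)
  h_k <- entropy_nats(colSums(a), n)
  # H(C|K) = sum_k (n_k / n) * H(C within cluster k); same expansion as the
  # double sum over a_ck/N log(a_ck / n_k)
  h_c_given_k <- sum(vapply(seq_len(ncol(a)), function(k) {
    nk <- sum(a[, k])
    if (nk == 0) return(0)
    (nk / n) * entropy_nats(a[, k], nk)
  }, numeric(1)))
  h_k_given_c <- sum(vapply(seq_len(nrow(a)), function(cc) {
    nc <- sum(a[cc, ])
    if (nc == 0) return(0)
    (nc / n) * entropy_nats(a[cc, ], nc)
  }, numeric(1)))
  h <- if (h_c_given_k == 0) 1 else 1 - h_c_given_k / h_c
  cc <- if (h_k_given_c == 0) 1 else 1 - h_k_given_c / h_k
  v <- if (beta * h + cc == 0) 0 else (1 + beta) * h * cc / (beta * h + cc)
  list(h = h, c = cc, v_beta = v, beta = beta,
       H_C = h_c, H_K = h_k,
       H_C_given_K = h_c_given_k, H_K_given_C = h_k_given_c)
}

#' Per-cluster purity
#'
#' Purity of a cluster is the fraction of its cells belonging to its most
#' represented class, max_c a_ck / n_k; bounded between 1/|C| and 1.
#'
#' @param cl A [contingency()] labeling or contingency matrix.
#' @return Named numeric vector, one purity per cluster.
#' @export
purity <- function(cl) {
  a <- if (inherits(cl, "cluster_labeling")) cl$a else as.matrix(cl)
  sizes <- colSums(a)
  if (any(sizes == 0)) stop("empty cluster in contingency table")
  stats::setNames(apply(a, 2, max) / sizes, colnames(a))
}

#' Pairwise replicate-membership correlations
#'
#' Batch-effect instrument: for every pair of biological replicates,
#' computes the Pearson correlation of their cluster-membership proportion
#' vectors over the shared cluster universe.
#'
#' @param clusters Cluster label per cell.
#' @param replicates Replicate label per cell.
#' @return Correlation matrix, replicates x replicates.
#' @export
replicate_membership_correlation <- function(clusters, replicates) {
  stopifnot(length(clusters) == length(replicates))
  reps <- sort(unique(as.character(replicates)))
  if (length(reps) < 2) stop("need at least two replicates")
  univ <- sort(unique(as.character(clusters)))
  props <- sapply(reps, function(r) {
    cnt <- table(factor(clusters[replicates == r], levels = univ))
    as.vector(cnt) / sum(cnt)
  })
  if (any(apply(props, 2, stats::sd) == 0)) {
    stop("zero-variance membership vector")
  }
  stats::cor(props)
}
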