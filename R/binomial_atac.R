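#' Exact two-sided binomial test
#'
#' The two-sided p-value is the total null probability of all outcomes no
#' more likely than the observed count: P = sum over {i : Pr(X = i) <=
#' Pr(X = k)} of the Binomial(n, pi0) pmf. Probability-mass ties at the
#' observed outcome are compared with a relative tolerance of 1e-7 to keep
#' the inequality stable under floating point; the sum is clipped at 1.
#'
#' @param k Number of successes (reference-allele reads).
#' @param n Number of trials (informative coverage).
#' @param pi0 Null success probability (default 0.5).
#' @return Two-sided p-value.
#' @export
exact_binomial_two_sided <- function(k, n, pi0 = 0.5) {
  stopifnot(length(k) == 1, length(n) == 1, n >= 1, k >= 0, k <= n)
  if (!(pi0 > 0 && pi0 < 1)) stop("pi0 must be in (0, 1)")
  pmf <- stats::dbinom(0:n, n, pi0)
  pk <- pmf[k + 1]
  min(1, sum(pmf[pmf <= pk * (1 + 1e-7)]))
}

#' Clopper-Pearson interval for the allele fraction
#'
#' Exact (Clopper-Pearson) confidence interval for the binomial success
#' probability, via beta quantiles; a Wilson score interval is available as
#' an option.
#'
#' @param k,n Successes and trials.
#' @param conf_level Confidence level (default 0.95).
#' @param method `"clopper-pearson"` (default) or `"wilson"`.
#' @return List with `estimate` (k/n), `lower`, `upper`.
#' @export
allele_fraction_ci <- function(k, n, conf_level = 0.95,
                               method = c("clopper-pearson", "wilson")) {
  method <- match.arg(method)
  stopifnot(n >= 1, k >= 0, k <= n)
  alpha <- 1 - conf_level
  est <- k / n
  if (method == "clopper-pearson") {
    lower <- if (k == 0) 0 else stats::qbeta(alpha / 2, k, n - k + 1)
    upper <- if (k == n) 1 else stats::qbeta(1 - alpha / 2, k + 1, n - k)
  } else {
    z <- stats::qnorm(1 - alpha / 2)
    denom <- 1 + z^2 / n
    center <- (est + z^2 / (2 * n)) / denom
    half <- z * sqrt(est * (1 - est) / n + z^2 / (4 * n^2)) / denom
    lower <- max(0, center - half)
    upper <- min(1, center + half)
  }
  list(estimate = est, lower = lower, upper = upper)
}

#' Convert a reference/alternate count ratio to a success probability
#'
#' A reported wildtype/mutant read-count ratio rho = k/(n - k) corresponds
#' to a binomial success-probability estimate rho / (1 + rho).
#'
#' @param ratio Reference over alternate count ratio.
#' @return Success probability estimate.
#' @export
ratio_to_success_prob <- function(ratio) {
  stopifnot(ratio >= 0)
  ratio / (1 + ratio)
}

#' Allelic-imbalance test across scATAC replicates ("binomial ATAC")
#'
#' Tests whether the reference allele fraction at a heterozygous regulatory
#' site departs from the null sampling probability, pooling reference and
#' alternate read counts across biological replicates and applying the exact
#' two-sided binomial test. Reports the pooled estimate, its exact
#' confidence interval, the reference/alternate count ratio, and
#' per-replicate results.
#'
#' @param replicates data.frame with columns `k` (reference count) and `n`
#'   (total informative reads), one row per replicate; an optional
#'   `replicate` column labels rows.
#' @param pi0 Null success probability (default 0.5).
#' @param pool Pool counts across replicates by summation (default TRUE).
#' @param conf_level CI level for the pooled estimate.
#' @return List with `pooled` (list: `k`, `n`, `estimate`, `ratio` =
#'   k/(n-k), `p_two_sided`, `ci95`) and `per_replicate` (data.frame with
#'   per-replicate estimates and p-values).
#' @export
binomial_atac <- function(replicates, pi0 = 0.5, pool = TRUE,
                          conf_level = 0.95) {
  stopifnot(nrow(replicates) >= 1,
            all(c("k", "n") %in% names(replicates)))
  per <- replicates
  per$estimate <- per$k / per$n
  per$p_two_sided <- mapply(exact_binomial_two_sided, per$k, per$n,
                            MoreArgs = list(pi0 = pi0))
  pooled <- NULL
  if (pool) {
    K <- sum(per$k); N <- sum(per$n)
    ci <- allele_fraction_ci(K, N, conf_level)
    pooled <- list(
      k = K, n = N,
      estimate = K / N,
      ratio = if (N - K > 0) K / (N - K) else Inf,
      p_two_sided = exact_binomial_two_sided(K, N, pi0),
      ci95 = c(ci$lower, ci$upper)
    )
  }
  list(pooled = pooled, per_replicate = per)
}
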