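#' Drop individuals with outlying de novo counts
#'
#' Individuals whose filtered de novo variant count exceeds the threshold
#' (strict inequality) are removed before enrichment testing.
#'
#' @param counts Named integer vector: de novo variants per individual.
#' @param threshold Count above which an individual is removed (default 75).
#' @return The retained subvector.
#' @export
remove_outlier_individuals <- function(counts,
                                       threshold =
                                         ccdd_defaults()$denovo_outlier_max) {
  stopifnot(all(counts >= 0))
  counts[counts <= threshold]
}

mask_by_chrom <- function(mask, chroms) {
  out <- lapply(chroms, function(ch) {
    if (is.null(mask) || !nrow(mask)) {
      return(data.frame(start = integer(0), end = integer(0)))
    }
    m <- mask[mask$chrom == ch, c("start", "end"), drop = FALSE]
    m[order(m$start), , drop = FALSE]
  })
  names(out) <- chroms
  out
}

#' Size-matched region randomization
#'
#' Draws one random interval per input interval, preserving each length,
#' such that the placed intervals do not overlap each other and lie entirely
#' outside the masked regions. Placement is by rejection sampling: widths
#' are placed longest-first, the chromosome is chosen with probability
#' proportional to the number of start positions it can host, and the start
#' is uniform on the chromosome. Intervals may move across chromosomes.
#'
#' @param intervals data.frame with `chrom`, `start`, `end` (only widths are
#'   used).
#' @param chrom_lengths Named numeric vector of chromosome lengths (bp).
#' @param mask Optional data.frame of excluded intervals (`chrom`, `start`,
#'   `end`).
#' @param max_retries Rejection-sampling attempts per interval before
#'   failing (default 10000).
#' @return data.frame of placed intervals (`chrom`, `start`, `end`), in
#'   decreasing width order.
#' @export
randomize_regions <- function(intervals, chrom_lengths, mask = NULL,
                              max_retries = 10000) {
  widths <- (intervals$end - intervals$start)
  stopifnot(all(widths > 0))
  chroms <- names(chrom_lengths)
  maskl <- mask_by_chrom(mask, chroms)
  # blocked regions per chromosome as flat start/end vectors (mask + placed)
  bstart <- lapply(maskl, function(m) as.numeric(m$start))
  bend <- lapply(maskl, function(m) as.numeric(m$end))
  ord <- order(widths, decreasing = TRUE)
  res_chrom <- character(length(widths))
  res_start <- numeric(length(widths))
  for (i in ord) {
    w <- widths[i]
    slots <- pmax(chrom_lengths - w + 1, 0)  # first arg keeps the names
    if (sum(slots) <= 0) {
      stop("no chromosome can host an interval of width ", w)
    }
    done <- FALSE
    for (try in seq_len(max_retries)) {
      ch <- if (length(chroms) == 1) chroms else
        sample(chroms, 1, prob = slots)
      s <- floor(stats::runif(1, min = 0, max = slots[[ch]]))
      e <- s + w
      if (any(s < bend[[ch]] & e > bstart[[ch]])) next
      bstart[[ch]] <- c(bstart[[ch]], s)
      bend[[ch]] <- c(bend[[ch]], e)
      res_chrom[i] <- ch
      res_start[i] <- s
      done <- TRUE
      break
    }
    if (!done) {
      stop("failed to place interval of width ", w, " after ", max_retries,
           " attempts; masked fraction may be too high (",
           length(widths), " intervals requested)")
    }
  }
  out <- data.frame(chrom = res_chrom[ord], start = res_start[ord],
                    end = res_start[ord] + widths[ord],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

# fast point-in-intervals count: variant positions are 1-based, intervals
# 0-based half-open
count_hits <- function(pos_by_chrom, intervals) {
  if (!nrow(intervals)) return(0L)
  total <- 0L
  for (i in seq_len(nrow(intervals))) {
    p <- pos_by_chrom[[intervals$chrom[i]]]
    if (is.null(p)) next
    # 0-based position pos-1 in [start, end)  <=>  start < pos <= end
    total <- total +
      (findInterval(intervals$end[i], p) -
         findInterval(intervals$start[i], p))
  }
  total
}

#' Permutation enrichment test of variants in a peak set
#'
#' Counts the variants falling inside the observed peak set, then repeatedly
#' randomizes a size-matched non-overlapping peak set over the unmasked
#' genome ([randomize_regions()]) and recounts. Reports the permutation
#' Z-score (observed minus null mean over null sd) and the add-one empirical
#' p-value (1 + #\{null >= observed\}) / (1 + n_iter), whose floor is
#' 1/(n_iter + 1).
#'
#' @param variants data.frame with `chrom` and 1-based `pos`.
#' @param intervals Observed peak set (`chrom`, `start`, `end`).
#' @param chrom_lengths Named vector of chromosome lengths.
#' @param mask Optional excluded intervals.
#' @param n_iter Number of iterations (default 5000).
#' @param seed Optional integer seed for reproducible null draws.
#' @return List of class `permutation_result`: `observed_count`,
#'   `null_counts`, `z` (NA when the null is degenerate), `p_empirical`,
#'   `n_iterations`, `seed`.
#' @export
permutation_test <- function(variants, intervals, chrom_lengths, mask = NULL,
                             n_iter = ccdd_defaults()$perm_n_iter,
                             seed = NULL) {
  stopifnot(n_iter >= 1)
  if (!is.null(seed)) set.seed(seed)
  pos_by_chrom <- lapply(split(variants$pos, variants$chrom), sort)
  observed <- count_hits(pos_by_chrom, intervals)
  null_counts <- integer(n_iter)
  for (it in seq_len(n_iter)) {
    rnd <- randomize_regions(intervals, chrom_lengths, mask)
    null_counts[it] <- count_hits(pos_by_chrom, rnd)
  }
  sd_null <- stats::sd(null_counts)
  z <- if (is.na(sd_null) || sd_null == 0) {
    NA_real_
  } else {
    (observed - mean(null_counts)) / sd_null
  }
  structure(
    list(observed_count = observed, null_counts = null_counts, z = z,
         p_empirical = (1 + sum(null_counts >= observed)) / (1 + n_iter),
         n_iterations = n_iter, seed = seed),
    class = "permutation_result"
  )
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf(
    "permutation_test: observed = %d, null mean = %.2f, z = %s, p = %.3g (%d iterations)\n",
    x$observed_count, mean(x$null_counts),
    if (is.na(x$z)) "NA" else sprintf("%.2f", x$z),
    x$p_empirical, x$n_iterations))
  invisible(x)
}
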