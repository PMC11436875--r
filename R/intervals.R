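#' @importFrom GenomicRanges GRanges reduce findOverlaps start end width
#'   seqnames makeGRangesFromDataFrame
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors queryHits subjectHits
NULL

# All intervals in this package are BED-style: 0-based, half-open [start, end).
# VCF positions are 1-based; the conversion to 0-based happens here and only
# here (see overlap_variants).

#' Construct a peak atlas
#'
#' A peak atlas holds one interval set per cell type (or cell type/stage),
#' each stored merged and sorted.
#'
#' @param sets Named list; each element a data.frame with columns
#'   `chrom`, `start`, `end` (0-based half-open). Empty data.frames allowed.
#' @param provenance Optional character label.
#' @return Object of class `peak_atlas`: named list of interval data.frames,
#'   each with a `peak_id` column, merged and sorted.
#' @export
peak_atlas <- function(sets, provenance = NA_character_) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  out <- lapply(names(sets), function(nm) {
    df <- merge_intervals(sets[[nm]])
    if (nrow(df)) {
      df$peak_id <- sprintf("%s:%s:%d-%d", nm, df$chrom, df$start, df$end)
    } else {
      df$peak_id <- character(0)
    }
    df
  })
  names(out) <- names(sets)
  structure(list(sets = out, provenance = provenance), class = "peak_atlas")
}

#' @export
print.peak_atlas <- function(x, ...) {
  cat("peak_atlas:", length(x$sets), "cell types/stages\n")
  for (nm in names(x$sets)) {
    cat(sprintf("  %-12s %5d peaks\n", nm, nrow(x$sets[[nm]])))
  }
  invisible(x)
}

as_granges <- function(df) {
  if (!nrow(df)) {
    return(GenomicRanges::GRanges())
  }
  # BED half-open [start, end) -> IRanges closed [start+1, end]
  GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start + 1L, df$end))
}

granges_to_bed <- function(gr) {
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end   = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
}

#' Merge overlapping and book-ended intervals
#'
#' Combines intervals that overlap or abut (distance 0), matching
#' `bedtools merge` defaults. Output is sorted and non-overlapping; total
#' covered bases are preserved.
#'
#' @param intervals data.frame with columns `chrom`, `start`, `end`
#'   (0-based half-open).
#' @return data.frame with the same columns, merged and sorted.
#' @export
merge_intervals <- function(intervals) {
  stopifnot(all(c("chrom", "start", "end") %in% names(intervals)))
  if (nrow(intervals) && any(intervals$start >= intervals$end)) {
    stop("invalid interval: start >= end")
  }
  if (!nrow(intervals)) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE))
  }
  gr <- as_granges(intervals)
  # reduce() with min.gapwidth = 1 merges overlapping and book-ended ranges,
  # i.e. bedtools merge -d 0 semantics.
  merged <- GenomicRanges::reduce(gr, min.gapwidth = 1L)
  out <- granges_to_bed(merged)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build the merged peak set for one disease group
#'
#' Union-merges the atlas interval sets of every cell type mapped to the
#' disease group, yielding the regions accessible in one or more of the
#' relevant cMN populations.
#'
#' @param atlas A [peak_atlas()].
#' @param dmap Disease map (named list, see [disease_map_default()]).
#' @param group Disease group name, must be a key of `dmap`.
#' @return Merged interval data.frame with a `peak_id` column.
#' @export
build_disease_peakset <- function(atlas, dmap, group) {
  stopifnot(inherits(atlas, "peak_atlas"))
  if (!group %in% names(dmap)) {
    stop("unknown disease group: ", group)
  }
  cts <- dmap[[group]]
  missing_ct <- setdiff(cts, names(atlas$sets))
  if (length(missing_ct)) {
    stop("disease map references cell types absent from atlas: ",
         paste(missing_ct, collapse = ", "))
  }
  all_iv <- do.call(rbind, lapply(atlas$sets[cts], function(df) {
    df[, c("chrom", "start", "end")]
  }))
  merged <- merge_intervals(all_iv)
  if (nrow(merged)) {
    merged$peak_id <- sprintf("%s:%s:%d-%d", group, merged$chrom,
                              merged$start, merged$end)
  } else {
    merged$peak_id <- character(0)
  }
  merged
}

#' Overlap variants with a peak set
#'
#' Applies the class-specific overlap rule: SNVs/indels hit a peak when the
#' 1-based variant position, converted to 0-based, lies within the half-open
#' interval; SVs hit on any overlap between their span and the interval; TE
#' insertions hit when the insertion point falls within the interval padded
#' by `padding` bp on each side.
#'
#' @param variants data.frame. For `type = "point"` needs `chrom`, `pos`
#'   (1-based). For `type = "span"` needs `chrom`, `start`, `end` (0-based
#'   half-open). For `type = "insertion"` needs `chrom`, `insertion_pos`
#'   (0-based point).
#' @param intervals Merged interval data.frame with optional `peak_id`.
#' @param type Overlap rule, one of `"point"`, `"span"`, `"insertion"`.
#' @param padding Padding in bp (used for `"insertion"`; default 0).
#' @return data.frame of hits: `variant_idx`, `interval_idx`, `peak_id`.
#' @export
overlap_variants <- function(variants, intervals,
                             type = c("point", "span", "insertion"),
                             padding = 0) {
  type <- match.arg(type)
  empty <- data.frame(variant_idx = integer(0), interval_idx = integer(0),
                      peak_id = character(0), stringsAsFactors = FALSE)
  if (!nrow(variants) || !nrow(intervals)) {
    return(empty)
  }
  qgr <- switch(type,
    point = GenomicRanges::GRanges(
      variants$chrom,
      # 1-based pos -> 0-based point; as closed 1-based IRanges that is [pos, pos]
      IRanges::IRanges(variants$pos, variants$pos)
    ),
    span = as_granges(variants),
    insertion = GenomicRanges::GRanges(
      variants$chrom,
      # 0-based point p occupies 1-based base p+1
      IRanges::IRanges(variants$insertion_pos + 1L, variants$insertion_pos + 1L)
    )
  )
  iv <- intervals
  if (type == "insertion" && padding > 0) {
    iv$start <- pmax(0L, iv$start - as.integer(padding))
    iv$end <- iv$end + as.integer(padding)
  }
  sgr <- as_granges(iv)
  # disjoint chromosome universes are legitimate (e.g. off-model contigs)
  ov <- suppressWarnings(GenomicRanges::findOverlaps(qgr, sgr))
  hits <- data.frame(
    variant_idx = S4Vectors::queryHits(ov),
    interval_idx = S4Vectors::subjectHits(ov),
    stringsAsFactors = FALSE
  )
  hits$peak_id <- if ("peak_id" %in% names(intervals)) {
    intervals$peak_id[hits$interval_idx]
  } else {
    sprintf("%s:%d-%d", intervals$chrom[hits$interval_idx],
            intervals$start[hits$interval_idx],
            intervals$end[hits$interval_idx])
  }
  hits
}

#' Read a BED3+ file
#'
#' @param path BED file path (0-based half-open, no header).
#' @return data.frame with `chrom`, `start`, `end` (plus `name` if present).
#' @export
read_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  names(df)[1:3] <- c("chrom", "start", "end")
  if (ncol(df) >= 4) names(df)[4] <- "name"
  df
}

#' Write intervals as BED
#'
#' @param intervals data.frame with `chrom`, `start`, `end` and optionally
#'   a fourth name-like column.
#' @param path Output path.
#' @export
write_bed <- function(intervals, path) {
  cols <- intersect(c("chrom", "start", "end", "peak_id", "name"),
                    names(intervals))
  utils::write.table(intervals[, cols, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
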