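## Group-consensus peaks and the consensus/read-support loop filter.

#' Build group-consensus peaks from per-sample peak calls
#'
#' Candidate regions are the merged union of all samples' peaks; a candidate
#' is retained when the fraction of distinct samples with at least one peak
#' overlapping it (by >= 1 bp) reaches `threshold_fraction`. This is the
#' "peak in at least 60\% of the group's samples" rule with region-level
#' support counting: chained overlaps are merged into one candidate before
#' counting, so region boundaries are stable across sample orderings.
#'
#' @param peaks_by_sample named list, one interval data.frame per sample.
#' @param threshold_fraction required supporting fraction in (0, 1];
#'   compared as an exact rational (3/5 passes 0.6).
#' @param group_id label carried on the result.
#' @return object of class `consensus_peaks`: list with `group_id`,
#'   `n_samples` and `regions` (disjoint sorted intervals with a
#'   `support` count column).
#' @examples
#' pk <- function(s, e) data.frame(chrom = "chr1", start = s, end = e)
#' ps <- list(a = pk(0, 100), b = pk(50, 150), c = pk(60, 90),
#'            d = pk(500, 600), e = pk(510, 620))
#' build_consensus_peaks(ps, 0.6)
#' @export
build_consensus_peaks <- function(peaks_by_sample, threshold_fraction = 0.6,
                                  group_id = "all") {
  if (!length(peaks_by_sample)) stop("need peaks for at least one sample")
  stopifnot(threshold_fraction > 0, threshold_fraction <= 1)
  for (df in peaks_by_sample) validate_intervals(df, "peak")
  n <- length(peaks_by_sample)
  all_peaks <- do.call(rbind, lapply(peaks_by_sample, function(df)
    df[, c("chrom", "start", "end"), drop = FALSE]))
  cand <- merge_intervals(all_peaks)
  support <- integer(nrow(cand))
  for (df in peaks_by_sample) {
    hits <- interval_overlaps(cand, df)
    support[unique(hits[, "query"])] <- support[unique(hits[, "query"])] + 1L
  }
  keep <- support >= count_threshold(threshold_fraction, n)
  regions <- cand[keep, , drop = FALSE]
  regions$support <- support[keep]
  rownames(regions) <- NULL
  structure(list(group_id = group_id, n_samples = n, regions = regions),
            class = "consensus_peaks")
}

#' @export
print.consensus_peaks <- function(x, ...) {
  cat("Consensus peaks for group '", x$group_id, "': ", nrow(x$regions),
      " region(s) from ", x$n_samples, " sample(s)\n", sep = "")
  if (nrow(x$regions)) print(utils::head(x$regions, 6))
  invisible(x)
}

#' Keep the top-scoring peaks of a sample
#'
#' Optional pre-filter mirroring per-sample retention of the highest-scoring
#' peak calls before consensus building (ranking by the `score` column,
#' descending).
#'
#' @param peaks interval data.frame with a `score` column.
#' @param n_top number of peaks to keep.
#' @return the `n_top` highest-scoring rows, original order preserved.
#' @export
top_peaks <- function(peaks, n_top = 100000L) {
  if (nrow(peaks) <= n_top) return(peaks)
  if (is.null(peaks$score)) stop("top_peaks needs a 'score' column")
  keep <- order(peaks$score, decreasing = TRUE)[seq_len(n_top)]
  peaks[sort(keep), , drop = FALSE]
}

#' Filter loops by read support and consensus anchoring
#'
#' A loop survives iff `read_support >= min_reads` and both anchors overlap
#' at least one consensus region by >= 1 bp. Input order is preserved; the
#' filter is idempotent.
#'
#' @param loops loop data.frame (see [read_bedpe()]).
#' @param consensus a `consensus_peaks` object (must be non-empty).
#' @param min_reads minimum supporting reads (default 2).
#' @param pad bp added to each side of every consensus region before the
#'   anchor overlap test (default 0).
#' @return the surviving subset of `loops`.
#' @export
filter_loops <- function(loops, consensus, min_reads = 2L, pad = 0) {
  stopifnot(inherits(consensus, "consensus_peaks"))
  if (nrow(consensus$regions) == 0L) stop("consensus peak set is empty")
  if (nrow(loops) == 0L) return(loops)
  a1 <- data.frame(chrom = loops$chrom1, start = loops$start1, end = loops$end1)
  a2 <- data.frame(chrom = loops$chrom2, start = loops$start2, end = loops$end2)
  on1 <- on2 <- logical(nrow(loops))
  h1 <- interval_overlaps(a1, consensus$regions, pad = pad)
  h2 <- interval_overlaps(a2, consensus$regions, pad = pad)
  on1[unique(h1[, "query"])] <- TRUE
  on2[unique(h2[, "query"])] <- TRUE
  out <- loops[loops$read_support >= min_reads & on1 & on2, , drop = FALSE]
  rownames(out) <- NULL
  out
}
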