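## Genomic interval primitives.
##
## Intervals are plain data.frames with columns chrom/start/end in the BED
## convention: 0-based start, exclusive end. Overlap and merge are delegated
## to GenomicRanges after conversion to 1-based closed coordinates, so a
## shared bp under the half-open convention maps exactly to a GRanges overlap
## and bookended intervals ([100,200) vs [200,300)) never touch.

#' Construct a validated interval table
#'
#' @param chrom character vector of chromosome names.
#' @param start 0-based inclusive start positions.
#' @param end 0-based exclusive end positions (`end > start`).
#' @param ... further equal-length columns carried along (e.g. `sample_id`).
#' @return data.frame with columns `chrom`, `start`, `end` and any extras.
#' @export
genomic_intervals <- function(chrom, start, end, ...) {
  df <- data.frame(chrom = as.character(chrom),
                   start = as.numeric(start),
                   end = as.numeric(end),
                   ...,
                   stringsAsFactors = FALSE)
  validate_intervals(df)
  df
}

validate_intervals <- function(df, what = "interval") {
  stopifnot(all(c("chrom", "start", "end") %in% names(df)))
  if (nrow(df) == 0L) return(invisible(df))
  bad <- !nzchar(df$chrom) | is.na(df$chrom)
  if (any(bad)) stop("empty chromosome name in ", what, " row(s) ",
                     paste(which(bad), collapse = ", "))
  bad <- is.na(df$start) | is.na(df$end) | df$start < 0 | df$end <= df$start
  if (any(bad)) stop("invalid coordinates (need 0 <= start < end) in ", what,
                     " row(s) ", paste(which(bad), collapse = ", "))
  invisible(df)
}

## 0-based half-open -> GRanges (1-based closed)
as_granges <- function(df) {
  if (nrow(df) == 0L) return(GenomicRanges::GRanges())
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(start = df$start + 1L, end = df$end))
}

granges_to_df <- function(gr) {
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1,
             end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}

#' Do two intervals share at least one base pair?
#'
#' Half-open convention: `chr1:[100,200)` does not overlap `chr1:[200,300)`.
#'
#' @param a,b single-row interval data.frames (or lists with `chrom`,
#'   `start`, `end`).
#' @return logical scalar.
#' @export
overlaps <- function(a, b) {
  a$chrom == b$chrom && max(a$start, b$start) < min(a$end, b$end)
}

#' Overlap hits between two interval tables
#'
#' @param query,subject interval data.frames.
#' @param pad non-negative bp added to both sides of every `subject` interval
#'   before the overlap test.
#' @return integer matrix with columns `query`, `subject`, one row per
#'   overlapping pair.
#' @export
interval_overlaps <- function(query, subject, pad = 0) {
  if (nrow(query) == 0L || nrow(subject) == 0L) {
    return(matrix(integer(0), ncol = 2, dimnames = list(NULL, c("query", "subject"))))
  }
  s <- subject
  if (pad > 0) {
    s$start <- pmax(0, s$start - pad)
    s$end <- s$end + pad
  }
  h <- GenomicRanges::findOverlaps(as_granges(query), as_granges(s))
  cbind(query = S4Vectors::queryHits(h), subject = S4Vectors::subjectHits(h))
}

#' Merge intervals into the minimal disjoint covering set
#'
#' Touching-but-not-overlapping intervals are kept separate (half-open
#' semantics: `[100,200)` and `[200,300)` do not merge).
#'
#' @param df interval data.frame (may be empty).
#' @return data.frame of disjoint intervals sorted by `(chrom, start)`.
#' @export
merge_intervals <- function(df) {
  if (nrow(df) == 0L) {
    return(data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
                      stringsAsFactors = FALSE))
  }
  validate_intervals(df)
  out <- granges_to_df(GenomicRanges::reduce(as_granges(df), min.gapwidth = 0L))
  out[order(out$chrom, out$start), , drop = FALSE] -> out
  rownames(out) <- NULL
  out
}

## Stable "chrom:start-end" labels, parseable back by parse_interval_ids().
interval_ids <- function(df) {
  if (nrow(df) == 0L) return(character(0))
  sprintf("%s:%d-%d", df$chrom, as.integer(df$start), as.integer(df$end))
}

#' Parse "chrom:start-end" feature identifiers into an interval table
#'
#' The inverse of the labels the package writes for peak-level features
#' (0-based half-open coordinates).
#'
#' @param ids character vector like `"chr1:1000-1600"`.
#' @return interval data.frame with an `id` column.
#' @export
parse_interval_ids <- function(ids) {
  m <- regmatches(ids, regexec("^(.+):([0-9]+)-([0-9]+)$", ids))
  bad <- vapply(m, length, 1L) != 4L
  if (any(bad)) stop("unparseable interval id(s): ",
                     paste(head(ids[bad], 5), collapse = ", "))
  df <- data.frame(chrom = vapply(m, `[`, "", 2L),
                   start = as.numeric(vapply(m, `[`, "", 3L)),
                   end = as.numeric(vapply(m, `[`, "", 4L)),
                   id = ids,
                   stringsAsFactors = FALSE)
  validate_intervals(df, "feature id")
  df
}

## ">= frac of n" with exact-rational intent; the 1e-9 guard absorbs binary
## float artifacts (0.6 * 5 == 3.0000000000000004).
count_threshold <- function(frac, n) {
  as.integer(ceiling(frac * n - 1e-9))
}
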