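## Count normalisation (CPM / log2-CPM), the expressed-gene filter, and the
## per-gene hub design matrix (other hub genes' expression + hub peak
## accessibility).

#' Counts per million
#'
#' @param counts non-negative integer matrix, features x samples.
#' @param lib_sizes per-sample library sizes; default column sums, in which
#'   case every CPM column sums to exactly 1e6.
#' @return numeric matrix of the same shape.
#' @export
cpm <- function(counts, lib_sizes = colSums(counts)) {
  if (any(lib_sizes <= 0)) stop("library sizes must be positive")
  sweep(counts, 2L, lib_sizes, "/") * 1e6
}

#' log2 counts per million with a prior count
#'
#' `log2((count + prior) / (lib_size + 2 * prior) * 1e6)`: finite at zero
#' counts and strictly monotone in the count. With equal library sizes this
#' coincides with edgeR's prior-protected log-CPM at the same prior.
#'
#' @inheritParams cpm
#' @param prior prior count added to every cell (default 0.5).
#' @return numeric matrix of log2-CPM values.
#' @export
log_cpm <- function(counts, lib_sizes = colSums(counts), prior = 0.5) {
  stopifnot(prior > 0)
  if (any(lib_sizes <= 0)) stop("library sizes must be positive")
  log2(sweep(counts + prior, 2L, lib_sizes + 2 * prior, "/") * 1e6)
}

#' Expressed-feature filter
#'
#' A feature is retained when at least `min_samples` samples have
#' CPM >= `min_cpm` (default: CPM of at least 1 in at least five samples).
#'
#' @inheritParams cpm
#' @param min_cpm CPM cutoff per sample.
#' @param min_samples required number of qualifying samples.
#' @return character vector of retained feature ids (rownames).
#' @export
expressed_filter <- function(counts, min_cpm = 1, min_samples = 5L,
                             lib_sizes = colSums(counts)) {
  v <- cpm(counts, lib_sizes)
  n_ok <- rowSums(v >= min_cpm)
  rownames(counts)[n_ok >= min_samples]
}

#' Assemble the per-gene design for a hub
#'
#' The response is the target gene's log-CPM across samples; the candidate
#' features are the log-CPM of every other member gene of the hub followed
#' by the log-CPM of every ATAC feature overlapping the hub's member peak
#' regions, transposed to samples x features. RNA and ATAC matrices must
#' cover the identical (matched) sample set; ATAC rows are matched to hub
#' peaks by interval overlap of their `chrom:start-end` rownames.
#'
#' @param hub a `regulatory_hub` with members assigned.
#' @param rna_logcpm gene-level log-CPM matrix (genes x samples).
#' @param atac_logcpm peak-level log-CPM matrix with `chrom:start-end`
#'   rownames (peaks x samples).
#' @param target_gene_id the modelled gene; must be a hub member present in
#'   `rna_logcpm`.
#' @return object of class `hub_design`: list with `target_gene_id`,
#'   `response` (named numeric), `features` (samples x features matrix) and
#'   `feature_meta` (data.frame `feature_id, type, chrom, start, end`).
#' @export
build_design <- function(hub, rna_logcpm, atac_logcpm, target_gene_id) {
  stopifnot(inherits(hub, "regulatory_hub"))
  if (is.null(hub$genes)) stop("hub has no members; run assign_members() first")
  rs <- colnames(rna_logcpm)
  as <- colnames(atac_logcpm)
  if (!setequal(rs, as) || length(rs) != length(as)) {
    stop("RNA and ATAC matrices must share an identical matched sample set")
  }
  atac_logcpm <- atac_logcpm[, rs, drop = FALSE]
  member_genes <- intersect(hub$genes$gene_id, rownames(rna_logcpm))
  if (!(target_gene_id %in% member_genes)) {
    stop("target gene '", target_gene_id, "' is not an expressed member of the hub")
  }
  other <- setdiff(member_genes, target_gene_id)
  peak_rows <- character(0)
  if (nrow(hub$peaks) && nrow(atac_logcpm)) {
    feat_iv <- parse_interval_ids(rownames(atac_logcpm))
    h <- interval_overlaps(feat_iv, hub$peaks[, c("chrom", "start", "end")])
    peak_rows <- rownames(atac_logcpm)[sort(unique(h[, "query"]))]
  }
  if (length(other) + length(peak_rows) < 1L) {
    stop("hub provides no candidate features for gene '", target_gene_id, "'")
  }
  gm <- hub$genes[match(other, hub$genes$gene_id), , drop = FALSE]
  meta <- rbind(
    if (length(other)) data.frame(feature_id = other, type = "gene",
                                  chrom = gm$chrom, start = gm$start,
                                  end = gm$end, stringsAsFactors = FALSE),
    if (length(peak_rows)) {
      iv <- parse_interval_ids(peak_rows)
      data.frame(feature_id = peak_rows, type = "peak", chrom = iv$chrom,
                 start = iv$start, end = iv$end, stringsAsFactors = FALSE)
    })
  rownames(meta) <- NULL
  features <- t(rbind(rna_logcpm[other, , drop = FALSE],
                      atac_logcpm[peak_rows, , drop = FALSE]))
  colnames(features) <- meta$feature_id
  structure(list(target_gene_id = target_gene_id,
                 response = rna_logcpm[target_gene_id, ],
                 features = features,
                 feature_meta = meta),
            class = "hub_design")
}

#' @export
print.hub_design <- function(x, ...) {
  cat("Hub design for gene '", x$target_gene_id, "': ", nrow(x$features),
      " sample(s), ", ncol(x$features), " candidate feature(s) (",
      sum(x$feature_meta$type == "gene"), " gene, ",
      sum(x$feature_meta$type == "peak"), " peak)\n", sep = "")
  invisible(x)
}
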