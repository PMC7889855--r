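## From retained features to Table-style rows: putative causal elements
## (retained features lying within a risk LD block) and the genes whose
## models retained them (putative target genes).

#' Name a regulatory element
#'
#' Elements overlapping a gene span take that gene's id (leftmost-start
#' tie-break when several genes overlap); intergenic elements are named
#' `Peak_<k>` with `k` the 0-based index of the first overlapping region in
#' the coordinate-sorted consensus peak list (a stable label, not a key).
#'
#' @param element single-row interval data.frame.
#' @param genes gene table (may be `NULL`).
#' @param peak_index coordinate-sorted interval data.frame used for
#'   `Peak_<k>` indexing (may be `NULL`).
#' @return character name.
#' @export
name_element <- function(element, genes = NULL, peak_index = NULL) {
  if (!is.null(genes) && nrow(genes)) {
    h <- interval_overlaps(element, genes[, c("chrom", "start", "end")])
    if (nrow(h)) {
      cand <- genes[h[, "subject"], , drop = FALSE]
      cand <- cand[order(cand$start, cand$gene_id), , drop = FALSE]
      if (nrow(cand) > 1L) {
        message("element ", interval_ids(element), " overlaps ", nrow(cand),
                " genes; naming by leftmost (", cand$gene_id[1], ")")
      }
      return(cand$gene_id[1])
    }
  }
  if (!is.null(peak_index) && nrow(peak_index)) {
    pi_sorted <- peak_index[order(peak_index$chrom, peak_index$start), , drop = FALSE]
    h <- interval_overlaps(element, pi_sorted)
    if (nrow(h)) return(sprintf("Peak_%d", min(h[, "subject"]) - 1L))
  }
  interval_ids(element)
}

#' Putative causal elements and their target genes
#'
#' Emits one row per retained feature overlapping a risk LD block, crossed
#' with every target gene whose selection retained that feature. Features
#' outside every block produce no rows. Output is sorted by
#' `(chrom, start, target_gene)` and is deterministic under permutation of
#' the inputs.
#'
#' @param results list of `stability_selection` objects (their
#'   `feature_meta` resolves feature ids to intervals).
#' @param ld_blocks data.frame `chrom, start, end, lead_snp`.
#' @param genes optional gene table for element naming.
#' @param peak_index optional interval table (e.g. ATAC consensus regions)
#'   for `Peak_<k>` naming of intergenic elements.
#' @param contained if `TRUE`, the element must lie entirely inside the
#'   block; default is any >= 1 bp overlap.
#' @return data.frame with columns `feature_chrom, feature_start,
#'   feature_stop, feature_name, target_gene, ld_lead_snp, is_de`
#'   (`is_de` initialised to `NA`; see [flag_de_targets()]).
#' @export
assign_causal_elements <- function(results, ld_blocks, genes = NULL,
                                   peak_index = NULL, contained = FALSE) {
  empty <- data.frame(feature_chrom = character(0), feature_start = numeric(0),
                      feature_stop = numeric(0), feature_name = character(0),
                      target_gene = character(0), ld_lead_snp = character(0),
                      is_de = logical(0), stringsAsFactors = FALSE)
  rows <- list()
  for (res in results) {
    if (!length(res$retained)) next
    meta <- res$feature_meta
    if (is.null(meta)) stop("selection result for '", res$target_gene_id,
                            "' carries no feature_meta; cannot resolve features")
    mi <- match(res$retained, meta$feature_id)
    if (anyNA(mi)) stop("unresolvable feature id(s): ",
                        paste(res$retained[is.na(mi)], collapse = ", "))
    fm <- meta[mi, , drop = FALSE]
    h <- interval_overlaps(fm[, c("chrom", "start", "end")], ld_blocks)
    if (contained && nrow(h)) {
      inside <- fm$start[h[, "query"]] >= ld_blocks$start[h[, "subject"]] &
        fm$end[h[, "query"]] <= ld_blocks$end[h[, "subject"]]
      h <- h[inside, , drop = FALSE]
    }
    if (!nrow(h)) next
    for (k in seq_len(nrow(h))) {
      el <- fm[h[k, "query"], , drop = FALSE]
      rows[[length(rows) + 1L]] <- data.frame(
        feature_chrom = el$chrom, feature_start = el$start,
        feature_stop = el$end,
        feature_name = name_element(el, genes, peak_index),
        target_gene = res$target_gene_id,
        ld_lead_snp = ld_blocks$lead_snp[h[k, "subject"]],
        is_de = NA, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(out$feature_chrom, out$feature_start, out$target_gene,
                   out$ld_lead_snp), , drop = FALSE]
  out <- out[!duplicated(out[, c("feature_chrom", "feature_start", "feature_stop",
                                 "target_gene", "ld_lead_snp")]), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Flag differentially expressed target genes
#'
#' Marks assignment rows whose target gene is in a supplied DE list
#' (DE analysis itself happens upstream of this package).
#'
#' @param assignments output of [assign_causal_elements()].
#' @param de_gene_ids character vector of DE gene ids, or `NULL` to leave
#'   the flags `NA`.
#' @return `assignments` with `is_de` filled.
#' @export
flag_de_targets <- function(assignments, de_gene_ids = NULL) {
  if (is.null(de_gene_ids)) {
    assignments$is_de <- NA
  } else {
    assignments$is_de <- assignments$target_gene %in% de_gene_ids
  }
  assignments
}
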