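## End-to-end orchestration: consensus -> loop filter -> hubs -> designs ->
## stability selection -> causal-element assignment, with a run manifest.

#' Pipeline parameters
#'
#' Defaults are the pipeline's reference thresholds: 60\% consensus support,
#' loops with at least 2 supporting reads, expressed = CPM >= 1 in at least
#' 5 samples, TSS +/- 2 kb promoters, 50 selection runs with 95\% retention.
#'
#' @param consensus_threshold fraction of samples required for a consensus
#'   peak.
#' @param min_reads minimum loop read support.
#' @param min_cpm,min_samples expressed-gene filter.
#' @param promoter_pad,anchor_pad bp pads used by [assign_members()].
#' @param contained require strict containment (not just overlap) of
#'   elements/anchors in LD blocks.
#' @param selection a [selection_params()] list.
#' @param de_genes optional character vector of differentially expressed
#'   gene ids used only to flag targets.
#' @return list of class `pipeline_params`.
#' @export
pipeline_params <- function(consensus_threshold = 0.6, min_reads = 2L,
                            min_cpm = 1, min_samples = 5L,
                            promoter_pad = 2000, anchor_pad = 0,
                            contained = FALSE,
                            selection = selection_params(),
                            de_genes = NULL) {
  structure(as.list(environment()), class = "pipeline_params")
}

#' Run the full regulatory-hub pipeline
#'
#' @param inputs a [simulate_bundle()] result or any list with elements
#'   `ctcf_peaks` (named list of per-sample interval data.frames), `loops`,
#'   `ld_blocks`, `genes`, `rna_counts`, `atac_counts` and `atac_peaks`
#'   (per-sample ATAC calls).
#' @param params a [pipeline_params()] list.
#' @return object of class `hub_pipeline`: consensus sets, filtered loops,
#'   anchor graph, hubs (with members), per-gene `stability_selection`
#'   results, the assignment table, and a `manifest` recording every
#'   parameter and per-stage counts. Identical inputs and seeds give
#'   identical results.
#' @export
run_pipeline <- function(inputs, params = pipeline_params()) {
  need <- c("ctcf_peaks", "loops", "ld_blocks", "genes", "rna_counts",
            "atac_counts", "atac_peaks")
  miss <- setdiff(need, names(inputs))
  if (length(miss)) stop("pipeline inputs missing: ", paste(miss, collapse = ", "))

  ctcf_cons <- build_consensus_peaks(inputs$ctcf_peaks,
                                     params$consensus_threshold, "ctcf")
  loops_kept <- filter_loops(inputs$loops, ctcf_cons, params$min_reads)
  graph <- build_anchor_graph(loops_kept)
  hubs <- find_hubs(graph, inputs$ld_blocks, contained = params$contained)
  inactive <- attr(hubs, "inactive_blocks")

  atac_cons <- build_consensus_peaks(inputs$atac_peaks,
                                     params$consensus_threshold, "atac")

  expressed <- expressed_filter(inputs$rna_counts, params$min_cpm,
                                params$min_samples)
  ## library sizes from the full matrices (the genome-wide analogue), then
  ## restrict to expressed genes
  rna_lc <- log_cpm(inputs$rna_counts)[expressed, , drop = FALSE]
  atac_lc <- log_cpm(inputs$atac_counts)

  hubs <- lapply(hubs, assign_members, genes = inputs$genes,
                 atac_consensus = atac_cons,
                 promoter_pad = params$promoter_pad,
                 anchor_pad = params$anchor_pad)

  ## one stability selection per expressed member gene, with a per-gene seed
  ## offset so results do not depend on processing order
  jobs <- do.call(rbind, lapply(hubs, function(h) {
    g <- intersect(h$genes$gene_id, rownames(rna_lc))
    if (!length(g)) return(NULL)
    data.frame(hub_id = h$hub_id, gene_id = g, stringsAsFactors = FALSE)
  }))
  selections <- list()
  skipped <- character(0)
  if (!is.null(jobs) && nrow(jobs)) {
    jobs <- jobs[order(jobs$hub_id, jobs$gene_id), , drop = FALSE]
    hub_by_id <- setNames(hubs, vapply(hubs, `[[`, "", "hub_id"))
    for (i in seq_len(nrow(jobs))) {
      sel_par <- params$selection
      sel_par$base_seed <- sel_par$base_seed + 7919L * i
      res <- tryCatch({
        d <- build_design(hub_by_id[[jobs$hub_id[i]]], rna_lc, atac_lc,
                          jobs$gene_id[i])
        stability_select(d, sel_par)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        skipped <- c(skipped, sprintf("%s: %s", jobs$gene_id[i],
                                      conditionMessage(res)))
      } else {
        selections[[jobs$gene_id[i]]] <- res
      }
    }
  }

  assignments <- assign_causal_elements(selections, inputs$ld_blocks,
                                        genes = inputs$genes,
                                        peak_index = atac_cons$regions,
                                        contained = params$contained)
  assignments <- flag_de_targets(assignments, params$de_genes)

  manifest <- list(
    package_version = as.character(utils::packageVersion("hublinker")),
    params = params[setdiff(names(params), "selection")],
    selection_params = unclass(params$selection),
    counts = list(
      n_samples_ctcf = length(inputs$ctcf_peaks),
      n_ctcf_consensus = nrow(ctcf_cons$regions),
      n_loops_in = nrow(inputs$loops),
      n_loops_kept = nrow(loops_kept),
      n_anchor_nodes = nrow(graph$nodes),
      n_ld_blocks = nrow(inputs$ld_blocks),
      n_ld_inactive = nrow(inactive),
      n_hubs = length(hubs),
      n_atac_consensus = nrow(atac_cons$regions),
      n_genes_expressed = length(expressed),
      n_genes_modelled = length(selections),
      n_genes_skipped = length(skipped),
      n_assignments = nrow(assignments)))

  structure(list(ctcf_consensus = ctcf_cons, atac_consensus = atac_cons,
                 loops_kept = loops_kept, graph = graph, hubs = hubs,
                 inactive_blocks = inactive, selections = selections,
                 skipped = skipped, assignments = assignments,
                 manifest = manifest),
            class = "hub_pipeline")
}

#' @export
print.hub_pipeline <- function(x, ...) {
  cn <- x$manifest$counts
  cat("Regulatory-hub pipeline run\n",
      "  CTCF consensus regions: ", cn$n_ctcf_consensus, "\n",
      "  loops kept:             ", cn$n_loops_kept, " of ", cn$n_loops_in, "\n",
      "  hubs (active LD blocks):", cn$n_hubs, " (", cn$n_ld_blocks -
        cn$n_ld_inactive, " of ", cn$n_ld_blocks, " blocks active)\n",
      "  genes modelled:         ", cn$n_genes_modelled, "\n",
      "  causal-element rows:    ", cn$n_assignments, "\n", sep = "")
  invisible(x)
}

#' Write pipeline outputs to a directory
#'
#' Consensus BEDs (support count in the name column), kept loops as BEDPE,
#' hubs as JSON, one selection TSV per modelled gene, the assignment TSV and
#' a JSON manifest. Output bytes depend only on the result object.
#'
#' @param result a `hub_pipeline`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_pipeline <- function(result, dir) {
  dir.create(file.path(dir, "selections"), recursive = TRUE, showWarnings = FALSE)
  write_bed(result$ctcf_consensus$regions, file.path(dir, "ctcf_consensus.bed"))
  write_bed(result$atac_consensus$regions, file.path(dir, "atac_consensus.bed"))
  write_bedpe(result$loops_kept, file.path(dir, "loops_kept.bedpe"))
  hubs_json <- lapply(result$hubs, function(h) {
    list(hub_id = h$hub_id, seed_blocks = h$seed_blocks, anchors = h$anchors,
         genes = h$genes$gene_id, peaks = h$peaks$peak_id)
  })
  jsonlite::write_json(hubs_json, file.path(dir, "hubs.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (g in names(result$selections)) {
    write_table(summary(result$selections[[g]]),
                file.path(dir, "selections", paste0(g, ".tsv")))
  }
  write_table(result$assignments, file.path(dir, "assignments.tsv"))
  jsonlite::write_json(result$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
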