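## Anchor graph and regulatory-hub discovery.
##
## The browser traversal "find everything the LD block touches, then
## everything those regions touch, and so forth" is transitive closure over
## the loop relation; we realise it as connected components of a graph whose
## nodes are merged loop anchors.

#' Build the anchor graph from filtered loops
#'
#' Nodes are the merged union of all loop anchors (disjoint, sorted); each
#' loop contributes one edge between the nodes containing its anchors, with
#' the edge weight counting supporting loops. A loop whose two anchors merge
#' into the same node is recorded as a self-edge.
#'
#' @param loops loop data.frame, already passed through [filter_loops()].
#' @return object of class `anchor_graph`: list with `nodes` (interval
#'   data.frame) and `edges` (data.frame `from`, `to`, `n_loops` with
#'   `from <= to`, node indices).
#' @export
build_anchor_graph <- function(loops) {
  anchors <- rbind(
    data.frame(chrom = loops$chrom1, start = loops$start1, end = loops$end1,
               stringsAsFactors = FALSE),
    data.frame(chrom = loops$chrom2, start = loops$start2, end = loops$end2,
               stringsAsFactors = FALSE))
  nodes <- merge_intervals(anchors)
  if (nrow(loops) == 0L) {
    return(structure(list(nodes = nodes,
                          edges = data.frame(from = integer(0), to = integer(0),
                                             n_loops = integer(0))),
                     class = "anchor_graph"))
  }
  n <- nrow(loops)
  i1 <- interval_overlaps(anchors[seq_len(n), , drop = FALSE], nodes)
  i2 <- interval_overlaps(anchors[n + seq_len(n), , drop = FALSE], nodes)
  ## anchors lie inside exactly one merged node
  node1 <- node2 <- integer(n)
  node1[i1[, "query"]] <- i1[, "subject"]
  node2[i2[, "query"]] <- i2[, "subject"]
  from <- pmin(node1, node2)
  to <- pmax(node1, node2)
  key <- paste(from, to)
  agg <- tapply(seq_len(n), key, length)
  pairs <- do.call(rbind, strsplit(names(agg), " ", fixed = TRUE))
  edges <- data.frame(from = as.integer(pairs[, 1L]),
                      to = as.integer(pairs[, 2L]),
                      n_loops = as.integer(agg))
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges), class = "anchor_graph")
}

#' @export
print.anchor_graph <- function(x, ...) {
  cat("Anchor graph: ", nrow(x$nodes), " node(s), ", nrow(x$edges),
      " edge(s)\n", sep = "")
  invisible(x)
}

graph_components <- function(graph) {
  n <- nrow(graph$nodes)
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (nrow(graph$edges)) {
    g <- igraph::add_edges(g, rbind(graph$edges$from, graph$edges$to))
  }
  igraph::components(g)$membership
}

#' Find regulatory hubs seeded by risk LD blocks
#'
#' For every LD block overlapping at least one anchor node, the hub is the
#' full connected component containing that node. Blocks overlapping no node
#' are inactive (reported in the `inactive_blocks` attribute and excluded).
#' Blocks sharing a component are merged into one hub with several seed
#' blocks, and a block touching several components unites them in one hub.
#'
#' @param graph an `anchor_graph`.
#' @param ld_blocks data.frame `chrom, start, end, lead_snp`.
#' @param contained if `TRUE` a block seeds a hub only when some node lies
#'   entirely inside it; default is any >= 1 bp overlap.
#' @return list of `regulatory_hub` objects (each with `hub_id`,
#'   `seed_blocks`, `anchors`, plus empty member slots to be filled by
#'   [assign_members()]), ordered by leftmost anchor. The attribute
#'   `inactive_blocks` holds the blocks that seeded nothing.
#' @export
find_hubs <- function(graph, ld_blocks, contained = FALSE) {
  stopifnot(inherits(graph, "anchor_graph"))
  memb <- graph_components(graph)
  nb <- nrow(ld_blocks)
  hits <- interval_overlaps(ld_blocks, graph$nodes)
  if (contained && nrow(hits)) {
    inside <- graph$nodes$start[hits[, "subject"]] >= ld_blocks$start[hits[, "query"]] &
      graph$nodes$end[hits[, "subject"]] <= ld_blocks$end[hits[, "query"]]
    hits <- hits[inside, , drop = FALSE]
  }
  active <- sort(unique(hits[, "query"]))
  inactive <- ld_blocks[setdiff(seq_len(nb), active), , drop = FALSE]
  rownames(inactive) <- NULL
  if (!length(active)) {
    return(structure(list(), inactive_blocks = inactive))
  }
  ## bipartite closure: blocks united through shared components and
  ## components united through shared blocks end up in the same hub
  comp_of_hit <- memb[hits[, "subject"]]
  g2 <- igraph::graph_from_edgelist(
    cbind(paste0("b", hits[, "query"]), paste0("c", comp_of_hit)),
    directed = FALSE)
  cl <- igraph::components(g2)$membership
  hub_ids <- sort(unique(cl))
  hubs <- lapply(hub_ids, function(h) {
    vs <- names(cl)[cl == h]
    blocks <- as.integer(sub("^b", "", vs[startsWith(vs, "b")]))
    comps <- as.integer(sub("^c", "", vs[startsWith(vs, "c")]))
    anchors <- graph$nodes[memb %in% comps, , drop = FALSE]
    anchors <- anchors[order(anchors$chrom, anchors$start), , drop = FALSE]
    rownames(anchors) <- NULL
    seeds <- ld_blocks[sort(blocks), , drop = FALSE]
    rownames(seeds) <- NULL
    structure(list(hub_id = NA_character_, seed_blocks = seeds,
                   anchors = anchors,
                   genes = NULL, peaks = NULL),
              class = "regulatory_hub")
  })
  ## deterministic ordering and ids by leftmost anchor
  ord <- order(vapply(hubs, function(h) h$anchors$chrom[1], ""),
               vapply(hubs, function(h) h$anchors$start[1], 1))
  hubs <- hubs[ord]
  for (i in seq_along(hubs)) hubs[[i]]$hub_id <- sprintf("hub_%d", i)
  structure(hubs, inactive_blocks = inactive)
}

#' @export
print.regulatory_hub <- function(x, ...) {
  cat("Regulatory hub ", x$hub_id, ": ", nrow(x$anchors), " anchor region(s), ",
      nrow(x$seed_blocks), " seed LD block(s)", sep = "")
  if (!is.null(x$genes)) cat(", ", nrow(x$genes), " gene(s), ",
                             nrow(x$peaks), " ATAC peak(s)", sep = "")
  cat("\n  seeds: ", paste(x$seed_blocks$lead_snp, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Attach member genes and ATAC peaks to a hub
#'
#' A gene is a member when its promoter window
#' `[tss - promoter_pad, tss + promoter_pad)` overlaps any anchor region
#' (padded by `anchor_pad`) or any seed LD block; an ATAC consensus region
#' is a member under the same test. Elements inside the risk LD block itself
#' are members even without touching an anchor, so in-block regulatory
#' elements are always scoreable.
#'
#' @param hub a `regulatory_hub` from [find_hubs()].
#' @param genes gene table (see [read_gene_table()]).
#' @param atac_consensus `consensus_peaks` of ATAC regions.
#' @param promoter_pad promoter half-width in bp around the TSS (default 2000).
#' @param anchor_pad bp added around anchor regions before overlap (default 0).
#' @return the hub with `genes` and `peaks` filled (coordinate-sorted;
#'   `peaks` has a `peak_id` column of `chrom:start-end` labels).
#' @export
assign_members <- function(hub, genes, atac_consensus, promoter_pad = 2000,
                           anchor_pad = 0) {
  stopifnot(inherits(hub, "regulatory_hub"),
            inherits(atac_consensus, "consensus_peaks"))
  targets <- rbind(
    hub$anchors[, c("chrom", "start", "end")],
    hub$seed_blocks[, c("chrom", "start", "end")])
  prom <- data.frame(chrom = genes$chrom,
                     start = pmax(0, genes$tss - promoter_pad),
                     end = genes$tss + promoter_pad)
  pad2 <- c(rep(anchor_pad, nrow(hub$anchors)), rep(0, nrow(hub$seed_blocks)))
  ## apply anchor_pad to anchors only (seed blocks are used as-is)
  t_pad <- targets
  t_pad$start <- pmax(0, t_pad$start - pad2)
  t_pad$end <- t_pad$end + pad2
  gh <- interval_overlaps(prom, t_pad)
  member_genes <- genes[sort(unique(gh[, "query"])), , drop = FALSE]
  member_genes <- member_genes[order(member_genes$chrom, member_genes$start,
                                     member_genes$gene_id), , drop = FALSE]
  rownames(member_genes) <- NULL
  ph <- interval_overlaps(atac_consensus$regions, t_pad)
  member_peaks <- atac_consensus$regions[sort(unique(ph[, "query"])), , drop = FALSE]
  member_peaks <- member_peaks[order(member_peaks$chrom, member_peaks$start),
                               c("chrom", "start", "end"), drop = FALSE]
  rownames(member_peaks) <- NULL
  if (nrow(member_peaks)) member_peaks <- cbind(peak_id = interval_ids(member_peaks),
                                                member_peaks)
  else member_peaks <- data.frame(peak_id = character(0), chrom = character(0),
                                  start = numeric(0), end = numeric(0))
  hub$genes <- member_genes
  hub$peaks <- member_peaks
  hub
}
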