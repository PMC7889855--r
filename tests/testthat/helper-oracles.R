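# Independent brute-force oracles. All work base-by-base (or by explicit
# transitive closure) on small coordinates and share no code with the
# package's interval/graph machinery.

# every covered base as a "chrom:pos" string
base_positions <- function(df) {
  if (nrow(df) == 0L) return(character(0))
  unlist(lapply(seq_len(nrow(df)), function(i) {
    paste0(df$chrom[i], ":", seq(df$start[i], df$end[i] - 1L))
  }), use.names = FALSE)
}

oracle_overlap <- function(a, b) {
  length(intersect(base_positions(a), base_positions(b))) > 0L
}

# disjoint segments of a base set, as a sorted data.frame
oracle_segments <- function(df) {
  pos <- unique(base_positions(df))
  if (!length(pos)) {
    return(data.frame(chrom = character(0), start = numeric(0), end = numeric(0)))
  }
  parts <- do.call(rbind, strsplit(pos, ":", fixed = TRUE))
  out <- do.call(rbind, lapply(sort(unique(parts[, 1L])), function(ch) {
    p <- sort(as.numeric(parts[parts[, 1L] == ch, 2L]))
    brk <- c(0L, which(diff(p) > 1L), length(p))
    do.call(rbind, lapply(seq_len(length(brk) - 1L), function(k) {
      data.frame(chrom = ch, start = p[brk[k] + 1L], end = p[brk[k + 1L]] + 1L)
    }))
  }))
  rownames(out) <- NULL
  out
}

# per-base consensus: count supporting samples at every base, threshold with
# exact rational comparison, return the retained base set
oracle_consensus_bases <- function(peaks_by_sample, thr) {
  n <- length(peaks_by_sample)
  per_sample <- lapply(peaks_by_sample, function(df) unique(base_positions(df)))
  tab <- table(unlist(per_sample, use.names = FALSE))
  need <- as.integer(ceiling(thr * n - 1e-9))
  names(tab)[as.integer(tab) >= need]
}

# transitive closure of the anchor-overlap/loop relation: returns, for each
# LD block family, the sorted base set of reachable anchor regions and the
# member lead SNPs
oracle_hubs <- function(loops, ld_blocks) {
  n <- nrow(loops)
  a1 <- data.frame(chrom = loops$chrom1, start = loops$start1, end = loops$end1)
  a2 <- data.frame(chrom = loops$chrom2, start = loops$start2, end = loops$end2)
  nodes <- oracle_segments(rbind(a1, a2))
  nn <- nrow(nodes)
  node_bases <- lapply(seq_len(nn), function(i) base_positions(nodes[i, ]))
  find_node <- function(iv) {
    b <- base_positions(iv)
    which(vapply(node_bases, function(nb) length(intersect(nb, b)) > 0L, logical(1)))
  }
  adj <- diag(nn) > 0
  for (k in seq_len(n)) {
    i <- find_node(a1[k, ]); j <- find_node(a2[k, ])
    adj[i, j] <- TRUE; adj[j, i] <- TRUE
  }
  reach <- adj
  repeat {
    nxt <- (reach %*% reach) > 0
    if (identical(nxt, reach)) break
    reach <- nxt
  }
  block_nodes <- lapply(seq_len(nrow(ld_blocks)), function(b) {
    seeds <- find_node(ld_blocks[b, ])
    if (!length(seeds)) return(integer(0))
    sort(which(colSums(reach[seeds, , drop = FALSE]) > 0))
  })
  active <- which(vapply(block_nodes, length, 1L) > 0L)
  groups <- lapply(active, function(b) list(blocks = b, nodes = block_nodes[[b]]))
  # merge block families sharing any reachable node
  changed <- TRUE
  while (changed && length(groups) > 1L) {
    changed <- FALSE
    for (i in seq_len(length(groups) - 1L)) {
      for (j in seq(i + 1L, length(groups))) {
        if (length(intersect(groups[[i]]$nodes, groups[[j]]$nodes))) {
          groups[[i]] <- list(blocks = sort(c(groups[[i]]$blocks, groups[[j]]$blocks)),
                              nodes = sort(union(groups[[i]]$nodes, groups[[j]]$nodes)))
          groups[[j]] <- NULL
          changed <- TRUE
          break
        }
      }
      if (changed) break
    }
  }
  lapply(groups, function(g) {
    list(lead_snps = sort(ld_blocks$lead_snp[g$blocks]),
         anchor_bases = sort(unlist(node_bases[g$nodes], use.names = FALSE)))
  })
}

# random small fixtures --------------------------------------------------

random_interval <- function(chroms = c("chr1", "chr2"), max_pos = 900,
                            max_w = 60) {
  st <- sample.int(max_pos, 1L)
  data.frame(chrom = sample(chroms, 1L), start = st,
             end = st + sample.int(max_w, 1L), stringsAsFactors = FALSE)
}

random_intervals <- function(n, ...) {
  do.call(rbind, replicate(n, random_interval(...), simplify = FALSE))
}

random_loops <- function(n_loops, n_anchor_pool = 8L, chroms = c("chr1", "chr2")) {
  pool <- random_intervals(n_anchor_pool, chroms = chroms)
  i <- sample.int(n_anchor_pool, n_loops, replace = TRUE)
  j <- sample.int(n_anchor_pool, n_loops, replace = TRUE)
  data.frame(chrom1 = pool$chrom[i], start1 = pool$start[i], end1 = pool$end[i],
             chrom2 = pool$chrom[j], start2 = pool$start[j], end2 = pool$end[j],
             read_support = sample(2:6, n_loops, replace = TRUE),
             group_id = "t", stringsAsFactors = FALSE)
}

# dropout fixture around fixed disjoint sites: identical coordinates across
# samples, so region-level and per-base consensus support coincide
dropout_peakset <- function(n_sites = 8L, n_samples = 5L, p_keep = 0.6) {
  st <- 100 + (seq_len(n_sites) - 1L) * 200
  sites <- data.frame(chrom = "chr1", start = st,
                      end = st + sample(20:60, n_sites, replace = TRUE),
                      stringsAsFactors = FALSE)
  peaks <- lapply(seq_len(n_samples), function(s) {
    sites[runif(n_sites) < p_keep, , drop = FALSE]
  })
  names(peaks) <- paste0("s", seq_len(n_samples))
  peaks
}

iv <- function(chrom, start, end) {
  data.frame(chrom = chrom, start = start, end = end, stringsAsFactors = FALSE)
}
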