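## Synthetic input bundles with planted structure: replicated peaks with
## sample drop-out, loops chaining hub anchors into connected components,
## risk LD blocks (active ones covering the planted elements), a gene
## annotation, and RNA/ATAC count matrices in which planted peak
## accessibilities linearly drive gene expression on the log scale with
## negative-binomial observation noise.

#' Simulation configuration
#'
#' Defaults define the reference desk-scale study: 20 matched samples, two
#' hubs of four chained anchors each, four genes and six ATAC peaks per hub,
#' four planted element-to-gene links at `beta = 2` (log2 expression units
#' per unit latent accessibility), one active LD block per hub covering the
#' planted elements plus one in-block decoy peak, and as many inactive
#' blocks again (`ld_block_fraction_active = 0.5`).
#'
#' @param seed integer master seed; every stage derives its stream from it.
#' @param n_samples matched samples with both RNA and ATAC data.
#' @param n_hubs planted hubs (one chromosome each).
#' @param anchors_per_hub chained CTCF anchors per hub.
#' @param genes_per_hub,peaks_per_hub hub members.
#' @param planted_links data.frame `hub, peak, gene, beta`; peak/gene are
#'   1-based within-hub indices. Planted peaks are placed inside the hub's
#'   active LD block.
#' @param peak_dropout_rate probability a true peak is missing from a
#'   sample's call set.
#' @param loop_read_mean mean of the `1 + Poisson(mean - 1)` read-support
#'   draw.
#' @param nb_dispersion negative-binomial dispersion (1/size) of count noise.
#' @param baseline_log_mean,baseline_log_sd normal prior of per-feature
#'   baseline log2 abundance.
#' @param noise_sd sd of the latent log2-expression noise.
#' @param n_decoy_loops loops between anchors connected to no LD block.
#' @param ld_block_fraction_active fraction of LD blocks that are active
#'   (the others overlap no anchor and must be reported inactive).
#' @param n_background_genes,n_background_peaks features outside all hubs
#'   (a fifth of background genes are near-silent so the expressed filter
#'   has work to do).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_samples = 20L, n_hubs = 2L,
                       anchors_per_hub = 4L, genes_per_hub = 4L,
                       peaks_per_hub = 6L,
                       planted_links = data.frame(
                         hub = c(1L, 1L, 2L, 2L),
                         peak = c(1L, 2L, 1L, 2L),
                         gene = c(1L, 2L, 1L, 2L),
                         beta = 2),
                       peak_dropout_rate = 0.1, loop_read_mean = 5,
                       nb_dispersion = 0.1, baseline_log_mean = 7,
                       baseline_log_sd = 1, noise_sd = 0.5,
                       n_decoy_loops = 4L, ld_block_fraction_active = 0.5,
                       n_background_genes = 100L, n_background_peaks = 40L) {
  stopifnot(peak_dropout_rate >= 0, peak_dropout_rate < 1,
            loop_read_mean >= 1, nb_dispersion > 0, noise_sd >= 0,
            ld_block_fraction_active > 0, ld_block_fraction_active <= 1,
            n_samples >= 2L, n_hubs >= 1L, anchors_per_hub >= 1L)
  if (nrow(planted_links)) {
    stopifnot(all(planted_links$hub >= 1L), all(planted_links$hub <= n_hubs),
              all(planted_links$peak >= 1L), all(planted_links$peak <= peaks_per_hub),
              all(planted_links$gene >= 1L), all(planted_links$gene <= genes_per_hub))
  }
  cfg <- as.list(environment())
  structure(cfg, class = "sim_config")
}

sub_seed <- function(seed, k) {
  as.integer((as.numeric(seed) + 999983 * k) %% .Machine$integer.max)
}

#' Replicated per-sample peak calls with drop-out
#'
#' Each true region is independently missing from each sample's call set
#' with probability `dropout`; coordinates are otherwise reproduced exactly.
#' Draws from the current RNG stream.
#'
#' @param regions interval data.frame of true regions.
#' @param sample_ids character vector of sample names.
#' @param dropout per-sample, per-region drop-out probability.
#' @return named list of interval data.frames, one per sample.
#' @export
simulate_replicate_peaks <- function(regions, sample_ids, dropout) {
  setNames(lapply(sample_ids, function(s) {
    keep <- runif(nrow(regions)) >= dropout
    out <- regions[keep, c("chrom", "start", "end"), drop = FALSE]
    rownames(out) <- NULL
    out
  }), sample_ids)
}

## NB counts around mean 2^latent, scaled by a per-sample depth factor.
nb_counts_from_latent <- function(latent, depth, dispersion) {
  mu <- sweep(2^latent, 2L, depth, "*")
  cnt <- matrix(rnbinom(length(mu), mu = as.numeric(mu), size = 1 / dispersion),
                nrow = nrow(mu), dimnames = dimnames(latent))
  storage.mode(cnt) <- "integer"
  cnt
}

#' Generate a complete synthetic input bundle
#'
#' See [sim_config()] for the study conditions. The bundle is internally
#' consistent: every loop anchor lies on a true CTCF site, every planted
#' element lies inside an active LD block, RNA and ATAC matrices share the
#' sample set, and the truth table lists the planted element-to-gene pairs.
#' Identical configurations (including seed) give identical bundles.
#'
#' @param config a [sim_config()].
#' @return list of class `sim_bundle` with elements `config`, `ctcf_peaks`
#'   and `atac_peaks` (per-sample lists), `loops`, `ld_blocks` (with an
#'   `active` flag), `genes`, `rna_counts`, `atac_counts`, `truth`.
#' @export
simulate_bundle <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  old <- save_rng()
  on.exit(restore_rng(old))
  samples <- sprintf("s%02d", seq_len(config$n_samples))
  A <- config$anchors_per_hub

  ## --- deterministic geometry ------------------------------------------
  planted_by_hub <- split(config$planted_links, config$planted_links$hub)
  n_in_block <- vapply(seq_len(config$n_hubs), function(h) {
    pl <- planted_by_hub[[as.character(h)]]
    np <- if (is.null(pl)) 0L else length(unique(pl$peak))
    ## planted peaks + one in-block decoy (when room allows)
    min(config$peaks_per_hub, np + 1L)
  }, 1L)
  anchor_w <- max(4000, 400 + max(c(n_in_block, 1L)) * 1200)
  anchors <- do.call(rbind, lapply(seq_len(config$n_hubs), function(h) {
    st <- 100000 + (seq_len(A) - 1L) * (anchor_w + 16000)
    data.frame(hub = h, anchor = seq_len(A), chrom = paste0("chr", h),
               start = st, end = st + anchor_w, stringsAsFactors = FALSE)
  }))
  ld_active <- do.call(rbind, lapply(seq_len(config$n_hubs), function(h) {
    a1 <- anchors[anchors$hub == h & anchors$anchor == 1L, ]
    data.frame(chrom = a1$chrom, start = a1$start - 1000, end = a1$end + 1000,
               lead_snp = sprintf("rs%d", 1000 + h), active = TRUE,
               stringsAsFactors = FALSE)
  }))
  n_total_blocks <- max(config$n_hubs,
                        round(config$n_hubs / config$ld_block_fraction_active))
  n_inactive <- n_total_blocks - config$n_hubs
  ld_inactive <- if (n_inactive > 0L) {
    st <- 10e6 + (seq_len(n_inactive) - 1L) * 50000
    data.frame(chrom = "chr1", start = st, end = st + 20000,
               lead_snp = sprintf("rs%d", 2000 + seq_len(n_inactive)),
               active = FALSE, stringsAsFactors = FALSE)
  } else NULL
  ld_blocks <- rbind(ld_active, ld_inactive)

  ## ATAC peaks: in-block peaks inside anchor 1, the rest round-robin over
  ## the remaining anchors
  peaks <- do.call(rbind, lapply(seq_len(config$n_hubs), function(h) {
    hub_anchors <- anchors[anchors$hub == h, ]
    nib <- n_in_block[h]
    rows <- lapply(seq_len(config$peaks_per_hub), function(p) {
      if (p <= nib) {
        a <- hub_anchors[1L, ]
        st <- a$start + 200 + (p - 1L) * 1200
      } else {
        k <- p - nib - 1L
        ai <- if (A > 1L) 2L + (k %% (A - 1L)) else 1L
        a <- hub_anchors[ai, ]
        st <- a$start + 200 + (k %/% max(A - 1L, 1L)) * 1200
      }
      data.frame(hub = h, peak = p, chrom = a$chrom, start = st, end = st + 600,
                 in_block = p <= nib, stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  }))
  bg_peaks <- if (config$n_background_peaks > 0L) {
    st <- 5e6 + (seq_len(config$n_background_peaks) - 1L) * 10000
    data.frame(hub = 0L, peak = seq_len(config$n_background_peaks),
               chrom = "chrBG", start = st, end = st + 600, in_block = FALSE,
               stringsAsFactors = FALSE)
  } else NULL
  all_peaks <- rbind(peaks, bg_peaks)
  all_peaks$peak_id <- interval_ids(all_peaks)

  ## genes: promoters at anchors 2..A (or anchor 1 for single-anchor hubs)
  genes <- do.call(rbind, lapply(seq_len(config$n_hubs), function(h) {
    hub_anchors <- anchors[anchors$hub == h, ]
    rows <- lapply(seq_len(config$genes_per_hub), function(g) {
      ai <- if (A > 1L) 2L + ((g - 1L) %% (A - 1L)) else 1L
      a <- hub_anchors[ai, ]
      tss <- a$start + 2000 + ((g - 1L) %/% max(A - 1L, 1L)) * 60
      data.frame(hub = h, gene = g, gene_id = sprintf("gene%d_%d", h, g),
                 chrom = a$chrom, start = tss, end = tss + 5000, strand = "+",
                 tss = tss, stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  }))
  bg_genes <- if (config$n_background_genes > 0L) {
    tss <- 1e6 + (seq_len(config$n_background_genes) - 1L) * 10000
    data.frame(hub = 0L, gene = seq_len(config$n_background_genes),
               gene_id = sprintf("bg_gene%d", seq_len(config$n_background_genes)),
               chrom = "chrBG", start = tss, end = tss + 5000, strand = "+",
               tss = tss, stringsAsFactors = FALSE)
  } else NULL
  all_genes <- rbind(genes, bg_genes)

  ## CTCF sites: hub anchors plus decoy loop anchors
  decoy_anchors <- if (config$n_decoy_loops > 0L) {
    st <- 5e6 + (seq_len(2L * config$n_decoy_loops) - 1L) * 10000
    data.frame(chrom = "chr1", start = st, end = st + 1000,
               stringsAsFactors = FALSE)
  } else NULL
  ctcf_sites <- rbind(anchors[, c("chrom", "start", "end")], decoy_anchors)

  ## --- loops ------------------------------------------------------------
  set.seed(sub_seed(config$seed, 1L))
  chain <- do.call(rbind, lapply(seq_len(config$n_hubs), function(h) {
    hub_anchors <- anchors[anchors$hub == h, ]
    if (A < 2L) return(NULL)
    idx <- seq_len(A - 1L)
    ## two independent observations per adjacent pair keep the chain intact
    ## after the >= 2-read filter
    do.call(rbind, lapply(c(1L, 2L), function(rep) {
      data.frame(chrom1 = hub_anchors$chrom[idx], start1 = hub_anchors$start[idx],
                 end1 = hub_anchors$end[idx],
                 chrom2 = hub_anchors$chrom[idx + 1L],
                 start2 = hub_anchors$start[idx + 1L],
                 end2 = hub_anchors$end[idx + 1L], stringsAsFactors = FALSE)
    }))
  }))
  decoy <- if (config$n_decoy_loops > 0L) {
    i <- 2L * seq_len(config$n_decoy_loops) - 1L
    data.frame(chrom1 = decoy_anchors$chrom[i], start1 = decoy_anchors$start[i],
               end1 = decoy_anchors$end[i], chrom2 = decoy_anchors$chrom[i + 1L],
               start2 = decoy_anchors$start[i + 1L], end2 = decoy_anchors$end[i + 1L],
               stringsAsFactors = FALSE)
  } else NULL
  loops <- rbind(chain, decoy)
  loops$read_support <- 1L + rpois(nrow(loops), config$loop_read_mean - 1)
  loops$group_id <- "sim"
  loops <- canonicalize_loops(loops)

  ## --- per-sample peak calls -------------------------------------------
  set.seed(sub_seed(config$seed, 2L))
  ctcf_by_sample <- simulate_replicate_peaks(ctcf_sites, samples,
                                             config$peak_dropout_rate)
  set.seed(sub_seed(config$seed, 3L))
  atac_by_sample <- simulate_replicate_peaks(all_peaks, samples,
                                             config$peak_dropout_rate)

  ## --- latent accessibility and expression -----------------------------
  set.seed(sub_seed(config$seed, 4L))
  np <- nrow(all_peaks)
  mu_p <- rnorm(np, config$baseline_log_mean, config$baseline_log_sd)
  acc <- matrix(rnorm(np * config$n_samples), nrow = np) + mu_p
  dimnames(acc) <- list(all_peaks$peak_id, samples)
  ng <- nrow(all_genes)
  base_g <- rnorm(ng, config$baseline_log_mean, config$baseline_log_sd)
  ## a fifth of background genes near-silent, for the expressed filter
  if (!is.null(bg_genes) && nrow(bg_genes) >= 5L) {
    silent <- which(all_genes$hub == 0L)[seq_len(nrow(bg_genes) %/% 5L)]
    base_g[silent] <- -3
  }
  expr <- matrix(rnorm(ng * config$n_samples, sd = config$noise_sd), nrow = ng) +
    base_g
  dimnames(expr) <- list(all_genes$gene_id, samples)
  if (nrow(config$planted_links)) {
    for (k in seq_len(nrow(config$planted_links))) {
      lk <- config$planted_links[k, ]
      pid <- all_peaks$peak_id[all_peaks$hub == lk$hub & all_peaks$peak == lk$peak]
      gid <- all_genes$gene_id[all_genes$hub == lk$hub & all_genes$gene == lk$gene]
      ## effect applied to centred accessibility: baseline absorbs beta*mu_p
      expr[gid, ] <- expr[gid, ] + lk$beta * (acc[pid, ] - mu_p[match(pid, all_peaks$peak_id)])
    }
  }

  ## --- observed counts --------------------------------------------------
  set.seed(sub_seed(config$seed, 5L))
  depth_rna <- runif(config$n_samples, 0.7, 1.3)
  depth_atac <- runif(config$n_samples, 0.7, 1.3)
  rna_counts <- nb_counts_from_latent(expr, depth_rna, config$nb_dispersion)
  atac_counts <- nb_counts_from_latent(acc, depth_atac, config$nb_dispersion)

  ## --- truth table ------------------------------------------------------
  truth <- if (nrow(config$planted_links)) {
    do.call(rbind, lapply(seq_len(nrow(config$planted_links)), function(k) {
      lk <- config$planted_links[k, ]
      pk <- all_peaks[all_peaks$hub == lk$hub & all_peaks$peak == lk$peak, ]
      data.frame(element_id = pk$peak_id, chrom = pk$chrom, start = pk$start,
                 end = pk$end,
                 gene_id = all_genes$gene_id[all_genes$hub == lk$hub &
                                               all_genes$gene == lk$gene],
                 beta = lk$beta,
                 ld_lead_snp = ld_active$lead_snp[lk$hub],
                 active = ld_active$active[lk$hub], stringsAsFactors = FALSE)
    }))
  } else {
    data.frame(element_id = character(0), chrom = character(0),
               start = numeric(0), end = numeric(0), gene_id = character(0),
               beta = numeric(0), ld_lead_snp = character(0),
               active = logical(0))
  }

  structure(list(config = config,
                 ctcf_peaks = ctcf_by_sample,
                 atac_peaks = atac_by_sample,
                 loops = loops,
                 ld_blocks = ld_blocks,
                 genes = all_genes[, c("gene_id", "chrom", "start", "end",
                                       "strand", "tss")],
                 rna_counts = rna_counts,
                 atac_counts = atac_counts,
                 truth = truth),
            class = "sim_bundle")
}

#' @export
print.sim_bundle <- function(x, ...) {
  cat("Synthetic bundle: ", length(x$ctcf_peaks), " sample(s), ",
      nrow(x$loops), " loop(s), ", nrow(x$ld_blocks), " LD block(s) (",
      sum(x$ld_blocks$active), " active), ", nrow(x$rna_counts), " gene(s), ",
      nrow(x$atac_counts), " ATAC peak(s), ", nrow(x$truth),
      " planted link(s)\n", sep = "")
  invisible(x)
}

#' Write / read a bundle as plain-text files
#'
#' Per-sample BEDs under `ctcf/` and `atac/`, `loops.bedpe`,
#' `ld_blocks.bed`, `genes.tsv`, `rna_counts.tsv`, `atac_counts.tsv`,
#' `truth.tsv`.
#'
#' @param bundle a `sim_bundle`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly (`write_bundle`); a `sim_bundle`-shaped list
#'   without `config` (`read_bundle`).
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(file.path(dir, "ctcf"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "atac"), recursive = TRUE, showWarnings = FALSE)
  for (s in names(bundle$ctcf_peaks)) {
    write_bed(bundle$ctcf_peaks[[s]], file.path(dir, "ctcf", paste0(s, ".bed")))
  }
  for (s in names(bundle$atac_peaks)) {
    write_bed(bundle$atac_peaks[[s]], file.path(dir, "atac", paste0(s, ".bed")))
  }
  write_bedpe(bundle$loops, file.path(dir, "loops.bedpe"))
  write_bed(bundle$ld_blocks, file.path(dir, "ld_blocks.bed"))
  write_table(bundle$genes[, c("gene_id", "chrom", "start", "end", "strand")],
              file.path(dir, "genes.tsv"))
  write_count_matrix(bundle$rna_counts, file.path(dir, "rna_counts.tsv"),
                     id_col = "gene_id")
  write_count_matrix(bundle$atac_counts, file.path(dir, "atac_counts.tsv"))
  write_table(bundle$truth, file.path(dir, "truth.tsv"))
  invisible(dir)
}

#' @rdname write_bundle
#' @export
read_bundle <- function(dir) {
  rd <- function(sub) {
    files <- sort(list.files(file.path(dir, sub), pattern = "\\.bed$",
                             full.names = TRUE))
    setNames(lapply(files, read_bed), sub("\\.bed$", "", basename(files)))
  }
  truth <- read.delim(file.path(dir, "truth.tsv"), stringsAsFactors = FALSE)
  ld <- read_ld_blocks(file.path(dir, "ld_blocks.bed"))
  structure(list(ctcf_peaks = rd("ctcf"), atac_peaks = rd("atac"),
                 loops = read_bedpe(file.path(dir, "loops.bedpe")),
                 ld_blocks = ld,
                 genes = read_gene_table(file.path(dir, "genes.tsv")),
                 rna_counts = read_count_matrix(file.path(dir, "rna_counts.tsv")),
                 atac_counts = read_count_matrix(file.path(dir, "atac_counts.tsv")),
                 truth = truth),
            class = "sim_bundle")
}

#' A small planted-signal design for selection benchmarking
#'
#' Independent standard-normal features; the response is
#' `beta * sum(planted features) + Normal(0, noise_sd)`, so `beta` is the
#' planted effect in units of the noise SD. Features carry synthetic
#' interval metadata so downstream assignment is exercisable.
#'
#' @param n_samples,n_features design size (defaults 20 x 12).
#' @param n_planted number of truly relevant features (the first ones).
#' @param beta planted effect size (default 2).
#' @param noise_sd response noise SD (default 1).
#' @param seed integer seed.
#' @return a `hub_design` whose `planted` attribute names the true features.
#' @export
simulate_selection_design <- function(n_samples = 20L, n_features = 12L,
                                      n_planted = 3L, beta = 2, noise_sd = 1,
                                      seed = 1L) {
  stopifnot(n_planted <= n_features)
  old <- save_rng()
  on.exit(restore_rng(old))
  set.seed(as.integer(seed))
  X <- matrix(rnorm(n_samples * n_features), nrow = n_samples)
  colnames(X) <- sprintf("x%02d", seq_len(n_features))
  rownames(X) <- sprintf("s%02d", seq_len(n_samples))
  y <- beta * rowSums(X[, seq_len(n_planted), drop = FALSE]) +
    rnorm(n_samples, sd = noise_sd)
  names(y) <- rownames(X)
  meta <- data.frame(feature_id = colnames(X), type = "peak", chrom = "chrS",
                     start = (seq_len(n_features) - 1L) * 1000,
                     end = (seq_len(n_features) - 1L) * 1000 + 500,
                     stringsAsFactors = FALSE)
  structure(list(target_gene_id = "target", response = y, features = X,
                 feature_meta = meta),
            class = "hub_design",
            planted = colnames(X)[seq_len(n_planted)])
}

#' Score assignments against the planted truth
#'
#' Sensitivity is the fraction of planted element-to-gene pairs in active LD
#' blocks that appear among the assignments (element matched by >= 1 bp
#' overlap, gene by id); the false-discovery fraction is the share of
#' emitted pairs matching no planted pair.
#'
#' @param assignments output of [assign_causal_elements()].
#' @param truth the `truth` table of the generating bundle.
#' @return list with `sensitivity`, `false_discovery_fraction`,
#'   `n_recovered`, `n_planted_active`, `n_emitted`.
#' @export
truth_compare <- function(assignments, truth) {
  emitted <- unique(assignments[, c("feature_chrom", "feature_start",
                                    "feature_stop", "target_gene")])
  pair_match <- function(tr_row) {
    same_gene <- emitted$target_gene == tr_row$gene_id
    if (!any(same_gene)) return(FALSE)
    e <- emitted[same_gene, , drop = FALSE]
    any(e$feature_chrom == tr_row$chrom &
          pmax(e$feature_start, tr_row$start) < pmin(e$feature_stop, tr_row$end))
  }
  active <- truth[truth$active, , drop = FALSE]
  n_rec <- if (nrow(active)) sum(vapply(seq_len(nrow(active)), function(i)
    pair_match(active[i, ]), logical(1))) else 0L
  emitted_planted <- if (nrow(emitted)) vapply(seq_len(nrow(emitted)), function(i) {
    e <- emitted[i, ]
    any(truth$gene_id == e$target_gene & truth$chrom == e$feature_chrom &
          pmax(truth$start, e$feature_start) < pmin(truth$end, e$feature_stop))
  }, logical(1)) else logical(0)
  list(sensitivity = if (nrow(active)) n_rec / nrow(active) else NA_real_,
       false_discovery_fraction = if (nrow(emitted))
         sum(!emitted_planted) / nrow(emitted) else NA_real_,
       n_recovered = n_rec,
       n_planted_active = nrow(active),
       n_emitted = nrow(emitted))
}
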