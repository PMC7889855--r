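small_cfg <- function(seed = 1L, ...) {
  sim_config(seed = seed, n_samples = 6L, n_hubs = 1L, anchors_per_hub = 3L,
             genes_per_hub = 2L, peaks_per_hub = 3L,
             planted_links = data.frame(hub = 1L, peak = 1L, gene = 1L, beta = 2),
             n_background_genes = 10L, n_background_peaks = 5L,
             n_decoy_loops = 1L, ...)
}

test_that("identical seeds give identical bundles, on disk too", {
  b1 <- simulate_bundle(small_cfg())
  b2 <- simulate_bundle(small_cfg())
  expect_identical(b1, b2)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_bundle(b1, d1); write_bundle(b2, d2)
  f1 <- list.files(d1, recursive = TRUE)
  expect_setequal(f1, list.files(d2, recursive = TRUE))
  for (f in f1) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
  expect_false(identical(b1, simulate_bundle(small_cfg(seed = 2L))))
})

test_that("bundles survive a write/read round trip", {
  b <- simulate_bundle(small_cfg())
  d <- withr::local_tempdir()
  write_bundle(b, d)
  r <- read_bundle(d)
  expect_identical(r$rna_counts, b$rna_counts)
  expect_identical(r$atac_counts, b$atac_counts)
  expect_equal(r$loops, b$loops)
  expect_equal(r$genes, b$genes)
  expect_equal(r$ld_blocks[, c("chrom", "start", "end", "lead_snp")],
               b$ld_blocks[, c("chrom", "start", "end", "lead_snp")])
  expect_equal(nrow(r$truth), nrow(b$truth))
})

test_that("bundle is internally consistent", {
  b <- simulate_bundle(sim_config(seed = 3L))
  # every loop anchor lies on a true CTCF site of every non-dropout sample set
  ctcf_union <- merge_intervals(do.call(rbind, b$ctcf_peaks))
  anchors <- rbind(iv(b$loops$chrom1, b$loops$start1, b$loops$end1),
                   iv(b$loops$chrom2, b$loops$start2, b$loops$end2))
  hits <- interval_overlaps(anchors, ctcf_union)
  expect_equal(sort(unique(hits[, "query"])), seq_len(nrow(anchors)))
  # planted elements lie inside active LD blocks
  act <- b$ld_blocks[b$ld_blocks$active, ]
  for (k in seq_len(nrow(b$truth))) {
    tr <- b$truth[k, ]
    expect_true(any(tr$chrom == act$chrom & tr$start >= act$start &
                      tr$end <= act$end))
  }
  # matched sample ids across assays and peak lists
  expect_identical(colnames(b$rna_counts), colnames(b$atac_counts))
  expect_identical(names(b$ctcf_peaks), colnames(b$rna_counts))
  # truth genes and elements exist in the matrices
  expect_true(all(b$truth$gene_id %in% rownames(b$rna_counts)))
  expect_true(all(b$truth$element_id %in% rownames(b$atac_counts)))
  # read support never below 1
  expect_true(all(b$loops$read_support >= 1L))
})

test_that("zero dropout keeps every peak in every sample", {
  b <- simulate_bundle(small_cfg(peak_dropout_rate = 0))
  n_atac <- nrow(b$atac_counts)
  for (s in names(b$atac_peaks)) expect_equal(nrow(b$atac_peaks[[s]]), n_atac)
  cons <- build_consensus_peaks(b$atac_peaks, 0.6)
  expect_equal(sum(cons$regions$support == length(b$atac_peaks)), nrow(cons$regions))
})

test_that("negative-binomial counts match the configured moments", {
  old <- hublinker:::save_rng(); on.exit(hublinker:::restore_rng(old))
  set.seed(77)
  n <- 10000L
  latent <- matrix(6, nrow = 1, ncol = n,
                   dimnames = list("f", paste0("s", 1:n)))
  disp <- 0.2
  cnt <- hublinker:::nb_counts_from_latent(latent, rep(1, n), disp)
  mu <- 2^6
  expect_equal(mean(cnt), mu, tolerance = 0.02)
  expect_equal(var(as.numeric(cnt)), mu + disp * mu^2, tolerance = 0.1)
})

test_that("truth_compare identities and set arithmetic", {
  b <- simulate_bundle(small_cfg())
  tr <- b$truth
  perfect <- data.frame(feature_chrom = tr$chrom, feature_start = tr$start,
                        feature_stop = tr$end, feature_name = "x",
                        target_gene = tr$gene_id, ld_lead_snp = tr$ld_lead_snp,
                        is_de = NA, stringsAsFactors = FALSE)
  m <- truth_compare(perfect, tr)
  expect_equal(m$sensitivity, 1)
  expect_equal(m$false_discovery_fraction, 0)
  empty <- perfect[0, ]
  m0 <- truth_compare(empty, tr)
  expect_equal(m0$sensitivity, 0)
  # one planted pair recovered, one alien pair emitted
  half <- rbind(perfect[1, ],
                data.frame(feature_chrom = "chr9", feature_start = 1,
                           feature_stop = 100, feature_name = "x",
                           target_gene = "nogene", ld_lead_snp = "rs0",
                           is_de = NA, stringsAsFactors = FALSE))
  mh <- truth_compare(half, tr)
  expect_equal(mh$n_recovered, 1L)
  expect_equal(mh$false_discovery_fraction, 0.5)
})

test_that("the benchmark selection design has the planted linear structure", {
  d <- simulate_selection_design(n_samples = 2000L, n_features = 5L,
                                 n_planted = 2L, beta = 2, seed = 9L)
  co <- coef(lm(d$response ~ d$features))[-1]
  expect_equal(unname(co[1:2]), c(2, 2), tolerance = 0.1)
  expect_equal(unname(co[3:5]), rep(0, 3), tolerance = 0.1)
  expect_identical(attr(d, "planted"), c("x01", "x02"))
  expect_identical(simulate_selection_design(seed = 4L),
                   simulate_selection_design(seed = 4L))
})
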