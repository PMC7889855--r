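count_fixture <- function(nf = 10L, ns = 6L, seed = 1L) {
  set.seed(seed)
  m <- matrix(rpois(nf * ns, 50), nrow = nf,
              dimnames = list(paste0("f", seq_len(nf)), paste0("s", seq_len(ns))))
  storage.mode(m) <- "integer"
  m
}

test_that("cpm matches its definition and the column-sum identity", {
  m <- matrix(c(100L, 0L), nrow = 2, dimnames = list(c("a", "b"), "s1"))
  expect_equal(cpm(m, lib_sizes = 1e6)["a", "s1"], 100)
  expect_equal(unname(cpm(m)["a", "s1"]), 1e6)
  zero_row <- rbind(count_fixture(), z = 0L)
  expect_true(all(cpm(zero_row)["z", ] == 0))
  expect_equal(colSums(cpm(count_fixture())), rep(1e6, 6),
               tolerance = 1e-6, ignore_attr = TRUE)
  expect_error(cpm(m, lib_sizes = c(0)), "positive")
})

test_that("log_cpm is finite at zero counts and strictly monotone", {
  m <- count_fixture()
  m[1, ] <- 0L
  lc <- log_cpm(m)
  expect_true(all(is.finite(lc)))
  # within one sample, a larger count gives a larger log-CPM
  for (s in colnames(m)) {
    ord <- order(m[, s])
    d <- diff(lc[ord, s])
    expect_true(all(d[diff(m[ord, s]) > 0] > 0))
    expect_true(all(d[diff(m[ord, s]) == 0] == 0))
  }
})

test_that("log_cpm inverts to the expected value on a constructed count", {
  # choose count so (count + 0.5) / (lib + 1) * 1e6 = 2^20
  lib <- 2e6
  count <- 2^20 * (lib + 1) / 1e6 - 0.5
  m <- matrix(c(count, 10), nrow = 2,
              dimnames = list(c("a", "b"), "s1"))
  expect_equal(log_cpm(m, lib_sizes = lib)["a", "s1"], 20)
})

test_that("log_cpm agrees with edgeR's prior-protected log-CPM at equal library sizes", {
  skip_if_not_installed("edgeR")
  m <- count_fixture(nf = 30L, ns = 4L, seed = 9)
  lib <- rep(5000L, 4L)
  ours <- log_cpm(m, lib_sizes = lib, prior = 0.5)
  theirs <- edgeR::cpm(m, lib.size = lib, log = TRUE, prior.count = 0.5)
  expect_equal(ours, theirs, tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("expressed filter boundary: exactly five qualifying samples pass", {
  ns <- 26L
  lib <- rep(1e6, ns)
  m <- matrix(0L, nrow = 3, ncol = ns,
              dimnames = list(c("five", "four_high", "zero"), paste0("s", 1:ns)))
  m["five", 1:5] <- 1L        # CPM exactly 1 in 5 samples
  m["four_high", 1:4] <- 50L  # CPM 50 but only 4 samples
  keep <- expressed_filter(m, min_cpm = 1, min_samples = 5L, lib_sizes = lib)
  expect_identical(keep, "five")
  all_zero <- matrix(0L, 2, 6, dimnames = list(c("a", "b"), paste0("s", 1:6)))
  expect_length(expressed_filter(all_zero, lib_sizes = rep(1e6, 6)), 0L)
})

test_that("expressed filter is monotone in min_samples", {
  m <- count_fixture(nf = 40L, ns = 10L, seed = 2)
  m[sample(length(m), 150)] <- 0L
  prev <- expressed_filter(m, min_samples = 1L)
  for (k in 2:10) {
    cur <- expressed_filter(m, min_samples = k)
    expect_true(all(cur %in% prev))
    prev <- cur
  }
})

design_fixture <- function() {
  loops <- data.frame(chrom1 = "chr1", start1 = 1000, end1 = 2000,
                      chrom2 = "chr1", start2 = 8000, end2 = 9000,
                      read_support = 3L, group_id = "g", stringsAsFactors = FALSE)
  ld <- data.frame(chrom = "chr1", start = 500, end = 2500, lead_snp = "rs1",
                   stringsAsFactors = FALSE)
  hub <- find_hubs(build_anchor_graph(loops), ld)[[1]]
  genes <- data.frame(gene_id = paste0("g", 1:3), chrom = "chr1",
                      start = c(1100, 8100, 8400), end = c(6100, 13100, 13400),
                      strand = "+", tss = c(1100, 8100, 8400),
                      stringsAsFactors = FALSE)
  peak_iv <- iv("chr1", c(1200, 1500, 8200, 8700), c(1300, 1600, 8300, 8800))
  atac_cons <- build_consensus_peaks(list(s1 = peak_iv), 0.6)
  hub <- assign_members(hub, genes, atac_cons, promoter_pad = 500)
  samples <- paste0("s", 1:8)
  set.seed(4)
  rna <- matrix(rnorm(3 * 8, 5), nrow = 3, dimnames = list(genes$gene_id, samples))
  atac <- matrix(rnorm(4 * 8, 5), nrow = 4,
                 dimnames = list(hublinker:::interval_ids(peak_iv), samples))
  list(hub = hub, rna = rna, atac = atac)
}

test_that("design has (T-1) + P feature columns and excludes the target", {
  fx <- design_fixture()
  d <- build_design(fx$hub, fx$rna, fx$atac, "g1")
  expect_equal(ncol(d$features), 2L + 4L)
  expect_false("g1" %in% colnames(d$features))
  expect_equal(d$feature_meta$type, c("gene", "gene", rep("peak", 4)))
  expect_identical(rownames(d$features), names(d$response))
  # target never leaks into its own features, whichever gene is modelled
  for (g in c("g2", "g3")) {
    expect_false(g %in% colnames(build_design(fx$hub, fx$rna, fx$atac, g)$features))
  }
})

test_that("design construction rejects unmatched samples and degenerate hubs", {
  fx <- design_fixture()
  expect_error(build_design(fx$hub, fx$rna, fx$atac[, 1:6], "g1"),
               "matched sample")
  lone <- fx$hub
  lone$genes <- lone$genes[1, , drop = FALSE]
  lone$peaks <- lone$peaks[0, , drop = FALSE]
  expect_error(build_design(lone, fx$rna[1, , drop = FALSE], fx$atac[0, , drop = FALSE], "g1"),
               "no candidate features")
  expect_error(build_design(fx$hub, fx$rna, fx$atac, "absent"), "not an expressed member")
})
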