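mk_loop <- function(c1, s1, e1, c2, s2, e2, rs = 3L) {
  data.frame(chrom1 = c1, start1 = s1, end1 = e1, chrom2 = c2, start2 = s2,
             end2 = e2, read_support = rs, group_id = "g",
             stringsAsFactors = FALSE)
}

test_that("anchor graph: shared exact anchor gives 3 nodes, 2 edges", {
  loops <- rbind(mk_loop("chr1", 0, 100, "chr1", 500, 600),
                 mk_loop("chr1", 500, 600, "chr1", 1000, 1100))
  g <- build_anchor_graph(loops)
  expect_equal(nrow(g$nodes), 3L)
  expect_equal(nrow(g$edges), 2L)
})

test_that("anchor graph: overlapping anchors merge into one node", {
  loops <- rbind(mk_loop("chr1", 0, 100, "chr1", 500, 600),
                 mk_loop("chr1", 550, 650, "chr1", 1000, 1100))
  g <- build_anchor_graph(loops)
  expect_equal(nrow(g$nodes), 3L)
  expect_true(any(g$nodes$start == 500 & g$nodes$end == 650))
})

test_that("node count equals the per-base anchor-union segment count", {
  set.seed(23)
  for (k in 1:20) {
    loops <- random_loops(sample(5:30, 1L))
    g <- build_anchor_graph(loops)
    seg <- oracle_segments(rbind(
      iv(loops$chrom1, loops$start1, loops$end1),
      iv(loops$chrom2, loops$start2, loops$end2)))
    expect_equal(nrow(g$nodes), nrow(seg))
  }
})

test_that("hub chain follows loops transitively; unseeded components are excluded", {
  loops <- rbind(mk_loop("chr1", 0, 100, "chr1", 500, 600),      # A-B
                 mk_loop("chr1", 500, 600, "chr1", 1000, 1100),  # B-C
                 mk_loop("chr1", 5000, 5100, "chr1", 6000, 6100)) # D-E
  ld <- data.frame(chrom = "chr1", start = 50, end = 80, lead_snp = "rs1",
                   stringsAsFactors = FALSE)
  hubs <- find_hubs(build_anchor_graph(loops), ld)
  expect_length(hubs, 1L)
  expect_equal(hubs[[1]]$anchors$start, c(0, 500, 1000))
  expect_equal(hubs[[1]]$seed_blocks$lead_snp, "rs1")
})

test_that("LD blocks overlapping no anchor are reported inactive", {
  loops <- mk_loop("chr1", 0, 100, "chr1", 500, 600)
  ld <- data.frame(chrom = c("chr1", "chr1"), start = c(50, 90000),
                   end = c(80, 91000), lead_snp = c("rs1", "rs2"),
                   stringsAsFactors = FALSE)
  hubs <- find_hubs(build_anchor_graph(loops), ld)
  expect_length(hubs, 1L)
  expect_equal(attr(hubs, "inactive_blocks")$lead_snp, "rs2")
})

test_that("blocks sharing a component merge into one hub with both seeds", {
  loops <- mk_loop("chr1", 0, 100, "chr1", 500, 600)
  ld <- data.frame(chrom = "chr1", start = c(10, 510), end = c(20, 520),
                   lead_snp = c("rs1", "rs2"), stringsAsFactors = FALSE)
  hubs <- find_hubs(build_anchor_graph(loops), ld)
  expect_length(hubs, 1L)
  expect_setequal(hubs[[1]]$seed_blocks$lead_snp, c("rs1", "rs2"))
})

test_that("hubs equal the brute-force transitive closure on random instances", {
  set.seed(31)
  for (k in 1:20) {
    loops <- random_loops(sample(3:20, 1L), n_anchor_pool = 6L)
    ld <- random_intervals(sample(1:5, 1L), max_pos = 900, max_w = 80)
    ld$lead_snp <- paste0("rs", seq_len(nrow(ld)))
    hubs <- find_hubs(build_anchor_graph(loops), ld)
    expected <- oracle_hubs(loops, ld)
    expect_length(hubs, length(expected))
    got <- lapply(hubs, function(h)
      list(lead_snps = sort(h$seed_blocks$lead_snp),
           anchor_bases = sort(base_positions(h$anchors))))
    key <- function(x) paste(x$lead_snps, collapse = ",")
    expect_setequal(vapply(got, key, ""), vapply(expected, key, ""))
    exp_by_key <- setNames(expected, vapply(expected, key, ""))
    for (h in got) {
      expect_identical(h$anchor_bases, exp_by_key[[key(h)]]$anchor_bases)
    }
  }
})

test_that("hub discovery is invariant to loop and block order", {
  set.seed(37)
  loops <- random_loops(15L, n_anchor_pool = 6L)
  ld <- random_intervals(4L, max_pos = 900, max_w = 80)
  ld$lead_snp <- paste0("rs", 1:4)
  h1 <- find_hubs(build_anchor_graph(loops), ld)
  h2 <- find_hubs(build_anchor_graph(loops[sample(nrow(loops)), ]),
                  ld[sample(nrow(ld)), ])
  strip <- function(hs) lapply(hs, function(h) {
    h$seed_blocks <- h$seed_blocks[order(h$seed_blocks$lead_snp), ]
    rownames(h$seed_blocks) <- NULL
    h
  })
  expect_equal(strip(h1), strip(h2), ignore_attr = TRUE)
})

test_that("nodes reachable from seeds are partitioned across hubs", {
  set.seed(41)
  for (k in 1:10) {
    loops <- random_loops(12L, n_anchor_pool = 6L)
    ld <- random_intervals(3L, max_pos = 900, max_w = 60)
    ld$lead_snp <- paste0("rs", 1:3)
    hubs <- find_hubs(build_anchor_graph(loops), ld)
    all_bases <- unlist(lapply(hubs, function(h) base_positions(h$anchors)))
    expect_identical(anyDuplicated(all_bases), 0L)
  }
})

test_that("member assignment: promoters, in-block peaks, distant genes", {
  loops <- mk_loop("chr1", 10000, 11000, "chr1", 50000, 51000)
  ld <- data.frame(chrom = "chr1", start = 9000, end = 12000, lead_snp = "rs1",
                   stringsAsFactors = FALSE)
  hub <- find_hubs(build_anchor_graph(loops), ld)[[1]]
  genes <- data.frame(
    gene_id = c("inA", "far"), chrom = "chr1",
    start = c(50500, 70000), end = c(55000, 75000), strand = "+",
    tss = c(50500, 70000), stringsAsFactors = FALSE)
  atac <- build_consensus_peaks(list(
    s1 = rbind(iv("chr1", 9100, 9400),     # inside seed block, not on an anchor
               iv("chr1", 10100, 10300),   # on an anchor
               iv("chr1", 200000, 200300))), 0.6)
  hub <- assign_members(hub, genes, atac, promoter_pad = 2000)
  expect_equal(hub$genes$gene_id, "inA")           # TSS inside an anchor
  expect_equal(hub$peaks$start, c(9100, 10100))    # seed-block peak is scoreable
  # gene 10 kb beyond every anchor stays out at promoter_pad 2000
  expect_false("far" %in% hub$genes$gene_id)
})
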