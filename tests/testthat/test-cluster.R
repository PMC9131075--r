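make_hits <- function(genes, pairs_idx) {
  do.call(rbind, lapply(pairs_idx, function(ij) {
    data.frame(gene_a = genes$gene_id[ij[1]], gene_b = genes$gene_id[ij[2]],
               chromosome = genes$chromosome[ij[1]], score = 100,
               bit_score = 60, bit_score_ratio = 0.9, evalue = 1e-30,
               coverage_a = 1, coverage_b = 1, stringsAsFactors = FALSE)
  }))
}

test_that("the intervening-gene rule keeps pairs up to 10 intervening genes", {
  genes <- make_gene_table(20)
  hits <- make_hits(genes, list(c(6, 8), c(6, 17), c(6, 18)))
  # ranks 5&7 -> 1 intervening; 5&16 -> 10 (boundary); 5&17 -> 11 (dropped)
  pairs <- build_pairs(hits, genes)
  expect_equal(pairs$n_intervening, c(1L, 10L))
  expect_equal(nrow(pairs), 2)
  # monotonicity: a larger allowance never yields fewer pairs
  n_prev <- 0
  for (mi in c(0, 2, 5, 10, 12)) {
    n <- nrow(build_pairs(hits, genes, max_intervening = mi))
    expect_gte(n, n_prev)
    n_prev <- n
  }
})

test_that("clusters are connected components with deterministic ids", {
  genes <- make_gene_table(20)
  hits <- make_hits(genes, list(c(1, 2), c(2, 3), c(10, 11)))
  pairs <- build_pairs(hits, genes)
  membership <- build_clusters(pairs, genes)
  sizes <- table(membership$cluster_id)
  expect_equal(length(sizes), 2)
  expect_setequal(as.integer(sizes), c(3L, 2L))
  first <- membership$cluster_id[membership$gene_id == genes$gene_id[1]]
  expect_equal(membership$gene_id[membership$cluster_id == first],
               genes$gene_id[1:3])
  # each gene belongs to at most one cluster; sizes sum to genes-in-clusters
  expect_false(any(duplicated(membership$gene_id)))
  expect_equal(sum(sizes), nrow(membership))
})

test_that("cluster summaries compute percentages from their own counts", {
  genes <- make_gene_table(20)
  hits <- make_hits(genes, list(c(1, 2), c(2, 3), c(10, 11)))
  pairs <- build_pairs(hits, genes)
  membership <- build_clusters(pairs, genes)
  s <- cluster_summary(membership, pairs, genes)
  expect_equal(s$n_clusters, 2)
  expect_equal(s$genes_in_clusters, 5)
  expect_equal(s$pct_genes_in_clusters, 25)
  expect_equal(s$pct_clusters_size2, 50)
  expect_equal(s$largest_cluster, 3L)
  # degenerate: no clusters
  s0 <- cluster_summary(membership[0, ], pairs[0, ], genes)
  expect_equal(s0$pct_genes_in_clusters, 0)
  expect_equal(s0$n_clusters, 0)
})

test_that("windowed density is the covered-base proportion after interval union", {
  lens <- c(chr01 = 1e6)
  one <- data.frame(chromosome = "chr01", start = 300001, end = 500000)
  d1 <- windowed_density(one, lens, window = 1e6)
  expect_equal(d1$density, 0.2)
  two <- data.frame(chromosome = "chr01",
                    start = c(100001, 150001), end = c(200000, 250000))
  d2 <- windowed_density(two, lens, window = 1e6)
  expect_equal(d2$density, 0.15)    # 150 kb covered after merging the overlap
  expect_error(windowed_density(
    data.frame(chromosome = "chr01", start = 1, end = 2e6), lens), "outside")
  # covered bases per chromosome equal the merged-interval total
  set.seed(71)
  feats <- data.frame(chromosome = "chr01",
                      start = sort(sample.int(9e5, 50)))
  feats$end <- feats$start + sample.int(2e4, 50)
  d3 <- windowed_density(feats, lens, window = 1e5)
  merged <- IRanges::reduce(IRanges::IRanges(feats$start, feats$end))
  expect_equal(sum(d3$density * (d3$win_end - d3$win_start + 1)),
               sum(IRanges::width(merged)))
})

test_that("the density model flags degenerate fits and matches the closed-form KS statistic", {
  lens <- c(chr01 = 1e6, chr02 = 1e6)
  set.seed(72)
  feats <- data.frame(chromosome = rep(c("chr01", "chr02"), each = 20),
                      start = sort(rep(seq(1, 9e5, length.out = 20), 2)))
  feats$start <- as.integer(feats$start)
  feats$end <- feats$start + 5000L
  track <- windowed_density(feats, lens, window = 1e5)
  # covariate identical to the response: residuals all zero -> degenerate
  m <- density_model(track, list(genes = track))
  expect_true(m$degenerate)
  expect_equal(m$ks_D, 1)
  expect_equal(unname(m$pearson_r["genes"]), 1)
  # arithmetic response against a flat covariate: scaled residuals form an
  # even grid, whose KS distance has a closed form
  n <- nrow(track)
  track2 <- track; track2$density <- seq(0.1, 0.3, length.out = n)
  flat <- track; flat$density <- rep(0.2, n)
  m2 <- density_model(track2, list(genes = flat))
  grid <- (seq_len(n) - 1) / (n - 1)
  expect_equal(m2$ks_D, ks_D_oracle(grid), tolerance = 1e-8)
  expect_false(m2$degenerate)
  expect_error(density_model(track[1, , drop = FALSE],
                             list(a = track[1, , drop = FALSE],
                                  b = track[1, , drop = FALSE])), "fewer")
})

test_that("concentrating features in few windows yields a large KS deviation", {
  lens <- c(chr01 = 2e6)
  # TDGs piled into 10% of the genome, background genes uniform
  tdg <- data.frame(chromosome = "chr01",
                    start = seq(1, 1.8e5, by = 2e3))
  tdg$end <- tdg$start + 1500
  bg <- data.frame(chromosome = "chr01", start = seq(1, 1.99e6, by = 2e4))
  bg$end <- bg$start + 5000
  m <- density_model(windowed_density(tdg, lens, 1e5),
                     list(genes = windowed_density(bg, lens, 1e5)))
  expect_gt(m$ks_D, 0.3)
})
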