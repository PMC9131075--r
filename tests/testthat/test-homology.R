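test_that("self-alignment gives full coverage and bit-score ratio exactly 1", {
  set.seed(11)
  s <- random_cds(100)
  hit <- align_cds(s, s)
  expect_equal(hit$coverage_a, 1)
  expect_equal(hit$coverage_b, 1)
  expect_equal(hit$bit_score, self_bit_score(s))
  expect_lt(hit$evalue, 1e-10)
})

test_that("unrelated random sequences fail the e-value threshold", {
  set.seed(12)
  a <- random_cds(100); b <- random_cds(100)
  hit <- align_cds(a, b)
  expect_gt(hit$evalue, 1e-10)
})

test_that("coverage reflects alignment span over each sequence length", {
  set.seed(13)
  long <- random_cds(100)                 # 300 nt
  short <- substr(long, 1, 120)
  hit <- align_cds(long, short)
  expect_equal(hit$coverage_b, 1)
  expect_equal(hit$coverage_a, 0.4)
  # such a pair fails the >= 50% both-sequences coverage rule
  th <- homology_thresholds()
  expect_lt(hit$coverage_a, th$coverage_min)
})

test_that("alignment statistics are symmetric in the two sequences", {
  set.seed(14)
  a <- random_cds(80)
  b <- mutate_dna(a, 0.05)
  h1 <- align_cds(a, b); h2 <- align_cds(b, a)
  expect_equal(h1$score, h2$score)
  expect_equal(h1$bit_score, h2$bit_score)
  expect_equal(h1$evalue, h2$evalue)
  expect_equal(h1$coverage_a, h2$coverage_b)
  expect_equal(h1$coverage_b, h2$coverage_a)
})

test_that("invalid symbols are rejected and N scores as a mismatch", {
  expect_error(align_cds("ACGTX", "ACGT"), "A, C, G, T or N")
  with_n <- align_cds("ACGTACGTNACGTACGT", "ACGTACGTAACGTACGT")
  exact <- align_cds("ACGTACGTAACGTACGT", "ACGTACGTAACGTACGT")
  expect_lt(with_n$score, exact$score)
})

test_that("local alignment score equals an exhaustive dynamic-programming reference", {
  set.seed(15)
  for (k in 1:12) {
    na <- sample(8:50, 1); nb <- sample(8:50, 1)
    a <- paste(sample(c("A", "C", "G", "T"), na, replace = TRUE), collapse = "")
    b <- if (k %% 3 == 0) mutate_dna(a, 0.15) else
      paste(sample(c("A", "C", "G", "T"), nb, replace = TRUE), collapse = "")
    expect_equal(align_cds(a, b)$score, sw_score_oracle(a, b), info = k)
  }
})

test_that("extra mismatches never increase the raw score", {
  set.seed(16)
  a <- random_cds(80)
  b <- a
  prev <- align_cds(a, b)$score
  for (step in 1:6) {
    b <- mutate_dna(b, 0.03)
    cur <- align_cds(a, b)$score
    expect_lte(cur, prev)
    prev <- cur
  }
})

test_that("same-chromosome pair calling applies all three thresholds", {
  genes <- make_gene_table(8, cds_codons = 100, seed = 21)
  # plant a duplicate of gene 2 at position 6 (3 genes apart) with 2% mutations
  set.seed(22)
  genes$cds[6] <- mutate_dna(genes$cds[2], 0.02)
  genes$protein[6] <- translate_cds(genes$cds[6])
  hits <- same_chromosome_pairs(genes)
  expect_equal(nrow(hits), 1)
  expect_equal(c(hits$gene_a, hits$gene_b), genes$gene_id[c(2, 6)])
  # homologs on different chromosomes are never reported
  genes2 <- genes
  genes2$chromosome[6] <- "chr02"
  genes2 <- tandemscan:::assign_ranks(genes2)
  expect_equal(nrow(same_chromosome_pairs(genes2)), 0)
  # heavy truncation drives the bit-score ratio below 30%
  genes3 <- genes
  genes3$cds[6] <- substr(genes$cds[2], 1, 60)
  hits3 <- same_chromosome_pairs(genes3)
  expect_false(any(hits3$gene_a == genes$gene_id[2] &
                     hits3$gene_b == genes$gene_id[6]))
})

test_that("k-mer prefilter accepts the same pairs as all-vs-all", {
  genes <- make_gene_table(12, cds_codons = 80, seed = 31)
  set.seed(32)
  genes$cds[5] <- mutate_dna(genes$cds[1], 0.05)
  genes$cds[9] <- mutate_dna(genes$cds[4], 0.10)
  for (i in c(5, 9)) genes$protein[i] <- translate_cds(genes$cds[i])
  with_pf <- same_chromosome_pairs(genes, prefilter = TRUE)
  without <- same_chromosome_pairs(genes, prefilter = FALSE)
  expect_equal(with_pf[order(with_pf$gene_a, with_pf$gene_b), ],
               without[order(without$gene_a, without$gene_b), ],
               ignore_attr = TRUE)
  expect_equal(nrow(with_pf), 2)
})
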