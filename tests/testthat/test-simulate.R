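small_cfg <- function(seed = 7) {
  sim_config(genotypes = c("G1", "G2"), n_chromosomes = 1,
             genes_per_chromosome = 60, frac_unplaced = 0.05, seed = seed)
}

test_that("the generator is byte-identical under a fixed seed", {
  d1 <- file.path(tempdir(), "sim_det1")
  d2 <- file.path(tempdir(), "sim_det2")
  simulate_tdg_data(small_cfg(), d1)
  simulate_tdg_data(small_cfg(), d2)
  f1 <- sort(list.files(d1))
  expect_identical(f1, sort(list.files(d2)))
  for (f in f1) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))), info = f)
  }
  d3 <- file.path(tempdir(), "sim_det3")
  simulate_tdg_data(small_cfg(seed = 8), d3)
  expect_false(identical(unname(tools::md5sum(file.path(d1, "G1.cds.fa"))),
                         unname(tools::md5sum(file.path(d3, "G1.cds.fa")))))
})

test_that("emitted bundles pass genome_io validation with no warnings", {
  sim <- simulate_tdg_data(small_cfg(seed = 9),
                           file.path(tempdir(), "sim_valid"))
  for (g in names(sim$paths)) {
    p <- sim$paths[[g]]
    expect_no_warning(
      genes <- load_genotype(p$gff3, p$cds, p$protein, p$annotation, g))
    truth_g <- sim$truth$genes[sim$truth$genes$genotype == g, ]
    expect_setequal(genes$gene_id, truth_g$gene_id)
    expect_equal(sum(!genes$located),
                 sum(truth_g$chromosome == "chrUn"))
    # planted TE fraction shows up in the annotation flags
    expect_equal(sum(genes$is_te), sum(truth_g$is_te))
    # promoters are recovered exactly as planted (both strands)
    genome <- Biostrings::readDNAStringSet(p$genome)
    names(genome) <- sub("\\s.*", "", names(genome))
    placed <- genes[genes$located, ]
    prom <- extract_promoters(placed, genome)
    expect_true(all(!is.na(prom$promoter)))
    expect_true(all(prom$length == 1000))
  }
})

test_that("planted clusters are recovered perfectly on the worked fixture", {
  sim <- get_worked_fixture()
  p <- sim$paths$GA
  genes <- load_genotype(p$gff3, p$cds, p$protein, p$annotation, "GA")
  filtered <- non_te_located_genes(genes)
  hits <- same_chromosome_pairs(filtered)
  pairs <- build_pairs(hits, filtered)
  membership <- build_clusters(pairs, filtered)
  truth_g <- sim$truth$genes[sim$truth$genes$genotype == "GA", ]
  planted <- truth_g$gene_id[truth_g$clustered]
  # precision = recall = 1 on cluster membership
  expect_setequal(membership$gene_id, planted)
  # the three-gene family is one cluster; the 11-intervening pair is rejected
  fam1 <- membership$cluster_id[membership$gene_id == "GA_c1a"]
  expect_setequal(membership$gene_id[membership$cluster_id == fam1],
                  c("GA_c1a", "GA_c1b", "GA_c1c"))
  expect_false(any(c("GA_r1", "GA_r2") %in% membership$gene_id))
  rej <- hits[hits$gene_a == "GA_r1" & hits$gene_b == "GA_r2", ]
  expect_equal(nrow(rej), 1)    # homologous, but 11 intervening genes apart
  expect_equal(build_pairs(rej, filtered)$n_intervening, integer(0))
  # the synonymous-only pair has Ka exactly 0
  cds <- stats::setNames(filtered$cds, filtered$gene_id)
  r <- kaks_pair(cds[["GA_y1"]], cds[["GA_y2"]])
  expect_equal(r$ka, 0)
  expect_gt(r$ks, 0)
})

test_that("planted omega is recovered within tolerance by the estimator", {
  set.seed(101)
  est <- replicate(40, {
    anc <- random_cds(300)
    der <- simulate_divergent_pair(anc, 0.3, 0.3)
    kaks_pair(anc, der)$omega
  })
  expect_lt(abs(mean(est, na.rm = TRUE) - 0.3), 0.15)
})

test_that("a zero-TDG configuration produces an empty cluster table without error", {
  cfg <- sim_config(genotypes = "G1", n_chromosomes = 1,
                    genes_per_chromosome = 40, frac_tdg = 0,
                    frac_unplaced = 0, seed = 13)
  sim <- simulate_tdg_data(cfg, file.path(tempdir(), "sim_zero"))
  p <- sim$paths$G1
  genes <- load_genotype(p$gff3, p$cds, p$protein, p$annotation, "G1")
  filtered <- non_te_located_genes(genes)
  hits <- same_chromosome_pairs(filtered)
  pairs <- build_pairs(hits, filtered)
  membership <- build_clusters(pairs, filtered)
  s <- cluster_summary(membership, pairs, filtered)
  expect_equal(s$n_clusters, 0)
  expect_equal(s$pct_genes_in_clusters, 0)
})
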