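make_membership <- function(spec) {
  # spec: list of (cluster_id, genotype, gene ids)
  do.call(rbind, lapply(spec, function(s) {
    data.frame(cluster_id = s[[1]], genotype = s[[2]], chromosome = "chr01",
               gene_id = s[[3]], stringsAsFactors = FALSE)
  }))
}

test_that("cluster categories follow the core/shared/private definitions", {
  gts <- c("G1", "G2", "G3", "G4")
  membership <- make_membership(list(
    list("G1_c1", "G1", c("G1_a1", "G1_a2")),
    list("G2_c1", "G2", c("G2_a1", "G2_a2")),
    list("G3_c1", "G3", c("G3_a1", "G3_a2")),
    list("G4_c1", "G4", c("G4_a1", "G4_a2")),   # OG A clustered everywhere
    list("G1_c2", "G1", c("G1_b1", "G1_b2")),   # OG B clustered in G1 only
    list("G1_c3", "G1", c("G1_d1", "G1_d2")),
    list("G2_c3", "G2", c("G2_d1", "G2_d2"))))  # OG D in two genotypes
  og <- data.frame(
    og_id = c(rep("OGA", 8), rep("OGB", 2), rep("OGD", 4), "OGB"),
    genotype = c(rep(gts, each = 2), "G1", "G1", rep(c("G1", "G2"), each = 2),
                 "G3"),
    gene_id = c("G1_a1", "G1_a2", "G2_a1", "G2_a2", "G3_a1", "G3_a2",
                "G4_a1", "G4_a2", "G1_b1", "G1_b2", "G1_d1", "G1_d2",
                "G2_d1", "G2_d2", "G3_x1"),   # OGB has a non-clustered member
    stringsAsFactors = FALSE)
  cats <- categorize_clusters(membership, og, gts)
  get <- function(id) cats$category[cats$cluster_id == id]
  expect_equal(get("G1_c1"), "core")
  expect_equal(get("G4_c1"), "core")
  # a non-clustered ortholog elsewhere does not rescue a private cluster
  expect_equal(get("G1_c2"), "private")
  expect_equal(get("G1_c3"), "shared")
  expect_equal(get("G2_c3"), "shared")
  # category partition covers all annotated clusters per genotype
  cs <- category_summary(cats)
  expect_equal(cs$per_genotype$n_private + cs$per_genotype$n_core +
                 cs$per_genotype$n_shared, cs$per_genotype$n_clusters)
})

test_that("planted category partitions are recovered exactly from noiseless orthogroups", {
  sim <- get_worked_fixture()
  truth <- sim$truth
  membership <- do.call(rbind, lapply(split(
    truth$genes[truth$genes$clustered, ],
    paste(truth$genes$genotype, truth$genes$family_id)[truth$genes$clustered]),
    function(df) data.frame(
      cluster_id = paste0(df$genotype[1], "_", df$family_id[1]),
      genotype = df$genotype[1], chromosome = df$chromosome[1],
      gene_id = df$gene_id, stringsAsFactors = FALSE)))
  og <- read_orthogroups(sim$orthogroups)
  cats <- categorize_clusters(membership, og, c("GA", "GB"))
  cats$family_id <- sub("^G[AB]_", "", cats$cluster_id)
  merged <- merge(cats, truth$clusters, by = "family_id")
  expect_true(all(merged$category.x == merged$category.y))
})

test_that("positional profiles detect planted pericentromeric bias of private clusters", {
  set.seed(91)
  lens <- c(chr01 = 1e6)
  centromere <- c(chr01 = 5e5)
  genes <- list(); membership <- list(); cats <- list()
  for (i in 1:30) {
    # private clusters near the centromere, others near the arms
    private <- i <= 15
    mid <- if (private) stats::runif(1, 4.4e5, 5.6e5) else
      sample(c(stats::runif(1, 0, 1.2e5), stats::runif(1, 8.8e5, 9.6e5)), 1)
    id <- sprintf("c%02d", i)
    g <- data.frame(gene_id = paste0(id, "_g", 1:2), genotype = "G1",
                    chromosome = "chr01",
                    start = round(mid) + c(0, 3000),
                    end = round(mid) + c(2000, 5000),
                    stringsAsFactors = FALSE)
    genes[[i]] <- g
    membership[[i]] <- data.frame(cluster_id = id, genotype = "G1",
                                  chromosome = "chr01", gene_id = g$gene_id,
                                  stringsAsFactors = FALSE)
    cats[[i]] <- data.frame(cluster_id = id, genotype = "G1",
                            category = if (private) "private" else "core",
                            stringsAsFactors = FALSE)
  }
  pp <- positional_profile(do.call(rbind, membership), do.call(rbind, genes),
                           do.call(rbind, cats), lens, centromere)
  expect_equal(pp$metric, "centromere_distance_fraction")
  expect_lt(pp$test$p.value, 0.05)
  # no centromere file: falls back to the normalized-midpoint metric
  pp2 <- positional_profile(do.call(rbind, membership), do.call(rbind, genes),
                            do.call(rbind, cats), lens)
  expect_equal(pp2$metric, "normalized_position")
  mid1 <- pp2$positions[pp2$positions$cluster_id == "c01", ]
  expect_equal(mid1$position, mid1$midpoint / 1e6)
})

test_that("divergence correlations recover identity, planted coupling and independence", {
  set.seed(92)
  n <- 300
  tab <- data.frame(r = stats::runif(n, -0.5, 1))
  tab$ps <- tab$r                      # identical columns -> r = 1
  tab$ks <- 1 - 0.6 * tab$ps + stats::rnorm(n, 0, 0.1)   # negative coupling
  tab$omega <- stats::runif(n, 0, 1.5)                   # independent
  out <- divergence_correlations(tab)
  expect_equal(out$r[out$comparison == "expression_r_vs_ps"], 1)
  expect_lt(out$r[out$comparison == "ps_vs_ks"], -0.5)
  expect_lt(out$p[out$comparison == "ps_vs_ks"], 1e-6)
  expect_lt(abs(out$r[out$comparison == "expression_r_vs_omega"]), 0.15)
  # fewer than 3 complete pairs: undefined
  out2 <- divergence_correlations(tab[1:2, ])
  expect_true(all(is.na(out2$r)))
})

test_that("fate rules assign sub-functionalization, redundancy and neo-functionalization", {
  tab <- data.frame(
    genotype = "G1",
    both_expressed = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE),
    expr_diverged = c(TRUE, FALSE, TRUE, TRUE, TRUE, NA),
    omega = c(0.3, 0.4, 1.5, NA, 0.5, 0.2),
    excluded = c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE),
    domains_identical = c(TRUE, TRUE, FALSE, TRUE, FALSE, TRUE),
    stringsAsFactors = FALSE)
  out <- call_fates(tab)
  expect_equal(out$fate, c("sub_functionalization", "genetic_redundancy",
                           "neo_functionalization", "unclassified",
                           "unclassified", "unclassified"))
  # precedence: diverged domains with omega < 1 are not forced into a class
  expect_equal(out$fate_reason[5], "no_rule_matched")
  expect_equal(out$fate_reason[4], "missing_input")
  # mutually exclusive and exhaustive over eligible pairs
  eligible <- out$both_expressed & !out$excluded & !is.na(out$omega)
  expect_true(all(out$fate[eligible] %in%
                    c("sub_functionalization", "genetic_redundancy",
                      "neo_functionalization", "unclassified")))
  fs <- summarize_fates(out)
  expect_equal(fs$per_genotype$n_eligible, 4)
})

test_that("cross-genotype averages are unweighted means of per-genotype percentages", {
  expect_equal(mean_pct(c(32.92, 18.37, 21.07, 27.73)), 25.02)
  expect_equal(mean_pct(50), 50)
})
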