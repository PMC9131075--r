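test_that("loading a genotype assigns ranks by start order and handles unplaced scaffolds", {
  fx <- write_tiny_genotype(file.path(tempdir(), "tiny_io"))
  genes <- load_genotype(fx$gff3, fx$cds, fx$protein, fx$annotation,
                         genotype = "T1")
  expect_equal(nrow(genes), 4)
  placed <- genes[genes$located, ]
  expect_equal(placed$gene_id[order(placed$rank)], c("g1", "g2", "g3"))
  expect_equal(sort(placed$rank), 0:2)
  g4 <- genes[genes$gene_id == "g4", ]
  expect_false(g4$located)
  expect_true(is.na(g4$rank))
  # sequences and annotations attached
  expect_equal(genes$cds[genes$gene_id == "g1"], unname(fx$cds_seqs["g1"]))
  expect_true(genes$is_te[genes$gene_id == "g4"])
  expect_equal(genes$ahrd_score[genes$gene_id == "g1"], 3L)
})

test_that("missing sequences are a hard error and frameshifted CDS are excluded with a warning", {
  fx <- write_tiny_genotype(file.path(tempdir(), "tiny_io_drop"),
                            drop_seq = "g2")
  expect_error(
    load_genotype(fx$gff3, fx$cds, fx$protein, fx$annotation, "T1"),
    "g2")
  fx2 <- write_tiny_genotype(file.path(tempdir(), "tiny_io_bad"),
                             bad_cds = "g3")
  expect_warning(
    genes <- load_genotype(fx2$gff3, fx2$cds, fx2$protein, fx2$annotation,
                           "T1"),
    "multiple of 3")
  expect_false("g3" %in% genes$gene_id)
})

test_that("TE-orthogroup rule follows the <30% TE and mean AHRD >= 2 criteria", {
  genes <- data.frame(
    gene_id = sprintf("g%02d", 1:24),
    is_te = c(rep(FALSE, 8), rep(TRUE, 2),          # og1: 2/10 TE
              rep(FALSE, 7), rep(TRUE, 3),          # og2: 3/10 TE (boundary)
              rep(FALSE, 4)),                       # og3: 0/4 TE, low AHRD
    ahrd_score = c(rep(3L, 5), rep(2L, 5), rep(3L, 10), rep(1L, 3), 2L),
    stringsAsFactors = FALSE)
  og <- data.frame(og_id = rep(c("og1", "og2", "og3"), c(10, 10, 4)),
                   gene_id = genes$gene_id, stringsAsFactors = FALSE)
  cls <- classify_te_orthogroups(og, genes)
  cls <- cls[order(cls$og_id), ]
  # og1: 20% TE, mean AHRD 2.5 -> non-TE
  expect_false(cls$is_te_og[cls$og_id == "og1"])
  # og2: exactly 30% TE -> TE (strict "less than")
  expect_true(cls$is_te_og[cls$og_id == "og2"])
  # og3: no TE but mean AHRD 1.25 < 2 -> TE
  expect_true(cls$is_te_og[cls$og_id == "og3"])
  # unknown gene id is a hard error
  bad <- rbind(og, data.frame(og_id = "og9", gene_id = "nope"))
  expect_error(classify_te_orthogroups(bad, genes), "unknown")
})

test_that("TE-orthogroup classification is idempotent through the gene filter", {
  genes <- make_gene_table(10)
  genes$is_te[9:10] <- TRUE
  genes$ahrd_score[9:10] <- 0L
  og <- data.frame(og_id = rep(c("ogA", "ogB"), each = 5),
                   gene_id = genes$gene_id, stringsAsFactors = FALSE)
  cls1 <- classify_te_orthogroups(og, genes)
  genes2 <- apply_te_og_filter(genes, og, cls1)
  cls2 <- classify_te_orthogroups(og, genes2)
  genes3 <- apply_te_og_filter(genes2, og, cls2)
  expect_identical(genes2$is_te, genes3$is_te)
  expect_identical(cls2$is_te_og, classify_te_orthogroups(og, genes3)$is_te_og)
})

test_that("non_te_located_genes filters and recomputes ranks", {
  genes <- make_gene_table(5)
  genes$is_te[2] <- TRUE
  genes$located[4] <- FALSE
  out <- non_te_located_genes(genes)
  expect_equal(nrow(out), 3)
  expect_equal(sort(out$rank), 0:2)
  expect_true(all(diff(out$start[order(out$rank)]) > 0))
  # degenerate: everything TE -> empty, no error downstream
  genes$is_te <- TRUE
  empty <- non_te_located_genes(genes)
  expect_equal(nrow(empty), 0)
  expect_equal(nrow(same_chromosome_pairs(empty)), 0)
})

test_that("gene tables round-trip through TSV", {
  genes <- make_gene_table(6)
  genes$pfam[1] <- "PF00001,PF00002"
  genes$go[2] <- "GO:0000001"
  path <- tempfile(fileext = ".tsv")
  write_gene_table(genes, path)
  back <- read_gene_table(path)
  for (col in names(genes)) {
    expect_equal(back[[col]], genes[[col]], info = col)
  }
})

test_that("ranks are a permutation of 0..n-1 per chromosome and monotone in start", {
  set.seed(5)
  for (rep in 1:5) {
    n <- sample(5:30, 1)
    genes <- make_gene_table(n, seed = rep)
    genes <- genes[sample(n), ]
    genes$chromosome <- sample(c("chr01", "chr02"), n, replace = TRUE)
    genes <- tandemscan:::assign_ranks(genes)
    for (chrom in unique(genes$chromosome)) {
      sub <- genes[genes$chromosome == chrom, ]
      expect_setequal(sub$rank, seq_len(nrow(sub)) - 1)
      ord <- order(sub$rank)
      expect_true(all(diff(sub$start[ord]) >= 0))
    }
  }
})
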