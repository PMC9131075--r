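# Shared fixtures, generated programmatically once per test run.

.fx_cache <- new.env()

get_worked_fixture <- function() {
  if (is.null(.fx_cache$fx)) {
    .fx_cache$fx <- worked_fixture(file.path(tempdir(), "ts_worked_fixture"))
  }
  .fx_cache$fx
}

# Hand-written minimal GFF3 + FASTA + annotation bundle: three placed genes on
# chr01 (in shuffled file order to exercise rank assignment) and one on the
# unplaced scaffold.
write_tiny_genotype <- function(dir, drop_seq = character(0),
                                bad_cds = character(0)) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(99)
  codons <- sense_codons_list()
  mk_cds <- function(n) paste(sample(codons, n, replace = TRUE), collapse = "")
  cds <- c(g1 = mk_cds(40), g2 = mk_cds(47), g3 = mk_cds(50), g4 = mk_cds(30))
  coords <- data.frame(
    gene_id = c("g3", "g1", "g2", "g4"),   # shuffled on purpose
    chrom = c("chr01", "chr01", "chr01", "chrUn"),
    start = c(2001L, 101L, 901L, 51L),
    strand = c("+", "+", "-", "+"), stringsAsFactors = FALSE)
  coords$end <- coords$start + nchar(cds[coords$gene_id]) - 1L

  lines <- "##gff-version 3"
  for (i in seq_len(nrow(coords))) {
    g <- coords$gene_id[i]
    base <- sprintf("%s\ttest\t%%s\t%d\t%d\t.\t%s\t%%s\t%%s", coords$chrom[i],
                    coords$start[i], coords$end[i], coords$strand[i])
    lines <- c(lines,
               sprintf(base, "gene", ".", sprintf("ID=%s", g)),
               sprintf(base, "mRNA", ".", sprintf("ID=%s.t1;Parent=%s", g, g)),
               sprintf(base, "CDS", "0",
                       sprintf("ID=%s.cds;Parent=%s.t1", g, g)))
  }
  writeLines(lines, file.path(dir, "tiny.gff3"))

  if (length(bad_cds)) {
    cds[bad_cds] <- paste0(cds[bad_cds], "A")  # break the frame
  }
  keep <- setdiff(names(cds), drop_seq)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(cds[keep]),
                              file.path(dir, "tiny.cds.fa"))
  prot <- translate_cds(ifelse(nchar(cds) %% 3 == 0, cds,
                               substr(cds, 1, 3 * (nchar(cds) %/% 3))))
  names(prot) <- names(cds)
  Biostrings::writeXStringSet(Biostrings::AAStringSet(prot[keep]),
                              file.path(dir, "tiny.protein.fa"))

  ann <- data.frame(gene_id = names(cds),
                    pfam = c("PF1,PF2", "", "PF1", ""),
                    go = c("GO:1", "", "", ""),
                    ahrd_stars = c(3L, 2L, 3L, 0L),
                    te_flag = c(0L, 0L, 0L, 1L))
  utils::write.table(ann, file.path(dir, "tiny.annotation.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  list(gff3 = file.path(dir, "tiny.gff3"),
       cds = file.path(dir, "tiny.cds.fa"),
       protein = file.path(dir, "tiny.protein.fa"),
       annotation = file.path(dir, "tiny.annotation.tsv"),
       cds_seqs = cds, coords = coords)
}

# Minimal gene table for in-memory tests (no files involved).
make_gene_table <- function(n, genotype = "GX", chromosome = "chr01",
                            cds_codons = 60, seed = 1) {
  set.seed(seed)
  codons <- sense_codons_list()
  cds <- vapply(seq_len(n), function(i)
    paste(sample(codons, cds_codons, replace = TRUE), collapse = ""),
    character(1))
  starts <- cumsum(rep(2000, n))
  data.frame(gene_id = sprintf("%s_g%03d", genotype, seq_len(n)),
             genotype = genotype, chromosome = chromosome,
             start = starts, end = starts + nchar(cds) - 1,
             strand = "+", located = TRUE, rank = seq_len(n) - 1L,
             is_te = FALSE, ahrd_score = 3L, pfam = "", go = "",
             cds = cds, protein = translate_cds(cds),
             stringsAsFactors = FALSE)
}
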