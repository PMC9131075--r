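# --- Input reading, validation and the TE-orthogroup filter -----------------

# Ranks are 0-based start-order indices per chromosome among located genes.
assign_ranks <- function(genes) {
  genes$rank <- rep(NA_integer_, nrow(genes))
  for (chrom in unique(genes$chromosome[genes$located])) {
    sel <- which(genes$chromosome == chrom & genes$located)
    ord <- order(genes$start[sel], genes$gene_id[sel])
    genes$rank[sel[ord]] <- seq_along(sel) - 1L
  }
  genes
}

read_fasta_named <- function(path, aa = FALSE) {
  x <- if (aa) Biostrings::readAAStringSet(path) else
    Biostrings::readDNAStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  x
}

#' Load one genotype's gene models, sequences and annotations
#'
#' Reads a GFF3 (gene/mRNA/CDS features), CDS and protein FASTA keyed by gene
#' id, and a per-gene annotation table (columns gene_id, pfam, go, ahrd_stars,
#' te_flag; pfam/go comma-joined). When a gene has several mRNAs, the
#' representative isoform is the one with the longest total CDS, ties broken
#' by lexicographic transcript id. Genes on unplaced scaffolds are kept with
#' `located = FALSE` and no rank. Genes whose CDS length is not a multiple of
#' 3, or whose protein does not equal the translation of their CDS, are
#' excluded with a warning. A gene id missing from either FASTA is an error.
#'
#' @param gff3_path path to the GFF3 file
#' @param cds_fasta,protein_fasta FASTA paths keyed by gene id
#' @param annotation_tsv annotation table path
#' @param genotype genotype label
#' @param unplaced_chroms chromosome names treated as unplaced (default "chrUn")
#' @return data.frame, one row per retained gene: gene_id, genotype,
#'   chromosome, start, end, strand, located, rank, transcript_id, is_te,
#'   ahrd_score, pfam, go, cds, protein
#' @export
load_genotype <- function(gff3_path, cds_fasta, protein_fasta, annotation_tsv,
                          genotype, unplaced_chroms = "chrUn") {
  gff <- rtracklayer::import(gff3_path)
  gtab <- as.data.frame(gff[gff$type == "gene"])
  mrna <- as.data.frame(gff[gff$type == "mRNA"])
  cdsf <- as.data.frame(gff[gff$type == "CDS"])

  genes <- data.frame(gene_id = gtab$ID,
                      genotype = genotype,
                      chromosome = as.character(gtab$seqnames),
                      start = gtab$start, end = gtab$end,
                      strand = as.character(gtab$strand),
                      stringsAsFactors = FALSE)
  genes$located <- !(genes$chromosome %in% unplaced_chroms)

  # representative isoform: longest total CDS, ties by transcript id
  if (nrow(mrna)) {
    parent <- vapply(mrna$Parent, function(p) p[1], character(1))
    cds_parent <- vapply(cdsf$Parent, function(p) p[1], character(1))
    cds_len <- tapply(cdsf$width, cds_parent, sum)
    mrna_len <- ifelse(mrna$ID %in% names(cds_len), cds_len[mrna$ID], 0)
    ord <- order(parent, -mrna_len, mrna$ID)
    rep_tx <- mrna$ID[ord][!duplicated(parent[ord])]
    names(rep_tx) <- parent[ord][!duplicated(parent[ord])]
    genes$transcript_id <- unname(rep_tx[genes$gene_id])
  } else {
    genes$transcript_id <- NA_character_
  }

  cds <- read_fasta_named(cds_fasta)
  prot <- read_fasta_named(protein_fasta, aa = TRUE)
  missing <- setdiff(genes$gene_id, intersect(names(cds), names(prot)))
  if (length(missing))
    stop("missing sequence for gene id(s): ", paste(missing, collapse = ", "))
  genes$cds <- as.character(cds[genes$gene_id])
  genes$protein <- as.character(prot[genes$gene_id])

  bad_len <- nchar(genes$cds) %% 3 != 0
  if (any(bad_len)) {
    warning("excluding ", sum(bad_len),
            " gene(s) with CDS length not a multiple of 3: ",
            paste(genes$gene_id[bad_len], collapse = ", "))
    genes <- genes[!bad_len, , drop = FALSE]
  }
  trans <- translate_cds(genes$cds)
  bad_tr <- trans != sub("\\*$", "", genes$protein)
  if (any(bad_tr)) {
    warning("excluding ", sum(bad_tr),
            " gene(s) whose protein does not match the CDS translation: ",
            paste(genes$gene_id[bad_tr], collapse = ", "))
    genes <- genes[!bad_tr, , drop = FALSE]
  }

  ann <- utils::read.delim(annotation_tsv, stringsAsFactors = FALSE,
                           colClasses = "character")
  i <- match(genes$gene_id, ann$gene_id)
  genes$is_te <- !is.na(i) & ann$te_flag[i] %in% c("1", "TRUE", "true")
  genes$ahrd_score <- ifelse(is.na(i), 0L, as.integer(ann$ahrd_stars[i]))
  genes$pfam <- ifelse(is.na(i), "", ann$pfam[i])
  genes$go <- ifelse(is.na(i), "", ann$go[i])
  genes$pfam[is.na(genes$pfam)] <- ""
  genes$go[is.na(genes$go)] <- ""

  genes <- assign_ranks(genes)
  rownames(genes) <- NULL
  genes
}

#' Read an orthogroup membership table
#'
#' @param path TSV with columns og_id, genotype, gene_id
#' @return data.frame
#' @export
read_orthogroups <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE,
                    colClasses = "character")
}

#' Classify orthogroups as TE or non-TE
#'
#' An orthogroup is non-TE when it contains less than 30% TE genes (strict)
#' and the mean AHRD score of its members is >= 2; otherwise it is a TE
#' orthogroup. The rule is idempotent.
#'
#' @param orthogroups data.frame with og_id, gene_id (genotype optional)
#' @param genes concatenated gene tables providing is_te and ahrd_score
#' @return data.frame: og_id, n_members, te_gene_fraction, mean_ahrd, is_te_og
#' @export
classify_te_orthogroups <- function(orthogroups, genes) {
  known <- orthogroups$gene_id %in% genes$gene_id
  if (!all(known))
    stop("orthogroup references unknown gene id(s): ",
         paste(utils::head(orthogroups$gene_id[!known], 10), collapse = ", "))
  i <- match(orthogroups$gene_id, genes$gene_id)
  df <- data.frame(og_id = orthogroups$og_id,
                   is_te = genes$is_te[i],
                   ahrd = genes$ahrd_score[i])
  agg <- do.call(rbind, lapply(split(df, df$og_id), function(d) {
    data.frame(og_id = d$og_id[1], n_members = nrow(d),
               te_gene_fraction = mean(d$is_te),
               mean_ahrd = mean(d$ahrd), stringsAsFactors = FALSE)
  }))
  agg$is_te_og <- !(agg$te_gene_fraction < 0.30 & agg$mean_ahrd >= 2)
  rownames(agg) <- NULL
  agg
}

#' Propagate the TE-orthogroup classification to genes
#'
#' Marks every member of a TE orthogroup as a TE gene.
#'
#' @param genes gene table of one genotype
#' @param orthogroups orthogroup membership table
#' @param og_class data.frame from [classify_te_orthogroups()]
#' @return `genes` with updated is_te
#' @export
apply_te_og_filter <- function(genes, orthogroups, og_class) {
  te_ogs <- og_class$og_id[og_class$is_te_og]
  te_genes <- orthogroups$gene_id[orthogroups$og_id %in% te_ogs]
  genes$is_te <- genes$is_te | genes$gene_id %in% te_genes
  genes
}

#' Restrict to non-TE genes with a known chromosomal location
#'
#' Ranks are recomputed on the filtered set, so intervening-gene counts
#' downstream operate on the analyzed gene universe.
#'
#' @param genes gene table
#' @return filtered gene table with recomputed ranks
#' @export
non_te_located_genes <- function(genes) {
  out <- genes[!genes$is_te & genes$located, , drop = FALSE]
  out <- assign_ranks(out)
  rownames(out) <- NULL
  out
}

#' Write / read an assembled gene table (round-trip safe)
#'
#' @param genes gene table
#' @param path TSV path
#' @return invisibly, the path
#' @export
write_gene_table <- function(genes, path) {
  utils::write.table(genes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_gene_table
#' @export
read_gene_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = "NA",
                          colClasses = "character")
  for (col in c("start", "end", "rank", "ahrd_score"))
    df[[col]] <- as.integer(df[[col]])
  for (col in c("located", "is_te")) df[[col]] <- as.logical(df[[col]])
  df$pfam[is.na(df$pfam)] <- ""
  df$go[is.na(df$go)] <- ""
  df
}

# Split comma-joined Pfam annotations into sets; identical-domain comparison
# for a pair of genes.
pfam_set <- function(s) {
  if (is.na(s) || !nzchar(s)) return(character(0))
  sort(unique(strsplit(s, ",", fixed = TRUE)[[1]]))
}

domains_identical <- function(pfam_a, pfam_b) {
  identical(pfam_set(pfam_a), pfam_set(pfam_b))
}
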