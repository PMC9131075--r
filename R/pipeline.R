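# --- End-to-end orchestration and summary tables ----------------------------

#' Pipeline configuration
#'
#' Defaults are the cluster-calling and divergence thresholds of the analysis:
#' e-value 1e-10, bit-score ratio 0.30, coverage 0.50, up to 10 intervening
#' genes, TPM cutoff 0.5, Ks exclusion above 2, FDR 0.05 with a minimum of 10
#' TDGs per term, 1 Mb density windows.
#'
#' @param evalue_max,bsr_min,coverage_min homology thresholds
#' @param max_intervening intervening-gene rule
#' @param tpm_cutoff expression cutoff
#' @param ks_max Ks exclusion threshold
#' @param fdr,min_term_count enrichment significance rule
#' @param window density window size in bp
#' @param seed master seed for the random-pair nulls
#' @param unplaced_chroms unplaced scaffold names
#' @param prefilter,kmer,min_shared_kmers homology candidate prefilter
#' @return list of configuration values
#' @export
run_config <- function(evalue_max = 1e-10, bsr_min = 0.30, coverage_min = 0.50,
                       max_intervening = 10, tpm_cutoff = 0.5, ks_max = 2,
                       fdr = 0.05, min_term_count = 10, window = 1e6,
                       seed = 1, unplaced_chroms = "chrUn",
                       prefilter = TRUE, kmer = 11, min_shared_kmers = 4) {
  as.list(environment())
}

# master per-pair table for one genotype: homology + intervening + Ka/Ks +
# expression + promoter + domain comparison
build_pair_table <- function(pairs, genes, tpm, promoters, config, seed) {
  if (nrow(pairs) == 0) return(pairs)
  # Ka/Ks
  cds <- stats::setNames(genes$cds, genes$gene_id)
  prot <- stats::setNames(sub("\\*$", "", genes$protein), genes$gene_id)
  kk <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
    a <- pairs$gene_a[i]; b <- pairs$gene_b[i]
    kaks(align_codons(cds[[a]], cds[[b]], prot[[a]], prot[[b]]),
         ks_max = config$ks_max)
  }))
  pairs <- cbind(pairs, kk[, c("ka", "ks", "omega", "n_sites", "s_sites",
                               "excluded", "reason")])
  # expression divergence against the random-pair null
  tdg_ids <- unique(c(pairs$gene_a, pairs$gene_b))
  expressed <- rowSums(tpm > config$tpm_cutoff) > 0
  n_expr_pairs <- sum(expressed[pairs$gene_a] & expressed[pairs$gene_b],
                      na.rm = TRUE)
  eligible_null <- sum(expressed & !(rownames(tpm) %in% tdg_ids))
  n_null <- min(max(n_expr_pairs, 20), eligible_null * (eligible_null - 1) / 2)
  null <- random_pair_null(tpm, tdg_ids, n_null, seed = seed,
                           cutoff = config$tpm_cutoff)
  pairs <- call_expression_divergence(pairs, tpm, null$q95,
                                      cutoff = config$tpm_cutoff)
  # promoter divergence against the random-pair null
  with_prom <- !is.na(promoters$promoter)
  n_prom_pairs <- sum(with_prom[match(pairs$gene_a, promoters$gene_id)] &
                        with_prom[match(pairs$gene_b, promoters$gene_id)])
  eligible_prom <- sum(with_prom & !(promoters$gene_id %in% tdg_ids))
  n_pnull <- min(max(n_prom_pairs, 20),
                 eligible_prom * (eligible_prom - 1) / 2)
  pnull <- promoter_null(promoters, tdg_ids, n_pnull, seed = seed + 1)
  pairs <- call_promoter_divergence(pairs, promoters, pnull$q95)
  # domain comparison
  pf <- stats::setNames(genes$pfam, genes$gene_id)
  pairs$domains_identical <- vapply(seq_len(nrow(pairs)), function(i) {
    domains_identical(pf[[pairs$gene_a[i]]], pf[[pairs$gene_b[i]]])
  }, logical(1))
  pairs
}

#' Per-genotype cluster summary row
#'
#' @param genes full gene table (after the TE-orthogroup filter)
#' @param filtered located non-TE gene table
#' @param membership cluster membership
#' @param pairs pair table
#' @param tpm TPM matrix
#' @param orthogroups orthogroup table
#' @param config pipeline configuration
#' @return one-row data.frame of counts and percentages
#' @export
genotype_summary <- function(genes, filtered, membership, pairs, tpm,
                             orthogroups, config) {
  tdg <- unique(membership$gene_id)
  ogs <- unique(orthogroups$og_id[orthogroups$gene_id %in% tdg])
  sizes <- if (nrow(membership)) table(membership$cluster_id) else integer(0)
  has_pf <- vapply(filtered$pfam[match(tdg, filtered$gene_id)],
                   function(s) length(pfam_set(s)) > 0, logical(1))
  expressed <- rowSums(tpm > config$tpm_cutoff) > 0
  data.frame(
    genotype = genes$genotype[1],
    n_non_te = sum(!genes$is_te),
    n_non_te_located = nrow(filtered),
    n_clusters = length(sizes),
    genes_in_clusters = length(tdg),
    pct_genes_in_clusters = pct(length(tdg), nrow(filtered)),
    n_orthogroups = length(ogs),
    pct_clusters_size2 = pct(sum(sizes == 2), length(sizes)),
    largest_cluster = if (length(sizes)) max(sizes) else 0L,
    pct_tdg_with_pfam = pct(sum(has_pf), length(tdg)),
    pct_tdg_expressed = pct(sum(expressed[tdg], na.rm = TRUE), length(tdg)),
    stringsAsFactors = FALSE)
}

#' TE-filter report
#'
#' @param genes_before,genes_after named lists of gene tables per genotype,
#'   before and after the TE-orthogroup filter
#' @return data.frame with per-genotype rows and a total row
#' @export
te_filter_summary <- function(genes_before, genes_after) {
  rows <- lapply(names(genes_before), function(g) {
    before <- nrow(genes_before[[g]])
    after <- sum(!genes_after[[g]]$is_te)
    data.frame(genotype = g, n_before = before, n_after = after,
               pct_te = pct(before - after, before), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  tot_b <- sum(out$n_before); tot_a <- sum(out$n_after)
  rbind(out, data.frame(genotype = "Total", n_before = tot_b, n_after = tot_a,
                        pct_te = pct(tot_b - tot_a, tot_b),
                        stringsAsFactors = FALSE))
}

#' Run the full multi-genotype analysis
#'
#' Loads each genotype, applies the TE-orthogroup filter, detects TDG pairs
#' and clusters, computes Ka/Ks, expression and promoter divergence against
#' random-pair nulls, classifies clusters across genotypes, tests Pfam and GO
#' enrichment, calls duplicate fates, and writes all tables to `out_dir`.
#' Deterministic given the configuration seed.
#'
#' @param inputs named list (per genotype) of lists with paths: gff3, cds,
#'   protein, genome, annotation, tpm (as returned in `$paths` by
#'   [simulate_tdg_data()])
#' @param orthogroups_path path to the orthogroup TSV
#' @param out_dir output directory
#' @param config see [run_config()]
#' @return list of all result tables
#' @export
run_pipeline <- function(inputs, orthogroups_path, out_dir,
                         config = run_config()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  gts <- names(inputs)
  og <- read_orthogroups(orthogroups_path)

  genes_raw <- lapply(stats::setNames(gts, gts), function(g) {
    load_genotype(inputs[[g]]$gff3, inputs[[g]]$cds, inputs[[g]]$protein,
                  inputs[[g]]$annotation, genotype = g,
                  unplaced_chroms = config$unplaced_chroms)
  })
  all_genes <- do.call(rbind, genes_raw)
  og_class <- classify_te_orthogroups(og, all_genes)
  genes_filtered_te <- lapply(genes_raw, apply_te_og_filter,
                              orthogroups = og, og_class = og_class)
  te_report <- te_filter_summary(genes_raw, genes_filtered_te)

  results <- list(genes = genes_filtered_te, te_filter = te_report,
                  og_class = og_class)
  membership_all <- list()
  pair_tables <- list()
  summaries <- list()
  enr_pfam <- list(); enr_go <- list()
  density <- list()
  correlations <- list()

  for (gi in seq_along(gts)) {
    g <- gts[gi]
    genes <- genes_filtered_te[[g]]
    filtered <- non_te_located_genes(genes)
    hits <- same_chromosome_pairs(
      filtered,
      thresholds = homology_thresholds(config$evalue_max, config$bsr_min,
                                       config$coverage_min),
      prefilter = config$prefilter, k = config$kmer,
      min_shared_kmers = config$min_shared_kmers)
    pairs <- build_pairs(hits, filtered,
                         max_intervening = config$max_intervening)
    membership <- build_clusters(pairs, filtered)
    tpm <- read_tpm(inputs[[g]]$tpm)
    genome <- read_fasta_named(inputs[[g]]$genome)
    promoters <- extract_promoters(filtered, genome)
    if (nrow(pairs)) {
      pairs$genotype <- g
      pairs <- build_pair_table(pairs, filtered, tpm, promoters, config,
                                seed = derive_seed(config$seed, gi))
      pairs$cluster_id <- membership$cluster_id[
        match(pairs$gene_a, membership$gene_id)]
    }
    pair_tables[[g]] <- pairs
    membership_all[[g]] <- membership
    summaries[[g]] <- genotype_summary(genes, filtered, membership, pairs,
                                       tpm, og, config)
    # enrichment over the located non-TE background
    term_tab <- function(col) {
      sets <- lapply(filtered[[col]], pfam_set)
      data.frame(gene_id = rep(filtered$gene_id, lengths(sets)),
                 term = unlist(sets), stringsAsFactors = FALSE)
    }
    tdg_ids <- unique(membership$gene_id)
    if (length(tdg_ids)) {
      enr_pfam[[g]] <- fisher_enrichment(term_tab("pfam"), tdg_ids,
                                         filtered$gene_id, fdr = config$fdr,
                                         min_count = config$min_term_count)
      enr_go[[g]] <- fisher_enrichment(term_tab("go"), tdg_ids,
                                       filtered$gene_id, fdr = config$fdr,
                                       min_count = config$min_term_count)
    }
    # density of TDGs vs non-TE genes in tiling windows
    chrom_lengths <- Biostrings::width(genome)
    names(chrom_lengths) <- names(genome)
    chrom_lengths <- chrom_lengths[setdiff(names(chrom_lengths),
                                           config$unplaced_chroms)]
    tdg_feat <- filtered[filtered$gene_id %in% tdg_ids,
                         c("chromosome", "start", "end")]
    gene_feat <- filtered[, c("chromosome", "start", "end")]
    tdg_track <- windowed_density(tdg_feat, chrom_lengths, config$window)
    gene_track <- windowed_density(gene_feat, chrom_lengths, config$window)
    # the uniformity model needs more windows than covariates; tiny genomes
    # simply skip it
    dens_model <- if (nrow(tdg_track) >= 3)
      density_model(tdg_track, list(genes = gene_track)) else NULL
    density[[g]] <- list(tdg = tdg_track, genes = gene_track,
                         model = dens_model)
    if (nrow(pairs)) correlations[[g]] <- divergence_correlations(pairs)
  }

  membership_df <- do.call(rbind, membership_all)
  rownames(membership_df) <- NULL
  categories <- categorize_clusters(membership_df, og, gts)
  cat_sum <- category_summary(categories)

  nonempty <- vapply(pair_tables, nrow, integer(1)) > 0
  if (any(nonempty)) {
    master <- do.call(rbind, pair_tables[nonempty])
    rownames(master) <- NULL
    fates <- call_fates(master)
    fate_sum <- summarize_fates(fates)
    selection <- classify_selection(master)
  } else {
    master <- data.frame()
    fates <- data.frame()
    fate_sum <- list(per_genotype = data.frame(), average = c())
    selection <- list(classes = data.frame(), proportions = c())
  }

  diff_enr <- if (length(enr_pfam) >= 2) differential_enrichment(enr_pfam)
    else NULL

  results <- c(results, list(
    membership = membership_df, pairs = fates, categories = categories,
    category_summary = cat_sum, summaries = do.call(rbind, summaries),
    fate_summary = fate_sum, selection_proportions = selection$proportions,
    enrichment_pfam = enr_pfam, enrichment_go = enr_go,
    differential_enrichment = diff_enr, density = density,
    correlations = correlations))

  # --- write tables ----------------------------------------------------------
  wt <- function(df, name) {
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  wt(te_report, "te_filter.tsv")
  wt(results$summaries, "cluster_summary.tsv")
  wt(membership_df, "cluster_membership.tsv")
  wt(categories, "cluster_categories.tsv")
  wt(cat_sum$per_genotype, "category_summary.tsv")
  wt(fates[, setdiff(names(fates), c("cds"))], "pair_table.tsv")
  wt(fate_sum$per_genotype, "fate_summary.tsv")
  for (g in names(enr_pfam)) {
    wt(enr_pfam[[g]], paste0(g, "_enrichment_pfam.tsv"))
    wt(enr_go[[g]], paste0(g, "_enrichment_go.tsv"))
  }
  if (!is.null(diff_enr))
    utils::write.table(data.frame(term = rownames(diff_enr), diff_enr,
                                  check.names = FALSE),
                       file.path(out_dir, "differential_enrichment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  if (length(correlations))
    wt(do.call(rbind, Map(function(df, g) cbind(genotype = g, df),
                          correlations, names(correlations))),
       "correlations.tsv")
  results
}
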