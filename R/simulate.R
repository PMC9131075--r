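# --- Multi-genotype synthetic data with planted ground truth ----------------

#' Configuration for the synthetic-data generator
#'
#' Defaults emulate the statistical structure of a multi-genotype potato-like
#' analysis at desk scale: four genotypes, ~18% of genes in tandem clusters,
#' two-gene clusters dominating (~67%), ~10% TE genes, a 25/30/45
#' private/core/shared cluster partition, mostly-purifying omega mix, ~75% of
#' duplicate pairs with diverged expression and ~70% with diverged promoters.
#'
#' @param genotypes genotype labels
#' @param n_chromosomes,genes_per_chromosome genome layout
#' @param spacer_range intergenic spacer range in bp
#' @param frac_te fraction of TE-flagged genes
#' @param frac_unplaced fraction of genes on the unplaced scaffold
#' @param frac_tdg target fraction of genes in tandem clusters
#' @param cluster_sizes,cluster_size_probs cluster-size distribution
#' @param intervening_probs distribution of intervening-gene counts (0..10)
#' @param omega_values,omega_probs planted omega mixture
#' @param ks_range planted synonymous-divergence range per derived copy
#' @param frac_private,frac_core,frac_shared cluster category partition
#' @param n_samples RNA-Seq sample count
#' @param frac_expressed fraction of genes expressed
#' @param frac_expr_diverged fraction of duplicate pairs with planted
#'   expression divergence (independent profiles; conserved pairs are
#'   noise-correlated copies)
#' @param expr_noise_sd log10-scale noise SD for conserved profiles
#' @param frac_promoter_diverged fraction of pairs with planted promoter
#'   turnover (independent promoter; conserved pairs mutated lightly)
#' @param promoter_mut_conserved per-base mutation rate of conserved promoters
#' @param neo_domain_prob probability that a positively selected copy gains an
#'   extra Pfam domain
#' @param codon_range CDS length range in codons
#' @param promoter_len promoter length in bp
#' @param unplaced_chrom name of the unplaced scaffold
#' @param seed master RNG seed
#' @return list of configuration values
#' @export
sim_config <- function(genotypes = paste0("G", 1:4),
                       n_chromosomes = 5,
                       genes_per_chromosome = 400,
                       spacer_range = c(300, 1500),
                       frac_te = 0.10,
                       frac_unplaced = 0.02,
                       frac_tdg = 0.18,
                       cluster_sizes = 2:6,
                       cluster_size_probs = c(0.67, 0.18, 0.08, 0.04, 0.03),
                       intervening_probs = c(0.50, 0.20, 0.10, 0.07, 0.05,
                                             0.03, 0.02, 0.01, 0.01, 0.005,
                                             0.005),
                       omega_values = c(0.2, 0.6, 1.5),
                       omega_probs = c(0.75, 0.18, 0.07),
                       ks_range = c(0.05, 0.5),
                       frac_private = 0.25,
                       frac_core = 0.30,
                       frac_shared = 0.45,
                       n_samples = 10,
                       frac_expressed = 0.75,
                       frac_expr_diverged = 0.75,
                       expr_noise_sd = 0.05,
                       frac_promoter_diverged = 0.70,
                       promoter_mut_conserved = 0.02,
                       neo_domain_prob = 0.5,
                       codon_range = c(100, 400),
                       promoter_len = 1000,
                       unplaced_chrom = "chrUn",
                       seed = 1) {
  cfg <- as.list(environment())
  stopifnot(abs(sum(cfg$cluster_size_probs) - 1) < 1e-6,
            abs(cfg$frac_private + cfg$frac_core + cfg$frac_shared - 1) < 1e-6,
            abs(sum(cfg$omega_probs) - 1) < 1e-6)
  cfg$intervening_probs <- cfg$intervening_probs / sum(cfg$intervening_probs)
  cfg
}

#' Random coding sequence of sense codons (no stop codons)
#'
#' @param n_codons number of codons
#' @return CDS string
#' @export
random_cds <- function(n_codons) {
  paste(sample(sense_codons(), n_codons, replace = TRUE), collapse = "")
}

#' Mutate DNA at a fixed per-base substitution rate
#'
#' @param seq DNA string
#' @param rate per-base substitution probability
#' @return mutated string
#' @export
mutate_dna <- function(seq, rate) {
  chars <- strsplit(seq, "")[[1]]
  hit <- which(stats::runif(length(chars)) < rate)
  for (i in hit) {
    chars[i] <- sample(setdiff(DNA_ALPHABET, chars[i]), 1)
  }
  paste(chars, collapse = "")
}

#' Derive a diverged copy of a CDS at a planted omega
#'
#' Proposes random single-nucleotide codon changes (uniform over positions
#' and alternative bases, the same mutational-opportunity measure the NG86
#' site convention uses); proposals creating stop codons are rejected;
#' synonymous proposals are accepted with probability min(1, 1/omega) and
#' nonsynonymous ones with probability min(1, omega), so the expected Ka/Ks
#' of the copy against the original is the planted omega. The number of
#' proposal rounds is set so the expected Ks is `target_ks`.
#'
#' @param cds ancestral CDS string (length divisible by 3, sense codons)
#' @param omega planted Ka/Ks
#' @param target_ks planted synonymous divergence
#' @return mutated CDS string
#' @export
simulate_divergent_pair <- function(cds, omega, target_ks) {
  codons <- split_codons(cds)
  L <- length(codons)
  p_syn <- min(1, 1 / omega)
  p_non <- min(1, omega)
  n_prop <- max(1L, round(3 * L * target_ks / p_syn))
  for (k in seq_len(n_prop)) {
    i <- sample.int(L, 1)
    pos <- sample.int(3, 1)
    cur <- codons[i]
    ref <- substr(cur, pos, pos)
    alt <- sample(setdiff(DNA_ALPHABET, ref), 1)
    mut <- cur
    substr(mut, pos, pos) <- alt
    if (codon_aa(mut) == "*") next
    syn <- codon_aa(mut) == codon_aa(cur)
    p <- if (syn) p_syn else p_non
    if (stats::runif(1) < p) codons[i] <- mut
  }
  paste(codons, collapse = "")
}

# Synonymous-only edits: for each codon, with probability `rate` substitute a
# random synonymous alternative (if one exists). Ka of the pair is exactly 0.
synonymous_edits <- function(cds, rate = 0.3) {
  # only synonymous alternatives reachable by a single nucleotide change, so
  # every edited codon pair differs by one strictly synonymous step and Ka is
  # exactly zero under pathway counting
  codons <- split_codons(cds)
  for (i in seq_along(codons)) {
    if (stats::runif(1) >= rate) next
    cur <- codons[i]
    aa <- codon_aa(cur)
    alts <- character(0)
    for (pos in 1:3) {
      for (nt in setdiff(DNA_ALPHABET, substr(cur, pos, pos))) {
        mut <- cur
        substr(mut, pos, pos) <- nt
        if (identical(codon_aa(mut), aa)) alts <- c(alts, mut)
      }
    }
    if (length(alts)) codons[i] <- sample(alts, 1)
  }
  paste(codons, collapse = "")
}

# ---------------------------------------------------------------------------
# Emission: lay genes on chromosomes, assemble genome sequence, write bundle.
# Gene bodies embed the CDS (forward strand) or its reverse complement;
# promoters are placed immediately upstream of the TSS on the coding strand so
# that extract_promoters() recovers the planted promoter exactly.
# ---------------------------------------------------------------------------
emit_genotype <- function(spec, genotype, dir, config) {
  # spec: data.frame in layout order with gene_id, chromosome, strand, cds,
  # promoter; coordinates assigned here.
  spec$start <- NA_integer_
  spec$end <- NA_integer_
  body_all <- spec$cds
  body_all[spec$strand == "-"] <- revcomp(spec$cds[spec$strand == "-"])
  prom_rc <- spec$promoter
  prom_rc[spec$strand == "-"] <- revcomp(spec$promoter[spec$strand == "-"])
  chrom_seqs <- list()
  for (chrom in unique(spec$chromosome)) {
    sel <- which(spec$chromosome == chrom)
    segs <- character(0)
    pos <- 0L
    for (i in sel) {
      spacer <- sample(config$spacer_range[1]:config$spacer_range[2], 1)
      body <- body_all[i]
      nb <- nchar(body)
      np <- nchar(spec$promoter[i])
      if (spec$strand[i] == "+") {
        segs <- c(segs, random_dna(spacer), spec$promoter[i], body)
        spec$start[i] <- pos + spacer + np + 1L
        spec$end[i] <- spec$start[i] + nb - 1L
        pos <- spec$end[i]
      } else {
        segs <- c(segs, random_dna(spacer), body, prom_rc[i])
        spec$start[i] <- pos + spacer + 1L
        spec$end[i] <- spec$start[i] + nb - 1L
        pos <- spec$end[i] + np
      }
    }
    segs <- c(segs, random_dna(sample(config$spacer_range[1]:config$spacer_range[2], 1)))
    chrom_seqs[[chrom]] <- paste(segs, collapse = "")
  }

  genome <- Biostrings::DNAStringSet(unlist(chrom_seqs))
  Biostrings::writeXStringSet(genome, file.path(dir, paste0(genotype, ".genome.fa")))

  # GFF3 in coordinate order per chromosome
  ord <- order(spec$chromosome, spec$start)
  g <- spec[ord, ]
  lines <- c("##gff-version 3")
  for (i in seq_len(nrow(g))) {
    base <- sprintf("%s\ttandemscan\t%%s\t%d\t%d\t.\t%s\t%%s\t%%s",
                    g$chromosome[i], g$start[i], g$end[i], g$strand[i])
    gid <- g$gene_id[i]
    lines <- c(lines,
               sprintf(base, "gene", ".", sprintf("ID=%s", gid)),
               sprintf(base, "mRNA", ".",
                       sprintf("ID=%s.t1;Parent=%s", gid, gid)),
               sprintf(base, "CDS", "0",
                       sprintf("ID=%s.t1.cds;Parent=%s.t1", gid, gid)))
  }
  writeLines(lines, file.path(dir, paste0(genotype, ".gff3")))

  cds_set <- Biostrings::DNAStringSet(stats::setNames(spec$cds, spec$gene_id))
  Biostrings::writeXStringSet(cds_set, file.path(dir, paste0(genotype, ".cds.fa")))
  prot <- translate_cds(spec$cds)
  prot_set <- Biostrings::AAStringSet(stats::setNames(prot, spec$gene_id))
  Biostrings::writeXStringSet(prot_set, file.path(dir, paste0(genotype, ".protein.fa")))

  spec
}

write_annotation <- function(spec, genotype, dir) {
  ann <- data.frame(gene_id = spec$gene_id, pfam = spec$pfam, go = spec$go,
                    ahrd_stars = spec$ahrd, te_flag = as.integer(spec$is_te),
                    stringsAsFactors = FALSE)
  utils::write.table(ann, file.path(dir, paste0(genotype, ".annotation.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
}

write_tpm <- function(tpm, genotype, dir) {
  df <- data.frame(gene_id = rownames(tpm),
                   round(tpm, 4), check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, file.path(dir, paste0(genotype, ".tpm.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a TPM matrix written by the generator
#'
#' @param path TSV with a gene_id column and one column per sample
#' @return numeric matrix with gene ids as rownames
#' @export
read_tpm <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$gene_id
  m
}

#' Generate a synthetic multi-genotype dataset with planted ground truth
#'
#' Emits, per genotype, a GFF3, genome/CDS/protein FASTA, an annotation table
#' and a TPM matrix, plus a cross-genotype orthogroup table and ground-truth
#' tables (gene cluster membership, per-pair planted omega / expression /
#' promoter divergence, per-family category). Deterministic under the seed.
#'
#' @param config from [sim_config()]
#' @param out_dir output directory (created if needed)
#' @return list: config, dir, paths (per genotype), truth (genes, pairs,
#'   clusters data.frames)
#' @export
simulate_tdg_data <- function(config = sim_config(), out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  gts <- config$genotypes
  n_g <- length(gts)
  G <- config$n_chromosomes * config$genes_per_chromosome
  mean_size <- sum(config$cluster_sizes * config$cluster_size_probs)
  n_clust <- round(config$frac_tdg * G / mean_size)
  n_priv <- round(config$frac_private * n_clust)
  n_core <- round(config$frac_core * n_clust)
  n_shared <- max(0L, n_clust - n_priv - n_core)

  # --- family plan -----------------------------------------------------------
  fams <- list()
  add_fam <- function(presence) {
    id <- length(fams) + 1L
    fams[[id]] <<- list(family_id = sprintf("FAM%04d", id),
                        og_id = sprintf("OG%05d", id),
                        presence = presence,
                        singleton_carriers = character(0))
  }
  if (n_g > 1) for (k in seq_len(n_core)) add_fam(gts)
  for (g in gts) for (k in seq_len(n_priv)) add_fam(g)
  if (n_g > 2) {
    slots <- stats::setNames(rep(n_shared, n_g), gts)
    while (sum(slots > 0) >= 2) {
      k <- min(sum(slots > 0), sample(2:3, 1))
      pick <- names(sort(slots, decreasing = TRUE))[seq_len(k)]
      add_fam(sort(pick))
      slots[pick] <- slots[pick] - 1
    }
  } else {
    # with < 3 genotypes "shared" is impossible; fold those slots into core
    for (k in seq_len(n_shared)) add_fam(gts)
  }
  # private families may have a non-clustered ortholog elsewhere: presence is
  # about *clustered* orthogroups, so such carriers must not flip the category
  for (id in seq_along(fams)) {
    f <- fams[[id]]
    if (length(f$presence) == 1 && n_g > 1 && stats::runif(1) < 0.5) {
      fams[[id]]$singleton_carriers <- sample(setdiff(gts, f$presence), 1)
    }
  }

  pool_pf_tdg <- sprintf("PF%05d", 1:30)
  pool_pf_bg <- sprintf("PF%05d", 101:600)
  pool_pf_neo <- sprintf("PF%05d", 901:950)
  pool_go_tdg <- sprintf("GO:%07d", 1:40)
  pool_go_bg <- sprintf("GO:%07d", 101:800)

  for (id in seq_along(fams)) {
    L <- sample(config$codon_range[1]:config$codon_range[2], 1)
    fams[[id]]$ancestor <- random_cds(L)
    fams[[id]]$pfam <- paste(sample(pool_pf_tdg, sample(1:2, 1)), collapse = ",")
    fams[[id]]$go <- paste(sample(pool_go_tdg, sample(1:3, 1)), collapse = ",")
  }

  # --- per-genotype construction --------------------------------------------
  truth_genes <- list(); truth_pairs <- list(); og_rows <- list()
  specs <- list(); tpms <- list()
  n_te <- round(config$frac_te * G)
  n_unplaced <- round(config$frac_unplaced * G)

  for (gi in seq_along(gts)) {
    g <- gts[gi]
    units <- list()   # each unit: data.frame rows in adjacency order
    next_id <- 0L
    new_gene_id <- function() {
      next_id <<- next_id + 1L
      sprintf("%s_g%05d", g, next_id)
    }
    mk_gene <- function(gene_id, cds, promoter, family_id, pfam, go,
                        is_te = FALSE, ahrd = NA_integer_) {
      if (is.na(ahrd))
        ahrd <- if (is_te) sample(0:1, 1, prob = c(0.6, 0.4)) else
          sample(0:3, 1, prob = c(0.01, 0.04, 0.30, 0.65))
      data.frame(gene_id = gene_id, family_id = family_id,
                 strand = sample(c("+", "-"), 1),
                 cds = cds, promoter = promoter, pfam = pfam, go = go,
                 is_te = is_te, ahrd = ahrd, stringsAsFactors = FALSE)
    }

    fam_here <- Filter(function(f) g %in% f$presence, fams)
    pair_rows <- list()
    cluster_units <- list()
    n_cluster_genes <- 0L
    for (f in fam_here) {
      size <- sample(config$cluster_sizes, 1, prob = config$cluster_size_probs)
      members <- list()
      p1 <- random_dna(config$promoter_len)
      m1 <- mk_gene(new_gene_id(), f$ancestor, p1, f$family_id,
                    f$pfam, f$go)
      members[[1]] <- m1
      for (j in seq_len(size - 1)) {
        omega <- sample(config$omega_values, 1, prob = config$omega_probs)
        ks <- stats::runif(1, config$ks_range[1], config$ks_range[2])
        cds_j <- simulate_divergent_pair(f$ancestor, omega, ks)
        prom_div <- stats::runif(1) < config$frac_promoter_diverged
        p_j <- if (prom_div) random_dna(config$promoter_len) else
          mutate_dna(p1, config$promoter_mut_conserved)
        pf_j <- f$pfam
        dom_diff <- FALSE
        if (omega > 1 && stats::runif(1) < config$neo_domain_prob) {
          pf_j <- paste(c(pfam_set(f$pfam), sample(pool_pf_neo, 1)),
                        collapse = ",")
          dom_diff <- TRUE
        }
        mj <- mk_gene(new_gene_id(), cds_j, p_j, f$family_id, pf_j, f$go)
        members[[j + 1]] <- mj
        pair_rows[[length(pair_rows) + 1]] <- data.frame(
          genotype = g, gene_a = m1$gene_id, gene_b = mj$gene_id,
          family_id = f$family_id, omega = omega, target_ks = ks,
          prom_diverged = prom_div, domains_differ = dom_diff,
          stringsAsFactors = FALSE)
      }
      cluster_units[[length(cluster_units) + 1]] <-
        list(family_id = f$family_id, members = members)
      n_cluster_genes <- n_cluster_genes + size
    }

    # singles: fill to G genes; carriers of private families first
    n_singles <- G - n_cluster_genes
    carriers <- Filter(function(f) g %in% f$singleton_carriers, fams)
    singles <- vector("list", n_singles)
    for (s in seq_len(n_singles)) {
      is_te <- s > n_singles - n_te
      fam <- if (s <= length(carriers)) carriers[[s]] else NULL
      L <- sample(config$codon_range[1]:config$codon_range[2], 1)
      pf <- if (!is.null(fam)) fam$pfam
        else if (is_te || stats::runif(1) < 0.4) ""
        else paste(sample(pool_pf_bg, sample(1:2, 1)), collapse = ",")
      go <- if (!is.null(fam)) fam$go
        else if (is_te || stats::runif(1) < 0.3) ""
        else paste(sample(pool_go_bg, sample(1:3, 1)), collapse = ",")
      singles[[s]] <- mk_gene(new_gene_id(), random_cds(L),
                              random_dna(config$promoter_len),
                              if (!is.null(fam)) fam$family_id else NA_character_,
                              pf, go, is_te = is_te)
    }
    singles_meta <- data.frame(
      gene_id = vapply(singles, function(x) x$gene_id, character(1)),
      single_index = seq_len(n_singles),
      stringsAsFactors = FALSE)

    # interleave: cluster units consume singles as intervening genes
    single_queue <- sample(seq_len(n_singles))
    q_pos <- 1L
    take_singles <- function(k) {
      if (k == 0 || q_pos > n_singles) return(list())
      k <- min(k, n_singles - q_pos + 1L)
      out <- singles[single_queue[q_pos:(q_pos + k - 1L)]]
      q_pos <<- q_pos + k
      out
    }
    for (cu in cluster_units) {
      rows <- list(cu$members[[1]])
      for (j in seq_along(cu$members)[-1]) {
        n_int <- sample(0:10, 1, prob = config$intervening_probs)
        rows <- c(rows, take_singles(n_int), cu$members[j])
      }
      units[[length(units) + 1]] <- do.call(rbind, rows)
    }
    while (q_pos <= n_singles) {
      units[[length(units) + 1]] <- singles[[single_queue[q_pos]]]
      q_pos <- q_pos + 1L
    }

    units <- units[sample(length(units))]
    spec <- do.call(rbind, units)

    # chromosome assignment: unplaced genes go to the unplaced scaffold;
    # the rest fill chromosomes in layout order
    unplaced_ids <- spec$gene_id[!spec$gene_id %in%
      unlist(lapply(cluster_units, function(cu)
        vapply(cu$members, function(m) m$gene_id, character(1))))]
    unplaced_ids <- utils::tail(unplaced_ids, n_unplaced)
    spec$chromosome <- NA_character_
    placed <- spec$gene_id[!spec$gene_id %in% unplaced_ids]
    per_chrom <- ceiling(length(placed) / config$n_chromosomes)
    chroms <- rep(sprintf("chr%02d", seq_len(config$n_chromosomes)),
                  each = per_chrom)[seq_along(placed)]
    spec$chromosome[match(placed, spec$gene_id)] <- chroms
    spec$chromosome[is.na(spec$chromosome)] <- config$unplaced_chrom

    spec <- emit_genotype(spec, g, out_dir, config)
    write_annotation(spec, g, out_dir)

    # expression
    tpm <- matrix(0, nrow(spec), config$n_samples,
                  dimnames = list(spec$gene_id,
                                  sprintf("S%02d", seq_len(config$n_samples))))
    expressed <- stats::runif(nrow(spec)) < config$frac_expressed
    names(expressed) <- spec$gene_id
    base_profile <- function() {
      mu <- stats::runif(1, 0.3, 1.5)
      10^stats::rnorm(config$n_samples, mu, 0.6)
    }
    for (i in which(expressed)) tpm[i, ] <- base_profile()
    # conserved pairs: copy + noise on the log scale
    pair_df <- if (length(pair_rows)) do.call(rbind, pair_rows) else NULL
    if (!is.null(pair_df)) {
      pair_df$expr_diverged <- stats::runif(nrow(pair_df)) <
        config$frac_expr_diverged
      for (k in seq_len(nrow(pair_df))) {
        a <- pair_df$gene_a[k]; b <- pair_df$gene_b[k]
        if (!pair_df$expr_diverged[k] && expressed[a] && expressed[b]) {
          la <- log10(tpm[a, ] + 1)
          tpm[b, ] <- pmax(0, 10^(la + stats::rnorm(config$n_samples, 0,
                                                    config$expr_noise_sd)) - 1)
        }
      }
      truth_pairs[[g]] <- pair_df
    }
    write_tpm(tpm, g, out_dir)
    tpms[[g]] <- tpm

    # orthogroups: family OGs (members + private-family carriers), singleton
    # OGs keyed by single index (shared across genotypes), all-TE OGs for TE
    # singles
    fam_og <- stats::setNames(
      vapply(fams, function(f) f$og_id, character(1)),
      vapply(fams, function(f) f$family_id, character(1)))
    in_fam <- !is.na(spec$family_id)
    if (any(in_fam)) {
      og_rows[[length(og_rows) + 1]] <- data.frame(
        og_id = unname(fam_og[spec$family_id[in_fam]]),
        genotype = g, gene_id = spec$gene_id[in_fam],
        stringsAsFactors = FALSE)
    }
    lone <- spec$gene_id[!in_fam]
    lone_idx <- singles_meta$single_index[match(lone, singles_meta$gene_id)]
    lone_te <- spec$is_te[match(lone, spec$gene_id)]
    og_rows[[length(og_rows) + 1]] <- data.frame(
      og_id = ifelse(lone_te, sprintf("OGT%05d", lone_idx),
                     sprintf("OGS%05d", lone_idx)),
      genotype = g, gene_id = lone, stringsAsFactors = FALSE)

    cluster_member_ids <- unlist(lapply(cluster_units, function(cu)
      vapply(cu$members, function(m) m$gene_id, character(1))))
    spec$genotype <- g
    specs[[g]] <- spec
    truth_genes[[g]] <- data.frame(
      gene_id = spec$gene_id, genotype = g, chromosome = spec$chromosome,
      family_id = spec$family_id,
      clustered = spec$gene_id %in% cluster_member_ids,
      is_te = spec$is_te,
      located = spec$chromosome != config$unplaced_chrom,
      stringsAsFactors = FALSE)
  }

  og_tab <- do.call(rbind, og_rows)
  utils::write.table(og_tab, file.path(out_dir, "orthogroups.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  truth_clusters <- if (length(fams)) do.call(rbind, lapply(fams, function(f) {
    np <- length(f$presence)
    data.frame(family_id = f$family_id, og_id = f$og_id,
               n_genotypes = np,
               category = if (np == n_g) "core" else if (np == 1) "private"
                 else "shared",
               presence = paste(f$presence, collapse = ","),
               stringsAsFactors = FALSE)
  })) else data.frame(family_id = character(0), og_id = character(0),
                      n_genotypes = integer(0), category = character(0),
                      presence = character(0), stringsAsFactors = FALSE)
  truth <- list(genes = do.call(rbind, truth_genes),
                pairs = if (length(truth_pairs))
                  do.call(rbind, truth_pairs) else NULL,
                clusters = truth_clusters)
  rownames(truth$genes) <- NULL
  if (!is.null(truth$pairs)) rownames(truth$pairs) <- NULL
  utils::write.table(truth$genes, file.path(out_dir, "truth_genes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(truth$pairs))
    utils::write.table(truth$pairs, file.path(out_dir, "truth_pairs.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(truth_clusters, file.path(out_dir, "truth_clusters.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  paths <- lapply(stats::setNames(gts, gts), function(g) {
    list(gff3 = file.path(out_dir, paste0(g, ".gff3")),
         cds = file.path(out_dir, paste0(g, ".cds.fa")),
         protein = file.path(out_dir, paste0(g, ".protein.fa")),
         genome = file.path(out_dir, paste0(g, ".genome.fa")),
         annotation = file.path(out_dir, paste0(g, ".annotation.tsv")),
         tpm = file.path(out_dir, paste0(g, ".tpm.tsv")))
  })
  list(config = config, dir = out_dir, paths = paths,
       orthogroups = file.path(out_dir, "orthogroups.tsv"),
       truth = truth)
}

#' Tiny two-genotype worked dataset with hand-checkable truth
#'
#' Genotype GA carries a three-gene cluster, a homologous pair separated by 11
#' intervening genes (rejected by the intervening rule), an adjacent pair with
#' synonymous-only edits (Ka = 0 exactly) and a private two-gene cluster;
#' genotype GB carries only the ortholog cluster of the first family. About 30
#' genes in total on one chromosome per genotype.
#'
#' @param out_dir output directory
#' @param seed RNG seed (default 42)
#' @return same structure as [simulate_tdg_data()]
#' @export
worked_fixture <- function(out_dir, seed = 42) {
  cfg <- sim_config(genotypes = c("GA", "GB"), n_chromosomes = 1,
                    genes_per_chromosome = 30, frac_te = 0.1,
                    frac_unplaced = 0, frac_tdg = 0, n_samples = 6,
                    seed = seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)

  anc1 <- random_cds(200)   # shared family (cluster in both genotypes)
  anc2 <- random_cds(150)   # rejected pair (11 intervening)
  anc3 <- random_cds(180)   # synonymous-only pair
  anc4 <- random_cds(160)   # private family (GA only)

  mk <- function(gene_id, cds, promoter, family_id, pfam, go, is_te = FALSE) {
    data.frame(gene_id = gene_id, family_id = family_id, strand = "+",
               cds = cds, promoter = promoter, pfam = pfam, go = go,
               is_te = is_te, ahrd = if (is_te) 0L else 3L,
               stringsAsFactors = FALSE)
  }
  p <- function() random_dna(cfg$promoter_len)

  singles_a <- lapply(1:20, function(i)
    mk(sprintf("GA_s%02d", i), random_cds(120), p(), NA, "", "",
       is_te = i > 18))
  p1 <- p(); p4 <- p()
  cl1 <- list(
    mk("GA_c1a", anc1, p1, "FAM1", "PF00001,PF00002", "GO:0000001"),
    mk("GA_c1b", simulate_divergent_pair(anc1, 0.2, 0.05), mutate_dna(p1, 0.02),
       "FAM1", "PF00001,PF00002", "GO:0000001"),
    mk("GA_c1c", simulate_divergent_pair(anc1, 0.2, 0.08), mutate_dna(p1, 0.02),
       "FAM1", "PF00001,PF00002", "GO:0000001"))
  rej <- list(mk("GA_r1", anc2, p(), "FAM2", "", ""),
              mk("GA_r2", simulate_divergent_pair(anc2, 0.2, 0.05), p(),
                 "FAM2", "", ""))
  syn <- list(mk("GA_y1", anc3, p(), "FAM3", "PF00003", ""),
              mk("GA_y2", synonymous_edits(anc3, 0.3), p(), "FAM3",
                 "PF00003", ""))
  priv <- list(mk("GA_p1", anc4, p4, "FAM4", "PF00004", ""),
               mk("GA_p2", simulate_divergent_pair(anc4, 0.2, 0.06),
                  random_dna(cfg$promoter_len), "FAM4", "PF00004", ""))

  # layout: cluster1 adjacent; rejected pair with 11 singles between;
  # synonymous pair adjacent; private cluster adjacent; leftovers at the end
  order_a <- c(cl1, syn, rej[1], singles_a[1:11], rej[2], priv,
               singles_a[12:20])
  spec_a <- do.call(rbind, order_a)
  spec_a$chromosome <- "chr01"

  singles_b <- lapply(1:8, function(i)
    mk(sprintf("GB_s%02d", i), random_cds(120), p(), NA, "", ""))
  pb <- p()
  clb <- list(
    mk("GB_c1a", anc1, pb, "FAM1", "PF00001,PF00002", "GO:0000001"),
    mk("GB_c1b", simulate_divergent_pair(anc1, 0.2, 0.05), mutate_dna(pb, 0.02),
       "FAM1", "PF00001,PF00002", "GO:0000001"))
  spec_b <- do.call(rbind, c(singles_b[1:4], clb, singles_b[5:8]))
  spec_b$chromosome <- "chr01"

  spec_a <- emit_genotype(spec_a, "GA", out_dir, cfg)
  spec_b <- emit_genotype(spec_b, "GB", out_dir, cfg)
  write_annotation(spec_a, "GA", out_dir)
  write_annotation(spec_b, "GB", out_dir)

  # expression: (c1a, c1b) diverged, (c1a, c1c) conserved, (y1, y2) conserved
  mk_tpm <- function(spec) {
    tpm <- matrix(0, nrow(spec), cfg$n_samples,
                  dimnames = list(spec$gene_id,
                                  sprintf("S%02d", seq_len(cfg$n_samples))))
    for (i in seq_len(nrow(spec)))
      tpm[i, ] <- 10^stats::rnorm(cfg$n_samples, 1, 0.6)
    tpm
  }
  tpm_a <- mk_tpm(spec_a)
  tpm_a["GA_c1c", ] <- pmax(0, 10^(log10(tpm_a["GA_c1a", ] + 1) +
    stats::rnorm(cfg$n_samples, 0, 0.05)) - 1)
  tpm_a["GA_y2", ] <- pmax(0, 10^(log10(tpm_a["GA_y1", ] + 1) +
    stats::rnorm(cfg$n_samples, 0, 0.05)) - 1)
  tpm_b <- mk_tpm(spec_b)
  write_tpm(tpm_a, "GA", out_dir)
  write_tpm(tpm_b, "GB", out_dir)

  og <- rbind(
    data.frame(og_id = "OG00001", genotype = "GA",
               gene_id = c("GA_c1a", "GA_c1b", "GA_c1c"),
               stringsAsFactors = FALSE),
    data.frame(og_id = "OG00001", genotype = "GB",
               gene_id = c("GB_c1a", "GB_c1b"), stringsAsFactors = FALSE),
    data.frame(og_id = "OG00002", genotype = "GA",
               gene_id = c("GA_r1", "GA_r2"), stringsAsFactors = FALSE),
    data.frame(og_id = "OG00003", genotype = "GA",
               gene_id = c("GA_y1", "GA_y2"), stringsAsFactors = FALSE),
    data.frame(og_id = "OG00004", genotype = "GA",
               gene_id = c("GA_p1", "GA_p2"), stringsAsFactors = FALSE))
  sa <- spec_a$gene_id[is.na(spec_a$family_id)]
  sb <- spec_b$gene_id[is.na(spec_b$family_id)]
  og <- rbind(og,
              data.frame(og_id = sprintf("OGS%03d", seq_along(sa)),
                         genotype = "GA", gene_id = sa,
                         stringsAsFactors = FALSE),
              data.frame(og_id = sprintf("OGS%03d", seq_along(sb)),
                         genotype = "GB", gene_id = sb,
                         stringsAsFactors = FALSE))
  utils::write.table(og, file.path(out_dir, "orthogroups.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  truth_clusters <- data.frame(
    family_id = c("FAM1", "FAM3", "FAM4"),
    og_id = c("OG00001", "OG00003", "OG00004"),
    n_genotypes = c(2L, 1L, 1L),
    category = c("core", "private", "private"),
    presence = c("GA,GB", "GA", "GA"), stringsAsFactors = FALSE)
  clustered_fams <- c("FAM1", "FAM3", "FAM4")
  truth_genes <- rbind(
    data.frame(gene_id = spec_a$gene_id, genotype = "GA",
               chromosome = spec_a$chromosome, family_id = spec_a$family_id,
               clustered = spec_a$family_id %in% clustered_fams,
               is_te = spec_a$is_te, located = TRUE, stringsAsFactors = FALSE),
    data.frame(gene_id = spec_b$gene_id, genotype = "GB",
               chromosome = spec_b$chromosome, family_id = spec_b$family_id,
               clustered = spec_b$family_id %in% clustered_fams,
               is_te = spec_b$is_te, located = TRUE, stringsAsFactors = FALSE))
  truth_pairs <- data.frame(
    genotype = "GA",
    gene_a = c("GA_c1a", "GA_c1a", "GA_y1", "GA_p1"),
    gene_b = c("GA_c1b", "GA_c1c", "GA_y2", "GA_p2"),
    family_id = c("FAM1", "FAM1", "FAM3", "FAM4"),
    omega = c(0.2, 0.2, 0, 0.2),
    target_ks = c(0.05, 0.08, NA, 0.06),
    prom_diverged = c(FALSE, FALSE, TRUE, TRUE),
    domains_differ = FALSE,
    expr_diverged = c(TRUE, FALSE, FALSE, NA),
    stringsAsFactors = FALSE)

  paths <- lapply(stats::setNames(c("GA", "GB"), c("GA", "GB")), function(g) {
    list(gff3 = file.path(out_dir, paste0(g, ".gff3")),
         cds = file.path(out_dir, paste0(g, ".cds.fa")),
         protein = file.path(out_dir, paste0(g, ".protein.fa")),
         genome = file.path(out_dir, paste0(g, ".genome.fa")),
         annotation = file.path(out_dir, paste0(g, ".annotation.tsv")),
         tpm = file.path(out_dir, paste0(g, ".tpm.tsv")))
  })
  list(config = cfg, dir = out_dir, paths = paths,
       orthogroups = file.path(out_dir, "orthogroups.tsv"),
       truth = list(genes = truth_genes, pairs = truth_pairs,
                    clusters = truth_clusters))
}
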