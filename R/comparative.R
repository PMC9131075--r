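# --- Cross-genotype comparison: categories, position, correlations, fates ---

#' Categorize TDG clusters as core, shared or private across genotypes
#'
#' A cluster's genotype-presence set is the set of genotypes possessing a TDG
#' cluster that shares at least one orthogroup with it (presence is computed
#' per orthogroup and OR-ed over the cluster's orthogroups). Category: present
#' in all genotypes -> core; exactly one -> private; otherwise shared.
#'
#' @param membership_all cluster membership rows across all genotypes
#'   (concatenated [build_clusters()] output)
#' @param orthogroups data.frame with og_id, genotype, gene_id
#' @param genotypes character vector of all genotypes in the analysis
#' @return data.frame: cluster_id, genotype, category, n_genotypes_present,
#'   genotypes_present (comma-joined)
#' @export
categorize_clusters <- function(membership_all, orthogroups, genotypes) {
  og_of <- stats::setNames(orthogroups$og_id, orthogroups$gene_id)
  m <- membership_all
  m$og_id <- og_of[m$gene_id]
  # genotypes possessing a tandem cluster per orthogroup
  og_presence <- unique(m[!is.na(m$og_id), c("og_id", "genotype")])
  presence_sets <- split(og_presence$genotype, og_presence$og_id)

  clusters <- unique(m[, c("cluster_id", "genotype")])
  cl_ogs <- split(m$og_id[!is.na(m$og_id)], m$cluster_id[!is.na(m$og_id)])
  res <- lapply(seq_len(nrow(clusters)), function(i) {
    cid <- clusters$cluster_id[i]
    ogs <- unique(cl_ogs[[cid]])
    if (is.null(ogs) || length(ogs) == 0) {
      warning("cluster ", cid, " has no orthogroup-annotated member")
      return(data.frame(cluster_id = cid, genotype = clusters$genotype[i],
                        category = "unset", n_genotypes_present = NA_integer_,
                        genotypes_present = NA_character_,
                        stringsAsFactors = FALSE))
    }
    present <- sort(unique(unlist(presence_sets[ogs])))
    cat <- if (length(present) == length(genotypes)) "core"
           else if (length(present) == 1) "private" else "shared"
    data.frame(cluster_id = cid, genotype = clusters$genotype[i],
               category = cat, n_genotypes_present = length(present),
               genotypes_present = paste(present, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Per-genotype core/shared/private category summary
#'
#' @param categories data.frame from [categorize_clusters()]
#' @return list with `per_genotype` (counts and percentages per genotype) and
#'   `average` (unweighted cross-genotype means of the percentages)
#' @export
category_summary <- function(categories) {
  cats <- categories[categories$category != "unset", , drop = FALSE]
  per <- do.call(rbind, lapply(split(cats, cats$genotype), function(df) {
    n <- nrow(df)
    data.frame(genotype = df$genotype[1], n_clusters = n,
               n_private = sum(df$category == "private"),
               pct_private = pct(sum(df$category == "private"), n),
               n_core = sum(df$category == "core"),
               pct_core = pct(sum(df$category == "core"), n),
               n_shared = sum(df$category == "shared"),
               pct_shared = pct(sum(df$category == "shared"), n),
               stringsAsFactors = FALSE)
  }))
  rownames(per) <- NULL
  list(per_genotype = per,
       average = c(private = mean_pct(per$pct_private),
                   core = mean_pct(per$pct_core),
                   shared = mean_pct(per$pct_shared)))
}

#' Positional profile of clusters along chromosomes
#'
#' Normalized position is the cluster midpoint divided by the chromosome
#' length; when centromere positions are supplied, the fraction |midpoint -
#' centromere| / chromosome length is used instead. Private clusters are
#' compared with core + shared clusters by a two-sample Mann-Whitney test.
#'
#' @param membership_all cluster membership with genotype, chromosome, gene_id
#' @param genes_all gene tables (concatenated) providing coordinates
#' @param categories data.frame from [categorize_clusters()]
#' @param chrom_lengths named vector of chromosome lengths
#' @param centromeres optional named vector of centromere positions
#' @return list: positions (per cluster), test (htest or NULL), metric
#' @export
positional_profile <- function(membership_all, genes_all, categories,
                               chrom_lengths, centromeres = NULL) {
  coords <- genes_all[match(membership_all$gene_id, genes_all$gene_id), ]
  lo <- tapply(coords$start, membership_all$cluster_id, min)
  hi <- tapply(coords$end, membership_all$cluster_id, max)
  chrom <- tapply(membership_all$chromosome, membership_all$cluster_id,
                  function(x) x[1])
  mid <- (lo + hi) / 2
  len <- chrom_lengths[chrom]
  metric <- "normalized_position"
  if (is.null(centromeres)) {
    val <- mid / len
  } else {
    metric <- "centromere_distance_fraction"
    val <- abs(mid - centromeres[chrom]) / len
  }
  positions <- data.frame(cluster_id = names(mid), chromosome = unname(chrom),
                          midpoint = unname(mid), position = unname(val),
                          stringsAsFactors = FALSE)
  positions$category <- categories$category[
    match(positions$cluster_id, categories$cluster_id)]
  priv <- positions$position[positions$category == "private"]
  rest <- positions$position[positions$category %in% c("core", "shared")]
  test <- if (length(priv) >= 2 && length(rest) >= 2)
    stats::wilcox.test(priv, rest) else NULL
  list(positions = positions, test = test, metric = metric)
}

#' Correlations among expression, promoter and coding divergence
#'
#' Pearson correlations (pairwise complete, two-sided tests) across TDG pairs
#' between: expression r and promoter similarity; promoter similarity and Ks;
#' expression r and Ks; expression r and Ka/Ks.
#'
#' @param pair_table master per-pair table with columns r (expression), ps,
#'   ks, omega
#' @return data.frame: comparison, r, p, n
#' @export
divergence_correlations <- function(pair_table) {
  specs <- list(
    c("expression_r_vs_ps", "r", "ps"),
    c("ps_vs_ks", "ps", "ks"),
    c("expression_r_vs_ks", "r", "ks"),
    c("expression_r_vs_omega", "r", "omega")
  )
  rows <- lapply(specs, function(sp) {
    x <- pair_table[[sp[2]]]; y <- pair_table[[sp[3]]]
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < 3) {
      return(data.frame(comparison = sp[1], r = NA_real_, p = NA_real_,
                        n = sum(ok), stringsAsFactors = FALSE))
    }
    ct <- stats::cor.test(x[ok], y[ok], method = "pearson")
    data.frame(comparison = sp[1], r = unname(ct$estimate), p = ct$p.value,
               n = sum(ok), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Duplicate-retention fate calls for TDG pairs
#'
#' Decision rules, in order, for pairs with an expression call, a retained
#' Ka/Ks estimate and Pfam sets for both copies:
#' 1. domain sets differ and omega > 1 -> neo_functionalization;
#' 2. expression diverged, omega < 1, identical domains -> sub_functionalization;
#' 3. expression conserved, omega < 1, identical domains -> genetic_redundancy;
#' 4. otherwise unclassified.
#' "Identical domains" is set equality of Pfam ids, ignoring copy number.
#'
#' @param pair_table master per-pair table with both_expressed, expr_diverged,
#'   omega, excluded, domains_identical columns
#' @return `pair_table` with `fate` and `fate_reason` columns
#' @export
call_fates <- function(pair_table) {
  n <- nrow(pair_table)
  fate <- rep("unclassified", n)
  reason <- rep(NA_character_, n)
  eligible <- pair_table$both_expressed %in% TRUE &
    !(pair_table$excluded %in% TRUE) &
    !is.na(pair_table$omega) &
    !is.na(pair_table$expr_diverged) &
    !is.na(pair_table$domains_identical)
  reason[!eligible] <- "missing_input"
  for (i in which(eligible)) {
    om <- pair_table$omega[i]
    div <- pair_table$expr_diverged[i]
    same_dom <- pair_table$domains_identical[i]
    fate[i] <- if (!same_dom && om > 1) "neo_functionalization"
      else if (div && om < 1 && same_dom) "sub_functionalization"
      else if (!div && om < 1 && same_dom) "genetic_redundancy"
      else "unclassified"
    if (fate[i] == "unclassified") reason[i] <- "no_rule_matched"
  }
  pair_table$fate <- fate
  pair_table$fate_reason <- reason
  pair_table
}

#' Fate proportions per genotype and cross-genotype averages
#'
#' Percentages are over eligible pairs (expressed, retained Ka/Ks, annotated);
#' the cross-genotype average is the unweighted mean of per-genotype
#' percentages.
#'
#' @param fates data.frame from [call_fates()] with a `genotype` column
#' @return list: per_genotype data.frame and `average` named vector
#' @export
summarize_fates <- function(fates) {
  eligible <- fates[is.na(fates$fate_reason) |
                      fates$fate_reason != "missing_input", , drop = FALSE]
  per <- do.call(rbind, lapply(split(eligible, eligible$genotype),
                               function(df) {
    n <- nrow(df)
    data.frame(genotype = df$genotype[1], n_eligible = n,
               pct_sub = pct(sum(df$fate == "sub_functionalization"), n),
               pct_redundancy = pct(sum(df$fate == "genetic_redundancy"), n),
               pct_neo = pct(sum(df$fate == "neo_functionalization"), n),
               pct_unclassified = pct(sum(df$fate == "unclassified"), n),
               stringsAsFactors = FALSE)
  }))
  rownames(per) <- NULL
  list(per_genotype = per,
       average = c(sub_functionalization = mean_pct(per$pct_sub),
                   genetic_redundancy = mean_pct(per$pct_redundancy),
                   neo_functionalization = mean_pct(per$pct_neo),
                   unclassified = mean_pct(per$pct_unclassified)))
}
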