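# --- TDG pairs, clusters, and genomic density ------------------------------

#' Tandem duplicate pairs from homology hits
#'
#' A homologous same-chromosome pair is a TDG pair when the two genes are
#' separated by at most `max_intervening` retained genes (counted over the
#' gene universe supplied in `genes`, i.e. the filtered non-TE located set by
#' default).
#'
#' @param hits data.frame from [same_chromosome_pairs()]
#' @param genes the gene universe used for rank/intervening counting
#' @param max_intervening maximum number of intervening genes (default 10)
#' @return data.frame: gene_a, gene_b, chromosome, n_intervening plus the hit
#'   statistics
#' @export
build_pairs <- function(hits, genes, max_intervening = 10) {
  if (nrow(hits) == 0) {
    hits$n_intervening <- integer(0)
    return(hits)
  }
  rank <- stats::setNames(genes$rank, genes$gene_id)
  ra <- rank[hits$gene_a]
  rb <- rank[hits$gene_b]
  swap <- !is.na(ra) & !is.na(rb) & ra > rb
  tmp <- hits$gene_a[swap]; hits$gene_a[swap] <- hits$gene_b[swap]
  hits$gene_b[swap] <- tmp
  lo <- pmin(ra, rb); hi <- pmax(ra, rb)
  hits$n_intervening <- as.integer(hi - lo - 1)
  out <- hits[!is.na(hits$n_intervening) &
                hits$n_intervening <= max_intervening, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Group TDG pairs into clusters
#'
#' Clusters are the connected components of the pair graph per chromosome
#' (single linkage). Cluster ids are deterministic: ordered by chromosome and
#' leftmost member rank.
#'
#' @param pairs data.frame from [build_pairs()]
#' @param genes gene universe (provides genotype, rank, coordinates)
#' @return data.frame membership: cluster_id, genotype, chromosome, gene_id,
#'   with one row per member gene
#' @export
build_clusters <- function(pairs, genes) {
  empty <- data.frame(cluster_id = character(0), genotype = character(0),
                      chromosome = character(0), gene_id = character(0),
                      stringsAsFactors = FALSE)
  if (nrow(pairs) == 0) return(empty)
  genotype <- unique(genes$genotype)
  stopifnot(length(genotype) == 1)
  g <- igraph::graph_from_data_frame(pairs[, c("gene_a", "gene_b")],
                                     directed = FALSE)
  comp <- igraph::components(g)
  member <- data.frame(gene_id = names(comp$membership),
                       comp = unname(comp$membership),
                       stringsAsFactors = FALSE)
  info <- genes[match(member$gene_id, genes$gene_id), ]
  member$chromosome <- info$chromosome
  member$rank <- info$rank
  # order components by chromosome, then leftmost member rank
  left <- stats::aggregate(rank ~ comp, data = member, FUN = min)
  left$chromosome <- member$chromosome[match(left$comp, member$comp)]
  left <- left[order(left$chromosome, left$rank), ]
  ids <- stats::setNames(
    sprintf("%s_%s_TDC%04d", genotype, left$chromosome, seq_len(nrow(left))),
    left$comp)
  out <- data.frame(cluster_id = unname(ids[as.character(member$comp)]),
                    genotype = genotype,
                    chromosome = member$chromosome,
                    gene_id = member$gene_id,
                    stringsAsFactors = FALSE)
  out <- out[order(out$cluster_id,
                   genes$rank[match(out$gene_id, genes$gene_id)]), ]
  rownames(out) <- NULL
  out
}

#' Summary statistics of a genotype's TDG clusters
#'
#' @param membership data.frame from [build_clusters()]
#' @param pairs data.frame from [build_pairs()]
#' @param genes the filtered gene universe of the genotype
#' @return list: counts, size distribution, intervening histogram
#' @export
cluster_summary <- function(membership, pairs, genes) {
  sizes <- if (nrow(membership)) table(membership$cluster_id) else table(integer(0))
  n_clusters <- length(sizes)
  genes_in <- nrow(membership)
  list(
    n_clusters = n_clusters,
    genes_in_clusters = genes_in,
    n_genes = nrow(genes),
    pct_genes_in_clusters = pct(genes_in, nrow(genes)),
    pct_clusters_size2 = pct(sum(sizes == 2), n_clusters),
    largest_cluster = if (n_clusters) max(sizes) else 0L,
    size_distribution = if (n_clusters) table(as.integer(sizes)) else table(integer(0)),
    intervening_histogram = if (nrow(pairs))
      table(factor(pairs$n_intervening, levels = 0:10)) else
      table(factor(integer(0), levels = 0:10))
  )
}

#' Per-window covered-base density of a feature set
#'
#' Tiling windows of `window` bp (the last window is truncated at the
#' chromosome end); density is the proportion of window bases covered by the
#' union of the feature intervals.
#'
#' @param features data.frame with chromosome, start, end (1-based inclusive)
#' @param chrom_lengths named vector of chromosome lengths
#' @param window window size in bp (default 1 Mb)
#' @return data.frame: chromosome, win_start, win_end, density
#' @export
windowed_density <- function(features, chrom_lengths, window = 1e6) {
  out <- list()
  for (chrom in names(chrom_lengths)) {
    len <- chrom_lengths[[chrom]]
    starts <- seq(1, len, by = window)
    ends <- pmin(starts + window - 1, len)
    f <- features[features$chromosome == chrom, , drop = FALSE]
    if (nrow(f) && any(f$end > len | f$start < 1))
      stop("feature outside chromosome ", chrom)
    cov <- numeric(length(starts))
    if (nrow(f)) {
      red <- IRanges::reduce(IRanges::IRanges(f$start, f$end))
      win <- IRanges::IRanges(starts, ends)
      ov <- IRanges::findOverlaps(win, red)
      if (length(ov)) {
        inter <- IRanges::pintersect(win[S4Vectors::queryHits(ov)],
                                     red[S4Vectors::subjectHits(ov)])
        w <- tapply(IRanges::width(inter), S4Vectors::queryHits(ov), sum)
        cov[as.integer(names(w))] <- w
      }
    }
    out[[chrom]] <- data.frame(chromosome = chrom, win_start = starts,
                               win_end = ends,
                               density = cov / (ends - starts + 1),
                               stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Linear model of TDG density on covariate densities, with uniformity test
#'
#' Ordinary least squares of TDG density on the covariate tracks; residuals are
#' min-max scaled to [0,1] and tested against Uniform(0,1) with a one-sample
#' Kolmogorov-Smirnov test. Pearson correlations of TDG density with each
#' covariate are also reported. Zero-variance residuals (a degenerate fit) are
#' flagged and reported with D = 1.
#'
#' @param tdg_track density track of TDGs from [windowed_density()]
#' @param covariate_tracks named list of covariate tracks on the same windows
#' @return list: coefficients, residuals, ks_D, ks_p, pearson_r, degenerate
#' @export
density_model <- function(tdg_track, covariate_tracks) {
  df <- data.frame(tdg = tdg_track$density)
  for (nm in names(covariate_tracks)) {
    cov <- covariate_tracks[[nm]]
    if (nrow(cov) != nrow(tdg_track)) stop("tracks must share windows")
    df[[nm]] <- cov$density
  }
  if (nrow(df) < ncol(df)) stop("fewer windows than covariates + 1")
  fit <- stats::lm(tdg ~ ., data = df)
  res <- stats::residuals(fit)
  pearson <- vapply(names(covariate_tracks), function(nm) {
    if (stats::sd(df[[nm]]) == 0 || stats::sd(df$tdg) == 0) return(NA_real_)
    stats::cor(df$tdg, df[[nm]])
  }, numeric(1))
  if (diff(range(res)) < .Machine$double.eps^0.5) {
    return(list(coefficients = stats::coef(fit), residuals = res,
                ks_D = 1, ks_p = NA_real_, pearson_r = pearson,
                degenerate = TRUE))
  }
  scaled <- (res - min(res)) / (max(res) - min(res))
  ks <- suppressWarnings(stats::ks.test(scaled, "punif"))
  list(coefficients = stats::coef(fit), residuals = res,
       ks_D = unname(ks$statistic), ks_p = ks$p.value,
       pearson_r = pearson, degenerate = FALSE)
}
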