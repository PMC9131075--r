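# --- Term over-representation among TDGs ------------------------------------

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment with monotonicity enforcement.
#'
#' @param p vector of p-values in [0, 1]
#' @return adjusted p-values
#' @export
bh_adjust <- function(p) {
  stats::p.adjust(p, method = "BH")
}

#' Fisher exact over-representation of terms among TDG genes
#'
#' For each term, a 2x2 table of term/non-term by TDG/non-TDG genes over the
#' background is tested with a Fisher exact test; p-values are BH-adjusted
#' over all tested terms. Significance additionally requires at least
#' `min_count` TDGs carrying the term.
#'
#' @param term_map data.frame with columns `gene_id` and `term`
#' @param tdg_genes TDG gene ids (must be a subset of the background)
#' @param background_genes the background gene universe (convention: all
#'   located non-TE genes of the genotype)
#' @param fdr FDR threshold (default 0.05)
#' @param min_count minimum TDGs with the term (default 10)
#' @param alternative Fisher sidedness (default "two.sided")
#' @return data.frame: term, a, b, c, d, odds_ratio, p, fdr, n_tdg_with_term,
#'   significant
#' @export
fisher_enrichment <- function(term_map, tdg_genes, background_genes,
                              fdr = 0.05, min_count = 10,
                              alternative = "two.sided") {
  if (length(background_genes) == 0) stop("empty background")
  if (!all(tdg_genes %in% background_genes))
    stop("tdg_genes must be a subset of background_genes")
  tdg_genes <- unique(tdg_genes)
  background_genes <- unique(background_genes)
  term_map <- term_map[term_map$gene_id %in% background_genes, , drop = FALSE]
  n_bg <- length(background_genes)
  n_tdg <- length(tdg_genes)
  terms <- unique(term_map$term)
  if (length(terms) == 0) {
    return(data.frame(term = character(0), a = integer(0), b = integer(0),
                      c = integer(0), d = integer(0), odds_ratio = numeric(0),
                      p = numeric(0), fdr = numeric(0),
                      n_tdg_with_term = integer(0),
                      significant = logical(0), stringsAsFactors = FALSE))
  }
  by_term <- split(term_map$gene_id, term_map$term)
  rows <- lapply(terms, function(tm) {
    g <- unique(by_term[[tm]])
    a <- sum(g %in% tdg_genes)          # term & TDG
    b <- length(g) - a                  # term & non-TDG
    cc <- n_tdg - a                     # non-term & TDG
    d <- (n_bg - n_tdg) - b             # non-term & non-TDG
    ft <- stats::fisher.test(matrix(c(a, b, cc, d), 2, byrow = TRUE),
                             alternative = alternative)
    # odds ratio undefined when a row of the table is empty (e.g. a term
    # present in every gene)
    or <- if ((cc == 0 && d == 0) || (a == 0 && b == 0)) NA_real_
      else unname(ft$estimate)
    data.frame(term = tm, a = a, b = b, c = cc, d = d,
               odds_ratio = or, p = ft$p.value, n_tdg_with_term = a,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- bh_adjust(out$p)
  out$significant <- out$fdr < fdr & out$n_tdg_with_term >= min_count
  out <- out[order(out$fdr, out$p, out$term),
             c("term", "a", "b", "c", "d", "odds_ratio", "p", "fdr",
               "n_tdg_with_term", "significant")]
  rownames(out) <- NULL
  out
}

#' Differential enrichment of terms across genotypes
#'
#' For every term significantly enriched in at least one genotype, the
#' fold-enrichment (fraction of TDGs with the term over the background
#' fraction) is computed per genotype and row z-scored across genotypes
#' (population SD). A term absent in a genotype contributes fold 0.
#'
#' @param per_genotype_results named list of [fisher_enrichment()] tables
#' @return matrix of z-scores, terms x genotypes
#' @export
differential_enrichment <- function(per_genotype_results) {
  if (length(per_genotype_results) < 2) stop("need results for >= 2 genotypes")
  keep <- unique(unlist(lapply(per_genotype_results,
                               function(df) df$term[df$significant])))
  if (length(keep) == 0) {
    return(matrix(numeric(0), nrow = 0, ncol = length(per_genotype_results),
                  dimnames = list(NULL, names(per_genotype_results))))
  }
  fold <- sapply(per_genotype_results, function(df) {
    i <- match(keep, df$term)
    f <- numeric(length(keep))
    has <- !is.na(i)
    a <- df$a[i[has]]; b <- df$b[i[has]]
    cc <- df$c[i[has]]; d <- df$d[i[has]]
    f[has] <- (a / (a + cc)) / ((a + b) / (a + b + cc + d))
    f
  })
  fold <- matrix(fold, nrow = length(keep),
                 dimnames = list(keep, names(per_genotype_results)))
  t(apply(fold, 1, function(x) {
    s <- sqrt(mean((x - mean(x))^2))
    if (s == 0) rep(0, length(x)) else (x - mean(x)) / s
  }))
}
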