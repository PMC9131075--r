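# --- Expression summaries and expression-divergence calls ------------------

#' Tau expression-specificity index
#'
#' tau = sum(1 - x_i / max(x)) / (n - 1), on linear TPM. 0 for a gene expressed
#' equally in all samples; 1 for a gene expressed in a single sample only.
#' Undefined (NA) when the profile is all zero.
#'
#' @param x numeric vector of TPM values over samples (n >= 2)
#' @return tau in [0, 1], or NA for an all-zero profile
#' @export
tau_specificity <- function(x) {
  stopifnot(length(x) >= 2, all(x >= 0))
  mx <- max(x)
  if (mx == 0) return(NA_real_)
  sum(1 - x / mx) / (length(x) - 1)
}

#' Per-gene expression summaries from a TPM matrix
#'
#' A gene is expressed when TPM > `cutoff` (strict) in at least one sample.
#' Breadth is the number (and percentage) of samples above the cutoff; level
#' is the mean linear TPM; tau is computed for expressed genes only.
#'
#' @param tpm numeric matrix, genes x samples, with gene ids as rownames
#' @param cutoff expression cutoff on TPM (default 0.5)
#' @return data.frame: gene_id, expressed, breadth, breadth_pct, level, tau
#' @export
summarize_expression <- function(tpm, cutoff = 0.5) {
  stopifnot(is.matrix(tpm), ncol(tpm) >= 2)
  above <- tpm > cutoff
  expressed <- rowSums(above) > 0
  breadth <- rowSums(above)
  tau <- rep(NA_real_, nrow(tpm))
  tau[expressed] <- apply(tpm[expressed, , drop = FALSE], 1, tau_specificity)
  data.frame(gene_id = rownames(tpm),
             expressed = expressed,
             breadth = as.integer(breadth),
             breadth_pct = pct(breadth, ncol(tpm)),
             level = rowMeans(tpm),
             tau = tau,
             row.names = NULL, stringsAsFactors = FALSE)
}

# Pearson r between the log10(TPM+1) profiles of two genes; NA when either
# profile has zero variance.
expression_r <- function(tpm, a, b, log10p1 = TRUE) {
  xa <- tpm[a, ]; xb <- tpm[b, ]
  if (log10p1) { xa <- log10(xa + 1); xb <- log10(xb + 1) }
  if (stats::sd(xa) == 0 || stats::sd(xb) == 0) return(NA_real_)
  stats::cor(xa, xb)
}

#' Null distribution of expression correlation over random non-TDG pairs
#'
#' Seeded sampling (without replacement over pairs) of gene pairs where neither
#' gene is tandemly duplicated and both are expressed; returns the sorted r
#' values and their 95% quantile (linear interpolation). Pairs with an
#' undefined correlation (constant profile) are dropped.
#'
#' @param tpm TPM matrix (genes x samples)
#' @param tdg_genes character vector of TDG gene ids to exclude
#' @param n_pairs number of random pairs (convention: the number of expressed
#'   TDG pairs)
#' @param seed RNG seed
#' @param cutoff expression cutoff
#' @param log10p1 correlate log10(TPM+1) profiles (default) or linear TPM
#' @return list: r (sorted), q95, n_pairs
#' @export
random_pair_null <- function(tpm, tdg_genes, n_pairs, seed = 1,
                             cutoff = 0.5, log10p1 = TRUE) {
  expressed <- rownames(tpm)[rowSums(tpm > cutoff) > 0]
  eligible <- setdiff(expressed, tdg_genes)
  n <- length(eligible)
  if (n < 3 || n_pairs < 1) stop("too few eligible genes for the null")
  max_pairs <- n * (n - 1) / 2
  if (n_pairs > max_pairs) stop("n_pairs exceeds available non-TDG pairs")
  withr_seed <- function(code) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    code
  }
  pairs <- withr_seed({
    seen <- character(0)
    out <- matrix(character(0), ncol = 2)
    while (nrow(out) < n_pairs) {
      need <- n_pairs - nrow(out)
      i <- sample.int(n, need * 2, replace = TRUE)
      j <- sample.int(n, need * 2, replace = TRUE)
      ok <- i != j
      lo <- pmin(i[ok], j[ok]); hi <- pmax(i[ok], j[ok])
      key <- paste(lo, hi)
      new <- !duplicated(key) & !(key %in% seen)
      seen <- c(seen, key[new])
      out <- rbind(out, cbind(eligible[lo[new]], eligible[hi[new]]))
    }
    out[seq_len(n_pairs), , drop = FALSE]
  })
  r <- vapply(seq_len(nrow(pairs)),
              function(k) expression_r(tpm, pairs[k, 1], pairs[k, 2], log10p1),
              numeric(1))
  r <- sort(r[!is.na(r)])
  list(r = r, q95 = unname(stats::quantile(r, 0.95, type = 7)),
       n_pairs = length(r))
}

#' Expression-divergence calls for TDG pairs
#'
#' A pair is eligible when both copies are expressed; it has diverged
#' expression when its Pearson r falls below the random-pair 95% quantile.
#' Pairs with a constant profile on either side carry r = NA and no call.
#'
#' @param pairs data.frame with gene_a, gene_b
#' @param tpm TPM matrix
#' @param q95 null 95% quantile from [random_pair_null()]
#' @param cutoff expression cutoff
#' @param log10p1 correlate log10(TPM+1) profiles
#' @return `pairs` with both_expressed, r, q95_null, expr_diverged columns
#' @export
call_expression_divergence <- function(pairs, tpm, q95, cutoff = 0.5,
                                       log10p1 = TRUE) {
  expressed <- rowSums(tpm > cutoff) > 0
  both <- expressed[pairs$gene_a] & expressed[pairs$gene_b]
  both[is.na(both)] <- FALSE
  r <- rep(NA_real_, nrow(pairs))
  for (k in which(both)) {
    r[k] <- expression_r(tpm, pairs$gene_a[k], pairs$gene_b[k], log10p1)
  }
  pairs$both_expressed <- as.logical(both)
  pairs$r <- r
  pairs$q95_null <- q95
  pairs$expr_diverged <- ifelse(both & !is.na(r), r < q95, NA)
  pairs
}
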