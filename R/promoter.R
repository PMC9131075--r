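# --- Promoter extraction and promoter-similarity calls ----------------------

#' Extract putative promoters (1 kb upstream of the TSS)
#'
#' For + strand genes the promoter is the `upstream` bp immediately before the
#' gene start; for - strand genes, the reverse complement of the `upstream` bp
#' after the gene end. The window is truncated at the chromosome boundary and
#' at the nearest neighbouring gene boundary on either strand ("non-overlapping"
#' promoters). Promoters containing N, and genes left with a zero-length
#' window, are excluded with a reason.
#'
#' @param genes gene table with gene_id, chromosome, start, end, strand, located
#' @param genome `Biostrings::DNAStringSet` named by chromosome
#' @param upstream window size in bp (default 1000)
#' @return data.frame: gene_id, promoter (NA when excluded), length, reason
#' @export
extract_promoters <- function(genes, genome, upstream = 1000) {
  out <- data.frame(gene_id = genes$gene_id, promoter = NA_character_,
                    length = 0L, reason = NA_character_,
                    stringsAsFactors = FALSE)
  for (chrom in unique(genes$chromosome)) {
    sel <- which(genes$chromosome == chrom)
    if (!chrom %in% names(genome)) {
      out$reason[sel] <- "no_chromosome_sequence"
      next
    }
    chrom_seq <- genome[[chrom]]
    clen <- length(chrom_seq)
    starts <- genes$start[sel]
    ends <- genes$end[sel]
    for (ii in seq_along(sel)) {
      i <- sel[ii]
      if (!is.na(genes$located[i]) && !genes$located[i]) {
        out$reason[i] <- "unplaced"
        next
      }
      if (genes$strand[i] == "+") {
        lo <- max(1, starts[ii] - upstream)
        others <- ends[-ii][ends[-ii] < starts[ii]]
        if (length(others)) lo <- max(lo, max(others) + 1)
        hi <- starts[ii] - 1
      } else {
        hi <- min(clen, ends[ii] + upstream)
        others <- starts[-ii][starts[-ii] > ends[ii]]
        if (length(others)) hi <- min(hi, min(others) - 1)
        lo <- ends[ii] + 1
      }
      if (hi < lo) {
        out$reason[i] <- "zero_length"
        next
      }
      s <- as.character(Biostrings::subseq(chrom_seq, lo, hi))
      if (genes$strand[i] == "-") s <- revcomp(s)
      if (grepl("N", s, fixed = TRUE)) {
        out$reason[i] <- "contains_N"
        next
      }
      out$promoter[i] <- s
      out$length[i] <- nchar(s)
    }
  }
  out
}

#' Scoring scheme for promoter local alignment
#'
#' EMBOSS matcher-like DNA scoring: match +5, mismatch -4, gap open 16,
#' gap extend 4.
#'
#' @param match,mismatch,gap_open,gap_extend alignment parameters
#' @return list of scoring parameters
#' @export
matcher_scoring <- function(match = 5, mismatch = -4,
                            gap_open = 16, gap_extend = 4) {
  list(match = match, mismatch = mismatch,
       gap_open = gap_open, gap_extend = gap_extend)
}

#' Promoter similarity of two sequences
#'
#' Best local (Waterman-Eggert-style, single best) alignment; similarity is
#' the number of identical aligned positions divided by the mean of the two
#' promoter lengths, giving Ps in [0, 1] with Ps(x, x) = 1.
#'
#' @param prom_a,prom_b promoter DNA strings (non-empty)
#' @param scoring see [matcher_scoring()]
#' @return Ps in [0, 1]
#' @export
promoter_similarity <- function(prom_a, prom_b, scoring = matcher_scoring()) {
  if (!nzchar(prom_a) || !nzchar(prom_b)) stop("empty promoter")
  letters <- c(DNA_ALPHABET, "N")
  m <- matrix(scoring$mismatch, 5, 5, dimnames = list(letters, letters))
  diag(m) <- scoring$match
  m["N", "N"] <- scoring$mismatch
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(prom_a), Biostrings::DNAString(prom_b),
    substitutionMatrix = m, gapOpening = scoring$gap_open,
    gapExtension = scoring$gap_extend, type = "local"
  )
  Biostrings::nmatch(aln) / mean(c(nchar(prom_a), nchar(prom_b)))
}

#' Null distribution of promoter similarity over random non-TDG pairs
#'
#' @param promoters data.frame from [extract_promoters()]
#' @param tdg_genes TDG gene ids to exclude
#' @param n_pairs number of random pairs
#' @param seed RNG seed
#' @param scoring see [matcher_scoring()]
#' @return list: ps (sorted), q95, n_pairs
#' @export
promoter_null <- function(promoters, tdg_genes, n_pairs, seed = 1,
                          scoring = matcher_scoring()) {
  ok <- promoters[!is.na(promoters$promoter) &
                    !(promoters$gene_id %in% tdg_genes), , drop = FALSE]
  n <- nrow(ok)
  if (n < 3 || n_pairs < 1) stop("too few eligible promoters for the null")
  if (n_pairs > n * (n - 1) / 2) stop("n_pairs exceeds available pairs")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  seen <- character(0)
  idx <- matrix(integer(0), ncol = 2)
  while (nrow(idx) < n_pairs) {
    need <- n_pairs - nrow(idx)
    i <- sample.int(n, need * 2, replace = TRUE)
    j <- sample.int(n, need * 2, replace = TRUE)
    sel <- i != j
    lo <- pmin(i[sel], j[sel]); hi <- pmax(i[sel], j[sel])
    key <- paste(lo, hi)
    new <- !duplicated(key) & !(key %in% seen)
    seen <- c(seen, key[new])
    idx <- rbind(idx, cbind(lo[new], hi[new]))
  }
  idx <- idx[seq_len(n_pairs), , drop = FALSE]
  ps <- vapply(seq_len(nrow(idx)), function(k) {
    promoter_similarity(ok$promoter[idx[k, 1]], ok$promoter[idx[k, 2]], scoring)
  }, numeric(1))
  ps <- sort(ps)
  list(ps = ps, q95 = unname(stats::quantile(ps, 0.95, type = 7)),
       n_pairs = length(ps))
}

#' Promoter-divergence calls for TDG pairs
#'
#' A pair's promoters have diverged when Ps falls below the random-pair 95%
#' quantile. Pairs where either promoter was excluded carry no call.
#'
#' @param pairs data.frame with gene_a, gene_b
#' @param promoters data.frame from [extract_promoters()]
#' @param q95 null 95% quantile from [promoter_null()]
#' @param scoring see [matcher_scoring()]
#' @return `pairs` with ps, ps_q95_null, prom_diverged, promoter_len_a/b
#' @export
call_promoter_divergence <- function(pairs, promoters, q95,
                                     scoring = matcher_scoring()) {
  prom <- stats::setNames(promoters$promoter, promoters$gene_id)
  len <- stats::setNames(promoters$length, promoters$gene_id)
  ps <- rep(NA_real_, nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    a <- prom[pairs$gene_a[k]]; b <- prom[pairs$gene_b[k]]
    if (!is.na(a) && !is.na(b)) ps[k] <- promoter_similarity(a, b, scoring)
  }
  pairs$ps <- ps
  pairs$ps_q95_null <- q95
  pairs$prom_diverged <- ifelse(is.na(ps), NA, ps < q95)
  pairs$promoter_len_a <- unname(len[pairs$gene_a])
  pairs$promoter_len_b <- unname(len[pairs$gene_b])
  pairs
}
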