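# --- Pairwise CDS homology with BLAST-style statistics ----------------------

#' Scoring scheme for CDS-vs-CDS local alignment
#'
#' BLASTN-like defaults: match +2, mismatch -3, affine gaps (open 5, extend 2),
#' with Karlin-Altschul parameters lambda and K for the bit-score/e-value
#' conversion. N matches nothing (scored as a mismatch).
#'
#' @param match,mismatch substitution scores
#' @param gap_open,gap_extend positive gap penalties; a gap of length L costs
#'   `gap_open + L * gap_extend`
#' @param lambda,K Karlin-Altschul parameters
#' @return list of scoring parameters
#' @export
homology_scoring <- function(match = 2, mismatch = -3,
                             gap_open = 5, gap_extend = 2,
                             lambda = 0.625, K = 0.41) {
  list(match = match, mismatch = mismatch,
       gap_open = gap_open, gap_extend = gap_extend,
       lambda = lambda, K = K)
}

#' Thresholds for accepting a homologous gene pair
#'
#' Defaults are the cluster-calling thresholds: e-value <= 1e-10, bit score
#' ratio >= 30%, and coverage of both sequences >= 50%.
#'
#' @param evalue_max,bsr_min,coverage_min thresholds
#' @return list of thresholds
#' @export
homology_thresholds <- function(evalue_max = 1e-10, bsr_min = 0.30,
                                coverage_min = 0.50) {
  list(evalue_max = evalue_max, bsr_min = bsr_min, coverage_min = coverage_min)
}

.dna_submat <- function(scoring) {
  letters <- c(DNA_ALPHABET, "N")
  m <- matrix(scoring$mismatch, 5, 5, dimnames = list(letters, letters))
  diag(m) <- scoring$match
  m["N", "N"] <- scoring$mismatch  # N never matches
  m
}

raw_to_bits <- function(score, scoring) {
  (scoring$lambda * score - log(scoring$K)) / log(2)
}

#' Best local alignment of two coding sequences
#'
#' Smith-Waterman local DNA alignment with a Karlin-Altschul conversion of the
#' raw score to bits and an e-value over the search space of the two sequence
#' lengths: bits = (lambda*S - ln K)/ln 2, e-value = m*n*2^(-bits).
#'
#' @param cds_a,cds_b DNA strings over ACGTN (other symbols are an error)
#' @param scoring see [homology_scoring()]
#' @return list: score, bit_score, evalue, coverage_a, coverage_b, nmatch
#' @export
align_cds <- function(cds_a, cds_b, scoring = homology_scoring()) {
  if (!nzchar(cds_a) || !nzchar(cds_b)) stop("empty sequence")
  if (grepl("[^ACGTN]", cds_a) || grepl("[^ACGTN]", cds_b))
    stop("sequences must contain only A, C, G, T or N")
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(cds_a), Biostrings::DNAString(cds_b),
    substitutionMatrix = .dna_submat(scoring),
    gapOpening = scoring$gap_open, gapExtension = scoring$gap_extend,
    type = "local"
  )
  score <- Biostrings::score(aln)
  bits <- raw_to_bits(score, scoring)
  m <- nchar(cds_a); n <- nchar(cds_b)
  pat <- aln@pattern@range
  sub <- aln@subject@range
  list(score = score,
       bit_score = bits,
       evalue = m * n * 2^(-bits),
       coverage_a = IRanges::width(pat) / m,
       coverage_b = IRanges::width(sub) / n,
       nmatch = Biostrings::nmatch(aln))
}

#' Self-alignment bit score of a sequence
#'
#' The best local self-alignment of an ungapped identical sequence scores
#' `match * length`; computed analytically.
#'
#' @param cds DNA string
#' @param scoring see [homology_scoring()]
#' @return bit score of the sequence aligned with itself
#' @export
self_bit_score <- function(cds, scoring = homology_scoring()) {
  raw_to_bits(scoring$match * nchar(cds), scoring)
}

# Candidate same-chromosome pairs sharing at least `min_shared` k-mers.
# Avoids the O(n^2) alignment pass; pairs of genuinely homologous CDS at the
# divergence levels that survive the e-value threshold share many k-mers.
kmer_candidate_pairs <- function(seqs, k = 11, min_shared = 2,
                                 max_genes_per_kmer = 100) {
  n <- length(seqs)
  if (n < 2) return(matrix(integer(0), ncol = 2))
  kmers <- lapply(seqs, function(s) {
    L <- nchar(s)
    if (L < k) return(character(0))
    unique(substring(s, 1:(L - k + 1), k:L))
  })
  idx <- rep(seq_len(n), lengths(kmers))
  km <- unlist(kmers, use.names = FALSE)
  groups <- split(idx, km)
  groups <- groups[lengths(groups) >= 2 & lengths(groups) <= max_genes_per_kmer]
  if (length(groups) == 0) return(matrix(integer(0), ncol = 2))
  pair_codes <- unlist(lapply(groups, function(g) {
    g <- sort.int(g)
    cmb <- utils::combn(g, 2)
    cmb[1, ] * (n + 1) + cmb[2, ]
  }), use.names = FALSE)
  tab <- table(pair_codes)
  keep <- as.integer(names(tab)[tab >= min_shared])
  cbind(keep %/% (n + 1), keep %% (n + 1))
}

#' Homologous gene pairs on the same chromosome
#'
#' Evaluates same-chromosome gene pairs by local CDS alignment and keeps hits
#' passing all three thresholds (e-value, bit-score ratio, coverage of both
#' sequences). The bit-score ratio is the pair bit score divided by the smaller
#' of the two self-alignment bit scores, so identical sequences score exactly 1.
#'
#' @param genes gene table (rows from [load_genotype()], typically after
#'   [non_te_located_genes()]); must carry `gene_id`, `chromosome`, `rank`, `cds`
#' @param thresholds see [homology_thresholds()]
#' @param scoring see [homology_scoring()]
#' @param prefilter use the shared-k-mer prefilter instead of all-vs-all
#' @param k,min_shared_kmers prefilter parameters; candidates must share at
#'   least `min_shared_kmers` k-mers (random ~900 nt CDS pairs share ~0.2 on
#'   average, genuinely duplicated pairs at the accepted divergence dozens)
#' @return data.frame of hits: gene_a, gene_b (gene_a has the smaller rank),
#'   chromosome, score, bit_score, bit_score_ratio, evalue, coverage_a,
#'   coverage_b
#' @export
same_chromosome_pairs <- function(genes,
                                  thresholds = homology_thresholds(),
                                  scoring = homology_scoring(),
                                  prefilter = TRUE, k = 11,
                                  min_shared_kmers = 4) {
  empty <- data.frame(gene_a = character(0), gene_b = character(0),
                      chromosome = character(0), score = numeric(0),
                      bit_score = numeric(0), bit_score_ratio = numeric(0),
                      evalue = numeric(0), coverage_a = numeric(0),
                      coverage_b = numeric(0), stringsAsFactors = FALSE)
  if (nrow(genes) < 2) return(empty)
  res <- list()
  for (chrom in unique(genes$chromosome)) {
    g <- genes[genes$chromosome == chrom, , drop = FALSE]
    g <- g[order(g$rank), , drop = FALSE]
    if (nrow(g) < 2) next
    if (prefilter) {
      cand <- kmer_candidate_pairs(g$cds, k = k, min_shared = min_shared_kmers)
    } else {
      cand <- t(utils::combn(nrow(g), 2))
    }
    if (nrow(cand) == 0) next
    self_bits <- vapply(g$cds, self_bit_score, numeric(1), scoring = scoring,
                        USE.NAMES = FALSE)
    for (r in seq_len(nrow(cand))) {
      i <- cand[r, 1]; j <- cand[r, 2]
      hit <- align_cds(g$cds[i], g$cds[j], scoring)
      bsr <- hit$bit_score / min(self_bits[i], self_bits[j])
      if (hit$evalue <= thresholds$evalue_max &&
          bsr >= thresholds$bsr_min &&
          hit$coverage_a >= thresholds$coverage_min &&
          hit$coverage_b >= thresholds$coverage_min) {
        res[[length(res) + 1]] <- data.frame(
          gene_a = g$gene_id[i], gene_b = g$gene_id[j], chromosome = chrom,
          score = hit$score, bit_score = hit$bit_score,
          bit_score_ratio = bsr, evalue = hit$evalue,
          coverage_a = hit$coverage_a, coverage_b = hit$coverage_b,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(res) == 0) return(empty)
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
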