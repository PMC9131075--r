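# Independent reference implementations used to check the package's
# computations. Deliberately simple and written differently from the package
# code paths they validate.

BASES <- c("A", "C", "G", "T")
GC <- Biostrings::GENETIC_CODE

# Smith-Waterman local alignment score by explicit affine-gap dynamic
# programming. A gap of length L costs open + L * ext.
sw_score_oracle <- function(a, b, match = 2, mismatch = -3,
                            open = 5, ext = 2) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)   # gap in a (move along b)
  F <- matrix(-Inf, n + 1, m + 1)   # gap in b (move along a)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- if (av[i - 1] == bv[j - 1] && av[i - 1] != "N") match else mismatch
      E[i, j] <- max(E[i, j - 1] - ext, H[i, j - 1] - open - ext)
      F[i, j] <- max(F[i - 1, j] - ext, H[i - 1, j] - open - ext)
      H[i, j] <- max(0, H[i - 1, j - 1] + s, E[i, j], F[i, j])
      best <- max(best, H[i, j])
    }
  }
  best
}

# All orderings of a set of positions, as a list (explicit recursion).
all_orderings <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in all_orderings(v[-i])) out <- c(out, list(c(v[i], rest)))
  }
  out
}

# Brute-force NG86 difference counting for one codon pair: enumerate every
# ordering of the differing positions, walk the path, drop paths through stop
# codons (all paths used if every one is blocked), average.
ng86_diffs_oracle <- function(c1, c2) {
  x <- strsplit(c1, "")[[1]]; y <- strsplit(c2, "")[[1]]
  pos <- which(x != y)
  if (length(pos) == 0) return(c(sd = 0, nd = 0))
  count_path <- function(ord, allow_stop) {
    cur <- x; sd <- 0; nd <- 0
    for (p in ord) {
      nxt <- cur; nxt[p] <- y[p]
      if (!allow_stop && GC[[paste(nxt, collapse = "")]] == "*") return(NULL)
      if (GC[[paste(cur, collapse = "")]] == GC[[paste(nxt, collapse = "")]])
        sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    c(sd = sd, nd = nd)
  }
  paths <- list()
  for (ord in all_orderings(pos)) {
    r <- count_path(ord, FALSE)
    if (!is.null(r)) paths <- c(paths, list(r))
  }
  if (length(paths) == 0)
    for (ord in all_orderings(pos)) paths <- c(paths, list(count_path(ord, TRUE)))
  colMeans(do.call(rbind, paths))
}

# Brute-force NG86 synonymous site count for one codon (stop-producing changes
# count as nonsynonymous).
ng86_sites_oracle <- function(codon) {
  v <- strsplit(codon, "")[[1]]
  syn <- 0
  for (p in 1:3) {
    for (nt in BASES[BASES != v[p]]) {
      w <- v; w[p] <- nt
      if (GC[[paste(w, collapse = "")]] == GC[[codon]]) syn <- syn + 1
    }
  }
  c(s = syn / 3, n = 3 - syn / 3)
}

# Two-sided Fisher exact p by hypergeometric enumeration over all tables with
# the observed margins.
fisher_p_oracle <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  xs <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(xs, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Benjamini-Hochberg by the hand formula: sort ascending, p_(i) * n / i,
# cumulative minimum from the largest rank down, cap at 1.
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

# One-sample KS statistic against Uniform(0,1) by the closed formula.
ks_D_oracle <- function(x) {
  x <- sort(x)
  n <- length(x)
  max(pmax(seq_len(n) / n - x, x - (seq_len(n) - 1) / n))
}

sense_codons_list <- function() {
  names(GC)[GC != "*"]
}

split_codons_ref <- function(cds) {
  substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
}
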