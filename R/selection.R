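# --- NG86-style Ka/Ks estimation -------------------------------------------
#
# Fractional synonymous/nonsynonymous site counting per codon, pathway
# averaging for multi-substitution codons, Jukes-Cantor multiple-hit
# correction. Changes that create a stop codon are counted as nonsynonymous in
# the site tally so that N + S = 3 x (aligned codons) holds exactly; mutational
# pathways passing through a stop codon are excluded from the averaging (all
# pathways are used as a fallback in the rare case every ordering is blocked).

.ng86 <- new.env(parent = emptyenv())

sense_codons <- function() {
  gc <- Biostrings::GENETIC_CODE
  names(gc)[gc != "*"]
}

codon_aa <- function(codon) {
  unname(Biostrings::GENETIC_CODE[codon])
}

# Per-codon synonymous site count: at each position, the fraction of the three
# possible single-nucleotide changes that preserve the amino acid.
ng86_codon_sites <- function() {
  if (!is.null(.ng86$sites)) return(.ng86$sites)
  codons <- sense_codons()
  syn <- vapply(codons, function(cd) {
    aa <- codon_aa(cd)
    s <- 0
    for (pos in 1:3) {
      ref <- substr(cd, pos, pos)
      for (nt in setdiff(DNA_ALPHABET, ref)) {
        mut <- cd
        substr(mut, pos, pos) <- nt
        if (identical(codon_aa(mut), aa)) s <- s + 1 / 3
      }
    }
    s
  }, numeric(1))
  .ng86$sites <- data.frame(codon = codons, s_sites = syn,
                            n_sites = 3 - syn, row.names = codons)
  .ng86$sites
}

.perm_list <- list(
  `1` = list(1L),
  `2` = list(c(1L, 2L), c(2L, 1L)),
  `3` = list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
             c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L))
)

# Average numbers of synonymous/nonsynonymous differences between two codons
# over all shortest mutational pathways.
ng86_codon_diffs <- function(codon_a, codon_b) {
  if (codon_a == codon_b) return(c(sd = 0, nd = 0))
  key <- paste0(codon_a, codon_b)
  cached <- .ng86$diffs[[key]]
  if (!is.null(cached)) return(cached)

  pos <- which(strsplit(codon_a, "")[[1]] != strsplit(codon_b, "")[[1]])
  perms <- .perm_list[[as.character(length(pos))]]

  walk <- function(order, allow_stop) {
    cur <- codon_a
    sd <- 0; nd <- 0
    for (p in pos[order]) {
      nxt <- cur
      substr(nxt, p, p) <- substr(codon_b, p, p)
      if (!allow_stop && codon_aa(nxt) == "*") return(NULL)
      if (codon_aa(nxt) == codon_aa(cur)) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    c(sd = sd, nd = nd)
  }

  paths <- Filter(Negate(is.null), lapply(perms, walk, allow_stop = FALSE))
  if (length(paths) == 0) {
    paths <- lapply(perms, walk, allow_stop = TRUE)
  }
  res <- colMeans(do.call(rbind, paths))
  if (is.null(.ng86$diffs)) .ng86$diffs <- new.env(parent = emptyenv())
  assign(key, res, envir = .ng86$diffs)
  res
}

# Jukes-Cantor distance; NA when the proportion saturates (p >= 3/4).
jc_correct <- function(p) {
  ifelse(p >= 0.75, NA_real_, -0.75 * log(1 - 4 * p / 3))
}

#' Codon-aware alignment of two coding sequences
#'
#' Globally aligns the translated proteins (Needleman-Wunsch, BLOSUM62, affine
#' gaps) and back-translates the alignment codon by codon. Gap columns and
#' codons containing ambiguous bases are removed.
#'
#' @param cds_a,cds_b CDS strings (lengths divisible by 3, no internal stops
#'   required here; stops are handled downstream by [kaks()])
#' @param protein_a,protein_b optional protein strings; translated from the CDS
#'   when omitted. Supplying a protein that does not match its CDS length is an
#'   error.
#' @return list with `codons_a` and `codons_b`, equal-length codon vectors
#' @export
align_codons <- function(cds_a, cds_b, protein_a = NULL, protein_b = NULL) {
  if (nchar(cds_a) %% 3 != 0 || nchar(cds_b) %% 3 != 0)
    stop("CDS length must be divisible by 3")
  if (is.null(protein_a)) protein_a <- translate_cds(cds_a)
  if (is.null(protein_b)) protein_b <- translate_cds(cds_b)
  ca <- split_codons(cds_a)
  cb <- split_codons(cds_b)
  # trailing stop codons are not part of the protein
  if (length(ca) == nchar(protein_a) + 1) ca <- ca[-length(ca)]
  if (length(cb) == nchar(protein_b) + 1) cb <- cb[-length(cb)]
  if (length(ca) != nchar(protein_a) || length(cb) != nchar(protein_b))
    stop("protein length does not match CDS length")

  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(protein_a), Biostrings::AAString(protein_b),
    substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 0.5,
    type = "global"
  )
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  pb <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]

  ia <- 0L; ib <- 0L
  keep_a <- character(0); keep_b <- character(0)
  for (k in seq_along(pa)) {
    if (pa[k] != "-") ia <- ia + 1L
    if (pb[k] != "-") ib <- ib + 1L
    if (pa[k] != "-" && pb[k] != "-") {
      keep_a <- c(keep_a, ca[ia])
      keep_b <- c(keep_b, cb[ib])
    }
  }
  clean <- grepl("^[ACGT]{3}$", keep_a) & grepl("^[ACGT]{3}$", keep_b)
  list(codons_a = keep_a[clean], codons_b = keep_b[clean])
}

#' Ka, Ks and omega for an aligned codon pair
#'
#' Nei-Gojobori fractional site counting averaged over both sequences,
#' pathway-averaged difference counting, and Jukes-Cantor correction.
#' Pairs are flagged excluded when Ks > `ks_max` (synonymous saturation makes
#' the rate unreliable), when the correction is undefined (p >= 3/4), or when
#' an internal stop codon is present.
#'
#' @param alignment list with `codons_a`, `codons_b` as from [align_codons()]
#' @param ks_max exclusion threshold on Ks (default 2)
#' @return one-row data.frame: ka, ks, omega, n_sites, s_sites, nd, sd,
#'   n_codons, excluded, reason
#' @export
kaks <- function(alignment, ks_max = 2) {
  ca <- alignment$codons_a
  cb <- alignment$codons_b
  stopifnot(length(ca) == length(cb))
  out <- data.frame(ka = NA_real_, ks = NA_real_, omega = NA_real_,
                    n_sites = NA_real_, s_sites = NA_real_,
                    nd = NA_real_, sd = NA_real_,
                    n_codons = length(ca),
                    excluded = TRUE, reason = NA_character_,
                    stringsAsFactors = FALSE)
  if (length(ca) == 0) {
    out$reason <- "empty_alignment"
    return(out)
  }
  if (any(codon_aa(ca) == "*") || any(codon_aa(cb) == "*")) {
    out$reason <- "internal_stop"
    return(out)
  }
  sites <- ng86_codon_sites()
  s_sites <- (sum(sites[ca, "s_sites"]) + sum(sites[cb, "s_sites"])) / 2
  n_sites <- 3 * length(ca) - s_sites
  diffs <- vapply(seq_along(ca), function(i) ng86_codon_diffs(ca[i], cb[i]),
                  numeric(2))
  sd_tot <- sum(diffs["sd", ])
  nd_tot <- sum(diffs["nd", ])
  ps <- if (s_sites > 0) sd_tot / s_sites else 0
  pn <- if (n_sites > 0) nd_tot / n_sites else 0
  ks <- jc_correct(ps)
  ka <- jc_correct(pn)

  out$n_sites <- n_sites; out$s_sites <- s_sites
  out$nd <- nd_tot; out$sd <- sd_tot
  out$ka <- ka; out$ks <- ks
  if (is.na(ks) || is.na(ka)) {
    out$reason <- "saturation"
    return(out)
  }
  if (ks > ks_max) {
    out$reason <- "ks_gt_max"
    return(out)
  }
  out$excluded <- FALSE
  out$omega <- if (ks == 0) NA_real_ else ka / ks
  if (ks == 0) out$reason <- "omega_undefined"
  out
}

#' Ka/Ks for a pair of coding sequences
#'
#' Convenience wrapper: [align_codons()] followed by [kaks()].
#'
#' @inheritParams align_codons
#' @inheritParams kaks
#' @return one-row data.frame as from [kaks()]
#' @export
kaks_pair <- function(cds_a, cds_b, ks_max = 2) {
  kaks(align_codons(cds_a, cds_b), ks_max = ks_max)
}

#' Selection class per pair and genome-level proportions
#'
#' Strict comparison on omega: omega < 1 purifying, > 1 positive, == 1 neutral.
#' Excluded pairs and pairs with undefined omega (Ks = 0) are unclassified.
#' Proportions are reported over classified (non-excluded, defined-omega) pairs.
#'
#' @param results data.frame of [kaks()] rows (one per pair)
#' @return list with `classes` (input plus a `class` column) and `proportions`
#'   (named vector of percentages over classified pairs)
#' @export
classify_selection <- function(results) {
  cls <- rep("unclassified", nrow(results))
  ok <- !results$excluded & !is.na(results$omega)
  cls[ok & results$omega < 1] <- "purifying"
  cls[ok & results$omega > 1] <- "positive"
  cls[ok & results$omega == 1] <- "neutral"
  results$class <- cls
  n <- sum(ok)
  props <- c(purifying = pct(sum(cls == "purifying"), n),
             positive = pct(sum(cls == "positive"), n),
             neutral = pct(sum(cls == "neutral"), n))
  list(classes = results, proportions = props)
}
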