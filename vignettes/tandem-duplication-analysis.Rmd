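---
title: "Detecting and characterizing tandemly duplicated gene clusters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and characterizing tandemly duplicated gene clusters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tandemscan)
```

## The analysis

Tandem duplication leaves a recognizable footprint: two or more homologous
genes sitting close together on the same chromosome. `tandemscan` detects
these tandemly duplicated gene (TDG) clusters in annotated genomes and then
asks what happened to the duplicate copies — how far they have diverged in
coding sequence, expression and promoter structure, whether the clusters are
shared across genotypes of the same species, and which retention model
(sub-functionalization, genetic redundancy, neo-functionalization) best
explains each pair. A synthetic multi-genotype generator with planted ground
truth validates every stage.

The workflow is organized as numbered driver scripts under `analysis/`
(simulate, run, score, report) over the package functions documented here;
`run_pipeline()` orchestrates the whole analysis for any set of genotypes.

## Cluster detection

A gene pair is a candidate when a Smith–Waterman local alignment of the two
coding sequences (longest isoform) passes all of:

* e-value $\le 10^{-10}$, with bits $= (\lambda S - \ln K)/\ln 2$ and
  e-value $= m\,n\,2^{-\text{bits}}$ over the two sequence lengths
  ($\lambda = 0.625$, $K = 0.41$, match $+2$ / mismatch $-3$, gap open 5 /
  extend 2 — BLASTN-like defaults, all configurable);
* bit-score ratio $\ge 30\%$ — the pair bit score over the **smaller** of the
  two self-alignment bit scores, so identical sequences score exactly 1. The
  ratio's denominator is a genuine design choice; normalizing by the smaller
  self-score makes the ratio symmetric and insensitive to length differences
  in the longer gene;
* coverage $\ge 50\%$ of **both** sequences, measured as the span of the
  single best local alignment over each sequence length.

A passing pair becomes a TDG pair when at most 10 genes lie strictly between
the two ranks. Ranks are start-order indices computed **after** removing TE
genes and genes without a chromosomal location, so intervening counts refer
to the analyzed gene universe (a config switch restores counting over all
genes). Clusters are the connected components of the pair graph per
chromosome — single linkage, the minimal rule consistent with clusters being
groups of pairs.

Alignments only run for pairs passing a shared-k-mer prefilter (k = 11, at
least 4 shared k-mers by default). Unrelated ~1 kb coding sequences share
about 0.2 eleven-mers on average whereas genuinely duplicated pairs at any
divergence the e-value threshold accepts share dozens, so the prefilter
changes no accepted pair (property-tested against all-vs-all) while removing
the quadratic alignment cost.

TE removal happens at the orthogroup level before detection: an orthogroup
is non-TE only when it contains fewer than 30% TE-flagged genes (strict) and
its members' mean annotation-quality (AHRD) score is at least 2 of 3 stars;
every member of a TE orthogroup is excluded. The per-gene TE flag and AHRD
score are consumed as inputs.

## Coding divergence: Ka/Ks

Duplicate pairs are aligned at the protein level (Needleman–Wunsch, BLOSUM62,
affine gaps), back-translated codon-by-codon, and scored with a
Nei–Gojobori-style estimator: fractional synonymous/nonsynonymous site counts
per codon averaged over both sequences, difference counts averaged over all
shortest mutational pathways, and a Jukes–Cantor correction
$d = -\tfrac{3}{4}\ln(1 - \tfrac{4}{3}p)$. Two conventions matter:

* changes that create a stop codon count as nonsynonymous in the **site**
  tally, which keeps the invariant $N + S = 3 \times$ aligned codons exact;
* pathways passing through a stop codon are excluded from the **difference**
  averaging, falling back to all orderings in the rare case every ordering is
  blocked.

Pairs with $K_s > 2$ are excluded (synonymous saturation makes rate estimates
unreliable), as are pairs where the correction is undefined ($p \ge 3/4$) or
an internal stop is present. $\omega = K_a/K_s$ is undefined when $K_s = 0$;
such pairs are left unclassified rather than forced into the positive class.
$\omega < 1$ is purifying, $> 1$ positive selection, strict comparisons.

This estimator deliberately omits transition/transversion bias and gamma rate
heterogeneity; the downstream uses — the $\omega$ = 1 threshold and $K_s$ as
an age axis — are insensitive to that refinement at the divergence levels
analyzed, and pair exclusions reproduce the same saturation rule.

## Expression divergence

A gene is expressed when TPM $> 0.5$ (strict) in at least one sample.
Breadth is the count (and percentage) of samples above the cutoff; level is
the mean linear TPM; specificity is Yanai's tau,
$\tau = \sum_i (1 - x_i/\max_j x_j)/(n-1)$, computed on linear TPM with zeros
included (a `tau` on log-transformed values is a config flag). Tau is 1 for a
gene seen in a single sample and 0 for perfectly uniform expression.

Pair divergence is Pearson's $r$ between the two copies' $\log_{10}(TPM+1)$
profiles — the log scale matches how expression levels are compared
throughout — judged against the 95% quantile of $r$ over an equal number of
random expressed non-TDG gene pairs (seeded, genome-wide, unmatched for
position). A pair with $r$ below the quantile has diverged expression. By
construction a pair drawn from the null itself is called diverged ~95% of the
time, so the conserved call is the conservative one; the calibration is
property-tested at ±2 points on ≥2,000 pairs. Pairs with an unexpressed copy
or a constant profile carry no call.

## Promoter divergence

The putative promoter is the 1 kb immediately upstream of the TSS on the
coding strand (reverse-complemented for minus-strand genes), truncated at the
chromosome edge and at the nearest neighbouring gene boundary on either
strand so promoters never overlap gene bodies; sequences containing N are
excluded. Similarity Ps is the number of identical positions in the best
local alignment (match +5 / mismatch −4, gap open 16 / extend 4 — EMBOSS
matcher-like) divided by the mean of the two promoter lengths, giving
Ps ∈ [0, 1] with Ps(x, x) = 1. The published Ps scale is ambiguous about its
denominator; because divergence calls compare Ps against a within-run
random-pair 95% quantile, the normalization cancels out of every call.

## Core, shared and private clusters

Orthogroups link clusters across genotypes. A cluster is *present* in a
genotype when that genotype has a **tandem-clustered** gene in one of the
cluster's orthogroups — a lone, un-clustered ortholog elsewhere does not
count (the stricter reading; the alternative would make "private" nearly
unattainable for any family with dispersed relatives). Presence is computed
per orthogroup and OR-ed over a cluster's orthogroups. Present in all
genotypes → core; exactly one → private; otherwise shared. Positional
structure is summarized by the cluster midpoint over the chromosome length
(or distance-to-centromere fraction when centromere positions are supplied),
with a Mann–Whitney test of private against core + shared.

## Duplicate-retention fates

For pairs with both copies expressed, a retained $\omega$, and Pfam
annotations, rules apply in order:

1. domain sets differ **and** $\omega > 1$ → neo-functionalization;
2. expression diverged, $\omega < 1$, identical domains → sub-functionalization;
3. expression conserved, $\omega < 1$, identical domains → genetic redundancy;
4. otherwise unclassified.

"Identical domains" is set equality of Pfam ids ignoring copy number. The
precedence resolves combinations the three models do not speak to (e.g.
diverged domains under purifying selection stay unclassified rather than
being forced into a class). Proportions are reported over eligible pairs, and
cross-genotype averages are unweighted means of per-genotype percentages.

## Enrichment

Pfam domains and GO terms are tested for over-representation among TDGs with
a two-sided Fisher exact test per term over the located non-TE background,
BH-adjusted; significance additionally requires at least 10 TDGs carrying the
term. GO terms are treated as flat annotations — no DAG propagation — so GO
results are conservative for high-level terms whose descendants are
annotated separately. Differential enrichment across genotypes row-z-scores
each significant term's fold-enrichment (population SD, so a 2/2/2/6 fold
vector gives z = −0.577, −0.577, −0.577, 1.732).

## Genomic density

Feature density is the covered-base proportion per tiling window (1 Mb by
default, 1.5 Mb as a variant; "sliding" with an unspecified step is read as
tiling). TDG density is regressed (OLS) on covariate densities (non-TE
genes, and TE tracks when available); the residuals are min–max scaled to
[0, 1] and tested against Uniform(0,1) with a one-sample KS test. Residuals
are not naturally on [0, 1], so the min–max scaling is a pragmatic choice:
the resulting D is a relative, not calibrated, measure of non-uniformity, and
a zero-variance residual vector is flagged degenerate instead of tested.

## The synthetic-data generator

`simulate_tdg_data()` emits, per genotype, a GFF3, genome/CDS/protein FASTA,
an annotation table and a TPM matrix, plus a cross-genotype orthogroup table
and full ground truth. Default conditions: 4 genotypes × 5 chromosomes × 400
genes; ~18% of genes in clusters with two-gene clusters dominating (67%);
10% TE genes; a 25/30/45 private/core/shared family partition; planted
$\omega \in \{0.2, 0.6, 1.5\}$ with weights 0.75/0.18/0.07 and
$K_s \sim U(0.05, 0.5)$; 10 expression samples with 75% of genes expressed,
75% of pairs planted expression-diverged and 70% promoter-diverged.

Mechanics worth knowing:

* **Omega planting** proposes uniform random single-nucleotide codon changes
  (the same mutational-opportunity measure the site counting uses), rejects
  stop-creating ones, and accepts synonymous/nonsynonymous proposals with
  probabilities $\min(1, 1/\omega)$ / $\min(1, \omega)$ — so the estimator's
  target is well defined. Rate heterogeneity across sites is not simulated.
* **Diverged expression and promoters are modelled as turnover** (an
  independent profile / sequence), not moderate mutation: a 95%-of-random
  threshold can only flag near-random similarity, so moderately mutated
  promoters (say 35% of sites) still score far above the null quantile and
  would never be called diverged. Consequently recovering a planted diverged
  fraction $f$ yields ~$0.95 f$, and the recovery tests assert exactly that.
* **Promoter placement is exact**: each gene's planted promoter is embedded
  immediately upstream of its TSS on the coding strand, so
  `extract_promoters()` returns the planted sequence byte-for-byte — an
  invariant the tests rely on.
* **Annotation quality**: genuine genes draw 0–3 AHRD stars with
  probabilities .01/.04/.30/.65 (mean 2.6), TE genes .6/.4 over 0–1. With
  four-member orthogroups this leaves ~3% of genuine orthogroups below the
  mean-2 rule — the TE filter is conservative by design, and this collateral
  is part of what the end-to-end tests run through.
* **TE genes are flags only** (no repeat-sequence realism), and orthogroups
  are emitted noiselessly — orthology inference is an input to the analysis,
  not part of it.

What passing tests therefore show: the detection, estimation and
classification machinery recovers planted structure under idealized
annotation, orthology and expression noise. What they do not show: robustness
to mis-annotation, fragmented assemblies, isoform ambiguity, or orthogroup
errors, none of which the generator emulates.

## Numerical choices and degenerate inputs

* Percentages are rounded half away from zero to 2 decimals; cross-genotype
  averages are means of per-genotype percentages, not pooled counts.
* Nulls are seeded per genotype from the run seed; re-running a pipeline on
  identical inputs is byte-identical (tested by file hash).
* Longest isoform = longest total CDS, ties by lexicographic transcript id.
* Empty gene sets, zero-cluster genotypes and all-TE inputs flow through
  every stage without error, producing empty tables and 0.00 percentages.
* Genomes too small for the density model (fewer than three windows) skip the
  uniformity test rather than fitting a meaningless regression.

## Problem sizes

The test suite validates the codon-level estimator against brute-force
enumeration on all 61×61 sense-codon pairs, omega recovery on 200 pairs of
300 codons, null calibration on 2,000+ pairs, and the complete analysis at
the default four-genotype × 2,000-gene scale; the worked fixture
(`worked_fixture()`) is a two-genotype, ~30-gene dataset small enough to
check by hand, on which cluster recovery is exact (F1 = 1).

## Known limitations

* NG86-style counting underestimates $K_a/K_s$ slightly when
  transition/transversion bias is strong; a maximum-likelihood or
  Gamma-MYN-class estimator can be substituted by importing its per-pair
  output in place of `kaks_pair()`.
* The single best local alignment defines coverage; multi-HSP homology over
  rearranged genes is not chained.
* GO enrichment without DAG propagation understates high-level terms.
* Cluster presence across genotypes is only as good as the orthogroups
  supplied; a cluster spanning several orthogroups uses the most permissive
  (OR) reading of presence.
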