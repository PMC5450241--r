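---
title: "Methods: comparative developmental transcriptomics with pupdevo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative developmental transcriptomics with pupdevo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

pupdevo implements an analysis pipeline for comparative developmental
transcriptomics: several closely related taxa (in the motivating system,
San Salvador Island pupfishes — two trophic specialists, a scale-biter and
a hard-shelled-prey specialist, plus two omnivore populations) are sampled
at several developmental stages with replicated RNA-seq, and the question
is which genes are differentially expressed in one taxon relative to *all*
others, when during development, and whether those differences persist
across development. A companion module extracts jointly well-covered
genomic intervals for phylogenomic supermatrix construction from the same
read data. Because real data of this design are large and entangled with
external databases, the package ships a negative-binomial simulator with
planted truth; every statistical claim in the test suite is checked
against that truth or against an independent brute-force oracle.

## The expression model

Counts for gene $g$ in sample $s$ are modelled as negative binomial,

$$y_{gs} \sim \mathrm{NB}\!\left(\mu_{gs},\ \phi_g\right),\qquad
\mu_{gs} = \lambda_{g,t(s)} \cdot N_s f_s,$$

where $\lambda$ is the expression rate of the gene in the sample's group
(taxon within a stage), $N_s$ the library size, $f_s$ the TMM scaling
factor, and $\phi_g$ the gene-wise dispersion
($\mathrm{Var} = \mu + \phi\mu^2$). All analyses are run within a
developmental stage; between-stage normalization is deliberately out of
scope because every contrast of interest compares taxa at the same stage.

### Filtering

Mitochondrial genes and pseudogenes are removed first. A gene is retained
at a stage when it reaches 1 CPM in at least half of that stage's samples
(with 16 samples: 8), or 2 CPM in at least a quarter (4). The second prong
deliberately retains genes expressed in only the four replicates of a
single taxon, which are exactly the taxon-restricted candidates the
intersection sets are meant to find. Fractional sample counts are rounded
up (`ceiling`), reading "at least … in half" as an inclusive bound; the
boundary convention of the 2-CPM prong is a package decision (inclusive)
since either reading is defensible.

### TMM normalization

`tmm_factors()` implements the trimmed mean of M-values: per sample, a
weighted mean of gene-wise log2 expression ratios against a reference
sample, after discarding the 30% most extreme ratios on each side and the
5% extremes of average log expression, with inverse-variance weights; the
reference is the sample whose 75th-percentile count fraction is closest to
the mean, and factors are rescaled to geometric mean 1. Genes with a zero
count in the sample or reference are excluded from the trimmed mean.
Library sizes default to column totals but can be supplied, in which case
pure depth changes are absorbed into the factor. The implementation is
checked in the tests against an independently coded literal-formula oracle
(agreement to 1e-10) and against `edgeR::calcNormFactors`.

One subtlety: because the weights depend on raw counts, TMM factors are
not *exactly* invariant to scaling a column (the weighted trimmed mean
shifts by ~0.1–1%); the tests assert stability at 2% relative rather than
exact invariance, and assert exactness in the one case where it truly
holds (a column that is an exact multiple of the reference, where every
M-value is identical).

### Dispersion estimation

The common dispersion maximizes the summed Cox–Reid adjusted profile
log-likelihood across genes, with group means profiled out by Newton
scoring at each candidate value and offsets equal to log effective library
size. The CR adjustment (minus half the log determinant of the
mean-parameter information) matters: the unadjusted profile likelihood
recovers a truth of 0.10 as ≈0.074 with four groups of four, while the
adjusted version recovers 0.101.

Per-gene dispersions maximize
$\ell_g(\phi) + w \cdot a(\phi)$, where $a$ is the per-observation anchor
likelihood and $w$ (`prior_weight`, default 10) counts pseudo-observations
supporting the anchor; $w=0$ gives per-gene MLEs and $w\to\infty$ the
anchor's maximizer. Two anchors are available:

* `"common"` — the global average likelihood, whose maximum is the common
  dispersion; this is the simplest scheme and the one all limit-case tests
  exercise.
* `"trend"` — the same average computed within abundance bins (quantiles
  of average log CPM, 20 bins, at least 50 genes per bin).

The analysis wrappers use the trend anchor. The reason is quantitative:
real (and simulated) dispersions fall with abundance, so shrinking every
gene toward one global value inflates the dispersions of well-expressed
genes — in our validation scenario enough to drop intersection-set recall
of planted effects from ≈0.93 to ≈0.86. Shrinking toward the typical
dispersion *at the gene's own abundance* removes that bias while keeping
the stabilizing effect of shrinkage; this mirrors the trended empirical
Bayes dispersions that are standard in the field. Maximization is over a
fixed geometric grid spanning ±8 octaves around the common value in 65
steps (≈19% resolution), which is ample given that downstream tests are
insensitive to dispersion errors of that size.

### Pairwise testing

`test_pairwise()` performs a per-gene likelihood-ratio test of one shared
mean versus separate means for the two taxa, with dispersions fixed at
their shrunken estimates and a $\chi^2_1$ reference distribution. A
likelihood-ratio GLM test was chosen over exact or quasi-likelihood
variants because it is directly verifiable against a brute-force grid
maximization of the same likelihood (the suite does exactly that, to
1e-4). The reported log2 fold change adds a prior count of 0.5 (scaled by
relative effective library size) to each group's pooled normalized counts,
so fold changes remain finite when a taxon is entirely silent — this is
the number the 0.2 threshold is applied to, so its definition is part of
the method. Benjamini–Hochberg adjustment is applied within each
comparison. Under a null simulation (4 taxa × 4 replicates, $\phi = 0.1$,
5000 genes) the realized fraction of $p < 0.05$ is ≈0.05 (0.044–0.065
across the seeds exercised in the tests and acceptance script).

## Discovery: intersection sets and constitutive expression

A focal taxon's intersection set at a stage contains the genes with
FDR ≤ 0.1 and log2 fold change ≥ 0.2 in magnitude, *with the same sign*,
in all three comparisons of the focal taxon against each other taxon. The
sign-consistency reading resolves an ambiguity (a threshold on signed
versus absolute fold change): since the sets are reported as over- and
underexpressed lists, mixed-sign genes belong to neither. Relaxing either
threshold can only grow a set (tested property).

Across stages, the union of a focal taxon's sets is partitioned into genes
appearing at one stage versus two or more ("multi-stage", reported with
its percentage of the union). A multi-stage gene is *constitutively*
differentially expressed when the mean log2 fold change over the three
comparisons has the same sign at every sampled stage, regardless of
per-stage significance — the mean is used because relative expression of
the focal taxon against all others is what the per-stage heatmaps of such
studies display. Genes filtered out at some stage have no fold change
there, cannot be assessed, and are reported in a diagnostics list rather
than silently dropped.

On simulated data with effects planted focal-vs-rest at |log2FC| = 1 in
10% of genes, the stage-level intersection sets recover ≥ 90% of planted
genes with baseline expression ≥ 50 CPM at an observed false-discovery
proportion below 0.05.

## Enrichment

Curated-list overrepresentation (e.g. a literature-derived list of
craniofacial/bone genes) is tested by drawing 1000 random gene sets of the
same size as the query from the analysis universe and counting curated
members; the empirical $p$ uses the add-one correction
$(1+\#\{\text{null} \ge \text{obs}\})/(1+n)$ so it is a valid Monte-Carlo
p-value. Because this null *is* hypergeometric, the exact upper tail
(`stats::phyper`) is reported alongside and the tests require the
empirical value to sit within three Monte-Carlo standard errors of it.

Pre-ranked GSEA uses the classic (unweighted) scoring scheme: walking the
ranked list, set members add $1/G$ and non-members subtract $1/(N-G)$; the
enrichment score is the running sum's maximum absolute deviation (positive
preferred on an exact tie; running-sum values are computed directly from
integer hit/miss counts so they are exactly reproducible). Rankings come
either from the mean log2 fold change of the three focal comparisons or
from gene loadings on a principal component; ties break by gene
identifier. The null distribution per set is the ES of random same-size
position draws — the standard gene-label null for pre-ranked mode, where
no sample-level permutation exists — shared across sets of equal size.
NES divides ES by the mean |ES| of same-sign null draws; the FDR q
compares the fraction of normalized null scores beyond a set's NES with
the fraction of observed NES beyond it, within matching-sign pools,
clipped at 1. This is one member of the family of q-value variants used by
GSEA implementations; it is documented here rather than asserted to match
any particular program's output. For small lists an exhaustive null
(`exhaustive = TRUE`) replaces sampling and the nominal $p$ becomes the
exact tail fraction, which the tests verify by full enumeration at
$N = 12$, $G = 3$.

## Ordination

Per-stage PCA operates on $\log_2(\mathrm{CPM} + 1)$ with genes centered
but not variance-scaled (standard for expression PCA; scaling would
up-weight noisy low-expression genes). CPM is used where the original
workflow used RPKM: gene length is constant within a gene and therefore
cancels from between-sample comparisons, and dropping it removes the
dependence on annotation lengths; this divergence is deliberate and only
affects the (unused) absolute scale of loadings. Components come from the
SVD of the centered matrix; variance fractions are
$\sigma_k^2/\sum\sigma^2$; each component's sign is fixed so its
largest-magnitude loading is positive, making loading rankings
deterministic.

## Supermatrix intervals

Coverage tracks (0-based, half-open, bedGraph interchange) are combined by
a per-base AND: maximal runs where *every* sample reaches 10 reads form
the interval catalog, so the resulting supermatrix has no missing data.
Intervals are then length-filtered; the bounds default to the strict
reading — strictly longer than 50 bp and strictly shorter than 1 kb
(encoded as inclusive 51–999) — with both bounds configurable because the
boundary convention is not recoverable from the procedure's description.
Consensus sequences (FASTA, one record per sample per scaffold) are
sliced at the cataloged intervals and concatenated; a coordinate map
records each interval's columns for downstream partitioning, and intervals
containing `N` are reported (and dropped under `strict = TRUE`). SNP
calling and consensus generation themselves are upstream input contracts,
not reimplemented.

## The simulator

`simulate_experiment()` emulates the study design: 4 taxa × 4 stages × 4
biological replicates (one parental pair per replicate), library sizes
uniform in 10–20 million (so 1 CPM ≈ 10–20 reads), gene baselines
log-normal (sdlog 1.5, a realistic dynamic range) and rescaled to sum to
one million so they are exact CPM values and realised library sizes match
the nominal ones, and a decreasing mean–dispersion
trend $\phi_g = d_0 + d_1/\mu_g$ with $d_0 = 0.04$ and $d_1 = 0.5$
(biological CV 0.2 at high abundance — the standard rule-of-thumb value
for experiments with genetically distinct replicates, here pools of
siblings from distinct parental pairs — rising toward ≈0.7 at 1 CPM). The
original study reports no within-taxon variance components, so these
defaults are package choices, stated here and in `sim_config()`'s
documentation.

Differential expression is planted as focal-vs-rest shifts: an affected
gene belongs to exactly one taxon and its mean is multiplied by
$2^{\pm\text{effect}}$ in that taxon only, making pairwise truth
well-defined in all three comparisons. The default planted magnitude is
0.4 log2 units (≈1.3-fold), matching the modest fold changes such
between-species comparisons typically find; validation scenarios that
measure recall plant 1.0 log2 units. A configurable fraction of affected
genes keeps the same sign at every stage (constitutive truth); the others
draw signs per stage and are re-signed if they accidentally agree
everywhere, keeping the two classes distinct. The coverage simulator
plants low-coverage gaps and substitutions and derives its truth catalog
by a per-base scan at generation time.

What the simulator does *not* emulate: gene–gene correlation, GC or
length biases, isoform-level variation, outlier replicates, and
sample-level batch effects. Passing tests therefore demonstrate
correctness of the inferential machinery under the stated model, not
robustness to every artefact of real libraries.

### Validation problem sizes

The test suite and `scripts/acceptance.R` use scenarios sized to exercise
each claim while staying quick: 5000-gene single-stage experiments for
calibration and recall, 4000 genes (two taxa) for fold-change bias
(≈2000 well-expressed planted genes), 10 000 permutations × 50 scenarios
for the enrichment null, 200 random instances (N ≤ 50) plus the
exhaustive $N=12$ null for GSEA, 100 random fixtures for interval
extraction, a 3000-gene taxon-structure scenario for ordination (10% of
genes per taxon at 1.5 log2 units, which puts roughly half the
log-expression variance among taxa, the partition such studies report),
and the full 10 000-gene 4 × 4 × 4 default configuration, run twice, for
end-to-end byte-identical reproducibility.

## Numerical and design notes

* Newton scoring on the log-mean with steps clamped to ±5 converges in a
  handful of iterations; all-zero genes contribute likelihood 1 and no
  dispersion information.
* Dispersion search runs in log space over $[10^{-6}, 20]$; Poisson-like
  data simply hit the lower region.
* Empirical p-values always use the add-one correction except under
  exhaustive enumeration, where the exact tail fraction is returned.
* The pipeline writes only plain-text formats (TSV/CSV/GMT/RNK/BED/
  bedGraph/FASTA/JSON) and its manifest stores an MD5 per output; reruns
  under the same configuration and seed are byte-identical.
* Known limitations: single-factor design only (no batch covariates or
  weights), no between-stage normalization, no weighted GSEA, and the
  GSEA FDR variant is package-defined (see above).
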