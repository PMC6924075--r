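---
title: "Methods: chromatin-associated RNA analysis with pirchkit"
author: "pirchkit authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chromatin-associated RNA analysis with pirchkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pirchkit)
```

## The assay and the analysis problem

Histone-mark-specific RNA pulldown sequencing (PIRCh-seq) crosslinks RNA
to chromatin, immunoprecipitates histone H3 or one of six histone
modifications (H3K4me1, H3K4me3, H3K27ac, H3K27me3, H3K9me3, H4K16ac),
and sequences the retrieved RNA. Comparing pulldown to input libraries
identifies non-coding RNAs that physically associate with chromatin, and
the *pattern* of association across marks carries functional information:
an ncRNA enriched on H3K4me3/H3K27ac chromatin sits in an active
promoter-like context, one enriched on H3K27me3/H3K9me3 in
heterochromatin, one enriched on both valences in a bivalent context.

`pirchkit` implements the downstream analysis as a tested R package:
depth normalization and a moderated pulldown-vs-input test per gene and
mark; silhouette-selected K-means classification of the enriched ncRNAs
into chromatin-association states; a transcript-coordinate peak caller
with a bootstrap null; structure (icSHAPE) and m6A overlays around peaks;
allele-specific enrichment tests from per-SNP biallelic counts;
intron-based nascent-transcript QC; and rank-concordance validation
against orthogonal RNA-DNA contact maps. Because the original sequencing
libraries are not needed to test any of this logic, a synthetic-data
generator with planted ground truth is a first-class module: every
statistical claim the package makes is exercised against data whose truth
is known by construction.

## Enrichment calling

Counts enter as a genes x samples matrix with sample metadata (assay,
replicate, cell type). Three steps mirror standard RNA-seq differential
practice:

1. **Depth normalization** scales every sample to a common total of
   $10^7$ reads (`depth_normalize()`, `target = 1e7`). This is a display
   and scoring convention; the test below renormalizes internally via
   counts-per-million.
2. **Expression filtering** keeps genes with raw count $\ge$ 10 in at
   least as many samples as the smallest assay group
   (`filter_expressed()`). The rule is deliberately a transparent
   raw-count threshold.
3. **Moderated testing** (`fit_moderated_test()`): per gene, a two-group
   linear model on $y = \log_2(\mathrm{CPM} + 0.5)$ contrasting pulldown
   against input. Residual variance is stabilized in two ways:
   observation-level precision weights $w = 1/\hat\sigma(\mu)^4$ from a
   lowess trend of $\sqrt{\mathrm{sd}}$ against average log-count
   (disabled below 11 genes, where no trend is estimable), and
   empirical-Bayes shrinkage of the per-gene variances toward a
   scaled-inverse-$\chi^2$ prior. The prior is moment-matched on the log
   scale: with $d$ residual df, $\mathrm{Var}[\log s^2]$ exceeds
   $\psi'(d/2)$ by $\psi'(d_0/2)$ under the prior, which is solved for
   the prior df $d_0$ by Newton inversion of the trigamma function. The
   moderated statistic is
   $t = \hat\beta \big/ \sqrt{\tilde s^2 c}$ with
   $\tilde s^2 = (d_0 s_0^2 + d s^2)/(d_0 + d)$, on $d_0 + d$ df. When
   the empirical spread of $\log s^2$ falls below the $\chi^2$ baseline
   the prior df is infinite and every posterior variance collapses to
   $s_0^2$ (taken as the arithmetic mean of the $s^2$, matching the
   limma convention); the unit tests cross-check both the shrinkage and
   the full statistic against limma.

A gene is **chromatin enriched** for a mark when $p < 0.05$ and
$\log_2\mathrm{FC} > 0$. Raw p-values are used for the call — that is the
field convention for this assay — and a BH-FDR column is emitted for
reference only. The display-scale **enrichment score** is
$\log_2\frac{\bar P + 1}{\bar I + 1}$ on depth-normalized counts with
replicates averaged *before* the ratio (the alternative, averaging
ratios, differs only at low counts; averaging first is the stabler
choice and is stated here as the package's convention). The **variation
score** is the sample SD (denominator $n-1$) of a gene's enrichment
scores across the six marks.

With 2 pulldown and 2 input replicates the pooled model has $d = 2$; if a
design ever leaves $d = 0$ the function refuses and points to
`welch = TRUE`, a gene-wise Welch fallback without moderation.

## State classification

Rows of the classification matrix are ncRNAs enriched in $\ge 1$ mark,
columns the six marks, entries the signed per-mark scores (signed, not
clipped at zero: depletion on the opposite valence is informative).
K-means (Euclidean distance on the raw scores, 25 restarts, fixed seed)
is fit for $K = 2..10$ and $K$ maximizes the mean silhouette width, ties
going to the smaller $K$. When no $K$ reaches mean silhouette 0.25 — the
conventional boundary below which a clustering shows no substantial
structure — the smallest $K$ is returned with a warning rather than
pretending a structure exists.

Clusters are labeled by cosine similarity between the centroid and six
fixed state templates (Active Promoter = H3K4me3 + H3K27ac,
Heterochromatin = H3K27me3 + H3K9me3, Weak Promoter = H3K4me3 alone,
Strong Enhancer = H3K4me1 + H3K27ac + H4K16ac, Bivalent = H3K4me3 +
H3K27me3, Weak Enhancer = H3K4me1 alone; characteristic marks at log2
effect 2, others 0). Cosine labeling makes the assignment invariant to
positive rescaling of the matrix. This is a transparent stand-in for
emission-based chromatin-state labeling (chromHMM-style), whose learned
emissions are not reproducible from published material; a centroid whose
best similarity falls below 0.3 is flagged `unassigned`. The attached
2-D embedding is classical MDS and exists for plotting only — any
embedding would do, and no inference reads it.

`bi_mono_classify()` calls a gene **bi-enriched** when enriched on at
least one active (H3K4me1/H3K4me3/H3K27ac/H4K16ac) and one repressive
(H3K27me3/H3K9me3) mark, **mono-enriched** on exactly one valence class.
H3 itself carries no valence and is excluded. Proportions between cell
types are compared by an uncorrected contingency chi-square
(`correct = FALSE`, so the statistic equals the textbook formula).

## Transcript peak calling

Pileups live in mature-transcript coordinates (introns spliced out),
5'→3', 0-based. Replicates are summed (optionally rescaled to $10^7$
depth first), then smoothed with a 5-base sliding mean evaluated every 2
bases, truncated at the ends. Candidate summits are strict local maxima
on that grid (plateaus keep the leftmost point) whose smoothed height
reaches **fivefold** the transcript baseline. "Median read count of the
transcript" is ambiguous when most bases are uncovered, and an all-zero
median would make a relative threshold vacuous; the baseline is
therefore the median over positive-coverage bases, falling back to the
global mean when fewer than 20 bases are covered. The peak extent — a
convention this package must fix, since only summits are standard — is
the maximal contiguous above-threshold grid run containing the summit,
projected to base coordinates; overlapping extents merge keeping the
higher summit.

Significance comes from a read-placement bootstrap: the transcript's
reads (count and length preserved) are re-placed uniformly at random
1000 times, each null pileup is smoothed identically, and the maximum
grid value recorded. The p-value is
$(1 + \#\{\max_{null} \ge h_{obs}\})/(B+1)$ — the add-one form keeps p
strictly positive for downstream log-scale use. Resampling reads rather
than per-base coverage values preserves the read-length autocorrelation
of coverage, which is what makes the null maxima comparable to observed
ones. Finally each peak's fold change over the input pileup is computed
over its extent with pseudocount 1, and peaks are kept at $p < 0.05$ and
input fold $> 1$.

## Structure and modification overlays

`shape_flank_profile()` averages per-base icSHAPE-like scores at every
offset within ±200 bases of peak summits and compares, per offset, with
scores around background positions drawn uniformly from the *same*
transcripts (matched composition — a background drawn from other
transcripts would confound transcript-level structure differences), by
two-tailed Welch t tests. Missing bases are skipped, never imputed;
offsets running past a transcript end simply contribute fewer
observations. Gene-level comparisons (`shape_group_comparison()`,
`top_k_comparison()` with k = 100) require $\ge 50$ scored bases per
gene. `m6a_overlap()` compares the fraction of peak bases inside m6A
intervals against length- and transcript-matched random regions, with a
permutation p in the same add-one form.

## Allele-specific enrichment

For an F1-hybrid line, each SNP yields allele-1/allele-2 read counts per
sample. The per-SNP ratio is $\log_2(a_1 + 1) - \log_2(a_2 + 1)$
(computed as a difference of logs so that swapping allele labels negates
it exactly). The gene-level expression ratio is the mean per-SNP ratio
across input samples; the enrichment ratio is the pulldown mean minus
the input mean, which cancels expression skew and isolates differential
chromatin association — the configuration of interest being a gene whose
*lowly expressed* allele is the chromatin-enriched one. Significance is
a two-sided Mann-Whitney test on per-SNP allele-1 fractions, pulldown
samples versus input samples, keeping replicates as separate
observations (pooling replicates would discard between-replicate
variability the test should see). Genes with fewer than 3 SNPs get
ratios but `p = NA`.

## Nascent-transcript QC

Truly chromatin-associated RNAs are mature; nascent transcripts carry
intronic signal. `intron_exon_ratio()` is base-level intronic over
exonic read overlap. `intron_metagene()` rescales, for every intron with
flanking exons, the region (upstream exon, intron, downstream exon) onto
300 windows — 100 per segment, the symmetric reading of "one exon length
up- and downstream"; flanks use the true neighboring exon rescaled, not
a fixed-length window. Window means use exact fractional integration of
the piecewise-constant coverage (linear interpolation of the cumulative
sum), which makes the profile exactly flat under uniform coverage and
exactly intron-length invariant; each window is $\log_2(x+1)$-transformed
(the offset avoids $-\infty$ on empty windows) before averaging across
introns. Minus-strand genes are flipped so profiles run 5'→3'.

## Validation against orthogonal maps

Where an ncRNA's genomic binding sites are known (ChIRP/CHART/RAP-style
maps), `overlap_ratio()` computes the fraction of its binding sites
intersecting a mark's ChIP-seq peaks ($\ge$ 1 bp counts), rescaled by
that mark's peak count relative to the mean across marks — the
under-specified "normalize by the total number of ChIP peaks" step,
resolved here as a relative per-mark scaling so the statistic stays an
interpretable fraction. `rank_concordance()` ranks each ncRNA's marks in
both the overlap and the enrichment matrix (rank 1 = most enriched, ties
averaged) and computes per-ncRNA Spearman correlations; the null
shuffles column labels, exhaustively over all $m!$ permutations when
that fits the permutation budget (so a 5-mark comparison is exact), and
the observed correlations are compared with the permuted population by
a two-tailed Welch t test. The default sampled budget is 10,000.

## The synthetic-data generator

`simulate_counts()` draws NB counts with variance
$\mu + \phi\mu^2$ (the standard RNA-seq parameterization), per-gene
log-normal baselines, and per-sample library sizes; planted
chromatin-associated ncRNAs carry their state template's per-mark log2
effects plus Gaussian jitter, inputs carry none, and the H3 pulldown
gets the mean positive template effect (H3 sees chromatin association
as such, not mark identity). Defaults define the emulated study
conditions: 2000 expressed genes, 30% non-coding, dispersion
$\phi = 0.1$ (typical replicate-level overdispersion for cell-line
RNA-seq), libraries 0.8–1.2 M reads, jitter SD 0.3, and 40 planted
ncRNAs per state — 240 in all, commensurate with the few hundred
chromatin-enriched ncRNAs such experiments report. Template magnitude
(2.0) and jitter were chosen once so that detection is neither trivial
nor hopeless at 2 + 2 replicates; none of these numbers is derived from
published effect sizes, which are not available.

`simulate_pileup()` places background reads uniformly and adds
$(a-1) \cdot n \cdot w/L$ reads inside each planted peak's ±width/2
window, so local coverage is about $a \times$ background — the simplest
shape the 5-base smoother resolves. `simulate_shape()` draws Beta scores
(concentration 10) with mean 0.3, elevated in the 6-base window 5–10 nt
5' of each planted summit, with 10% of bases missing.
`simulate_allele()` draws binomial allele-1 counts at fixed depth with
logistic-transformed skews, SNPs spaced one per 100 bases as in a dense
F1 hybrid. `simulate_annotation()` lays out non-overlapping multi-exon
genes and round-trips through the GTF writer/reader.

Every generator is bit-reproducible from its seed, and all pipeline
randomness descends from one top-level seed through fixed per-stage
offsets (recorded in the run manifest).

**What passing tests do and do not show.** The generator emulates
count overdispersion, library-size variation, mark-specific effect
patterns, read-level pileup noise, missing structure scores and
binomial allelic sampling. It does not emulate GC or length bias,
mappability artifacts, batch effects, correlated replicate noise,
transcript-abundance-coupled peak density, or the heavy-tailed effect
size distribution of real enrichment. Green tests therefore certify the
*logic and calibration* of the statistics under the stated model, not
performance on any particular sequencing data set.

## Problem sizes and numerical conventions

The test-suite and the acceptance script run at sizes chosen to make
Monte-Carlo checks stable while keeping the default run short: 2000-gene
count simulations (10 seeds for the type-I check), 240-row
classification matrices, 50 seeded transcripts for peak recall and 200
for bootstrap-null calibration (B = 499 there; the analysis default is
B = 1000), 100 seeds for allele-specific power. Key numerical
conventions, collected: pseudocount 1 on all display ratios; add-one
permutation/bootstrap p-values; strict-maximum, leftmost-plateau summit
policy; median-over-positive-bases peak baseline with a global-mean
fallback below 20 covered bases; deterministic name-based tie-breaks in
the GSEA ranking; closed ±100 kb neighbor boundary (a gene exactly at
the edge is included); 0-based half-open intervals everywhere
internally, converted at the GTF/BED boundary.

## Known limitations

The moderated test assumes a common design across genes and two
conditions; complex designs (paired replicates, covariates) are out of
scope. Cosine-to-template labeling is an interpretation, not a learned
emission model, and state names inherit its assumptions. The peak
extent definition is a convention of this package. The bootstrap
assumes exchangeable read placement within a transcript, which ignores
positional coverage bias. The allele-specific test treats SNPs within a
gene as exchangeable observations and ignores linkage between them.
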