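# pirchkit

Downstream analysis for histone-mark-specific RNA pulldown sequencing
(PIRCh-seq): identify chromatin-enriched non-coding RNAs from pulldown
versus input count data, classify them into functional
chromatin-association states, call intra-transcript chromatin-contact
peaks, and integrate RNA structure (icSHAPE), m6A modification and
allele-specific signals. A synthetic-data generator with planted ground
truth makes every stage testable without sequencing data.

The package is for computational biologists analyzing chromatin-RNA
association assays, and is organized as an analysis workflow: all
computation lives in the package (`R/`), and the numbered scripts under
`analysis/` drive it end to end on generated data.

## The statistics at the core

Per gene and mark, enrichment is tested with a moderated two-group
linear model on log2 counts-per-million: precision weights from a
lowess mean-variance trend, and per-gene variances shrunk by empirical
Bayes toward a scaled-inverse-chi-square prior,

    t = log2FC / sqrt(s2_post * c),   s2_post = (d0*s0^2 + d*s^2) / (d0 + d)

on `d0 + d` degrees of freedom. A non-coding gene with `p < 0.05` and
`log2FC > 0` in at least one mark is chromatin enriched. Enriched
ncRNAs form a genes x marks score matrix; K-means with
silhouette-selected K classifies them into six association states
(active promoter, heterochromatin, weak promoter, strong enhancer,
bivalent, weak enhancer). Within transcripts, peaks are local maxima of
5-bp-smoothed coverage at least fivefold above the transcript median,
with significance from a 1000-fold read-placement bootstrap. See
`vignettes/pirchkit-methods.Rmd` for the full model description.

## Worked example

```r
library(pirchkit)

# synthetic study data: 2000 genes, six marks + H3 + inputs, 2 replicates,
# 240 planted chromatin-associated ncRNAs (40 per state)
sim  <- simulate_counts(sim_config(seed = 1))
filt <- filter_expressed(sim$counts)
enr  <- pirch_enrich(filt, alpha = 0.05)

mat <- enrichment_matrix(enr)      # enriched ncRNAs x 6 marks
k   <- select_k(mat, seed = 1)
st  <- cluster_states(mat, as.integer(k), seed = 1)
table(st$state)
```

Running the staged scripts prints, for seed 1:

```
$ Rscript analysis/01_simulate.R
simulated 2000 genes x 16 samples; 240 planted chromatin-associated ncRNAs; ...
$ Rscript analysis/02_enrich.R
chromatin-enriched ncRNAs: 251; planted-truth recall 0.98
variation score nc vs coding: 0.607 vs 0.326 (Welch p = 3.5e-55)
$ Rscript analysis/03_classify.R
selected K = 6
$ Rscript analysis/04_peaks.R
planted-peak recall: 1.00; transcripts with false peaks: 0 of 15 null transcripts
```

251 of the 2000 genes are called chromatin-enriched ncRNAs (98% of the
240 planted ones), non-coding genes show roughly double the
across-mark variation score of coding genes, silhouette selection
recovers the six planted association states, and the peak caller finds
every planted transcript peak with no calls on null transcripts.
Stages 05–07 overlay structure scores on the peaks, run the
allele-specific tests, and validate enrichment rankings against a
concordant orthogonal matrix.

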