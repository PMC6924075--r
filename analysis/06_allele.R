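#!/usr/bin/env Rscript
# Stage 6: allele-specific expression and chromatin-enrichment tests on
# the per-SNP biallelic counts; the first ten genes carry a planted
# enrichment skew of log2 = 2.

suppressMessages(library(pirchkit))
al <- read_allele("results/data/allele.tsv")
truth <- read.delim("results/data/planted_allele.tsv")

res <- allelic_tests(al)
res$significant <- !is.na(res$p_value) & res$p_value < 0.05
write.table(res, "results/allelic.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

skewed <- truth$gene_id[truth$enrich_skew != 0]
cat(sprintf(paste0("allele-specific test over %d genes: %d significant;",
                   " power on planted skew %.2f; false-positive rate on",
                   " null genes %.3f\n"),
            nrow(res), sum(res$significant),
            mean(res$significant[res$gene_id %in% skewed]),
            mean(res$significant[!res$gene_id %in% skewed])))
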