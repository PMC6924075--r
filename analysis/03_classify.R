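#!/usr/bin/env Rscript
# Stage 3: build the enriched-ncRNA x mark score matrix, pick K by
# silhouette, cluster with K-means, and label the functional
# chromatin-association states; classify bi-/mono-valent enrichment.

suppressMessages(library(pirchkit))
enr <- read.delim("results/enrichment.tsv")

mat <- enrichment_matrix(enr)
k <- select_k(mat, k_range = 2:10, seed = 1)
states <- cluster_states(mat, as.integer(k), seed = 1)
write.table(states, "results/states.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cat("enrichment matrix:", nrow(mat), "ncRNAs x", ncol(mat), "marks\n")
cat("silhouette profile:\n")
print(round(attr(k, "silhouette"), 3))
cat("selected K =", as.integer(k), "\n")
print(table(states$state))

# bi/mono classification from the per-mark enriched flags
flags <- split(enr$mark[enr$enriched & enr$mark != "H3"],
               enr$gene_id[enr$enriched & enr$mark != "H3"])
cls <- bi_mono_classify(flags)
cat("bi/mono/none:", sum(cls == "bi"), "/", sum(cls == "mono"), "/",
    sum(cls == "none"), "\n")
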