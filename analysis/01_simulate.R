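#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study data set with planted ground truth
# (counts for inputs, H3 and six histone-mark pulldowns in two replicates;
# a gene annotation; transcript pileups with planted chromatin-contact
# peaks; structure tracks; allele counts) and write everything under
# results/data/.

suppressMessages(library(pirchkit))
seed <- if (length(commandArgs(TRUE))) as.integer(commandArgs(TRUE)[1]) else 1L
out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cfg <- sim_config(seed = seed)
sim <- simulate_counts(cfg)
write_counts(sim$counts, file.path(out, "counts.tsv"),
             file.path(out, "samples.tsv"))
write.table(sim$truth$enriched, file.path(out, "planted_enriched.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

models <- simulate_annotation(100, 3, 5e5, seed = seed + 1)
write_gtf(models, file.path(out, "genes.gtf"))

# 30 transcripts, half with a planted peak
pile <- list(); truth <- list()
for (i in 1:30) {
  pk <- if (i <= 15) data.frame(summit = 600, width = 60, amplitude = 12)
        else NULL
  for (r in 1:2) {
    s <- simulate_pileup(1200, 250, 30, peaks = pk, seed = seed * 100 + i * 2 + r,
                         transcript_id = sprintf("tx%02d", i),
                         sample = paste0("H3K4me3_rep", r))
    pile[[length(pile) + 1]] <- s$pileup
  }
  if (!is.null(pk)) {
    truth[[length(truth) + 1]] <- cbind(transcript_id = sprintf("tx%02d", i), pk)
  }
}
write_pileup(pile, file.path(out, "pileups.tsv"))
write.table(do.call(rbind, truth), file.path(out, "planted_peaks.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

lens <- setNames(rep(1200L, 30), sprintf("tx%02d", 1:30))
shape <- simulate_shape(lens, do.call(rbind, truth), baseline_mean = 0.3,
                        elevation = 0.3, missing_frac = 0.05,
                        seed = seed + 2)
write_shape(shape, file.path(out, "shape.tsv"))

al <- simulate_allele(60, 20, expr_skew = 0,
                      enrich_skew = c(rep(2, 10), rep(0, 50)),
                      depth = 200, seed = seed + 3)
write_allele(al$counts, file.path(out, "allele.tsv"))
write.table(al$truth, file.path(out, "planted_allele.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

cat("simulated", nrow(sim$counts$counts), "genes x",
    ncol(sim$counts$counts), "samples;",
    nrow(sim$truth$enriched), "planted chromatin-associated ncRNAs;",
    "30 transcripts (15 with planted peaks); 60 allele-count genes\n")
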