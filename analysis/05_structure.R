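#!/usr/bin/env Rscript
# Stage 5: overlay icSHAPE-like structure scores on the called peaks:
# the flank profile around summits shows whether bases just upstream of
# chromatin-contact sites are more single-stranded.

suppressMessages(library(pirchkit))
lens <- setNames(rep(1200L, 30), sprintf("tx%02d", 1:30))
shape <- read_shape("results/data/shape.tsv", lengths = lens)
pk <- read_bed("results/peaks.bed")
# the BED stores extents; use the extent midpoint as the summit anchor
peaks <- data.frame(transcript_id = pk$chrom,
                    summit = (pk$start + pk$end) %/% 2)
prof <- shape_flank_profile(peaks, shape, flank = 50, n_background = 100,
                            seed = 5)
write.table(prof, "results/flank_profile.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

up <- prof$offset %in% -10:-5
cat(sprintf(paste0("flank profile over %d peaks: upstream (-10..-5 nt)",
                   " mean %.3f vs background %.3f; max upstream Welch",
                   " p = %.2g\n"),
            nrow(peaks), mean(prof$mean[up]), mean(prof$bg_mean[up]),
            max(prof$p_value[up])))
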