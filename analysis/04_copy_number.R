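#!/usr/bin/env Rscript

# Step 4: copy-number segmentation and gene-level calls.
#
# Segments every sample's probe track (F-statistic recursive splitting,
# 250 kb flank rule, |z| >= 3 and |mean| >= 0.09 filters), projects
# segment means onto genes, calls gains/losses at +0.25 / -0.32, and
# tabulates per-bin alteration frequencies by group.

suppressPackageStartupMessages(library(entiresist))

groups <- read.delim("results/cohort/groups.tsv")
group_map <- setNames(groups$group, groups$sample)
coords <- read_gene_coords("results/cohort/gene_coords.tsv")

segments <- do.call(rbind, lapply(groups$sample, function(s)
  segment_track(read_probe_track(sprintf("results/cohort/probes_%s.tsv", s)),
                sample_id = s)))

dir.create("results/cna", showWarnings = FALSE, recursive = TRUE)
write_seg(segments, "results/cna/segments.seg")

calls <- call_gains_losses(project_to_genes(segments, coords))
write.table(calls, "results/cna/gene_calls.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

freq <- alteration_frequency(calls, coords, group_map)
write.table(freq, "results/cna/alteration_frequency.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

n_loss <- sum(calls$call == "loss")
message(sprintf("%d significant segments across %d samples; %d gene-level loss calls",
                nrow(segments), length(unique(segments$sample)), n_loss))
worst <- freq[which.max(freq$loss_freq), ]
message(sprintf("peak loss frequency %.0f%% in group '%s' at %s:[%g,%g)",
                100 * worst$loss_freq, worst$group, worst$chromosome,
                worst$bin_start, worst$bin_end))
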