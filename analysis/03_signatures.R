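#!/usr/bin/env Rscript

# Step 3: signature derivation and scoring.
#
# Clusters the SAM-called genes over the cohort (median-centered rows,
# centroid linkage on Pearson correlation), extracts the maximal nodes
# with >= 10 genes and node correlation > 0.5, and scores every sample by
# the median expression of each signature.

suppressPackageStartupMessages(library(entiresist))

expr <- read_expression("results/cohort/expression.tsv",
                        "results/cohort/groups.tsv")
sets <- read_gmt("results/de/sam_calls.gmt")

signatures <- list()
for (nm in names(sets)) {
  genes <- sets[[nm]]$genes
  if (length(genes) < 2L) next
  dend <- cluster_genes(expr, genes)
  direction <- if (grepl("up", nm)) "up" else "down"
  signatures <- c(signatures,
                  extract_signatures(dend, direction = direction,
                                     name_prefix = paste0(direction, "_sig")))
}
stopifnot(length(signatures) > 0L)

dir.create("results/signatures", showWarnings = FALSE, recursive = TRUE)
write_gmt(setNames(lapply(signatures, function(s)
  list(description = sprintf("%s node_correlation=%.3f", s$direction,
                             s$node_correlation), genes = s$genes)),
  vapply(signatures, `[[`, character(1), "name")),
  "results/signatures/signatures.gmt")

scores <- score_signatures(expr, signatures)
write.table(scores, "results/signatures/scores.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

for (s in signatures)
  message(sprintf("%s: %d genes (%s), node correlation %.3f",
                  s$name, length(s$genes), s$direction, s$node_correlation))
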