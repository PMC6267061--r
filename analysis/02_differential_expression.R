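#!/usr/bin/env Rscript

# Step 2: SAM-style differential expression, untreated vs resistant.
#
# Calls genes at the strictest threshold (FDR 0%: no permuted exceedances
# in the median permutation) and writes the per-gene statistics plus the
# up/down call lists as GMT for the signature step.

suppressPackageStartupMessages(library(entiresist))

seed <- if (length(commandArgs(TRUE))) as.integer(commandArgs(TRUE)[[1]]) else 1L
expr <- read_expression("results/cohort/expression.tsv",
                        "results/cohort/groups.tsv")

res <- sam_permute(expr, "untreated", "resistant", n_permutations = 200,
                   seed = spawn_seed(seed, "sam"))
delta <- select_delta(res, 0)
calls <- sam_calls(res, delta)

dir.create("results/de", showWarnings = FALSE, recursive = TRUE)
write.table(calls, "results/de/sam_calls.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
up <- calls$gene[calls$call == "up"]
down <- calls$gene[calls$call == "down"]
sets <- list()
if (length(up)) sets$sam_up <- list(description = "upregulated", genes = up)
if (length(down)) sets$sam_down <- list(description = "downregulated",
                                        genes = down)
write_gmt(sets, "results/de/sam_calls.gmt")

message(sprintf(
  "SAM (s0 = %.3f, pi0 = %.2f, %d permutations): delta %.3f calls %d up / %d down",
  res$s0, res$pi0, res$n_permutations, delta, length(up), length(down)))
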