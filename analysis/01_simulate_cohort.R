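#!/usr/bin/env Rscript

# Step 1: generate the synthetic study cohort.
#
# Emulates the study design downstream steps expect: an untreated arm, a
# treated arm (drug-responsive expression program), and a resistant arm
# carrying a planted chromosome-4 deletion over the planted driver gene,
# whose network out-neighborhood (the planted co-expressed module) is
# upregulated. Writes every standard-format input the later steps read.

suppressPackageStartupMessages(library(entiresist))

seed <- if (length(commandArgs(TRUE))) as.integer(commandArgs(TRUE)[[1]]) else 1L
out <- "results/cohort"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cfg <- sim_config(seed = seed)
cohort <- simulate_cohort(cfg)

write_expression(cohort$expr, file.path(out, "expression.tsv"))
write.table(data.frame(sample = names(cohort$expr$groups),
                       group = unname(cohort$expr$groups)),
            file.path(out, "groups.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
for (s in names(cohort$tracks))
  write.table(cohort$tracks[[s]],
              file.path(out, sprintf("probes_%s.tsv", s)),
              sep = "\t", quote = FALSE, row.names = FALSE)
write.table(cohort$edges, file.path(out, "network_edges.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(cohort$coords, file.path(out, "gene_coords.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(cohort$surv, file.path(out, "survival.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
jsonlite::write_json(cohort$truth, file.path(out, "ground_truth.json"),
                     auto_unbox = TRUE, digits = NA)

grp <- table(cohort$expr$groups)
message(sprintf(
  "cohort (seed %d): %d genes x %d samples (%s); planted driver %s inside %s:[%g,%g)",
  seed, nrow(cohort$expr$values), ncol(cohort$expr$values),
  paste(sprintf("%s=%d", names(grp), grp), collapse = ", "),
  cohort$truth$driver, cohort$truth$segments$chromosome[1],
  cohort$truth$segments$start[1], cohort$truth$segments$end[1]))
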