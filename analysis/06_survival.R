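#!/usr/bin/env Rscript

# Step 6: survival stratification.
#
# Samples are stratified into tertiles of the top signature score and into
# driver-deleted vs non-deleted; both stratifications are compared by
# two-sided log-rank tests and univariate Cox regression, and the crossed
# groups by pairwise log-rank with BH adjustment.

suppressPackageStartupMessages(library(entiresist))

surv <- read_survival("results/cohort/survival.tsv")
scores <- read.delim("results/signatures/scores.tsv")
calls <- read.delim("results/cna/gene_calls.tsv")
truth <- jsonlite::read_json("results/cohort/ground_truth.json",
                             simplifyVector = TRUE)

sig <- scores$signature[[1L]]
sc <- scores[scores$signature == sig, ]
sc <- setNames(sc$score, sc$sample)[surv$sample]

dir.create("results/survival", showWarnings = FALSE, recursive = TRUE)

## signature tertiles
tert <- stratify_tertiles(sc)
surv$group <- tert[surv$sample]
lr <- logrank_test(surv, "lower", "top")
cx <- cox_univariate(surv, as.vector(scale(sc)))
km <- do.call(rbind, lapply(unique(surv$group), function(g)
  cbind(group = g, km_estimate(surv, g))))
write.table(km, "results/survival/km_curves.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
message(sprintf(
  "signature %s tertiles: log-rank chi2 %.2f (p = %.3g); Cox log HR per SD %.2f (p = %.3g)",
  sig, lr$chisq, lr$p, cx$beta, cx$p))

## driver deletion status
deleted <- unique(calls$sample[calls$gene == truth$driver &
                                 calls$call == "loss"])
surv$group <- ifelse(surv$sample %in% deleted, "deleted", "intact")
lr_del <- logrank_test(surv, "deleted", "intact")
cx_del <- cox_univariate(surv, as.integer(surv$sample %in% deleted))
message(sprintf(
  "%s deletion (%d/%d samples): log-rank chi2 %.2f (p = %.3g); Cox log HR %.2f",
  truth$driver, length(deleted), nrow(surv), lr_del$chisq, lr_del$p,
  cx_del$beta))

## crossed stratification
cross <- stratify_cross(surv,
                        setNames(ifelse(names(sc) %in% deleted, "del", "wt"),
                                 names(sc)),
                        tert)
write.table(cross$comparisons, "results/survival/crossed_logrank.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

comparisons <- data.frame(
  contrast = c(sprintf("%s tertile lower vs top", sig),
               sprintf("%s deleted vs intact", truth$driver)),
  chisq = c(lr$chisq, lr_del$chisq),
  logrank_p = c(lr$p, lr_del$p),
  cox_loghr = c(cx$beta, cx_del$beta),
  cox_p = c(cx$p, cx_del$p))
write.table(comparisons, "results/survival/comparisons.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
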