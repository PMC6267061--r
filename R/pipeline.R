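## End-to-end orchestration on a synthetic cohort: simulate -> SAM ->
## signatures -> segmentation -> gene-level calls -> driver ranking ->
## survival stratification.

#' Run the full analysis pipeline on a simulated cohort
#'
#' Generates a cohort with [simulate_cohort()], then: SAM differential
#' expression (untreated vs resistant) at the requested FDR; signature
#' derivation from the called genes by centroid-linkage clustering with
#' the 10-gene / 0.5-node-correlation rule; median signature scoring;
#' F-statistic segmentation of every sample's probe track with gene-level
#' gain/loss calls; network-propagation driver ranking aggregated per
#' group and restricted to altered genes; and survival analysis of the
#' top-scoring signature (tertile stratification, log-rank, univariate
#' Cox) plus a one-sided rank-sum comparison of signature scores between
#' driver-deleted and non-deleted samples.
#'
#' @param config a [sim_config()].
#' @param target_fdr SAM target FDR (default 0, the strictest call set).
#' @param n_permutations SAM permutations.
#' @return list with elements `cohort`, `sam`, `de_genes`, `signatures`,
#'   `scores`, `segments`, `gene_calls`, `driver_table`, `survival`.
#' @export
run_pipeline <- function(config, target_fdr = 0, n_permutations = 200L) {
  cohort <- simulate_cohort(config)
  expr <- cohort$expr

  ## differential expression: untreated vs resistant (the contrast that
  ## carries the planted driver neighborhood)
  sam <- sam_permute(expr, "untreated", "resistant",
                     n_permutations = n_permutations,
                     seed = spawn_seed(config$seed, "sam"))
  delta <- select_delta(sam, target_fdr)
  calls <- sam_calls(sam, delta)
  de_genes <- calls$gene[calls$call != "none"]

  ## signatures from the called genes over the whole cohort
  signatures <- list()
  if (length(de_genes) >= 2L) {
    dend <- cluster_genes(expr, de_genes)
    signatures <- extract_signatures(dend, name_prefix = "resistance_sig")
  }
  scores <- if (length(signatures) > 0L)
    score_signatures(expr, signatures) else NULL

  ## copy number: segment every sample's track, project, call
  segments <- do.call(rbind, lapply(names(cohort$tracks), function(s)
    segment_track(cohort$tracks[[s]], sample_id = s)))
  gene_calls <- call_gains_losses(project_to_genes(segments, cohort$coords))

  driver_table <- rank_drivers(expr, cohort$edges, gene_calls,
                               reference_group = "untreated",
                               coords = cohort$coords)

  ## survival on the best-covered signature (highest node correlation)
  surv_res <- NULL
  if (!is.null(scores)) {
    sig_name <- signatures[[1L]]$name
    sc <- scores[scores$signature == sig_name, , drop = FALSE]
    sv <- cohort$surv
    sc <- sc[match(sv$sample, sc$sample), , drop = FALSE]
    tert <- stratify_tertiles(stats::setNames(sc$score, sc$sample))
    sv$group <- tert[sv$sample]
    lr <- logrank_test(sv, "lower", "top")
    cx <- cox_univariate(sv, sc$score)
    ## driver-deleted vs non-deleted samples (by gene-level call)
    deleted <- unique(gene_calls$sample[
      gene_calls$gene == config$planted_driver & gene_calls$call == "loss"])
    wt <- stats::wilcox.test(sc$score[sc$sample %in% deleted],
                             sc$score[!sc$sample %in% deleted],
                             alternative = "greater", exact = FALSE)
    surv_res <- list(signature = sig_name, tertiles = tert, logrank = lr,
                     cox = cx, deleted_samples = deleted,
                     score_wilcoxon_p = wt$p.value)
  }

  list(cohort = cohort, sam = sam, de_genes = de_genes,
       signatures = signatures, scores = scores, segments = segments,
       gene_calls = gene_calls, driver_table = driver_table,
       survival = surv_res)
}
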