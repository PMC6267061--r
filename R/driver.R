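## Per-sample driver ranking by personalized network propagation: a gene's
## score accumulates from the differential expression of the genes it
## points at (its regulatory targets), so a deleted regulator with a
## strongly perturbed out-neighborhood rises to the top of the ranking.

#' Personalized propagation scores over a directed network
#'
#' The personalization vector `g` is the normalized absolute differential
#' expression. Mass flows against edge direction (from target back to
#' regulator): each node distributes its mass equally among its
#' in-neighbors, and nodes without in-neighbors (dangling in the reversed
#' walk) redistribute to `g`. Iterates `r <- (1 - d) g + d T r` to an L1
#' tolerance.
#'
#' @param edges data.frame `from`, `to` (directed; see [network_edges()]).
#' @param diff_expression named numeric vector of per-gene differential
#'   expression; genes of the network absent from it count as 0.
#' @param damping damping factor `d` in `[0, 1)`.
#' @param tol L1 convergence tolerance.
#' @param max_iter iteration cap; non-convergence is an error.
#' @return list: `scores` (named, sums to 1), `iterations`, `converged`.
#' @export
propagate <- function(edges, diff_expression, damping = 0.85,
                      tol = 1e-6, max_iter = 1000L) {
  if (nrow(edges) == 0L) ers_stop("empty network")
  nodes <- sort(unique(c(edges$from, edges$to)))
  n <- length(nodes)
  if (any(!is.finite(diff_expression)))
    ers_stop("differential expression values must be finite")
  g <- stats::setNames(numeric(n), nodes)
  common <- intersect(names(diff_expression), nodes)
  g[common] <- abs(diff_expression[common])
  if (sum(g) == 0) g[] <- 1  # uniform personalization fallback
  g <- g / sum(g)

  src <- match(edges$from, nodes)
  tgt <- match(edges$to, nodes)
  indeg <- tabulate(tgt, nbins = n)      # regulators per node
  ## node j (column) passes r_j / indeg(j) to each regulator i
  w <- 1 / indeg[tgt]
  dangling <- indeg == 0

  r <- g
  for (it in seq_len(max_iter)) {
    inflow <- numeric(n)
    contrib <- r[tgt] * w
    agg <- rowsum(contrib, group = src)
    inflow[as.integer(rownames(agg))] <- agg[, 1L]
    dmass <- sum(r[dangling])
    r_new <- (1 - damping) * g + damping * (inflow + dmass * g)
    delta <- sum(abs(r_new - r))
    r <- r_new
    if (delta < tol)
      return(list(scores = stats::setNames(r, nodes), iterations = it,
                  converged = TRUE))
  }
  ers_stop("propagation did not converge in %d iterations (residual %.3g)",
           max_iter, delta)
}

#' Percent ranks of a score vector
#'
#' `(rank - 1) / (N - 1)` with average ranks for ties, so the top gene of
#' a sample has percentrank 1.
#'
#' @param scores numeric vector (N >= 2).
#' @return numeric vector of percent ranks in `[0, 1]`.
#' @export
percentrank <- function(scores) {
  n <- length(scores)
  if (n < 2L) ers_stop("percentrank needs at least 2 genes")
  (rank(scores, ties.method = "average") - 1) / (n - 1)
}

#' Aggregate per-sample percent ranks by group
#'
#' @param score_matrix genes x samples matrix of propagation scores (all
#'   samples scored over the same gene universe).
#' @param group_map named character vector, sample -> group.
#' @param altered_genes optional named list, group -> character vector of
#'   genes with a copy-number alteration in at least one sample of that
#'   group; when given, each group's report is restricted to them.
#' @return data.frame `group`, `gene`, `percentrank`, sorted within group
#'   by descending percentrank.
#' @export
percentrank_aggregate <- function(score_matrix, group_map,
                                  altered_genes = NULL) {
  pr <- apply(score_matrix, 2L, percentrank)
  rownames(pr) <- rownames(score_matrix)
  out <- lapply(unique(group_map), function(grp) {
    samp <- names(group_map)[group_map == grp]
    agg <- rowMeans(pr[, samp, drop = FALSE])
    df <- data.frame(group = grp, gene = names(agg),
                     percentrank = unname(agg), stringsAsFactors = FALSE)
    if (!is.null(altered_genes))
      df <- df[df$gene %in% altered_genes[[grp]], , drop = FALSE]
    df[order(-df$percentrank), , drop = FALSE]
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' End-to-end driver ranking for a cohort
#'
#' Per sample, differential expression is the absolute shift of the
#' sample's expression from the reference-group mean; propagation scores
#' are computed over the network and percent ranks aggregated per group.
#' The report is restricted to genes with a gain or loss call in at least
#' one sample of the group.
#'
#' @param expr an [expression_matrix()] with group labels.
#' @param edges directed network edge list.
#' @param gene_calls data.frame `sample`, `gene`, `call` (from
#'   [call_gains_losses()]); pass `NULL` to report all network genes.
#' @param reference_group label of the reference (e.g. untreated) group.
#' @param coords optional [gene_coords()] to annotate chromosomes.
#' @param damping,tol,max_iter propagation parameters.
#' @return data.frame `group`, `gene`, `percentrank` (and `chromosome`
#'   when coords given).
#' @export
rank_drivers <- function(expr, edges, gene_calls, reference_group,
                         coords = NULL, damping = 0.85, tol = 1e-6,
                         max_iter = 1000L) {
  if (!reference_group %in% expr$groups)
    ers_stop("reference group '%s' absent from the cohort", reference_group)
  ref_mean <- rowMeans(expr$values[, expr$groups == reference_group,
                                   drop = FALSE])
  nodes <- sort(unique(c(edges$from, edges$to)))
  scores <- sapply(colnames(expr$values), function(s) {
    diff <- abs(expr$values[, s] - ref_mean)
    propagate(edges, diff, damping = damping, tol = tol,
              max_iter = max_iter)$scores[nodes]
  })
  rownames(scores) <- nodes

  altered <- NULL
  if (!is.null(gene_calls)) {
    altered <- lapply(unique(expr$groups), function(grp) {
      samp <- names(expr$groups)[expr$groups == grp]
      sub <- gene_calls[gene_calls$sample %in% samp &
                          gene_calls$call != "neutral", , drop = FALSE]
      unique(sub$gene)
    })
    names(altered) <- unique(expr$groups)
    if (all(lengths(altered) == 0L))
      ers_warn("no altered genes in any group; driver report is empty")
  }
  out <- percentrank_aggregate(scores, expr$groups, altered)
  if (!is.null(coords))
    out$chromosome <- coords$chromosome[match(out$gene, coords$gene)]
  out
}
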