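# In-code fixtures shared across the suite. Everything is generated at test
# time; nothing is read from disk except files the tests themselves write.

# a small deterministic expression matrix with two groups
tiny_expr <- function(n_genes = 6L, n_per_group = 3L, seed = 1L) {
  set.seed(seed)
  n <- 2L * n_per_group
  x <- matrix(rnorm(n_genes * n), n_genes,
              dimnames = list(sprintf("g%02d", seq_len(n_genes)),
                              sprintf("s%02d", seq_len(n))))
  groups <- setNames(rep(c("a", "b"), each = n_per_group), colnames(x))
  expression_matrix(x, groups)
}

# expression matrix from explicit per-group gene values (genes x samples)
expr_from_values <- function(values_a, values_b) {
  na <- ncol(values_a); nb <- ncol(values_b)
  x <- cbind(values_a, values_b)
  rownames(x) <- sprintf("g%02d", seq_len(nrow(x)))
  colnames(x) <- sprintf("s%02d", seq_len(na + nb))
  groups <- setNames(rep(c("a", "b"), c(na, nb)), colnames(x))
  expression_matrix(x, groups)
}

# noiseless piecewise-constant probe track
step_track <- function(chrom = "chr1", spacing = 200L, n = 5000L,
                       shifts = list()) {
  pos <- seq(0L, by = spacing, length.out = n)
  lr <- numeric(n)
  for (s in shifts) lr[pos >= s$start & pos < s$end] <- s$mean
  probe_track(data.frame(chromosome = chrom, position = pos, log_ratio = lr))
}

# hand-built annotated dendrogram for extraction-rule tests
fake_dendrogram <- function(nodes, merge) {
  structure(list(merge = merge, height = seq_len(nrow(merge)),
                 labels = unique(unlist(lapply(nodes, `[[`, "members"))),
                 nodes = nodes),
            class = "gene_dendrogram")
}

# brute-force mean pairwise Pearson correlation
brute_node_correlation <- function(x, members) {
  cm <- cor(t(x[members, , drop = FALSE]))
  mean(cm[upper.tri(cm)])
}

# dense linear-solve oracle for personalized propagation
solve_propagation <- function(edges, diff_expression, damping = 0.85) {
  nodes <- sort(unique(c(edges$from, edges$to)))
  n <- length(nodes)
  g <- setNames(numeric(n), nodes)
  common <- intersect(names(diff_expression), nodes)
  g[common] <- abs(diff_expression[common])
  if (sum(g) == 0) g[] <- 1
  g <- g / sum(g)
  A <- matrix(0, n, n, dimnames = list(nodes, nodes))
  indeg <- table(factor(edges$to, levels = nodes))
  for (k in seq_len(nrow(edges)))
    A[edges$from[k], edges$to[k]] <- 1 / indeg[[edges$to[k]]]
  dangling <- as.numeric(indeg == 0)
  M <- damping * (A + outer(g, dangling))
  setNames(solve(diag(n) - M, (1 - damping) * g), nodes)
}

# by-hand two-group log-rank statistic (observed-minus-expected, with the
# hypergeometric variance at each event time)
hand_logrank <- function(time, event, group) {
  ts <- sort(unique(time[event == 1]))
  o_minus_e <- 0; v <- 0
  for (t in ts) {
    at_risk <- time >= t
    n1 <- sum(at_risk & group == unique(group)[1L])
    n0 <- sum(at_risk)
    d <- sum(event == 1 & time == t)
    d1 <- sum(event == 1 & time == t & group == unique(group)[1L])
    o_minus_e <- o_minus_e + d1 - d * n1 / n0
    if (n0 > 1)
      v <- v + d * (n1 / n0) * (1 - n1 / n0) * (n0 - d) / (n0 - 1)
  }
  (o_minus_e)^2 / v
}

# Breslow partial log-likelihood for a single covariate
breslow_loglik <- function(beta, time, event, x) {
  ll <- 0
  for (i in which(event == 1)) {
    risk <- time >= time[i]
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}
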