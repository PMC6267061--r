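test_that("perfectly correlated genes merge first with node correlation 1", {
  set.seed(1)
  base <- rnorm(30)
  x <- rbind(g1 = base, g2 = 2 * base + 5, g3 = rnorm(30), g4 = rnorm(30))
  colnames(x) <- sprintf("s%02d", 1:30)
  dend <- cluster_genes(expression_matrix(x))
  first <- dend$nodes[[1L]]
  expect_setequal(first$members, c("g1", "g2"))
  expect_equal(first$node_correlation, 1, tolerance = 1e-12)
  expect_equal(dend$height[1L], 0, tolerance = 1e-12)
})

test_that("node correlations equal the brute-force pairwise mean", {
  cfg <- sim_config(seed = 2, n_genes = 40, n_de_genes = 0, module_size = 8,
                    n_samples_per_group = c(untreated = 15, treated = 15))
  sim <- simulate_expression(cfg)
  dend <- cluster_genes(sim$expr)
  for (nd in dend$nodes) {
    if (length(nd$members) > 30) next
    expect_equal(nd$node_correlation,
                 brute_node_correlation(sim$expr$values, nd$members),
                 tolerance = 1e-9)
  }
})

test_that("zero-variance genes are dropped before clustering", {
  x <- rbind(g1 = rnorm(10), g2 = rnorm(10), g3 = rep(2, 10))
  colnames(x) <- sprintf("s%02d", 1:10)
  expect_warning(dend <- cluster_genes(expression_matrix(x)),
                 "zero-variance")
  expect_setequal(dend$labels, c("g1", "g2"))
})

test_that("signature extraction enforces size, correlation and maximality", {
  # 9 genes, high correlation: too small
  nd_small <- list(list(members = sprintf("g%02d", 1:9),
                        node_correlation = 0.9))
  d1 <- fake_dendrogram(nd_small, merge = matrix(c(-1, -2), 1))
  expect_length(extract_signatures(d1), 0L)

  # 15 genes but correlation at/below 0.5 (strict threshold): rejected
  nd_weak <- list(list(members = sprintf("g%02d", 1:15),
                       node_correlation = 0.49),
                  list(members = sprintf("g%02d", 1:15),
                       node_correlation = 0.5))
  d2 <- fake_dendrogram(nd_weak[1L], merge = matrix(c(-1, -2), 1))
  expect_length(extract_signatures(d2), 0L)
  d2b <- fake_dendrogram(nd_weak[2L], merge = matrix(c(-1, -2), 1))
  expect_length(extract_signatures(d2b), 0L)

  # a 12-gene node (r = 0.6) nested inside a qualifying 40-gene ancestor
  # (r = 0.55): only the maximal ancestor is reported
  nodes <- list(list(members = sprintf("g%02d", 1:12),
                     node_correlation = 0.6),
                list(members = sprintf("g%02d", 1:40),
                     node_correlation = 0.55))
  d3 <- fake_dendrogram(nodes, merge = rbind(c(-1, -2), c(1, -3)))
  sigs <- extract_signatures(d3)
  expect_length(sigs, 1L)
  expect_length(sigs[[1L]]$genes, 40L)
})

test_that("extracted signatures are pairwise disjoint on real clusterings", {
  cfg <- sim_config(seed = 7, n_genes = 200, n_de_genes = 0,
                    module_size = 25,
                    n_samples_per_group = c(untreated = 40, treated = 40))
  sim <- simulate_expression(cfg)
  sigs <- extract_signatures(cluster_genes(sim$expr))
  expect_gt(length(sigs), 0L)
  all_genes <- unlist(lapply(sigs, `[[`, "genes"))
  expect_equal(anyDuplicated(all_genes), 0L)
  for (sg in sigs) {
    expect_gte(length(sg$genes), 10L)
    expect_gt(sg$node_correlation, 0.5)
  }
})

test_that("signature scores are per-sample medians, order-invariant", {
  x <- rbind(gA = c(1, 4), gB = c(2, 5), gC = c(10, 6))
  colnames(x) <- c("s1", "s2")
  ex <- expression_matrix(x)
  sc <- score_signatures(ex, list(sig = c("gA", "gB", "gC")))
  expect_equal(sc$score[sc$sample == "s1"], 2)   # median of 1, 2, 10
  expect_equal(sc$score[sc$sample == "s2"], 5)

  # single-gene signature equals that gene's values
  s1 <- score_signatures(ex, list(one = "gB"))
  expect_equal(s1$score, unname(x["gB", ]))

  # gene order irrelevant; an absent gene only changes coverage
  sc_rev <- score_signatures(ex, list(sig = c("gC", "gB", "gA")))
  expect_equal(sc_rev$score, sc$score)
  sc_ext <- suppressMessages(
    score_signatures(ex, list(sig = c("gA", "gB", "gC", "gZ"))))
  expect_equal(sc_ext$score, sc$score)
  expect_equal(unique(sc_ext$coverage), 0.75)

  # constant matrix gives constant scores
  xc <- matrix(3, 2, 2, dimnames = list(c("gA", "gB"), c("s1", "s2")))
  expect_true(all(score_signatures(expression_matrix(xc),
                                   list(s = c("gA", "gB")))$score == 3))

  # zero overlap is an error naming the signature
  expect_error(score_signatures(ex, list(ghost = c("gX", "gY"))), "ghost")
})

test_that("ortholog mapping expands, deduplicates and drops unmapped genes", {
  map <- data.frame(from = c("A", "A", "B"), to = c("a1", "a2", "a1"))
  expect_equal(sort(map_orthologs(c("A", "B"), map, "human_to_mouse")),
               c("a1", "a2"))
  expect_equal(suppressMessages(
    map_orthologs(c("A", "C"), data.frame(from = "A", to = "a"),
                  "human_to_mouse")), "a")
  expect_error(map_orthologs(c("A"), map[0, ], "human_to_mouse"), "empty")
  expect_error(map_orthologs(c("Z"), map, "human_to_mouse"), "zero genes")
  # reverse direction uses the table transposed
  expect_equal(sort(map_orthologs("a1", map, "mouse_to_human")),
               c("A", "B"))
})

test_that("hypergeometric overlap p-values match direct combinatorics", {
  # full overlap of a 10-gene query with a 10-gene set in a 100-gene universe
  res <- overlap_test(sprintf("g%02d", 1:10),
                      list(ref = sprintf("g%02d", 1:10)), 100)
  expect_equal(res$p, 1 / choose(100, 10), tolerance = 1e-12)

  # disjoint query: P(X >= 0) = 1
  res0 <- overlap_test(sprintf("g%02d", 1:10),
                       list(ref = sprintf("h%02d", 1:20)), 100)
  expect_equal(res0$overlap, 0L)
  expect_equal(res0$p, 1)

  # saturated case: query = reference = universe
  resS <- overlap_test(sprintf("g%02d", 1:10),
                       list(ref = sprintf("g%02d", 1:10)), 10)
  expect_equal(resS$overlap, 10L)
  expect_equal(resS$p, 1)

  # exact tail oracle: sum of the hypergeometric pmf
  q <- sprintf("g%02d", 1:15)
  ref <- sprintf("g%02d", 10:40)
  k <- length(intersect(q, ref))
  pmf <- sapply(k:15, function(i)
    choose(31, i) * choose(100 - 31, 15 - i) / choose(100, 15))
  res2 <- overlap_test(q, list(ref = ref), 100)
  expect_equal(res2$p, sum(pmf), tolerance = 1e-9)

  # BH adjustment across a collection and validity of p
  coll <- list(a = sprintf("g%02d", 1:12), b = sprintf("g%02d", 30:45),
               c = sprintf("h%02d", 1:8))
  resm <- overlap_test(q, coll, 100)
  expect_true(all(resm$p > 0 & resm$p <= 1))
  expect_equal(resm$q, p.adjust(resm$p, "BH"))
  expect_error(overlap_test(q, coll, 5), "universe")
})
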