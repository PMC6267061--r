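## Signature derivation in the Cluster-3.0 tradition: genes are median
## centered, clustered by centroid linkage under a 1 - Pearson correlation
## distance over a reference cohort, and every dendrogram node is annotated
## with its "node correlation" (mean pairwise Pearson correlation of member
## genes). Signatures are the maximal nodes with >= `min_genes` members and
## node correlation above `min_node_correlation`.

#' Hierarchical clustering of genes with node-correlation annotation
#'
#' Rows are median centered; the dissimilarity between clusters is
#' `1 - cor(centroid_i, centroid_j)` (centroid linkage on Pearson
#' correlation, as in Cluster 3.0, which [stats::hclust()]'s
#' Euclidean-only centroid method cannot express). Each internal node
#' records its members and the mean pairwise Pearson correlation between
#' them, computed across the cohort samples.
#'
#' @param expr an [expression_matrix()] (the reference cohort).
#' @param gene_subset genes to cluster (default: all rows). Genes with
#'   zero variance across the cohort are dropped with a warning.
#' @return object of class `gene_dendrogram`: `merge` (hclust-style merge
#'   matrix), `height`, `labels`, and `nodes`, a list with `members`
#'   (gene ids) and `node_correlation` per internal node.
#' @export
cluster_genes <- function(expr, gene_subset = NULL) {
  x <- expr$values
  if (!is.null(gene_subset)) {
    missing <- setdiff(gene_subset, rownames(x))
    if (length(missing) > 0L)
      ers_stop("gene_subset contains genes absent from the matrix: %s",
               paste(utils::head(missing, 5L), collapse = ", "))
    x <- x[gene_subset, , drop = FALSE]
  }
  ## mean-impute missing values per gene (clustering tolerates gaps)
  if (anyNA(x)) {
    ers_log("INFO", sprintf("mean-imputing %d missing value(s) for clustering",
                            sum(is.na(x))))
    for (i in which(rowSums(is.na(x)) > 0L))
      x[i, is.na(x[i, ])] <- mean(x[i, ], na.rm = TRUE)
  }
  zero_var <- apply(x, 1L, stats::sd) == 0
  if (any(zero_var)) {
    ers_warn("dropping %d zero-variance gene(s) before clustering",
             sum(zero_var))
    x <- x[!zero_var, , drop = FALSE]
  }
  n <- nrow(x)
  if (n < 2L) ers_stop("need >= 2 genes with variance to cluster")
  p <- ncol(x)
  x <- x - apply(x, 1L, stats::median)          # median center rows
  z <- t(scale(t(x)))                           # unit rows: cor = z z'/(p-1)

  centroids <- x                                # cluster centroid profiles
  zsum <- z                                     # running sum of member z rows
  size <- rep(1L, n)
  active <- rep(TRUE, n)
  id <- -seq_len(n)                             # hclust convention: leaves < 0
  members <- as.list(seq_len(n))

  D <- 1 - stats::cor(t(x))
  diag(D) <- Inf
  D[lower.tri(D)] <- Inf                        # use upper triangle only

  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  nodes <- vector("list", n - 1L)
  for (step in seq_len(n - 1L)) {
    k <- arrayInd(which.min(D), dim(D))
    i <- k[1L]; j <- k[2L]
    merge[step, ] <- c(id[i], id[j])
    height[step] <- D[i, j]
    mem <- c(members[[i]], members[[j]])
    sz <- size[i] + size[j]
    zs <- zsum[i, ] + zsum[j, ]
    ## mean pairwise r from the standardized-row sum:
    ## sum_{a<b} r_ab = (||Z||^2/(p-1) - k) / 2
    node_cor <- if (sz > 1L)
      (sum(zs^2) / (p - 1) - sz) / (sz * (sz - 1L)) else 1
    nodes[[step]] <- list(members = rownames(x)[mem],
                          node_correlation = node_cor)
    ## collapse into slot i
    centroids[i, ] <- (size[i] * centroids[i, ] + size[j] * centroids[j, ]) / sz
    zsum[i, ] <- zs
    size[i] <- sz
    members[[i]] <- mem
    id[i] <- step
    active[j] <- FALSE
    D[j, ] <- Inf; D[, j] <- Inf
    if (any(active[-i])) {
      others <- which(active); others <- others[others != i]
      newd <- 1 - suppressWarnings(
        stats::cor(centroids[i, ], t(centroids[others, , drop = FALSE])))
      newd[is.na(newd)] <- 1  # degenerate (constant) centroid
      lo <- pmin(i, others); hi <- pmax(i, others)
      D[cbind(lo, hi)] <- newd
    }
  }
  structure(list(merge = merge, height = height, labels = rownames(x),
                 nodes = nodes),
            class = "gene_dendrogram")
}

#' @export
print.gene_dendrogram <- function(x, ...) {
  cat(sprintf("gene_dendrogram: %d genes, %d internal nodes\n",
              length(x$labels), length(x$nodes)))
  invisible(x)
}

#' Extract maximal qualifying signatures from an annotated dendrogram
#'
#' A node qualifies when it has at least `min_genes` members and a node
#' correlation strictly greater than `min_node_correlation`. Only maximal
#' qualifying nodes are reported (a qualifying node is suppressed when an
#' ancestor also qualifies), so the returned signatures are disjoint.
#'
#' @param dend a [cluster_genes()] result.
#' @param min_genes minimum member count (default 10).
#' @param min_node_correlation correlation threshold (default 0.5, strict).
#' @param direction label attached to each signature (`"up"`/`"down"`).
#' @param name_prefix signature names are `<prefix>_1`, `<prefix>_2`, ...
#'   in descending node-correlation order.
#' @return list of `GeneSignature` lists: `name`, `genes`, `direction`,
#'   `node_correlation`.
#' @export
extract_signatures <- function(dend, min_genes = 10L,
                               min_node_correlation = 0.5,
                               direction = NA_character_,
                               name_prefix = "sig") {
  n_nodes <- length(dend$nodes)
  qualifies <- function(k) {
    nd <- dend$nodes[[k]]
    length(nd$members) >= min_genes &&
      nd$node_correlation > min_node_correlation
  }
  picked <- integer(0)
  visit <- function(k) {
    if (k < 0L) return(invisible(NULL))   # leaf
    if (qualifies(k)) {
      picked <<- c(picked, k)
      return(invisible(NULL))             # maximality: do not descend
    }
    visit(dend$merge[k, 1L])
    visit(dend$merge[k, 2L])
  }
  visit(n_nodes)
  if (length(picked) == 0L) return(list())
  ord <- order(vapply(dend$nodes[picked], `[[`, numeric(1L),
                      "node_correlation"), decreasing = TRUE)
  picked <- picked[ord]
  lapply(seq_along(picked), function(i) {
    nd <- dend$nodes[[picked[[i]]]]
    list(name = sprintf("%s_%d", name_prefix, i),
         genes = nd$members,
         direction = direction,
         node_correlation = nd$node_correlation)
  })
}

#' Score samples by median signature expression
#'
#' The score of a sample for a signature is the median expression of the
#' signature genes present in the matrix; `coverage` records the fraction
#' of signature genes found.
#'
#' @param expr an [expression_matrix()].
#' @param signatures list of signatures ([extract_signatures()] output) or
#'   a named list of character vectors.
#' @return data.frame with columns `signature`, `sample`, `score`,
#'   `coverage`.
#' @export
score_signatures <- function(expr, signatures) {
  sigs <- normalize_signatures(signatures)
  out <- lapply(names(sigs), function(nm) {
    genes <- intersect(sigs[[nm]], rownames(expr$values))
    if (length(genes) == 0L)
      ers_stop("signature '%s' has no genes in the expression matrix", nm)
    cov <- length(genes) / length(sigs[[nm]])
    if (cov < 1)
      ers_log("INFO", sprintf("signature '%s': coverage %.2f", nm, cov))
    sc <- apply(expr$values[genes, , drop = FALSE], 2L, stats::median)
    data.frame(signature = nm, sample = names(sc), score = unname(sc),
               coverage = cov, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

normalize_signatures <- function(signatures) {
  if (length(signatures) == 0L) ers_stop("no signatures given")
  if (!is.null(signatures$genes) && is.character(signatures$genes))
    signatures <- list(signatures)
  if (is.null(names(signatures)) || all(!nzchar(names(signatures)))) {
    nms <- vapply(signatures, function(s)
      if (is.list(s) && !is.null(s$name)) s$name else NA_character_,
      character(1L))
    if (anyNA(nms)) ers_stop("signatures must be named")
    names(signatures) <- nms
  }
  lapply(signatures, function(s) if (is.list(s)) s$genes else s)
}

#' Map a signature between species through an ortholog table
#'
#' Genes without a mapping are dropped (logged); one-to-many mappings
#' expand to all targets; duplicates collapse.
#'
#' @param signature a `GeneSignature` list or plain character vector.
#' @param mapping data.frame whose first column is human and second column
#'   mouse identifiers (as from [read_ortholog_map()]).
#' @param direction `"human_to_mouse"` or `"mouse_to_human"`.
#' @return the signature with mapped gene ids.
#' @export
map_orthologs <- function(signature, mapping,
                          direction = c("human_to_mouse", "mouse_to_human")) {
  direction <- match.arg(direction)
  if (nrow(mapping) == 0L) ers_stop("empty ortholog mapping table")
  if (direction == "mouse_to_human") mapping <- mapping[, 2:1]
  genes <- if (is.list(signature)) signature$genes else signature
  hit <- mapping[mapping[[1L]] %in% genes, , drop = FALSE]
  dropped <- setdiff(genes, hit[[1L]])
  if (length(dropped) > 0L)
    ers_log("INFO", sprintf("%d gene(s) without ortholog dropped",
                            length(dropped)))
  mapped <- unique(hit[[2L]])
  if (length(mapped) == 0L)
    ers_stop("signature maps to zero genes through the ortholog table")
  if (is.list(signature)) {
    signature$genes <- mapped
    signature
  } else mapped
}

#' Hypergeometric over-representation test against a gene-set collection
#'
#' For each reference set, the one-sided hypergeometric tail probability of
#' observing at least the seen overlap with the query, with
#' Benjamini-Hochberg adjustment across the collection.
#'
#' @param query character vector of gene ids (must fit in the universe).
#' @param reference_collection named list of character vectors, or a
#'   [read_gmt()] collection.
#' @param universe_size number of genes in the universe.
#' @return data.frame `set`, `set_size`, `overlap`, `p`, `q`, sorted by p.
#' @export
overlap_test <- function(query, reference_collection, universe_size) {
  sets <- normalize_signatures(reference_collection)
  query <- unique(query)
  n_q <- length(query)
  if (n_q > universe_size)
    ers_stop("query larger than the universe")
  sizes <- lengths(sets)
  if (any(sizes > universe_size))
    ers_stop("universe smaller than reference set '%s'",
             names(sets)[which.max(sizes)])
  ov <- vapply(sets, function(s) length(intersect(query, s)), integer(1L))
  p <- stats::phyper(ov - 1L, sizes, universe_size - sizes, n_q,
                     lower.tail = FALSE)
  out <- data.frame(set = names(sets), set_size = unname(sizes),
                    overlap = unname(ov), p = unname(p),
                    q = stats::p.adjust(unname(p), method = "BH"),
                    stringsAsFactors = FALSE)
  out[order(out$p), , drop = FALSE]
}
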