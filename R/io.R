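## Readers and writers for the external formats the pipeline touches.
## Internal coordinates are 0-based half-open everywhere; SEG output follows
## the SEG convention (1-based inclusive).

#' Construct a validated expression matrix
#'
#' The container used throughout the pipeline: a numeric matrix of log2
#' expression values (genes as rows, samples as columns) plus an optional
#' mapping from sample to group label.
#'
#' @param values numeric matrix with unique rownames (genes) and colnames
#'   (samples). `NA` is allowed (flagged missing); infinite values are not.
#' @param groups optional named character vector, `sample -> group label`.
#' @return an object of class `ExpressionMatrix` (a list with elements
#'   `values` and `groups`).
#' @export
expression_matrix <- function(values, groups = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    ers_stop("expression values must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    ers_stop("expression matrix needs gene rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    ers_stop("duplicate gene identifiers in expression matrix")
  if (anyDuplicated(colnames(values)))
    ers_stop("duplicate sample identifiers in expression matrix")
  if (any(is.infinite(values)))
    ers_stop("expression matrix contains non-finite (infinite) values")
  if (!is.null(groups)) {
    groups <- as.character(groups[colnames(values)])
    if (anyNA(groups))
      ers_stop("group map does not cover every sample of the matrix")
    names(groups) <- colnames(values)
  }
  structure(list(values = values, groups = groups), class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d samples\n",
              nrow(x$values), ncol(x$values)))
  if (!is.null(x$groups)) {
    tab <- table(x$groups)
    cat("groups:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Read a gene x sample expression TSV
#'
#' Expects a header row of sample identifiers and gene identifiers in the
#' first column. Rows sharing a gene identifier are averaged (as is done
#' when several array probes map to the same gene), with a logged count.
#'
#' @param path expression TSV.
#' @param group_path optional two-column TSV (`sample`, `group`); every
#'   sample named there must exist in the matrix.
#' @return an [expression_matrix()].
#' @export
read_expression <- function(path, group_path = NULL) {
  raw <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                           colClasses = "character", sep = "\t")
  if (ncol(raw) < 2L)
    ers_stop("malformed expression header in %s: need gene column plus samples", path)
  genes <- raw[[1L]]
  vals <- as.matrix(raw[, -1L, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals),
                                dimnames = dimnames(vals)))
  bad <- which(is.na(num) & !(vals %in% c("NA", "", "NaN")), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    ers_stop("non-numeric expression value '%s' at gene '%s', sample '%s'",
             vals[bad[1L, 1L], bad[1L, 2L]], genes[bad[1L, 1L]],
             colnames(vals)[bad[1L, 2L]])
  if (anyDuplicated(genes)) {
    ndup <- sum(duplicated(genes))
    ers_log("INFO", sprintf("averaging %d duplicate gene row(s) in %s", ndup, path))
    num <- rowsum(num, group = genes, reorder = FALSE) /
      as.vector(table(factor(genes, levels = unique(genes))))
    genes <- unique(raw[[1L]])
  }
  rownames(num) <- genes
  groups <- NULL
  if (!is.null(group_path)) {
    gm <- utils::read.delim(group_path, header = TRUE, sep = "\t",
                            colClasses = "character")
    unknown <- setdiff(gm[[1L]], colnames(num))
    if (length(unknown) > 0L)
      ers_stop("group map sample(s) not in expression matrix: %s",
               paste(unknown, collapse = ", "))
    groups <- stats::setNames(gm[[2L]], gm[[1L]])
  }
  expression_matrix(num, groups)
}

#' Write an expression matrix as TSV
#' @param expr an [expression_matrix()].
#' @param path output file.
#' @export
write_expression <- function(expr, path) {
  df <- data.frame(gene = rownames(expr$values), expr$values,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}

#' Read a GMT gene-set file
#'
#' @param path GMT file: per line, set name, description, then member gene
#'   identifiers, tab-separated.
#' @return named list; each element has `description` and a character vector
#'   `genes` (unique within the set).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(parts) < 3L)
      ers_stop("GMT line %d has fewer than 3 fields (empty set?)", i)
    genes <- unique(parts[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (length(genes) == 0L)
      ers_stop("GMT line %d defines an empty set", i)
    sets[[parts[[1L]]]] <- list(description = parts[[2L]], genes = genes)
  }
  sets
}

#' Write a GMT gene-set file
#' @param sets named list as returned by [read_gmt()], or a named list of
#'   plain character vectors.
#' @param path output file.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    s <- sets[[nm]]
    if (is.character(s)) s <- list(description = "", genes = s)
    paste(c(nm, if (nzchar(s$description)) s$description else "na", s$genes),
          collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(NULL)
}

#' Read a probe-level log-ratio track
#'
#' @param path TSV with columns `chromosome`, `position` (bp), `log_ratio`.
#'   Probes with missing log-ratio are dropped with a logged count.
#' @return data.frame sorted by (chromosome, position), positions strictly
#'   increasing within each chromosome.
#' @export
read_probe_track <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t")
  names(df)[1:3] <- c("chromosome", "position", "log_ratio")
  probe_track(df)
}

#' Validate a probe track data.frame
#' @param df data.frame with columns chromosome, position, log_ratio.
#' @return the validated (NA-dropped, ordered) data.frame.
#' @export
probe_track <- function(df) {
  stopifnot(all(c("chromosome", "position", "log_ratio") %in% names(df)))
  n_na <- sum(is.na(df$log_ratio))
  if (n_na > 0L) {
    ers_log("INFO", sprintf("dropping %d probe(s) with missing log-ratio", n_na))
    df <- df[!is.na(df$log_ratio), , drop = FALSE]
  }
  if (any(df$position < 0)) ers_stop("probe positions must be >= 0")
  df <- df[order(df$chromosome, df$position), , drop = FALSE]
  dup <- stats::ave(df$position, df$chromosome,
                    FUN = function(p) c(FALSE, diff(p) <= 0))
  if (any(dup == 1))
    ers_stop("probe positions not strictly increasing within a chromosome")
  rownames(df) <- NULL
  df
}

#' Write segments in SEG format (1-based inclusive coordinates)
#'
#' @param segments data.frame with columns `sample`, `chromosome`, `start`,
#'   `end` (internal 0-based half-open), `n_probes`, `seg_mean`.
#' @param path output file.
#' @export
write_seg <- function(segments, path) {
  cols <- c("sample", "chromosome", "start", "end", "n_probes", "seg_mean")
  stopifnot(all(cols %in% names(segments)))
  if (nrow(segments) > 0L) {
    key <- split(segments, list(segments$sample, segments$chromosome), drop = TRUE)
    for (grp in key) {
      grp <- grp[order(grp$start), , drop = FALSE]
      if (nrow(grp) > 1L && any(grp$start[-1L] < grp$end[-nrow(grp)]))
        ers_stop("overlapping segments for sample %s chromosome %s",
                 grp$sample[1L], grp$chromosome[1L])
    }
  }
  out <- data.frame(sample = segments$sample,
                    chromosome = segments$chromosome,
                    start = segments$start + 1L,  # SEG is 1-based inclusive
                    end = segments$end,
                    num_probes = segments$n_probes,
                    seg_mean = segments$seg_mean)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}

#' Read a SEG file back into internal 0-based half-open coordinates
#' @param path SEG file written by [write_seg()].
#' @return segments data.frame.
#' @export
read_seg <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t")
  data.frame(sample = as.character(df$sample),
             chromosome = as.character(df$chromosome),
             start = df$start - 1L,
             end = df$end,
             n_probes = df$num_probes,
             seg_mean = df$seg_mean)
}

#' Read a survival table
#'
#' @param path TSV with columns `sample`, `time`, `event` and optionally
#'   `group`.
#' @return validated data.frame.
#' @export
read_survival <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t")
  survival_table(df)
}

#' Validate a survival table
#' @param df data.frame with `sample`, `time` (>= 0), `event` (0/1) and
#'   optionally `group` columns.
#' @return the validated data.frame.
#' @export
survival_table <- function(df) {
  stopifnot(all(c("sample", "time", "event") %in% names(df)))
  if (any(!is.finite(df$time)) || any(df$time < 0))
    ers_stop("survival times must be finite and >= 0")
  if (!all(df$event %in% c(0, 1)))
    ers_stop("event indicator must be 0 or 1")
  if (nrow(df) > 0L && all(df$time == 0))
    ers_stop("degenerate survival table: all observation times are 0")
  df
}

#' Read a directed edge list
#'
#' Self-loops are dropped (logged) and duplicate edges collapsed.
#'
#' @param path two-column TSV (`from`, `to`), header optional but expected.
#' @return data.frame with columns `from`, `to`.
#' @export
read_network_edges <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character")
  network_edges(df[[1L]], df[[2L]])
}

#' Validate/construct a directed edge list
#' @param from,to character vectors of equal length.
#' @return data.frame `from`,`to` with self-loops dropped and duplicates
#'   collapsed.
#' @export
network_edges <- function(from, to) {
  stopifnot(length(from) == length(to))
  self <- from == to
  if (any(self))
    ers_log("INFO", sprintf("dropping %d self-loop(s)", sum(self)))
  df <- unique(data.frame(from = from[!self], to = to[!self],
                          stringsAsFactors = FALSE))
  rownames(df) <- NULL
  df
}

#' Read a BED-like gene coordinate table
#'
#' @param path TSV with columns `gene`, `chromosome`, `start`, `end`
#'   (0-based half-open, as in BED).
#' @return validated data.frame.
#' @export
read_gene_coords <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t")
  names(df)[1:4] <- c("gene", "chromosome", "start", "end")
  gene_coords(df)
}

#' Validate a gene coordinate table
#' @param df data.frame with gene, chromosome, start, end (0-based half-open).
#' @return the validated data.frame.
#' @export
gene_coords <- function(df) {
  stopifnot(all(c("gene", "chromosome", "start", "end") %in% names(df)))
  if (anyDuplicated(df$gene)) ers_stop("duplicate gene_id in coordinate table")
  if (any(df$start >= df$end)) ers_stop("gene coordinates need start < end")
  df
}

#' Read a two-column ortholog mapping table
#' @param path TSV, first column source identifiers, second column targets.
#' @return data.frame with columns `from`, `to`.
#' @export
read_ortholog_map <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character")
  stats::setNames(df[, 1:2], c("from", "to"))
}
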