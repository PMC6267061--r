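## SWITCHdna-style copy-number analysis: recursive binary segmentation of
## probe-level log-ratio tracks at the split maximizing the two-group
## ANOVA F statistic, with 250 kb minimum flanks, z-score and intensity
## significance filters, segment-to-gene projection, and threshold-based
## gain/loss calls.

#' Segment a probe track by recursive F-statistic splitting
#'
#' Within each chromosome, the candidate breakpoint maximizing the
#' two-group ANOVA F statistic of probe log-ratios is selected among
#' positions with more than `min_region_bp` of chromosome on either side
#' (so aberrations narrower than the flank rule can still be bracketed by
#' two admissible breakpoints, but no breakpoint sits within 250 kb of a
#' chromosome end). A split is
#' accepted while it is significant at the scale of the final filters:
#' the between-side mean difference must reach `intensity_min` and its
#' z-score (difference over `global_sd * sqrt(1/n1 + 1/n2)`, the
#' square-root-of-F scale for a two-group split) must reach `z_min`.
#' Recursion continues on both sides. Of the resulting segments, only
#' those with `|z| >= z_min` and `|seg_mean| >= intensity_min` are
#' reported, where `z = seg_mean / (global_sd / sqrt(n_probes))` and
#' `global_sd` is the standard deviation of all probes of the track.
#'
#' @param track a [probe_track()] data.frame (one sample).
#' @param min_region_bp minimum span of each flank of a breakpoint (bp).
#' @param z_min minimum absolute segment z-score.
#' @param intensity_min minimum absolute segment mean log-ratio.
#' @param min_probes minimum probes per segment.
#' @param sample_id label written into the output.
#' @return data.frame of reported segments: `sample`, `chromosome`,
#'   `start`, `end` (0-based half-open bp), `n_probes`, `seg_mean`,
#'   `z_score`. Internal coordinates put segment boundaries at probe
#'   positions (the end of the last segment extends one probe spacing
#'   beyond its last probe).
#' @export
segment_track <- function(track, min_region_bp = 250000, z_min = 3,
                          intensity_min = 0.09, min_probes = 20L,
                          sample_id = "sample") {
  track <- probe_track(track)
  global_sd <- stats::sd(track$log_ratio)
  out <- lapply(split(track, track$chromosome), function(chr) {
    segment_chromosome(chr, global_sd, min_region_bp, z_min,
                       intensity_min, min_probes, sample_id)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(sample = character(0), chromosome = character(0),
                      start = numeric(0), end = numeric(0),
                      n_probes = integer(0), seg_mean = numeric(0),
                      z_score = numeric(0))
  rownames(out) <- NULL
  out
}

segment_chromosome <- function(chr, global_sd, min_region_bp, z_min,
                               intensity_min, min_probes, sample_id) {
  pos <- chr$position
  x <- chr$log_ratio
  n <- length(pos)
  spacing <- if (n > 1L) stats::median(diff(pos)) else 1
  bound <- c(pos, pos[n] + spacing)  # boundary i..i+1 lies at bound[i+1]
  span <- bound[n + 1L] - bound[1L]
  if (span < 2 * min_region_bp || n < 2L * min_probes) {
    ers_log("INFO", sprintf("chromosome %s too short to segment (%g bp)",
                            chr$chromosome[[1L]], span))
    return(NULL)
  }
  cs <- cumsum(x)

  seg_z <- function(m, k) {
    if (global_sd == 0) return(if (m != 0) Inf else 0)
    m / (global_sd / sqrt(k))
  }

  breaks <- integer(0)  # probe index of last probe of the left side
  recurse <- function(lo, hi) {
    n_here <- hi - lo + 1L
    if (n_here < 2L * min_probes) return(invisible(NULL))
    j <- (lo + min_probes - 1L):(hi - min_probes)  # split after probe j
    if (length(j) == 0L) return(invisible(NULL))
    ok <- (bound[j + 1L] - bound[1L] > min_region_bp) &
      (bound[n + 1L] - bound[j + 1L] > min_region_bp)
    j <- j[ok]
    if (length(j) == 0L) return(invisible(NULL))
    n1 <- j - lo + 1L
    n2 <- hi - j
    s1 <- cs[j] - (if (lo > 1L) cs[lo - 1L] else 0)
    s2 <- (cs[hi] - cs[j])
    m1 <- s1 / n1
    m2 <- s2 / n2
    dm <- m2 - m1
    ## maximizing the two-group ANOVA F over splits == maximizing
    ## SSB = n1*n2/(n1+n2) * (m1-m2)^2 given fixed total SS; leftmost max
    ssb <- n1 * n2 / (n1 + n2) * dm^2
    best <- which.max(ssb)
    jb <- j[best]
    dmb <- abs(dm[best])
    z_split <- if (global_sd == 0) (if (dmb > 0) Inf else 0) else
      dmb / (global_sd * sqrt(1 / n1[best] + 1 / n2[best]))
    if (dmb < intensity_min || z_split < z_min) return(invisible(NULL))
    breaks <<- c(breaks, jb)
    recurse(lo, jb)
    recurse(jb + 1L, hi)
  }
  recurse(1L, n)

  ## refinement: re-fit each breakpoint within the window bounded by its
  ## neighbors (backfitting), which removes the localization bias a
  ## greedy first split inherits from other change-points in its window
  best_split <- function(lo, hi) {
    if (hi - lo + 1L < 2L) return(NULL)
    j <- lo:(hi - 1L)
    ok <- (bound[j + 1L] - bound[1L] > min_region_bp) &
      (bound[n + 1L] - bound[j + 1L] > min_region_bp)
    j <- j[ok]
    if (length(j) == 0L) return(NULL)
    n1 <- j - lo + 1L
    n2 <- hi - j
    m1 <- (cs[j] - (if (lo > 1L) cs[lo - 1L] else 0)) / n1
    m2 <- (cs[hi] - cs[j]) / n2
    ssb <- n1 * n2 / (n1 + n2) * (m2 - m1)^2
    best <- which.max(ssb)
    dmb <- abs(m2[best] - m1[best])
    z_split <- if (global_sd == 0) (if (dmb > 0) Inf else 0) else
      dmb / (global_sd * sqrt(1 / n1[best] + 1 / n2[best]))
    list(j = j[best], dm = dmb, z = z_split)
  }
  if (length(breaks) > 0L) {
    breaks <- sort(unique(breaks))
    for (pass in 1:10) {
      prev <- breaks
      k <- 1L
      while (k <= length(breaks)) {
        lo <- if (k == 1L) 1L else breaks[k - 1L] + 1L
        hi <- if (k == length(breaks)) n else breaks[k + 1L]
        s <- best_split(lo, hi)
        if (is.null(s) || s$dm < intensity_min || s$z < z_min) {
          breaks <- breaks[-k]          # no longer a significant change
        } else {
          breaks[k] <- s$j
          k <- k + 1L
        }
      }
      breaks <- sort(unique(breaks))
      if (identical(breaks, prev)) break
    }
  }

  cuts <- sort(unique(c(0L, breaks, n)))
  segs <- lapply(seq_len(length(cuts) - 1L), function(k) {
    lo <- cuts[k] + 1L; hi <- cuts[k + 1L]
    m <- mean(x[lo:hi])
    data.frame(sample = sample_id, chromosome = chr$chromosome[[1L]],
               start = bound[lo], end = bound[hi + 1L],
               n_probes = hi - lo + 1L, seg_mean = m,
               z_score = seg_z(m, hi - lo + 1L))
  })
  segs <- do.call(rbind, segs)
  keep <- abs(segs$z_score) >= z_min & abs(segs$seg_mean) >= intensity_min &
    segs$n_probes >= min_probes
  segs[keep, , drop = FALSE]
}

#' Project segment means onto genes
#'
#' A gene inherits the length-weighted mean of the reported segments it
#' overlaps, with uncovered gene territory contributing 0 (so a gene half
#' inside a segment of mean -0.4 gets -0.2). Genes overlapping no segment
#' get 0.
#'
#' @param segments output of [segment_track()] (one or more samples).
#' @param coords a [gene_coords()] table.
#' @return data.frame `sample`, `gene`, `cn_value`.
#' @export
project_to_genes <- function(segments, coords) {
  coords <- gene_coords(coords)
  samples <- unique(segments$sample)
  if (length(samples) == 0L) samples <- "sample"
  out <- lapply(samples, function(s) {
    seg <- segments[segments$sample == s, , drop = FALSE]
    cn <- stats::setNames(numeric(nrow(coords)), coords$gene)
    for (chr in unique(seg$chromosome)) {
      sc <- seg[seg$chromosome == chr, , drop = FALSE]
      gc <- coords[coords$chromosome == chr, , drop = FALSE]
      if (nrow(gc) == 0L) next
      gr <- IRanges::IRanges(start = gc$start + 1L, end = gc$end)
      sr <- IRanges::IRanges(start = sc$start + 1L, end = sc$end)
      hits <- IRanges::findOverlaps(gr, sr)
      if (length(hits) == 0L) next
      ov <- IRanges::width(IRanges::pintersect(
        gr[S4Vectors::queryHits(hits)], sr[S4Vectors::subjectHits(hits)]))
      contrib <- ov * sc$seg_mean[S4Vectors::subjectHits(hits)]
      agg <- rowsum(contrib, group = gc$gene[S4Vectors::queryHits(hits)])
      cn[rownames(agg)] <- agg[, 1L] /
        (gc$end - gc$start)[match(rownames(agg), gc$gene)]
    }
    data.frame(sample = s, gene = names(cn), cn_value = unname(cn),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Call gains and losses from gene-level copy-number values
#'
#' @param gene_cn data.frame with a `cn_value` column (e.g. from
#'   [project_to_genes()]).
#' @param gain_threshold call `gain` when `cn_value >=` this (default 0.25).
#' @param loss_threshold call `loss` when `cn_value <=` this (default -0.32).
#' @return `gene_cn` with a `call` column in {loss, neutral, gain}.
#' @export
call_gains_losses <- function(gene_cn, gain_threshold = 0.25,
                              loss_threshold = -0.32) {
  if (gain_threshold <= loss_threshold)
    ers_stop("gain threshold must exceed loss threshold")
  if (any(!is.finite(gene_cn$cn_value)))
    ers_stop("non-finite copy-number values")
  gene_cn$call <- ifelse(gene_cn$cn_value >= gain_threshold, "gain",
                         ifelse(gene_cn$cn_value <= loss_threshold,
                                "loss", "neutral"))
  gene_cn
}

#' Deleted / non-deleted labels from categorical (GISTIC-like) codes
#'
#' @param codes integer codes in {-2, -1, 0, 1, 2} (named by sample if
#'   desired). -2 is a possibly homozygous and -1 a possibly heterozygous
#'   deletion.
#' @param loss_codes codes counted as deleted.
#' @return logical vector, `TRUE` where deleted.
#' @export
categorical_loss_filter <- function(codes, loss_codes = c(-1L, -2L)) {
  if (!all(codes %in% -2:2))
    ers_stop("unknown categorical copy-number code: %s",
             paste(setdiff(unique(codes), -2:2), collapse = ", "))
  stats::setNames(codes %in% loss_codes, names(codes))
}

#' Per-bin alteration frequencies by group
#'
#' For each genomic bin and sample group, the fraction of samples with at
#' least one gene called `gain` (resp. `loss`) overlapping the bin.
#'
#' @param gene_calls data.frame `sample`, `gene`, `cn_value`, `call` (from
#'   [call_gains_losses()]), covering every sample.
#' @param coords a [gene_coords()] table for the genes.
#' @param group_map named character vector, sample -> group.
#' @param bin_bp bin width in bp (default 1 Mb).
#' @return data.frame `chromosome`, `bin_start`, `bin_end`, `group`,
#'   `gain_freq`, `loss_freq`.
#' @export
alteration_frequency <- function(gene_calls, coords, group_map,
                                 bin_bp = 1e6) {
  coords <- gene_coords(coords)
  if (!all(gene_calls$sample %in% names(group_map)))
    ers_stop("group map does not cover every sample with calls")
  gene_calls <- merge(gene_calls, coords, by = "gene")
  out <- list()
  for (chr in unique(coords$chromosome)) {
    gc <- gene_calls[gene_calls$chromosome == chr, , drop = FALSE]
    lim <- max(coords$end[coords$chromosome == chr])
    starts <- seq(0, lim - 1, by = bin_bp)
    for (grp in unique(group_map)) {
      samp <- names(group_map)[group_map == grp]
      sub <- gc[gc$sample %in% samp, , drop = FALSE]
      gain_f <- loss_f <- numeric(length(starts))
      for (b in seq_along(starts)) {
        b0 <- starts[b]; b1 <- min(b0 + bin_bp, lim)
        inbin <- sub$start < b1 & sub$end > b0
        gain_f[b] <- length(unique(sub$sample[inbin & sub$call == "gain"])) /
          length(samp)
        loss_f[b] <- length(unique(sub$sample[inbin & sub$call == "loss"])) /
          length(samp)
      }
      out[[length(out) + 1L]] <- data.frame(
        chromosome = chr, bin_start = starts,
        bin_end = pmin(starts + bin_bp, lim), group = grp,
        gain_freq = gain_f, loss_freq = loss_f)
    }
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
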