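## Synthetic cohorts with planted ground truth: differential expression,
## a co-expressed module, copy-number segments, a network driver, and
## survival structure. Every downstream stage of the pipeline can be
## validated against what was planted.

#' Simulation configuration
#'
#' Defaults describe the study conditions emulated throughout the package:
#' a two-arm treated/untreated expression design plus a "resistant" arm
#' carrying a planted chromosome-4 deletion spanning the planted driver,
#' aCGH-like probe tracks at 200 bp spacing, and exponential survival whose
#' hazard depends on a planted signature score.
#'
#' @param seed master seed; per-component streams are derived with
#'   [spawn_seed()] so components do not perturb each other.
#' @param n_genes total genes in the expression universe.
#' @param n_samples_per_group named integer vector of group sizes.
#' @param n_de_genes number of planted differentially expressed genes.
#' @param de_effect log2 shift applied to DE genes in treated samples.
#' @param module_size,module_correlation size and target pairwise Pearson
#'   correlation of the planted co-expressed module.
#' @param chrom_length_bp length of the simulated chromosome carrying probes.
#' @param probe_spacing_bp spacing between contiguous probes (bp).
#' @param planted_segments data.frame with columns `chromosome`, `start`,
#'   `end` (0-based half-open bp), `mean_shift`, `group` (the sample group
#'   that carries the aberration).
#' @param probe_noise_sd standard deviation of probe-level noise.
#' @param n_network_genes nodes in the simulated interaction network.
#' @param planted_driver gene id of the planted driver.
#' @param driver_neighbor_effect log2 shift applied to the driver's
#'   out-neighbors in resistant samples.
#' @param driver_loss_effect downward log2 expression shift of the driver
#'   itself in resistant samples.
#' @param baseline_hazard,signature_log_hazard_ratio exponential survival
#'   model parameters: hazard = baseline * exp(logHR * standardized score).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 1000L,
                       n_samples_per_group = c(untreated = 10L, treated = 10L,
                                               resistant = 20L),
                       n_de_genes = 50L,
                       de_effect = 2,
                       module_size = 20L,
                       module_correlation = 0.8,
                       chrom_length_bp = 1e6,
                       probe_spacing_bp = 200L,
                       planted_segments = data.frame(
                         chromosome = "chr4", start = 4e5, end = 6e5,
                         mean_shift = -0.5, group = "resistant"),
                       probe_noise_sd = 0.2,
                       n_network_genes = 300L,
                       planted_driver = "DRV1",
                       driver_neighbor_effect = 2,
                       driver_loss_effect = 1.5,
                       baseline_hazard = 0.1,
                       signature_log_hazard_ratio = 1) {
  cfg <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
              n_samples_per_group = n_samples_per_group,
              n_de_genes = as.integer(n_de_genes), de_effect = de_effect,
              module_size = as.integer(module_size),
              module_correlation = module_correlation,
              chrom_length_bp = chrom_length_bp,
              probe_spacing_bp = as.integer(probe_spacing_bp),
              planted_segments = planted_segments,
              probe_noise_sd = probe_noise_sd,
              n_network_genes = as.integer(n_network_genes),
              planted_driver = planted_driver,
              driver_neighbor_effect = driver_neighbor_effect,
              driver_loss_effect = driver_loss_effect,
              baseline_hazard = baseline_hazard,
              signature_log_hazard_ratio = signature_log_hazard_ratio)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (n_genes <= 0L || any(n_samples_per_group <= 0L) || n_network_genes <= 0L)
      ers_stop("all counts in the simulation config must be positive")
    if (is.null(names(n_samples_per_group)))
      ers_stop("n_samples_per_group must be a named vector of group sizes")
    if (module_correlation <= 0 || module_correlation >= 1)
      ers_stop("module_correlation must lie in (0, 1)")
    if (probe_spacing_bp < 1L) ers_stop("probe_spacing_bp must be >= 1")
    if (n_de_genes + module_size > n_genes)
      ers_stop("n_de_genes + module_size exceeds n_genes")
    ps <- planted_segments
    if (nrow(ps) > 0L) {
      if (any(ps$start < 0) || any(ps$end > chrom_length_bp) ||
          any(ps$start >= ps$end))
        ers_stop("planted segments must lie within [0, chrom_length_bp)")
      for (chr in unique(ps$chromosome)) {
        s <- ps[ps$chromosome == chr, , drop = FALSE]
        s <- s[order(s$start), , drop = FALSE]
        if (nrow(s) > 1L && any(s$start[-1L] < s$end[-nrow(s)]))
          ers_stop("planted segments overlap on %s", chr)
      }
    }
  })
  invisible(cfg)
}

gene_universe <- function(cfg) {
  ids <- sprintf("G%04d", seq_len(cfg$n_genes))
  ids[1L] <- cfg$planted_driver
  ids
}

#' Simulate a two-class expression matrix with planted structure
#'
#' Background genes are i.i.d. Normal(0, 1) across samples. The planted DE
#' genes receive an additive `de_effect` shift in every non-"untreated"
#' group. The planted module is driven by a single latent factor per sample:
#' `x = sqrt(rho) * f + sqrt(1 - rho) * eps`, which yields pairwise
#' correlation `rho` in expectation.
#'
#' @param config a [sim_config()].
#' @return list with `expr` (an [expression_matrix()]) and `truth`
#'   (`de_genes`, `module_genes`).
#' @export
simulate_expression <- function(config) {
  cfg <- validate_sim_config(config)
  genes <- gene_universe(cfg)
  groups <- rep(names(cfg$n_samples_per_group), cfg$n_samples_per_group)
  n <- length(groups)
  samples <- sprintf("S%03d", seq_len(n))
  set.seed(spawn_seed(cfg$seed, "expression"))
  x <- matrix(stats::rnorm(cfg$n_genes * n), nrow = cfg$n_genes,
              dimnames = list(genes, samples))
  ## driver (row 1) stays out of the DE/module universes
  pool <- genes[-1L]
  de_genes <- pool[seq_len(cfg$n_de_genes)]
  module_genes <- pool[cfg$n_de_genes + seq_len(cfg$module_size)]
  treated <- groups != "untreated"
  x[de_genes, treated] <- x[de_genes, treated] + cfg$de_effect
  rho <- cfg$module_correlation
  f <- stats::rnorm(n)
  x[module_genes, ] <- sqrt(rho) * matrix(f, cfg$module_size, n, byrow = TRUE) +
    sqrt(1 - rho) * x[module_genes, ]
  expr <- expression_matrix(x, stats::setNames(groups, samples))
  list(expr = expr, truth = list(de_genes = de_genes,
                                 module_genes = module_genes))
}

#' Simulate an aCGH-like probe track for one sample
#'
#' Probes tile `[0, chrom_length_bp)` every `probe_spacing_bp`. The
#' log-ratio of a probe is the `mean_shift` of a planted segment when the
#' probe lies inside it and `sample_group` carries the aberration, plus
#' Normal(0, `probe_noise_sd`) noise.
#'
#' @param config a [sim_config()].
#' @param sample_group group label of the simulated sample.
#' @param chromosome chromosome label for the track.
#' @param seed optional explicit seed (defaults to a stream derived from
#'   the config's master seed and the group label).
#' @return a [probe_track()] data.frame.
#' @export
simulate_probe_track <- function(config, sample_group,
                                 chromosome = NULL, seed = NULL) {
  cfg <- validate_sim_config(config)
  ps <- cfg$planted_segments
  chromosome <- chromosome %||%
    (if (nrow(ps) > 0L) ps$chromosome[[1L]] else "chr1")
  if (is.null(seed))
    seed <- spawn_seed(cfg$seed, paste0("probes:", sample_group))
  set.seed(seed)
  pos <- seq(0L, cfg$chrom_length_bp - 1L, by = cfg$probe_spacing_bp)
  lr <- stats::rnorm(length(pos), sd = cfg$probe_noise_sd)
  carried <- ps[ps$chromosome == chromosome & ps$group == sample_group, ,
                drop = FALSE]
  for (i in seq_len(nrow(carried))) {
    inside <- pos >= carried$start[[i]] & pos < carried$end[[i]]
    lr[inside] <- lr[inside] + carried$mean_shift[[i]]
  }
  probe_track(data.frame(chromosome = chromosome, position = pos,
                         log_ratio = lr))
}

#' Simulate a directed scale-free interaction network
#'
#' Preferential-attachment growth (heavy-tailed degrees); edges are oriented
#' out of the older, better-connected node, and the planted driver is
#' assigned to the highest-out-degree node so it has at least 5 out-neighbors.
#'
#' @param config a [sim_config()].
#' @return list with `edges` (data.frame `from`,`to`) and `truth`
#'   (`driver`, `driver_out_neighbors`).
#' @export
simulate_network <- function(config) {
  cfg <- validate_sim_config(config)
  if (cfg$n_network_genes < 10L) ers_stop("n_network_genes must be >= 10")
  set.seed(spawn_seed(cfg$seed, "network"))
  g <- igraph::sample_pa(cfg$n_network_genes, m = 3, directed = TRUE)
  ## sample_pa points each new vertex at older ones; flip so hubs emit edges
  el <- igraph::as_edgelist(g, names = FALSE)
  el <- el[, 2:1, drop = FALSE]
  ## network nodes are the first n_network_genes of the gene universe,
  ## with the driver mapped to the top out-degree hub
  ids <- gene_universe(cfg)[seq_len(cfg$n_network_genes)]
  outdeg <- tabulate(el[, 1L], nbins = cfg$n_network_genes)
  hub <- which.max(outdeg)
  node_ids <- character(cfg$n_network_genes)
  node_ids[hub] <- cfg$planted_driver
  node_ids[-hub] <- ids[-1L]
  edges <- network_edges(node_ids[el[, 1L]], node_ids[el[, 2L]])
  out_nb <- unique(edges$to[edges$from == cfg$planted_driver])
  if (length(out_nb) < 5L)
    ers_stop("planted driver has out-degree < 5; increase n_network_genes")
  list(edges = edges,
       truth = list(driver = cfg$planted_driver, driver_out_neighbors = out_nb))
}

#' Simulate survival times whose hazard depends on a signature score
#'
#' Exponential event times with hazard
#' `baseline_hazard * exp(signature_log_hazard_ratio * z(score))` where
#' `z()` standardizes the scores, plus independent uniform censoring on
#' `[0, 2 / baseline_hazard]`.
#'
#' @param scores named numeric vector, one signature score per sample.
#' @param config a [sim_config()].
#' @param seed optional explicit seed.
#' @return a [survival_table()] data.frame.
#' @export
simulate_survival <- function(scores, config, seed = NULL) {
  cfg <- validate_sim_config(config)
  if (any(!is.finite(scores))) ers_stop("signature scores must be finite")
  if (is.null(seed)) seed <- spawn_seed(cfg$seed, "survival")
  set.seed(seed)
  z <- if (stats::sd(scores) > 0) as.vector(scale(scores)) else scores * 0
  hazard <- cfg$baseline_hazard * exp(cfg$signature_log_hazard_ratio * z)
  t_event <- stats::rexp(length(scores), rate = hazard)
  t_cens <- stats::runif(length(scores), 0, 2 / cfg$baseline_hazard)
  survival_table(data.frame(
    sample = names(scores) %||% sprintf("S%03d", seq_along(scores)),
    time = pmin(t_event, t_cens),
    event = as.integer(t_event <= t_cens)))
}

#' Simulate a full cohort with a planted resistance driver
#'
#' Ties the individual generators together the way the modelled biology
#' ties them: the planted driver sits inside the planted deletion (carried
#' only by "resistant" samples); the planted co-expressed module genes are
#' wired as out-neighbors of the driver and additionally shifted up by
#' `driver_neighbor_effect` in resistant samples, while the driver's own
#' expression is shifted down; survival hazard follows the module
#' signature score.
#'
#' @param config a [sim_config()].
#' @return list with `expr`, `edges`, `tracks` (per-sample probe tracks),
#'   `coords` (gene coordinates for network genes), `surv`, and `truth`.
#' @export
simulate_cohort <- function(config) {
  cfg <- validate_sim_config(config)
  if (cfg$n_de_genes + cfg$module_size + 1L > cfg$n_network_genes)
    ers_stop("cohort simulation needs DE and module genes inside the network")
  net <- simulate_network(cfg)
  sim <- simulate_expression(cfg)
  expr <- sim$expr
  groups <- expr$groups

  ## wire the co-expressed module as the driver's out-neighborhood
  module_genes <- sim$truth$module_genes
  de_genes <- sim$truth$de_genes
  edges <- network_edges(c(net$edges$from, rep(cfg$planted_driver,
                                               length(module_genes))),
                         c(net$edges$to, module_genes))

  resistant <- groups == "resistant"
  expr$values[module_genes, resistant] <-
    expr$values[module_genes, resistant] + cfg$driver_neighbor_effect
  expr$values[cfg$planted_driver, resistant] <-
    expr$values[cfg$planted_driver, resistant] - cfg$driver_loss_effect

  ## probe track per sample; resistant samples carry the planted segments
  tracks <- lapply(names(groups), function(s)
    simulate_probe_track(cfg, groups[[s]],
                         seed = spawn_seed(cfg$seed, paste0("probes:", s))))
  names(tracks) <- names(groups)

  coords <- cohort_gene_coords(cfg)
  score <- apply(expr$values[module_genes, , drop = FALSE], 2L, stats::median)
  surv <- simulate_survival(score, cfg)
  surv$group <- groups[surv$sample]

  list(expr = expr, edges = edges, tracks = tracks, coords = coords,
       surv = surv,
       truth = list(de_genes = de_genes, module_genes = module_genes,
                    driver = cfg$planted_driver,
                    segments = cfg$planted_segments,
                    signature_score = score))
}

## coordinates for the network genes: the driver plus a few others inside
## the planted deletion, the rest tiled on chr1
cohort_gene_coords <- function(cfg) {
  ids <- gene_universe(cfg)[seq_len(cfg$n_network_genes)]
  ps <- cfg$planted_segments
  chr_alt <- if (nrow(ps) > 0L) ps$chromosome[[1L]] else "chr4"
  lo <- if (nrow(ps) > 0L) ps$start[[1L]] else 0
  hi <- if (nrow(ps) > 0L) ps$end[[1L]] else cfg$chrom_length_bp
  n_in <- min(10L, length(ids))
  inside <- ids[seq_len(n_in)]     # includes the driver (slot 1)
  outside <- setdiff(ids, inside)
  w <- floor((hi - lo) / n_in)
  co_in <- data.frame(gene = inside, chromosome = chr_alt,
                      start = lo + (seq_len(n_in) - 1L) * w,
                      end = lo + (seq_len(n_in) - 1L) * w + min(1e4, w - 1))
  co_out <- data.frame(gene = outside, chromosome = "chr1",
                       start = (seq_along(outside) - 1L) * 5e4,
                       end = (seq_along(outside) - 1L) * 5e4 + 1e4)
  gene_coords(rbind(co_in, co_out))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
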