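## Group construction and survival comparison: signature-score tertiles,
## follow-up truncation, Kaplan-Meier curves, two-sided log-rank tests and
## univariate Cox regression (Breslow ties), wrapping the survival package.

#' Split samples into score tertiles
#'
#' Rank-order split into `lower`, `middle`, `top` thirds. When the sample
#' count is not divisible by 3, remainders go to the lower groups first
#' (10 samples -> 4/3/3). Ties are broken by stable input order, with a
#' warning.
#'
#' @param scores named numeric vector of signature scores (>= 3 samples).
#' @return named character vector of labels in {lower, middle, top}.
#' @export
stratify_tertiles <- function(scores) {
  n <- length(scores)
  if (n < 3L) ers_stop("tertile stratification needs >= 3 samples")
  if (any(!is.finite(scores))) ers_stop("scores must be finite")
  if (anyDuplicated(scores))
    ers_warn("tied scores broken by stable sample order")
  o <- order(scores)  # stable: ties keep input order
  base <- n %/% 3L
  rem <- n %% 3L
  sizes <- c(lower = base + (rem >= 1L), middle = base + (rem >= 2L),
             top = base)
  labels <- rep(c("lower", "middle", "top"), times = sizes)
  stats::setNames(labels[order(o)], names(scores))
}

#' Drop records beyond a follow-up horizon
#'
#' @param table a [survival_table()].
#' @param max_years records with `time >` this are removed (strict, so a
#'   record at exactly the horizon is retained); count logged.
#' @return the filtered table.
#' @export
filter_followup <- function(table, max_years = 20) {
  drop <- table$time > max_years
  if (any(drop))
    ers_log("INFO", sprintf("excluding %d record(s) with follow-up > %g years",
                            sum(drop), max_years))
  table[!drop, , drop = FALSE]
}

#' Kaplan-Meier curve for one group
#'
#' @param table a [survival_table()].
#' @param group optional group label to subset on (`table$group`).
#' @return data.frame `time`, `n_risk`, `n_event`, `surv` (product-limit
#'   estimate, starting at 1 and non-increasing).
#' @export
km_estimate <- function(table, group = NULL) {
  if (!is.null(group)) {
    table <- table[table$group == group, , drop = FALSE]
    if (nrow(table) == 0L) ers_stop("no records in group '%s'", group)
  }
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = table)
  data.frame(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
             surv = fit$surv)
}

#' Two-sided log-rank test between two groups
#'
#' @param table a [survival_table()] with a `group` column.
#' @param group_a,group_b the two group labels to compare.
#' @return list `chisq`, `p` (two-sided, 1 df), `n` (per-group sizes),
#'   `n_events`.
#' @export
logrank_test <- function(table, group_a, group_b) {
  sub <- table[table$group %in% c(group_a, group_b), , drop = FALSE]
  if (!all(c(group_a, group_b) %in% sub$group))
    ers_stop("both groups must be non-empty")
  if (sum(sub$event) == 0L) {
    ers_warn("no events in either group; log-rank p set to 1")
    return(list(chisq = 0, p = 1,
                n = table(sub$group)[c(group_a, group_b)], n_events = 0L))
  }
  sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = sub)
  chisq <- sd$chisq
  list(chisq = chisq, p = stats::pchisq(chisq, df = 1L, lower.tail = FALSE),
       n = sd$n, n_events = sum(sub$event))
}

#' Univariate Cox proportional-hazards regression (Breslow ties)
#'
#' @param table a [survival_table()].
#' @param covariate per-sample numeric (or 0/1) covariate aligned with the
#'   table rows.
#' @return list `beta` (log hazard ratio), `se`, `p` (Wald), `n`,
#'   `n_events`. A constant covariate returns `beta = 0` exactly (no
#'   information) with a warning; monotone likelihood (perfect separation)
#'   is an error.
#' @export
cox_univariate <- function(table, covariate) {
  if (length(covariate) != nrow(table))
    ers_stop("covariate length must match the survival table")
  if (any(!is.finite(covariate))) ers_stop("covariate must be finite")
  if (sum(table$event) < 1L) ers_stop("Cox regression needs >= 1 event")
  if (stats::sd(covariate) == 0) {
    ers_warn("constant covariate carries no information; beta = 0")
    return(list(beta = 0, se = Inf, p = 1, n = nrow(table),
                n_events = sum(table$event)))
  }
  df <- data.frame(time = table$time, event = table$event, x = covariate)
  diverged <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(time, event) ~ x, data = df,
                    ties = "breslow"),
    warning = function(w) {
      if (grepl("infinite|converge", conditionMessage(w))) {
        diverged <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  if (diverged || abs(stats::coef(fit)[[1L]]) > 15)
    ers_stop(paste("monotone partial likelihood: the covariate perfectly",
                   "separates events (degenerate covariate?)"))
  s <- summary(fit)
  list(beta = unname(stats::coef(fit)[[1L]]),
       se = unname(s$coefficients[1L, "se(coef)"]),
       p = unname(s$coefficients[1L, "Pr(>|z|)"]),
       n = nrow(df), n_events = sum(df$event))
}

#' Joint stratification and pairwise log-rank comparison
#'
#' Crosses two label sets (e.g. deletion status x signature tertile) and
#' runs all pairwise two-sided log-rank tests with Benjamini-Hochberg
#' adjustment.
#'
#' @param table a [survival_table()].
#' @param labels_a,labels_b named character vectors (sample -> label).
#' @return list `groups` (sample -> crossed label) and `comparisons`
#'   (data.frame `group_a`, `group_b`, `chisq`, `p`, `q`).
#' @export
stratify_cross <- function(table, labels_a, labels_b) {
  common <- intersect(names(labels_a), names(labels_b))
  cross <- stats::setNames(paste(labels_a[common], labels_b[common],
                                 sep = "/"), common)
  tab <- table[table$sample %in% common, , drop = FALSE]
  tab$group <- cross[tab$sample]
  lvls <- unique(tab$group)
  if (length(lvls) < 2L) ers_stop("need >= 2 crossed groups")
  pairs <- utils::combn(lvls, 2L)
  cmp <- lapply(seq_len(ncol(pairs)), function(k) {
    lr <- logrank_test(tab, pairs[1L, k], pairs[2L, k])
    data.frame(group_a = pairs[1L, k], group_b = pairs[2L, k],
               chisq = lr$chisq, p = lr$p, stringsAsFactors = FALSE)
  })
  cmp <- do.call(rbind, cmp)
  cmp$q <- stats::p.adjust(cmp$p, method = "BH")
  list(groups = cross, comparisons = cmp)
}
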