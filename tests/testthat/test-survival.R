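test_that("tertile stratification splits by rank with remainders low first", {
  sc9 <- setNames(c(5, 1, 9, 3, 7, 2, 8, 4, 6), paste0("p", 1:9))
  lab <- stratify_tertiles(sc9)
  expect_equal(unname(table(lab)[c("lower", "middle", "top")]),
               c(3L, 3L, 3L), ignore_attr = TRUE)
  expect_setequal(names(lab)[lab == "top"],
                  names(sort(sc9, decreasing = TRUE))[1:3])

  sc10 <- setNames(1:10, paste0("p", 1:10))
  lab10 <- stratify_tertiles(sc10)
  expect_equal(as.integer(table(lab10)[c("lower", "middle", "top")]),
               c(4L, 3L, 3L))

  expect_warning(labt <- stratify_tertiles(setNames(rep(1, 6), paste0("p", 1:6))),
                 "tied")
  expect_equal(as.integer(table(labt)), c(2L, 2L, 2L))
  expect_error(stratify_tertiles(c(a = 1, b = 2)), ">= 3")
})

test_that("follow-up filtering is strict at the horizon", {
  tab <- survival_table(data.frame(sample = c("a", "b", "c"),
                                   time = c(25, 20, 5),
                                   event = c(1, 0, 1)))
  kept <- suppressMessages(filter_followup(tab, 20))
  expect_setequal(kept$sample, c("b", "c"))   # exactly 20 retained
  expect_equal(nrow(filter_followup(tab[0, ], 20)), 0L)
})

test_that("Kaplan-Meier estimates follow the product-limit arithmetic", {
  tab <- survival_table(data.frame(sample = paste0("p", 1:3),
                                   time = c(1, 2, 3), event = 1))
  km <- km_estimate(tab)
  expect_equal(km$surv, c(2/3, 1/3, 0), tolerance = 1e-12)
  expect_equal(km$n_risk, c(3, 2, 1))

  # all censored: constant 1
  tabc <- survival_table(data.frame(sample = paste0("p", 1:4),
                                    time = 1:4, event = 0))
  expect_true(all(km_estimate(tabc)$surv == 1))

  # single subject with an event: step from 1 to 0
  tab1 <- survival_table(data.frame(sample = "p", time = 2, event = 1))
  expect_equal(km_estimate(tab1)$surv, 0)

  # curves are non-increasing within [0, 1], at-risk non-increasing
  cfg <- sim_config(seed = 3)
  sc <- setNames(rnorm(50), sprintf("P%02d", 1:50))
  tabr <- simulate_survival(sc, cfg)
  kmr <- km_estimate(tabr)
  expect_true(all(diff(kmr$surv) <= 1e-12))
  expect_true(all(kmr$surv >= 0 & kmr$surv <= 1))
  expect_true(all(diff(kmr$n_risk) <= 0))
})

test_that("log-rank matches the by-hand oracle and is label-symmetric", {
  tab <- survival_table(data.frame(sample = paste0("p", 1:4),
                                   time = c(1, 3, 2, 4), event = 1,
                                   group = c("A", "A", "B", "B")))
  lr <- logrank_test(tab, "A", "B")
  oracle <- hand_logrank(tab$time, tab$event, tab$group)
  expect_equal(lr$chisq, oracle, tolerance = 1e-4)
  expect_equal(lr$p, pchisq(oracle, 1, lower.tail = FALSE), tolerance = 1e-4)
  lr_swap <- logrank_test(tab, "B", "A")
  expect_equal(lr$chisq, lr_swap$chisq, tolerance = 1e-12)

  # identical groups: statistic 0, p 1
  dup <- rbind(transform(tab, group = "A"), transform(tab, group = "B"))
  lr0 <- logrank_test(survival_table(dup), "A", "B")
  expect_equal(lr0$chisq, 0, tolerance = 1e-12)
  expect_equal(lr0$p, 1)

  # zero events: p = 1 with a warning
  none <- survival_table(data.frame(sample = paste0("p", 1:4),
                                    time = 1:4, event = 0,
                                    group = c("A", "A", "B", "B")))
  expect_warning(lrn <- logrank_test(none, "A", "B"), "no events")
  expect_equal(lrn$p, 1)
})

test_that("Cox estimates maximize the Breslow partial likelihood", {
  tab <- survival_table(data.frame(
    sample = paste0("p", 1:6),
    time = c(2, 4, 4, 6, 8, 9),
    event = c(1, 1, 0, 1, 1, 0)))
  x <- c(0.5, -1.2, 0.8, 1.5, -0.3, 0.1)
  fit <- cox_univariate(tab, x)
  grid <- seq(-3, 3, by = 1e-4)
  ll <- vapply(grid, breslow_loglik, numeric(1),
               time = tab$time, event = tab$event, x = x)
  expect_equal(fit$beta, grid[which.max(ll)], tolerance = 1e-3)
  # partial likelihood at the estimate is no worse than at zero
  expect_gte(breslow_loglik(fit$beta, tab$time, tab$event, x),
             breslow_loglik(0, tab$time, tab$event, x))

  # constant covariate: exactly zero information
  expect_warning(fit0 <- cox_univariate(tab, rep(2, 6)), "constant")
  expect_identical(fit0$beta, 0)

  # perfect separation is refused
  sep <- survival_table(data.frame(sample = paste0("p", 1:6),
                                   time = 1:6, event = 1))
  expect_error(cox_univariate(sep, -(1:6)), "monotone|degenerate")
})

test_that("cross-stratification builds crossed groups with BH-adjusted tests", {
  cfg <- sim_config(seed = 12, signature_log_hazard_ratio = 1.5)
  sc <- setNames(rnorm(90), sprintf("P%02d", 1:90))
  tab <- simulate_survival(sc, cfg)
  del <- setNames(rep(c("del", "wt"), length.out = 90), names(sc))
  tert <- stratify_tertiles(sc)
  res <- stratify_cross(tab, del, tert)
  expect_setequal(unique(res$groups),
                  as.vector(outer(c("del", "wt"), c("lower", "middle", "top"),
                                  paste, sep = "/")))
  expect_equal(nrow(res$comparisons), choose(6, 2))
  expect_true(all(res$comparisons$q >= res$comparisons$p - 1e-12))
})
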