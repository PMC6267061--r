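test_that("a flat track produces no segments", {
  tr <- step_track(n = 5000L)
  expect_equal(nrow(segment_track(tr)), 0L)
})

test_that("noise-free steps are recovered exactly", {
  tr <- step_track(shifts = list(list(start = 4e5, end = 6e5, mean = -0.5)))
  seg <- segment_track(tr)
  expect_equal(nrow(seg), 1L)
  expect_equal(seg$start, 4e5)
  expect_equal(seg$end, 6e5)
  expect_equal(seg$seg_mean, -0.5, tolerance = 1e-12)
  expect_equal(seg$n_probes, 1000L)
})

test_that("breakpoints within 250 kb of a chromosome end are disallowed", {
  # a strong step whose only admissible breakpoint has a 200 kb flank
  tr <- step_track(n = 2500L,  # 500 kb chromosome
                   shifts = list(list(start = 0, end = 2e5, mean = -1)))
  seg <- segment_track(tr)
  # the 200 kb flank forbids the split regardless of F; no sub-segment is
  # reported (the whole-chromosome mean does not pass the filters)
  expect_false(any(abs(seg$end - 2e5) < 1e4))
})

test_that("z and intensity filters suppress weak or shallow segments", {
  # shallow mean (-0.05): suppressed even though the step is clean
  tr1 <- step_track(shifts = list(list(start = 4e5, end = 6e5, mean = -0.05)))
  expect_equal(nrow(segment_track(tr1)), 0L)
  # strong mean but tiny z (high noise relative to n): filtered
  set.seed(42)
  tr2 <- step_track(n = 5000L)
  tr2$log_ratio <- rnorm(5000, sd = 4)   # global sd swamps any segment
  inside <- tr2$position >= 4e5 & tr2$position < 6e5
  tr2$log_ratio[inside] <- tr2$log_ratio[inside] - 0.4
  expect_equal(nrow(segment_track(tr2)), 0L)
  # same depth with low noise: reported
  tr3 <- simulate_probe_track(sim_config(seed = 5), "resistant")
  seg3 <- segment_track(tr3)
  expect_true(any(seg3$seg_mean < -0.4))
})

test_that("reported segments always satisfy the significance filters", {
  for (s in 1:5) {
    tr <- simulate_probe_track(sim_config(seed = s), "resistant")
    seg <- segment_track(tr)
    expect_true(all(abs(seg$z_score) >= 3))
    expect_true(all(abs(seg$seg_mean) >= 0.09))
    # non-overlap within the sample/chromosome
    if (nrow(seg) > 1L) {
      seg <- seg[order(seg$start), ]
      expect_true(all(seg$start[-1L] >= seg$end[-nrow(seg)]))
    }
    # seg_mean equals the arithmetic mean of member probes
    for (k in seq_len(nrow(seg))) {
      inside <- tr$position >= seg$start[k] & tr$position < seg$end[k]
      expect_equal(seg$seg_mean[k], mean(tr$log_ratio[inside]),
                   tolerance = 1e-9)
    }
  }
})

test_that("segmentation ignores probes with missing values", {
  tr <- step_track(shifts = list(list(start = 4e5, end = 6e5, mean = -0.5)))
  tr2 <- tr
  tr2$log_ratio[seq(10, 4900, by = 100)] <- NA
  expect_equal(suppressMessages(segment_track(tr2))$start,
               segment_track(tr)$start)
})

test_that("a chromosome shorter than twice the flank rule yields nothing", {
  tr <- step_track(n = 2000L,  # 400 kb
                   shifts = list(list(start = 0, end = 4e5, mean = -1)))
  expect_equal(nrow(segment_track(tr)), 0L)
})

test_that("segment-to-gene projection length-weights the overlap", {
  seg <- data.frame(sample = "s1", chromosome = "chr1", start = 0, end = 1000,
                    n_probes = 50L, seg_mean = -0.5, z_score = -6)
  co <- gene_coords(data.frame(gene = c("in", "half", "out", "other_chr"),
                               chromosome = c("chr1", "chr1", "chr1", "chr9"),
                               start = c(100, 500, 2000, 0),
                               end = c(200, 1500, 2500, 100)))
  cn <- project_to_genes(seg, co)
  v <- setNames(cn$cn_value, cn$gene)
  expect_equal(unname(v["in"]), -0.5)
  expect_equal(unname(v["half"]), -0.25)    # half inside, half counts as 0
  expect_equal(unname(v["out"]), 0)
  expect_equal(unname(v["other_chr"]), 0)

  # a gene spanning two segments takes the length-weighted mean
  seg2 <- rbind(seg, transform(seg, start = 1000, end = 1500, seg_mean = -0.1))
  v2 <- setNames(project_to_genes(seg2, co)$cn_value,
                 project_to_genes(seg2, co)$gene)
  expect_equal(unname(v2["half"]), (500 * -0.5 + 500 * -0.1) / 1000)

  # no segments at all: everything 0 and neutral
  cn0 <- call_gains_losses(project_to_genes(seg[0, ], co))
  expect_true(all(cn0$cn_value == 0))
  expect_true(all(cn0$call == "neutral"))
})

test_that("gain and loss calls follow the +0.25 / -0.32 thresholds", {
  cn <- data.frame(sample = "s", gene = letters[1:5],
                   cn_value = c(-0.40, -0.32, 0.0, 0.25, 0.30))
  calls <- call_gains_losses(cn)
  expect_equal(calls$call, c("loss", "loss", "neutral", "gain", "gain"))
  expect_error(call_gains_losses(cn, gain_threshold = -0.5,
                                 loss_threshold = 0), "exceed")
})

test_that("categorical loss codes -1 and -2 mean deleted", {
  expect_equal(unname(categorical_loss_filter(c(-2, -1, 0, 1, 2))),
               c(TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_error(categorical_loss_filter(c(0, 3)), "unknown")
})

test_that("alteration frequencies count carrier samples per bin and group", {
  co <- gene_coords(data.frame(gene = c("gA", "gB"), chromosome = "chr1",
                               start = c(0, 1.5e6), end = c(1e4, 1.51e6)))
  calls <- data.frame(sample = rep(c("s1", "s2"), each = 2),
                      gene = rep(c("gA", "gB"), 2),
                      cn_value = c(-0.5, 0, 0, 0),
                      call = c("loss", "neutral", "neutral", "neutral"))
  fr <- alteration_frequency(calls, co, c(s1 = "g1", s2 = "g1"))
  bin1 <- fr[fr$bin_start == 0 & fr$group == "g1", ]
  expect_equal(bin1$loss_freq, 0.5)   # one of two samples
  expect_equal(bin1$gain_freq, 0)
  bin2 <- fr[fr$bin_start == 1e6, ]
  expect_equal(bin2$loss_freq, 0)

  # single sample with a loss: frequency 1 in covered bins
  fr1 <- alteration_frequency(calls[calls$sample == "s1", ], co,
                              c(s1 = "g1"))
  expect_equal(fr1$loss_freq[fr1$bin_start == 0], 1)
})

test_that("planted deletions show loss frequency 1 in the carrier group", {
  cohort <- simulate_cohort(sim_config(seed = 10))
  segs <- do.call(rbind, lapply(names(cohort$tracks), function(s)
    segment_track(cohort$tracks[[s]], sample_id = s)))
  calls <- call_gains_losses(project_to_genes(segs, cohort$coords))
  grp <- cohort$expr$groups
  fr <- alteration_frequency(calls, cohort$coords, grp)
  del <- cohort$truth$segments
  inbin <- fr$chromosome == del$chromosome[1] & fr$group == "resistant" &
    fr$bin_start < del$end[1] & fr$bin_end > del$start[1]
  expect_true(all(fr$loss_freq[inbin] == 1))
  unaffected <- fr$group == "untreated" & fr$chromosome == del$chromosome[1]
  expect_true(all(fr$loss_freq[unaffected] == 0))
})
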