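test_that("assign_group implements the size partition", {
  expect_equal(assign_group(27.7), "0-50")
  expect_equal(assign_group(50.0), "50-100")   # half-open at 50
  expect_equal(assign_group(100.0), "100-150") # half-open at 100
  expect_equal(assign_group(150.0), "100-150") # closed top
  expect_equal(assign_group(160), "ungrouped")
  expect_equal(assign_group(160, extend_top = TRUE), "100-150")
  expect_error(assign_group(-1))
})

test_that("ols_slope matches closed form, oracle, and lm", {
  t2 <- read.csv(system.file("extdata", "table2.csv", package = "filatrack"))
  d <- t2[t2$group == "50-100", ]
  f <- ols_slope(d$day, d$mean_cells)
  expect_equal(f$slope, 0.467, tolerance = 1e-3)

  expect_equal(ols_slope(c(0, 28), c(0, 28))$slope, 1.0)
  fc <- ols_slope(c(0, 7, 14), rep(5, 3))
  expect_equal(fc$slope, 0)
  expect_equal(fc$r_squared, 0)
  expect_error(ols_slope(c(3, 3), c(1, 2)), "times")

  set.seed(31)
  for (i in 1:15) {
    n <- sample(3:8, 1)
    tt <- sort(runif(n, 0, 30))
    yy <- runif(1, -2, 2) * tt + rnorm(n, 0, 3)
    f <- ols_slope(tt, yy)
    expect_equal(f$slope, brute_force_slope(tt, yy), tolerance = 1e-6)
    lmf <- lm(yy ~ tt)
    expect_equal(f$slope, unname(coef(lmf)[2]), tolerance = 1e-9)
    expect_equal(f$intercept, unname(coef(lmf)[1]), tolerance = 1e-9)
    expect_equal(f$r_squared, summary(lmf)$r.squared, tolerance = 1e-9)
  }
})

test_that("normalized rate peaks for the intermediate size group", {
  expect_equal(normalized_rate(0, c(10, 20)), 0)
  expect_error(normalized_rate(1, c(0, 0)))
  ft <- fit_paper_tables()
  nr <- setNames(ft$fits$normalized_rate, ft$fits$group)
  expect_equal(unname(nr["50-100"]), 6.2e-3, tolerance = 0.02)
  expect_equal(names(which.max(nr)), "50-100")
})

test_that("summarize_groups reproduces a fractional-increment schedule", {
  # tracks that follow the reference growth-table means exactly: group
  # means, increments, lengths, and slopes must round to the printed values
  tracks <- tracks_from_table2(n_per_group = 2)
  s <- summarize_groups(tracks)
  expect_named(s, c("0-50", "50-100", "100-150"))
  tab <- increment_summary_table(s)
  t1 <- read.csv(system.file("extdata", "table1.csv", package = "filatrack"))
  # week-1 increments match the growth-curve table differences (the
  # printed week-1 mean for 50-100, 3.5, is a paper-side rounding artifact:
  # the curve-table difference is 3.4)
  wk1 <- tab[tab$interval_end_day == 7, ]
  expect_equal(wk1$mean_increment_cells[wk1$group == "0-50"], 0.3)
  expect_equal(wk1$mean_increment_cells[wk1$group == "100-150"], 7.7)
  expect_equal(wk1$sd_increment_cells, rep(0, 3))
  slopes <- vapply(s, `[[`, numeric(1), "slope")
  expect_equal(unname(round(slopes, 2)), c(0.09, 0.47, 0.39))
  # monotone ordering of the three group slopes
  expect_true(slopes["0-50"] < slopes["100-150"] &&
                slopes["100-150"] < slopes["50-100"])

  # single flat track: SD 0, slope 0
  s1 <- suppressWarnings(summarize_groups(list(make_track(c(0, 7, 14),
                                                          rep(30, 3)))))
  expect_equal(s1[["0-50"]]$slope, 0)
  expect_equal(s1[["0-50"]]$sd_cells_by_day, rep(0, 3))
})

test_that("per-filament fit option averages per-track slopes", {
  tr1 <- make_track(c(0, 7), c(20, 22), track_id = "a")
  tr2 <- make_track(c(0, 7), c(30, 44), track_id = "b", lane_id = 2L)
  s <- suppressWarnings(summarize_groups(list(tr1, tr2), fit = "per_filament"))
  expect_equal(s[["0-50"]]$slope, mean(c(2 / 7, 14 / 7)))
})

test_that("compare_groups reproduces hand-computed statistics", {
  inc <- data.frame(
    group = rep(c("0-50", "50-100"), each = 3),
    interval_end_day = 7,
    cells_added = c(1, 2, 3, 4, 5, 6))
  cmp <- compare_groups(inc)
  w <- cmp$weeks[["7"]]
  expect_equal(w$pairwise$t, -3.674, tolerance = 1e-3)
  expect_equal(w$pairwise$df, 4)
  expect_equal(w$pairwise$p, 0.0213, tolerance = 1e-2)
  expect_true(w$pairwise$significant)
  # groups sharing no letter differ
  expect_false(any(strsplit(w$letters[1], "")[[1]] %in%
                     strsplit(w$letters[2], "")[[1]]))
  # oracle: stats::t.test with pooled variance and stats::aov
  tt <- t.test(c(1, 2, 3), c(4, 5, 6), var.equal = TRUE)
  expect_equal(w$pairwise$t, unname(tt$statistic), tolerance = 1e-9)
  expect_equal(w$pairwise$p, tt$p.value, tolerance = 1e-9)
  av <- summary(aov(cells_added ~ group, data = inc))[[1]]
  expect_equal(w$anova$F, av$`F value`[1], tolerance = 1e-9)
  expect_equal(w$anova$p, av$`Pr(>F)`[1], tolerance = 1e-9)
})

test_that("compare_groups edge behavior and invariances", {
  # identical groups: F = 0, nothing significant, one shared letter
  inc <- data.frame(group = rep(c("0-50", "50-100"), each = 3),
                    interval_end_day = 7, cells_added = rep(c(1, 2, 3), 2))
  cmp <- compare_groups(inc)
  expect_equal(cmp$weeks[["7"]]$anova$F, 0)
  expect_false(any(cmp$weeks[["7"]]$pairwise$significant))
  expect_equal(unname(cmp$weeks[["7"]]$letters), c("a", "a"))

  # wide separation with tiny jitter is significant
  set.seed(4)
  inc2 <- data.frame(group = rep(c("0-50", "50-100"), each = 3),
                     interval_end_day = 7,
                     cells_added = c(rnorm(3, 0, 0.01), rnorm(3, 10, 0.01)))
  expect_true(all(compare_groups(inc2)$weeks[["7"]]$pairwise$significant))

  # permutation of within-group values leaves results unchanged
  set.seed(5)
  inc3 <- data.frame(group = rep(size_group_labels(), each = 4),
                     interval_end_day = 7, cells_added = rnorm(12, 3, 1))
  cmp3 <- compare_groups(inc3)
  inc3p <- inc3[sample(nrow(inc3)), ]
  expect_equal(compare_groups(inc3p)$weeks[["7"]]$anova,
               cmp3$weeks[["7"]]$anova)

  # degenerate: zero variance everywhere but separated means -> error
  inc4 <- data.frame(group = rep(c("0-50", "50-100"), each = 3),
                     interval_end_day = 7, cells_added = rep(c(0, 10), each = 3))
  expect_error(compare_groups(inc4), "variance")
})

test_that("hormogonia_flag separates dormant short filaments", {
  # six-cell filament with no increment: hormogonium-like
  expect_true(hormogonia_flag(make_track(c(0, 7, 14), rep(6, 3)))$flagged)
  # long filament: never flagged
  expect_false(hormogonia_flag(make_track(c(0, 7), c(111.6, 111.6)))$flagged)
  # short but growing (reference 0-50 row adds 2.25 cells in total)
  t2 <- read.csv(system.file("extdata", "table2.csv", package = "filatrack"))
  d <- t2[t2$group == "0-50", ]
  expect_false(hormogonia_flag(make_track(d$day, d$mean_cells))$flagged)
  # negative noise increments are clipped before totalling
  noisy <- make_track(c(0, 7, 14), c(20, 19.5, 20.4))
  expect_equal(hormogonia_flag(noisy)$total_increment, 0.9, tolerance = 1e-9)
  expect_true(hormogonia_flag(noisy)$flagged)
})
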