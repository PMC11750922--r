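sd0_schedule <- function() {
  t1 <- read.csv(system.file("extdata", "table1.csv", package = "filatrack"))
  t1$sd_increment_cells <- 0
  growth_schedule(t1)
}

test_that("simulate_growth accumulates rounded schedule increments", {
  fil <- data.frame(filament_id = "F", lane_id = 1L, anchor_um = 60,
                    initial_cells = 110L)
  sc <- synthetic_scene(fil, n_lanes = 1L, length_um = 320, seed = 1)
  gt <- simulate_growth(sc, sd0_schedule())
  # 110 + round(7.7) + round(3) + round(1.3) + round(1.5) = 124 (half-up)
  expect_equal(gt$true_cells, c(110, 118, 121, 122, 124))
  expect_equal(gt$true_area_um2, gt$true_cells * 6.844)

  zero <- growth_schedule(data.frame(
    group = rep(size_group_labels(), each = 4),
    interval_end_day = rep(c(7, 14, 21, 28), 3),
    mean_increment_cells = 0, sd_increment_cells = 0))
  gt0 <- simulate_growth(sc, zero)
  expect_equal(gt0$true_cells, rep(110, 5))

  expect_error(
    synthetic_scene(data.frame(filament_id = "F", lane_id = 1L,
                               anchor_um = 60, initial_cells = 0L),
                    n_lanes = 1L),
    "> 0")
})

test_that("simulation is seed-deterministic and counts never decrease", {
  fil <- data.frame(filament_id = sprintf("F%d", 1:3), lane_id = 1:3,
                    anchor_um = c(50, 60, 70),
                    initial_cells = c(30L, 70L, 120L))
  sc1 <- synthetic_scene(fil, n_lanes = 3L, length_um = 350, seed = 8)
  g1 <- simulate_growth(sc1)
  g2 <- simulate_growth(sc1)
  expect_identical(g1, g2)
  sc2 <- synthetic_scene(fil, n_lanes = 3L, length_um = 350, seed = 9)
  expect_false(identical(simulate_growth(sc2)$true_cells, g1$true_cells))
  for (f in unique(g1$filament_id))
    expect_true(all(diff(g1$true_cells[g1$filament_id == f]) >= 0))
})

test_that("expected_weekly_increment matches Monte Carlo", {
  expect_equal(expected_weekly_increment(7.7, 0), 8)
  expect_equal(expected_weekly_increment(1.5, 0), 2)  # half-up
  set.seed(77)
  for (p in list(c(0.3, 0.4), c(1, 0.7), c(3.5, 1.9), c(7.7, 1.9))) {
    draws <- truncnorm::rtruncnorm(40000, a = 0, mean = p[1], sd = p[2])
    mc <- mean(floor(draws + 0.5))
    expect_equal(expected_weekly_increment(p[1], p[2]), mc, tolerance = 0.02)
  }
})

test_that("render produces the stated geometry and exact areas", {
  # one 50-cell filament: 90 um x ~3.8 um dark rectangle
  fil <- data.frame(filament_id = "F", lane_id = 1L, anchor_um = 60,
                    initial_cells = 50L)
  sc <- synthetic_scene(fil, n_lanes = 1L, length_um = 250, seed = 2)
  gt <- simulate_growth(sc, sd0_schedule())
  img <- render_micrograph(sc, gt, 0, noise_free())
  fg <- abs(img$pixels - 0.35) < 0.01  # filament intensity, not walls
  expect_equal(sum(fg) * sc$pixel_size_um^2, 50 * 6.844, tolerance = 0.05)
  cols <- range(which(colSums(fg) > 0))
  expect_equal(diff(cols) + 1, 90 / sc$pixel_size_um)  # 450 px long

  # determinism of the noisy render
  i1 <- render_micrograph(sc, gt, 7, noise_params())
  i2 <- render_micrograph(sc, gt, 7, noise_params())
  expect_identical(i1$pixels, i2$pixels)

  # a filament that would overflow the field errors out in simulation
  tight <- synthetic_scene(
    data.frame(filament_id = "F", lane_id = 1L, anchor_um = 0,
               initial_cells = 138L),
    n_lanes = 1L, length_um = 250, seed = 2)
  expect_error(simulate_growth(tight, sd0_schedule()), "beyond")
})

test_that("make_paper_like_experiment builds the reference design", {
  exp <- make_paper_like_experiment(seed = 42, noise = noise_free())
  d0 <- exp$truth[exp$truth$timepoint_days == 0, ]
  expect_equal(nrow(d0), 20)
  expect_equal(length(unique(exp$truth$filament_id)), 20)
  grp <- table(assign_group(d0$true_cells))
  expect_equal(unname(grp[size_group_labels()]), c(7L, 7L, 6L),
               ignore_attr = TRUE)
  expect_true(check_min_gap(exp$truth, 5))
  expect_equal(length(exp$scenes), 2)
  expect_equal(sort(unique(exp$truth$timepoint_days)), c(0, 7, 14, 21, 28))
})

test_that("recovered week-1 increments are unbiased over replicates", {
  # 50 seeded replicates of the large-filament group: the mean simulated
  # week-1 increment must sit within one schedule SD (1.9) of the mean 7.7
  fil <- data.frame(filament_id = sprintf("F%d", 1:6), lane_id = 1:6,
                    anchor_um = rep(50, 6),
                    initial_cells = rep(c(110L, 120L, 135L), 2))
  wk1 <- vapply(1:50, function(s) {
    sc <- synthetic_scene(fil, n_lanes = 6L, length_um = 350, seed = s)
    gt <- simulate_growth(sc)
    mean(gt$true_cells[gt$timepoint_days == 7] -
           gt$true_cells[gt$timepoint_days == 0])
  }, numeric(1))
  expect_lt(abs(mean(wk1) - 7.7), 1.9)
})

test_that("experiment round-trips through PNG files and manifest", {
  exp <- make_paper_like_experiment(seed = 3, noise = noise_params(),
                                    n_per_group = c(1L, 1L, 1L),
                                    lanes_per_strip = 3L)
  dir <- withr::local_tempdir()
  man <- write_experiment(exp, dir)
  expect_equal(nrow(man), 5)  # 1 strip x 5 timepoints
  expect_true(all(file.exists(file.path(dir, man$path))))
  expect_true(file.exists(file.path(dir, "ground_truth.csv")))
  expect_true(file.exists(file.path(dir, "scene.json")))

  # read back one image; segmentation on the decoded file matches the
  # in-memory render to PNG quantization
  img0 <- render_micrograph(exp$scenes[[1]], exp$truth, 0, exp$noise)
  back <- read_micrograph_png(file.path(dir, man$path[man$timepoint_days == 0]),
                              pixel_size_um = man$pixel_size_um[1])
  expect_equal(back$strip_id, "strip01")
  expect_equal(back$timepoint_days, 0)
  expect_lt(max(abs(back$pixels - img0$pixels)), 1 / 255)
  o1 <- segment_micrograph(img0, n_lanes = 3)
  o2 <- segment_micrograph(back, n_lanes = 3)
  expect_equal(nrow(o1), nrow(o2))
  expect_equal(o1$area_um2, o2$area_um2, tolerance = 0.02)
})
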