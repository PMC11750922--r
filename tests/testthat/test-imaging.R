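# small helper scenes used throughout
two_filament_scene <- function(gap_um = 20, n_lanes = 1L, seed = 3) {
  fil <- data.frame(filament_id = c("A", "B"), lane_id = c(1L, 1L),
                    anchor_um = c(50, 50 + 30 * 1.8 + gap_um),
                    initial_cells = c(30L, 25L))
  synthetic_scene(fil, n_lanes = n_lanes, length_um = 250, seed = seed)
}

test_that("compiled component labeling matches the flood-fill oracle", {
  set.seed(42)
  for (rep in 1:8) {
    mask <- matrix(runif(40 * 40) < 0.35, 40, 40)
    lab <- filatrack:::cc_label(mask, TRUE)
    oracle <- flood_fill_label(mask, eight = TRUE)
    expect_equal(attr(lab, "n_components"), max(oracle))
    # identical partitions and identical first-encounter ordering
    expect_equal(as.integer(lab), as.integer(oracle))
    areas <- tabulate(lab[lab > 0])
    expect_equal(sort(areas), sort(tabulate(oracle[oracle > 0])))
  }
})

test_that("otsu_threshold separates a bimodal sample", {
  set.seed(7)
  x <- c(rnorm(4000, 0.3, 0.03), rnorm(6000, 0.8, 0.03))
  t <- otsu_threshold(x)
  expect_gt(t, 0.4)
  expect_lt(t, 0.7)
  expect_error(otsu_threshold(c(0.5, NA)), "non-finite")
})

test_that("measure_area converts pixel counts to um^2", {
  expect_equal(measure_area(100, 0.5), 25.0)
  expect_equal(measure_area(matrix(FALSE, 4, 4), 0.5), 0)
  expect_equal(measure_area(27376, 0.05), 68.44)  # 10 cells at A_cell
  expect_error(measure_area(10, 0))
})

test_that("detect_capillaries finds rendered lanes and falls back sanely", {
  sc <- two_filament_scene(n_lanes = 3L)
  gt <- simulate_growth(sc)
  img <- render_micrograph(sc, gt, 0, noise_params(cell_texture = FALSE))
  rois <- detect_capillaries(img, 3)
  expect_length(rois, 3)
  geom <- filatrack:::lane_geometry(sc)
  truth_centers <- geom$lane_r0 + geom$lane_px / 2
  centers <- vapply(rois, function(r) mean(r$row_span), numeric(1))
  expect_true(all(abs(centers - truth_centers) <= 3))
  expect_true(all(diff(vapply(rois, function(r) r$row_span[1], numeric(1))) > 0))

  # uniform image: fallback to equal bands
  flat <- micrograph(matrix(0.5, 120, 60), 1)
  rois <- detect_capillaries(flat, 4)
  expect_length(rois, 4)
  expect_equal(vapply(rois, function(r) diff(r$row_span), numeric(1)),
               rep(30, 4))
  expect_error(detect_capillaries(flat, 4, fallback = FALSE), "fallback")

  # single bright band
  px <- matrix(0.2, 100, 50)
  px[40:60, ] <- 0.9
  r1 <- detect_capillaries(micrograph(px, 1), 1)
  expect_length(r1, 1)
  expect_true(r1[[1]]$row_span[1] >= 35 && r1[[1]]$row_span[2] <= 65)
})

test_that("a lane-splitting dark filament does not break lane detection", {
  # large filament covering most of the lane width: its band must be
  # re-merged rather than split into two lanes
  fil <- data.frame(filament_id = "big", lane_id = 2L, anchor_um = 20,
                    initial_cells = 140L)
  sc <- synthetic_scene(fil, n_lanes = 3L, length_um = 300, seed = 1)
  gt <- simulate_growth(sc)
  img <- render_micrograph(sc, gt, 0, noise_free())
  rois <- detect_capillaries(img, 3)
  geom <- filatrack:::lane_geometry(sc)
  widths <- vapply(rois, function(r) diff(r$row_span), numeric(1))
  expect_true(all(abs(widths - geom$lane_px) <= 6))
})

test_that("segment_filaments recovers filaments and rejects blanks", {
  fil <- data.frame(filament_id = "F1", lane_id = 1L, anchor_um = 60,
                    initial_cells = 50L)
  sc <- synthetic_scene(fil, n_lanes = 1L, length_um = 250, seed = 5)
  gt <- simulate_growth(sc)

  # noisy render: one observation, area within 10% of 50 x A_cell
  img <- render_micrograph(sc, gt, 0, noise_params())
  obs <- segment_micrograph(img, n_lanes = 1)
  expect_equal(nrow(obs), 1)
  expect_lt(abs(obs$area_um2 - 342.2) / 342.2, 0.10)
  expect_false(obs$touches_roi_edge)

  # determinism: identical image, identical result
  obs2 <- segment_micrograph(img, n_lanes = 1)
  expect_identical(obs, obs2)

  # blank lane (background + noise only) -> no observations
  blank <- synthetic_scene(fil[0, ], n_lanes = 1L, length_um = 250, seed = 5)
  bimg <- render_micrograph(blank, gt[0, ], 0, noise_params())
  expect_equal(nrow(segment_micrograph(bimg, n_lanes = 1)), 0)
  bimg0 <- render_micrograph(blank, gt[0, ], 0, noise_free())
  expect_equal(nrow(segment_micrograph(bimg0, n_lanes = 1)), 0)

  # non-finite pixels are rejected
  roi <- detect_capillaries(img, 1)[[1]]
  bad <- img
  bad$pixels[roi$row_span[1] + 5, roi$col_span[1] + 5] <- NA
  expect_error(segment_filaments(bad, roi), "non-finite")
})

test_that("nearby filaments separated by >= 5 um stay distinct", {
  sc <- two_filament_scene(gap_um = 5)
  gt <- simulate_growth(sc)
  img <- render_micrograph(sc, gt, 0, noise_params())
  obs <- segment_micrograph(img, n_lanes = 1)
  expect_equal(nrow(obs), 2)
})

test_that("noise-free areas are within 10% of truth for >= 10-cell filaments", {
  for (n0 in c(10L, 24L, 60L, 120L)) {
    fil <- data.frame(filament_id = "F", lane_id = 1L, anchor_um = 40,
                      initial_cells = n0)
    sc <- synthetic_scene(fil, n_lanes = 1L, length_um = 320, seed = 2)
    gt <- simulate_growth(sc, growth_schedule())
    img <- render_micrograph(sc, gt, 0, noise_free())
    obs <- segment_micrograph(img, n_lanes = 1)
    true_area <- n0 * 6.844
    expect_gt(obs$area_um2, 0.9 * true_area)
    expect_lt(obs$area_um2, 1.1 * true_area)
    # foreground never exceeds the ROI area
    roi <- detect_capillaries(img, 1)[[1]]
    expect_lt(sum(obs$area_um2),
              diff(roi$row_span) * diff(roi$col_span) * sc$pixel_size_um^2)
  }
})

test_that("field-border-truncated filaments are flagged", {
  fil <- data.frame(filament_id = "F", lane_id = 1L, anchor_um = 0,
                    initial_cells = 40L)  # starts at the image border
  sc <- synthetic_scene(fil, n_lanes = 1L, length_um = 200, seed = 2)
  gt <- simulate_growth(sc, growth_schedule(data.frame(
    group = "0-50", interval_end_day = c(7, 14, 21, 28),
    mean_increment_cells = 0, sd_increment_cells = 0)))
  img <- render_micrograph(sc, gt, 0, noise_free())
  obs <- segment_micrograph(img, n_lanes = 1)
  expect_true(obs$touches_roi_edge[1])
})
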