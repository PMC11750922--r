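# Independent oracles and small fixture builders used across test files.

# brute-force flood-fill component labeling (oracle for the compiled
# two-pass union-find); label order = first encounter in column-major scan
flood_fill_label <- function(mask, eight = TRUE) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  k <- 0L
  nbr <- if (eight) {
    rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1),
          c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
  } else {
    rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  }
  for (c in seq_len(ncol(mask))) for (r in seq_len(nrow(mask))) {
    if (!mask[r, c] || lab[r, c] != 0L) next
    k <- k + 1L
    stack <- list(c(r, c))
    lab[r, c] <- k
    while (length(stack) > 0) {
      p <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      for (i in seq_len(nrow(nbr))) {
        rr <- p[1] + nbr[i, 1]; cc <- p[2] + nbr[i, 2]
        if (rr >= 1 && rr <= nrow(mask) && cc >= 1 && cc <= ncol(mask) &&
            mask[rr, cc] && lab[rr, cc] == 0L) {
          lab[rr, cc] <- k
          stack[[length(stack) + 1L]] <- c(rr, cc)
        }
      }
    }
  }
  lab
}

# brute-force OLS slope: profile out the intercept and minimize SSE over
# the slope with a 1-D golden-section search
brute_force_slope <- function(times, values) {
  sse <- function(b) {
    a <- mean(values) - b * mean(times)
    sum((values - a - b * times)^2)
  }
  span <- diff(range(values)) / max(diff(range(times)), 1) + 1
  stats::optimize(sse, c(-10 * span, 10 * span), tol = 1e-12)$minimum
}

# turn simulated ground truth into idealized observation rows (bypasses
# rendering; isolates tracking/statistics from imaging)
truth_to_obs <- function(truth, pixel_size_um = 0.2, area_noise_um2 = 0) {
  n <- nrow(truth)
  noise <- if (area_noise_um2 > 0) rnorm(n, 0, area_noise_um2) else 0
  data.frame(
    obs_id = sprintf("%s_d%g_L%02d_%s", truth$strip_id,
                     truth$timepoint_days, truth$lane_id, truth$filament_id),
    strip_id = truth$strip_id,
    lane_id = truth$lane_id,
    timepoint_days = truth$timepoint_days,
    area_um2 = pmax(truth$true_area_um2 + noise, 0.01),
    centroid_row = truth$centroid_row,
    centroid_col = truth$centroid_col,
    bbox_r0 = 0L, bbox_r1 = 1L, bbox_c0 = 0L, bbox_c1 = 1L,
    touches_roi_edge = FALSE,
    pixel_size_um = pixel_size_um,
    stringsAsFactors = FALSE
  )
}

# hand-built track object for statistics tests
make_track <- function(timepoints, n_cells, track_id = "T001",
                       strip_id = "s", lane_id = 1L, complete = TRUE,
                       morph = oscillatoria_morphometry()) {
  structure(list(
    track_id = track_id, strip_id = strip_id, lane_id = lane_id,
    timepoints = timepoints,
    areas_um2 = n_cells * morph$mean_area_um2,
    n_cells = n_cells,
    lengths_um = n_cells * morph$mean_length_um,
    obs_ids = sprintf("%s_%d", track_id, seq_along(timepoints)),
    touches_edge = FALSE, complete = complete
  ), class = "filament_track")
}

# three-group track set whose per-track series follow the packaged growth
# table means exactly (fractional increments, zero within-group spread
# unless jitter is supplied)
tracks_from_table2 <- function(n_per_group = 2, jitter_sd = 0, seed = 1) {
  t2 <- read.csv(system.file("extdata", "table2.csv", package = "filatrack"),
                 stringsAsFactors = FALSE)
  set.seed(seed)
  tracks <- list()
  for (g in unique(t2$group)) {
    d <- t2[t2$group == g, ]
    d <- d[order(d$day), ]
    for (i in seq_len(n_per_group)) {
      cells <- d$mean_cells + if (jitter_sd > 0)
        rnorm(nrow(d), 0, jitter_sd) else 0
      tracks[[length(tracks) + 1L]] <- make_track(
        d$day, cells, track_id = sprintf("%s_%d", g, i),
        strip_id = "s", lane_id = length(tracks) + 1L)
    }
  }
  tracks
}
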