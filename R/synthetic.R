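#' Growth schedule (mean/SD weekly cell increments per size group)
#'
#' A growth schedule gives, per size group and weekly interval, the mean and
#' SD of the number of cells added. The default schedule is the packaged
#' reference table shipped with the package (`extdata/table1.csv`),
#' describing apical growth of *Oscillatoria* filaments over four weeks:
#' large filaments add ~7.7 cells in week one, decaying over time; small
#' filaments add less than one cell per week.
#'
#' @param df data.frame with columns `group`, `interval_end_day`,
#'   `mean_increment_cells`, `sd_increment_cells`; default: packaged table
#' @return object of class `growth_schedule`
#' @export
growth_schedule <- function(df = NULL) {
  if (is.null(df)) {
    path <- system.file("extdata", "table1.csv", package = "filatrack",
                        mustWork = TRUE)
    df <- read.csv(path, stringsAsFactors = FALSE)
  }
  need <- c("group", "interval_end_day", "mean_increment_cells",
            "sd_increment_cells")
  if (!all(need %in% names(df)))
    stopf("schedule must have columns: %s", paste(need, collapse = ","))
  if (any(df$mean_increment_cells < 0) || any(df$sd_increment_cells < 0))
    stopf("schedule means and SDs must be >= 0")
  structure(df, class = c("growth_schedule", "data.frame"))
}

schedule_lookup <- function(schedule, group, end_day) {
  i <- which(schedule$group == group & schedule$interval_end_day == end_day)
  if (length(i) != 1)
    stopf("schedule has no entry for group %s, interval ending day %s",
          group, format(end_day))
  schedule[i, ]
}

#' Expected weekly increment under the simulation model
#'
#' Closed-form expectation of `round(X)` where X ~ Normal(mean, sd)
#' truncated at 0 and rounding is half-up — the per-week increment
#' distribution used by [simulate_growth()]. Used as an independent oracle
#' for schedule-implied growth trajectories.
#'
#' @param mean,sd schedule mean and SD (cells)
#' @return expected integer increment (fractional value)
#' @export
expected_weekly_increment <- function(mean, sd) {
  if (sd == 0) return(floor(mean + 0.5))
  z <- 1 - pnorm(0, mean, sd)         # truncation mass
  kmax <- ceiling(mean + 10 * sd)
  k <- 0:kmax
  lo <- pmax(k - 0.5, 0)
  hi <- k + 0.5
  p <- (pnorm(hi, mean, sd) - pnorm(lo, mean, sd)) / z
  sum(k * p)
}

#' Synthetic microcapillary scene
#'
#' Static layout of one strip: parallel lanes (default 10, mean bore
#' 206 µm) separated by walls, with filaments anchored at fixed along-lane
#' positions. Filaments are rendered parallel to the lane axis (growth in
#' the capillaries is effectively one-dimensional). Anchors and cell
#' dimensions are snapped to the pixel grid so that rasterized area equals
#' ground-truth area to well under one cell equivalent (see the methods
#' vignette).
#'
#' @param filaments data.frame with columns `filament_id`, `lane_id`,
#'   `anchor_um` (along-lane position of the left tip at day 0) and
#'   `initial_cells` (integer > 0)
#' @param n_lanes number of capillary lanes
#' @param lane_width_um lane bore (µm); default 206
#' @param wall_um wall thickness between lanes (µm)
#' @param length_um along-lane field-of-view length (µm)
#' @param timepoints observation days
#' @param pixel_size_um render pixel size; default 0.2 µm/px (one cell =
#'   exactly 9 px along the axis)
#' @param seed integer seed governing all randomness derived from this
#'   scene
#' @param strip_id strip label
#' @param min_gap_um minimum along-lane gap between filaments sharing a
#'   lane, enforced at the largest simulated size
#' @param morph a [cell_morphometry()]
#' @return object of class `synthetic_scene`
#' @export
synthetic_scene <- function(filaments, n_lanes = 10L, lane_width_um = 206,
                            wall_um = 8, length_um = 400,
                            timepoints = c(0, 7, 14, 21, 28),
                            pixel_size_um = 0.2, seed = 1L,
                            strip_id = "strip01", min_gap_um = 5,
                            morph = oscillatoria_morphometry()) {
  need <- c("filament_id", "lane_id", "anchor_um", "initial_cells")
  if (!all(need %in% names(filaments)))
    stopf("filaments must have columns: %s", paste(need, collapse = ","))
  if (any(filaments$initial_cells <= 0))
    stopf("initial cell counts must be > 0")
  if (any(filaments$lane_id < 1 | filaments$lane_id > n_lanes))
    stopf("lane_id out of range")
  p <- pixel_size_um
  filaments$anchor_um <- round(filaments$anchor_um / p) * p  # pixel-snap
  len0 <- filaments$initial_cells * morph$mean_length_um
  if (any(filaments$anchor_um < 0 |
          filaments$anchor_um + len0 > length_um))
    stopf("filament extends beyond the field of view at day 0")
  structure(list(
    filaments = filaments, n_lanes = as.integer(n_lanes),
    lane_width_um = lane_width_um, wall_um = wall_um,
    length_um = length_um, timepoints = timepoints,
    pixel_size_um = p, seed = as.integer(seed),
    strip_id = strip_id, min_gap_um = min_gap_um,
    morph = morph
  ), class = "synthetic_scene")
}

# lane geometry in pixels: 0-based start row and width per lane
lane_geometry <- function(scene) {
  p <- scene$pixel_size_um
  wall_px <- round(scene$wall_um / p)
  lane_px <- round(scene$lane_width_um / p)
  r0 <- wall_px + (seq_len(scene$n_lanes) - 1L) * (lane_px + wall_px)
  list(wall_px = wall_px, lane_px = lane_px, lane_r0 = r0,
       n_rows = scene$n_lanes * lane_px + (scene$n_lanes + 1L) * wall_px,
       n_cols = round(scene$length_um / p))
}

#' Simulate apical growth with ground truth
#'
#' Per weekly interval, each filament adds `round(X)` cells with
#' X ~ Normal(mean, sd) truncated at 0 (schedule values by the filament's
#' size group, assigned from its initial cell number), split between the
#' two tips by a fair coin per cell. Counts therefore never decrease.
#' Deterministic given the scene seed.
#'
#' @param scene a [synthetic_scene()]
#' @param schedule a [growth_schedule()]
#' @return `ground_truth` data.frame: `filament_id, lane_id,
#'   timepoint_days, true_cells, true_area_um2, x0_um, x1_um, centroid_row,
#'   centroid_col` — `true_area_um2` is exactly `true_cells * mean cell
#'   area`; centroids are 0-based pixel coordinates of the rendered
#'   rectangle
#' @export
simulate_growth <- function(scene, schedule = growth_schedule()) {
  stopifnot(inherits(scene, "synthetic_scene"))
  morph <- scene$morph
  geom <- lane_geometry(scene)
  p <- scene$pixel_size_um
  tps <- scene$timepoints
  set.seed(scene$seed)
  out <- list()
  for (i in seq_len(nrow(scene$filaments))) {
    f <- scene$filaments[i, ]
    if (f$initial_cells <= 0) stopf("initial cells must be > 0")
    grp <- assign_group(f$initial_cells, extend_top = TRUE)
    n <- f$initial_cells
    x0 <- f$anchor_um
    x1 <- f$anchor_um + n * morph$mean_length_um
    rows <- data.frame(timepoint_days = tps[1], true_cells = n,
                       x0_um = x0, x1_um = x1)
    for (k in seq_along(tps)[-1]) {
      sch <- schedule_lookup(schedule, grp, tps[k])
      inc <- if (sch$sd_increment_cells == 0) sch$mean_increment_cells
      else truncnorm::rtruncnorm(1, a = 0, mean = sch$mean_increment_cells,
                                 sd = sch$sd_increment_cells)
      inc <- floor(inc + 0.5)
      left <- rbinom(1, inc, 0.5)
      n <- n + inc
      x0 <- x0 - left * morph$mean_length_um
      x1 <- x1 + (inc - left) * morph$mean_length_um
      if (x0 < 0 || x1 > scene$length_um)
        stopf("filament %s grows beyond the field of view", f$filament_id)
      rows <- rbind(rows, data.frame(timepoint_days = tps[k], true_cells = n,
                                     x0_um = x0, x1_um = x1))
    }
    rows$filament_id <- f$filament_id
    rows$lane_id <- f$lane_id
    out[[i]] <- rows
  }
  gt <- do.call(rbind, out)
  gt$true_area_um2 <- gt$true_cells * morph$mean_area_um2
  lane_r0 <- geom$lane_r0[gt$lane_id]
  gt$centroid_row <- lane_r0 + floor(geom$lane_px / 2)
  gt$centroid_col <- (gt$x0_um + gt$x1_um) / 2 / p - 0.5
  gt$strip_id <- scene$strip_id
  gt[, c("filament_id", "strip_id", "lane_id", "timepoint_days",
         "true_cells", "true_area_um2", "x0_um", "x1_um",
         "centroid_row", "centroid_col")]
}

#' Check the minimum-gap invariant of a simulated scene
#'
#' @param truth ground truth from [simulate_growth()]
#' @param min_gap_um required along-lane clearance
#' @return TRUE invisibly, or an error naming the first violating pair
#' @export
check_min_gap <- function(truth, min_gap_um = 5) {
  last <- max(truth$timepoint_days)
  tf <- truth[truth$timepoint_days == last, , drop = FALSE]
  if (is.null(tf$strip_id)) tf$strip_id <- "strip"
  lanes <- unique(tf[, c("strip_id", "lane_id")])
  for (j in seq_len(nrow(lanes))) {
    d <- tf[tf$lane_id == lanes$lane_id[j] &
              tf$strip_id == lanes$strip_id[j], , drop = FALSE]
    ln <- lanes$lane_id[j]
    if (nrow(d) < 2) next
    d <- d[order(d$x0_um), , drop = FALSE]
    gaps <- d$x0_um[-1] - d$x1_um[-nrow(d)]
    if (any(gaps < min_gap_um))
      stopf("filaments %s and %s in lane %d violate the %g um minimum gap",
            d$filament_id[which(gaps < min_gap_um)[1]],
            d$filament_id[which(gaps < min_gap_um)[1] + 1], ln, min_gap_um)
  }
  invisible(TRUE)
}

#' Rendering noise parameters
#'
#' @param sigma_psf Gaussian point-spread blur (px); default 1
#' @param sigma_noise additive Gaussian intensity noise SD; default 0.05
#' @param cell_texture draw a one-pixel darker cross-wall line between
#'   consecutive cells (visual texture; does not alter the segmented mask)
#' @return list of class `noise_params`
#' @export
noise_params <- function(sigma_psf = 1, sigma_noise = 0.05,
                         cell_texture = TRUE) {
  structure(list(sigma_psf = sigma_psf, sigma_noise = sigma_noise,
                 cell_texture = cell_texture), class = "noise_params")
}

#' @rdname noise_params
#' @export
noise_free <- function() noise_params(sigma_psf = 0, sigma_noise = 0,
                                      cell_texture = FALSE)

# separable Gaussian blur with edge replication (shift-and-add)
gaussian_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- max(1L, ceiling(3 * sigma))
  k <- dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  conv1 <- function(x) {  # along rows (dim 1)
    n <- nrow(x)
    out <- matrix(0, n, ncol(x))
    for (j in seq_along(k)) {
      off <- j - r - 1L
      idx <- pmin(pmax(seq_len(n) + off, 1L), n)
      out <- out + k[j] * x[idx, , drop = FALSE]
    }
    out
  }
  t(conv1(t(conv1(m))))
}

#' Render a synthetic micrograph at one timepoint
#'
#' Brightfield-like rendering: lane interior 0.85, walls 0.3, filaments
#' drawn as dark (0.35) axis-aligned rectangles of length
#' `cells x mean cell length` and area-consistent width (mean cell area /
#' mean cell length, ~3.8 µm), optional per-cell cross-wall texture, then
#' Gaussian blur and additive Gaussian noise, clipped to \[0, 1\].
#' Deterministic given `seed`.
#'
#' @param scene a [synthetic_scene()]
#' @param truth ground truth from [simulate_growth()]
#' @param timepoint which day to render (must be in `scene$timepoints`)
#' @param noise a [noise_params()]
#' @param seed RNG seed for the noise field; default derives from the scene
#'   seed and the timepoint index
#' @return a [micrograph()]
#' @export
render_micrograph <- function(scene, truth, timepoint,
                              noise = noise_params(), seed = NULL) {
  stopifnot(inherits(scene, "synthetic_scene"))
  ti <- match(timepoint, scene$timepoints)
  if (is.na(ti)) stopf("timepoint %s is not in the scene", format(timepoint))
  geom <- lane_geometry(scene)
  p <- scene$pixel_size_um
  morph <- scene$morph
  img <- matrix(0.3, geom$n_rows, geom$n_cols)
  for (r0 in geom$lane_r0)
    img[(r0 + 1):(r0 + geom$lane_px), ] <- 0.85

  w_eff_um <- morph$mean_area_um2 / morph$mean_length_um  # area-consistent
  wpx <- round(w_eff_um / p)
  cell_px <- round(morph$mean_length_um / p)
  tt <- truth[truth$timepoint_days == timepoint, , drop = FALSE]
  for (i in seq_len(nrow(tt))) {
    c0 <- round(tt$x0_um[i] / p)
    c1 <- round(tt$x1_um[i] / p)
    r0 <- geom$lane_r0[tt$lane_id[i]] + floor(geom$lane_px / 2) -
      floor(wpx / 2)
    rows <- (r0 + 1):(r0 + wpx)
    img[rows, (c0 + 1):c1] <- 0.35
    if (isTRUE(noise$cell_texture) && tt$true_cells[i] > 1) {
      walls <- c0 + cell_px * seq_len(tt$true_cells[i] - 1)
      img[rows, walls] <- 0.25
    }
  }
  img <- gaussian_blur(img, noise$sigma_psf)
  if (noise$sigma_noise > 0) {
    if (is.null(seed)) seed <- scene$seed + 7919L * ti
    set.seed(seed %% .Machine$integer.max)
    img <- img + rnorm(length(img), 0, noise$sigma_noise)
  }
  img <- pmin(pmax(img, 0), 1)  # matrix first: pmax(0, img) drops dims
  micrograph(img, p, timepoint, scene$strip_id)
}

#' Build a complete 20-filament synthetic experiment
#'
#' Emulates the reference experiment: 20 filaments tracked over 5 weekly
#' timepoints (days 0–28), populating the three size groups 7/7/6 with
#' initial sizes drawn uniformly from 20–45, 55–95, and 105–145 cells. The
#' filaments are laid out one per lane across 2 strips of 10 capillary
#' lanes (206 µm bore). Growth follows the default [growth_schedule()].
#'
#' @param seed integer master seed
#' @param noise a [noise_params()] used when rendering
#' @param pixel_size_um render resolution (default 0.2 µm/px)
#' @param length_um field-of-view length per lane
#' @param timepoints observation days
#' @param n_per_group filament counts for the three size groups (default
#'   7/7/6, i.e. 20 filaments); smaller designs are useful for fast tests
#' @param lanes_per_strip capillaries per strip (default 10, the physical
#'   device); one filament per lane, extra strips added as needed
#' @param schedule a [growth_schedule()]
#' @param morph a [cell_morphometry()]
#' @return object of class `synthetic_experiment`: list with `scenes`
#'   (per strip), `truth` (combined ground truth), `noise`, `morph`,
#'   `schedule`, `seed`
#' @export
make_paper_like_experiment <- function(seed = 42L, noise = noise_params(),
                                       pixel_size_um = 0.2, length_um = 400,
                                       timepoints = c(0, 7, 14, 21, 28),
                                       n_per_group = c(7L, 7L, 6L),
                                       lanes_per_strip = 10L,
                                       schedule = growth_schedule(),
                                       morph = oscillatoria_morphometry()) {
  set.seed(seed)
  init <- c(sample(20:45, n_per_group[1], replace = TRUE),
            sample(55:95, n_per_group[2], replace = TRUE),
            sample(105:145, n_per_group[3], replace = TRUE))
  nf <- length(init)
  ord <- sample(nf)  # spread groups across strips/lanes
  init <- init[ord]
  n_strips <- ceiling(nf / lanes_per_strip)
  margin <- 40  # worst-case one-sided apical extension is ~27 um
  scenes <- list()
  truths <- list()
  for (s in seq_len(n_strips)) {
    idx <- ((s - 1) * lanes_per_strip + 1):min(s * lanes_per_strip, nf)
    len0 <- init[idx] * morph$mean_length_um
    anchor <- margin + runif(length(idx)) * (length_um - len0 - 2 * margin)
    fil <- data.frame(
      filament_id = sprintf("F%02d", idx),
      lane_id = seq_along(idx),
      anchor_um = anchor,
      initial_cells = init[idx]
    )
    sc <- synthetic_scene(fil, n_lanes = lanes_per_strip,
                          length_um = length_um,
                          timepoints = timepoints,
                          pixel_size_um = pixel_size_um,
                          seed = seed + s, strip_id = sprintf("strip%02d", s),
                          morph = morph)
    scenes[[s]] <- sc
    truths[[s]] <- simulate_growth(sc, schedule)
  }
  structure(list(scenes = scenes, truth = do.call(rbind, truths),
                 noise = noise, morph = morph, schedule = schedule,
                 seed = seed),
            class = "synthetic_experiment")
}

#' @export
print.synthetic_experiment <- function(x, ...) {
  nf <- length(unique(x$truth$filament_id))
  cat(sprintf("Synthetic experiment: %d filaments, %d strips, days %s (seed %d)\n",
              nf, length(x$scenes),
              paste(x$scenes[[1]]$timepoints, collapse = ","), x$seed))
  invisible(x)
}

#' Segment every micrograph of a synthetic experiment
#'
#' Renders each strip at each timepoint (one full-strip image per
#' timepoint), detects lanes, and segments filaments — the front half of
#' the pipeline, run against known ground truth. Images are rendered
#' transiently, one at a time.
#'
#' @param exp a [make_paper_like_experiment()] result
#' @param params a [segmentation_params()]
#' @return observations data.frame (see [segment_filaments()])
#' @export
segment_experiment <- function(exp, params = segmentation_params()) {
  stopifnot(inherits(exp, "synthetic_experiment"))
  out <- list()
  for (sc in exp$scenes) {
    truth <- exp$truth[exp$truth$strip_id == sc$strip_id, , drop = FALSE]
    for (tp in sc$timepoints) {
      img <- render_micrograph(sc, truth, tp, exp$noise)
      out[[length(out) + 1L]] <-
        segment_micrograph(img, n_lanes = sc$n_lanes, params = params,
                           morph = exp$morph)
    }
  }
  do.call(rbind, out)
}

#' Write a synthetic experiment to disk
#'
#' Writes per-strip, per-timepoint PNG micrographs (named
#' `<strip>_<day>d.png`), `manifest.csv`, `ground_truth.csv`, and
#' `scene.json` (all scene parameters including the seed).
#'
#' @param exp a [make_paper_like_experiment()] result
#' @param dir output directory (created if missing)
#' @return the manifest data.frame, invisibly
#' @export
write_experiment <- function(exp, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list()
  for (sc in exp$scenes) {
    truth <- exp$truth[exp$truth$strip_id == sc$strip_id, , drop = FALSE]
    for (tp in sc$timepoints) {
      img <- render_micrograph(sc, truth, tp, exp$noise)
      fn <- sprintf("%s_%gd.png", sc$strip_id, tp)
      write_micrograph_png(img, file.path(dir, fn))
      manifest[[length(manifest) + 1L]] <- data.frame(
        path = fn, strip_id = sc$strip_id, timepoint_days = tp,
        pixel_size_um = sc$pixel_size_um, stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, manifest)
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  write.csv(exp$truth, file.path(dir, "ground_truth.csv"), row.names = FALSE)
  scpar <- lapply(exp$scenes, function(sc)
    c(sc[c("n_lanes", "lane_width_um", "wall_um", "length_um",
           "timepoints", "pixel_size_um", "seed", "strip_id",
           "min_gap_um")],
      list(filaments = sc$filaments)))
  jsonlite::write_json(
    list(seed = exp$seed, noise = unclass(exp$noise),
         morphometry = unclass(exp$morph), strips = scpar),
    file.path(dir, "scene.json"), auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
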