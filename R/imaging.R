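#' Micrograph container
#'
#' A grayscale micrograph of one microcapillary strip: an intensity matrix in
#' \[0, 1\] (row-major visual convention: row 1 is the top of the image) plus
#' the physical pixel size and acquisition metadata.
#'
#' @param pixels numeric matrix with values in \[0, 1\]
#' @param pixel_size_um physical size of one pixel (µm/px); micrographs of
#'   the microcapillary strips have no standardized magnification, so this
#'   must always be supplied (the synthetic generator default is 0.2 µm/px)
#' @param timepoint_days days since loading of the strip
#' @param strip_id strip label
#' @return object of class `micrograph`
#' @export
micrograph <- function(pixels, pixel_size_um, timepoint_days = NA_real_,
                       strip_id = NA_character_) {
  if (!is.matrix(pixels) || !is.numeric(pixels) || length(pixels) == 0)
    stopf("pixels must be a non-empty numeric matrix")
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1 ||
      !is.finite(pixel_size_um) || pixel_size_um <= 0)
    stopf("pixel_size_um must be a single positive number")
  if (!is.na(timepoint_days) && timepoint_days < 0)
    stopf("timepoint_days must be >= 0")
  structure(list(pixels = pixels, pixel_size_um = pixel_size_um,
                 timepoint_days = timepoint_days,
                 strip_id = as.character(strip_id)),
            class = "micrograph")
}

#' @export
print.micrograph <- function(x, ...) {
  cat(sprintf("Micrograph %s, day %s: %d x %d px at %.3g um/px (%.0f x %.0f um)\n",
              x$strip_id, format(x$timepoint_days),
              nrow(x$pixels), ncol(x$pixels), x$pixel_size_um,
              nrow(x$pixels) * x$pixel_size_um,
              ncol(x$pixels) * x$pixel_size_um))
  invisible(x)
}

#' Capillary lane region of interest
#'
#' Half-open pixel intervals (0-based) delimiting one capillary lane within
#' a strip micrograph. Rows select across-lane extent, columns the
#' along-lane extent.
#'
#' @param lane_id integer lane index (1-based, numbered top to bottom)
#' @param row_span integer vector `c(r0, r1)`, half-open \[r0, r1)
#' @param col_span integer vector `c(c0, c1)`, half-open \[c0, c1)
#' @return object of class `capillary_roi`
#' @export
capillary_roi <- function(lane_id, row_span, col_span) {
  if (row_span[2] <= row_span[1] || col_span[2] <= col_span[1])
    stopf("ROI spans must be non-empty half-open intervals")
  if (any(c(row_span, col_span) < 0))
    stopf("ROI spans must be non-negative")
  structure(list(lane_id = as.integer(lane_id),
                 row_span = as.integer(row_span),
                 col_span = as.integer(col_span)),
            class = "capillary_roi")
}

#' Detect capillary lanes in a strip micrograph
#'
#' Finds the bright capillary lanes (interior background) separated by dark
#' walls by smoothing the cross-lane mean-intensity profile and extracting
#' bands brighter than the midpoint between the profile's extremes. If the
#' profile contrast (max - min of the smoothed profile) is below
#' `min_contrast`, or fewer than `n_lanes` bands are found and
#' `fallback = TRUE`, the image is partitioned into `n_lanes` equal bands
#' instead.
#'
#' @param img a [micrograph()]
#' @param n_lanes expected number of lanes (the strip devices carry 10
#'   parallel capillaries)
#' @param orientation `"horizontal"` (lane axis runs along columns; default)
#'   or `"vertical"`
#' @param smooth_window running-mean window (px) applied to the profile
#' @param min_contrast minimum profile contrast for profile-based detection
#' @param fallback if `TRUE`, fall back to equal partition when detection
#'   fails; if `FALSE`, raise an error
#' @return list of [capillary_roi()], sorted by position
#' @export
detect_capillaries <- function(img, n_lanes, orientation = c("horizontal", "vertical"),
                               smooth_window = 5L, min_contrast = 0.05,
                               fallback = TRUE) {
  stopifnot(inherits(img, "micrograph"))
  orientation <- match.arg(orientation)
  px <- img$pixels
  if (orientation == "vertical") px <- t(px)
  n_lanes <- as.integer(n_lanes)
  if (n_lanes < 1) stopf("n_lanes must be >= 1")
  if (nrow(px) <= n_lanes) stopf("image too small for %d lanes", n_lanes)

  profile <- rowMeans(px)
  k <- max(1L, as.integer(smooth_window))
  if (k > 1) {
    kern <- rep(1 / k, k)
    pad <- c(rep(profile[1], k), profile, rep(profile[length(profile)], k))
    sm <- stats::filter(pad, kern, sides = 2)
    profile <- as.numeric(sm[(k + 1):(k + length(profile))])
  }

  contrast <- max(profile) - min(profile)
  rois <- NULL
  if (contrast >= min_contrast) {
    thr <- (max(profile) + min(profile)) / 2
    above <- profile > thr
    rle_ <- rle(above)
    ends <- cumsum(rle_$lengths)
    starts <- ends - rle_$lengths + 1L
    bands <- data.frame(start = starts[rle_$values], end = ends[rle_$values])
    # a dense dark filament can pull part of a lane below the midpoint and
    # split its band; true inter-lane walls sit near the profile minimum,
    # so merge bands whose separating gap stays well above the wall level
    wall_level <- min(profile) + 0.25 * contrast
    i <- 1L
    while (i < nrow(bands)) {
      gap <- (bands$end[i] + 1L):(bands$start[i + 1L] - 1L)
      if (mean(profile[gap]) > wall_level) {
        bands$end[i] <- bands$end[i + 1L]
        bands <- bands[-(i + 1L), , drop = FALSE]
      } else i <- i + 1L
    }
    if (nrow(bands) >= n_lanes) {
      bands$width <- bands$end - bands$start + 1L
      keep <- order(bands$width, decreasing = TRUE)[seq_len(n_lanes)]
      bands <- bands[sort(keep), , drop = FALSE]
      rois <- mapply(function(s, e, i)
        capillary_roi(i, c(s - 1L, e), c(0L, ncol(px))),
        bands$start, bands$end, seq_len(n_lanes), SIMPLIFY = FALSE)
    }
  }
  if (is.null(rois)) {
    if (!fallback)
      stopf("found fewer than %d lane bands and fallback is disabled", n_lanes)
    edges <- round(seq(0, nrow(px), length.out = n_lanes + 1))
    rois <- lapply(seq_len(n_lanes), function(i)
      capillary_roi(i, c(edges[i], edges[i + 1]), c(0L, ncol(px))))
  }
  rois
}

#' Otsu threshold of an intensity sample
#'
#' Classic histogram-based threshold maximizing between-class variance.
#'
#' @param x numeric vector or matrix of intensities
#' @param n_bins histogram resolution
#' @return a single threshold value; pixels `<= t` form the darker class
#' @export
otsu_threshold <- function(x, n_bins = 256L) {
  x <- as.numeric(x)
  if (any(!is.finite(x))) stopf("non-finite pixel values")
  r <- range(x)
  if (diff(r) == 0) return(r[1])
  bin <- pmin(n_bins, 1L + floor((x - r[1]) / diff(r) * n_bins))
  h <- tabulate(bin, n_bins)
  p <- h / sum(h)
  w <- cumsum(p)
  mu <- cumsum(p * seq_len(n_bins))
  mu_t <- mu[n_bins]
  sigma_b <- (mu_t * w - mu)^2 / (w * (1 - w))
  sigma_b[!is.finite(sigma_b)] <- -Inf
  k <- which.max(sigma_b)
  r[1] + (k / n_bins) * diff(r)
}

#' Segmentation parameters
#'
#' @param min_cells smallest object kept, in cell equivalents: components
#'   with area < `min_cells` × A_cell are discarded as debris (default 3,
#'   about 20.5 µm²)
#' @param dark_foreground `TRUE` (default) for brightfield images where
#'   filaments absorb light and appear darker than the lane interior; set
#'   `FALSE` to segment bright objects
#' @param min_contrast minimum separation between background and foreground
#'   class means for the Otsu threshold to be trusted; below it a robust
#'   background model (median - `bg_k` × MAD) is used instead (Otsu is
#'   unreliable when foreground occupies well under ~1% of the ROI)
#' @param bg_k MAD multiplier of the robust background threshold
#' @param max_cells_warn warn when a single component exceeds this many cell
#'   equivalents (possible touching/overlapping filaments)
#' @return list of class `segmentation_params`
#' @export
segmentation_params <- function(min_cells = 3, dark_foreground = TRUE,
                                min_contrast = 0.15, bg_k = 6,
                                max_cells_warn = 150) {
  if (min_cells < 1) stopf("min_cells must be >= 1")
  structure(list(min_cells = min_cells, dark_foreground = dark_foreground,
                 min_contrast = min_contrast, bg_k = bg_k,
                 max_cells_warn = max_cells_warn),
            class = "segmentation_params")
}

#' Segment filaments within one capillary lane
#'
#' Thresholds the ROI (Otsu, with a robust-background fallback when class
#' separation is poor; see [segmentation_params()]), labels 8-connected
#' components, and converts each retained component to a calibrated
#' observation with its area in µm². Components touching the lateral (left
#' or right) image border are flagged `touches_roi_edge`: their area is
#' truncated by the field of view and would bias cell counts.
#'
#' @param img a [micrograph()]
#' @param roi a [capillary_roi()]
#' @param params a [segmentation_params()]
#' @param morph a [cell_morphometry()] (used for the `min_cells` area gate)
#' @return data.frame of observations with columns `obs_id, strip_id,
#'   lane_id, timepoint_days, area_um2, centroid_row, centroid_col,
#'   bbox_r0, bbox_r1, bbox_c0, bbox_c1, touches_roi_edge, pixel_size_um`
#'   (pixel coordinates are 0-based, image-absolute)
#' @export
segment_filaments <- function(img, roi, params = segmentation_params(),
                              morph = oscillatoria_morphometry()) {
  stopifnot(inherits(img, "micrograph"), inherits(roi, "capillary_roi"))
  r0 <- roi$row_span[1]; r1 <- roi$row_span[2]
  c0 <- roi$col_span[1]; c1 <- roi$col_span[2]
  if (r1 > nrow(img$pixels) || c1 > ncol(img$pixels))
    stopf("ROI exceeds image bounds")
  sub <- img$pixels[(r0 + 1):r1, (c0 + 1):c1, drop = FALSE]
  if (any(!is.finite(sub))) stopf("non-finite pixel values in ROI")
  if (!params$dark_foreground) sub <- 1 - sub

  empty <- observations_df(0)
  if (diff(range(sub)) == 0) return(empty)

  thr <- otsu_threshold(sub)
  fg <- sub <= thr
  if (!any(fg) || all(fg)) return(empty)
  sep <- mean(sub[!fg]) - mean(sub[fg])
  if (!is.finite(sep) || sep < params$min_contrast) {
    # robust background model: background is the dominant population
    med <- median(sub)
    s <- mad(sub)
    thr <- if (s > 0) med - params$bg_k * s else med - params$min_contrast
    fg <- sub <= thr
    if (!any(fg)) return(empty)
  }

  lab <- cc_label(fg, TRUE)
  ncomp <- attr(lab, "n_components")
  if (ncomp == 0) return(empty)
  st <- cc_stats(lab, ncomp, 0L, ncol(sub))
  p2 <- img$pixel_size_um^2
  area <- st$n_pixels * p2
  keep <- area >= params$min_cells * morph$mean_area_um2
  if (!any(keep)) return(empty)

  idx <- which(keep)
  big <- area[idx] > params$max_cells_warn * morph$mean_area_um2
  if (any(big))
    warnf("%d component(s) exceed %g cell-equivalents; possible touching filaments",
          sum(big), params$max_cells_warn)

  # lateral borders: ROI column limits that coincide with the image border
  lat_left <- c0 == 0
  lat_right <- c1 == ncol(img$pixels)
  touches <- (st$col_min[idx] == 0 & lat_left) |
    (st$col_max[idx] == ncol(sub) - 1 & lat_right)

  out <- data.frame(
    obs_id = sprintf("%s_d%s_L%02d_%03d",
                     img$strip_id, format(img$timepoint_days),
                     roi$lane_id, seq_along(idx)),
    strip_id = img$strip_id,
    lane_id = roi$lane_id,
    timepoint_days = img$timepoint_days,
    area_um2 = area[idx],
    centroid_row = st$centroid_row[idx] + r0,
    centroid_col = st$centroid_col[idx] + c0,
    bbox_r0 = st$row_min[idx] + r0, bbox_r1 = st$row_max[idx] + 1L + r0,
    bbox_c0 = st$col_min[idx] + c0, bbox_c1 = st$col_max[idx] + 1L + c0,
    touches_roi_edge = touches,
    pixel_size_um = img$pixel_size_um,
    stringsAsFactors = FALSE
  )
  out[order(out$centroid_col), , drop = FALSE]
}

observations_df <- function(n) {
  data.frame(obs_id = character(n), strip_id = character(n),
             lane_id = integer(n), timepoint_days = numeric(n),
             area_um2 = numeric(n), centroid_row = numeric(n),
             centroid_col = numeric(n),
             bbox_r0 = integer(n), bbox_r1 = integer(n),
             bbox_c0 = integer(n), bbox_c1 = integer(n),
             touches_roi_edge = logical(n), pixel_size_um = numeric(n),
             stringsAsFactors = FALSE)
}

#' Segment all lanes of a micrograph
#'
#' Convenience wrapper: [detect_capillaries()] followed by
#' [segment_filaments()] per lane.
#'
#' @inheritParams segment_filaments
#' @inheritParams detect_capillaries
#' @param ... passed to [detect_capillaries()]
#' @return combined observations data.frame (see [segment_filaments()])
#' @export
segment_micrograph <- function(img, n_lanes = 10L,
                               params = segmentation_params(),
                               morph = oscillatoria_morphometry(), ...) {
  rois <- detect_capillaries(img, n_lanes, ...)
  out <- lapply(rois, function(roi) segment_filaments(img, roi, params, morph))
  do.call(rbind, out)
}

#' Pixel-mask area
#'
#' @param mask logical matrix/vector of foreground pixels, or a single pixel
#'   count
#' @param pixel_size_um µm per pixel
#' @return area in µm²: `|mask| * pixel_size_um^2`
#' @export
measure_area <- function(mask, pixel_size_um) {
  if (pixel_size_um <= 0) stopf("pixel_size_um must be > 0")
  n <- if (is.logical(mask)) sum(mask) else as.numeric(mask)
  n * pixel_size_um^2
}
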