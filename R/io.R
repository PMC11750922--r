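#' Write a micrograph to a grayscale PNG
#'
#' Intensities are clipped to \[0, 1\] and written as 16-bit grayscale.
#' Physical metadata (pixel size, strip, timepoint) is not stored in the
#' PNG; use a manifest CSV or the `<strip>_<day>d.png` filename convention.
#'
#' @param img a [micrograph()]
#' @param path output path (`.png`)
#' @export
write_micrograph_png <- function(img, path) {
  stopifnot(inherits(img, "micrograph"))
  px <- pmin(pmax(img$pixels, 0), 1)
  png::writePNG(px, target = path)
  invisible(path)
}

#' Read a grayscale micrograph from PNG
#'
#' Color images are converted to grayscale by channel averaging. Metadata
#' not recoverable from the file is supplied by arguments or parsed from the
#' filename convention `<strip>_<day>d.png` (e.g. `strip03_14d.png`).
#'
#' @param path PNG file
#' @param pixel_size_um µm per pixel (required; micrograph files carry no
#'   calibration)
#' @param strip_id,timepoint_days optional overrides; if `NA`, parsed from
#'   the filename when it matches the convention
#' @return a [micrograph()]
#' @export
read_micrograph_png <- function(path, pixel_size_um,
                                strip_id = NA_character_,
                                timepoint_days = NA_real_) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 3) px <- apply(px[, , 1:3, drop = FALSE], c(1, 2), mean)
  meta <- parse_micrograph_filename(path)
  if (is.na(strip_id)) strip_id <- meta$strip_id
  if (is.na(timepoint_days)) timepoint_days <- meta$timepoint_days
  micrograph(px, pixel_size_um, timepoint_days, strip_id)
}

#' Parse the `<strip>_<day>d.<ext>` micrograph filename convention
#'
#' @param path file path, e.g. `"strip01_7d.png"`
#' @return list with `strip_id` and `timepoint_days` (`NA` when the name
#'   does not match)
#' @export
parse_micrograph_filename <- function(path) {
  base <- tools::file_path_sans_ext(basename(path))
  m <- regmatches(base, regexec("^(.*)_([0-9]+(?:\\.[0-9]+)?)d$", base))[[1]]
  if (length(m) == 3)
    list(strip_id = m[2], timepoint_days = as.numeric(m[3]))
  else
    list(strip_id = NA_character_, timepoint_days = NA_real_)
}

#' Read an image manifest CSV
#'
#' Schema: `path,strip_id,timepoint_days,pixel_size_um`. Relative paths are
#' resolved against the manifest's directory.
#'
#' @param path manifest CSV
#' @return data.frame with absolute image paths
#' @export
read_manifest <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("path", "strip_id", "timepoint_days", "pixel_size_um")
  if (!all(need %in% names(df)))
    stopf("manifest must have columns: %s", paste(need, collapse = ","))
  rel <- !grepl("^(/|[A-Za-z]:)", df$path)
  df$path[rel] <- file.path(dirname(normalizePath(path)), df$path[rel])
  df
}

#' Write observation / track / increment CSV artifacts
#'
#' Column layouts follow the pipeline's external interfaces:
#' * observations: `obs_id,strip_id,lane_id,timepoint_days,area_um2,centroid_row,centroid_col,touches_roi_edge`
#' * tracks: `track_id,strip_id,lane_id,timepoint_days,area_um2,n_cells,length_um,complete`
#' * increments: `track_id,interval_start_day,interval_end_day,cells_added`
#'
#' @param obs observations data.frame (from [segment_filaments()])
#' @param path output CSV path
#' @export
write_observations_csv <- function(obs, path) {
  cols <- c("obs_id", "strip_id", "lane_id", "timepoint_days", "area_um2",
            "centroid_row", "centroid_col", "touches_roi_edge")
  write.csv(obs[, cols], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_observations_csv
#' @export
read_observations_csv <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}
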