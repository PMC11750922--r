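#' Cell morphometry calibration constants
#'
#' Container for the per-cell morphometry used to convert segmented filament
#' areas into cell counts and lengths. Values are typically derived from SEM
#' measurements of individual cells within filaments (cells project as
#' shallow disks stacked along the trichome axis).
#'
#' @param mean_length_um mean cell length along the filament axis (µm)
#' @param mean_width_um mean cell width across the filament axis (µm)
#' @param mean_area_um2 mean projected area of one cell (µm²). If `NULL`,
#'   defaults to `mean_length_um * mean_width_um`. Note the default
#'   calibration [oscillatoria_morphometry()] carries a measured mean area
#'   (6.844 µm²) that is *smaller* than the product of the mean length and
#'   width (7.02 µm²), consistent with per-cell pairing of length and width.
#' @param sd_length_um,sd_width_um,sd_area_um2 sample standard deviations
#' @param n number of cells measured
#' @return an object of class `cell_morphometry`
#' @seealso [measure_cells()] to build one from raw per-cell measurements
#' @export
cell_morphometry <- function(mean_length_um, mean_width_um,
                             mean_area_um2 = NULL,
                             sd_length_um = 0, sd_width_um = 0,
                             sd_area_um2 = 0, n = NA_integer_) {
  if (is.null(mean_area_um2)) mean_area_um2 <- mean_length_um * mean_width_um
  vals <- c(mean_length_um, mean_width_um, mean_area_um2)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stopf("cell morphometry means must be finite and > 0")
  sds <- c(sd_length_um, sd_width_um, sd_area_um2)
  if (any(is.finite(sds) & sds < 0))
    stopf("cell morphometry SDs must be >= 0")
  structure(list(
    mean_length_um = mean_length_um, sd_length_um = sd_length_um,
    mean_width_um = mean_width_um, sd_width_um = sd_width_um,
    mean_area_um2 = mean_area_um2, sd_area_um2 = sd_area_um2,
    n = as.integer(n)
  ), class = "cell_morphometry")
}

#' Default Oscillatoria cell morphometry
#'
#' SEM-derived calibration for *Oscillatoria nigroviridis*-type cells:
#' 1.8 ± 0.4 µm long, 3.9 ± 0.7 µm wide, mean projected area
#' 6.844 ± 2.194 µm² (n = 56). The mean area is used directly (it is not
#' the product 1.8 × 3.9 = 7.02 µm²; per-cell length–width pairing gives a
#' smaller mean product).
#'
#' @return a `cell_morphometry` object
#' @export
oscillatoria_morphometry <- function() {
  cell_morphometry(
    mean_length_um = 1.8, sd_length_um = 0.4,
    mean_width_um = 3.9, sd_width_um = 0.7,
    mean_area_um2 = 6.844, sd_area_um2 = 2.194,
    n = 56L
  )
}

#' @export
print.cell_morphometry <- function(x, ...) {
  cat(sprintf(
    "Cell morphometry (n = %s cells):\n  length %.3g +/- %.3g um\n  width  %.3g +/- %.3g um\n  area   %.4g +/- %.4g um^2\n",
    ifelse(is.na(x$n), "?", x$n),
    x$mean_length_um, x$sd_length_um,
    x$mean_width_um, x$sd_width_um,
    x$mean_area_um2, x$sd_area_um2))
  invisible(x)
}

#' Summarize per-cell measurements into a morphometry calibration
#'
#' Computes mean and sample SD of cell length, width, and per-cell projected
#' area (length × width, paired per cell) from a table of individual cell
#' measurements.
#'
#' @param measurements data.frame with columns `length_um` and `width_um`
#'   (one row per measured cell), or a two-column numeric matrix
#'   (length, width)
#' @return a `cell_morphometry` object with `mean_area_um2` equal to the
#'   mean of the per-cell length × width products
#' @export
measure_cells <- function(measurements) {
  if (is.matrix(measurements))
    measurements <- data.frame(length_um = measurements[, 1],
                               width_um = measurements[, 2])
  if (!is.data.frame(measurements) ||
      !all(c("length_um", "width_um") %in% names(measurements)))
    stopf("measurements must have columns length_um and width_um")
  if (nrow(measurements) == 0) stopf("no measurements")
  l <- measurements$length_um
  w <- measurements$width_um
  if (any(!is.finite(l)) || any(!is.finite(w)) || any(l <= 0) || any(w <= 0))
    stopf("cell lengths and widths must be finite and > 0")
  a <- l * w
  sd0 <- function(x) if (length(x) > 1) sd(x) else 0
  cell_morphometry(
    mean_length_um = mean(l), sd_length_um = sd0(l),
    mean_width_um = mean(w), sd_width_um = sd0(w),
    mean_area_um2 = mean(a), sd_area_um2 = sd0(a),
    n = length(l)
  )
}

#' Convert a filament area to a (fractional) cell count
#'
#' The number of cells in a filament at time t is its projected area divided
#' by the mean area of one cell:
#' \deqn{n_{cells}(t) = A_{filament}(t) / A_{cell}}
#' Counts are deliberately kept fractional; rounding happens only when
#' reports are serialized.
#'
#' @param area_um2 filament area(s), µm² (vectorized)
#' @param morph a [cell_morphometry()] object
#' @return fractional cell count(s)
#' @export
area_to_cells <- function(area_um2, morph = oscillatoria_morphometry()) {
  stopifnot(inherits(morph, "cell_morphometry"))
  if (!is.numeric(area_um2) || any(!is.finite(area_um2)))
    stopf("area must be finite numeric")
  if (any(area_um2 < 0)) stopf("area must be >= 0")
  if (morph$mean_area_um2 <= 0) stopf("mean cell area must be > 0")
  area_um2 / morph$mean_area_um2
}

#' Convert a cell count to a filament length
#'
#' \deqn{L_{filament}(t) = n_{cells}(t) \times L_{cell}}
#'
#' @param n_cells (fractional) cell count(s)
#' @inheritParams area_to_cells
#' @return filament length(s), µm
#' @export
cells_to_length <- function(n_cells, morph = oscillatoria_morphometry()) {
  stopifnot(inherits(morph, "cell_morphometry"))
  if (!is.numeric(n_cells) || any(!is.finite(n_cells)))
    stopf("cell count must be finite numeric")
  if (any(n_cells < 0)) stopf("cell count must be >= 0")
  n_cells * morph$mean_length_um
}

#' Read / write cell measurement CSV
#'
#' CSV schema: `cell_id,length_um,width_um`.
#'
#' @param path file path
#' @return `read_cell_measurements`: data.frame with `cell_id`, `length_um`,
#'   `width_um`
#' @export
read_cell_measurements <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("cell_id", "length_um", "width_um")
  if (!all(need %in% names(df)))
    stopf("cell measurement CSV must have columns: %s", paste(need, collapse = ","))
  df
}

#' @rdname read_cell_measurements
#' @param measurements data.frame with `length_um`, `width_um` (a `cell_id`
#'   column is added if missing)
#' @export
write_cell_measurements <- function(measurements, path) {
  if (is.null(measurements$cell_id))
    measurements$cell_id <- seq_len(nrow(measurements))
  write.csv(measurements[, c("cell_id", "length_um", "width_um")],
            path, row.names = FALSE)
  invisible(path)
}

#' Serialize / deserialize morphometry as JSON
#'
#' JSON keys: `mean_length_um, sd_length_um, mean_width_um, sd_width_um,
#' mean_area_um2, sd_area_um2, n`.
#'
#' @param morph a `cell_morphometry`
#' @param path file path
#' @export
write_morphometry_json <- function(morph, path) {
  stopifnot(inherits(morph, "cell_morphometry"))
  jsonlite::write_json(unclass(morph), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_morphometry_json
#' @export
read_morphometry_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  cell_morphometry(
    mean_length_um = x$mean_length_um, sd_length_um = x$sd_length_um %||% 0,
    mean_width_um = x$mean_width_um, sd_width_um = x$sd_width_um %||% 0,
    mean_area_um2 = x$mean_area_um2, sd_area_um2 = x$sd_area_um2 %||% 0,
    n = x$n %||% NA_integer_
  )
}
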