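#' Matching parameters for filament re-identification
#'
#' Filaments in sealed microcapillaries are essentially static (no gliding;
#' only slight oscillation of loose ends), and they grow — they never shrink
#' appreciably. Matching therefore constrains centroid displacement and
#' relative area shrinkage between consecutive timepoints.
#'
#' @param max_centroid_shift_um maximum centroid displacement between
#'   consecutive timepoints (µm); default 20
#' @param max_relative_shrinkage maximum tolerated relative area decrease
#'   (fraction); default 0.1
#' @return list of class `matching_params`
#' @export
matching_params <- function(max_centroid_shift_um = 20,
                            max_relative_shrinkage = 0.1) {
  if (max_centroid_shift_um < 0 || max_relative_shrinkage < 0)
    stopf("matching parameters must be >= 0")
  structure(list(max_centroid_shift_um = max_centroid_shift_um,
                 max_relative_shrinkage = max_relative_shrinkage),
            class = "matching_params")
}

#' Link filament observations between two timepoints
#'
#' Within each lane, finds the globally optimal one-to-one assignment
#' (Hungarian algorithm) minimizing summed centroid distance, subject to
#' distance <= `max_centroid_shift_um` and
#' `area(t1) >= (1 - max_relative_shrinkage) * area(t0)`. Ties in distance
#' are broken toward the pair with the smaller absolute area difference
#' (then by along-lane position), deterministically.
#'
#' @param obs_t0,obs_t1 observation data.frames (see [segment_filaments()])
#'   from the same strip; `obs_t1` at the later timepoint
#' @param params a [matching_params()]
#' @return list with `matches` (data.frame `obs_id_t0, obs_id_t1,
#'   distance_um`), `unmatched_t0`, `unmatched_t1` (character vectors of
#'   obs_ids)
#' @export
link_timepoints <- function(obs_t0, obs_t1, params = matching_params()) {
  if (nrow(obs_t0) > 0 && nrow(obs_t1) > 0) {
    if (length(unique(c(obs_t0$strip_id, obs_t1$strip_id))) > 1)
      stopf("cannot link observations from different strips")
  }
  matches <- data.frame(obs_id_t0 = character(), obs_id_t1 = character(),
                        distance_um = numeric(), stringsAsFactors = FALSE)
  un0 <- character(); un1 <- character()
  lanes <- union(obs_t0$lane_id, obs_t1$lane_id)
  BIG <- 1e9
  for (ln in lanes) {
    a <- obs_t0[obs_t0$lane_id == ln, , drop = FALSE]
    b <- obs_t1[obs_t1$lane_id == ln, , drop = FALSE]
    if (nrow(a) == 0) { un1 <- c(un1, b$obs_id); next }
    if (nrow(b) == 0) { un0 <- c(un0, a$obs_id); next }
    ps <- a$pixel_size_um[1]
    d <- outer(seq_len(nrow(a)), seq_len(nrow(b)), function(i, j) {
      sqrt((a$centroid_row[i] - b$centroid_row[j])^2 +
             (a$centroid_col[i] - b$centroid_col[j])^2) * ps
    })
    feas <- d <= params$max_centroid_shift_um &
      outer(a$area_um2, b$area_um2,
            function(x, y) y >= (1 - params$max_relative_shrinkage) * x)
    darea <- abs(outer(a$area_um2, b$area_um2, `-`))
    pos <- outer(rep(0, nrow(a)), b$centroid_col, `+`)
    # tiny deterministic tie-break terms; distances are in µm so 1e-6 and
    # 1e-9 scale terms never override a genuine distance difference
    cost <- d + 1e-6 * darea / (1 + darea) + 1e-9 * pos / (1 + pos)
    cost[!feas] <- BIG
    n <- max(nrow(a), nrow(b))
    cm <- matrix(BIG, n, n)
    cm[seq_len(nrow(a)), seq_len(nrow(b))] <- cost
    sol <- clue::solve_LSAP(cm)
    for (i in seq_len(nrow(a))) {
      j <- sol[i]
      if (j <= nrow(b) && cost[i, j] < BIG) {
        matches <- rbind(matches, data.frame(
          obs_id_t0 = a$obs_id[i], obs_id_t1 = b$obs_id[j],
          distance_um = d[i, j], stringsAsFactors = FALSE))
      } else {
        un0 <- c(un0, a$obs_id[i])
      }
    }
    un1 <- c(un1, setdiff(b$obs_id, matches$obs_id_t1))
  }
  list(matches = matches, unmatched_t0 = un0, unmatched_t1 = un1)
}

#' Build filament tracks across all timepoints
#'
#' Chains pairwise consecutive-timepoint links ([link_timepoints()]) into
#' tracks. No gap closing: a filament missed at one timepoint terminates its
#' track (mirroring a manual protocol of continuous weekly relocation).
#' Cell counts and lengths are filled in via the calibration conversions.
#'
#' @param obs observations data.frame covering >= 2 distinct timepoints
#'   (may span several strips; linking is per strip)
#' @param params a [matching_params()]
#' @param morph a [cell_morphometry()]
#' @return list of `filament_track` objects; each has `track_id`,
#'   `strip_id`, `lane_id`, `timepoints`, `areas_um2`, `n_cells`,
#'   `lengths_um`, `obs_ids`, `touches_edge` (any observation truncated at
#'   the field border), and `complete` (spans every timepoint of its strip)
#' @export
build_tracks <- function(obs, params = matching_params(),
                         morph = oscillatoria_morphometry()) {
  tps <- sort(unique(obs$timepoint_days))
  if (length(tps) < 2) stopf("need observations at >= 2 distinct timepoints")
  tracks <- list()
  for (strip in unique(obs$strip_id)) {
    so <- obs[obs$strip_id == strip, , drop = FALSE]
    stps <- sort(unique(so$timepoint_days))
    # successor map obs_id -> obs_id at next timepoint
    succ <- character(0)
    for (k in seq_len(length(stps) - 1)) {
      l <- link_timepoints(so[so$timepoint_days == stps[k], , drop = FALSE],
                           so[so$timepoint_days == stps[k + 1], , drop = FALSE],
                           params)
      succ <- c(succ, setNames(l$matches$obs_id_t1, l$matches$obs_id_t0))
    }
    is_succ <- unname(succ)
    heads <- so$obs_id[!(so$obs_id %in% is_succ)]
    # deterministic ordering of track starts
    heads <- heads[order(so$timepoint_days[match(heads, so$obs_id)],
                         so$lane_id[match(heads, so$obs_id)],
                         so$centroid_col[match(heads, so$obs_id)])]
    for (h in heads) {
      chain <- h
      while (!is.na(succ[tail(chain, 1)] %||% NA_character_))
        chain <- c(chain, unname(succ[tail(chain, 1)]))
      rows <- so[match(chain, so$obs_id), , drop = FALSE]
      tr <- structure(list(
        track_id = sprintf("%s_T%03d", strip, length(tracks) + 1L),
        strip_id = strip,
        lane_id = rows$lane_id[1],
        timepoints = rows$timepoint_days,
        areas_um2 = rows$area_um2,
        n_cells = area_to_cells(rows$area_um2, morph),
        lengths_um = cells_to_length(area_to_cells(rows$area_um2, morph), morph),
        obs_ids = rows$obs_id,
        touches_edge = any(rows$touches_roi_edge),
        complete = length(chain) == length(stps)
      ), class = "filament_track")
      tracks[[length(tracks) + 1L]] <- tr
    }
  }
  tracks
}

#' @export
print.filament_track <- function(x, ...) {
  cat(sprintf("Track %s (strip %s, lane %d, %s): days %s; cells %s\n",
              x$track_id, x$strip_id, x$lane_id,
              if (x$complete) "complete" else "incomplete",
              paste(x$timepoints, collapse = ","),
              paste(round_half_up(x$n_cells, 1), collapse = ",")))
  invisible(x)
}

#' Per-interval cell increments of one track
#'
#' For consecutive timepoints t(k-1), t(k):
#' `increment = n_cells(t_k) - n_cells(t_{k-1})`. Increments stay
#' fractional and may be slightly negative under measurement noise; they
#' sum exactly to `n_cells(last) - n_cells(first)`.
#'
#' @param track a `filament_track` from [build_tracks()]
#' @return data.frame `interval_start_day, interval_end_day, cells_added`
#' @export
compute_increments <- function(track) {
  stopifnot(inherits(track, "filament_track"))
  k <- length(track$timepoints)
  if (k < 2) stopf("track has a single timepoint; no increments")
  data.frame(
    track_id = track$track_id,
    interval_start_day = track$timepoints[-k],
    interval_end_day = track$timepoints[-1],
    cells_added = diff(track$n_cells),
    stringsAsFactors = FALSE
  )
}

#' Flatten tracks to the tracks-CSV layout
#'
#' @param tracks list of `filament_track`
#' @return data.frame `track_id,strip_id,lane_id,timepoint_days,area_um2,
#'   n_cells,length_um,complete`
#' @export
tracks_to_df <- function(tracks) {
  do.call(rbind, lapply(tracks, function(tr) data.frame(
    track_id = tr$track_id, strip_id = tr$strip_id, lane_id = tr$lane_id,
    timepoint_days = tr$timepoints, area_um2 = tr$areas_um2,
    n_cells = tr$n_cells, length_um = tr$lengths_um,
    complete = tr$complete, stringsAsFactors = FALSE)))
}
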