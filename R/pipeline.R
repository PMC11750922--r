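#' Pipeline configuration
#'
#' Assembles and validates the configuration consumed by [run_pipeline()].
#' A configuration either points at real micrographs (`manifest`) or
#' carries a `simulate` block; exactly one input source is required.
#'
#' @param config named list, or path to a JSON file with the same layout.
#'   Recognized top-level fields:
#'   * `seed` — integer, governs every stochastic stage
#'   * `out_dir` — output directory for all artifacts
#'   * `pixel_size_um` — µm/px of input images (required with `manifest`
#'     unless the manifest carries `pixel_size_um`)
#'   * `morphometry` — either a list of constants
#'     (`mean_length_um`, `mean_width_um`, `mean_area_um2`, ...), a path to
#'     a morphometry JSON, or a path to a cell-measurement CSV; default:
#'     the packaged Oscillatoria calibration
#'   * `manifest` — path to an image manifest CSV
#'   * `simulate` — list of arguments for [make_paper_like_experiment()]
#'     (e.g. `noise = list(sigma_psf = 1, sigma_noise = 0.05)`)
#'   * `segmentation`, `matching` — parameter blocks for
#'     [segmentation_params()] / [matching_params()]
#'   * `stats` — list with optional `fit`, `alpha`, `bonferroni`,
#'     `extend_top`
#' @return validated config (class `pipeline_config`)
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config)) {
    if (!file.exists(config)) stopf("config file not found: %s", config)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  cfg <- config
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  cfg$out_dir <- cfg$out_dir %||% "filatrack_out"
  if (is.null(cfg$simulate) && is.null(cfg$manifest))
    stopf("config error: need either a 'simulate' block or a 'manifest'")
  if (!is.null(cfg$manifest) && !file.exists(cfg$manifest))
    stopf("config error: manifest not found: %s", cfg$manifest)
  cfg$morphometry <- resolve_morphometry(cfg$morphometry)
  cfg$segmentation <- do.call(segmentation_params,
                              as.list(cfg$segmentation %||% list()))
  cfg$matching <- do.call(matching_params, as.list(cfg$matching %||% list()))
  cfg$stats <- cfg$stats %||% list()
  structure(cfg, class = "pipeline_config")
}

resolve_morphometry <- function(m) {
  if (is.null(m)) return(oscillatoria_morphometry())
  if (inherits(m, "cell_morphometry")) return(m)
  if (is.character(m)) {
    if (grepl("\\.json$", m)) return(read_morphometry_json(m))
    return(measure_cells(read_cell_measurements(m)))
  }
  do.call(cell_morphometry, as.list(m))
}

#' Run the full growth-quantification pipeline
#'
#' Stages: (optional) simulate -> segment -> track -> quantify -> group
#' statistics. Writes `observations.csv`, `tracks.csv`, `increments.csv`,
#' `group_summary.csv`, `increments_summary.csv`, `fits.json`,
#' `stats.json`, and `run.log` under `out_dir`. Idempotent given the seed.
#' On stage failure, partial outputs are retained next to a `FAILED` marker
#' naming the stage.
#'
#' @param config a [pipeline_config()] (or list/path coercible to one)
#' @return result bundle (list with `observations`, `tracks`, `summaries`,
#'   `comparison`, `out_dir`), invisibly
#' @export
run_pipeline <- function(config) {
  cfg <- if (inherits(config, "pipeline_config")) config
  else pipeline_config(config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(cfg$out_dir, "run.log")
  log_line <- function(...) cat(sprintf(...), "\n", sep = "",
                                file = logf, append = TRUE)
  cat(sprintf("filatrack %s | started %s | seed %d\n",
              as.character(packageVersion("filatrack")),
              format(Sys.time()), cfg$seed),
      file = logf)
  stage <- "init"
  res <- tryCatch({
    morph <- cfg$morphometry

    stage <- "segment"
    if (!is.null(cfg$simulate)) {
      stage <- "simulate"
      sim_args <- as.list(cfg$simulate)
      if (!is.null(sim_args$noise))
        sim_args$noise <- do.call(noise_params, as.list(sim_args$noise))
      sim_args$seed <- sim_args$seed %||% cfg$seed
      sim_args$morph <- morph
      exp <- do.call(make_paper_like_experiment, sim_args)
      write.csv(exp$truth, file.path(cfg$out_dir, "ground_truth.csv"),
                row.names = FALSE)
      log_line("simulate: %d filaments, seed %d",
               length(unique(exp$truth$filament_id)), exp$seed)
      stage <- "segment"
      obs <- segment_experiment(exp, cfg$segmentation)
    } else {
      man <- read_manifest(cfg$manifest)
      obs <- do.call(rbind, lapply(seq_len(nrow(man)), function(i) {
        ps <- man$pixel_size_um[i] %||% cfg$pixel_size_um
        img <- read_micrograph_png(man$path[i], ps,
                                   man$strip_id[i], man$timepoint_days[i])
        segment_micrograph(img, n_lanes = cfg$n_lanes %||% 10L,
                           params = cfg$segmentation, morph = morph)
      }))
    }
    write_observations_csv(obs, file.path(cfg$out_dir, "observations.csv"))
    log_line("segment: %d observations", nrow(obs))

    stage <- "track"
    tracks <- build_tracks(obs, cfg$matching, morph)
    write.csv(tracks_to_df(tracks), file.path(cfg$out_dir, "tracks.csv"),
              row.names = FALSE)
    incs <- do.call(rbind, lapply(Filter(function(t)
      length(t$timepoints) > 1, tracks), compute_increments))
    write.csv(incs, file.path(cfg$out_dir, "increments.csv"),
              row.names = FALSE)
    log_line("track: %d tracks (%d complete)", length(tracks),
             sum(vapply(tracks, `[[`, logical(1), "complete")))

    stage <- "quantify"
    st <- cfg$stats
    summaries <- summarize_groups(
      tracks, morph,
      fit = st$fit %||% "group_mean",
      extend_top = isTRUE(st$extend_top))
    write.csv(group_summary_table(summaries),
              file.path(cfg$out_dir, "group_summary.csv"), row.names = FALSE)
    write.csv(increment_summary_table(summaries),
              file.path(cfg$out_dir, "increments_summary.csv"),
              row.names = FALSE)
    fits <- lapply(summaries, function(s) list(
      slope = round_half_up(s$slope, 2),
      intercept = round_half_up(s$intercept, 2),
      r_squared = round_half_up(s$r_squared, 4),
      normalized_rate = signif(s$normalized_rate, 4),
      n_tracks = s$n_tracks))
    jsonlite::write_json(fits, file.path(cfg$out_dir, "fits.json"),
                         auto_unbox = TRUE, digits = NA)

    stage <- "stats"
    by_track_group <- merge(
      incs,
      do.call(rbind, lapply(tracks, function(t) data.frame(
        track_id = t$track_id,
        group = assign_group(t$n_cells[1], isTRUE(st$extend_top)),
        complete = t$complete, stringsAsFactors = FALSE))),
      by = "track_id")
    by_track_group <- by_track_group[by_track_group$complete &
                                       by_track_group$group != "ungrouped", ]
    comparison <- tryCatch(
      compare_groups(by_track_group, alpha = st$alpha %||% 0.05,
                     bonferroni = isTRUE(st$bonferroni)),
      error = function(e) {
        log_line("stats: comparison skipped (%s)", conditionMessage(e))
        NULL
      })
    if (!is.null(comparison)) {
      stats_json <- lapply(comparison$weeks, function(w) list(
        interval_end_day = w$interval_end_day,
        anova = w$anova, pairwise = w$pairwise,
        letters = as.list(w$letters)))
      jsonlite::write_json(stats_json, file.path(cfg$out_dir, "stats.json"),
                           auto_unbox = TRUE, digits = NA)
    }
    log_line("done")
    list(observations = obs, tracks = tracks, summaries = summaries,
         comparison = comparison, out_dir = cfg$out_dir)
  }, error = function(e) {
    writeLines(sprintf("stage %s failed: %s", stage, conditionMessage(e)),
               file.path(cfg$out_dir, "FAILED"))
    stopf("pipeline stage '%s' failed: %s", stage, conditionMessage(e))
  })
  invisible(res)
}

#' Fit the packaged reference growth tables
#'
#' Recomputes the growth statistics directly from a growth-curve table of
#' per-group mean cell numbers (the packaged `extdata/table2.csv` by
#' default): per-group OLS slope (dN/dt), intercept, r², normalized rate,
#' week-over-week mean increments (differences of consecutive group means),
#' and filament lengths via the cell-length calibration.
#'
#' @param table2 data.frame with columns `group, day, mean_cells`
#'   (optionally `sd_cells`, `length_um`), or a path to such a CSV;
#'   default: the packaged table
#' @param morph a [cell_morphometry()]
#' @return list of class `table_fits`: `fits` (data.frame per group:
#'   `slope, intercept, r_squared, normalized_rate`), `increments`
#'   (data.frame `group, interval_end_day, cells_added`), `lengths`
#'   (data.frame `group, day, mean_cells, length_um`)
#' @export
fit_paper_tables <- function(table2 = NULL,
                             morph = oscillatoria_morphometry()) {
  if (is.null(table2))
    table2 <- system.file("extdata", "table2.csv", package = "filatrack",
                          mustWork = TRUE)
  if (is.character(table2)) table2 <- read.csv(table2, stringsAsFactors = FALSE)
  need <- c("group", "day", "mean_cells")
  miss <- setdiff(need, names(table2))
  if (length(miss) > 0)
    stopf("growth table is missing column(s): %s", paste(miss, collapse = ","))
  groups <- intersect(size_group_labels(), unique(table2$group))
  if (length(groups) < length(size_group_labels()))
    warnf("growth table covers only groups: %s", paste(groups, collapse = ", "))
  fits <- list(); incs <- list(); lens <- list()
  for (g in groups) {
    d <- table2[table2$group == g, , drop = FALSE]
    d <- d[order(d$day), , drop = FALSE]
    if (anyNA(d$mean_cells))
      stopf("growth table group %s has a missing mean at day %s",
            g, paste(d$day[is.na(d$mean_cells)], collapse = ","))
    f <- ols_slope(d$day, d$mean_cells)
    fits[[g]] <- data.frame(
      group = g, slope = f$slope, intercept = f$intercept,
      r_squared = f$r_squared,
      normalized_rate = normalized_rate(f$slope, d$mean_cells),
      stringsAsFactors = FALSE)
    incs[[g]] <- data.frame(
      group = g, interval_end_day = d$day[-1],
      cells_added = diff(d$mean_cells), stringsAsFactors = FALSE)
    lens[[g]] <- data.frame(
      group = g, day = d$day, mean_cells = d$mean_cells,
      length_um = cells_to_length(d$mean_cells, morph),
      stringsAsFactors = FALSE)
  }
  structure(list(fits = do.call(rbind, fits),
                 increments = do.call(rbind, incs),
                 lengths = do.call(rbind, lens)),
            class = "table_fits")
}

#' @export
print.table_fits <- function(x, ...) {
  f <- x$fits
  for (i in seq_len(nrow(f)))
    cat(sprintf("Group %s: dN/dt = %.2f cells/day (r2 = %.3f), normalized %.2e /day\n",
                f$group[i], f$slope[i], f$r_squared[i], f$normalized_rate[i]))
  invisible(x)
}

#' Command-line entry point
#'
#' Subcommands: `run` (all stages), `simulate`, `fit-tables`. Flags:
#' `--config <json>`, `--seed <int>`, `--out <dir>`, `--pixel-size <um>`,
#' `--manifest <csv>`, `--fixtures-dir <dir>` (alternate location of the
#' growth tables for `fit-tables`). Exit codes: 0 success, 2 config error,
#' 3 stage error.
#'
#' @param args character vector of CLI arguments (default: the process
#'   command line)
#' @return integer exit status, invisibly (callers embedding the CLI pass
#'   it to `quit(status = )`)
#' @export
filatrack_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- "usage: filatrack <run|simulate|fit-tables> [--config F] [--seed N] [--out D] [--pixel-size X] [--manifest F] [--fixtures-dir D]"
  if (length(args) == 0) { message(usage); return(invisible(2L)) }
  cmd <- args[1]
  opt <- parse_cli_flags(args[-1])
  if (!is.null(opt$error)) { message(opt$error); return(invisible(2L)) }

  status <- tryCatch({
    if (cmd %in% c("run", "simulate")) {
      cfg <- tryCatch({
        base <- if (!is.null(opt$config)) pipeline_config(opt$config)
        else {
          init <- list()
          if (cmd == "simulate" || is.null(opt$manifest))
            init$simulate <- list()
          init$manifest <- opt$manifest
          init
        }
        base <- unclass(base)
        if (!is.null(opt$seed)) base$seed <- opt$seed
        if (!is.null(opt$out)) base$out_dir <- opt$out
        if (!is.null(opt$pixel_size)) base$pixel_size_um <- opt$pixel_size
        if (!is.null(opt$manifest)) base$manifest <- opt$manifest
        pipeline_config(base)
      }, error = function(e) {
        message(conditionMessage(e)); NULL
      })
      if (is.null(cfg)) return(invisible(2L))
      run_pipeline(cfg)
      0L
    } else if (cmd == "fit-tables") {
      t2 <- if (!is.null(opt$fixtures_dir))
        file.path(opt$fixtures_dir, "table2.csv") else NULL
      ft <- fit_paper_tables(t2)
      out <- opt$out %||% "."
      dir.create(out, recursive = TRUE, showWarnings = FALSE)
      fits <- lapply(split(ft$fits, ft$fits$group), function(r) list(
        slope = round_half_up(r$slope, 2), intercept = r$intercept,
        r_squared = r$r_squared, normalized_rate = r$normalized_rate))
      jsonlite::write_json(fits, file.path(out, "fits.json"),
                           auto_unbox = TRUE, digits = NA)
      print(ft)
      0L
    } else {
      message(usage)
      2L
    }
  }, error = function(e) {
    message(conditionMessage(e))
    3L
  })
  invisible(as.integer(status))
}

parse_cli_flags <- function(args) {
  opt <- list()
  i <- 1
  while (i <= length(args)) {
    a <- args[i]
    take <- function() {
      if (i + 1 > length(args)) stopf("flag %s needs a value", a)
      args[i + 1]
    }
    res <- tryCatch({
      switch(a,
             "--config" = opt$config <- take(),
             "--seed" = opt$seed <- as.integer(take()),
             "--out" = opt$out <- take(),
             "--pixel-size" = opt$pixel_size <- as.numeric(take()),
             "--manifest" = opt$manifest <- take(),
             "--fixtures-dir" = opt$fixtures_dir <- take(),
             stopf("unknown flag: %s", a))
      NULL
    }, error = function(e) conditionMessage(e))
    if (!is.null(res)) return(list(error = res))
    i <- i + 2
  }
  opt
}
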