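#' Size-group definitions and assignment
#'
#' Filaments are grouped by their cell number at the start of the
#' experiment: shorter (0–50 cells), medium (50–100), and longer (100–150).
#' Bins are half-open at 50 and 100 and closed at 150; counts above 150 are
#' "ungrouped" and excluded from group statistics by default.
#'
#' @return `size_group_labels`: the three group labels in increasing size
#'   order
#' @export
size_group_labels <- function() c("0-50", "50-100", "100-150")

#' @rdname size_group_labels
#' @param initial_cells (fractional) cell count(s) at the first timepoint
#' @param extend_top if `TRUE`, counts above 150 fall into "100-150"
#'   instead of "ungrouped"
#' @return `assign_group`: character vector of group labels ("ungrouped"
#'   when outside the partition)
#' @export
assign_group <- function(initial_cells, extend_top = FALSE) {
  if (any(initial_cells < 0)) stopf("initial cell count must be >= 0")
  out <- ifelse(initial_cells < 50, "0-50",
         ifelse(initial_cells < 100, "50-100",
         ifelse(initial_cells <= 150 | extend_top, "100-150", "ungrouped")))
  out
}

#' Ordinary least-squares slope (rate of increase of population)
#'
#' Closed-form simple linear regression of cell number on time. The slope is
#' the rate of increase of population, dN/dt (cells/day).
#'
#' @param times numeric vector (days)
#' @param values numeric vector (cells), same length
#' @return list `slope`, `intercept`, `r_squared` (defined as 0 when the
#'   response is constant)
#' @export
ols_slope <- function(times, values) {
  if (length(times) != length(values) || length(times) < 2)
    stopf("need >= 2 paired (time, value) points")
  if (length(unique(times)) < 2) stopf("all times equal; slope undefined")
  tb <- mean(times); yb <- mean(values)
  sxx <- sum((times - tb)^2)
  sxy <- sum((times - tb) * (values - yb))
  slope <- sxy / sxx
  intercept <- yb - slope * tb
  sst <- sum((values - yb)^2)
  r2 <- if (sst == 0) 0 else {
    sse <- sum((values - intercept - slope * times)^2)
    1 - sse / sst
  }
  list(slope = slope, intercept = intercept, r_squared = r2)
}

#' Population-size-normalized growth rate
#'
#' dN/dt divided by the population size N, with N taken as the mean over
#' timepoints of the group-mean cell number (1/day). Distinguishes
#' size-dependence of growth from the trivial fact that bigger filaments
#' add more cells.
#'
#' @param slope dN/dt (cells/day)
#' @param mean_cells_by_day numeric vector of group-mean cell numbers, one
#'   per timepoint
#' @return normalized rate (1/day)
#' @export
normalized_rate <- function(slope, mean_cells_by_day) {
  nbar <- mean(mean_cells_by_day)
  if (!is.finite(nbar) || nbar <= 0) stopf("mean population size must be > 0")
  slope / nbar
}

#' Group-level growth summary (growth-curve tables and dN/dt fits)
#'
#' Assigns each complete track to a size group by its initial cell number,
#' then per group computes: mean ± SD cells per timepoint, corresponding
#' lengths, mean ± SD weekly increments, the OLS fit of group-mean cells vs
#' day (slope = dN/dt), and the normalized rate.
#'
#' @param tracks list of `filament_track` (see [build_tracks()])
#' @param morph a [cell_morphometry()]
#' @param complete_only drop tracks not observed at every timepoint
#'   (default TRUE)
#' @param exclude_edge drop tracks with any field-border-truncated
#'   observation (default TRUE; partial areas bias cell counts)
#' @param fit `"group_mean"` (default): dN/dt from OLS on the group-mean
#'   growth curve; `"per_filament"`: dN/dt as the mean of per-track OLS
#'   slopes
#' @param extend_top see [assign_group()]
#' @return list of `group_growth_summary` objects (one per non-empty group,
#'   in size order), each with `group`, `days`, `mean_cells_by_day`,
#'   `sd_cells_by_day`, `length_um_by_day`, `mean_increment_by_week`,
#'   `sd_increment_by_week`, `slope`, `intercept`, `r_squared`,
#'   `normalized_rate`, `n_tracks`
#' @export
summarize_groups <- function(tracks, morph = oscillatoria_morphometry(),
                             complete_only = TRUE, exclude_edge = TRUE,
                             fit = c("group_mean", "per_filament"),
                             extend_top = FALSE) {
  fit <- match.arg(fit)
  if (complete_only) tracks <- Filter(function(t) t$complete, tracks)
  if (exclude_edge) tracks <- Filter(function(t) !t$touches_edge, tracks)
  if (length(tracks) == 0) stopf("no usable tracks")
  init <- vapply(tracks, function(t) t$n_cells[1], numeric(1))
  grp <- assign_group(init, extend_top)
  if (any(grp == "ungrouped")) {
    warnf("%d track(s) above 150 initial cells excluded (ungrouped)",
          sum(grp == "ungrouped"))
  }
  out <- list()
  for (g in size_group_labels()) {
    tg <- tracks[grp == g]
    if (length(tg) == 0) {
      warnf("group %s has no tracks; omitted", g)
      next
    }
    days <- sort(unique(unlist(lapply(tg, `[[`, "timepoints"))))
    cells <- vapply(tg, function(t) t$n_cells[match(days, t$timepoints)],
                    numeric(length(days)))
    cells <- matrix(cells, nrow = length(days))
    mean_cells <- rowMeans(cells)
    sd_cells <- apply(cells, 1, function(x) if (length(x) > 1) sd(x) else 0)
    incs <- apply(cells, 2, diff)
    incs <- matrix(incs, nrow = length(days) - 1)
    mean_inc <- rowMeans(incs)
    sd_inc <- apply(incs, 1, function(x) if (length(x) > 1) sd(x) else 0)
    f <- if (fit == "group_mean") {
      ols_slope(days, mean_cells)
    } else {
      sl <- vapply(tg, function(t) ols_slope(t$timepoints, t$n_cells)$slope,
                   numeric(1))
      list(slope = mean(sl), intercept = NA_real_, r_squared = NA_real_)
    }
    out[[g]] <- structure(list(
      group = g, days = days,
      mean_cells_by_day = mean_cells, sd_cells_by_day = sd_cells,
      length_um_by_day = cells_to_length(mean_cells, morph),
      interval_end_day = days[-1],
      mean_increment_by_week = mean_inc, sd_increment_by_week = sd_inc,
      slope = f$slope, intercept = f$intercept, r_squared = f$r_squared,
      normalized_rate = normalized_rate(f$slope, mean_cells),
      n_tracks = length(tg)
    ), class = "group_growth_summary")
  }
  out
}

#' @export
print.group_growth_summary <- function(x, ...) {
  cat(sprintf("Group %s (%d filaments): dN/dt = %.2f cells/day (r2 = %.3f), normalized %.2e /day\n",
              x$group, x$n_tracks, x$slope, x$r_squared, x$normalized_rate))
  invisible(x)
}

#' Report tables from group summaries
#'
#' `group_summary_table` emits the growth-curve table (per group and day:
#' mean ± SD cells, length); `increment_summary_table` the weekly-increment
#' table. Values are rounded only here, at report time (counts 2 decimals,
#' increments and lengths 1 decimal).
#'
#' @param summaries list from [summarize_groups()]
#' @return data.frame in the respective report schema
#' @export
group_summary_table <- function(summaries) {
  do.call(rbind, lapply(summaries, function(s) data.frame(
    group = s$group, day = s$days,
    mean_cells = round_half_up(s$mean_cells_by_day, 2),
    sd_cells = round_half_up(s$sd_cells_by_day, 2),
    length_um = round_half_up(s$length_um_by_day, 1),
    stringsAsFactors = FALSE)))
}

#' @rdname group_summary_table
#' @export
increment_summary_table <- function(summaries) {
  do.call(rbind, lapply(summaries, function(s) data.frame(
    group = s$group, interval_end_day = s$interval_end_day,
    mean_increment_cells = round_half_up(s$mean_increment_by_week, 1),
    sd_increment_cells = round_half_up(s$sd_increment_by_week, 1),
    stringsAsFactors = FALSE)))
}

# pooled-variance two-sample two-tailed Student t-test, closed form
student_t_pooled <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  df <- nx + ny - 2
  p <- 2 * pt(-abs(t), df)
  list(t = t, df = df, p = p)
}

# one-way fixed-effects ANOVA, closed form
oneway_anova <- function(values, groups) {
  groups <- as.factor(groups)
  k <- nlevels(groups); n <- length(values)
  gm <- mean(values)
  means <- tapply(values, groups, mean)
  ns <- tapply(values, groups, length)
  ssb <- sum(ns * (means - gm)^2)
  ssw <- sum((values - means[groups])^2)
  df1 <- k - 1; df2 <- n - k
  if (df2 <= 0 || ssw == 0) {
    if (ssb == 0) return(list(F = 0, df1 = df1, df2 = df2, p = 1))
    stopf("zero within-group variance; F undefined")
  }
  F <- (ssb / df1) / (ssw / df2)
  list(F = F, df1 = df1, df2 = df2, p = pf(F, df1, df2, lower.tail = FALSE))
}

# compact letter display: groups sharing a letter are NOT significantly
# different; letters = maximal cliques of the non-significance graph,
# ordered by group mean
compact_letters <- function(labels, sig_pairs) {
  k <- length(labels)
  adj <- matrix(TRUE, k, k, dimnames = list(labels, labels))
  for (p in sig_pairs) adj[p[1], p[2]] <- adj[p[2], p[1]] <- FALSE
  cliques <- list()
  for (s in seq_len(2^k - 1)) {  # k is tiny (3 groups); brute force
    mem <- which(bitwAnd(s, 2^(seq_len(k) - 1)) > 0)
    if (all(adj[mem, mem])) cliques[[length(cliques) + 1]] <- mem
  }
  maximal <- Filter(function(m) !any(vapply(cliques, function(o)
    length(o) > length(m) && all(m %in% o), logical(1))), cliques)
  maximal <- maximal[order(vapply(maximal, min, numeric(1)))]
  letters_out <- setNames(rep("", k), labels)
  for (i in seq_along(maximal))
    for (m in maximal[[i]])
      letters_out[m] <- paste0(letters_out[m], letters[i])
  letters_out
}

#' Compare weekly increments across size groups
#'
#' Per weekly interval: single-factor (one-way) ANOVA across groups, all
#' pairwise two-tailed Student t-tests with pooled variance at alpha = 0.05
#' (no multiple-testing correction unless `bonferroni = TRUE`), and a
#' compact letter display in which groups sharing no letter differ at
#' p < 0.05.
#'
#' @param increments data.frame with columns `group`, `interval_end_day`,
#'   `cells_added` (one row per track and interval; see
#'   [compute_increments()])
#' @param alpha significance level (default 0.05, i.e. 95% confidence)
#' @param bonferroni if TRUE, divide alpha by the number of pairwise tests
#'   per week
#' @return object of class `group_comparison`: per week, `anova`
#'   (F, df, p), `pairwise` (data.frame group_i, group_j, t, df, p,
#'   significant), and `letters`
#' @export
compare_groups <- function(increments, alpha = 0.05, bonferroni = FALSE) {
  need <- c("group", "interval_end_day", "cells_added")
  if (!all(need %in% names(increments)))
    stopf("increments must have columns: %s", paste(need, collapse = ","))
  weeks <- sort(unique(increments$interval_end_day))
  out <- list()
  for (w in weeks) {
    dw <- increments[increments$interval_end_day == w, , drop = FALSE]
    gs <- intersect(size_group_labels(), unique(dw$group))
    if (length(gs) < 2 ||
        any(vapply(gs, function(g) sum(dw$group == g) < 2, logical(1))))
      stopf("need >= 2 groups with >= 2 values each at day %s", format(w))
    an <- oneway_anova(dw$cells_added[dw$group %in% gs],
                       droplevels(factor(dw$group[dw$group %in% gs])))
    pairs <- utils::combn(gs, 2, simplify = FALSE)
    a_eff <- if (bonferroni) alpha / length(pairs) else alpha
    pw <- do.call(rbind, lapply(pairs, function(p) {
      tt <- student_t_pooled(dw$cells_added[dw$group == p[1]],
                             dw$cells_added[dw$group == p[2]])
      data.frame(group_i = p[1], group_j = p[2], t = tt$t, df = tt$df,
                 p = tt$p, significant = tt$p < a_eff,
                 stringsAsFactors = FALSE)
    }))
    sig <- lapply(which(pw$significant),
                  function(i) c(pw$group_i[i], pw$group_j[i]))
    out[[format(w)]] <- list(
      interval_end_day = w, anova = an, pairwise = pw,
      letters = compact_letters(gs, sig))
  }
  structure(list(weeks = out, alpha = alpha, bonferroni = bonferroni),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  for (w in x$weeks) {
    cat(sprintf("Day %s: ANOVA F(%d,%d) = %.3f, p = %.4g; letters: %s\n",
                format(w$interval_end_day), w$anova$df1, w$anova$df2,
                w$anova$F, w$anova$p,
                paste(sprintf("%s=%s", names(w$letters), w$letters),
                      collapse = " ")))
  }
  invisible(x)
}

#' Flag hormogonium-like tracks
#'
#' Short filaments at or below the hormogonium size threshold (default 28
#' cells, ~50 µm) that show essentially no growth (total increment, with
#' negative weekly values clipped to zero, below `min_growth_cells`) behave
#' like dispersal hormogonia rather than growing trichomes.
#'
#' @param track a `filament_track`
#' @param threshold_cells size threshold on the initial cell count
#'   (default 28)
#' @param min_growth_cells growth below which the track counts as
#'   non-growing (default 1 cell)
#' @return list `flagged` (logical), `initial_cells`, `total_increment`
#'   (clipped), `threshold_cells`
#' @export
hormogonia_flag <- function(track, threshold_cells = 28, min_growth_cells = 1) {
  stopifnot(inherits(track, "filament_track"))
  init <- track$n_cells[1]
  total <- if (length(track$n_cells) > 1)
    sum(pmax(diff(track$n_cells), 0)) else 0
  list(flagged = init <= threshold_cells && total < min_growth_cells,
       initial_cells = init, total_increment = total,
       threshold_cells = threshold_cells)
}
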