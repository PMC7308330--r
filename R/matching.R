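# Event-to-grid matching.
#
# Strikes and events of one instrument are two sorted point sets on the time
# line; an optimal one-to-one assignment that first maximizes the number of
# matches within tolerance and then minimizes the total absolute deviation can
# always be taken non-crossing (uncrossing two matched pairs on a line never
# increases either objective), so it is found exactly by a monotone dynamic
# program. Events feasible for disjoint slot ranges cannot interact, which
# splits the DP into small independent components and keeps matching linear in
# practice for long performances.

# DP over one connected component. ev, sl: numeric vectors (sorted).
# Returns integer vector over slots: matched event index or NA.
match_component <- function(ev, sl, tol) {
  p <- length(ev); q <- length(sl)
  m <- matrix(0L, p + 1L, q + 1L)        # matches
  cst <- matrix(0, p + 1L, q + 1L)       # total |deviation|
  chc <- matrix(0L, p + 1L, q + 1L)      # 1 skip event, 2 skip slot, 3 match
  for (i in seq_len(p)) {
    for (j in seq_len(q)) {
      # tie preference: skip-event > skip-slot > match, so ties on distance
      # resolve toward the earlier event (and earlier slot)
      bm <- m[i, j + 1L]; bc <- cst[i, j + 1L]; bh <- 1L
      if (m[i + 1L, j] > bm || (m[i + 1L, j] == bm && cst[i + 1L, j] < bc)) {
        bm <- m[i + 1L, j]; bc <- cst[i + 1L, j]; bh <- 2L
      }
      d <- abs(ev[i] - sl[j])
      if (d <= tol) {
        mm <- m[i, j] + 1L; mc <- cst[i, j] + d
        if (mm > bm || (mm == bm && mc < bc)) { bm <- mm; bc <- mc; bh <- 3L }
      }
      m[i + 1L, j + 1L] <- bm; cst[i + 1L, j + 1L] <- bc; chc[i + 1L, j + 1L] <- bh
    }
  }
  out <- rep(NA_integer_, q)
  i <- p; j <- q
  while (i > 0L && j > 0L) {
    h <- chc[i + 1L, j + 1L]
    if (h == 1L) i <- i - 1L
    else if (h == 2L) j <- j - 1L
    else { out[j] <- i; i <- i - 1L; j <- j - 1L }
  }
  out
}

# One instrument over the whole grid: split into components, DP each.
match_instrument <- function(ev, sl, tol) {
  out <- rep(NA_integer_, length(sl))
  if (!length(ev) || !length(sl)) return(out)
  lo <- findInterval(ev - tol, sl, left.open = TRUE) + 1L  # first slot >= ev - tol
  hi <- findInterval(ev + tol, sl)                         # last slot  <= ev + tol
  feas <- which(lo <= hi)
  if (!length(feas)) return(out)
  comp_start <- 1L
  cur_hi <- hi[feas[1L]]; cur_lo <- lo[feas[1L]]
  flush <- function(a, b, slo, shi) {
    idx <- match_component(ev[feas[a:b]], sl[slo:shi], tol)
    hit <- which(!is.na(idx))
    out[slo + hit - 1L] <<- feas[a:b][idx[hit]]
  }
  for (t in seq_along(feas)[-1L]) {
    i <- feas[t]
    if (lo[i] <= cur_hi) {
      cur_hi <- max(cur_hi, hi[i])
    } else {
      flush(comp_start, t - 1L, cur_lo, cur_hi)
      comp_start <- t; cur_lo <- lo[i]; cur_hi <- hi[i]
    }
  }
  flush(comp_start, length(feas), cur_lo, cur_hi)
  out
}

#' Match drum events to a beat grid
#'
#' For each instrument separately, assigns events to the grid's expected
#' strikes one-to-one (each event consumed at most once), maximizing the
#' number of strikes matched within the tolerance and, among such assignments,
#' minimizing the total absolute deviation; ties on distance go to the earlier
#' event. Extra, unmatched events are ignored; unmatched strikes are recorded
#' as missing.
#'
#' @param events a `drum_events` tibble (already clipped to the window if
#'   desired) sorted by onset.
#' @param grid a [build_grid()] result.
#' @param tolerance_ms matching tolerance in ms; defaults to the grid's.
#' @return a tibble of class `drum_matches`: the grid columns plus
#'   `event_onset_ms`, `deviation_ms` (event minus nominal) and `matched`.
#' @export
match_events <- function(events, grid, tolerance_ms = attr(grid, "tolerance_ms")) {
  stopifnot(inherits(grid, "beat_grid"), is.finite(tolerance_ms), tolerance_ms > 0)
  res <- tibble::as_tibble(grid)
  res$event_onset_ms <- NA_real_
  for (inst in unique(res$instrument)) {
    si <- which(res$instrument == inst)
    si <- si[order(res$nominal_ms[si])]
    ei <- which(events$instrument == inst)
    if (!length(ei)) next
    hit <- match_instrument(events$onset_ms[ei], res$nominal_ms[si], tolerance_ms)
    res$event_onset_ms[si] <- events$onset_ms[ei][hit]
  }
  res$deviation_ms <- res$event_onset_ms - res$nominal_ms
  res$matched <- !is.na(res$event_onset_ms)
  attr(res, "tolerance_ms") <- tolerance_ms
  attr(res, "pattern_id") <- attr(grid, "pattern_id")
  class(res) <- c("drum_matches", class(res))
  res
}

#' Per-bar completion outcomes
#'
#' A bar is completed when every expected strike in it is matched within the
#' tolerance.
#'
#' @param matches a [match_events()] result.
#' @return a tibble with one row per bar: `bar_index`, `n_expected`,
#'   `n_matched`, `completed`.
#' @export
bar_results <- function(matches) {
  stopifnot(inherits(matches, "drum_matches"))
  matches |>
    dplyr::group_by(.data$bar_index) |>
    dplyr::summarise(n_expected = dplyr::n(),
                     n_matched = sum(.data$matched),
                     completed = all(.data$matched),
                     .groups = "drop")
}

#' Percentage of bars completed
#'
#' @param results a [match_events()] result or a [bar_results()] tibble.
#' @return percent of scored bars completed, 0-100.
#' @export
pct_bars_completed <- function(results) {
  if (inherits(results, "drum_matches")) results <- bar_results(results)
  if (!nrow(results)) stop("no bars scored")
  100 * sum(results$completed) / nrow(results)
}

#' Flam errors of completed bars
#'
#' For every slot that expects two or more strikes, the flam error is the time
#' from the first to the last of the matched events at that slot (so a
#' three-limb slot uses the spread across all three). Incomplete bars are
#' excluded so a breaking-down performance cannot exaggerate the error.
#'
#' @param matches a [match_events()] result.
#' @return a tibble with `bar_index`, `slot_index`, `n_strikes`, `flam_ms`.
#' @export
flam_errors <- function(matches) {
  stopifnot(inherits(matches, "drum_matches"))
  done <- bar_results(matches)
  done <- done$bar_index[done$completed]
  if (!length(done))
    return(tibble::tibble(bar_index = integer(), slot_index = integer(),
                          n_strikes = integer(), flam_ms = numeric()))
  matches |>
    dplyr::filter(.data$bar_index %in% done) |>
    dplyr::group_by(.data$bar_index, .data$slot_index) |>
    dplyr::summarise(n_strikes = dplyr::n(),
                     flam_ms = max(.data$event_onset_ms) - min(.data$event_onset_ms),
                     .groups = "drop") |>
    dplyr::filter(.data$n_strikes >= 2L)
}

#' HRS coordination error
#'
#' The hi-hat(pedal)/ride/snare measure: the mean flam error over the
#' three-limb slots (beats 2 and 4) of the quarter-note pattern, pooled across
#' all completed bars. Defined only for the quarter pattern.
#'
#' @param matches a [match_events()] result for the quarter pattern.
#' @param template the matching [make_template()] (used to assert the pattern).
#' @return mean HRS flam error in ms, or `NA` if no bar was completed.
#' @export
hrs_error <- function(matches, template) {
  stopifnot(inherits(template, "pattern_template"))
  if (template$pattern_id != "quarter_pattern")
    stop("HRS error is defined on the quarter-note pattern only")
  fl <- flam_errors(matches)
  fl <- fl[fl$slot_index %in% c(2L, 4L), ]
  if (!nrow(fl)) return(NA_real_)
  mean(fl$flam_ms)
}

#' Score one performance
#'
#' Builds the grid, matches the events and returns the summary measures used
#' by the assessment: percentage of bars completed and (for the quarter
#' pattern) the HRS flam error.
#'
#' @param events a `drum_events` tibble.
#' @param template a [make_template()] result.
#' @param window a [capture_window()].
#' @param song_offset_ms nominal time of bar 1 in ms.
#' @param clip clip events to the window before matching (default `TRUE`).
#' @return a list of class `performance_summary`: `pattern_id`,
#'   `pct_bars_completed`, `hrs_flam_mean_ms` (`NA` unless quarter pattern with
#'   completed bars), `n_bars_scored`, `n_bars_completed`.
#' @export
score_performance <- function(events, template, window = capture_window(),
                              song_offset_ms = 0, clip = TRUE) {
  if (clip) events <- clip_window(events, window)
  grid <- build_grid(template, window, song_offset_ms)
  matches <- match_events(events, grid)
  bars <- bar_results(matches)
  structure(list(
    pattern_id = template$pattern_id,
    pct_bars_completed = pct_bars_completed(bars),
    hrs_flam_mean_ms = if (template$pattern_id == "quarter_pattern")
      hrs_error(matches, template) else NA_real_,
    n_bars_scored = nrow(bars),
    n_bars_completed = sum(bars$completed)
  ), class = "performance_summary")
}

#' @export
print.performance_summary <- function(x, ...) {
  cat(sprintf("<performance_summary> %s: %.1f%% bars completed (%d/%d)",
              x$pattern_id, x$pct_bars_completed,
              x$n_bars_completed, x$n_bars_scored))
  if (!is.na(x$hrs_flam_mean_ms))
    cat(sprintf(", HRS flam %.1f ms", x$hrs_flam_mean_ms))
  cat("\n")
  invisible(x)
}

#' Pre/post delta scores
#'
#' Post-training minus pre-training change of the performance measures. The
#' HRS change is reported both as a raw ms difference (`delta_hrs_ms`,
#' post - pre; negative is improvement) and as percent precision change
#' (`delta_hrs_pct`, `100 * (pre - post) / pre`; positive is improvement).
#'
#' @param pre,post `performance_summary` objects from the same pattern.
#' @return a list with `delta_pct_bars`, `delta_hrs_ms`, `delta_hrs_pct`.
#' @export
delta_score <- function(pre, post) {
  stopifnot(inherits(pre, "performance_summary"),
            inherits(post, "performance_summary"))
  if (pre$pattern_id != post$pattern_id)
    stop("pre and post summaries are from different patterns")
  hrs_ok <- !is.na(pre$hrs_flam_mean_ms) && !is.na(post$hrs_flam_mean_ms)
  list(
    delta_pct_bars = post$pct_bars_completed - pre$pct_bars_completed,
    delta_hrs_ms = if (hrs_ok) post$hrs_flam_mean_ms - pre$hrs_flam_mean_ms else NA_real_,
    delta_hrs_pct = if (hrs_ok && pre$hrs_flam_mean_ms != 0)
      100 * (pre$hrs_flam_mean_ms - post$hrs_flam_mean_ms) / pre$hrs_flam_mean_ms
    else NA_real_
  )
}
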