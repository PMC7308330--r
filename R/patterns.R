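#' Build an assessment pattern template
#'
#' Two fixed-tempo assessment patterns are defined, each one bar of 4/4:
#'
#' * `quarter_pattern` — four quarter notes: beats 1 and 3 are ride + kick
#'   (right hand with right foot), beats 2 and 4 are ride + snare + pedal
#'   hi-hat (right hand, left hand and left foot together). Beats 2 and 4 are
#'   the three-limb HRS (hi-hat/ride/snare) coordination slots.
#' * `eighth_pattern` — a closed hi-hat on all eight eighth notes, kick on main
#'   beats 1 and 3, snare on main beats 2 and 4.
#'
#' The completion tolerance is half of the pattern's subdivision interval: at
#' the default 120 bpm that is 250 ms for the quarter pattern and 125 ms for
#' the eighth pattern.
#'
#' @param pattern_id `"quarter_pattern"` or `"eighth_pattern"`.
#' @param tempo_bpm beats per minute (> 0); default 120.
#' @param tolerance_override optional tolerance in ms replacing the half-beat
#'   default.
#' @return a list of class `pattern_template` with fields `pattern_id`,
#'   `tempo_bpm`, `beats_per_bar`, `slots_per_bar`, `expected` (one tibble row
#'   per required strike: `slot_index`, `limb`, `instrument`) and
#'   `tolerance_ms`.
#' @examples
#' make_template("quarter_pattern", 120)$tolerance_ms  # 250
#' make_template("eighth_pattern", 120)$tolerance_ms   # 125
#' @export
make_template <- function(pattern_id = c("quarter_pattern", "eighth_pattern"),
                          tempo_bpm = 120, tolerance_override = NULL) {
  pattern_id <- match.arg(pattern_id)
  stopifnot(is.finite(tempo_bpm), tempo_bpm > 0)
  beat_ms <- 60000 / tempo_bpm

  if (pattern_id == "quarter_pattern") {
    slots_per_bar <- 4L
    expected <- tibble::tibble(
      slot_index = c(1L, 1L, 2L, 2L, 2L, 3L, 3L, 4L, 4L, 4L),
      instrument = c("ride", "kick",
                     "ride", "snare", "hihat_pedal",
                     "ride", "kick",
                     "ride", "snare", "hihat_pedal")
    )
    tol <- 0.5 * beat_ms
  } else {
    slots_per_bar <- 8L
    expected <- tibble::tibble(
      slot_index = c(1:8, 1L, 5L, 3L, 7L),
      instrument = c(rep("hihat_closed", 8L), "kick", "kick", "snare", "snare")
    )
    expected <- expected[order(expected$slot_index, expected$instrument), ]
    tol <- 0.25 * beat_ms
  }
  i2l <- default_limb_map()$instrument_to_limb
  expected$limb <- unname(i2l[expected$instrument])
  expected <- expected[, c("slot_index", "limb", "instrument")]

  structure(list(pattern_id = pattern_id,
                 tempo_bpm = tempo_bpm,
                 beats_per_bar = 4L,
                 slots_per_bar = slots_per_bar,
                 expected = expected,
                 tolerance_ms = if (is.null(tolerance_override)) tol
                                else as.numeric(tolerance_override)),
            class = "pattern_template")
}

#' Lay out the beat grid of expected strikes over a capture window
#'
#' Bars are anchored to the song's first bar at `song_offset_ms`; a bar is in
#' the window if and only if its bar-start nominal time falls in
#' `[start_s, end_s)` (half-open). One row per expected strike.
#'
#' @param template a [make_template()] result.
#' @param window a [capture_window()].
#' @param song_offset_ms nominal time of bar 1, ms; default 0.
#' @return a tibble of class `beat_grid` with columns `bar_index` (1-based),
#'   `slot_index`, `nominal_ms`, `limb`, `instrument`; attribute
#'   `tolerance_ms`.
#' @export
build_grid <- function(template, window = capture_window(), song_offset_ms = 0) {
  stopifnot(inherits(template, "pattern_template"),
            inherits(window, "capture_window"))
  beat_ms <- 60000 / template$tempo_bpm
  bar_ms <- template$beats_per_bar * beat_ms
  start_ms <- window$start_s * 1000
  end_ms <- window$end_s * 1000
  if (end_ms - start_ms < bar_ms)
    stop("capture window shorter than one bar (", bar_ms, " ms)")

  k <- seq(from = max(0L, ceiling((start_ms - song_offset_ms) / bar_ms)),
           by = 1L,
           length.out = ceiling((end_ms - song_offset_ms) / bar_ms))
  bar_start <- song_offset_ms + k * bar_ms
  keep <- bar_start >= start_ms & bar_start < end_ms
  k <- k[keep]; bar_start <- bar_start[keep]
  if (!length(k)) stop("no bar starts inside the capture window")

  slot_ms <- bar_ms / template$slots_per_bar
  grid <- tidyr::crossing(bar = seq_along(k), template$expected)
  grid <- tibble::tibble(
    bar_index = grid$bar,
    slot_index = grid$slot_index,
    nominal_ms = bar_start[grid$bar] + (grid$slot_index - 1L) * slot_ms,
    limb = grid$limb,
    instrument = grid$instrument
  )
  grid <- grid[order(grid$nominal_ms, grid$instrument), ]
  attr(grid, "tolerance_ms") <- template$tolerance_ms
  attr(grid, "pattern_id") <- template$pattern_id
  class(grid) <- c("beat_grid", class(grid))
  grid
}
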