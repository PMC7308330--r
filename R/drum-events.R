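#' @importFrom rlang .data
#' @importFrom stats lm pnorm pf rnorm runif rpois rbinom coef residuals
#'   setNames shapiro.test wilcox.test chisq.test cor.test var sd integrate
#'   p.adjust
#' @importFrom utils read.csv write.csv
NULL

#' Recognised drum-kit instruments and limbs
#'
#' The kit pieces used by the two assessment patterns, plus `"other"` /
#' `"unknown"` catch-alls for unmapped percussion notes.
#'
#' @name kit-vocabulary
#' @keywords internal
NULL

.instruments <- c("kick", "snare", "ride", "hihat_closed", "hihat_pedal", "other")
.limbs <- c("RH", "LH", "RF", "LF", "unknown")

#' Construct a drum event stream
#'
#' A drum event stream is a tibble with one row per percussive onset and
#' columns `onset_ms` (milliseconds from song start, finite and non-negative),
#' `instrument`, `limb` and `velocity` (integer 0-127). Rows are kept sorted by
#' `onset_ms`.
#'
#' @param onset_ms numeric vector of onset times in milliseconds.
#' @param instrument character vector; one of `kick`, `snare`, `ride`,
#'   `hihat_closed`, `hihat_pedal`, `other`.
#' @param limb character vector; one of `RH`, `LH`, `RF`, `LF`, `unknown`.
#' @param velocity integer vector in 0-127.
#' @return a tibble of class `drum_events`, sorted by `onset_ms`.
#' @export
drum_events <- function(onset_ms = numeric(), instrument = character(),
                        limb = character(), velocity = integer()) {
  if (length(onset_ms)) {
    stopifnot(all(is.finite(onset_ms)), all(onset_ms >= 0))
    if (!all(instrument %in% .instruments))
      stop("unknown instrument: ", paste(setdiff(instrument, .instruments), collapse = ", "))
    if (!all(limb %in% .limbs))
      stop("unknown limb: ", paste(setdiff(limb, .limbs), collapse = ", "))
    stopifnot(all(velocity >= 0 & velocity <= 127))
  }
  ev <- tibble::tibble(
    onset_ms = as.numeric(onset_ms),
    instrument = as.character(instrument),
    limb = as.character(limb),
    velocity = as.integer(velocity)
  )
  ev <- ev[order(ev$onset_ms), ]
  class(ev) <- c("drum_events", class(ev))
  ev
}

#' Default percussion-note to limb mapping
#'
#' Follows the General MIDI percussion assignment for the kit pieces the
#' assessment patterns use: note 36 kick, 38 snare, 51 ride, 44 pedal hi-hat,
#' 42 closed hi-hat. Limbs follow the kit assignment of the quarter-note
#' pattern: right hand on the ride, left hand on the snare, right foot on the
#' kick, left foot on the hi-hat pedal; the closed (stick) hi-hat of the
#' eighth-note pattern is played by the right hand. Notes absent from the map
#' are routed to `other`/`unknown`.
#'
#' @param note_to_instrument named list/vector, MIDI note number -> instrument.
#' @param instrument_to_limb named list/vector, instrument -> limb.
#' @return a list of class `limb_map` with elements `note_to_instrument` and
#'   `instrument_to_limb`.
#' @export
limb_map <- function(note_to_instrument = c(`36` = "kick", `38` = "snare",
                                            `51` = "ride", `44` = "hihat_pedal",
                                            `42` = "hihat_closed"),
                     instrument_to_limb = c(kick = "RF", snare = "LH",
                                            ride = "RH", hihat_pedal = "LF",
                                            hihat_closed = "RH", other = "unknown")) {
  n2i <- unlist(note_to_instrument)
  i2l <- unlist(instrument_to_limb)
  if (!all(n2i %in% .instruments))
    stop("note_to_instrument maps to unknown instrument(s)")
  if (!all(i2l %in% .limbs))
    stop("instrument_to_limb maps to unknown limb(s)")
  structure(list(note_to_instrument = n2i, instrument_to_limb = i2l),
            class = "limb_map")
}

#' @rdname limb_map
#' @export
default_limb_map <- function() limb_map()

#' Read a limb map from a YAML config file
#'
#' The file must contain `note_to_instrument` (note number -> instrument) and
#' may contain `instrument_to_limb`; missing limb entries fall back to the
#' default kit assignment.
#'
#' @param path path to a YAML file.
#' @return a `limb_map`.
#' @export
read_limb_map_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$note_to_instrument))
    stop("limb map YAML must define note_to_instrument")
  i2l <- default_limb_map()$instrument_to_limb
  if (!is.null(cfg$instrument_to_limb)) {
    upd <- unlist(cfg$instrument_to_limb)
    i2l[names(upd)] <- upd
  }
  limb_map(note_to_instrument = unlist(cfg$note_to_instrument),
           instrument_to_limb = i2l)
}

map_note <- function(note, map) {
  inst <- unname(map$note_to_instrument[as.character(note)])
  inst[is.na(inst)] <- "other"
  limb <- unname(map$instrument_to_limb[inst])
  limb[is.na(limb)] <- "unknown"
  list(instrument = inst, limb = limb)
}

#' Capture window for assessment scoring
#'
#' The assessment scores a fixed period of each song; the default keeps the
#' two-minute stretch from 60 s to 180 s (minutes 1-3). The interval is
#' half-open, `[start_s, end_s)`.
#'
#' @param start_s window start in seconds (default 60).
#' @param end_s window end in seconds (default 180).
#' @return a list of class `capture_window`.
#' @export
capture_window <- function(start_s = 60, end_s = 180) {
  stopifnot(is.finite(start_s), is.finite(end_s), start_s >= 0, start_s < end_s)
  structure(list(start_s = start_s, end_s = end_s), class = "capture_window")
}

#' Clip an event stream to a capture window
#'
#' Keeps events with `start_s*1000 <= onset_ms < end_s*1000`, preserving order.
#' Idempotent; an empty result is allowed.
#'
#' @param events a `drum_events` tibble.
#' @param window a [capture_window()].
#' @return the clipped `drum_events`.
#' @export
clip_window <- function(events, window = capture_window()) {
  stopifnot(inherits(window, "capture_window"))
  keep <- events$onset_ms >= window$start_s * 1000 &
    events$onset_ms < window$end_s * 1000
  events[keep, ]
}

#' Read / write drum event streams as CSV
#'
#' The CSV schema is fixed: columns `onset_ms,instrument,limb,velocity`.
#' `write_events_csv()` followed by `read_events_csv()` is lossless.
#'
#' @param path file path.
#' @param events a `drum_events` tibble.
#' @return `read_events_csv()` returns a `drum_events` tibble;
#'   `write_events_csv()` returns `path` invisibly.
#' @export
read_events_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("onset_ms", "instrument", "limb", "velocity")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("event CSV ", path, " lacks required column(s): ",
         paste(missing, collapse = ", "))
  drum_events(df$onset_ms, df$instrument, df$limb, df$velocity)
}

#' @rdname read_events_csv
#' @export
write_events_csv <- function(events, path) {
  utils::write.csv(as.data.frame(events)[, c("onset_ms", "instrument", "limb", "velocity")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
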