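# Standard MIDI File (SMF) type 0/1 reading and writing.
#
# Only what drum assessment needs: note-on extraction with tick -> millisecond
# conversion from tempo meta-events (piecewise-constant tempo), and a type-0
# writer used for round-trips and synthetic performances. SMPTE time division
# is not supported.

be_uint <- function(raw, from, nbytes) {
  v <- 0
  for (k in seq_len(nbytes)) v <- v * 256 + as.integer(raw[from + k - 1L])
  v
}

be_bytes <- function(value, nbytes) {
  out <- raw(nbytes)
  for (k in nbytes:1) {
    out[k] <- as.raw(value %% 256)
    value <- value %/% 256
  }
  out
}

# variable-length quantity at position pos; returns list(value, next_pos)
read_varlen <- function(raw, pos) {
  v <- 0
  repeat {
    b <- as.integer(raw[pos]); pos <- pos + 1L
    v <- v * 128 + (b %% 128)
    if (b < 128) break
  }
  list(value = v, pos = pos)
}

write_varlen <- function(value) {
  bytes <- as.raw(value %% 128)
  value <- value %/% 128
  while (value > 0) {
    bytes <- c(as.raw(128 + value %% 128), bytes)
    value <- value %/% 128
  }
  bytes
}

# Parse one MTrk chunk body; returns note-ons (tick, note, velocity) and
# tempo events (tick, us_per_qn).
parse_track <- function(raw, pos, end) {
  tick <- 0
  status <- NULL
  notes <- list()
  tempos <- list()
  while (pos < end) {
    dv <- read_varlen(raw, pos); pos <- dv$pos
    tick <- tick + dv$value
    b <- as.integer(raw[pos])
    if (b >= 128L) { status <- b; pos <- pos + 1L }
    if (is.null(status)) stop("corrupt SMF track: data byte with no running status")
    if (status == 255L) {                      # meta event
      type <- as.integer(raw[pos]); pos <- pos + 1L
      lv <- read_varlen(raw, pos); pos <- lv$pos
      if (type == 81L && lv$value == 3L)
        tempos[[length(tempos) + 1L]] <- c(tick, be_uint(raw, pos, 3L))
      if (type == 47L) { pos <- pos + lv$value; break }   # end of track
      pos <- pos + lv$value
    } else if (status %in% c(240L, 247L)) {    # sysex
      lv <- read_varlen(raw, pos); pos <- lv$pos + lv$value
    } else {
      hi <- status %/% 16L
      ndata <- if (hi %in% c(12L, 13L)) 1L else 2L
      if (hi == 9L) {                          # note-on
        note <- as.integer(raw[pos]); vel <- as.integer(raw[pos + 1L])
        if (vel > 0L) notes[[length(notes) + 1L]] <- c(tick, note, vel)
      }
      pos <- pos + ndata
    }
  }
  list(notes = notes, tempos = tempos, pos = pos)
}

ticks_to_ms <- function(ticks, tempo_map, ppq) {
  # tempo_map: matrix with columns tick, us_per_qn, sorted by tick, first row
  # at tick 0. Cumulative ms at each segment start, then linear within.
  seg_ms <- c(0, cumsum(diff(tempo_map[, 1L]) * tempo_map[-nrow(tempo_map), 2L] / (ppq * 1000)))
  idx <- findInterval(ticks, tempo_map[, 1L])
  seg_ms[idx] + (ticks - tempo_map[idx, 1L]) * tempo_map[idx, 2L] / (ppq * 1000)
}

#' Read a drum performance from a Standard MIDI File
#'
#' Parses an SMF type 0 or 1 file, takes every note-on event with velocity
#' greater than zero as a percussive onset, converts ticks to milliseconds
#' using the file's tempo meta-events (500000 us per quarter note assumed
#' before the first tempo event, piecewise-constant after), and maps note
#' numbers to instruments and limbs.
#'
#' @param path path to an SMF type 0/1 file with pulses-per-quarter-note time
#'   division.
#' @param map a [limb_map()]; notes absent from it become `other`/`unknown`.
#' @return a `drum_events` tibble sorted by `onset_ms`.
#' @seealso [write_smf()] for the inverse used in round-trip tests.
#' @export
read_smf <- function(path, map = default_limb_map()) {
  if (!file.exists(path)) stop("SMF file not found: ", path)
  raw <- readBin(path, "raw", file.size(path))
  if (length(raw) < 14L || rawToChar(raw[1:4]) != "MThd" || be_uint(raw, 5L, 4L) != 6L)
    stop("not a Standard MIDI File (bad MThd header): ", path)
  format <- be_uint(raw, 9L, 2L)
  ntrks <- be_uint(raw, 11L, 2L)
  division <- be_uint(raw, 13L, 2L)
  if (!format %in% c(0L, 1L)) stop("unsupported SMF format ", format, ": ", path)
  if (division >= 32768L) stop("SMPTE time division not supported: ", path)

  pos <- 15L
  notes <- list(); tempos <- list()
  for (t in seq_len(ntrks)) {
    if (pos + 7L > length(raw) || rawToChar(raw[pos:(pos + 3L)]) != "MTrk")
      stop("corrupt SMF (missing MTrk chunk): ", path)
    len <- be_uint(raw, pos + 4L, 4L)
    body <- parse_track(raw, pos + 8L, pos + 8L + len)
    notes <- c(notes, body$notes)
    tempos <- c(tempos, body$tempos)
    pos <- pos + 8L + len
  }
  if (!length(notes)) stop("SMF contains no note-on events: ", path)

  tm <- if (length(tempos)) do.call(rbind, tempos) else matrix(numeric(0), ncol = 2)
  tm <- tm[order(tm[, 1L]), , drop = FALSE]
  if (!nrow(tm) || tm[1L, 1L] > 0) tm <- rbind(c(0, 500000), tm)
  nm <- do.call(rbind, notes)
  ms <- ticks_to_ms(nm[, 1L], tm, division)
  mapped <- map_note(nm[, 2L], map)
  drum_events(ms, mapped$instrument, mapped$limb, nm[, 3L])
}

#' Write a drum event stream to a Standard MIDI File
#'
#' Emits an SMF type 0 file at constant tempo on MIDI channel 10, with note
#' numbers taken from the inverse of the limb map's note-to-instrument table.
#' Onsets are quantized to the tick grid, so `read_smf(write_smf(x))`
#' reproduces onsets to within one tick.
#'
#' @param events a `drum_events` tibble.
#' @param path output file path.
#' @param ppq pulses (ticks) per quarter note; default 480.
#' @param tempo_us microseconds per quarter note; default 500000 (120 bpm).
#' @param map a [limb_map()] used to pick note numbers; instruments without a
#'   note are written as note 37.
#' @return `path`, invisibly.
#' @export
write_smf <- function(events, path, ppq = 480L, tempo_us = 500000L,
                      map = default_limb_map()) {
  inst2note <- setNames(as.integer(names(map$note_to_instrument)),
                        unname(map$note_to_instrument))
  note <- inst2note[events$instrument]
  note[is.na(note)] <- 37L
  tick <- round(events$onset_ms * ppq / (tempo_us / 1000))

  ev <- rbind(
    data.frame(tick = tick, status = 0x99, note = note, data2 = events$velocity),
    data.frame(tick = tick + max(1L, ppq %/% 8L), status = 0x89, note = note, data2 = 0L)
  )
  ev <- ev[order(ev$tick, ev$status), ]   # note-offs (0x89) before note-ons at a tick

  body <- list(write_varlen(0), as.raw(c(0xFF, 0x51, 0x03)), be_bytes(tempo_us, 3L))
  last <- 0
  for (i in seq_len(nrow(ev))) {
    body[[length(body) + 1L]] <- write_varlen(ev$tick[i] - last)
    body[[length(body) + 1L]] <- as.raw(c(ev$status[i], ev$note[i], ev$data2[i]))
    last <- ev$tick[i]
  }
  body[[length(body) + 1L]] <- c(write_varlen(0), as.raw(c(0xFF, 0x2F, 0x00)))
  body <- unlist(body)

  con <- file(path, "wb"); on.exit(close(con))
  writeBin(c(charToRaw("MThd"), be_bytes(6, 4L), be_bytes(0, 2L), be_bytes(1, 2L),
             be_bytes(ppq, 2L),
             charToRaw("MTrk"), be_bytes(length(body), 4L), body), con)
  invisible(path)
}
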