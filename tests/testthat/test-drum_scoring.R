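quarter <- make_template("quarter_pattern", 120)

# perfect stream for a grid: one event per expected strike at nominal time
perfect_stream <- function(grid) {
  drum_events(grid$nominal_ms, grid$instrument, grid$limb,
              rep(100L, nrow(grid)))
}

test_that("templates reproduce the half-beat tolerances and strike layout", {
  expect_equal(quarter$tolerance_ms, 250)
  expect_equal(make_template("eighth_pattern", 120)$tolerance_ms, 125)
  expect_equal(make_template("quarter_pattern", 60)$tolerance_ms, 500)
  expect_equal(make_template("quarter_pattern", 120, tolerance_override = 99)$tolerance_ms, 99)

  # quarter: beats 1/3 two-limb (ride+kick), beats 2/4 three-limb (HRS)
  per_slot <- table(quarter$expected$slot_index)
  expect_equal(as.integer(per_slot), c(2L, 3L, 2L, 3L))
  s2 <- quarter$expected[quarter$expected$slot_index == 2, ]
  expect_setequal(s2$instrument, c("ride", "snare", "hihat_pedal"))
  expect_setequal(s2$limb, c("RH", "LH", "LF"))

  # eighth: hi-hat on all 8 slots, kick on 1/5, snare on 3/7
  e <- make_template("eighth_pattern", 120)$expected
  expect_equal(sum(e$instrument == "hihat_closed"), 8L)
  expect_equal(e$slot_index[e$instrument == "kick"], c(1L, 5L))
  expect_equal(e$slot_index[e$instrument == "snare"], c(3L, 7L))
  expect_equal(nrow(e), 12L)
})

test_that("grid has the right bar count, spacing and offset translation", {
  g <- build_grid(quarter, capture_window(60, 180))
  expect_equal(length(unique(g$bar_index)), 60L)  # 120 s / 2 s bars
  expect_equal(min(g$nominal_ms), 60000)
  slots <- sort(unique(g$nominal_ms))
  expect_true(all(abs(diff(slots) - 500) < 1e-9))

  g2 <- build_grid(make_template("quarter_pattern", 60), capture_window(0, 8))
  expect_equal(length(unique(g2$bar_index)), 2L)

  off <- build_grid(quarter, capture_window(60, 180), song_offset_ms = 130)
  expect_equal(off$nominal_ms, g$nominal_ms + 130)

  expect_error(build_grid(quarter, capture_window(0, 1)), "shorter than one bar")
})

test_that("matching handles perfect, displaced and tied streams as specified", {
  g <- build_grid(quarter, capture_window(0, 8))  # 4 bars
  ev <- perfect_stream(g)
  m <- match_events(ev, g)
  expect_true(all(m$matched))
  expect_true(all(m$deviation_ms == 0))
  expect_equal(pct_bars_completed(m), 100)

  # one snare displaced +300 ms (tolerance 250) in bar 2 breaks only bar 2
  ev2 <- ev
  i <- which(ev2$instrument == "snare")[3]  # bar 2, beat 2 snare
  ev2$onset_ms[i] <- ev2$onset_ms[i] + 300
  m2 <- match_events(ev2[order(ev2$onset_ms), ], g)
  br <- bar_results(m2)
  expect_equal(br$completed, c(TRUE, FALSE, TRUE, TRUE))
  expect_equal(pct_bars_completed(m2), 75)

  # two candidate events equidistant from one slot: earlier one is taken
  g1 <- build_grid(quarter, capture_window(0, 4))
  slot <- g1[g1$instrument == "snare", ][1, ]
  ev3 <- drum_events(slot$nominal_ms + c(-50, 50), rep("snare", 2),
                     rep("LH", 2), rep(100L, 2))
  m3 <- match_events(ev3, g1)
  hit <- m3[m3$instrument == "snare" & m3$matched, ]
  expect_equal(hit$deviation_ms[1], -50)
})

test_that("matcher equals the exhaustive assignment oracle on small streams", {
  g <- build_grid(quarter, capture_window(0, 8))  # 4 bars, 40 strikes
  withr::with_seed(20, {
    for (rep in 1:40) {
      ev <- random_small_stream(g, tol = 250, n_extra = 1, keep_prob = 0.45)
      m <- match_events(ev, g)
      o <- oracle_score(ev, g, tol = 250)
      expect_equal(bar_results(m)$completed, o$completed)
      expect_equal(sum(m$matched), o$count)
      expect_equal(sum(abs(m$deviation_ms[m$matched])), o$cost, tolerance = 1e-9)
    }
  })
})

test_that("completion never decreases as tolerance grows", {
  g <- build_grid(quarter, capture_window(0, 16))
  withr::with_seed(21, {
    ev <- random_small_stream(g, tol = 200, n_extra = 4)
  })
  pcts <- sapply(c(50, 100, 150, 200, 250, 350, 500),
                 function(tol) pct_bars_completed(match_events(ev, g, tol)))
  expect_true(all(diff(pcts) >= 0))
})

test_that("flam errors are first-to-last spreads in completed bars only", {
  g <- build_grid(quarter, capture_window(0, 2))  # one bar
  ev <- perfect_stream(g)
  # beat 2 (three limbs): events at +0, +10, +25 -> flam 25
  i2 <- which(g$slot_index == 2)
  ev$onset_ms[i2] <- g$nominal_ms[i2] + c(0, 10, 25)
  m <- match_events(ev[order(ev$onset_ms), ], g)
  fl <- flam_errors(m)
  expect_equal(fl$flam_ms[fl$slot_index == 2], 25)
  expect_equal(fl$flam_ms[fl$slot_index == 1], 0)   # simultaneous pair
  expect_equal(nrow(fl), 4L)                        # every slot is multi-strike

  # break the bar: no flam entries at all
  ev2 <- ev[-1, ]
  m2 <- match_events(ev2, g)
  expect_equal(nrow(flam_errors(m2)), 0L)
})

test_that("HRS error pools beats 2 and 4 of completed quarter bars", {
  g <- build_grid(quarter, capture_window(0, 8))  # 4 bars
  ev <- perfect_stream(g)
  m <- match_events(ev, g)
  expect_equal(hrs_error(m, quarter), 0)

  # shift the pedal hi-hat +10 at beat 2 and +30 at beat 4 in every bar
  sh <- ev$instrument == "hihat_pedal"
  beat <- rep(c(10, 30), 4)
  ev$onset_ms[sh] <- ev$onset_ms[sh] + beat
  m2 <- match_events(ev[order(ev$onset_ms), ], g)
  expect_equal(hrs_error(m2, quarter), 20)

  # beats 1/3 flams do not enter HRS
  fl <- flam_errors(m2)
  expect_true(all(fl$flam_ms[fl$slot_index %in% c(1, 3)] == 0))

  eighth <- make_template("eighth_pattern", 120)
  expect_error(hrs_error(m2, eighth), "quarter")
  # no completed bars -> NA
  m3 <- match_events(drum_events(0, "kick", "RF", 100L), g)
  expect_true(is.na(hrs_error(m3, quarter)))
})

test_that("all scores are invariant to a common time translation", {
  w <- capture_window(0, 16)
  ev <- simulate_performance(quarter, w, drummer_params(jitter_sd_ms = 60,
                                                        miss_prob = 0.1,
                                                        extra_rate = 0.5),
                             seed = 9)
  s0 <- score_performance(ev, quarter, w, clip = FALSE)
  shift <- 1234
  ev2 <- ev
  ev2$onset_ms <- ev2$onset_ms + shift
  s1 <- score_performance(ev2, quarter, w, song_offset_ms = shift, clip = FALSE)
  expect_equal(s1$pct_bars_completed, s0$pct_bars_completed)
  expect_equal(s1$hrs_flam_mean_ms, s0$hrs_flam_mean_ms)
})

test_that("delta scores report change in both conventions", {
  mk <- function(pct, hrs) structure(
    list(pattern_id = "quarter_pattern", pct_bars_completed = pct,
         hrs_flam_mean_ms = hrs, n_bars_scored = 60L,
         n_bars_completed = as.integer(round(0.6 * pct))),
    class = "performance_summary")
  d <- delta_score(mk(13, 100), mk(47, 82))
  expect_equal(d$delta_pct_bars, 34)
  expect_equal(d$delta_hrs_ms, -18)
  expect_equal(d$delta_hrs_pct, 18)

  d0 <- delta_score(mk(40, 55), mk(40, 55))
  expect_equal(d0$delta_pct_bars, 0)
  expect_equal(d0$delta_hrs_ms, 0)

  expect_true(is.na(delta_score(mk(10, NA), mk(20, 50))$delta_hrs_ms))
})
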