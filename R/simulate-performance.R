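#' Drummer simulation parameters
#'
#' Controls the timing structure of a synthetic performance. Per-limb values
#' may be a single number (recycled) or a named vector over
#' `RH`, `LH`, `RF`, `LF`.
#'
#' @param jitter_sd_ms per-limb Gaussian timing jitter SD, ms (>= 0). The
#'   default 60 ms sits in the middle of a plausible novice range; jitter
#'   magnitudes for true beginners are not well established, so treat this as
#'   an adjustable placeholder.
#' @param lag_ms per-limb systematic offset, ms.
#' @param miss_prob per-strike dropout probability in `[0, 1]`.
#' @param extra_rate spurious strikes per bar (Poisson mean, >= 0).
#' @param learning_gain multiplicative reduction of jitter and miss
#'   probability after training, in `(0, 1]`; a trained performance uses
#'   `jitter_sd_ms * learning_gain` and `miss_prob * learning_gain`.
#' @param ar1_phi optional AR(1) coefficient in `[0, 1)` adding slow drift
#'   correlation between successive strikes of a limb; 0 (default) keeps
#'   strikes independent so closed-form completion probabilities apply.
#' @return a list of class `drummer_params`.
#' @export
drummer_params <- function(jitter_sd_ms = 60, lag_ms = 0, miss_prob = 0.05,
                           extra_rate = 0.2, learning_gain = 1, ar1_phi = 0) {
  limbs <- c("RH", "LH", "RF", "LF")
  expand <- function(v) {
    if (length(v) == 1L && is.null(names(v))) return(setNames(rep(v, 4), limbs))
    out <- setNames(rep(0, 4), limbs)
    out[names(v)] <- v
    out
  }
  jitter_sd_ms <- expand(jitter_sd_ms); lag_ms <- expand(lag_ms)
  stopifnot(all(jitter_sd_ms >= 0), miss_prob >= 0, miss_prob <= 1,
            extra_rate >= 0, learning_gain > 0, learning_gain <= 1,
            ar1_phi >= 0, ar1_phi < 1)
  structure(list(jitter_sd_ms = jitter_sd_ms, lag_ms = lag_ms,
                 miss_prob = miss_prob, extra_rate = extra_rate,
                 learning_gain = learning_gain, ar1_phi = ar1_phi),
            class = "drummer_params")
}

#' Apply the learning gain to drummer parameters
#'
#' Returns the post-training parameter set: jitter SD and miss probability
#' scaled by `learning_gain`.
#'
#' @param params a [drummer_params()].
#' @return a `drummer_params` describing the trained drummer.
#' @export
after_training <- function(params) {
  stopifnot(inherits(params, "drummer_params"))
  params$jitter_sd_ms <- params$jitter_sd_ms * params$learning_gain
  params$miss_prob <- params$miss_prob * params$learning_gain
  params$learning_gain <- 1
  params
}

#' Simulate a drum performance against a pattern grid
#'
#' For every expected strike of the grid, with probability `1 - miss_prob` an
#' event is emitted at `nominal + lag_ms[limb] + N(0, jitter_sd_ms[limb])`
#' (plus optional AR(1) drift). Poisson-distributed extra events are spread
#' uniformly over the window on randomly chosen instruments, so they carry no
#' information about the grid. Bit-identical output for identical seeds.
#'
#' @param template a [make_template()] result.
#' @param window a [capture_window()].
#' @param params a [drummer_params()].
#' @param song_offset_ms nominal time of bar 1 in ms.
#' @param seed optional integer seed; when given, the stream is a pure
#'   function of the arguments.
#' @return a `drum_events` tibble.
#' @export
simulate_performance <- function(template, window = capture_window(),
                                 params = drummer_params(),
                                 song_offset_ms = 0, seed = NULL) {
  stopifnot(inherits(template, "pattern_template"),
            inherits(params, "drummer_params"))
  gen <- function() {
    grid <- build_grid(template, window, song_offset_ms)
    keep <- runif(nrow(grid)) >= params$miss_prob
    g <- grid[keep, ]
    jit <- rnorm(nrow(g)) * params$jitter_sd_ms[g$limb]
    if (params$ar1_phi > 0) {
      for (lb in unique(g$limb)) {
        i <- which(g$limb == lb)
        jit[i] <- as.numeric(stats::filter(jit[i], params$ar1_phi,
                                           method = "recursive")) *
          sqrt(1 - params$ar1_phi^2)
      }
    }
    onset <- g$nominal_ms + params$lag_ms[g$limb] + jit
    vel <- 60L + as.integer(round(runif(nrow(g), 0, 50)))

    n_bars <- length(unique(grid$bar_index))
    n_extra <- rpois(1, params$extra_rate * n_bars)
    kit <- setdiff(.instruments, "other")
    extra_inst <- sample(kit, n_extra, replace = TRUE)
    i2l <- default_limb_map()$instrument_to_limb
    ex <- tibble::tibble(
      onset_ms = runif(n_extra, window$start_s * 1000, window$end_s * 1000),
      instrument = extra_inst,
      limb = unname(i2l[extra_inst]),
      velocity = 60L + as.integer(round(runif(n_extra, 0, 50)))
    )
    onset <- pmax(onset, 0)
    drum_events(c(onset, ex$onset_ms),
                c(g$instrument, ex$instrument),
                c(g$limb, ex$limb),
                c(vel, ex$velocity))
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

#' Closed-form bar completion probability
#'
#' Analytic oracle for the simulator at `ar1_phi = 0`: with i.i.d. Gaussian
#' jitter of SD `jitter_sd`, per-strike miss probability `miss_prob` and `k`
#' expected strikes per bar, each strike is independently present and within
#' tolerance with probability `(1 - m) * (2 * pnorm(tol / sd) - 1)`, so
#'
#' `P(bar completed) = ((1 - m) * (2 * pnorm(tol / sd) - 1))^k`
#'
#' At zero jitter the Gaussian factor is 1.
#'
#' @param jitter_sd Gaussian jitter SD, ms (>= 0).
#' @param miss_prob per-strike miss probability in `[0, 1]`.
#' @param tolerance_ms matching tolerance, ms (> 0).
#' @param strikes_per_bar number of expected strikes per bar (>= 1).
#' @return completion probability in `[0, 1]`.
#' @examples
#' closed_form_completion_prob(100, 0, 250, 10)  # about 0.883
#' @export
closed_form_completion_prob <- function(jitter_sd, miss_prob, tolerance_ms,
                                        strikes_per_bar) {
  stopifnot(jitter_sd >= 0, miss_prob >= 0, miss_prob <= 1, tolerance_ms > 0,
            strikes_per_bar >= 1)
  within <- if (jitter_sd == 0) 1 else 2 * pnorm(tolerance_ms / jitter_sd) - 1
  ((1 - miss_prob) * within)^strikes_per_bar
}
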