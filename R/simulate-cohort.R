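#' Default synthetic measure dictionary
#'
#' One row per brain or performance measure the cohort generator emits:
#' baseline mean, between-subject SD and within-subject (scan-to-scan or
#' test-to-test) SD, in the measure's own units. Lobular volume and diffusion
#' baselines follow published two-group pre/post values where available
#' (vermis Crus I, left VIIIa, left/right VIIIb, inferior-peduncle FA/MD,
#' the four cortical-thickness regions); the remaining lobules use typical
#' atlas-parcellation proportions. Drum-score rows get larger SDs reflecting
#' the high variability of novice performance.
#'
#' Column types: `volume` (enters the TCV sum), `vermis` (TCV-corrected but
#' outside the sum), `fa`, `md`, `thickness`, `drum`.
#'
#' @return a tibble with columns `measure`, `type`, `baseline`, `between_sd`,
#'   `within_sd`.
#' @export
default_cohort_measures <- function() {
  lob <- cerebellar_lobules()
  lob_base <- c(i_iv = 6000, v = 7500, vi = 14000, crus_i = 18000,
                crus_ii = 14000, viib = 8000, viiia = 5500, viiib = 4600,
                ix = 5500, x = 1200)
  vol <- tibble::tibble(
    measure = c(paste0("vol_left_", lob), paste0("vol_right_", lob)),
    type = "volume",
    baseline = unname(c(lob_base, lob_base))
  )
  vol$baseline[vol$measure == "vol_left_viiia"] <- 5555
  vol$baseline[vol$measure == "vol_left_viiib"] <- 4534
  vol$baseline[vol$measure == "vol_right_viiib"] <- 4662

  other <- tibble::tibble(
    measure = c("vol_vermis_crus_i",
                "fa_left_icp", "fa_right_icp", "fa_left_mcp", "fa_right_mcp",
                "fa_left_scp", "fa_right_scp",
                "md_left_icp", "md_right_icp", "md_left_mcp", "md_right_mcp",
                "md_left_scp", "md_right_scp",
                "ct_lparc", "ct_lsfg", "ct_rpcun", "ct_rsfg",
                "drum_pct_quarter", "drum_pct_eighth", "drum_hrs_ms"),
    type = c("vermis", rep("fa", 6), rep("md", 6), rep("thickness", 4),
             rep("drum", 3)),
    baseline = c(24,
                 0.564, 0.578, 0.50, 0.50, 0.55, 0.55,
                 0.720, 0.711, 0.65, 0.65, 0.75, 0.75,
                 2.425, 2.835, 2.59, 2.71,
                 15, 10, 60)
  )
  out <- dplyr::bind_rows(vol, other)
  out$between_sd <- 0.05 * out$baseline
  out$within_sd <- 0.015 * out$baseline
  drum_rows <- out$type == "drum"
  out$between_sd[drum_rows] <- c(8, 6, 20)
  out$within_sd[drum_rows] <- c(12, 10, 15)
  out
}

#' Cohort simulation parameters
#'
#' @param n_per_group named integer vector `c(drum = , control = )`; default
#'   15 drummers and 16 controls.
#' @param sex_counts named list of `c(male, female)` counts per group;
#'   default drum 7/8, control 8/8 (the matched-design shape).
#' @param group_time_effects named numeric vector: additive change applied to
#'   the named measure for the drum group at T2 only, in the measure's units.
#'   Default empty (a null cohort: no group-by-time effect anywhere).
#' @param measures a measure dictionary as from [default_cohort_measures()].
#' @param tcv_cv coefficient of variation of the latent total cerebellar
#'   volume across subjects; lobular volumes scale with it so TCV correction
#'   has real shared-size structure to remove. Default 0.07.
#' @param age_range years, ages drawn uniformly; default `c(16, 19)`.
#' @return a list of class `cohort_params`.
#' @export
cohort_params <- function(n_per_group = c(drum = 15L, control = 16L),
                          sex_counts = list(drum = c(male = 7L, female = 8L),
                                            control = c(male = 8L, female = 8L)),
                          group_time_effects = numeric(),
                          measures = default_cohort_measures(),
                          tcv_cv = 0.07,
                          age_range = c(16, 19)) {
  stopifnot(all(n_per_group >= 2), all(c("drum", "control") %in% names(n_per_group)),
            all(measures$between_sd > 0), all(measures$within_sd > 0),
            tcv_cv >= 0, length(age_range) == 2, age_range[1] <= age_range[2])
  for (g in c("drum", "control"))
    stopifnot(sum(sex_counts[[g]]) == n_per_group[[g]])
  if (length(group_time_effects))
    stopifnot(!is.null(names(group_time_effects)),
              all(names(group_time_effects) %in% measures$measure))
  structure(list(n_per_group = n_per_group, sex_counts = sex_counts,
                 group_time_effects = group_time_effects, measures = measures,
                 tcv_cv = tcv_cv, age_range = age_range),
            class = "cohort_params")
}

#' Simulate a two-group pre/post cohort measure table
#'
#' Each measure follows `baseline + subject_level + time_noise +
#' effect * [drum group at T2]`, with `subject_level ~ N(0, between_sd)` and
#' `time_noise ~ N(0, within_sd)` drawn independently at each timepoint.
#' Lobular volumes are additionally scaled by a latent per-subject total
#' cerebellar volume factor, so the generated lobules share size variance
#' that [tcv_correct()] genuinely removes. Deterministic given `seed`.
#'
#' @param params a [cohort_params()].
#' @param seed optional integer seed.
#' @return a tibble with one row per subject-by-timepoint: `subject_id`,
#'   `group`, `sex`, `age`, `timepoint` (`T1`/`T2`), then one column per
#'   measure.
#' @export
simulate_cohort <- function(params = cohort_params(), seed = NULL) {
  stopifnot(inherits(params, "cohort_params"))
  gen <- function() {
    meas <- params$measures
    groups <- c(rep("drum", params$n_per_group[["drum"]]),
                rep("control", params$n_per_group[["control"]]))
    sex <- unlist(lapply(c("drum", "control"), function(g)
      rep(c("male", "female"), params$sex_counts[[g]])))
    n <- length(groups)
    subj <- sprintf("S%02d", seq_len(n))
    age <- round(runif(n, params$age_range[1], params$age_range[2]), 1)
    tcv_factor <- 1 + rnorm(n, 0, params$tcv_cv)

    level <- matrix(rnorm(n * nrow(meas), 0, rep(meas$between_sd, each = n)),
                    n, nrow(meas), dimnames = list(NULL, meas$measure))
    values <- lapply(c("T1", "T2"), function(tp) {
      noise <- matrix(rnorm(n * nrow(meas), 0, rep(meas$within_sd, each = n)),
                      n, nrow(meas))
      base <- matrix(rep(meas$baseline, each = n), n, nrow(meas))
      scale_tcv <- meas$type %in% c("volume", "vermis")
      base[, scale_tcv] <- base[, scale_tcv] * tcv_factor
      v <- base + level + noise
      if (tp == "T2" && length(params$group_time_effects)) {
        for (m in names(params$group_time_effects)) {
          j <- which(meas$measure == m)
          v[groups == "drum", j] <- v[groups == "drum", j] +
            params$group_time_effects[[m]]
        }
      }
      colnames(v) <- meas$measure
      v
    })

    out <- dplyr::bind_rows(lapply(1:2, function(t) {
      dplyr::bind_cols(
        tibble::tibble(subject_id = subj, group = groups, sex = sex, age = age,
                       timepoint = c("T1", "T2")[t]),
        tibble::as_tibble(values[[t]])
      )
    }))
    # keep bounded measures in range
    fa_cols <- meas$measure[meas$type == "fa"]
    out[fa_cols] <- lapply(out[fa_cols], function(v) pmin(pmax(v, 0), 1))
    pct_cols <- c("drum_pct_quarter", "drum_pct_eighth")
    out[pct_cols] <- lapply(out[pct_cols], function(v) pmin(pmax(v, 0), 100))
    out$drum_hrs_ms <- pmax(out$drum_hrs_ms, 1)
    out
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}
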