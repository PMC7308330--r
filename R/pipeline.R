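#' Run the full measure-table analysis pipeline
#'
#' Reproduces the analysis flow for a two-group (drum / control) pre-post
#' cohort table, as produced by [simulate_cohort()] or read from a tidy CSV
#' with the same layout (one row per subject-by-timepoint; measure columns
#' named `vol_*`, `fa_*`, `md_*`, `ct_*`, `drum_*`):
#'
#' 1. Subjects missing either timepoint are excluded (with a warning).
#' 2. Lobular volumes (`vol_*`) are TCV-residualized pooled across all rows;
#'    vermis columns are corrected but excluded from the TCV sum.
#' 3. Per brain measure, an ANCOVA of the per-subject change score (T2 - T1)
#'    on group plus covariates (default: sex, coded male = 0 / female = 1);
#'    corrected-model F and type-III group F are reported with a significance
#'    flag at `p <= alpha` on the group effect.
#' 4. Drum scores: change scores are screened with Shapiro-Wilk per group; if
#'    either group deviates from normality (p < 0.05) a Mann-Whitney U test on
#'    the deltas is used, otherwise Welch's t-test. Baseline (T1) group
#'    differences are tested with Mann-Whitney.
#' 5. Demographics: chi-squared for sex-by-group, Mann-Whitney for age.
#' 6. Rank correlation (Spearman's rho and Kendall's tau-b, two-sided) between
#'    TCV-corrected left VIIIa volume at T2 and HRS precision change
#'    (`100 * (pre - post) / pre`), within the drum group.
#'
#' No multiplicity correction is applied to the per-measure tests by default
#' (per-measure alpha); set `adjust = "BH"` to append a labelled
#' Benjamini-Hochberg column.
#'
#' @param measures tidy data frame, one row per subject-by-timepoint, with
#'   columns `subject_id`, `group`, `sex`, `age`, `timepoint` and measure
#'   columns.
#' @param covariates covariate column names for the ANCOVAs; default `"sex"`.
#'   Add `"age"` to mirror the covariate set with age included.
#' @param design ANCOVA design, `"on_delta"` (default) or
#'   `"on_post_adjusting_pre"`.
#' @param alpha significance threshold for the flag column; default 0.05.
#' @param chisq_correct Yates correction for the sex table; default `FALSE`.
#' @param hrs_delta which HRS delta the Mann-Whitney consumes: `"ms"` (raw
#'   post - pre, default) or `"pct"` (percent precision change).
#' @param adjust optional p-adjustment method (e.g. `"BH"`) appended as
#'   `p_group_adj`; `NULL` (default) reports raw p only.
#' @return a list of class `table2_report`: `measure_table` (per-measure
#'   before/after group means, F and p values, flag), `drum_tests`,
#'   `baseline_tests`, `correlations`, `n_subjects`, `excluded_subjects`.
#' @export
run_table2_pipeline <- function(measures, covariates = "sex",
                                design = c("on_delta", "on_post_adjusting_pre"),
                                alpha = 0.05, chisq_correct = FALSE,
                                hrs_delta = c("ms", "pct"), adjust = NULL) {
  design <- match.arg(design)
  hrs_delta <- match.arg(hrs_delta)
  req <- c("subject_id", "group", "sex", "age", "timepoint")
  missing_cols <- setdiff(req, names(measures))
  if (length(missing_cols))
    stop("measure table lacks column(s): ", paste(missing_cols, collapse = ", "))
  stopifnot(all(measures$timepoint %in% c("T1", "T2")),
            all(measures$group %in% c("drum", "control")))

  tp_count <- table(measures$subject_id)
  incomplete <- names(tp_count)[tp_count != 2L]
  if (length(incomplete)) {
    warning("excluding subject(s) without both timepoints: ",
            paste(incomplete, collapse = ", "))
    measures <- measures[!measures$subject_id %in% incomplete, ]
  }
  if (!nrow(measures)) stop("no complete subjects")

  vol_cols <- grep("^vol_", names(measures), value = TRUE)
  vermis_cols <- grep("^vol_vermis", vol_cols, value = TRUE)
  tcv_cols <- setdiff(vol_cols, vermis_cols)
  if (length(tcv_cols) >= 1 && nrow(measures) >= 3)
    measures <- tcv_correct(measures, tcv_cols, vermis_cols)

  brain_cols <- c(vol_cols, grep("^fa_|^md_|^ct_", names(measures), value = TRUE))
  drum_cols <- grep("^drum_", names(measures), value = TRUE)

  covs <- measures[measures$timepoint == "T1",
                   c("subject_id", "group", "sex", "age")]
  covs$sex_code <- as.numeric(covs$sex == "female")
  cov_names <- vapply(covariates, function(cv)
    if (cv == "sex") "sex_code" else cv, character(1))

  # align the two timepoints once; per-measure frames are then cheap slices
  t1 <- measures[measures$timepoint == "T1", ]
  t2 <- measures[measures$timepoint == "T2", ]
  t2 <- t2[match(t1$subject_id, t2$subject_id), ]
  covs <- covs[match(t1$subject_id, covs$subject_id), ]
  wide <- function(col) {
    w <- covs
    w$T1 <- t1[[col]]
    w$T2 <- t2[[col]]
    w$delta <- w$T2 - w$T1
    w
  }

  measure_table <- dplyr::bind_rows(lapply(brain_cols, function(col) {
    w <- wide(col)
    an <- ancova_group(w, response = if (design == "on_delta") "delta" else "T2",
                       group = "group", covariates = cov_names,
                       pre = "T1", design = design)
    gm <- function(g, tp) mean(w[[tp]][w$group == g])
    tibble::tibble(
      measure = col,
      before_control = gm("control", "T1"), before_drum = gm("drum", "T1"),
      after_control = gm("control", "T2"), after_drum = gm("drum", "T2"),
      F_model = an$model$statistic, p_model = an$model$p_value,
      F_group = an$group$statistic, p_group = an$group$p_value,
      significant = an$group$p_value <= alpha
    )
  }))
  if (!is.null(adjust) && nrow(measure_table))
    measure_table$p_group_adj <- p.adjust(measure_table$p_group, method = adjust)

  drum_tests <- dplyr::bind_rows(lapply(drum_cols, function(col) {
    w <- wide(col)
    if (col == "drum_hrs_ms" && hrs_delta == "pct")
      w$delta <- 100 * (w$T1 - w$T2) / w$T1
    dx <- w$delta[w$group == "drum"]; cx <- w$delta[w$group == "control"]
    sw_p <- vapply(list(dx, cx), function(v)
      if (length(unique(v)) < 3L) 0 else shapiro.test(v)$p.value, numeric(1))
    normal <- all(sw_p >= 0.05)
    res <- if (normal) {
      tt <- stats::t.test(dx, cx)
      stat_result("welch_t", tt$statistic, tt$p.value, df = unname(tt$parameter))
    } else mann_whitney_u(dx, cx)
    base <- mann_whitney_u(w$T1[w$group == "drum"], w$T1[w$group == "control"])
    tibble::tibble(
      measure = col,
      delta_kind = if (col == "drum_hrs_ms") hrs_delta else "raw",
      median_delta_drum = stats::median(dx),
      median_delta_control = stats::median(cx),
      shapiro_normal = normal, test = res$test_name,
      statistic = res$statistic, p_delta = res$p_value,
      p_baseline = base$p_value,
      significant = res$p_value <= alpha
    )
  }))

  sex_tab <- table(covs$group, covs$sex)
  baseline_tests <- list(
    sex = chi_squared_independence(as.matrix(sex_tab)[c("drum", "control"),
                                                      , drop = FALSE],
                                   correct = chisq_correct),
    age = mann_whitney_u(covs$age[covs$group == "drum"],
                         covs$age[covs$group == "control"])
  )

  correlations <- NULL
  if (all(c("vol_left_viiia", "drum_hrs_ms") %in% names(measures))) {
    w_vol <- wide("vol_left_viiia"); w_hrs <- wide("drum_hrs_ms")
    sel <- w_vol$group == "drum"
    vol_t2 <- w_vol$T2[sel]
    hrs_gain <- 100 * (w_hrs$T1[sel] - w_hrs$T2[sel]) / w_hrs$T1[sel]
    if (sum(sel) >= 3 && var(vol_t2) > 0 && var(hrs_gain) > 0)
      correlations <- list(
        spearman = rank_correlation(vol_t2, hrs_gain, "spearman_rho"),
        kendall = rank_correlation(vol_t2, hrs_gain, "kendall_tau_b")
      )
  }

  structure(list(measure_table = measure_table, drum_tests = drum_tests,
                 baseline_tests = baseline_tests, correlations = correlations,
                 n_subjects = length(unique(measures$subject_id)),
                 excluded_subjects = incomplete,
                 alpha = alpha, design = design, covariates = covariates),
            class = "table2_report")
}

#' @export
print.table2_report <- function(x, ...) {
  cat(sprintf("<table2_report> %d subjects, design = %s, covariates = %s\n",
              x$n_subjects, x$design, paste(x$covariates, collapse = "+")))
  sig <- x$measure_table$measure[x$measure_table$significant]
  cat(sprintf("  brain measures tested: %d; flagged at p <= %.2f: %s\n",
              nrow(x$measure_table), x$alpha,
              if (length(sig)) paste(sig, collapse = ", ") else "none"))
  invisible(x)
}

#' Write a pipeline report to CSV and JSON
#'
#' Writes `measure_table.csv`, `drum_tests.csv` and `report.json` (requires
#' the jsonlite package) into a directory.
#'
#' @param report a [run_table2_pipeline()] result.
#' @param dir output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "table2_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$measure_table, file.path(dir, "measure_table.csv"),
                   row.names = FALSE)
  utils::write.csv(report$drum_tests, file.path(dir, "drum_tests.csv"),
                   row.names = FALSE)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    strip <- function(x) {
      if (is.data.frame(x)) as.data.frame(x)
      else if (is.list(x)) lapply(unclass(x), strip)
      else x
    }
    jsonlite::write_json(strip(unclass(report)), file.path(dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(dir)
}
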