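#' Standard cerebellar lobule set
#'
#' The ten lobules whose sum defines total cerebellar volume (TCV):
#' I-IV, V, VI, Crus I, Crus II, VIIb, VIIIa, VIIIb, IX and X.
#'
#' @return character vector of lobule labels.
#' @export
cerebellar_lobules <- function() {
  c("i_iv", "v", "vi", "crus_i", "crus_ii", "viib", "viiia", "viiib", "ix", "x")
}

#' Residualize lobular volumes against total cerebellar volume
#'
#' TCV is the row-wise sum of the hemispheric lobular volume columns. For each
#' volume column an ordinary least-squares regression of volume on TCV is
#' fitted pooled across all rows (both groups and both timepoints), and the
#' column is replaced by its residual plus the column's grand mean, so
#' corrected volumes keep the original units and scale but are uncorrelated
#' with TCV across the fitted sample. Vermis regions can be corrected the same
#' way without contributing to the TCV sum via `extra_cols`.
#'
#' If TCV has zero variance the slope is unidentifiable; the volumes are
#' returned unchanged with a warning (residual about the mean plus the mean).
#'
#' @param data data frame with one row per subject-by-timepoint.
#' @param volume_cols names of the lobular volume columns summed into TCV and
#'   corrected.
#' @param extra_cols names of additional volume columns corrected against TCV
#'   but excluded from the TCV sum (e.g. vermis subregions). Default none.
#' @return `data` with the volume columns residualized and a new `tcv` column;
#'   attribute `tcv_slopes` holds the fitted slope per column.
#' @examples
#' d <- data.frame(v = c(4, 5, 6), rest = c(96, 105, 114))
#' tcv_correct(d, volume_cols = c("v", "rest"))$v  # 5 5 5
#' @export
tcv_correct <- function(data, volume_cols, extra_cols = character()) {
  stopifnot(nrow(data) >= 3, all(volume_cols %in% names(data)),
            all(extra_cols %in% names(data)))
  vols <- as.matrix(data[, volume_cols, drop = FALSE])
  if (any(!is.finite(vols)) || any(vols <= 0))
    stop("lobular volumes must be finite and positive")
  tcv <- rowSums(vols)
  slopes <- setNames(numeric(0), character(0))
  all_cols <- c(volume_cols, extra_cols)
  if (var(tcv) == 0) {
    warning("TCV has zero variance; returning mean-centred volumes unchanged")
    slopes <- setNames(rep(0, length(all_cols)), all_cols)
  } else {
    for (cl in all_cols) {
      fit <- stats::lm(data[[cl]] ~ tcv)
      slopes[cl] <- coef(fit)[["tcv"]]
      data[[cl]] <- unname(residuals(fit)) + mean(data[[cl]])
    }
  }
  data$tcv <- tcv
  attr(data, "tcv_slopes") <- slopes
  data
}
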