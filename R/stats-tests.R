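#' Named statistical test result
#'
#' Lightweight container for a test outcome: the statistic, optional degrees
#' of freedom, p-value and sidedness.
#'
#' @param test_name character label.
#' @param statistic numeric statistic value.
#' @param p_value p-value in `[0, 1]`.
#' @param df optional degrees of freedom (scalar or pair).
#' @param two_sided logical.
#' @param estimate optional effect-size / coefficient estimate.
#' @param method optional method note (e.g. "exact", "normal approximation").
#' @return a list of class `stat_result`.
#' @export
stat_result <- function(test_name, statistic, p_value, df = NULL,
                        two_sided = TRUE, estimate = NULL, method = NULL) {
  stopifnot(is.na(p_value) || (p_value >= 0 && p_value <= 1))
  structure(list(test_name = test_name, statistic = unname(statistic),
                 df = df, p_value = unname(p_value), two_sided = two_sided,
                 estimate = unname(estimate), method = method),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  dfs <- if (is.null(x$df)) "" else sprintf("(%s)", paste(round(x$df, 2), collapse = ","))
  cat(sprintf("<stat_result> %s%s = %.4g, p = %.4g%s\n", x$test_name, dfs,
              x$statistic, x$p_value,
              if (is.null(x$method)) "" else paste0(" [", x$method, "]")))
  invisible(x)
}

#' Mann-Whitney U test
#'
#' Two-sample rank test on the U statistic of `x`. The p-value is exact (from
#' the full null distribution of U, equivalent to enumerating all rank
#' arrangements) when the combined sample size is at most 20 and there are no
#' ties; otherwise the normal approximation with tie and continuity correction
#' is used. When every value in both samples is identical the test is
#' degenerate and p = 1 is returned.
#'
#' @param x,y numeric samples (non-empty).
#' @param two_sided logical; default `TRUE`.
#' @param exact force exact (`TRUE`) or approximate (`FALSE`); default chooses
#'   as above.
#' @return a [stat_result()] with the U statistic of `x`.
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6))  # U = 0, exact p = 0.1
#' @export
mann_whitney_u <- function(x, y, two_sided = TRUE, exact = NULL) {
  stopifnot(length(x) >= 1, length(y) >= 1)
  if (length(unique(c(x, y))) == 1L)
    return(stat_result("mann_whitney_U", length(x) * length(y) / 2, 1,
                       two_sided = two_sided, method = "degenerate (all values equal)"))
  ties <- anyDuplicated(c(x, y)) > 0L
  if (is.null(exact)) exact <- (length(x) + length(y) <= 20L) && !ties
  wt <- suppressWarnings(stats::wilcox.test(
    x, y, alternative = if (two_sided) "two.sided" else "greater",
    exact = exact, correct = TRUE))
  stat_result("mann_whitney_U", wt$statistic, wt$p.value,
              two_sided = two_sided,
              method = if (exact) "exact" else "normal approximation, tie/continuity corrected")
}

#' Chi-squared test of group-by-sex independence
#'
#' Pearson chi-squared on a 2x2 contingency table; the Yates continuity
#' correction is off by default.
#'
#' @param counts 2x2 matrix of non-negative integer counts with positive
#'   margins.
#' @param correct apply Yates continuity correction; default `FALSE`.
#' @return a [stat_result()] with the chi-squared statistic and df = 1.
#' @export
chi_squared_independence <- function(counts, correct = FALSE) {
  counts <- as.matrix(counts)
  stopifnot(all(dim(counts) == c(2L, 2L)), all(counts >= 0),
            all(counts == round(counts)))
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("contingency table has a zero margin")
  ct <- suppressWarnings(stats::chisq.test(counts, correct = correct))
  stat_result("chi_squared", ct$statistic, ct$p.value, df = unname(ct$parameter),
              method = if (correct) "Yates corrected" else "uncorrected")
}

#' ANCOVA on a group effect with covariates
#'
#' Ordinary least-squares linear model of a response on group plus covariates.
#' With `design = "on_delta"` the response is the per-subject change score;
#' with `design = "on_post_adjusting_pre"` the response is the post value and
#' the pre value enters as an additional covariate. Reports the corrected-model
#' F (all predictors against the intercept-only model) and the type-III group
#' effect F.
#'
#' @param data data frame with one row per subject.
#' @param response name of the response column (delta, or post value).
#' @param group name of the two-level group column.
#' @param covariates character vector of covariate column names (numeric;
#'   e.g. sex coded male = 0, female = 1). May be empty.
#' @param pre name of the pre/baseline column, required for
#'   `design = "on_post_adjusting_pre"`.
#' @param design `"on_delta"` (default) or `"on_post_adjusting_pre"`.
#' @return a list with `stat_result` elements `model` (corrected-model F) and
#'   `group` (type-III group F), plus the fitted `lm` as `fit`.
#' @export
ancova_group <- function(data, response, group = "group", covariates = "sex",
                         pre = NULL,
                         design = c("on_delta", "on_post_adjusting_pre")) {
  design <- match.arg(design)
  stopifnot(response %in% names(data), group %in% names(data),
            all(covariates %in% names(data)))
  data[[group]] <- factor(data[[group]])
  if (nlevels(data[[group]]) != 2L) stop("group must have exactly two levels")
  if (min(table(data[[group]])) < 2L) stop("need at least 2 subjects per group")
  rhs <- c(group, covariates)
  if (design == "on_post_adjusting_pre") {
    if (is.null(pre) || !pre %in% names(data))
      stop("design 'on_post_adjusting_pre' requires a pre column")
    rhs <- c(rhs, pre)
  }
  if (var(data[[response]]) == 0) {
    z <- stat_result("F", 0, 1, df = c(length(rhs), nrow(data) - length(rhs) - 1L),
                     method = "degenerate (constant response)")
    return(list(model = z, group = z, fit = NULL))
  }
  fml <- stats::reformulate(rhs, response)
  fit <- stats::lm(fml, data = data, contrasts =
                     setNames(list("contr.sum"), group))
  if (any(is.na(coef(fit)))) {
    bad <- names(coef(fit))[is.na(coef(fit))]
    stop("rank-deficient ANCOVA design; aliased term(s): ",
         paste(bad, collapse = ", "))
  }
  fs <- summary(fit)$fstatistic
  model_res <- stat_result("F_model", fs["value"],
                           pf(fs["value"], fs["numdf"], fs["dendf"], lower.tail = FALSE),
                           df = unname(fs[c("numdf", "dendf")]))
  a3 <- car::Anova(fit, type = 3)
  gi <- which(rownames(a3) == group)
  group_res <- stat_result("F_group", a3$`F value`[gi], a3$`Pr(>F)`[gi],
                           df = c(a3$Df[gi], a3$Df[nrow(a3)]))
  list(model = model_res, group = group_res, fit = fit)
}

#' Rank correlation (Spearman's rho or Kendall's tau-b)
#'
#' Two-sided by default. The p-value is exact (permutation null) for n <= 7
#' without ties, asymptotic otherwise; with ties the Kendall coefficient is
#' tau-b.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @param method `"spearman_rho"`/`"spearman"` or
#'   `"kendall_tau_b"`/`"kendall"`.
#' @param two_sided logical; default `TRUE`.
#' @return a [stat_result()] with the coefficient as `estimate`.
#' @export
rank_correlation <- function(x, y,
                             method = c("spearman_rho", "kendall_tau_b",
                                        "spearman", "kendall"),
                             two_sided = TRUE) {
  method <- match.arg(method)
  base_method <- if (startsWith(method, "spearman")) "spearman" else "kendall"
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (var(x) == 0 || var(y) == 0)
    stop("rank correlation undefined: zero variance in a sample")
  ties <- anyDuplicated(x) > 0L || anyDuplicated(y) > 0L
  exact <- length(x) <= 7L && !ties
  ct <- suppressWarnings(stats::cor.test(
    x, y, method = base_method,
    alternative = if (two_sided) "two.sided" else "greater",
    exact = exact))
  stat_result(if (base_method == "spearman") "spearman_rho" else "kendall_tau_b",
              ct$statistic, ct$p.value, estimate = ct$estimate,
              two_sided = two_sided,
              method = if (exact) "exact permutation" else "asymptotic")
}
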