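test_that("Mann-Whitney U matches the enumeration oracle and handles edge cases", {
  r <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 0.1)  # 2/20 labelings as extreme

  # random tie-free fixtures, exact branch vs enumeration
  withr::with_seed(31, {
    for (rep in 1:20) {
      nx <- sample(2:5, 1); ny <- sample(2:5, 1)
      v <- sample(1000, nx + ny)
      x <- v[1:nx]; y <- v[-(1:nx)]
      o <- oracle_mann_whitney(x, y)
      r <- mann_whitney_u(x, y)
      expect_equal(r$statistic, o$U)
      expect_equal(r$p_value, o$p, tolerance = 1e-12)
    }
  })

  # identical multisets and degenerate samples give p = 1
  expect_equal(mann_whitney_u(c(5, 5, 5), c(5, 5, 5))$p_value, 1)
  # large-sample approximation close to exact at n = 10 + 10
  withr::with_seed(32, {
    v <- sample(10000, 20)
    x <- v[1:10]; y <- v[11:20]
  })
  expect_lt(abs(mann_whitney_u(x, y, exact = FALSE)$p_value -
                mann_whitney_u(x, y, exact = TRUE)$p_value), 0.01)
})

test_that("chi-squared independence test reproduces hand-computed tables", {
  r <- chi_squared_independence(matrix(c(5, 0, 0, 5), 2))
  expect_equal(r$statistic, 10)           # sum (O-E)^2 / E with E = 2.5
  expect_equal(r$df, 1)
  expect_equal(r$p_value, pchisq(10, 1, lower.tail = FALSE))

  prop <- chi_squared_independence(matrix(c(10, 20, 10, 20), 2))
  expect_equal(prop$statistic, 0)
  expect_equal(prop$p_value, 1)

  # the matched two-group sex composition is far from significant
  r2 <- chi_squared_independence(matrix(c(7, 8, 8, 8), 2, byrow = TRUE))
  expect_gt(r2$p_value, 0.05)

  expect_error(chi_squared_independence(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)),
               "margin")
})

test_that("TCV residualization removes shared size variance exactly", {
  # hand OLS toy: volumes 4,5,6 against tcv 100,110,120 -> slope 1/10,
  # residuals 0, corrected volumes all equal to the grand mean 5
  d <- data.frame(v = c(4, 5, 6), rest = c(96, 105, 114))
  out <- tcv_correct(d, volume_cols = c("v", "rest"))
  expect_equal(out$tcv, c(100, 110, 120))
  expect_equal(out$v, c(5, 5, 5))
  expect_equal(unname(attr(out, "tcv_slopes")["v"]), 0.1)

  # orthogonality and mean preservation on a synthetic cohort
  co <- simulate_cohort(seed = 41)
  vol_cols <- setdiff(grep("^vol_", names(co), value = TRUE), "vol_vermis_crus_i")
  cc <- tcv_correct(co, vol_cols, extra_cols = "vol_vermis_crus_i")
  for (cl in c(vol_cols, "vol_vermis_crus_i")) {
    expect_lt(abs(cov(cc[[cl]], cc$tcv)), 1e-10 * sd(co[[cl]]) * sd(cc$tcv) * nrow(co))
    expect_equal(mean(cc[[cl]]), mean(co[[cl]]))
  }

  # degenerate: constant tcv returns volumes unchanged with a warning
  d2 <- data.frame(a = c(4, 5, 6), b = c(6, 5, 4))
  expect_warning(out2 <- tcv_correct(d2, c("a", "b")), "zero variance")
  expect_equal(out2$a, d2$a)
})

test_that("ANCOVA recovers hand-computed F and respects invariances", {
  # balanced 4+4 fixture, no covariate: F equals the one-way ANOVA value
  d <- data.frame(delta = c(1, 2, 3, 4, 3, 4, 5, 6),
                  group = rep(c("control", "drum"), each = 4),
                  sexn = c(0, 1, 0, 1, 0, 1, 0, 1))
  a <- ancova_group(d, "delta", covariates = character(0))
  grand <- mean(d$delta)
  ssb <- 4 * sum((tapply(d$delta, d$group, mean) - grand)^2)
  ssw <- sum((d$delta - ave(d$delta, d$group))^2)
  f_hand <- (ssb / 1) / (ssw / 6)
  expect_equal(a$group$statistic, f_hand)
  expect_equal(a$model$statistic, f_hand)

  # group F invariant to affine rescaling of the covariate
  a1 <- ancova_group(d, "delta", covariates = "sexn")
  d2 <- d; d2$sexn <- 100 * d$sexn - 7
  a2 <- ancova_group(d2, "delta", covariates = "sexn")
  expect_equal(a1$group$statistic, a2$group$statistic)
  expect_equal(a1$group$p_value, a2$group$p_value)

  # constant response -> F = 0, p = 1
  d3 <- d; d3$delta <- 2
  a3 <- ancova_group(d3, "delta", covariates = "sexn")
  expect_equal(a3$group$statistic, 0)
  expect_equal(a3$group$p_value, 1)

  # aliased covariate -> informative error
  d4 <- d; d4$dup <- as.numeric(d4$group == "drum")
  expect_error(ancova_group(d4, "delta", covariates = "dup"), "aliased")
})

test_that("ANCOVA rejection rate matches noncentral-F power", {
  n1 <- 15; n2 <- 16
  g <- c(rep(1, n1), rep(0, n2))
  sexn <- c(rep(c(0, 1), c(7, 8)), rep(c(0, 1), c(8, 8)))
  X <- cbind(1, sexn)
  delta <- 1; sigma <- 1
  power <- oracle_ancova_power(g, X, delta, sigma)
  nrep <- 400
  withr::with_seed(33, {
    rej <- replicate(nrep, {
      d <- data.frame(delta = delta * g + rnorm(n1 + n2, 0, sigma),
                      group = ifelse(g == 1, "drum", "control"), sexn = sexn)
      ancova_group(d, "delta", covariates = "sexn")$group$p_value <= 0.05
    })
  })
  se <- sqrt(power * (1 - power) / nrep)
  expect_lt(abs(mean(rej) - power), 3 * se)
})

test_that("rank correlations match brute-force tau-b and behave at extremes", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(rank_correlation(x, x * 2 + 1, "spearman_rho")$estimate, 1)
  expect_equal(rank_correlation(x, rev(x), "kendall_tau_b")$estimate, -1)
  expect_equal(rank_correlation(c(1, 2, 3), c(3, 2, 1), "spearman_rho")$estimate, -1)

  y <- c(1, 2, 3, 5, 4)  # one discordant swap
  expect_equal(rank_correlation(x, y, "kendall_tau_b")$estimate,
               oracle_tau_b(x, y))
  withr::with_seed(34, {
    for (rep in 1:10) {
      a <- sample(20, 6); b <- sample(c(1, 1, 2, 3, 4, 5))  # ties in b
      expect_equal(unname(rank_correlation(a, b, "kendall_tau_b")$estimate),
                   oracle_tau_b(a, b), tolerance = 1e-12)
    }
  })
  expect_error(rank_correlation(x, rep(1, 5)), "zero variance")
})

test_that("the pipeline flags an injected left-VIIIa gain and nothing spurious at scale", {
  meas <- default_cohort_measures()
  wsd <- meas$within_sd[meas$measure == "vol_left_viiia"]
  par <- cohort_params(group_time_effects = c(vol_left_viiia = 5 * wsd))
  rep1 <- run_table2_pipeline(simulate_cohort(par, seed = 51))
  row <- rep1$measure_table[rep1$measure_table$measure == "vol_left_viiia", ]
  expect_true(row$significant)
  expect_gt(row$after_drum - row$before_drum, row$after_control - row$before_control)

  # constant cohort: nothing flagged, degenerate p = 1
  co <- simulate_cohort(seed = 52)
  num <- setdiff(names(co), c("subject_id", "group", "sex", "age", "timepoint"))
  co[num] <- lapply(co[num], function(v) rep(mean(v), length(v)))
  suppressWarnings(rep2 <- run_table2_pipeline(co))
  expect_false(any(rep2$measure_table$significant))
  expect_true(all(rep2$measure_table$p_group == 1))
  expect_false(any(rep2$drum_tests$significant))
  expect_null(rep2$correlations)
})

test_that("the pipeline excludes incomplete subjects and supports options", {
  co <- simulate_cohort(seed = 53)
  co <- co[!(co$subject_id == "S01" & co$timepoint == "T2"), ]
  expect_warning(rep <- run_table2_pipeline(co), "S01")
  expect_equal(rep$excluded_subjects, "S01")
  expect_equal(rep$n_subjects, 30L)

  co2 <- simulate_cohort(seed = 54)
  rep2 <- run_table2_pipeline(co2, covariates = c("sex", "age"),
                              design = "on_post_adjusting_pre",
                              adjust = "BH", hrs_delta = "pct")
  expect_true("p_group_adj" %in% names(rep2$measure_table))
  expect_equal(rep2$drum_tests$delta_kind[rep2$drum_tests$measure == "drum_hrs_ms"],
               "pct")
  expect_true(all(rep2$measure_table$p_group_adj >= rep2$measure_table$p_group - 1e-12))
})
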