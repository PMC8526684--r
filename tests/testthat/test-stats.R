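test_that("degenerate groups summarize with zero spread and no outliers", {
  tbl <- toy_cohort(4, seed = 1)
  tbl$T1 <- 300
  tbl$sex <- "male"; tbl$origin <- "Mauritius"; tbl$side <- "OD"
  tbl$eye_id <- sprintf("e%d", 1:4)
  s <- summarize_cohort(tbl, coefficients = "T1")
  expect_identical(nrow(s), 1L)
  expect_equal(s$mean, 300)
  expect_equal(s$std, 0)
  expect_equal(s$iqr, 0)
  expect_identical(s$n_outliers, 0L)
  expect_equal(s$whisker_low, 300)
  expect_equal(s$whisker_high, 300)
})

test_that("quantiles and whiskers match a hand computation", {
  tbl <- toy_cohort(100, seed = 2)
  tbl$sex <- "male"; tbl$origin <- "Asian"; tbl$side <- "OD"
  tbl$T1 <- as.numeric(1:100)
  s <- summarize_cohort(tbl, coefficients = "T1")
  # type-7 quantiles of 1..100: Q1 = 25.75, median = 50.5, Q3 = 75.25
  expect_equal(c(s$q1, s$median, s$q3), c(25.75, 50.5, 75.25))
  expect_equal(s$iqr, 49.5)
  # fences at -48.5 / 149.5: whiskers reach the extremes, no outliers
  expect_equal(c(s$whisker_low, s$whisker_high), c(1, 100))
  expect_identical(s$n_outliers, 0L)
  # a displaced datum falls outside the whisker
  tbl$T1[100] <- 1000
  s2 <- summarize_cohort(tbl, coefficients = "T1")
  expect_equal(s2$whisker_high, 99)
  expect_identical(s2$n_outliers, 1L)
})

test_that("correlations match the from-definition oracle", {
  x <- c(1, 3, 4, 8, 9)
  y <- c(2, 1, 5, 7, 12)
  tbl <- toy_cohort(5, seed = 3)
  tbl$T1 <- x; tbl$T2 <- y; tbl$T3 <- -x
  cm <- correlation_matrix(tbl, columns = c("T1", "T2", "T3"))
  r_def <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(cm["T1", "T2"], r_def, tolerance = 1e-10)
  expect_equal(cm["T1", "T1"], 1)
  expect_equal(cm["T1", "T3"], -1)
  expect_true(isSymmetric(cm))
  tbl$T4 <- 5
  expect_error(correlation_matrix(tbl, columns = c("T1", "T4")), "T4")
})

test_that("PCA matches closed forms and conserves total variance", {
  # rank-1 table: PC1 explains 100%
  tbl <- toy_cohort(30, seed = 4)
  base <- withr::with_seed(5, rnorm(30))
  for (k in 1:9) tbl[[paste0("T", k)]] <- 300 + k * base
  tbl$side <- "OS"
  p1 <- cohort_pca(tbl, eye = "left")
  expect_equal(p1$cum_var_pct[1], 100, tolerance = 1e-9)
  # generic table: eigenvalue sum equals total variance; prcomp agrees
  tbl2 <- toy_cohort(60, seed = 6)
  tbl2$side <- "OS"
  p2 <- cohort_pca(tbl2, eye = "left")
  x <- as.matrix(tbl2[, paste0("T", 1:9)])
  expect_equal(sum(p2$eigenvalues), sum(apply(x, 2, var)), tolerance = 1e-10)
  pr <- prcomp(x)
  expect_equal(p2$eigenvalues, unname(pr$sdev^2), tolerance = 1e-9)
  expect_equal(p2$cum_var_pct[9], 100, tolerance = 1e-12)
  # loadings are eigenvectors scaled by sqrt(eigenvalue)
  expect_equal(unname(p2$loadings[, 1]),
               unname(p2$rotation[, 1] * sqrt(p2$eigenvalues[1])), tolerance = 1e-12)
  expect_gt(mean(p2$loadings[, 1]), 0)
})

test_that("a 2-D correlated sample matches the closed-form 2x2 eigensolve", {
  tbl <- toy_cohort(50, seed = 7)
  tbl$side <- "OD"
  x <- as.matrix(tbl[, c("T1", "T2")])
  p <- cohort_pca(tbl, eye = "right", columns = c("T1", "T2"))
  s <- cov(x)
  tr <- s[1, 1] + s[2, 2]
  det_s <- s[1, 1] * s[2, 2] - s[1, 2]^2
  lam <- c((tr + sqrt(tr^2 - 4 * det_s)) / 2, (tr - sqrt(tr^2 - 4 * det_s)) / 2)
  expect_equal(p$eigenvalues, lam, tolerance = 1e-10)
})

test_that("Wilks' lambda equals det(E)/det(E+H) from hand-built projections", {
  tbl <- toy_cohort(12, seed = 8, sex_shift = -6, origin_shift = rep(4, 9))
  tbl$side <- "OD"
  mv <- cohort_manova(tbl, eye = "right", dependents = c("T1", "T2"))
  # oracle: explicit projection matrices, Type II
  y <- as.matrix(tbl[, c("T1", "T2")])
  proj <- function(x) x %*% solve(crossprod(x)) %*% t(x)
  x_full <- model.matrix(~ sex + origin, data = tbl)
  e_mat <- t(y) %*% (diag(12) - proj(x_full)) %*% y
  for (f in c("sex", "origin")) {
    x_red <- model.matrix(stats::reformulate(setdiff(c("sex", "origin"), f)),
                          data = tbl)
    h_mat <- t(y) %*% (proj(x_full) - proj(x_red)) %*% y
    lam <- det(e_mat) / det(e_mat + h_mat)
    expect_equal(mv$table$wilks[mv$table$factor == f], lam, tolerance = 1e-10)
  }
})

test_that("identical group means give lambda 1 and F 0", {
  # mirrored construction: each female row duplicates a male row's values
  base <- toy_cohort(20, seed = 9)
  base$side <- "OD"; base$origin <- rep(c("Mauritius", "Asian"), 10)
  male <- base; male$sex <- "male"
  female <- base; female$sex <- "female"
  female$eye_id <- sprintf("f%03d", 1:20)
  both <- dplyr::bind_rows(male, female)
  mv <- cohort_manova(both, eye = "right", dependents = c("T1", "T2", "T3"))
  expect_equal(mv$table$wilks[mv$table$factor == "sex"], 1, tolerance = 1e-12)
  expect_equal(mv$table$statistic[mv$table$factor == "sex"], 0, tolerance = 1e-9)
})

test_that("lambda shrinks monotonically as group separation grows", {
  lams <- vapply(c(0, 5, 10, 20), function(d) {
    tbl <- toy_cohort(60, seed = 10, origin_shift = rep(d, 9))
    tbl$side <- "OD"
    mv <- cohort_manova(tbl, eye = "right")
    mv$table$wilks[mv$table$factor == "origin"]
  }, numeric(1))
  expect_true(all(diff(lams) < 0))
})

test_that("MANOVA and ANOVA agree with car's Type II tests", {
  skip_if_not_installed("car")
  tbl <- toy_cohort(80, seed = 11, sex_shift = -5, origin_shift = rep(6, 9))
  tbl$side <- "OD"
  mv <- cohort_manova(tbl, eye = "right")
  fit <- lm(as.matrix(tbl[, paste0("T", 1:9)]) ~ sex + origin, data = tbl)
  ref <- summary(car::Anova(fit, type = "II", test.statistic = "Wilks"))
  for (f in c("sex", "origin")) {
    sscp <- ref$multivariate.tests[[f]]
    expect_equal(mv$table$wilks[mv$table$factor == f],
                 det(sscp$SSPE) / det(sscp$SSPE + sscp$SSPH),
                 tolerance = 1e-10)
  }
  av <- cohort_anova(tbl, eye = "right")
  ref1 <- car::Anova(lm(T5 ~ sex + origin, data = tbl), type = "II")
  expect_equal(av$p.value[av$coefficient == "T5" & av$factor == "origin"],
               ref1[["Pr(>F)"]][rownames(ref1) == "origin"], tolerance = 1e-10)
})

test_that("two-way ANOVA collapses to one-way with a constant second factor", {
  tbl <- toy_cohort(30, seed = 12)
  tbl$side <- "OD"; tbl$origin <- "Mauritius"
  av <- cohort_anova(tbl, eye = "right", dependents = "T1", factors = "sex")
  # from-definition one-way F
  y <- tbl$T1; g <- tbl$sex
  means <- tapply(y, g, mean); ns <- table(g)
  ssb <- sum(ns * (means - mean(y))^2)
  ssw <- sum((y - means[g])^2)
  f_def <- (ssb / 1) / (ssw / (30 - 2))
  expect_equal(av$statistic, f_def, tolerance = 1e-10)
})

test_that("a pure origin shift on T5 is detected for T5 and not for sex", {
  tbl <- toy_cohort(120, seed = 13)
  tbl$side <- "OD"
  tbl$T5 <- tbl$T5 + (tbl$origin == "Asian") * 15
  av <- cohort_anova(tbl, eye = "right")
  p_t5_origin <- av$p.value[av$coefficient == "T5" & av$factor == "origin"]
  expect_lt(p_t5_origin, 0.001 / 9)
  expect_identical(av$stars[av$coefficient == "T5" & av$factor == "origin"], "***")
  p_sex <- av$p.value[av$factor == "sex"]
  expect_true(all(p_sex > 0.05 / 9))
})

test_that("Bonferroni star categories use thresholds divided by nine", {
  p <- c(0.001 / 9 * 0.9, 0.01 / 9 * 0.9, 0.05 / 9 * 0.9, 0.1 / 9 * 0.9, 0.5)
  expect_identical(foveametry:::bonferroni_stars(p, 9),
                   c("***", "**", "*", ".", ""))
})

test_that("unknown-origin rows are excluded from the factorial analyses", {
  tbl <- toy_cohort(60, seed = 14, origin_shift = rep(8, 9))
  tbl$side <- "OD"
  tbl$origin[1:10] <- "unknown"
  mv <- cohort_manova(tbl, eye = "right")
  expect_identical(mv$n, 50L)
  tbl$origin <- "unknown"
  expect_error(cohort_manova(tbl, eye = "right"), "fewer than two levels")
})

test_that("multivariate outliers are flagged by the chi-square criterion", {
  tbl <- toy_cohort(200, seed = 15)
  x <- as.matrix(tbl[, paste0("T", 1:9)])
  shifted <- tbl
  shifted[1, paste0("T", 1:9)] <- as.list(colMeans(x) + 10 * apply(x, 2, sd))
  flagged <- flag_multivariate_outliers(shifted)
  expect_true(flagged$.outlier[1])
  expect_identical(sum(flagged$.outlier), 1L)
  removed <- suppressMessages(remove_multivariate_outliers(shifted))
  expect_identical(nrow(removed), 199L)
  expect_false(".outlier" %in% names(removed))
  # clean cohorts flag at roughly the nominal 0.1% rate
  flags <- vapply(1:20, function(s) {
    sum(flag_multivariate_outliers(toy_cohort(200, seed = 100 + s))$.outlier)
  }, numeric(1))
  expect_lt(mean(flags) / 200, 0.02)
  # no-op when nothing is flagged
  clean <- toy_cohort(50, seed = 16)
  expect_equal(suppressMessages(remove_multivariate_outliers(clean)),
               clean[, names(clean)])
})

test_that("simulated cohorts are deterministic and carry the built-in effects", {
  a <- simulate_cohort(n = 40, seed = 77)
  b <- simulate_cohort(n = 40, seed = 77)
  expect_identical(a, b)
  big <- simulate_cohort(n = 300, seed = 78)
  grp <- summarize_cohort(big, group_by = "origin", coefficients = "T5")
  expect_gt(grp$mean[grp$origin == "Asian"], grp$mean[grp$origin == "Mauritius"])
  # thickness/area pairs correlate strongly, as in real cohorts
  cm <- correlation_matrix(big)
  expect_gt(cm["T1", "A1"], 0.8)
  expect_gt(cm["T5", "TUn"], 0.8)
})

test_that("tidy and glance methods return well-formed tibbles", {
  tbl <- simulate_cohort(n = 120, seed = 79)
  p <- cohort_pca(tbl, eye = "left")
  td <- tidy(p)
  expect_identical(nrow(td), 81L)
  expect_named(td, c("component", "term", "loading"))
  gl <- glance(p)
  expect_identical(gl$eye, "left")
  mv <- cohort_manova(tbl, eye = "left")
  expect_named(tidy(mv), c("factor", "wilks", "statistic", "df1", "df2", "p.value"))
  av <- cohort_anova(tbl, eye = "left")
  expect_s3_class(tidy(av), "tbl_df")
  expect_s3_class(autoplot(p), "ggplot")
  expect_s3_class(plot_cohort_boxplots(tbl), "ggplot")
  expect_s3_class(plot_thickness_profile(tbl[1:3, ]), "ggplot")
})
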