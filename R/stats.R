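# Reference-database statistics over a cohort of per-eye measurement records
# (the tibble produced by profile_eye()/read_measurements()).

t_cols <- function() paste0("T", 1:9)
all_coefficients <- function() c(thickness_columns(), area_columns())

check_cohort <- function(tbl, columns = NULL) {
  if (!nrow(tbl)) abort("empty cohort table")
  if (anyDuplicated(tbl[, c("eye_id", "side")])) {
    abort("cohort rows must be unique per (eye_id, side)")
  }
  if (!is.null(columns) && !all(columns %in% names(tbl))) {
    abort(paste0("cohort lacks column(s): ",
                 paste(setdiff(columns, names(tbl)), collapse = ", ")))
  }
  invisible(tbl)
}

filter_eye <- function(tbl, eye) {
  eye <- match.arg(eye, c("combined", "left", "right"))
  switch(eye,
    combined = tbl,
    left = dplyr::filter(tbl, .data$side == "OS"),
    right = dplyr::filter(tbl, .data$side == "OD")
  )
}

# Boxplot statistics under the whisker rule used throughout: the upper
# whisker is the last datum strictly smaller than Q3 + 1.5 IQR, the lower
# whisker the first datum strictly greater than Q1 - 1.5 IQR; data beyond
# the whiskers are outliers. Quantiles use linear interpolation between
# order statistics (type 7).
boxplot_stats <- function(x) {
  q <- unname(quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE))
  iqr <- q[3] - q[1]
  hi_lim <- q[3] + 1.5 * iqr
  lo_lim <- q[1] - 1.5 * iqr
  upper <- if (any(x < hi_lim)) max(x[x < hi_lim]) else q[3]
  lower <- if (any(x > lo_lim)) min(x[x > lo_lim]) else q[1]
  tibble::tibble(
    q1 = q[1], median = q[2], q3 = q[3], iqr = iqr,
    whisker_low = lower, whisker_high = upper,
    n_outliers = sum(x > upper | x < lower)
  )
}

#' Grouped summary statistics with boxplot components
#'
#' Per group (by default eye side x sex x origin) and per coefficient:
#' mean, min, max, sample standard deviation (n - 1 denominator; `NA` for
#' single-row groups), and the boxplot statistics (quartiles, IQR, whisker
#' ends under the strict 1.5 IQR rule, outlier count).
#'
#' @param tbl Cohort tibble of measurement records.
#' @param group_by Character vector of grouping columns.
#' @param coefficients Coefficient columns to summarize (default: all 21).
#' @return Long tibble: grouping columns, `coefficient`, then the statistics.
#' @export
summarize_cohort <- function(tbl, group_by = c("side", "sex", "origin"),
                             coefficients = all_coefficients()) {
  check_cohort(tbl, c(group_by, coefficients))
  long <- tidyr::pivot_longer(tbl[, c(group_by, coefficients)],
                              dplyr::all_of(coefficients),
                              names_to = "coefficient", values_to = "value")
  long$coefficient <- factor(long$coefficient, levels = coefficients)
  long |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(group_by, "coefficient")))) |>
    dplyr::reframe(
      n = length(.data$value),
      mean = mean(.data$value),
      min = min(.data$value),
      max = max(.data$value),
      std = if (length(.data$value) > 1L) sd(.data$value) else NA_real_,
      boxplot_stats(.data$value)
    )
}

#' Pearson correlation matrix of measurement coefficients
#'
#' @param tbl Cohort tibble.
#' @param columns Coefficient columns (default: all 21).
#' @param eyes `"combined"` (default; left and right eyes pooled), `"left"`
#'   or `"right"`.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(tbl, columns = all_coefficients(),
                               eyes = "combined") {
  tbl <- filter_eye(check_cohort(tbl, columns), eyes)
  if (nrow(tbl) < 3L) abort("need at least 3 rows for correlations")
  x <- as.matrix(tbl[, columns])
  v <- apply(x, 2, stats::var)
  if (any(v == 0)) {
    abort(paste0("zero-variance column(s): ",
                 paste(columns[v == 0], collapse = ", ")))
  }
  cor(x)
}

#' Principal component analysis of the thickness profile
#'
#' Eigendecomposition of the covariance matrix of the nine thickness
#' coefficients (raw um values, not standardized), run on one eye side at a
#' time so paired eyes cannot correlate the sample. Loadings are reported on
#' the thickness scale as eigenvector times the square root of the
#' eigenvalue; the first component's sign is fixed so its mean loading is
#' positive (an overall-thickness factor).
#'
#' @param tbl Cohort tibble.
#' @param eye `"left"` or `"right"`.
#' @param columns Thickness columns (default T1..T9).
#' @return Object of class `cohort_pca`: eigenvalues, cumulative explained
#'   variance (percent), loadings and unit eigenvectors (columns = PCs),
#'   `eye`, `n`.
#' @export
cohort_pca <- function(tbl, eye, columns = t_cols()) {
  tbl <- filter_eye(check_cohort(tbl, columns), eye)
  x <- as.matrix(tbl[, columns])
  if (nrow(x) <= length(columns)) {
    abort(sprintf("need more than %d rows for PCA, got %d", length(columns), nrow(x)))
  }
  e <- eigen(cov(x), symmetric = TRUE)
  vals <- pmax(e$values, 0)
  vecs <- e$vectors
  if (mean(vecs[, 1]) < 0) vecs[, 1] <- -vecs[, 1]
  loadings <- vecs %*% diag(sqrt(vals))
  dimnames(loadings) <- list(columns, paste0("PC", seq_along(vals)))
  dimnames(vecs) <- dimnames(loadings)
  structure(list(
    eigenvalues = vals,
    cum_var_pct = cumsum(vals) / sum(vals) * 100,
    loadings = loadings, rotation = vecs,
    eye = eye, n = nrow(x)
  ), class = "cohort_pca")
}

#' @export
print.cohort_pca <- function(x, ...) {
  cat(sprintf("<cohort_pca> %s eyes, n = %d; first 3 PCs explain %.1f%% of variance\n",
              x$eye, x$n, x$cum_var_pct[3]))
  invisible(x)
}

# ---- MANOVA / ANOVA (additive two-way, Type II sums of squares) -------------

drop_unknown <- function(tbl, factors) {
  for (f in factors) tbl <- tbl[tbl[[f]] != "unknown", ]
  tbl
}

# Rao's F approximation for Wilks' lambda with p dependents, q hypothesis df
# and ve error df.
wilks_to_f <- function(lambda, p, q, ve) {
  s <- if (p^2 + q^2 - 5 > 0) sqrt((p^2 * q^2 - 4) / (p^2 + q^2 - 5)) else 1
  df1 <- p * q
  df2 <- s * (ve - (p - q + 1) / 2) - (p * q - 2) / 2
  ls <- lambda^(1 / s)
  f <- (1 - ls) / ls * df2 / df1
  tibble::tibble(statistic = f, df1 = df1, df2 = df2,
                 p.value = pf(f, df1, df2, lower.tail = FALSE))
}

#' Two-way MANOVA of the thickness profile (Wilks' lambda)
#'
#' Additive two-way MANOVA of T1..T9 on sex and origin for one eye side
#' (the interaction is not part of the model). For each factor, the Type II
#' hypothesis SSCP is the difference between the residual cross-products of
#' the model without that factor and the full additive model; Wilks' lambda
#' is `det(E) / det(E + H)` and p-values use Rao's F approximation.
#' Unknown-origin (and unknown-sex) eyes are excluded.
#'
#' @param tbl Cohort tibble.
#' @param eye `"left"` or `"right"`.
#' @param dependents Dependent columns (default T1..T9).
#' @param factors Factor columns (default sex and origin).
#' @param remove_outliers Drop multivariate outliers first (Mahalanobis
#'   distance on the dependents, chi-square 0.999 cutoff); default FALSE.
#' @return Object of class `cohort_manova` with one row per factor:
#'   `factor`, `wilks`, `statistic` (approximate F), `df1`, `df2`,
#'   `p.value`; plus `eye`, `n`, `n_outliers_removed`.
#' @export
cohort_manova <- function(tbl, eye, dependents = t_cols(),
                          factors = c("sex", "origin"),
                          remove_outliers = FALSE) {
  tbl <- drop_unknown(filter_eye(check_cohort(tbl, c(dependents, factors)), eye),
                      factors)
  n_out <- 0L
  if (remove_outliers) {
    flagged <- flag_multivariate_outliers(tbl, columns = dependents)
    n_out <- sum(flagged$.outlier)
    tbl <- flagged[!flagged$.outlier, names(tbl)]
  }
  for (f in factors) {
    if (length(unique(tbl[[f]])) < 2L) {
      abort(sprintf("factor '%s' has fewer than two levels after exclusions", f))
    }
  }
  y <- as.matrix(tbl[, dependents])
  dat <- as.data.frame(tbl[, factors])
  full <- stats::lm(stats::reformulate(factors, response = quote(y)),
                    data = cbind(dat, list(y = y)))
  e_mat <- crossprod(stats::resid(full))
  if (abs(det(e_mat)) < .Machine$double.xmin) abort("singular error matrix")
  ve <- stats::df.residual(full)
  rows <- lapply(factors, function(f) {
    others <- setdiff(factors, f)
    reduced <- stats::lm(
      if (length(others)) stats::reformulate(others, response = quote(y))
      else y ~ 1,
      data = cbind(dat, list(y = y))
    )
    h_mat <- crossprod(stats::resid(reduced)) - e_mat
    q <- stats::df.residual(reduced) - ve
    lambda <- det(e_mat) / det(e_mat + h_mat)
    dplyr::bind_cols(tibble::tibble(factor = f, wilks = lambda),
                     wilks_to_f(lambda, ncol(y), q, ve))
  })
  structure(list(table = dplyr::bind_rows(rows), eye = eye, n = nrow(tbl),
                 n_outliers_removed = n_out),
            class = "cohort_manova")
}

#' @export
print.cohort_manova <- function(x, ...) {
  cat(sprintf("<cohort_manova> %s eyes, n = %d (outliers removed: %d)\n",
              x$eye, x$n, x$n_outliers_removed))
  print(x$table)
  invisible(x)
}

bonferroni_stars <- function(p, m) {
  cut_levels <- c(0.001, 0.01, 0.05, 0.1) / m
  dplyr::case_when(
    p < cut_levels[1] ~ "***",
    p < cut_levels[2] ~ "**",
    p < cut_levels[3] ~ "*",
    p < cut_levels[4] ~ ".",
    TRUE ~ ""
  )
}

#' Per-coefficient two-way ANOVA with Bonferroni-adjusted significance
#'
#' For each thickness coefficient individually, an additive two-way ANOVA on
#' sex and origin (Type II F: each factor tested against the full additive
#' model). Raw p-values are reported; significance categories divide the
#' conventional levels by the number of tests (m = 9): `***` for
#' p < 0.001/9, `**` for p < 0.01/9, `*` for p < 0.05/9 and `.` for
#' p < 0.1/9. Unknown-level rows are excluded.
#'
#' @inheritParams cohort_manova
#' @return Tibble (class `cohort_anova`): `coefficient`, `factor`,
#'   `statistic` (F), `df1`, `df2`, `p.value`, `stars`.
#' @export
cohort_anova <- function(tbl, eye, dependents = t_cols(),
                         factors = c("sex", "origin")) {
  tbl <- drop_unknown(filter_eye(check_cohort(tbl, c(dependents, factors)), eye),
                      factors)
  for (f in factors) {
    if (length(unique(tbl[[f]])) < 2L) {
      abort(sprintf("factor '%s' has fewer than two levels after exclusions", f))
    }
  }
  dat <- as.data.frame(tbl[, factors])
  m <- length(dependents)
  out <- purrr::map_dfr(dependents, function(dep) {
    y <- tbl[[dep]]
    full <- stats::lm(stats::reformulate(factors, response = quote(y)),
                      data = cbind(dat, list(y = y)))
    rss_full <- sum(stats::resid(full)^2)
    ve <- stats::df.residual(full)
    purrr::map_dfr(factors, function(f) {
      others <- setdiff(factors, f)
      reduced <- stats::lm(
        if (length(others)) stats::reformulate(others, response = quote(y))
        else y ~ 1,
        data = cbind(dat, list(y = y))
      )
      q <- stats::df.residual(reduced) - ve
      fstat <- ((sum(stats::resid(reduced)^2) - rss_full) / q) / (rss_full / ve)
      tibble::tibble(coefficient = dep, factor = f, statistic = fstat,
                     df1 = q, df2 = ve,
                     p.value = pf(fstat, q, ve, lower.tail = FALSE))
    })
  })
  out$stars <- bonferroni_stars(out$p.value, m)
  class(out) <- c("cohort_anova", class(out))
  out
}

#' Flag or remove multivariate outliers in the thickness profile
#'
#' Declares a row an outlier when its squared Mahalanobis distance from the
#' sample mean of the selected columns exceeds the chi-square cutoff (df =
#' number of columns) at the given level. With the default level 0.999, a
#' clean multivariate normal cohort flags about 0.1 percent of rows.
#'
#' @param tbl Cohort tibble.
#' @param columns Columns defining the multivariate space (default T1..T9).
#' @param eye Optional eye filter (`"left"`, `"right"`, `"combined"`).
#' @param level Chi-square quantile used as cutoff (default 0.999).
#' @return `flag_multivariate_outliers()` returns `tbl` (filtered to `eye`)
#'   with logical column `.outlier` and numeric `.mahalanobis` added;
#'   `remove_multivariate_outliers()` returns the table without the flagged
#'   rows (and messages how many were dropped).
#' @export
flag_multivariate_outliers <- function(tbl, columns = t_cols(), eye = "combined",
                                       level = 0.999) {
  tbl <- filter_eye(check_cohort(tbl, columns), eye)
  x <- as.matrix(tbl[, columns])
  d2 <- mahalanobis(x, colMeans(x), cov(x))
  tbl$.mahalanobis <- d2
  tbl$.outlier <- d2 > qchisq(level, df = length(columns))
  tbl
}

#' @rdname flag_multivariate_outliers
#' @export
remove_multivariate_outliers <- function(tbl, columns = t_cols(),
                                         eye = "combined", level = 0.999) {
  flagged <- flag_multivariate_outliers(tbl, columns, eye, level)
  n <- sum(flagged$.outlier)
  if (n > 0) message(sprintf("removed %d multivariate outlier(s)", n))
  flagged[!flagged$.outlier, setdiff(names(flagged), c(".outlier", ".mahalanobis"))]
}
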