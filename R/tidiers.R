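#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a cohort PCA
#'
#' @param x A `cohort_pca` object.
#' @param ... Unused.
#' @return One row per (component, thickness coefficient) with the loading
#'   (eigenvector scaled by the square root of the eigenvalue, on the
#'   thickness scale).
#' @method tidy cohort_pca
#' @export
tidy.cohort_pca <- function(x, ...) {
  terms <- rownames(x$loadings)
  purrr::map_dfr(seq_along(x$eigenvalues), function(k) {
    tibble::tibble(component = k, term = terms, loading = x$loadings[, k])
  })
}

#' @rdname tidy.cohort_pca
#' @return `glance()`: one row with `eye`, `n`, total variance, and the
#'   cumulative explained variance (percent) of the first three components.
#' @method glance cohort_pca
#' @export
glance.cohort_pca <- function(x, ...) {
  tibble::tibble(eye = x$eye, n = x$n,
                 total_variance = sum(x$eigenvalues),
                 cum_var_pct_3 = x$cum_var_pct[3])
}

#' Scree plot of a cohort PCA
#'
#' @param object A `cohort_pca` object.
#' @param ... Unused.
#' @return A ggplot showing cumulative explained variance per component.
#' @method autoplot cohort_pca
#' @export
autoplot.cohort_pca <- function(object, ...) {
  d <- tibble::tibble(component = seq_along(object$eigenvalues),
                      cum_var_pct = object$cum_var_pct)
  ggplot2::ggplot(d, ggplot2::aes(.data$component, .data$cum_var_pct)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_continuous(breaks = d$component) +
    ggplot2::labs(x = "Principal component",
                  y = "Cumulative explained variance (%)",
                  title = sprintf("PCA scree, %s eyes (n = %d)", object$eye, object$n))
}

#' Tidy a cohort MANOVA
#'
#' @param x A `cohort_manova` object.
#' @param ... Unused.
#' @return One row per factor: `factor`, `wilks`, `statistic`, `df1`,
#'   `df2`, `p.value`.
#' @method tidy cohort_manova
#' @export
tidy.cohort_manova <- function(x, ...) x$table

#' @rdname tidy.cohort_manova
#' @method glance cohort_manova
#' @export
glance.cohort_manova <- function(x, ...) {
  tibble::tibble(eye = x$eye, n = x$n,
                 n_outliers_removed = x$n_outliers_removed)
}

#' Tidy a per-coefficient ANOVA table
#'
#' @param x A `cohort_anova` tibble.
#' @param ... Unused.
#' @return The underlying tibble.
#' @method tidy cohort_anova
#' @export
tidy.cohort_anova <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' Boxplots of cohort coefficients by group
#'
#' Draws the distribution of each coefficient per sex-by-origin group, one
#' panel layout mirroring a reference-database boxplot figure. Whiskers
#' follow ggplot2's standard 1.5 IQR rule, which matches the summary-table
#' rule up to the treatment of data exactly at the fence.
#'
#' @param tbl Cohort tibble.
#' @param coefficients Coefficient columns to plot (default T1..T9).
#' @param eyes `"combined"`, `"left"` or `"right"`.
#' @return A ggplot.
#' @export
plot_cohort_boxplots <- function(tbl, coefficients = t_cols(),
                                 eyes = "combined") {
  tbl <- filter_eye(check_cohort(tbl, coefficients), eyes)
  long <- tidyr::pivot_longer(tbl, dplyr::all_of(coefficients),
                              names_to = "coefficient", values_to = "value")
  long$coefficient <- factor(long$coefficient, levels = coefficients)
  ggplot2::ggplot(long, ggplot2::aes(.data$coefficient, .data$value,
                                     fill = interaction(.data$origin, .data$sex))) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::labs(x = NULL, y = "Thickness (µm)", fill = "origin.sex")
}

#' Plot a measured foveal thickness profile
#'
#' @param records Measurement tibble (one line per eye is drawn).
#' @return A ggplot of thickness against lateral offset from the nulla
#'   (nasal negative).
#' @export
plot_thickness_profile <- function(records) {
  offs <- c(seq(-2000, 2000, by = 500), -100, 100)
  labels <- c(paste0("T", 1:9), "TUn", "TUt")
  long <- tidyr::pivot_longer(records, dplyr::all_of(labels),
                              names_to = "label", values_to = "thickness_um")
  long$offset_um <- offs[match(long$label, labels)]
  ggplot2::ggplot(long, ggplot2::aes(.data$offset_um, .data$thickness_um,
                                     group = .data$eye_id)) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "Offset from nulla (µm, nasal < 0)",
                  y = "Retinal thickness (µm)")
}
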