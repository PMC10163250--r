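#' Two-sided F-test of variance equality
#'
#' The gate that routes each analyte to the pooled-variance Student's t-test
#' (variances compatible) or to the Mann-Whitney U test (variances unequal).
#'
#' @param x,y Numeric vectors, each of length >= 2.
#' @return A list with `statistic` (the variance ratio `var(x)/var(y)`),
#'   `p` (two-sided), and `degenerate` (`TRUE` when both variances are zero,
#'   in which case `p = 1`).
#' @export
variance_equality_test <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  stopifnot(length(x) >= 2, length(y) >= 2)
  vx <- var(x); vy <- var(y)
  if (vx == 0 && vy == 0) {
    return(list(statistic = NA_real_, p = 1, degenerate = TRUE))
  }
  f <- vx / vy
  df1 <- length(x) - 1
  df2 <- length(y) - 1
  if (vy == 0) {
    p <- 0
  } else {
    lower <- pf(f, df1, df2)
    p <- min(1, 2 * min(lower, 1 - lower))
  }
  list(statistic = f, p = p, degenerate = FALSE)
}

band_for <- function(p) {
  dplyr::case_when(p < 0.001 ~ "p<0.001", p < 0.01 ~ "p<0.01", TRUE ~ "ns")
}

#' Per-analyte two-group comparison with an equal-variance gate
#'
#' For each analyte, tests control vs case concentrations: when the two-sided
#' F-test of variance equality is non-significant at `alpha_var` the
#' pooled-variance Student's t-test is used, otherwise the Mann-Whitney U test
#' (normal approximation with tie correction).  Returns the mean +/- SD table
#' with a significance band per analyte (`p<0.001`, `p<0.01`, `ns`).
#'
#' @param data A cohort tibble with both groups present (>= 2 samples each).
#' @param alpha_var Significance level of the variance gate (default 0.05).
#' @param adjust `"none"` (default; raw bands as conventionally reported) or
#'   `"BH"` for Benjamini-Hochberg adjusted p-values.
#' @return A `plasmanet_univariate` tibble with one row per analyte:
#'   `analyte_id`, `mean_control`, `sd_control`, `mean_case`, `sd_case`,
#'   `test_used` (`t_equal_var`/`mann_whitney`/`degenerate`), `p_value`,
#'   `significance_band`.
#' @export
compare_groups <- function(data, alpha_var = 0.05, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  data <- validate_cohort(data)
  n_ctrl <- sum(data$group == "control")
  n_case <- sum(data$group == "case")
  if (n_ctrl < 2 || n_case < 2) {
    abort("both groups need at least 2 samples")
  }
  analytes <- cohort_analytes(data)
  is_case <- data$group == "case"
  out <- purrr::map_dfr(analytes, function(a) {
    x <- data[[a]][!is_case]  # control
    y <- data[[a]][is_case]   # case
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    gate <- variance_equality_test(x, y)
    if (gate$degenerate) {
      # both groups constant: no dispersion to test against
      test <- "degenerate"
      p <- 1
    } else if (gate$p >= alpha_var) {
      test <- "t_equal_var"
      p <- stats::t.test(x, y, var.equal = TRUE)$p.value
    } else {
      test <- "mann_whitney"
      p <- stats::wilcox.test(x, y, exact = FALSE, correct = FALSE)$p.value
    }
    tibble::tibble(
      analyte_id = a,
      mean_control = mean(x), sd_control = sd(x),
      mean_case = mean(y), sd_case = sd(y),
      test_used = test, p_value = p
    )
  })
  if (adjust == "BH") {
    out$p_value <- stats::p.adjust(out$p_value, method = "BH")
  }
  out$significance_band <- band_for(out$p_value)
  class(out) <- c("plasmanet_univariate", class(out))
  out
}

#' @export
autoplot.plasmanet_univariate <- function(object, ...) {
  df <- dplyr::mutate(object,
    analyte_id = stats::reorder(.data$analyte_id, -log10(.data$p_value)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$analyte_id,
                                   y = -log10(.data$p_value),
                                   fill = .data$significance_band)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = -log10(c(0.01, 0.001)), linetype = 2) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = expression(-log[10](p)),
                  fill = "band") +
    ggplot2::theme_minimal()
}
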