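#' Kaplan-Meier product-limit estimator
#'
#' Wraps a product-limit fit into the pipeline's survival-curve table:
#' one row per distinct event time with the at-risk count, the number of
#' events, the survival estimate `S(t) = prod(1 - d_i/n_i)` and its
#' Greenwood standard error.  Censored times reduce the risk set without a
#' step.
#'
#' @param data A data frame with time/event columns.
#' @param time,event Unquoted column names: positive follow-up times and
#'   event indicators (1 = event, 0 = censored).
#' @return A `plasmanet_km` object; `tidy()` returns the step table,
#'   `glance()` the n / events / median-survival summary.
#' @export
km_estimator <- function(data, time = time, event = event) {
  t <- rlang::eval_tidy(enquo(time), data)
  d <- rlang::eval_tidy(enquo(event), data)
  if (length(t) == 0) abort("empty survival input")
  stopifnot(length(t) == length(d), all(t > 0), all(d %in% c(0, 1)))
  fit <- survival::survfit(survival::Surv(t, d) ~ 1)
  keep <- fit$n.event > 0
  steps <- tibble::tibble(
    time = fit$time[keep],
    at_risk = fit$n.risk[keep],
    events = fit$n.event[keep],
    survival = fit$surv[keep],
    std_error = fit$surv[keep] * fit$std.err[keep]  # Greenwood, S-scale
  )
  structure(
    list(steps = steps, n = length(t), n_events = sum(d),
         median_survival = unname(
           summary(fit)$table["median"]),
         fit = fit),
    class = "plasmanet_km"
  )
}

#' @export
tidy.plasmanet_km <- function(x, ...) x$steps

#' @export
glance.plasmanet_km <- function(x, ...) {
  tibble::tibble(n = x$n, n_events = x$n_events,
                 median_survival = x$median_survival)
}

#' @export
print.plasmanet_km <- function(x, ...) {
  cat("Kaplan-Meier estimate:", x$n, "subjects,", x$n_events, "events",
      "| median survival", signif(x$median_survival, 4), "\n")
  print(x$steps)
  invisible(x)
}

#' @export
autoplot.plasmanet_km <- function(object, ...) {
  df <- dplyr::bind_rows(
    tibble::tibble(time = 0, survival = 1),
    dplyr::select(object$steps, "time", "survival"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$survival)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "time", y = "survival probability") +
    ggplot2::theme_minimal()
}

#' Survival probability at a time point
#'
#' Right-continuous step lookup: the estimate at the largest event time not
#' exceeding `t` (1 before the first event).
#'
#' @param km A `plasmanet_km`.
#' @param t Positive time.
#' @return Survival probability in `[0, 1]`.
#' @export
survival_rate_at <- function(km, t) {
  stopifnot(t > 0)
  steps <- km$steps
  i <- findInterval(t, steps$time)
  if (i == 0) 1 else steps$survival[i]
}

#' Median split of a continuous expression vector
#'
#' Samples strictly above the sample median are labelled `high`, the rest
#' (including ties at the median) `low`; the labelling is invariant under
#' strictly monotone transforms of the input.
#'
#' @param expression Numeric vector (>= 2 values, not all identical).
#' @return Character vector of `"high"`/`"low"` labels.
#' @export
median_split <- function(expression) {
  stopifnot(length(expression) >= 2)
  if (length(unique(expression)) == 1) {
    abort("all values identical; no split possible")
  }
  ifelse(expression > median(expression), "high", "low")
}

#' Two-group log-rank test
#'
#' Standard log-rank comparison: expected events per group from pooled risk
#' sets at each event time; the statistic is chi-squared with 1 degree of
#' freedom.  With no events at all the test is degenerate and reported as
#' statistic 0, p 1.
#'
#' @param data A data frame with time, event and group columns.
#' @param time,event,group Unquoted column names; `group` must have exactly
#'   two levels, both non-empty.
#' @return A `plasmanet_logrank` object with `statistic`, `df`, `p` and the
#'   per-group observed/expected table (observed minus expected sums to 0).
#' @export
logrank_test <- function(data, time = time, event = event, group = group) {
  t <- rlang::eval_tidy(enquo(time), data)
  d <- rlang::eval_tidy(enquo(event), data)
  grp <- as.factor(rlang::eval_tidy(enquo(group), data))
  if (nlevels(grp) != 2 || any(table(grp) == 0)) {
    abort("exactly two non-empty groups are required")
  }
  if (sum(d) == 0) {
    return(structure(
      list(statistic = 0, df = 1L, p = 1,
           groups = tibble::tibble(group = levels(grp),
                                   n = as.integer(table(grp)),
                                   observed = 0, expected = 0),
           degenerate = TRUE),
      class = "plasmanet_logrank"))
  }
  sd_fit <- survival::survdiff(survival::Surv(t, d) ~ grp)
  structure(
    list(statistic = unname(sd_fit$chisq), df = 1L,
         p = pchisq(unname(sd_fit$chisq), df = 1, lower.tail = FALSE),
         groups = tibble::tibble(group = levels(grp),
                                 n = as.integer(sd_fit$n),
                                 observed = unname(sd_fit$obs),
                                 expected = unname(sd_fit$exp)),
         degenerate = FALSE),
    class = "plasmanet_logrank"
  )
}

#' @export
tidy.plasmanet_logrank <- function(x, ...) x$groups

#' @export
glance.plasmanet_logrank <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, df = x$df, p.value = x$p,
                 degenerate = x$degenerate)
}

#' @export
print.plasmanet_logrank <- function(x, ...) {
  cat(sprintf("Log-rank test: chi-squared = %.4f (df %d), p = %.4g\n",
              x$statistic, x$df, x$p))
  print(x$groups)
  invisible(x)
}
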