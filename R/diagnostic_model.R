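outcome_vector <- function(data, outcome, positive) {
  y <- as.integer(data[[outcome]] == positive)
  if (length(unique(y)) < 2) {
    abort("both classes must be present", class = "plasmanet_validation_error")
  }
  y
}

#' Multivariate logistic regression with Wald odds-ratio reporting
#'
#' Maximum-likelihood logistic fit (iteratively reweighted least squares,
#' with intercept).  Standard errors are Wald, from the observed information;
#' odds ratios are `exp(coef)` with 95% CIs `exp(coef +/- 1.96 SE)`.
#'
#' @param data A data frame containing the outcome and predictor columns.
#' @param predictors Character vector of predictor column names.
#' @param outcome Name of the outcome column (default `"group"`).
#' @param positive Outcome level coded 1 (default `"case"`).
#' @return A `plasmanet_logistic` object; see [tidy()] and [glance()]
#'   methods.  Perfect separation is flagged via `converged = FALSE`;
#'   rank-deficient predictors raise an error naming the collinear columns.
#' @export
fit_logistic <- function(data, predictors, outcome = "group",
                         positive = "case") {
  stopifnot(length(predictors) >= 1)
  y <- outcome_vector(data, outcome, positive)
  X <- as.matrix(data[, predictors, drop = FALSE])
  storage.mode(X) <- "double"
  Xi <- cbind(`(Intercept)` = 1, X)
  qx <- qr(Xi)
  if (qx$rank < ncol(Xi)) {
    aliased <- colnames(Xi)[qx$pivot[-seq_len(qx$rank)]]
    abort(paste0("rank-deficient design; collinear column(s): ",
                 paste(aliased, collapse = ", ")),
          class = "plasmanet_rank_error")
  }
  fit <- suppressWarnings(glm.fit(Xi, y, family = binomial()))
  beta <- fit$coefficients
  p <- fit$rank
  covmat <- chol2inv(fit$qr$qr[seq_len(p), seq_len(p), drop = FALSE])
  se <- sqrt(diag(covmat))
  names(se) <- names(beta)
  mu <- fit$fitted.values
  ll <- sum(y * log(pmax(mu, 1e-300)) + (1 - y) * log(pmax(1 - mu, 1e-300)))
  # separation shows up as diverging standardized slopes (per-SD log-odds)
  std_slopes <- abs(beta[-1]) * apply(X, 2, sd)
  converged <- isTRUE(fit$converged) && !isTRUE(fit$boundary) &&
    (length(std_slopes) == 0 || max(std_slopes) < 15)
  terms <- tibble::tibble(
    term = names(beta),
    estimate = unname(beta),
    std.error = unname(se),
    statistic = unname(beta / se),
    p.value = 2 * pnorm(-abs(unname(beta / se))),
    odds.ratio = exp(unname(beta)),
    conf.low = exp(unname(beta - 1.96 * se)),
    conf.high = exp(unname(beta + 1.96 * se))
  )
  structure(
    list(variables = predictors, terms = terms, converged = converged,
         log_likelihood = ll, n = length(y), outcome = outcome,
         positive = positive, empty = FALSE, trace = NULL),
    class = "plasmanet_logistic"
  )
}

intercept_only_fit <- function(data, outcome, positive, trace = NULL) {
  y <- outcome_vector(data, outcome, positive)
  p0 <- mean(y)
  b0 <- log(p0 / (1 - p0))
  se0 <- sqrt(1 / (length(y) * p0 * (1 - p0)))
  structure(
    list(variables = character(),
         terms = tibble::tibble(
           term = "(Intercept)", estimate = b0, std.error = se0,
           statistic = b0 / se0, p.value = 2 * pnorm(-abs(b0 / se0)),
           odds.ratio = exp(b0), conf.low = exp(b0 - 1.96 * se0),
           conf.high = exp(b0 + 1.96 * se0)),
         converged = TRUE,
         log_likelihood = sum(y * log(p0) + (1 - y) * log(1 - p0)),
         n = length(y), outcome = outcome, positive = positive,
         empty = TRUE, trace = trace),
    class = "plasmanet_logistic"
  )
}

#' Predict from a fitted diagnostic model
#'
#' @param object A `plasmanet_logistic` fit.
#' @param data New data holding the model's predictor columns.
#' @param type `"link"` (linear predictor / combined marker score) or
#'   `"response"` (probability of the positive class).
#' @param ... Unused.
#' @return Numeric vector of scores.
#' @export
predict.plasmanet_logistic <- function(object, data,
                                       type = c("link", "response"), ...) {
  type <- match.arg(type)
  beta <- setNames(object$terms$estimate, object$terms$term)
  eta <- rep(beta[["(Intercept)"]], nrow(data))
  for (v in object$variables) eta <- eta + beta[[v]] * data[[v]]
  if (type == "link") eta else 1 / (1 + exp(-eta))
}

#' @export
print.plasmanet_logistic <- function(x, ...) {
  cat("Logistic diagnostic model (", length(x$variables), " variable(s), n = ",
      x$n, ")\n", sep = "")
  if (!x$converged) cat("  [flagged: not converged / separation]\n")
  print(x$terms)
  invisible(x)
}

#' @export
tidy.plasmanet_logistic <- function(x, ...) x$terms

#' @export
glance.plasmanet_logistic <- function(x, ...) {
  tibble::tibble(
    n = x$n, n_variables = length(x$variables),
    log_likelihood = x$log_likelihood,
    AIC = -2 * x$log_likelihood + 2 * nrow(x$terms),
    converged = x$converged
  )
}

stratified_folds <- function(y, n_folds, seed) {
  stopifnot(n_folds >= 2)
  if (min(table(y)) < n_folds) {
    abort("cannot stratify: a class has fewer samples than folds",
          class = "plasmanet_stratification_error")
  }
  foldid <- integer(length(y))
  set.seed(derive_seed(seed, "cvfolds"))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    foldid[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
  }
  foldid
}

#' Cross-validated LASSO logistic screening
#'
#' L1-penalised logistic regression over a geometric lambda grid (100 points
#' down to `1e-4 * lambda_max`, where `lambda_max` is the smallest penalty
#' with an all-zero solution).  Predictors are z-scored internally and
#' coefficients reported on the original scale.  `lambda_min` minimises the
#' mean binomial deviance over seeded, class-stratified cross-validation
#' folds; the selected set is the nonzero support at `lambda_min`.
#'
#' @param data A data frame with the outcome and candidate analyte columns.
#' @param predictors Candidate columns; default every analyte column.
#' @param outcome,positive Outcome column and positive level.
#' @param n_folds Number of CV folds (default 10).
#' @param seed Integer seed for fold assignment.
#' @return A `plasmanet_lasso` object with elements `lambdas`,
#'   `coefficients` (variables x lambda sparse matrix), `cv_deviance`
#'   (per-lambda mean and SE), `lambda_min`, `selected`.
#' @export
lasso_logistic_cv <- function(data, predictors = NULL, outcome = "group",
                              positive = "case", n_folds = 10, seed = 1) {
  predictors <- predictors %||% cohort_analytes(data)
  y <- outcome_vector(data, outcome, positive)
  X <- as.matrix(data[, predictors, drop = FALSE])
  foldid <- stratified_folds(y, n_folds, seed)
  cvfit <- glmnet::cv.glmnet(
    X, y, family = "binomial", foldid = foldid, nlambda = 100,
    lambda.min.ratio = 1e-4, standardize = TRUE, type.measure = "deviance"
  )
  cf <- coef(cvfit, s = "lambda.min")
  nz <- rownames(cf)[as.vector(cf != 0)]
  structure(
    list(lambdas = cvfit$lambda,
         coefficients = cvfit$glmnet.fit$beta,
         cv_deviance = tibble::tibble(lambda = cvfit$lambda,
                                      mean = cvfit$cvm, se = cvfit$cvsd),
         lambda_min = cvfit$lambda.min,
         selected = setdiff(nz, "(Intercept)"),
         n_folds = n_folds, seed = seed, cvfit = cvfit),
    class = "plasmanet_lasso"
  )
}

#' @export
print.plasmanet_lasso <- function(x, ...) {
  cat("LASSO logistic screening: lambda_min =", signif(x$lambda_min, 4),
      "selecting", length(x$selected), "analyte(s)\n")
  cat(" ", paste(x$selected, collapse = ", "), "\n")
  invisible(x)
}

#' @export
tidy.plasmanet_lasso <- function(x, ...) {
  cf <- coef(x$cvfit, s = "lambda.min")
  tibble::tibble(term = rownames(cf), estimate = as.vector(cf)) |>
    dplyr::filter(.data$estimate != 0, .data$term != "(Intercept)")
}

#' @export
glance.plasmanet_lasso <- function(x, ...) {
  i <- which.min(abs(x$lambdas - x$lambda_min))
  tibble::tibble(
    lambda_min = x$lambda_min,
    n_selected = length(x$selected),
    cv_deviance_min = x$cv_deviance$mean[i],
    n_folds = x$n_folds
  )
}

#' @export
autoplot.plasmanet_lasso <- function(object, ...) {
  ggplot2::ggplot(object$cv_deviance,
                  ggplot2::aes(x = log(.data$lambda), y = .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$se,
                                      ymax = .data$mean + .data$se),
                         alpha = 0.25) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = log(object$lambda_min), linetype = 2) +
    ggplot2::labs(x = expression(log(lambda)), y = "CV binomial deviance") +
    ggplot2::theme_minimal()
}

univariate_or <- function(data, variable, outcome, positive) {
  fit <- fit_logistic(data, variable, outcome, positive)
  fit$terms$odds.ratio[fit$terms$term == variable]
}

#' Backward stepwise logistic modelling with OR-based collinearity elimination
#'
#' Iterates two rules until neither fires: (a) while any candidate pair is
#' collinear (`|Pearson r| >= collinearity_r`), the member of the
#' most-correlated pair with the higher odds ratio is eliminated;
#' (b) otherwise the model is refit and the variable with the largest Wald p
#' is dropped if that p exceeds `alpha_stay`.  ORs for rule (a) are
#' single-variable logistic ORs, which remain defined for exactly duplicated
#' predictors (where a joint fit is aliased); ties break lexicographically.
#'
#' @param data A data frame with outcome and candidate columns.
#' @param candidates Candidate predictor names (e.g. a LASSO-selected set).
#' @param outcome,positive Outcome column and positive level.
#' @param alpha_stay Wald p-value above which a variable is dropped
#'   (default 0.05).
#' @param collinearity_r Absolute Pearson correlation at or above which a
#'   pair is collinear (default 0.8).
#' @param or_rule `"literal"` (drop the larger OR, the rule as usually
#'   stated) or `"magnitude"` (drop the larger of OR and 1/OR).
#' @return The final `plasmanet_logistic` fit, with the elimination trace in
#'   `$trace` (see [stepwise_trace()]).  If every candidate is eliminated an
#'   intercept-only fit with an empty variable list is returned, flagged via
#'   `$empty`.
#' @export
backward_stepwise <- function(data, candidates, outcome = "group",
                              positive = "case", alpha_stay = 0.05,
                              collinearity_r = 0.8,
                              or_rule = c("literal", "magnitude")) {
  or_rule <- match.arg(or_rule)
  stopifnot(length(candidates) >= 1, alpha_stay > 0, alpha_stay < 1,
            collinearity_r > 0, collinearity_r <= 1)
  current <- candidates
  trace <- list()
  note <- function(rule, dropped, detail) {
    trace[[length(trace) + 1]] <<- tibble::tibble(
      step = length(trace) + 1, rule = rule, dropped = dropped,
      detail = detail)
  }
  repeat {
    if (length(current) == 0) break
    if (length(current) >= 2) {
      r <- abs(cor(as.matrix(data[, current, drop = FALSE])))
      diag(r) <- 0
      if (max(r, na.rm = TRUE) >= collinearity_r) {
        idx <- which(r == max(r, na.rm = TRUE), arr.ind = TRUE)[1, ]
        pair <- sort(current[idx])
        ors <- vapply(pair, univariate_or, numeric(1),
                      data = data, outcome = outcome, positive = positive)
        key <- if (or_rule == "literal") ors else pmax(ors, 1 / ors)
        # ties (exact duplicates) fall to the lexicographically later name
        drop_var <- pair[order(-key, pair)][1]
        note("collinearity", drop_var,
             sprintf("|r|=%.4f within pair {%s}; OR %.4f vs %.4f (%s rule)",
                     max(r, na.rm = TRUE), paste(pair, collapse = ", "),
                     ors[1], ors[2], or_rule))
        current <- setdiff(current, drop_var)
        next
      }
    }
    fit <- fit_logistic(data, current, outcome, positive)
    wald <- dplyr::filter(fit$terms, .data$term != "(Intercept)")
    worst <- which.max(wald$p.value)
    if (wald$p.value[worst] > alpha_stay) {
      note("wald", wald$term[worst],
           sprintf("Wald p=%.4f > alpha_stay=%.3f",
                   wald$p.value[worst], alpha_stay))
      current <- setdiff(current, wald$term[worst])
    } else {
      break
    }
  }
  trace <- if (length(trace)) dplyr::bind_rows(trace) else
    tibble::tibble(step = integer(), rule = character(),
                   dropped = character(), detail = character())
  if (length(current) == 0) {
    return(intercept_only_fit(data, outcome, positive, trace = trace))
  }
  fit <- fit_logistic(data, current, outcome, positive)
  fit$trace <- trace
  fit
}

#' Elimination trace of a stepwise fit
#'
#' @param fit A `plasmanet_logistic` returned by [backward_stepwise()].
#' @return Tibble with columns `step`, `rule` (`collinearity`/`wald`),
#'   `dropped`, `detail`.
#' @export
stepwise_trace <- function(fit) {
  fit$trace %||% abort("fit carries no stepwise trace")
}

#' Rank-based AUROC
#'
#' The Mann-Whitney formulation with half-credit for ties: the probability
#' that a random positive outranks a random negative.
#'
#' @param score Numeric marker scores.
#' @param labels Logical vector (or coercible) marking positives.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(score, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) {
    abort("both classes must be present", class = "plasmanet_validation_error")
  }
  r <- rank(score)
  u <- sum(r[labels]) - n1 * (n1 + 1) / 2
  u / (n1 * n0)
}

#' ROC evaluation of a marker or model score
#'
#' Computes the full sensitivity/specificity profile over observed score
#' values, the rank-based AUROC, the Youden-optimal cutoff
#' (maximising sensitivity + specificity - 1; ties resolve to the lower,
#' more sensitive cutoff) and the cutoff's positive and negative predictive
#' values at sample prevalence.
#'
#' @param data A data frame holding the score and outcome columns.
#' @param score Unquoted column name (or a numeric expression in `data`'s
#'   columns) giving the marker score, oriented so larger means more
#'   case-like.
#' @param outcome,positive Outcome column and positive level.
#' @param direction `">"` (higher score = more case-like, the default),
#'   `"<"` (lower = more case-like; the score is negated internally), or
#'   `"auto"` (orientation chosen so AUROC >= 0.5, as conventional for
#'   per-analyte panels containing both up- and down-markers).
#' @return A `plasmanet_roc` object; `glance()` returns the one-row summary
#'   (auroc, cutoff, sensitivity, specificity, ppv, npv), `tidy()` the
#'   threshold-wise curve.
#' @export
roc_analysis <- function(data, score, outcome = "group", positive = "case",
                         direction = c(">", "<", "auto")) {
  direction <- match.arg(direction)
  sc <- rlang::eval_tidy(enquo(score), data)
  if (is.character(sc) && length(sc) == 1) sc <- data[[sc]]
  y <- data[[outcome]] == positive
  keep <- !is.na(sc) & !is.na(y)
  sc <- sc[keep]; y <- y[keep]
  if (!any(y) || all(y)) {
    abort("both classes must be present", class = "plasmanet_validation_error")
  }
  if (direction == "auto") {
    direction <- if (auroc(sc, y) >= 0.5) ">" else "<"
  }
  if (direction == "<") sc <- -sc
  a <- auroc(sc, y)
  thresholds <- sort(unique(sc))
  sens <- vapply(thresholds, function(t) mean(sc[y] >= t), numeric(1))
  spec <- vapply(thresholds, function(t) mean(sc[!y] < t), numeric(1))
  j <- sens + spec - 1
  cut_i <- which(j == max(j))[1]
  cutoff <- thresholds[cut_i]
  tp <- sum(y & sc >= cutoff); fp <- sum(!y & sc >= cutoff)
  fn <- sum(y & sc < cutoff); tn <- sum(!y & sc < cutoff)
  structure(
    list(thresholds = thresholds, sensitivity = sens, specificity = spec,
         auroc = a,
         # cutoff reported on the original score scale; direction gives the
         # case-like side (">": score >= cutoff, "<": score <= cutoff)
         cutoff = if (direction == "<") -cutoff else cutoff,
         sens_at_cutoff = sens[cut_i], spec_at_cutoff = spec[cut_i],
         ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
         npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_,
         direction = direction,
         n_positive = sum(y), n_negative = sum(!y)),
    class = "plasmanet_roc"
  )
}

#' @export
print.plasmanet_roc <- function(x, ...) {
  cat(sprintf(
    "ROC: AUROC %.4f | cutoff %.4g (sens %.3f, spec %.3f, ppv %.3f, npv %.3f)\n",
    x$auroc, x$cutoff, x$sens_at_cutoff, x$spec_at_cutoff, x$ppv, x$npv))
  invisible(x)
}

#' @export
tidy.plasmanet_roc <- function(x, ...) {
  tibble::tibble(threshold = x$thresholds, sensitivity = x$sensitivity,
                 specificity = x$specificity)
}

#' @export
glance.plasmanet_roc <- function(x, ...) {
  tibble::tibble(
    auroc = x$auroc, cutoff = x$cutoff, direction = x$direction,
    sensitivity = x$sens_at_cutoff, specificity = x$spec_at_cutoff,
    ppv = x$ppv, npv = x$npv,
    n_positive = x$n_positive, n_negative = x$n_negative
  )
}

#' @export
autoplot.plasmanet_roc <- function(object, ...) {
  df <- tidy(object) |> dplyr::arrange(dplyr::desc(.data$threshold))
  df <- dplyr::bind_rows(
    tibble::tibble(threshold = Inf, sensitivity = 0, specificity = 1), df,
    tibble::tibble(threshold = -Inf, sensitivity = 1, specificity = 0))
  ggplot2::ggplot(df, ggplot2::aes(x = 1 - .data$specificity,
                                   y = .data$sensitivity)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 3,
                         colour = "grey60") +
    ggplot2::geom_path() +
    ggplot2::annotate("text", x = 0.7, y = 0.1,
                      label = sprintf("AUROC = %.3f", object$auroc)) +
    ggplot2::labs(x = "1 - specificity", y = "sensitivity") +
    ggplot2::theme_minimal()
}
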