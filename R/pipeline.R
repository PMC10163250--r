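#' Configure an end-to-end pipeline run
#'
#' One config drives the whole analysis chain: detection filtering,
#' univariate screening, LASSO + backward stepwise diagnostic modelling, ROC
#' evaluation, per-group and per-stage correlation networks, and an optional
#' survival verification stage.  The run is a pure function of the config
#' (and input data): identical configs give identical reports.
#'
#' @param input_path Optional path to a concentration CSV; when `NULL` the
#'   `simulation` config is used to generate the cohort.
#' @param input_format `"csv"` or `"tsv"` for `input_path`.
#' @param simulation A [simulation_config()]; defaults to the paper-shaped
#'   cohort (78 controls, 64 cases) seeded from `seed`.
#' @param detection_max_missing Detection-filter threshold (default 0.2).
#' @param alpha_var Variance-gate level for [compare_groups()].
#' @param n_folds LASSO cross-validation folds (default 10).
#' @param alpha_stay,collinearity_r,or_rule Stepwise controls; see
#'   [backward_stepwise()].
#' @param r_min,edge_alpha,signed Network construction controls; see
#'   [threshold_graph()].
#' @param equal_n If `TRUE` (default) the stage comparison subsamples the
#'   larger stage to the size of the smaller before building networks.
#' @param survival A [survival_sim_config()], `TRUE` for a default seeded
#'   config, or `NULL` to skip the survival stage.
#' @param seed Integer master seed; stage seeds derive from it.
#' @return A `plasmanet_pipeline_config` list.
#' @export
pipeline_config <- function(input_path = NULL, input_format = "csv",
                            simulation = NULL,
                            detection_max_missing = 0.2, alpha_var = 0.05,
                            n_folds = 10, alpha_stay = 0.05,
                            collinearity_r = 0.8, or_rule = "literal",
                            r_min = 0.8, edge_alpha = 0.05, signed = TRUE,
                            equal_n = TRUE, survival = TRUE, seed = 1) {
  seed <- as.integer(seed)
  if (is.null(input_path) && is.null(simulation)) {
    simulation <- simulation_config(seed = derive_seed(seed, "simulate"))
  }
  if (isTRUE(survival)) {
    survival <- survival_sim_config(seed = derive_seed(seed, "survsim"))
  }
  stopifnot(alpha_var > 0, alpha_var < 1, alpha_stay > 0, alpha_stay < 1,
            edge_alpha > 0, edge_alpha < 1, r_min > 0, r_min <= 1)
  if (!is.null(input_path) && !file.exists(input_path)) {
    abort(paste0("input path does not exist: ", input_path))
  }
  structure(
    list(input_path = input_path, input_format = input_format,
         simulation = simulation,
         detection_max_missing = detection_max_missing,
         alpha_var = alpha_var, n_folds = n_folds,
         alpha_stay = alpha_stay, collinearity_r = collinearity_r,
         or_rule = or_rule, r_min = r_min, edge_alpha = edge_alpha,
         signed = signed, equal_n = equal_n, survival = survival,
         seed = seed),
    class = "plasmanet_pipeline_config"
  )
}

#' Run the full analysis pipeline
#'
#' Executes, in order: cohort input (read or simulate), detection filtering,
#' univariate screening, cross-validated LASSO screening, backward stepwise
#' modelling, ROC evaluation (per selected marker and for the combined model
#' score), per-group and per-stage threshold networks with full topology
#' reports and signed comparisons, and the optional survival stage
#' (median-split Kaplan-Meier + log-rank on a simulated expression marker).
#' Every decision (seeds, thresholds, dropped analytes, elimination rules)
#' is appended to the run log.
#'
#' @param cfg A [pipeline_config()].
#' @return A `plasmanet_run` report list; see [write_run_report()].
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "plasmanet_pipeline_config"))
  report <- list(config = cfg)
  log <- list()
  note <- function(stage, message) {
    log[[length(log) + 1]] <<- tibble::tibble(stage = stage,
                                              message = message)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      report$log <- dplyr::bind_rows(log)
      abort(paste0("pipeline stage '", name, "' failed: ",
                   conditionMessage(e)),
            class = "plasmanet_stage_error", stage = name,
            partial_report = report)
    })
  }

  data <- stage("input", {
    if (!is.null(cfg$input_path)) {
      note("input", paste("read", cfg$input_path))
      read_concentration_table(cfg$input_path, cfg$input_format)
    } else {
      note("input", paste("simulated cohort, seed", cfg$simulation$seed))
      simulate_cohort(cfg$simulation)
    }
  })

  data <- stage("detection", {
    out <- filter_detected(data, cfg$detection_max_missing)
    rep <- detection_report(out)
    note("detection", sprintf("%d/%d analytes retained (threshold %.2f)",
                              sum(rep$retained), nrow(rep),
                              cfg$detection_max_missing))
    for (a in rep$analyte_id[!rep$retained]) {
      note("detection", paste("dropped analyte", a))
    }
    report$detection <- rep
    out
  })

  report$univariate <- stage("univariate", {
    compare_groups(data, alpha_var = cfg$alpha_var)
  })
  note("univariate", sprintf("%d analytes below p<0.001",
                             sum(report$univariate$significance_band ==
                                   "p<0.001")))

  report$lasso <- stage("lasso", {
    lasso_logistic_cv(data, n_folds = cfg$n_folds,
                      seed = derive_seed(cfg$seed, "lasso"))
  })
  note("lasso", sprintf("lambda_min %.4g selecting %d analytes",
                        report$lasso$lambda_min,
                        length(report$lasso$selected)))

  report$model <- stage("stepwise", {
    if (length(report$lasso$selected) == 0) {
      note("stepwise", "skipped: LASSO selected no analytes")
      NULL
    } else {
      fit <- backward_stepwise(data, report$lasso$selected,
                               alpha_stay = cfg$alpha_stay,
                               collinearity_r = cfg$collinearity_r,
                               or_rule = cfg$or_rule)
      for (i in seq_len(nrow(fit$trace))) {
        note("stepwise", paste0("eliminated ", fit$trace$dropped[i], " (",
                                fit$trace$rule[i], "): ",
                                fit$trace$detail[i]))
      }
      note("stepwise", paste("final model:",
                             paste(fit$variables, collapse = ", ")))
      fit
    }
  })

  report$roc <- stage("roc", {
    if (is.null(report$model) || report$model$empty) {
      note("roc", "skipped: no final model")
      NULL
    } else {
      per_marker <- purrr::map_dfr(report$model$variables, function(v) {
        g <- glance(roc_analysis(data, !!rlang::sym(v), direction = "auto"))
        dplyr::bind_cols(tibble::tibble(marker = v), g)
      })
      score <- predict(report$model, data, type = "link")
      combined <- glance(roc_analysis(
        dplyr::mutate(data, .score = score), .data$.score))
      dplyr::bind_rows(per_marker,
                       dplyr::bind_cols(tibble::tibble(marker = "combined"),
                                        combined))
    }
  })

  report$networks <- stage("network", {
    nets <- list()
    for (grp in c("control", "case")) {
      corr <- pearson_matrix(data, grp)
      g <- threshold_graph(corr, cfg$r_min, cfg$edge_alpha, cfg$signed)
      nets[[grp]] <- list(graph = g, topology = topology_report(g))
      note("network", sprintf("%s: N=%d L=%d (%d isolated removed)", grp,
                              length(g$nodes), nrow(g$edges), g$n_isolated))
    }
    stages_present <- unique(stats::na.omit(data$stage))
    if (all(c("early", "advanced") %in% stages_present)) {
      n_early <- sum(data$stage == "early", na.rm = TRUE)
      n_adv <- sum(data$stage == "advanced", na.rm = TRUE)
      n_sub <- if (cfg$equal_n) min(n_early, n_adv) else NA
      for (stg in c("early", "advanced")) {
        sub <- data[!is.na(data$stage) & data$stage == stg, , drop = FALSE]
        if (cfg$equal_n && nrow(sub) > n_sub) {
          sub <- subsample_group(data, stg, n_sub,
                                 seed = derive_seed(cfg$seed, "subsample"))
          note("network", sprintf("subsampled %s to n=%d", stg, n_sub))
        }
        if (nrow(sub) < 3) {
          note("network", paste("stage", stg,
                                "skipped: fewer than 3 samples"))
          next
        }
        corr <- pearson_matrix(sub, "case")
        g <- threshold_graph(corr, cfg$r_min, cfg$edge_alpha, cfg$signed)
        nets[[stg]] <- list(graph = g, topology = topology_report(g))
        note("network", sprintf("%s: N=%d L=%d", stg, length(g$nodes),
                                nrow(g$edges)))
      }
    } else {
      note("network", "stage networks skipped: both stages not present")
    }
    nets
  })

  report$comparisons <- stage("network", {
    cmp <- list()
    cmp$control_vs_case <- compare_topologies(
      report$networks$control$topology, report$networks$case$topology)
    if (!is.null(report$networks$early) &&
        !is.null(report$networks$advanced)) {
      cmp$early_vs_advanced <- compare_topologies(
        report$networks$early$topology, report$networks$advanced$topology)
    }
    cmp
  })

  report$survival <- stage("survival", {
    if (is.null(cfg$survival)) {
      note("survival", "skipped: no survival config")
      NULL
    } else {
      surv <- simulate_survival_cohort(cfg$survival)
      surv$expression_group <- median_split(surv$expression)
      lr <- logrank_test(surv, .data$time, .data$event,
                         .data$expression_group)
      note("survival", sprintf("log-rank p = %.4g over median split", lr$p))
      list(
        cohort = surv,
        km = purrr::map(split(surv, surv$expression_group), km_estimator),
        logrank = lr
      )
    }
  })

  report$log <- dplyr::bind_rows(log)
  class(report) <- "plasmanet_run"
  report
}

#' @export
print.plasmanet_run <- function(x, ...) {
  cat("plasmanet pipeline run (seed ", x$config$seed, ")\n", sep = "")
  if (!is.null(x$model)) {
    cat("final model:", paste(x$model$variables, collapse = ", "), "\n")
  }
  if (!is.null(x$roc)) {
    cat("combined AUROC:",
        signif(x$roc$auroc[x$roc$marker == "combined"], 4), "\n")
  }
  cat("networks:", paste(names(x$networks), collapse = ", "), "\n")
  invisible(x)
}

#' Signed comparison of two topology reports
#'
#' Per-parameter difference `b - a` with a direction label
#' (`increased` / `decreased` / `unchanged`), refusing to compare reports
#' computed under different construction settings.  Undefined parameters
#' (NA on either side) are reported as `undefined` rather than a number.
#'
#' @param a,b `plasmanet_topology` reports computed with identical settings.
#' @return Tibble with columns `parameter`, `a`, `b`, `difference`,
#'   `direction`.
#' @export
compare_topologies <- function(a, b) {
  stopifnot(inherits(a, "plasmanet_topology"),
            inherits(b, "plasmanet_topology"))
  if (!identical(a$settings, b$settings) ||
      !identical(a$heterogeneity_variance, b$heterogeneity_variance)) {
    abort(paste0(
      "topology reports were computed with different settings:\n  a: ",
      paste(deparse(a$settings), collapse = ""), "\n  b: ",
      paste(deparse(b$settings), collapse = "")),
      class = "plasmanet_settings_error")
  }
  ta <- tidy(a); tb <- tidy(b)
  out <- tibble::tibble(
    parameter = ta$parameter, a = ta$value, b = tb$value,
    difference = tb$value - ta$value
  )
  out$direction <- dplyr::case_when(
    is.na(out$difference) ~ "undefined",
    out$difference > 0 ~ "increased",
    out$difference < 0 ~ "decreased",
    TRUE ~ "unchanged"
  )
  out
}

serialize_topology <- function(tp) {
  c(as.list(tidy(tp) |> tidyr::pivot_wider(names_from = "parameter",
                                           values_from = "value")),
    list(hubs = as.list(tp$hubs), n_isolated = tp$n_isolated))
}

#' Serialise a run report to JSON
#'
#' Deterministic JSON rendering of the report's tabular content; two runs of
#' the same config produce byte-identical output.
#'
#' @param report A `plasmanet_run`.
#' @return A JSON string.
#' @export
run_report_json <- function(report) {
  x <- list(
    seed = report$config$seed,
    detection = as.list(report$detection),
    univariate = as.list(report$univariate),
    lasso = list(lambda_min = report$lasso$lambda_min,
                 selected = report$lasso$selected),
    model = if (!is.null(report$model)) as.list(tidy(report$model)),
    roc = if (!is.null(report$roc)) as.list(report$roc),
    topology = purrr::map(report$networks,
                          function(n) serialize_topology(n$topology)),
    comparisons = purrr::map(report$comparisons, as.list),
    survival = if (!is.null(report$survival)) list(
      logrank = as.list(glance(report$survival$logrank)),
      km = purrr::map(report$survival$km,
                      function(k) as.list(glance(k)))
    ),
    log = as.list(report$log)
  )
  as.character(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                                na = "null", null = "null"))
}

#' Write run artifacts to a directory
#'
#' Writes the univariate table, LASSO selection, final model terms, ROC
#' table, per-network edge lists and topology tables (plus a wide
#' parameters-by-group CSV), survival outputs, the run log and the full
#' JSON report, with a manifest of the files written.
#'
#' @param report A `plasmanet_run`.
#' @param dir Output directory (created if needed).
#' @return Character vector of files written, invisibly.
#' @export
write_run_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  put_csv <- function(df, name) {
    path <- file.path(dir, name)
    readr::write_csv(df, path)
    files <<- c(files, name)
  }
  put_csv(report$detection, "detection.csv")
  put_csv(report$univariate, "univariate.csv")
  put_csv(tidy(report$lasso), "lasso_selected.csv")
  if (!is.null(report$model)) put_csv(tidy(report$model), "model_terms.csv")
  if (!is.null(report$roc)) put_csv(report$roc, "roc.csv")
  wide <- purrr::imap_dfr(report$networks, function(n, grp) {
    dplyr::mutate(tidy(n$topology), network = grp)
  }) |>
    tidyr::pivot_wider(names_from = "network", values_from = "value")
  put_csv(wide, "topology_parameters.csv")
  for (grp in names(report$networks)) {
    path <- file.path(dir, paste0("edges_", grp, ".tsv"))
    write_edge_list(report$networks[[grp]]$graph, path)
    files <- c(files, basename(path))
  }
  if (!is.null(report$survival)) {
    put_csv(report$survival$cohort, "survival_cohort.csv")
    put_csv(purrr::imap_dfr(report$survival$km, function(k, grp) {
      dplyr::mutate(tidy(k), expression_group = grp)
    }), "survival_km.csv")
  }
  put_csv(report$log, "run_log.csv")
  writeLines(run_report_json(report), file.path(dir, "report.json"))
  files <- c(files, "report.json")
  writeLines(files, file.path(dir, "MANIFEST"))
  invisible(files)
}

config_to_list <- function(cfg) {
  out <- unclass(cfg)
  if (!is.null(out$simulation)) {
    sim <- unclass(out$simulation)
    sim$panel <- as.list(sim$panel)
    # yaml drops names on atomic vectors; store named vectors as maps
    sim$effects <- as.list(sim$effects)
    if (!is.null(sim$log_mean)) sim$log_mean <- as.list(sim$log_mean)
    if (length(sim$log_sd) > 1) sim$log_sd <- as.list(sim$log_sd)
    out$simulation <- sim
  }
  if (!is.null(out$survival)) out$survival <- unclass(out$survival)
  out
}

#' Write / read a pipeline config as YAML
#'
#' Human-editable round-trip of [pipeline_config()] (including any embedded
#' simulation and survival configs).
#'
#' @param cfg A `plasmanet_pipeline_config`.
#' @param path YAML file path.
#' @return `write_pipeline_config()` returns `path` invisibly;
#'   `read_pipeline_config()` returns the config.
#' @export
write_pipeline_config <- function(cfg, path) {
  yaml::write_yaml(config_to_list(cfg), path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- yaml::read_yaml(path)
  sim <- NULL
  if (!is.null(x$simulation)) {
    s <- x$simulation
    sim <- simulation_config(
      n_control = s$n_control, n_case = s$n_case,
      n_case_early = s$n_case_early,
      panel = tibble::as_tibble(s$panel),
      log_mean = if (!is.null(s$log_mean)) unlist(s$log_mean),
      log_sd = if (length(s$log_sd) > 1) unlist(s$log_sd) else s$log_sd,
      effects = unlist(s$effects),
      blocks = s$blocks, missing_rate = s$missing_rate, seed = s$seed)
  }
  surv <- NULL
  if (!is.null(x$survival)) {
    surv <- survival_sim_config(
      n = x$survival$n, baseline_hazard = x$survival$baseline_hazard,
      log_hazard_ratio_per_sd = x$survival$log_hazard_ratio_per_sd,
      censoring_rate = x$survival$censoring_rate, seed = x$survival$seed)
  }
  pipeline_config(
    input_path = x$input_path, input_format = x$input_format %||% "csv",
    simulation = sim, detection_max_missing = x$detection_max_missing,
    alpha_var = x$alpha_var, n_folds = x$n_folds,
    alpha_stay = x$alpha_stay, collinearity_r = x$collinearity_r,
    or_rule = x$or_rule, r_min = x$r_min, edge_alpha = x$edge_alpha,
    signed = x$signed, equal_n = x$equal_n, survival = surv,
    seed = x$seed)
}
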