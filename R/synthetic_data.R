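#' Default 121-analyte panel annotation
#'
#' A synthetic panel emulating the analyte classes of a targeted-metabolomics
#' kit after detection filtering: 24 acylcarnitines, 21 amino acids, 12
#' biogenic amines, 10 lysophosphatidylcholines, 30 diacyl and 17 acyl-alkyl
#' phosphatidylcholines, 6 sphingomyelins and the hexose sum (121 analytes).
#'
#' @return Tibble with columns `analyte_id`, `analyte_class`.
#' @export
default_panel <- function() {
  ac <- c("C0", "C2", "C3", "C4", "C5", "C6", "C8", "C10", "C10.1", "C12",
          "C14", "C14.1", "C16", "C16.1", "C18", "C18.1", "C18.2", "C3.DC",
          "C5.DC", "C5.OH", "C4.OH", "C6.1", "C7.DC", "C9")
  aa <- c("Ala", "Arg", "Asn", "Asp", "Cit", "Gln", "Glu", "Gly", "His",
          "Ile", "Leu", "Lys", "Met", "Orn", "Phe", "Pro", "Ser", "Thr",
          "Trp", "Tyr", "Val")
  ba <- c("total.DMA", "ADMA", "Creatinine", "Kynurenine", "Putrescine",
          "Sarcosine", "Serotonin", "Spermidine", "Spermine", "Taurine",
          "alpha.AAA", "t4.OH.Pro")
  lpc <- c("lysoPC.a.C16.0", "lysoPC.a.C16.1", "lysoPC.a.C17.0",
           "lysoPC.a.C18.0", "lysoPC.a.C18.1", "lysoPC.a.C18.2",
           "lysoPC.a.C20.3", "lysoPC.a.C20.4", "lysoPC.a.C24.0",
           "lysoPC.a.C28.1")
  pc_aa <- c("PC.aa.C30.0", "PC.aa.C32.0", "PC.aa.C32.1", "PC.aa.C32.3",
             "PC.aa.C34.1", "PC.aa.C34.2", "PC.aa.C34.3", "PC.aa.C34.4",
             "PC.aa.C36.0", "PC.aa.C36.1", "PC.aa.C36.2", "PC.aa.C36.3",
             "PC.aa.C36.4", "PC.aa.C36.5", "PC.aa.C36.6", "PC.aa.C38.0",
             "PC.aa.C38.3", "PC.aa.C38.4", "PC.aa.C38.5", "PC.aa.C38.6",
             "PC.aa.C40.2", "PC.aa.C40.4", "PC.aa.C40.5", "PC.aa.C40.6",
             "PC.aa.C42.0", "PC.aa.C42.1", "PC.aa.C42.2", "PC.aa.C42.4",
             "PC.aa.C42.5", "PC.aa.C42.6")
  pc_ae <- c("PC.ae.C30.0", "PC.ae.C32.1", "PC.ae.C32.2", "PC.ae.C34.0",
             "PC.ae.C34.1", "PC.ae.C34.2", "PC.ae.C34.3", "PC.ae.C36.1",
             "PC.ae.C36.2", "PC.ae.C36.3", "PC.ae.C38.3", "PC.ae.C38.5",
             "PC.ae.C38.6", "PC.ae.C40.6", "PC.ae.C42.2", "PC.ae.C42.3",
             "PC.ae.C44.5")
  sm <- c("SM.C16.0", "SM.C16.1", "SM.C18.0", "SM.C18.1", "SM.C24.0",
          "SM.OH.C22.1")
  validate_panel(tibble::tibble(
    analyte_id = c(ac, aa, ba, lpc, pc_aa, pc_ae, sm, "H1"),
    analyte_class = c(rep("acylcarnitine", length(ac)),
                      rep("amino_acid", length(aa)),
                      rep("biogenic_amine", length(ba)),
                      rep("lysoPC", length(lpc)),
                      rep("PC_aa", length(pc_aa)),
                      rep("PC_ae", length(pc_ae)),
                      rep("sphingomyelin", length(sm)),
                      "hexose")
  ))
}

# Class-level baseline log-mean concentrations (log uM), loosely matched to
# typical plasma ranges for each class.
class_log_means <- c(
  acylcarnitine = -1.5, amino_acid = 4.5, biogenic_amine = 0.5,
  lysoPC = 3.0, PC_aa = 3.5, PC_ae = 1.5, sphingomyelin = 4.0, hexose = 8.5
)

#' Default correlation-block layout for [simulation_config()]
#'
#' Three blocks representing lipid co-regulation: a 27-member
#' glycerophospholipid/sphingomyelin module (diacyl PCs, acyl-alkyl PCs,
#' sphingomyelins, which co-vary strongly in plasma), a 6-member lysoPC
#' block and an 8-member acylcarnitine block.  Within-block correlation is
#' 0.78 in controls and 0.88 in cases: with the usual inclusive `r >= 0.8`
#' edge threshold, control correlations sit just below the cut (so the
#' healthy network keeps most block analytes connected through the pairs
#' that fluctuate above it) while case correlations sit above it (so the
#' disease network is wired much denser) — the direction of the
#' disease-vs-healthy topology contrast, with both networks large enough
#' that isolate removal does not degenerate the density comparison.  The
#' planted diagnostic markers are deliberately left out of the blocks so
#' that marker selection and network density are controlled by separate
#' knobs.
#'
#' @param panel A panel tibble, as from [default_panel()].
#' @param r_control,r_case Within-block correlations for each group.
#' @return A list of blocks, each `list(members, r_control, r_case)`.
#' @export
default_blocks <- function(panel = default_panel(),
                           r_control = 0.78, r_case = 0.88) {
  pick <- function(cls, n, exclude = character()) {
    ids <- setdiff(panel$analyte_id[panel$analyte_class == cls], exclude)
    head(ids, n)
  }
  members <- list(
    lipid = c(pick("PC_aa", 12, exclude = "PC.aa.C38.3"),
              pick("PC_ae", 10),
              pick("sphingomyelin", 5)),
    lpc = pick("lysoPC", 6, exclude = "lysoPC.a.C16.0"),
    ac = pick("acylcarnitine", 8)
  )
  purrr::map(members, function(m) {
    list(members = m, r_control = r_control, r_case = r_case)
  })
}

#' Default planted group effects
#'
#' Signed shifts of the case log-mean (in log units) for the three marker
#' analytes: a strong amino-acid marker up and two moderate lipid markers
#' (one down, one up).  With the default per-analyte log-SD of 0.30 the
#' implied single-analyte AUROCs are approximately 0.90 (arginine), 0.80
#' (lysoPC.a.C16.0) and 0.83 (PC.aa.C38.3) — strong enough that the trio is
#' jointly identifiable by penalised screening plus stepwise modelling at
#' cohort sizes of ~140, while keeping the combined panel below the
#' separation regime where joint maximum-likelihood inference degenerates.
#'
#' @return Named numeric vector of log-scale case shifts.
#' @export
default_effects <- function() {
  c(Arg = 0.55, lysoPC.a.C16.0 = -0.36, PC.aa.C38.3 = 0.40)
}

#' Configure a synthetic case-control cohort
#'
#' Describes a two-group cohort with log-normal analyte concentrations:
#' per-sample latent vectors are multivariate normal on the log scale with a
#' group-specific block-correlation matrix, planted effects shift the case
#' log-means, and the result is exponentiated to concentrations in uM.
#'
#' @param n_control,n_case Group sizes (defaults 78 and 64).
#' @param n_case_early Number of cases labelled stage `early`; the remainder
#'   are `advanced`.
#' @param panel Panel tibble (`analyte_id`, `analyte_class`).
#' @param log_mean Optional named numeric vector of per-analyte baseline
#'   log-means; analytes not named fall back to class-level defaults.
#' @param log_sd Per-analyte log-scale standard deviation (scalar or named
#'   vector), default 0.30 (~31% CV, typical of targeted plasma assays).
#' @param effects Named numeric vector of signed case log-mean shifts.
#' @param blocks List of correlation blocks, each
#'   `list(members, r_control, r_case)`; memberships must be disjoint.
#' @param missing_rate Probability a cell is punched out (missing at random),
#'   for exercising the detection filter.  Default 0.
#' @param seed Integer seed; all sampling derives child seeds from it.
#' @return A `plasmanet_sim_config` list.
#' @export
simulation_config <- function(n_control = 78, n_case = 64, n_case_early = 44,
                              panel = default_panel(), log_mean = NULL,
                              log_sd = 0.3, effects = default_effects(),
                              blocks = default_blocks(panel),
                              missing_rate = 0, seed = 1) {
  panel <- validate_panel(panel)
  stopifnot(n_control >= 1, n_case >= 1,
            n_case_early >= 0, n_case_early <= n_case,
            missing_rate >= 0, missing_rate < 1)
  members <- unlist(purrr::map(blocks, "members"))
  if (anyDuplicated(members)) {
    abort("block memberships must be disjoint", class = "plasmanet_config_error")
  }
  unknown <- setdiff(members, panel$analyte_id)
  if (length(unknown) > 0) {
    abort(paste0("block member(s) not in panel: ", paste(unknown, collapse = ", ")),
          class = "plasmanet_config_error")
  }
  for (b in blocks) {
    if (any(c(b$r_control, b$r_case) <= -1) || any(c(b$r_control, b$r_case) >= 1)) {
      abort("block correlations must lie in (-1, 1)",
            class = "plasmanet_config_error")
    }
  }
  unknown_eff <- setdiff(names(effects), panel$analyte_id)
  if (length(unknown_eff) > 0) {
    abort(paste0("effect analyte(s) not in panel: ",
                 paste(unknown_eff, collapse = ", ")),
          class = "plasmanet_config_error")
  }
  structure(
    list(n_control = n_control, n_case = n_case, n_case_early = n_case_early,
         panel = panel, log_mean = log_mean, log_sd = log_sd,
         effects = effects, blocks = blocks, missing_rate = missing_rate,
         seed = as.integer(seed)),
    class = "plasmanet_sim_config"
  )
}

# Assemble the group's log-scale correlation matrix from the block layout and
# verify positive definiteness before any sampling happens.
build_correlation <- function(cfg, group) {
  ids <- cfg$panel$analyte_id
  r <- diag(length(ids))
  dimnames(r) <- list(ids, ids)
  for (b in cfg$blocks) {
    rho <- if (group == "control") b$r_control else b$r_case
    idx <- match(b$members, ids)
    r[idx, idx] <- rho
    diag(r)[idx] <- 1
  }
  ok <- tryCatch({ chol(r); TRUE }, error = function(e) FALSE)
  if (!ok) {
    abort(paste0("block correlation specification for group '", group,
                 "' is not positive definite"),
          class = "plasmanet_config_error")
  }
  r
}

analyte_log_means <- function(cfg) {
  ids <- cfg$panel$analyte_id
  mu <- unname(class_log_means[cfg$panel$analyte_class])
  names(mu) <- ids
  if (!is.null(cfg$log_mean)) {
    mu[names(cfg$log_mean)] <- cfg$log_mean
  }
  mu
}

analyte_log_sds <- function(cfg) {
  ids <- cfg$panel$analyte_id
  s <- rep_len(if (length(cfg$log_sd) == 1) cfg$log_sd else NA_real_, length(ids))
  names(s) <- ids
  if (length(cfg$log_sd) > 1) {
    s[] <- cfg$log_sd[ids]
  }
  stopifnot(all(s > 0))
  s
}

#' Simulate a case-control concentration cohort
#'
#' Draws log-scale latent vectors from the group's block-correlated
#' multivariate normal, adds planted effects to case log-means,
#' exponentiates to concentrations, labels the first `n_case_early` cases
#' `early` and the rest `advanced`, and (optionally) punches missing-at-random
#' holes.  Fully reproducible from the config seed.
#'
#' @param cfg A [simulation_config()].
#' @return A validated cohort tibble (`sample_id`, `group`, `stage`, then one
#'   column per analyte).
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "plasmanet_sim_config"))
  ids <- cfg$panel$analyte_id
  mu <- analyte_log_means(cfg)
  sds <- analyte_log_sds(cfg)
  draw <- function(n, group) {
    r <- build_correlation(cfg, group)
    sigma <- r * tcrossprod(sds)
    m <- mu
    if (group == "case" && length(cfg$effects) > 0) {
      m[names(cfg$effects)] <- m[names(cfg$effects)] + cfg$effects
    }
    set.seed(derive_seed(cfg$seed, paste0("cohort-", group)))
    z <- MASS::mvrnorm(n, mu = m, Sigma = sigma)
    if (n == 1) z <- matrix(z, nrow = 1)
    exp(z)
  }
  ctrl <- draw(cfg$n_control, "control")
  case <- draw(cfg$n_case, "case")
  values <- rbind(ctrl, case)
  colnames(values) <- ids
  out <- tibble::tibble(
    sample_id = c(sprintf("CTRL%03d", seq_len(cfg$n_control)),
                  sprintf("CASE%03d", seq_len(cfg$n_case))),
    group = c(rep("control", cfg$n_control), rep("case", cfg$n_case)),
    stage = c(rep(NA_character_, cfg$n_control),
              rep(c("early", "advanced"),
                  c(cfg$n_case_early, cfg$n_case - cfg$n_case_early)))
  )
  out <- dplyr::bind_cols(out, tibble::as_tibble(values))
  if (cfg$missing_rate > 0) {
    set.seed(derive_seed(cfg$seed, "missing"))
    for (a in ids) {
      holes <- runif(nrow(out)) < cfg$missing_rate
      out[[a]][holes] <- NA_real_
    }
  }
  validate_cohort(out)
}

#' Mean within-block correlation of log-concentrations
#'
#' Generator validation: the mean pairwise Pearson correlation of
#' log-concentrations among the block's members, within one group.
#'
#' @param data A cohort tibble.
#' @param block Character vector of analyte ids (at least two present).
#' @param group `"control"` or `"case"`.
#' @return The mean pairwise correlation (a single number).
#' @export
empirical_block_correlation <- function(data, block, group) {
  if (!group %in% data$group) {
    abort(paste0("group '", group, "' absent from data"))
  }
  block <- intersect(block, cohort_analytes(data))
  if (length(block) < 2) {
    abort("block must have at least two members present in the data")
  }
  rows <- data$group == group
  logs <- log(as.matrix(data[rows, block]))
  r <- cor(logs)
  mean(r[upper.tri(r)])
}

#' Configure a synthetic survival cohort
#'
#' Event times are exponential with hazard
#' `baseline_hazard * exp(log_hazard_ratio_per_sd * z)` where `z` is the
#' z-scored expression of a marker gene; censoring is independent exponential.
#'
#' @param n Number of subjects.
#' @param baseline_hazard Baseline event hazard (per unit time), > 0.
#' @param log_hazard_ratio_per_sd Log hazard ratio per expression SD.
#' @param censoring_rate Exponential censoring hazard, > 0.
#' @param seed Integer seed.
#' @return A `plasmanet_surv_config` list.
#' @export
survival_sim_config <- function(n = 500, baseline_hazard = 0.1,
                                log_hazard_ratio_per_sd = 0.5,
                                censoring_rate = 0.05, seed = 1) {
  stopifnot(n >= 1, baseline_hazard > 0, censoring_rate > 0)
  structure(
    list(n = n, baseline_hazard = baseline_hazard,
         log_hazard_ratio_per_sd = log_hazard_ratio_per_sd,
         censoring_rate = censoring_rate, seed = as.integer(seed)),
    class = "plasmanet_surv_config"
  )
}

#' Simulate a survival cohort
#'
#' @param cfg A [survival_sim_config()].
#' @return Tibble with columns `sample_id`, `time` (positive), `event`
#'   (1 = event observed, 0 = censored) and `expression`.
#' @export
simulate_survival_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "plasmanet_surv_config"))
  set.seed(derive_seed(cfg$seed, "survival"))
  expression <- rnorm(cfg$n)
  z <- as.numeric(scale(expression))
  hazard <- cfg$baseline_hazard * exp(cfg$log_hazard_ratio_per_sd * z)
  t_event <- rexp(cfg$n, rate = hazard)
  t_cens <- rexp(cfg$n, rate = cfg$censoring_rate)
  tibble::tibble(
    sample_id = sprintf("S%04d", seq_len(cfg$n)),
    time = pmin(t_event, t_cens),
    event = as.integer(t_event <= t_cens),
    expression = expression
  )
}
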