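#' Analyte classes of the targeted panel
#'
#' The eight analyte classes covered by the targeted metabolomics kit the
#' pipeline assumes: acylcarnitines, amino acids, biogenic amines,
#' lysophosphatidylcholines, diacyl and acyl-alkyl phosphatidylcholines,
#' sphingomyelins and the hexose sum.
#'
#' @return Character vector of valid `analyte_class` values.
#' @export
analyte_classes <- function() {
  c("acylcarnitine", "amino_acid", "biogenic_amine", "lysoPC",
    "PC_aa", "PC_ae", "sphingomyelin", "hexose")
}

#' Column names reserved for sample metadata in a cohort table
#' @noRd
reserved_columns <- function() c("sample_id", "group", "stage")

#' Analyte columns of a cohort table
#'
#' @param data A cohort tibble (see [read_concentration_table()]).
#' @return Character vector of analyte column names, in table order.
#' @export
cohort_analytes <- function(data) {
  setdiff(names(data), reserved_columns())
}

#' Validate a wide-format concentration table
#'
#' Checks the structural invariants of the pipeline's universal input: unique
#' sample ids, group labels restricted to `control`/`case`, numeric
#' non-negative concentrations (missing allowed), and stage labels
#' (`early`/`advanced`) carried only by cases.
#'
#' @param data A data frame with columns `sample_id`, `group`, optionally
#'   `stage`, then one numeric column per analyte (concentrations in uM).
#' @return The validated data, as a tibble, invisibly usable in a pipe.
#' @export
validate_cohort <- function(data) {
  data <- tibble::as_tibble(data)
  if (!all(c("sample_id", "group") %in% names(data))) {
    abort("cohort table must have 'sample_id' and 'group' columns",
          class = "plasmanet_format_error")
  }
  if (anyDuplicated(data$sample_id)) {
    dup <- unique(data$sample_id[duplicated(data$sample_id)])
    abort(paste0("duplicate sample id(s): ", paste(dup, collapse = ", ")),
          class = "plasmanet_format_error")
  }
  bad_group <- setdiff(unique(data$group), c("control", "case"))
  if (length(bad_group) > 0) {
    abort(paste0("unknown group label(s): ", paste(bad_group, collapse = ", "),
                 " (expected 'control' or 'case')"),
          class = "plasmanet_validation_error")
  }
  if ("stage" %in% names(data)) {
    bad_stage <- setdiff(unique(data$stage[!is.na(data$stage)]),
                         c("early", "advanced"))
    if (length(bad_stage) > 0) {
      abort(paste0("unknown stage label(s): ", paste(bad_stage, collapse = ", ")),
            class = "plasmanet_validation_error")
    }
    if (any(!is.na(data$stage) & data$group == "control")) {
      abort("controls must not carry a stage label",
            class = "plasmanet_validation_error")
    }
  }
  for (a in cohort_analytes(data)) {
    v <- data[[a]]
    if (!is.numeric(v)) {
      abort(paste0("analyte column '", a, "' is not numeric"),
            class = "plasmanet_parse_error")
    }
    if (any(v < 0, na.rm = TRUE)) {
      abort(paste0("negative concentration in analyte '", a, "'"),
            class = "plasmanet_validation_error")
    }
  }
  data
}

#' Read a wide-format concentration table
#'
#' Reads a CSV/TSV whose first column is the sample id, with a reserved
#' `group` column (values `control`/`case`), an optional reserved `stage`
#' column (`early`/`advanced`, cases only), and one column per analyte
#' holding concentrations in uM.  Empty cells are missing values.  Analyte
#' order from the header is preserved.
#'
#' @param path Path to the file.
#' @param format `"csv"` or `"tsv"`.
#' @return A validated cohort tibble.
#' @seealso [write_concentration_table()], [filter_detected()]
#' @export
read_concentration_table <- function(path, format = c("csv", "tsv")) {
  format <- match.arg(format)
  delim <- if (format == "csv") "," else "\t"
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(
    .default = readr::col_character()
  ), na = c("", "NA"), progress = FALSE)
  if (names(raw)[1] != "sample_id") {
    names(raw)[1] <- "sample_id"
  }
  analytes <- setdiff(names(raw), reserved_columns())
  for (a in analytes) {
    v <- raw[[a]]
    num <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & is.na(num))
    if (length(bad) > 0) {
      abort(paste0("non-numeric concentration '", v[bad[1]], "' at row ",
                   bad[1], ", column '", a, "'"),
            class = "plasmanet_parse_error")
    }
    raw[[a]] <- num
  }
  validate_cohort(raw)
}

#' Write a cohort table to CSV/TSV
#'
#' Inverse of [read_concentration_table()]: round-tripping a valid table
#' reproduces it up to floating-point formatting.
#'
#' @param data A cohort tibble.
#' @param path Output path.
#' @param format `"csv"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_concentration_table <- function(data, path, format = c("csv", "tsv")) {
  format <- match.arg(format)
  data <- validate_cohort(data)
  if (format == "csv") {
    readr::write_csv(data, path, na = "")
  } else {
    readr::write_tsv(data, path, na = "")
  }
  invisible(path)
}

#' Read an analyte panel annotation
#'
#' Two-column CSV mapping each analyte id to one of the eight panel classes
#' (see [analyte_classes()]).
#'
#' @param path Path to the CSV.
#' @return Tibble with columns `analyte_id`, `analyte_class`.
#' @export
read_analyte_panel <- function(path) {
  panel <- readr::read_csv(path, col_types = "cc", progress = FALSE)
  names(panel)[1:2] <- c("analyte_id", "analyte_class")
  validate_panel(panel)
}

#' Validate an analyte panel annotation
#'
#' @param panel Data frame with columns `analyte_id`, `analyte_class`.
#' @return The validated panel tibble.
#' @export
validate_panel <- function(panel) {
  panel <- tibble::as_tibble(panel)
  if (anyDuplicated(panel$analyte_id)) {
    abort("duplicate analyte ids in panel", class = "plasmanet_format_error")
  }
  bad <- setdiff(unique(panel$analyte_class), analyte_classes())
  if (length(bad) > 0) {
    abort(paste0("unknown analyte class(es): ", paste(bad, collapse = ", ")),
          class = "plasmanet_validation_error")
  }
  panel
}

#' Filter analytes by detection rate and impute residual missingness
#'
#' An analyte is retained when its missing (below-detection) fraction does not
#' exceed `max_missing_fraction`; the default 20% rule is a standard targeted
#' metabolomics convention.  Remaining missing cells of retained analytes are
#' imputed at half the analyte's observed minimum (the usual stand-in for a
#' value below the limit of detection).  An entirely missing analyte is always
#' dropped, since no imputable minimum exists.  The returned table therefore
#' contains no missing values, and the operation is idempotent.
#'
#' @param data A cohort tibble.
#' @param max_missing_fraction Maximum tolerated missing fraction in `[0, 1]`.
#' @return The filtered, imputed cohort tibble.  The per-analyte report is
#'   attached as attribute `"detection"` and retrievable with
#'   [detection_report()].
#' @export
filter_detected <- function(data, max_missing_fraction = 0.2) {
  stopifnot(is.numeric(max_missing_fraction),
            max_missing_fraction >= 0, max_missing_fraction <= 1)
  data <- validate_cohort(data)
  analytes <- cohort_analytes(data)
  n <- nrow(data)
  report <- purrr::map_dfr(analytes, function(a) {
    miss <- sum(is.na(data[[a]])) / n
    tibble::tibble(
      analyte_id = a,
      missing_fraction = miss,
      retained = miss <= max_missing_fraction && miss < 1
    )
  })
  keep <- report$analyte_id[report$retained]
  out <- data[, c(intersect(reserved_columns(), names(data)), keep)]
  for (a in keep) {
    v <- out[[a]]
    if (anyNA(v)) {
      v[is.na(v)] <- min(v, na.rm = TRUE) / 2
      out[[a]] <- v
    }
  }
  attr(out, "detection") <- report
  out
}

#' Retrieve the detection-filter report
#'
#' @param data A cohort tibble returned by [filter_detected()].
#' @return Tibble with columns `analyte_id`, `missing_fraction`, `retained`.
#' @export
detection_report <- function(data) {
  rep <- attr(data, "detection")
  if (is.null(rep)) {
    abort("no detection report attached; run filter_detected() first")
  }
  rep
}
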