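#' Construct an IPD table
#'
#' Assembles patient-level records from multiple randomized trials into the
#' tabular container used by every other function in the package: one row per
#' patient, a study label, a treatment label, a binary outcome, and numeric
#' covariate columns. Categorical covariates are expanded into indicator
#' columns deterministically (levels in alphabetical order, the first level
#' as the baseline), so the same input always yields the same design.
#'
#' @param data A data frame with one row per patient.
#' @param study,treatment,outcome Names (strings) of the study, treatment and
#'   outcome columns in `data`. The outcome must contain only 0, 1 or `NA`.
#' @param covariates Character vector of covariate column names. Defaults to
#'   every column other than study, treatment and outcome.
#' @param reference Label of the overall reference treatment (e.g. the
#'   placebo arm). Defaults to the alphabetically first treatment label.
#' @param external Set `TRUE` for an external single-arm anchoring dataset
#'   (e.g. pooled placebo arms); this relaxes the requirement that every
#'   study randomizes at least two treatments.
#' @param transforms Optional named list mapping covariate names to `"log"`
#'   or `"identity"`; `"log"` covariates are log-transformed (values must be
#'   positive). Nothing is transformed automatically.
#' @return A tibble of class `ipd_tbl` with columns `study`, `treatment`,
#'   `outcome` and one numeric column per (expanded) covariate. Metadata is
#'   kept in attributes; see [ipd_covariates()], [ipd_reference()].
#' @seealso [read_ipd()] to build one directly from a CSV file,
#'   [filter_missing()], [prune_correlated()], [complete_case()].
#' @examples
#' df <- data.frame(study = "s1", trt = c("A", "B", "A"),
#'                  y = c(0, 1, 1), age = c(40, 52, 61))
#' ipd_table(df, study = "study", treatment = "trt", outcome = "y")
#' @export
ipd_table <- function(data, study = "study", treatment = "treatment",
                      outcome = "outcome", covariates = NULL,
                      reference = NULL, external = FALSE,
                      transforms = NULL) {
  stopifnot(is.data.frame(data))
  need <- c(study, treatment, outcome)
  miss <- setdiff(need, names(data))
  if (length(miss) > 0) {
    abort_ipdnmr(paste0("Required column(s) not found: ",
                        paste(miss, collapse = ", ")),
                 "ipdnmr_missing_column")
  }
  covariates <- covariates %||% setdiff(names(data), need)
  miss <- setdiff(covariates, names(data))
  if (length(miss) > 0) {
    abort_ipdnmr(paste0("Covariate column(s) not found: ",
                        paste(miss, collapse = ", ")),
                 "ipdnmr_missing_column")
  }

  y <- data[[outcome]]
  if (is.logical(y)) y <- as.numeric(y)
  y_num <- suppressWarnings(as.numeric(y))
  bad <- !is.na(y_num) & !(y_num %in% c(0, 1))
  if (any(bad) || (any(!is.na(y)) && all(is.na(y_num[!is.na(y)])))) {
    abort_ipdnmr("Outcome must be binary (0/1, NA allowed before filtering).",
                 "ipdnmr_outcome_domain")
  }

  out <- tibble::tibble(
    study = as.character(data[[study]]),
    treatment = as.character(data[[treatment]]),
    outcome = y_num
  )

  for (cv in covariates) {
    col <- data[[cv]]
    tr <- transforms[[cv]] %||% "identity"
    if (is.numeric(col) || is.logical(col)) {
      col <- as.numeric(col)
      if (identical(tr, "log")) {
        if (any(col <= 0, na.rm = TRUE)) {
          abort_ipdnmr(paste0("log transform requires positive values: ", cv),
                       "ipdnmr_transform")
        }
        col <- log(col)
      }
      out[[cv]] <- col
    } else {
      # indicator expansion, alphabetical levels, first level as baseline
      lev <- sort(unique(as.character(col[!is.na(col)])))
      if (length(lev) < 2) {
        out[[cv]] <- ifelse(is.na(col), NA_real_, 0)
        next
      }
      for (l in lev[-1]) {
        out[[paste0(cv, "_", l)]] <- ifelse(is.na(col), NA_real_,
                                            as.numeric(col == l))
      }
    }
  }

  reference <- reference %||% sort(unique(out$treatment))[1]
  if (!reference %in% out$treatment && !external) {
    abort_ipdnmr(paste0("Reference treatment '", reference,
                        "' not present in the data."),
                 "ipdnmr_reference")
  }

  if (!external) {
    n_arms <- tapply(out$treatment, out$study, function(t) length(unique(t)))
    if (any(n_arms < 2)) {
      abort_ipdnmr(paste0("Every study must randomize >= 2 treatments ",
                          "(use external = TRUE for single-arm reference data): ",
                          paste(names(n_arms)[n_arms < 2], collapse = ", ")),
                   "ipdnmr_single_arm")
    }
  }

  new_ipd_tbl(out,
              covariates = setdiff(names(out), c("study", "treatment", "outcome")),
              reference = reference,
              external = external,
              preprocess = list())
}

new_ipd_tbl <- function(data, covariates, reference, external = FALSE,
                        preprocess = list()) {
  out <- tibble::as_tibble(data)
  attr(out, "covariates") <- covariates
  attr(out, "reference") <- reference
  attr(out, "external") <- external
  attr(out, "preprocess") <- preprocess
  class(out) <- c("ipd_tbl", class(tibble::tibble()))
  out
}

# carry ipd metadata from `from` onto plain tibble `data`
restore_ipd <- function(data, from, covariates = NULL, extra_report = NULL) {
  pp <- attr(from, "preprocess") %||% list()
  if (!is.null(extra_report)) pp <- c(pp, list(extra_report))
  new_ipd_tbl(data,
              covariates = covariates %||% attr(from, "covariates"),
              reference = attr(from, "reference"),
              external = attr(from, "external") %||% FALSE,
              preprocess = pp)
}

#' IPD table metadata accessors
#'
#' @param x An `ipd_tbl` created by [ipd_table()] or [read_ipd()].
#' @return `ipd_covariates()`: character vector of covariate column names;
#'   `ipd_reference()`: the overall reference treatment label.
#' @export
ipd_covariates <- function(x) attr(x, "covariates")

#' @rdname ipd_covariates
#' @export
ipd_reference <- function(x) attr(x, "reference")

#' Read an IPD table from a delimited file
#'
#' Reads a CSV file with a header row and applies the column-role
#' configuration to produce an [ipd_table()]. The configuration can be a
#' list or a path to a JSON/YAML file with fields `study`, `treatment`,
#' `outcome`, and optionally `covariates`, `reference`, `external`,
#' `transforms` and `treatments` (the admissible treatment labels; labels in
#' the file but absent from this set raise an error).
#'
#' @param path Path to a delimited text file with a header.
#' @param config Column-role configuration (list, or path to JSON/YAML).
#' @param sep Field separator, default comma.
#' @return An `ipd_tbl`; see [ipd_table()].
#' @export
read_ipd <- function(path, config, sep = ",") {
  config <- load_config(config)
  raw <- utils::read.csv(path, sep = sep, stringsAsFactors = FALSE,
                         check.names = FALSE)
  if (!is.null(config$treatments)) {
    extra <- setdiff(unique(as.character(raw[[config$treatment]])),
                     config$treatments)
    if (length(extra) > 0) {
      abort_ipdnmr(paste0("Treatment label(s) absent from config's treatment ",
                          "set: ", paste(extra, collapse = ", ")),
                   "ipdnmr_treatment_set")
    }
  }
  ipd_table(raw,
            study = config$study %||% "study",
            treatment = config$treatment %||% "treatment",
            outcome = config$outcome %||% "outcome",
            covariates = config$covariates,
            reference = config$reference,
            external = isTRUE(config$external),
            transforms = config$transforms)
}

load_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (grepl("\\.json$", config, ignore.case = TRUE)) {
      config <- jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      config <- yaml::read_yaml(config)
    }
  }
  stopifnot(is.list(config))
  config
}

#' @export
`[.ipd_tbl` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out)) {
    out <- restore_ipd(out, x,
                       covariates = intersect(attr(x, "covariates"),
                                              names(out)))
  }
  out
}

#' @export
print.ipd_tbl <- function(x, ...) {
  cat("<IPD table> ", nrow(x), " patients, ",
      length(unique(x$study)), " studies, ",
      length(unique(x$treatment)), " treatments (reference: ",
      ipd_reference(x), ")\n", sep = "")
  NextMethod()
}
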