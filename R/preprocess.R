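#' Pre-modeling filters for IPD tables
#'
#' Three filters applied, in order, before any risk model is fitted:
#'
#' * `filter_missing()` drops covariates whose missing fraction strictly
#'   exceeds `max_missing` (default 50%).
#' * `prune_correlated()` resolves highly correlated covariate pairs
#'   (absolute Pearson correlation strictly above `threshold`, default 0.7)
#'   by keeping the covariate that appears earlier in `keep_priority` —
#'   a stand-in for subject-matter judgement about which of two collinear
#'   variables is the more plausible prognostic factor.
#' * `complete_case()` drops every record with a missing covariate or
#'   outcome value, assuming missingness is unrelated to the outcome risk.
#'
#' Each filter records what it removed; retrieve the accumulated log with
#' [preprocess_report()]. `preprocess_ipd()` chains all three.
#'
#' @param data An `ipd_tbl` (see [ipd_table()]).
#' @param max_missing Missing-fraction threshold; covariates with a missing
#'   fraction strictly greater than this are dropped.
#' @param threshold Absolute Pearson correlation above which (strictly) one
#'   covariate of a pair is dropped.
#' @param keep_priority Character vector ordering covariates from most to
#'   least preferred; defaults to the table's column order. Must cover every
#'   covariate involved in a flagged pair.
#' @return The filtered `ipd_tbl` with an updated preprocess log.
#' @examples
#' df <- data.frame(study = rep(c("s1", "s2"), each = 4),
#'                  treatment = rep(c("A", "B"), 4),
#'                  outcome = rep(c(0, 1), 4),
#'                  age = c(NA, NA, NA, 50, 41, 39, 62, 55),
#'                  bmi = c(24, 27, NA, 22, 25, 28, 21, 26))
#' tbl <- ipd_table(df)
#' tbl |> filter_missing() |> complete_case() |> preprocess_report()
#' @export
filter_missing <- function(data, max_missing = 0.5) {
  stopifnot(inherits(data, "ipd_tbl"))
  covs <- ipd_covariates(data)
  if (length(covs) == 0) return(data)
  frac <- vapply(covs, function(cv) mean(is.na(data[[cv]])), numeric(1))
  drop <- covs[frac > max_missing]
  report <- list(step = "filter_missing",
                 max_missing = max_missing,
                 dropped_missing = as.list(stats::setNames(frac[drop], drop)))
  kept <- setdiff(covs, drop)
  out <- data[, c("study", "treatment", "outcome", kept)]
  restore_ipd(out, data, covariates = kept, extra_report = report)
}

#' @rdname filter_missing
#' @export
prune_correlated <- function(data, threshold = 0.7, keep_priority = NULL) {
  stopifnot(inherits(data, "ipd_tbl"))
  covs <- ipd_covariates(data)
  keep_priority <- keep_priority %||% covs
  dropped <- character(0)
  triples <- list()
  # priority order: examine most-preferred covariates first and drop the
  # lower-priority member of every flagged pair
  ordered <- c(intersect(keep_priority, covs), setdiff(covs, keep_priority))
  for (i in seq_along(ordered)) {
    a <- ordered[i]
    if (a %in% dropped) next
    for (b in ordered[-seq_len(i)]) {
      if (b %in% dropped) next
      r <- suppressWarnings(
        stats::cor(data[[a]], data[[b]], use = "pairwise.complete.obs"))
      if (!is.na(r) && abs(r) > threshold) {
        if (!(a %in% keep_priority) || !(b %in% keep_priority)) {
          abort_ipdnmr(paste0("keep_priority omits a covariate in the ",
                              "correlated pair (", a, ", ", b, ")."),
                       "ipdnmr_keep_priority")
        }
        dropped <- c(dropped, b)
        triples <- c(triples, list(list(kept = a, dropped = b,
                                        correlation = unname(r))))
      }
    }
  }
  report <- list(step = "prune_correlated", threshold = threshold,
                 dropped_correlated = triples)
  kept <- setdiff(covs, dropped)
  out <- data[, c("study", "treatment", "outcome", kept)]
  restore_ipd(out, data, covariates = kept, extra_report = report)
}

#' @rdname filter_missing
#' @export
complete_case <- function(data) {
  stopifnot(inherits(data, "ipd_tbl"))
  covs <- ipd_covariates(data)
  keep <- stats::complete.cases(data[, c("outcome", covs)])
  if (!any(keep)) {
    abort_ipdnmr("No complete-case records remain.", "ipdnmr_empty")
  }
  report <- list(step = "complete_case",
                 n_before = nrow(data), n_after = sum(keep))
  restore_ipd(data[keep, ], data, extra_report = report)
}

#' @rdname filter_missing
#' @export
preprocess_ipd <- function(data, max_missing = 0.5, threshold = 0.7,
                           keep_priority = NULL) {
  data |>
    filter_missing(max_missing = max_missing) |>
    prune_correlated(threshold = threshold, keep_priority = keep_priority) |>
    complete_case()
}

#' Retrieve the preprocessing report
#'
#' @param data An `ipd_tbl` that has passed through one or more of the
#'   filters documented at [filter_missing()].
#' @return A list of class `preprocess_report`, one element per filter step,
#'   serializable with [jsonlite::toJSON()].
#' @export
preprocess_report <- function(data) {
  structure(attr(data, "preprocess") %||% list(), class = "preprocess_report")
}

#' @export
print.preprocess_report <- function(x, ...) {
  cat("<preprocess report>\n")
  for (step in x) {
    cat("*", step$step, "\n")
    if (!is.null(step$dropped_missing) && length(step$dropped_missing)) {
      for (nm in names(step$dropped_missing)) {
        cat("    dropped", nm, sprintf("(%.0f%% missing)\n",
                                       100 * step$dropped_missing[[nm]]))
      }
    }
    if (!is.null(step$dropped_correlated)) {
      for (tr in step$dropped_correlated) {
        cat(sprintf("    dropped %s (r = %.2f with %s)\n",
                    tr$dropped, tr$correlation, tr$kept))
      }
    }
    if (!is.null(step$n_before)) {
      cat("    records:", step$n_before, "->", step$n_after, "\n")
    }
  }
  invisible(x)
}
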