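#' Events per variable
#'
#' Number of outcome events per candidate model degree of freedom, the
#' classical quick check of whether a dataset can support a logistic
#' prediction model of a given complexity. Categorical covariates and
#' nonlinear terms count with all their degrees of freedom.
#'
#' @param events Number of outcome events.
#' @param model_df Candidate model degrees of freedom (must be >= 1).
#' @return Events per variable, reported to one decimal.
#' @examples
#' compute_epv(742, 45) # 16.5
#' compute_epv(742, 14) # 53
#' @export
compute_epv <- function(events, model_df) {
  stopifnot(events >= 0)
  if (model_df < 1) {
    abort_ipdnmr("model_df must be >= 1.", "ipdnmr_epv_df")
  }
  round(events / model_df, 1)
}

#' Minimum sample size for developing a binary-outcome risk model
#'
#' Implements the three sample-size criteria of Riley and colleagues for a
#' new logistic prediction model:
#'
#' 1. global shrinkage of predictor effects of at least `shrinkage` (S):
#'    `n1 = ceiling(P / ((S - 1) * log(1 - R2cs / S)))`;
#' 2. at most a small (0.05) absolute optimism in apparent model fit,
#'    obtained by substituting `S2 = R2cs / (R2cs + 0.05 * maxR2cs)` into the
#'    criterion-1 formula, where `maxR2cs = 1 - exp(2 * lnull)` is the largest
#'    attainable Cox-Snell R-squared at the outcome prevalence;
#' 3. precise estimation of the intercept / overall risk:
#'    `n3 = ceiling((1.96 / intercept_margin)^2 * phi * (1 - phi))`.
#'
#' The required size is the maximum of the three. The anticipated model fit
#' can be supplied either as a Cox-Snell R-squared (`r2_cs`) or as a
#' Nagelkerke R-squared (`r2_nagelkerke`), which is converted internally via
#' `r2_cs = r2_nagelkerke * maxR2cs`; prediction studies usually report
#' Nagelkerke values, and the conversion depends on the prevalence.
#'
#' @param model_df Number of candidate model parameters P.
#' @param prevalence Anticipated outcome prevalence (events / n).
#' @param r2_cs Anticipated Cox-Snell R-squared (0 < r2_cs < shrinkage).
#' @param r2_nagelkerke Alternative to `r2_cs`: anticipated Nagelkerke
#'   R-squared, converted internally.
#' @param shrinkage Target expected shrinkage factor S, default 0.9.
#' @param intercept_margin Absolute error margin for the intercept criterion,
#'   default 0.05 (with z = 1.96).
#' @return A list of class `sample_size_report` with per-criterion sizes,
#'   `n_required`, the implied events `n_events = ceiling(n_required *
#'   prevalence)` and `epv` at the required size.
#' @examples
#' # a 45-parameter model at prevalence 742/2000 and Nagelkerke R2 = 0.15
#' riley_min_n(45, prevalence = 742 / 2000, r2_nagelkerke = 0.15)
#' @export
riley_min_n <- function(model_df, prevalence, r2_cs = NULL,
                        r2_nagelkerke = NULL, shrinkage = 0.9,
                        intercept_margin = 0.05) {
  stopifnot(model_df >= 1, prevalence > 0, prevalence < 1,
            shrinkage > 0, shrinkage < 1)
  lnull <- prevalence * log(prevalence) + (1 - prevalence) * log(1 - prevalence)
  max_r2cs <- 1 - exp(2 * lnull)
  if (is.null(r2_cs)) {
    if (is.null(r2_nagelkerke)) {
      abort_ipdnmr("Supply r2_cs or r2_nagelkerke.", "ipdnmr_riley_r2")
    }
    stopifnot(r2_nagelkerke > 0, r2_nagelkerke < 1)
    r2_cs <- r2_nagelkerke * max_r2cs
  }
  if (r2_cs <= 0 || r2_cs >= shrinkage) {
    abort_ipdnmr("Need 0 < r2_cs < shrinkage.", "ipdnmr_riley_r2")
  }

  crit_n <- function(P, S) ceiling(P / ((S - 1) * log(1 - r2_cs / S)))
  n1 <- crit_n(model_df, shrinkage)
  s2 <- r2_cs / (r2_cs + 0.05 * max_r2cs)
  n2 <- crit_n(model_df, s2)
  n3 <- ceiling((1.96 / intercept_margin)^2 * prevalence * (1 - prevalence))
  n_required <- max(n1, n2, n3)
  events <- ceiling(n_required * prevalence)

  structure(list(
    model_df = model_df,
    prevalence = prevalence,
    r2_cs = r2_cs,
    max_r2cs = max_r2cs,
    shrinkage = shrinkage,
    intercept_margin = intercept_margin,
    criterion_values = c(shrinkage = n1, optimism = n2, intercept = n3),
    n_required = n_required,
    n_events = events,
    epv = compute_epv(events, model_df)
  ), class = "sample_size_report")
}

#' @export
print.sample_size_report <- function(x, ...) {
  cat("<minimum sample size for a binary-outcome prediction model>\n")
  cat(sprintf("  parameters P = %d, prevalence = %.3f, Cox-Snell R2 = %.4f, S = %.2f\n",
              x$model_df, x$prevalence, x$r2_cs, x$shrinkage))
  cat(sprintf("  criterion sizes: shrinkage %d | optimism %d | intercept %d\n",
              x$criterion_values[["shrinkage"]], x$criterion_values[["optimism"]],
              x$criterion_values[["intercept"]]))
  cat(sprintf("  required: n = %d (%d events, EPV %.1f)\n",
              x$n_required, x$n_events, x$epv))
  invisible(x)
}

#' @method glance sample_size_report
#' @export
glance.sample_size_report <- function(x, ...) {
  tibble::tibble(model_df = x$model_df, prevalence = x$prevalence,
                 r2_cs = x$r2_cs, shrinkage = x$shrinkage,
                 n_required = x$n_required, n_events = x$n_events,
                 epv = x$epv)
}
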