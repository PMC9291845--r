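#' Concordance statistic (c-statistic / AUC)
#'
#' Probability that a randomly chosen patient who experienced the event has
#' a higher score than a randomly chosen patient who did not, with ties
#' counting one half. Computed from the rank (Wilcoxon) representation, so
#' it is invariant to any strictly increasing transform of the scores.
#'
#' @param scores Numeric predictions (risks, logits, or any monotone score).
#' @param outcomes Binary outcomes (0/1), same length.
#' @return The c-statistic in \[0, 1\].
#' @examples
#' c_statistic(c(0.2, 0.4, 0.6, 0.8), c(0, 0, 1, 1)) # 1
#' @export
c_statistic <- function(scores, outcomes) {
  stopifnot(length(scores) == length(outcomes),
            all(outcomes %in% c(0, 1)))
  n1 <- sum(outcomes == 1)
  n0 <- sum(outcomes == 0)
  if (n1 == 0 || n0 == 0) {
    abort_ipdnmr("Both outcome classes are required.", "ipdnmr_single_class")
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[outcomes == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Calibration slope
#'
#' Slope from a logistic regression of the observed outcomes on the
#' predicted logits, with a free intercept. A slope of 1 indicates
#' well-scaled predictions; below 1 indicates overfitting (predictions too
#' extreme), above 1 over-shrunk predictions.
#'
#' @param logit_scores Predicted logits (finite).
#' @param outcomes Binary outcomes (0/1).
#' @return The calibration slope; `Inf` with a warning under separation.
#' @export
calibration_slope <- function(logit_scores, outcomes) {
  stopifnot(length(logit_scores) == length(outcomes),
            all(is.finite(logit_scores)), all(outcomes %in% c(0, 1)))
  if (length(unique(outcomes)) < 2) {
    abort_ipdnmr("Both outcome classes are required.", "ipdnmr_single_class")
  }
  if (stats::sd(logit_scores) == 0) return(NA_real_)
  fit <- suppressWarnings(
    stats::glm(outcomes ~ logit_scores, family = stats::binomial()))
  slope <- unname(stats::coef(fit)[2])
  if (!fit$converged || abs(slope) > 100) {
    warning("Separation in the calibration model; slope reported as Inf.")
    return(sign(slope) * Inf)
  }
  slope
}

#' Bootstrap optimism-corrected internal validation
#'
#' Internal validation of a stage-1 risk model by the bootstrap: the entire
#' model-building procedure (including any variable selection) is rerun on
#' each of `B` bootstrap resamples of the patients, each bootstrap model is
#' evaluated both on its own bootstrap sample and on the original sample,
#' and the average difference is the optimism. Corrected performance is the
#' apparent performance of the final model minus the optimism, for both the
#' c-statistic and the calibration slope. Rerunning the selection inside
#' every resample is what keeps the optimism estimate honest.
#'
#' Bootstrap samples in which the outcome is single-class (or on which the
#' fitter fails) are redrawn, up to 10 attempts each, so `B` stays fixed.
#' Resampling is at the patient level, ignoring study membership.
#'
#' @param data A complete-case `ipd_tbl`.
#' @param fitter Function `data -> risk_fit` encapsulating the full pipeline
#'   (selection and estimation), e.g.
#'   `function(d) fit_lasso(d, seed = 1)`.
#' @param B Number of bootstrap resamples (default 500).
#' @param seed Integer seed; the same seed gives an identical report.
#' @return A list of class `validation_report` with apparent, optimism and
#'   corrected c-statistic and calibration slope.
#' @export
bootstrap_validate <- function(data, fitter, B = 500, seed = 1) {
  stopifnot(inherits(data, "ipd_tbl"), is.function(fitter), B >= 1)
  apparent_fit <- fitter(data)
  orig_scores <- score(data, apparent_fit)
  apparent_c <- c_statistic(orig_scores$logit_risk, data$outcome)
  apparent_slope <- calibration_slope(orig_scores$logit_risk, data$outcome)

  set.seed(seed)
  n <- nrow(data)
  opt_c <- numeric(B)
  opt_slope <- numeric(B)
  redraws <- 0L
  for (b in seq_len(B)) {
    done <- FALSE
    for (attempt in 1:10) {
      idx <- sample.int(n, n, replace = TRUE)
      boot <- restore_ipd(data[idx, ], data)
      if (length(unique(boot$outcome)) < 2) { redraws <- redraws + 1L; next }
      bfit <- tryCatch(fitter(boot), error = function(e) NULL)
      if (is.null(bfit)) { redraws <- redraws + 1L; next }
      s_boot <- score(boot, bfit)
      s_orig <- score(data, bfit)
      opt_c[b] <- c_statistic(s_boot$logit_risk, boot$outcome) -
        c_statistic(s_orig$logit_risk, data$outcome)
      opt_slope[b] <- calibration_slope(s_boot$logit_risk, boot$outcome) -
        calibration_slope(s_orig$logit_risk, data$outcome)
      done <- TRUE
      break
    }
    if (!done) {
      abort_ipdnmr("Could not draw a usable bootstrap sample in 10 attempts.",
                   "ipdnmr_bootstrap")
    }
  }

  optimism_c <- mean(opt_c)
  optimism_slope <- mean(opt_slope)
  structure(list(
    apparent_c = apparent_c,
    apparent_slope = apparent_slope,
    optimism_c = optimism_c,
    optimism_slope = optimism_slope,
    corrected_c = apparent_c - optimism_c,
    corrected_slope = apparent_slope - optimism_slope,
    n_bootstrap = B,
    n_redraws = redraws,
    seed = seed
  ), class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<internal validation>", x$n_bootstrap, "bootstrap resamples\n")
  cat(sprintf("  c-statistic      : apparent %.3f | optimism %.3f | corrected %.3f\n",
              x$apparent_c, x$optimism_c, x$corrected_c))
  cat(sprintf("  calibration slope: apparent %.3f | optimism %.3f | corrected %.3f\n",
              x$apparent_slope, x$optimism_slope, x$corrected_slope))
  invisible(x)
}

#' @method glance validation_report
#' @export
glance.validation_report <- function(x, ...) {
  tibble::tibble(apparent_c = x$apparent_c, optimism_c = x$optimism_c,
                 corrected_c = x$corrected_c,
                 apparent_slope = x$apparent_slope,
                 optimism_slope = x$optimism_slope,
                 corrected_slope = x$corrected_slope,
                 n_bootstrap = x$n_bootstrap, seed = x$seed)
}
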