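#' Estimate the reference-treatment anchor for absolute predictions
#'
#' Absolute risk predictions for new patients are anchored on a reference
#' population treated with the reference treatment (e.g. pooled placebo
#' arms): `alpha` is the logit outcome probability of a patient on the
#' reference treatment whose baseline risk score equals the population mean,
#' and `mean_logit_risk` is that population mean. `alpha` is the intercept
#' of a logistic regression of the outcomes on the centered logit risk in
#' the anchoring population.
#'
#' @param data An `ipd_tbl` containing only reference-treatment patients
#'   (e.g. read with `external = TRUE`).
#' @param scores A `risk_scores` tibble for the same patients (or a numeric
#'   vector of logit risks).
#' @param source Free-text description of the anchoring population, stored
#'   for the record.
#' @return A list of class `reference_anchor` with `alpha`,
#'   `mean_logit_risk` and `source`.
#' @export
estimate_anchor <- function(data, scores, source = "reference arms") {
  stopifnot(inherits(data, "ipd_tbl"))
  if (nrow(data) == 0) abort_ipdnmr("Empty anchoring table.", "ipdnmr_empty")
  bad <- setdiff(unique(data$treatment), ipd_reference(data))
  if (length(bad) > 0) {
    abort_ipdnmr(paste0("Anchoring table must contain only the reference ",
                        "treatment; found: ", paste(bad, collapse = ", ")),
                 "ipdnmr_reference")
  }
  lp <- if (inherits(scores, "risk_scores")) scores$logit_risk else as.numeric(scores)
  stopifnot(length(lp) == nrow(data))
  y <- data$outcome
  if (anyNA(y) || anyNA(lp)) {
    abort_ipdnmr("Outcomes and scores must be complete.", "ipdnmr_incomplete")
  }
  if (length(unique(y)) < 2) {
    abort_ipdnmr("Anchoring outcomes are single-class.", "ipdnmr_single_class")
  }
  mean_lp <- mean(lp)
  cc <- lp - mean_lp
  alpha <- if (stats::sd(cc) == 0) {
    logit(mean(y))
  } else {
    unname(stats::coef(stats::glm(y ~ cc, family = stats::binomial()))[1])
  }
  structure(list(alpha = alpha, mean_logit_risk = mean_lp, source = source),
            class = "reference_anchor")
}

#' @export
print.reference_anchor <- function(x, ...) {
  cat(sprintf("<reference anchor> alpha = %.4f (risk %.3f at mean logit risk %.4f)\n",
              x$alpha, inv_logit(x$alpha), x$mean_logit_risk))
  cat("  source:", x$source, "\n")
  invisible(x)
}

#' Predict a new patient's absolute outcome risk under each treatment
#'
#' For a new patient with stage-1 logit risk `logit_risk` and a candidate
#' treatment, every posterior draw gives
#' `logit(p) = alpha + delta_t + (gamma0 + gamma_t) * (logit_risk -
#' mean_logit_risk)`, with `delta_ref = gamma_ref = 0` on the reference
#' treatment. The anchor is treated as a fixed plug-in. Returns the
#' posterior mean and central 95% credible interval of `p`.
#'
#' @param logit_risk Numeric vector of stage-1 logit baseline risks.
#' @param treatment Treatment label(s), recycled against `logit_risk`.
#' @param anchor A [estimate_anchor()] result (or a list with `alpha` and
#'   `mean_logit_risk`).
#' @param posterior An `nmr_fit` or [nmr_posterior()].
#' @return A tibble with one row per patient-treatment combination:
#'   `treatment`, `logit_risk`, `risk` (the baseline risk), `estimate`,
#'   `conf.low`, `conf.high`.
#' @examples
#' post <- nmr_posterior(
#'   data.frame(`delta[N]` = -1.22, gamma0 = 1.26, `gamma[N]` = -0.26,
#'              check.names = FALSE),
#'   treatments = c("Placebo", "N"), reference = "Placebo")
#' anchor <- list(alpha = logit(0.37), mean_logit_risk = 0)
#' predict_patient(0, "N", anchor, post) # risk 0.1478
#' @export
predict_patient <- function(logit_risk, treatment, anchor, posterior) {
  stopifnot(inherits(posterior, "nmr_fit"))
  grid <- tibble::tibble(logit_risk = logit_risk, treatment = treatment)
  unknown <- setdiff(unique(grid$treatment), posterior$treatments)
  if (length(unknown) > 0) {
    abort_ipdnmr(paste0("Unknown treatment label(s): ",
                        paste(unknown, collapse = ", ")),
                 "ipdnmr_treatment")
  }
  draws <- patient_prob_draws(grid$logit_risk, grid$treatment, anchor, posterior)
  grid$risk <- inv_logit(grid$logit_risk)
  grid$estimate <- colMeans(draws)
  grid$conf.low <- apply(draws, 2, stats::quantile, 0.025)
  grid$conf.high <- apply(draws, 2, stats::quantile, 0.975)
  grid
}

# draws x patients matrix of predicted probabilities
patient_prob_draws <- function(logit_risk, treatment, anchor, posterior) {
  d <- posterior$draws
  ndraw <- nrow(d)
  zeros <- rep(0, ndraw)
  col_or_zero <- function(col) if (col %in% names(d)) d[[col]] else zeros
  cc <- logit_risk - anchor$mean_logit_risk
  g0 <- col_or_zero("gamma0")
  out <- matrix(NA_real_, ndraw, length(logit_risk))
  for (i in seq_along(logit_risk)) {
    t <- treatment[i]
    dlt <- if (t == posterior$reference) zeros else col_or_zero(paste0("delta[", t, "]"))
    gmt <- if (t == posterior$reference) zeros else col_or_zero(paste0("gamma[", t, "]"))
    out[, i] <- inv_logit(anchor$alpha + dlt + (g0 + gmt) * cc[i])
  }
  out
}

#' Number needed to treat
#'
#' Patients that must receive the preferred treatment instead of the
#' comparator to prevent one event: the reciprocal of the absolute risk
#' difference, rounded up to a whole patient.
#'
#' @param risk_a Event risk under the comparator.
#' @param risk_b Event risk under the preferred treatment; must be smaller
#'   than `risk_a`.
#' @return `ceiling(1 / (risk_a - risk_b))`.
#' @examples
#' nnt(0.84, 0.69) # 7
#' nnt(0.93, 0.82) # 10
#' @export
nnt <- function(risk_a, risk_b) {
  stopifnot(risk_a >= 0, risk_a <= 1, risk_b >= 0, risk_b <= 1)
  if (any(risk_a <= risk_b)) {
    abort_ipdnmr("NNT is undefined unless risk_a > risk_b.", "ipdnmr_nnt")
  }
  ceiling(1 / (risk_a - risk_b))
}

#' Absolute and relative benefits by risk stratum
#'
#' Summarizes, for a population of scored patients, the expected outcome
#' under every treatment within baseline-risk strata: the default strata are
#' all patients, low-risk patients (baseline risk below `strata[1]` = 30%)
#' and high-risk patients (baseline risk above `strata[2]` = 50%). Per group
#' and treatment the predicted probability is the average over the group's
#' patients of each patient's posterior-mean probability (a marginal
#' summary). Pairwise absolute risk differences are reported in percentage
#' points with the NNT where the difference is positive; odds ratios versus
#' the reference are posterior means of `exp(delta_t + gamma_t * c)`
#' evaluated at the group's mean centered logit risk.
#'
#' @param scores A `risk_scores` tibble (or numeric vector of logit risks)
#'   for the target population.
#' @param treatments Treatments to compare; default all in the posterior.
#' @param anchor A [estimate_anchor()] result.
#' @param posterior An `nmr_fit`.
#' @param strata Two risk cutpoints `c(low, high)`; the low stratum is
#'   `risk < strata[1]`, the high stratum `risk > strata[2]`.
#' @return A list of class `benefit_table` with tibbles `groups`
#'   (per group and treatment: predicted probability with credible interval,
#'   OR vs reference) and `pairs` (per group and treatment pair: absolute
#'   risk difference in percentage points, NNT). Empty strata are omitted.
#' @export
benefit_summary <- function(scores, treatments = NULL, anchor, posterior,
                            strata = c(0.30, 0.50)) {
  stopifnot(inherits(posterior, "nmr_fit"), length(strata) == 2)
  lp <- if (inherits(scores, "risk_scores")) scores$logit_risk else as.numeric(scores)
  if (length(lp) == 0) abort_ipdnmr("No patients to summarize.", "ipdnmr_empty")
  treatments <- treatments %||% posterior$treatments
  risk <- inv_logit(lp)
  groups <- list(all = rep(TRUE, length(lp)),
                 low = risk < strata[1],
                 high = risk > strata[2])
  names(groups) <- c("all",
                     sprintf("risk < %d%%", round(100 * strata[1])),
                     sprintf("risk > %d%%", round(100 * strata[2])))
  groups <- groups[vapply(groups, any, logical(1))]

  d <- posterior$draws
  zeros <- rep(0, nrow(d))
  col_or_zero <- function(col) if (col %in% names(d)) d[[col]] else zeros

  group_rows <- list(); pair_rows <- list()
  for (gname in names(groups)) {
    sel <- groups[[gname]]
    cbar <- mean(lp[sel]) - anchor$mean_logit_risk
    probs <- vapply(treatments, function(t) {
      pd <- patient_prob_draws(lp[sel], rep(t, sum(sel)), anchor, posterior)
      pat_mean <- colMeans(pd)            # posterior mean per patient
      draw_mean <- rowMeans(pd)           # group mean per draw
      c(mean(pat_mean),
        stats::quantile(draw_mean, 0.025),
        stats::quantile(draw_mean, 0.975))
    }, numeric(3))
    ors <- vapply(treatments, function(t) {
      if (t == posterior$reference) return(1)
      mean(exp(col_or_zero(paste0("delta[", t, "]")) +
                 col_or_zero(paste0("gamma[", t, "]")) * cbar))
    }, numeric(1))
    group_rows[[gname]] <- tibble::tibble(
      group = gname, n = sum(sel), treatment = treatments,
      estimate = probs[1, ], conf.low = probs[2, ], conf.high = probs[3, ],
      or_vs_ref = unname(ors))

    if (length(treatments) < 2) next
    cmb <- utils::combn(treatments, 2)
    pair_rows[[gname]] <- purrr::map_dfr(seq_len(ncol(cmb)), function(k) {
      a <- cmb[1, k]; b <- cmb[2, k]
      pa <- probs[1, a]; pb <- probs[1, b]
      # orient so the benefit (risk reduction) of b over a is reported
      if (pa < pb) { tmp <- a; a <- b; b <- tmp; tmp <- pa; pa <- pb; pb <- tmp }
      tibble::tibble(group = gname, comparator = a, treatment = b,
                     risk_comparator = pa, risk_treatment = pb,
                     benefit_pp = 100 * (pa - pb),
                     nnt = if (pa > pb) nnt(pa, pb) else NA_real_)
    })
  }
  structure(list(groups = dplyr::bind_rows(group_rows),
                 pairs = dplyr::bind_rows(pair_rows),
                 strata = strata, reference = posterior$reference),
            class = "benefit_table")
}

#' @export
print.benefit_table <- function(x, ...) {
  cat("<benefit table> reference:", x$reference, "\n")
  cat("Predicted probabilities by group:\n")
  print(x$groups, n = Inf)
  cat("Pairwise absolute benefits:\n")
  print(x$pairs, n = Inf)
  invisible(x)
}

#' @method tidy benefit_table
#' @export
tidy.benefit_table <- function(x, ...) x$groups
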