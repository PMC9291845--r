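#' Plot the baseline-risk distribution by observed outcome
#'
#' Density of the predicted baseline risk, split by whether the patient
#' experienced the event — a visual check that the risk score is prognostic
#' (event patients shifted right) with, typically, considerable overlap.
#'
#' @param object A `risk_scores` tibble from [score()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot risk_scores
#' @export
autoplot.risk_scores <- function(object, ...) {
  df <- dplyr::filter(object, !is.na(.data$outcome))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$risk,
                                   fill = factor(.data$outcome,
                                                 labels = c("no event", "event")))) +
    ggplot2::geom_density(alpha = 0.45, colour = NA) +
    ggplot2::geom_vline(xintercept = mean(df$risk), linetype = 2) +
    ggplot2::labs(x = "predicted baseline risk", y = "density",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' Forest plot of the network meta-regression posterior
#'
#' Posterior means and central 95% intervals of the relative-effect and
#' interaction basic parameters plus the prognostic coefficient; study
#' nuisance intercepts are omitted.
#'
#' @param object An `nmr_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot nmr_fit
#' @export
autoplot.nmr_fit <- function(object, ...) {
  td <- tidy(object)
  td <- td[!grepl("^u\\[|^d\\[|^g\\[", td$term), ]
  ggplot2::ggplot(td, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 3) +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$conf.low,
                                          xmax = .data$conf.high)) +
    ggplot2::labs(x = "posterior mean (95% credible interval)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Predicted absolute risk as a function of baseline risk
#'
#' Draws, for each treatment, the posterior-mean predicted probability of
#' the outcome (with a 95% credible band) across a grid of baseline risks —
#' the curve a clinician would read to compare treatments for a patient of
#' known baseline risk.
#'
#' @param anchor A [estimate_anchor()] result.
#' @param posterior An `nmr_fit`.
#' @param treatments Treatments to draw; default all.
#' @param risk_range Baseline-risk interval to cover, default 0.1 to 0.9.
#' @param n_points Grid resolution.
#' @return A ggplot.
#' @export
plot_benefit_curve <- function(anchor, posterior, treatments = NULL,
                               risk_range = c(0.1, 0.9), n_points = 60) {
  treatments <- treatments %||% posterior$treatments
  grid_risk <- seq(risk_range[1], risk_range[2], length.out = n_points)
  df <- purrr::map_dfr(treatments, function(t) {
    out <- predict_patient(logit(grid_risk), rep(t, n_points), anchor, posterior)
    out$treatment <- t
    out
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$risk, y = .data$estimate,
                                   colour = .data$treatment,
                                   fill = .data$treatment)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$conf.low,
                                      ymax = .data$conf.high),
                         alpha = 0.15, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "baseline risk", y = "predicted outcome probability",
                  colour = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}
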