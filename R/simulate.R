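#' Configure a multi-trial IPD simulation
#'
#' Describes a network of randomized trials with known generating
#' parameters: per-study sample sizes and arm lists, a covariate model
#' (correlated latent normals, emitted as continuous values or as binary
#' indicators by thresholding), the true baseline-risk coefficients, and the
#' true stage-2 parameters (study intercepts, relative effects, prognostic
#' coefficient and interactions on the basic-parameter scale). Outcomes are
#' generated from the network meta-regression mean structure using the true
#' centered logit risk, with the study-specific centering constant computed
#' analytically from the covariate distribution.
#'
#' @param studies Tibble/data frame with columns `study`, `n` and `arms`
#'   (list-column of treatment labels).
#' @param covariates Tibble/data frame with columns `name`,
#'   `type` (`"normal"` or `"binary"`), `mean`, `sd` (normal) and `prob`
#'   (binary).
#' @param correlation Covariate correlation matrix of the latent normals
#'   (default identity); must be positive definite.
#' @param study_shift Optional named list: per-study numeric vectors (named
#'   by covariate) added to the means of continuous covariates, letting
#'   trial populations differ.
#' @param beta0,beta True risk-model intercept and named coefficient vector.
#' @param u Named per-study true baseline-arm log-odds at the study-mean
#'   risk score.
#' @param delta,gamma Named true log-OR and interaction basic parameters per
#'   non-reference treatment.
#' @param gamma0 True prognostic coefficient of the centered logit risk.
#' @param reference Reference treatment label.
#' @param missingness Named covariate missingness rates, injected completely
#'   at random after outcome generation.
#' @param seed Default seed for [simulate_ipd()].
#' @return A list of class `simulation_config`.
#' @seealso [default_ms_like_config()] for a packaged three-trial,
#'   four-treatment configuration; [simulate_ipd()] to generate data.
#' @export
simulation_config <- function(studies, covariates, correlation = NULL,
                              study_shift = NULL, beta0, beta, u, delta,
                              gamma, gamma0, reference,
                              missingness = NULL, seed = 1) {
  studies <- tibble::as_tibble(studies)
  covariates <- tibble::as_tibble(covariates)
  stopifnot(all(c("study", "n", "arms") %in% names(studies)),
            all(c("name", "type") %in% names(covariates)),
            all(covariates$type %in% c("normal", "binary")),
            setequal(names(beta), covariates$name),
            setequal(names(u), studies$study))
  trts <- sort(unique(unlist(studies$arms)))
  stopifnot(reference %in% trts,
            setequal(names(delta), setdiff(trts, reference)),
            setequal(names(gamma), setdiff(trts, reference)))
  np <- nrow(covariates)
  correlation <- correlation %||% diag(np)
  stopifnot(nrow(correlation) == np, ncol(correlation) == np)
  ev <- eigen(correlation, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10) {
    abort_ipdnmr("Covariate correlation matrix is not positive definite.",
                 "ipdnmr_correlation")
  }
  structure(list(studies = studies, covariates = covariates,
                 correlation = correlation, study_shift = study_shift,
                 beta0 = beta0, beta = beta[covariates$name],
                 u = u, delta = delta, gamma = gamma, gamma0 = gamma0,
                 reference = reference,
                 missingness = missingness %||%
                   stats::setNames(rep(0, np), covariates$name),
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' A packaged simulation shaped like a three-trial RRMS network
#'
#' A ready-made [simulation_config()] emulating a network of three phase III
#' relapsing-remitting multiple sclerosis trials comparing placebo,
#' Natalizumab, Dimethyl Fumarate and Glatiramer Acetate (arm structures
#' 2/3/2, sample sizes 939/1417/1234, binary outcome "relapse within two
#' years"): eight prognostic covariates (age, disability score, prior
#' relapses, two quality-of-life summaries, months since last relapse, sex,
#' prior treatment), placebo-arm event rates in the 40-55% range and
#' moderately negative log-ORs for the active drugs, with the centered logit
#' risk as a strong prognostic factor and weak effect modifier.
#'
#' @param seed Integer seed stored in the config.
#' @return A `simulation_config`.
#' @export
default_ms_like_config <- function(seed = 1) {
  studies <- tibble::tibble(
    study = c("TRIAL1", "TRIAL2", "TRIAL3"),
    n = c(939L, 1417L, 1234L),
    arms = list(c("Placebo", "Natalizumab"),
                c("Placebo", "DimethylFumarate", "GlatiramerAcetate"),
                c("Placebo", "DimethylFumarate"))
  )
  covariates <- tibble::tibble(
    name = c("age", "edss", "relapses_1y", "sf36_pcs", "sf36_mcs",
             "months_since_relapse", "male", "prior_treatment"),
    type = c(rep("normal", 6), "binary", "binary"),
    mean = c(37, 2.4, 1.4, 45, 47, 5, NA, NA),
    sd = c(9, 1.2, 0.9, 8, 10, 3, NA, NA),
    prob = c(rep(NA, 6), 0.30, 0.40)
  )
  beta <- c(age = -0.018, edss = 0.17, relapses_1y = 0.60,
            sf36_pcs = -0.020, sf36_mcs = 0.004,
            months_since_relapse = -0.013, male = -0.14,
            prior_treatment = 0.19)
  # intercept set so the mean logit risk sits near logit(0.37)
  mean_x <- c(37, 2.4, 1.4, 45, 47, 5, 0.30, 0.40)
  beta0 <- logit(0.37) - sum(beta * mean_x)
  simulation_config(
    studies = studies,
    covariates = covariates,
    correlation = diag(8),
    study_shift = list(TRIAL1 = c(age = -1.0, edss = -0.1),
                       TRIAL2 = c(age = 0.3, edss = 0.2),
                       TRIAL3 = c(age = 1.5)),
    beta0 = beta0, beta = beta,
    u = c(TRIAL1 = 0.26, TRIAL2 = -0.36, TRIAL3 = -0.22),
    delta = c(DimethylFumarate = -0.89, GlatiramerAcetate = -0.71,
              Natalizumab = -1.22),
    gamma = c(DimethylFumarate = 0.25, GlatiramerAcetate = 0.23,
              Natalizumab = -0.26),
    gamma0 = 1.26,
    reference = "Placebo",
    missingness = c(age = 0, edss = 0, relapses_1y = 0, sf36_pcs = 0.03,
                    sf36_mcs = 0.03, months_since_relapse = 0, male = 0,
                    prior_treatment = 0),
    seed = seed
  )
}

#' Simulate multi-trial IPD with known truth
#'
#' Draws patients study by study: correlated latent normals give the
#' covariates (binary covariates threshold the latent at the configured
#' rate), treatments are assigned uniformly at random within each study's
#' arm list, the true logit risk follows the configured risk model, and the
#' outcome is Bernoulli with the network meta-regression mean structure
#' evaluated at the true centered logit risk (centering at the analytic
#' study mean). Covariate missingness is then injected completely at random.
#' Fully reproducible from the seed.
#'
#' @param config A [simulation_config()].
#' @param seed Integer seed; defaults to the one in the config.
#' @return A list with `data` (an `ipd_tbl`; missing covariate values
#'   possible if configured) and `truth`, a list carrying every generating
#'   parameter plus per-patient `logit_risk`, the per-study analytic mean
#'   logit risks and the per-study baseline treatments.
#' @export
simulate_ipd <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(seed)
  cv <- config$covariates
  np <- nrow(cv)
  Rchol <- chol(config$correlation)
  rows <- list()
  truth_lp <- list()
  mu_study <- stats::setNames(numeric(nrow(config$studies)),
                              config$studies$study)
  h <- stats::setNames(character(nrow(config$studies)), config$studies$study)

  for (j in seq_len(nrow(config$studies))) {
    s <- config$studies$study[j]
    n <- config$studies$n[j]
    arms <- sort(config$studies$arms[[j]])
    h[s] <- if (config$reference %in% arms) config$reference else arms[1]

    shift <- stats::setNames(rep(0, np), cv$name)
    sh <- config$study_shift[[s]]
    if (!is.null(sh)) shift[names(sh)] <- sh

    Z <- matrix(stats::rnorm(n * np), n, np) %*% Rchol
    X <- matrix(NA_real_, n, np, dimnames = list(NULL, cv$name))
    means_j <- numeric(np)
    for (k in seq_len(np)) {
      if (cv$type[k] == "normal") {
        X[, k] <- cv$mean[k] + shift[k] + cv$sd[k] * Z[, k]
        means_j[k] <- cv$mean[k] + shift[k]
      } else {
        X[, k] <- as.numeric(Z[, k] > stats::qnorm(1 - cv$prob[k]))
        means_j[k] <- cv$prob[k]
      }
    }
    lp <- config$beta0 + drop(X %*% config$beta)
    mu_study[s] <- config$beta0 + sum(config$beta * means_j)
    cc <- lp - mu_study[s]

    trt <- sample(arms, n, replace = TRUE)
    dlt <- ifelse(trt == h[s], 0,
                  basic_value(config$delta, trt, h[s], config$reference))
    gmt <- ifelse(trt == h[s], 0,
                  basic_value(config$gamma, trt, h[s], config$reference))
    eta <- linear_predictor(config$u[[s]], dlt, config$gamma0, gmt, cc,
                            trt == h[s])
    y <- stats::rbinom(n, 1, inv_logit(eta))

    rows[[j]] <- tibble::tibble(study = s, treatment = trt, outcome = y) |>
      dplyr::bind_cols(tibble::as_tibble(X))
    truth_lp[[j]] <- lp
  }

  data <- dplyr::bind_rows(rows)
  # completely-at-random missingness
  for (k in seq_len(np)) {
    rate <- config$missingness[[cv$name[k]]] %||% 0
    if (rate > 0) {
      hide <- stats::runif(nrow(data)) < rate
      data[[cv$name[k]]][hide] <- NA_real_
    }
  }
  tbl <- new_ipd_tbl(data, covariates = cv$name,
                     reference = config$reference)
  truth <- list(beta0 = config$beta0, beta = config$beta, u = config$u,
                delta = config$delta, gamma = config$gamma,
                gamma0 = config$gamma0, reference = config$reference,
                logit_risk = unlist(truth_lp),
                mean_logit_risk = mu_study,
                baselines = h, seed = seed)
  list(data = tbl, truth = truth)
}

# contrast of treatment t vs study baseline h on the basic-parameter scale
basic_value <- function(basic, t, h, reference) {
  val <- function(x) ifelse(x == reference, 0, basic[x])
  unname(val(t) - val(h))
}
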