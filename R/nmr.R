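#' Specification of the IPD network meta-regression model
#'
#' Collects the model and sampler settings for [fit_nmr()]. The model is a
#' Bernoulli network meta-regression on patient-level data in which the
#' within-study-centered logit baseline-risk score enters both as a
#' prognostic factor (coefficient `gamma0`, common across studies) and as a
#' modifier of every relative treatment effect (coefficients `gamma_t`).
#' Relative effects and interactions are parametrized through basic
#' parameters versus the overall reference treatment and obey the
#' consistency constraints `D_ht = delta_t - delta_h`,
#' `G_ht = gamma_t - gamma_h` by construction.
#'
#' @param reference Label of the overall reference treatment
#'   (`delta_ref = gamma_ref = 0`).
#' @param effect_model `"common"` (study contrasts identical) or `"random"`
#'   (study contrasts drawn around the consistency means with SD `sigma_d`).
#' @param interaction_model `"common"` or `"random"`, analogously, for the
#'   risk-score-by-treatment interactions.
#' @param include_interaction Set `FALSE` (or use [reduce_to_nma()]) to
#'   constrain `gamma0` and every `gamma_t` to zero, reducing the model to a
#'   plain network meta-analysis.
#' @param prior_variance Variance of the Normal(0, .) priors on all location
#'   parameters (default 1000, i.e. SD about 31.6). Note this is a
#'   *variance*; some MCMC dialects write N(mean, precision).
#' @param sigma_upper Upper bound of the Uniform(0, .) priors on the
#'   between-study SDs used by the random-effects options.
#' @param chains,iterations,burn_in,thin MCMC settings; defaults are 2
#'   chains of 10000 iterations, 1000 discarded, keeping every 10th, i.e.
#'   `chains * (iterations - burn_in) / thin` retained draws.
#' @param seed Integer seed; fits are reproducible given the seed.
#' @return A list of class `nmr_spec`.
#' @export
nmr_spec <- function(reference,
                     effect_model = c("common", "random"),
                     interaction_model = c("common", "random"),
                     include_interaction = TRUE,
                     prior_variance = 1000,
                     sigma_upper = 5,
                     chains = 2, iterations = 10000, burn_in = 1000,
                     thin = 10, seed = 1) {
  effect_model <- match.arg(effect_model)
  interaction_model <- match.arg(interaction_model)
  stopifnot(burn_in < iterations, thin >= 1, prior_variance > 0,
            chains >= 1, sigma_upper > 0)
  structure(list(reference = as.character(reference),
                 effect_model = effect_model,
                 interaction_model = interaction_model,
                 include_interaction = isTRUE(include_interaction),
                 prior_variance = prior_variance,
                 sigma_upper = sigma_upper,
                 chains = as.integer(chains),
                 iterations = as.integer(iterations),
                 burn_in = as.integer(burn_in),
                 thin = as.integer(thin),
                 seed = as.integer(seed)),
            class = "nmr_spec")
}

#' Reduce a meta-regression spec to a plain network meta-analysis
#'
#' Returns the same specification with the risk-score terms (`gamma0` and
#' all `gamma_t`) constrained to zero. Idempotent.
#'
#' @param spec An `nmr_spec`.
#' @return The reduced `nmr_spec`.
#' @export
reduce_to_nma <- function(spec) {
  stopifnot(inherits(spec, "nmr_spec"))
  spec$include_interaction <- FALSE
  spec
}

#' Arm-level linear predictor of the network meta-regression
#'
#' The mean structure of the model, exposed for clarity and testing: on a
#' study's baseline arm the log-odds are `u_j + gamma0 * c`; on any other
#' arm they are `u_j + d + gamma0 * c + g * c`, where `c` is the patient's
#' logit risk centered at the study mean and `d`, `g` are the study-level
#' contrast and interaction versus the study's baseline treatment.
#'
#' @param u Study nuisance intercept.
#' @param delta Study-level log-OR contrast vs the study's baseline arm
#'   (ignored on the baseline arm).
#' @param gamma0 Prognostic coefficient of the centered logit risk.
#' @param gamma_t Interaction contrast vs the baseline arm (ignored on the
#'   baseline arm).
#' @param centered_logit_risk `logit(R) -` study mean logit risk.
#' @param is_baseline_arm Logical.
#' @return The linear predictor (log-odds).
#' @examples
#' inv_logit(linear_predictor(-0.5, 0, 0, 0, 0, TRUE)) # 0.3775
#' @export
linear_predictor <- function(u, delta, gamma0, gamma_t, centered_logit_risk,
                             is_baseline_arm) {
  ifelse(is_baseline_arm,
         u + gamma0 * centered_logit_risk,
         u + delta + gamma0 * centered_logit_risk +
           gamma_t * centered_logit_risk)
}

# ---- model frame ----------------------------------------------------------

# per-study baseline treatment: the overall reference when present,
# otherwise the alphabetically first arm
study_baselines <- function(data, reference) {
  arms <- split(data$treatment, data$study)
  vapply(arms, function(a) {
    a <- sort(unique(a))
    if (reference %in% a) reference else a[1]
  }, character(1))
}

check_connected <- function(data, reference) {
  trts <- sort(unique(data$treatment))
  if (!reference %in% trts) {
    abort_ipdnmr("Reference treatment absent from the data.", "ipdnmr_reference")
  }
  reached <- reference
  repeat {
    grow <- FALSE
    for (arms in split(data$treatment, data$study)) {
      arms <- unique(arms)
      if (any(arms %in% reached) && !all(arms %in% reached)) {
        reached <- union(reached, arms)
        grow <- TRUE
      }
    }
    if (!grow) break
  }
  if (!setequal(reached, trts)) {
    abort_ipdnmr(paste0("Treatment network is disconnected; unreachable: ",
                        paste(setdiff(trts, reached), collapse = ", ")),
                 "ipdnmr_disconnected")
  }
  trts
}

# Builds the response, the common-effects design matrix (one column per
# sampled parameter) and bookkeeping for the random-effects design.
nmr_model_frame <- function(data, scores, spec) {
  stopifnot(inherits(data, "ipd_tbl"))
  if (inherits(scores, "risk_scores")) {
    stopifnot(nrow(scores) == nrow(data))
    lp <- scores$logit_risk
  } else {
    lp <- as.numeric(scores)
    stopifnot(length(lp) == nrow(data))
  }
  if (anyNA(data$outcome) || anyNA(lp)) {
    abort_ipdnmr("Outcome and scores must be complete.", "ipdnmr_incomplete")
  }
  n_arms <- tapply(data$treatment, data$study, function(t) length(unique(t)))
  if (any(n_arms < 2)) {
    abort_ipdnmr(paste0("Study with a single arm: ",
                        paste(names(n_arms)[n_arms < 2], collapse = ", ")),
                 "ipdnmr_single_arm")
  }
  trts <- check_connected(data, spec$reference)

  studies <- sort(unique(data$study))
  h <- study_baselines(data, spec$reference)
  cmeans <- tapply(lp, data$study, mean)
  cc <- lp - as.numeric(cmeans[data$study])

  nonref <- setdiff(trts, spec$reference)
  # +1/-1 loading of a (study, arm) pair on the basic parameters
  basic_load <- function(study, trt) {
    v <- stats::setNames(numeric(length(nonref)), nonref)
    if (trt == h[[study]]) return(v)
    if (trt != spec$reference) v[trt] <- v[trt] + 1
    if (h[[study]] != spec$reference) v[h[[study]]] <- v[h[[study]]] - 1
    v
  }

  n <- nrow(data)
  U <- matrix(0, n, length(studies),
              dimnames = list(NULL, paste0("u[", studies, "]")))
  U[cbind(seq_len(n), match(data$study, studies))] <- 1
  L <- t(vapply(seq_len(n),
                function(i) basic_load(data$study[i], data$treatment[i]),
                numeric(length(nonref))))
  if (length(nonref) == 1) L <- matrix(L, ncol = 1)
  colnames(L) <- paste0("delta[", nonref, "]")
  X <- cbind(U, L)
  if (spec$include_interaction) {
    G <- L * cc
    colnames(G) <- paste0("gamma[", nonref, "]")
    X <- cbind(X, gamma0 = cc, G)
  }

  # per-(study, non-baseline-arm) contrast bookkeeping for random effects
  pairs <- do.call(rbind, lapply(studies, function(s) {
    a <- setdiff(sort(unique(data$treatment[data$study == s])), h[[s]])
    if (length(a) == 0) return(NULL)
    data.frame(study = s, treatment = a, stringsAsFactors = FALSE)
  }))
  B <- t(vapply(seq_len(nrow(pairs)),
                function(k) basic_load(pairs$study[k], pairs$treatment[k]),
                numeric(length(nonref))))
  if (length(nonref) == 1) B <- matrix(B, ncol = 1)
  colnames(B) <- nonref

  list(y = data$outcome, X = X, centered = cc,
       studies = studies, treatments = trts, nonref = nonref,
       baselines = h, pairs = pairs, B = B,
       study_of = match(data$study, studies),
       pair_of = match(paste(data$study, data$treatment),
                       paste(pairs$study, pairs$treatment)))
}

# MAP estimate and curvature of a Bernoulli GLM with Gaussian ridge,
# used to seed and scale the Metropolis proposal
logistic_map <- function(X, y, prior_prec, max_iter = 50) {
  p <- ncol(X)
  theta <- rep(0, p)
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% theta)
    pr <- inv_logit(eta)
    w <- pmax(pr * (1 - pr), 1e-10)
    grad <- drop(crossprod(X, y - pr)) - prior_prec * theta
    H <- crossprod(X, X * w) + diag(prior_prec, p)
    step <- solve(H, grad)
    if (max(abs(step)) > 5) step <- step * 5 / max(abs(step))
    theta <- theta + step
    if (max(abs(step)) < 1e-8) break
  }
  eta <- drop(X %*% theta)
  pr <- inv_logit(eta)
  w <- pmax(pr * (1 - pr), 1e-10)
  H <- crossprod(X, X * w) + diag(prior_prec, p)
  list(theta = theta, cov = solve(H))
}

#' Fit the Bayesian IPD network meta-regression
#'
#' Samples the posterior of the network meta-regression with the centered
#' logit baseline-risk score as prognostic factor and effect modifier, under
#' a Bernoulli likelihood and the consistency constraints. Location
#' parameters (study nuisance intercepts `u_j`, basic log-OR parameters
#' `delta_t`, prognostic coefficient `gamma0`, interaction basic parameters
#' `gamma_t`) get Normal(0, `prior_variance`) priors; the between-study SDs
#' of the random-effects options get Uniform(0, `sigma_upper`) priors.
#'
#' Sampling uses an adaptive random-walk Metropolis algorithm whose proposal
#' is scaled from the Laplace (penalized-likelihood) approximation of the
#' model, with Gibbs updates of the consistency means and
#' Metropolis-within-Gibbs updates of the between-study SDs under the
#' random-effects options. Adaptation stops at the end of burn-in. Chains
#' start at `delta = gamma = 0` with `u_j` at the observed baseline-arm
#' log-odds, jittered across chains.
#'
#' Split-chain R-hat and effective sample sizes are computed for every
#' retained parameter; a warning is raised if any R-hat exceeds 1.05.
#'
#' @param data An `ipd_tbl` with complete outcomes, every study randomizing
#'   at least two treatments and every treatment connected to the reference.
#' @param scores A `risk_scores` tibble from [score()] aligned with `data`
#'   (or a numeric vector of logit risks). Scores are centered within study
#'   at the mean over that study's analyzed patients.
#' @param spec An [nmr_spec()].
#' @return An object of class `nmr_fit`: posterior `draws` (tibble, one
#'   column per parameter plus `.chain` and `.draw`), `diagnostics`
#'   (parameter summaries with R-hat and ESS), treatments, studies, the
#'   spec, and per-study centering constants.
#' @export
fit_nmr <- function(data, scores, spec) {
  stopifnot(inherits(spec, "nmr_spec"))
  mf <- nmr_model_frame(data, scores, spec)
  random_d <- spec$effect_model == "random"
  random_g <- spec$interaction_model == "random" && spec$include_interaction

  if (!random_d && !random_g) {
    draws <- sample_common(mf, spec)
  } else {
    draws <- sample_random(mf, spec, random_d, random_g)
  }

  diagnostics <- mcmc_diagnostics(draws)
  if (any(diagnostics$rhat > 1.05, na.rm = TRUE)) {
    warning("R-hat > 1.05 for: ",
            paste(diagnostics$parameter[which(diagnostics$rhat > 1.05)],
                  collapse = ", "))
  }
  structure(list(draws = draws,
                 diagnostics = diagnostics,
                 treatments = mf$treatments,
                 reference = spec$reference,
                 studies = mf$studies,
                 baselines = mf$baselines,
                 centering = tapply(mf$centered, mf$study_of, mean),
                 spec = spec),
            class = "nmr_fit")
}

# common-effects sampler: one adaptive RW-Metropolis block over all
# location parameters
sample_common <- function(mf, spec) {
  X <- mf$X; y <- mf$y
  p <- ncol(X)
  prior_prec <- 1 / spec$prior_variance
  map <- logistic_map(X, y, prior_prec)
  prop_chol <- chol((2.38^2 / p) * (map$cov + diag(1e-10, p)))

  log_post <- function(theta) {
    bernoulli_loglik(y, drop(X %*% theta)) -
      0.5 * prior_prec * sum(theta^2)
  }

  keep_iters <- seq(spec$burn_in + spec$thin, spec$iterations, by = spec$thin)
  out <- vector("list", spec$chains)
  for (ch in seq_len(spec$chains)) {
    set.seed(spec$seed + 7919L * ch)
    theta <- init_theta(mf, spec, jitter = 0.2 * (ch - 1))
    lp <- log_post(theta)
    scale <- 1
    kept <- matrix(NA_real_, length(keep_iters), p,
                   dimnames = list(NULL, colnames(X)))
    k <- 0L
    acc <- 0L
    for (it in seq_len(spec$iterations)) {
      prop <- theta + scale * drop(stats::rnorm(p) %*% prop_chol)
      lp_prop <- log_post(prop)
      if (log(stats::runif(1)) < lp_prop - lp) {
        theta <- prop; lp <- lp_prop; acc <- acc + 1L
      }
      if (it <= spec$burn_in && it %% 50 == 0) {
        scale <- exp(log(scale) + (acc / it - 0.3) / sqrt(it / 50))
      }
      if (k < length(keep_iters) && it == keep_iters[k + 1L]) {
        k <- k + 1L
        kept[k, ] <- theta
      }
    }
    out[[ch]] <- tibble::as_tibble(kept) |>
      dplyr::mutate(.chain = ch, .draw = seq_len(nrow(kept)), .before = 1)
  }
  dplyr::bind_rows(out)
}

# random-effects sampler: a Metropolis block over the free likelihood-level
# parameters (basic parameters for common components, per-study contrasts
# for random ones), Gibbs updates of the consistency means and Metropolis
# updates of the between-study SDs
sample_random <- function(mf, spec, random_d, random_g) {
  y <- mf$y
  n <- length(y)
  studies <- mf$studies; nonref <- mf$nonref
  npair <- nrow(mf$pairs)
  prior_prec <- 1 / spec$prior_variance

  U <- mf$X[, paste0("u[", studies, "]"), drop = FALSE]
  Dpair <- matrix(0, n, npair)
  idx <- which(!is.na(mf$pair_of))
  Dpair[cbind(idx, mf$pair_of[idx])] <- 1
  L <- mf$X[, paste0("delta[", nonref, "]"), drop = FALSE]

  eff_cols <- if (random_d) {
    colnames(Dpair) <- paste0("d[", mf$pairs$study, ":", mf$pairs$treatment, "]")
    Dpair
  } else L
  X <- cbind(U, eff_cols)
  if (spec$include_interaction) {
    int_cols <- if (random_g) {
      G <- Dpair * mf$centered
      colnames(G) <- paste0("g[", mf$pairs$study, ":", mf$pairs$treatment, "]")
      G
    } else {
      G <- L * mf$centered
      colnames(G) <- paste0("gamma[", nonref, "]")
      G
    }
    X <- cbind(X, gamma0 = mf$centered, int_cols)
  }
  p <- ncol(X)
  iu <- seq_along(studies)
  n_eff <- if (random_d) npair else length(nonref)
  id <- length(studies) + seq_len(n_eff)
  off <- length(studies) + n_eff
  ig0 <- if (spec$include_interaction) off + 1L else integer(0)
  ig <- if (spec$include_interaction) {
    off + 1L + seq_len(if (random_g) npair else length(nonref))
  } else integer(0)

  map <- logistic_map(X, y, prior_prec)
  prop_chol <- chol((2.38^2 / p) * (map$cov + diag(1e-10, p)))
  B <- mf$B  # pair -> basic-parameter loading

  keep_iters <- seq(spec$burn_in + spec$thin, spec$iterations, by = spec$thin)
  par_names <- c(colnames(X),
                 if (random_d) paste0("delta[", nonref, "]"),
                 if (random_g) paste0("gamma[", nonref, "]"),
                 if (random_d) "sigma_d",
                 if (random_g) "sigma_g")
  out <- vector("list", spec$chains)

  gibbs_means <- function(v, sigma) {
    # consistency means given study contrasts v: v ~ N(B %*% beta, sigma^2)
    prec <- crossprod(B) / sigma^2 + diag(prior_prec, length(nonref))
    ch <- chol(prec)
    m <- backsolve(ch, forwardsolve(t(ch), crossprod(B, v) / sigma^2))
    drop(m + backsolve(ch, stats::rnorm(length(nonref))))
  }
  log_sigma_target <- function(sigma, v, mu) {
    if (sigma <= 0 || sigma >= spec$sigma_upper) return(-Inf)
    sum(stats::dnorm(v, mu, sigma, log = TRUE))
  }

  for (chn in seq_len(spec$chains)) {
    set.seed(spec$seed + 7919L * chn)
    theta <- rep(0, p)
    theta[iu] <- init_u(mf, jitter = 0.2 * (chn - 1))
    delta <- stats::setNames(rep(0, length(nonref)), nonref)
    gamma <- stats::setNames(rep(0, length(nonref)), nonref)
    sigma_d <- 0.2
    sigma_g <- 0.2
    scale <- 1; acc <- 0L
    kept <- matrix(NA_real_, length(keep_iters), length(par_names),
                   dimnames = list(NULL, par_names))
    k <- 0L

    log_post <- function(th) {
      ll <- bernoulli_loglik(y, drop(X %*% th))
      # vague normal priors on every directly sampled location parameter
      pr <- -0.5 * prior_prec * sum(th[c(iu, ig0)]^2)
      if (random_d) {
        pr <- pr + sum(stats::dnorm(th[id], drop(B %*% delta), sigma_d,
                                    log = TRUE))
      } else {
        pr <- pr - 0.5 * prior_prec * sum(th[id]^2)
      }
      if (spec$include_interaction) {
        if (random_g) {
          pr <- pr + sum(stats::dnorm(th[ig], drop(B %*% gamma), sigma_g,
                                      log = TRUE))
        } else {
          pr <- pr - 0.5 * prior_prec * sum(th[ig]^2)
        }
      }
      ll + pr
    }
    lp <- log_post(theta)

    for (it in seq_len(spec$iterations)) {
      prop <- theta + scale * drop(stats::rnorm(p) %*% prop_chol)
      lp_prop <- log_post(prop)
      if (log(stats::runif(1)) < lp_prop - lp) {
        theta <- prop; lp <- lp_prop; acc <- acc + 1L
      }

      if (random_d) {
        delta <- stats::setNames(gibbs_means(theta[id], sigma_d), nonref)
        s_prop <- sigma_d + stats::rnorm(1, 0, 0.1)
        mu_d <- drop(B %*% delta)
        if (log(stats::runif(1)) < log_sigma_target(s_prop, theta[id], mu_d) -
            log_sigma_target(sigma_d, theta[id], mu_d)) {
          sigma_d <- s_prop
        }
        lp <- log_post(theta)
      }
      if (random_g) {
        gamma <- stats::setNames(gibbs_means(theta[ig], sigma_g), nonref)
        s_prop <- sigma_g + stats::rnorm(1, 0, 0.1)
        mu_g <- drop(B %*% gamma)
        if (log(stats::runif(1)) < log_sigma_target(s_prop, theta[ig], mu_g) -
            log_sigma_target(sigma_g, theta[ig], mu_g)) {
          sigma_g <- s_prop
        }
        lp <- log_post(theta)
      }

      if (it <= spec$burn_in && it %% 50 == 0) {
        scale <- exp(log(scale) + (acc / it - 0.3) / sqrt(it / 50))
      }
      if (k < length(keep_iters) && it == keep_iters[k + 1L]) {
        k <- k + 1L
        kept[k, ] <- c(theta,
                       if (random_d) delta,
                       if (random_g) gamma,
                       if (random_d) sigma_d,
                       if (random_g) sigma_g)
      }
    }
    out[[chn]] <- tibble::as_tibble(kept) |>
      dplyr::mutate(.chain = chn, .draw = seq_len(nrow(kept)), .before = 1)
  }
  dplyr::bind_rows(out)
}

init_u <- function(mf, jitter = 0) {
  u0 <- vapply(seq_along(mf$studies), function(j) {
    on_base <- mf$study_of == j & is.na(mf$pair_of)
    e <- sum(mf$y[on_base]); m <- sum(on_base)
    log((e + 0.5) / (m - e + 0.5))
  }, numeric(1))
  u0 + if (jitter > 0) stats::rnorm(length(u0), 0, jitter) else 0
}

init_theta <- function(mf, spec, jitter = 0) {
  theta <- rep(0, ncol(mf$X))
  names(theta) <- colnames(mf$X)
  theta[seq_along(mf$studies)] <- init_u(mf, jitter = jitter)
  theta
}

mcmc_diagnostics <- function(draws) {
  pars <- setdiff(names(draws), c(".chain", ".draw"))
  chains <- split(draws[pars], draws$.chain)
  mlist <- coda::mcmc.list(lapply(chains, function(d) coda::mcmc(as.matrix(d))))
  rhat <- rep(NA_real_, length(pars))
  if (length(chains) >= 2) {
    rhat <- vapply(pars, function(pp) {
      v <- vapply(chains, function(d) stats::var(d[[pp]]), numeric(1))
      if (all(v < 1e-12)) return(1)
      tryCatch(coda::gelman.diag(mlist[, pp, drop = FALSE],
                                 autoburnin = FALSE)$psrf[1, 1],
               error = function(e) NA_real_)
    }, numeric(1))
  }
  ess <- tryCatch(coda::effectiveSize(mlist),
                  error = function(e) rep(NA_real_, length(pars)))
  m <- as.matrix(draws[pars])
  tibble::tibble(
    parameter = pars,
    mean = colMeans(m),
    sd = apply(m, 2, stats::sd),
    q2.5 = apply(m, 2, stats::quantile, 0.025),
    q50 = apply(m, 2, stats::quantile, 0.5),
    q97.5 = apply(m, 2, stats::quantile, 0.975),
    rhat = unname(rhat[pars]),
    ess = unname(ess[pars])
  )
}

#' Posterior draws of a relative effect between any two treatments
#'
#' Derived contrasts obey the consistency equations exactly for every draw:
#' the log-OR of `treatment` versus `vs` is `delta_t - delta_h` and its
#' interaction contrast is `gamma_t - gamma_h`.
#'
#' @param fit An `nmr_fit` (or an [nmr_posterior()]).
#' @param treatment,vs Treatment labels; `vs` defaults to the reference.
#' @return A tibble with columns `log_or` and (when the model includes the
#'   risk-score terms) `interaction`, one row per posterior draw.
#' @export
relative_effect <- function(fit, treatment, vs = fit$reference) {
  stopifnot(inherits(fit, "nmr_fit"))
  get_basic <- function(prefix, t) {
    if (t == fit$reference) return(rep(0, nrow(fit$draws)))
    col <- paste0(prefix, "[", t, "]")
    if (!col %in% names(fit$draws)) {
      abort_ipdnmr(paste0("Unknown treatment: ", t), "ipdnmr_treatment")
    }
    fit$draws[[col]]
  }
  out <- tibble::tibble(log_or = get_basic("delta", treatment) -
                          get_basic("delta", vs))
  if (any(grepl("^gamma\\[", names(fit$draws))) || "gamma0" %in% names(fit$draws)) {
    g <- function(t) {
      if (t == fit$reference) return(rep(0, nrow(fit$draws)))
      col <- paste0("gamma[", t, "]")
      if (col %in% names(fit$draws)) fit$draws[[col]] else rep(0, nrow(fit$draws))
    }
    out$interaction <- g(treatment) - g(vs)
  }
  out
}

#' Assemble a posterior object from existing draws
#'
#' Builds the posterior container used by the prediction functions from a
#' data frame of draws — e.g. point values from a published table (a
#' single-row, degenerate posterior) or draws imported from another sampler.
#' Columns follow the fitted naming: `delta[<treatment>]`, `gamma0`,
#' `gamma[<treatment>]`; missing `gamma` columns are treated as zero.
#'
#' @param draws Data frame of posterior draws.
#' @param treatments Character vector of all treatment labels, reference
#'   included.
#' @param reference The reference treatment label.
#' @return An object of class `nmr_fit`.
#' @examples
#' nmr_posterior(data.frame(`delta[N]` = -1.22, gamma0 = 1.26,
#'                          check.names = FALSE),
#'               treatments = c("Placebo", "N"), reference = "Placebo")
#' @export
nmr_posterior <- function(draws, treatments, reference) {
  draws <- tibble::as_tibble(draws)
  stopifnot(reference %in% treatments)
  for (t in setdiff(treatments, reference)) {
    dcol <- paste0("delta[", t, "]")
    if (!dcol %in% names(draws)) {
      abort_ipdnmr(paste0("Missing draws column: ", dcol), "ipdnmr_draws")
    }
  }
  if (!"gamma0" %in% names(draws)) draws$gamma0 <- 0
  structure(list(draws = draws, diagnostics = NULL,
                 treatments = treatments, reference = reference,
                 studies = character(0), baselines = NULL,
                 centering = NULL, spec = NULL),
            class = "nmr_fit")
}

#' @export
print.nmr_fit <- function(x, ...) {
  cat("<IPD network meta-regression posterior>\n")
  cat("  treatments:", paste(x$treatments, collapse = ", "),
      "(reference:", paste0(x$reference, ")"), "\n")
  cat("  draws:", nrow(x$draws), "\n")
  if (!is.null(x$diagnostics)) {
    keep <- !grepl("^u\\[|^d\\[|^g\\[", x$diagnostics$parameter)
    print(x$diagnostics[keep, ], n = 20)
  }
  invisible(x)
}

#' Tidiers for network meta-regression fits
#'
#' @param x An `nmr_fit`.
#' @param ... Unused.
#' @return `tidy()`: posterior mean, SD, central 95% interval, R-hat and ESS
#'   per parameter. `glance()`: one-row fit summary.
#' @method tidy nmr_fit
#' @export
tidy.nmr_fit <- function(x, ...) {
  if (!is.null(x$diagnostics)) {
    dplyr::rename(x$diagnostics, term = "parameter", estimate = "mean",
                  std.error = "sd", conf.low = "q2.5", conf.high = "q97.5")
  } else {
    m <- as.matrix(x$draws[setdiff(names(x$draws), c(".chain", ".draw"))])
    tibble::tibble(term = colnames(m), estimate = colMeans(m),
                   std.error = apply(m, 2, stats::sd),
                   conf.low = apply(m, 2, stats::quantile, 0.025),
                   conf.high = apply(m, 2, stats::quantile, 0.975))
  }
}

#' @rdname tidy.nmr_fit
#' @method glance nmr_fit
#' @export
glance.nmr_fit <- function(x, ...) {
  tibble::tibble(
    n_treatments = length(x$treatments),
    n_studies = length(x$studies),
    n_draws = nrow(x$draws),
    max_rhat = if (!is.null(x$diagnostics)) max(x$diagnostics$rhat, na.rm = TRUE) else NA_real_,
    min_ess = if (!is.null(x$diagnostics)) min(x$diagnostics$ess, na.rm = TRUE) else NA_real_
  )
}
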