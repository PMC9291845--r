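#' Fit the baseline-risk model by LASSO
#'
#' Fits the stage-1 multivariable logistic model of baseline risk, pooling
#' all trial arms and ignoring treatment assignment (the model is developed
#' blinded to treatment, on the whole randomized population). Variable
#' selection and coefficient shrinkage are both done by the LASSO: a
#' decreasing penalty path is cross-validated (stratified by outcome,
#' `folds` folds) with the area under the ROC curve as the criterion, and
#' the chosen penalty is the largest one whose CV AUC is within one standard
#' error of the maximum (the one-SE rule, favouring parsimony). Covariates
#' are standardized internally before penalization; reported coefficients
#' are on the original scale and the intercept is never penalized.
#'
#' @param data A complete-case `ipd_tbl` with numeric covariates.
#' @param folds Number of cross-validation folds (default 10).
#' @param seed Integer seed controlling fold assignment; with the seed fixed
#'   the fit is fully reproducible.
#' @param lambda Optional fixed penalty. When supplied, cross-validation is
#'   skipped and coefficients are extracted exactly at this penalty
#'   (``lambda = 0`` recovers the unpenalized maximum-likelihood fit).
#' @param nlambda,lambda_min_ratio Penalty path: `nlambda` log-spaced values
#'   from just above the smallest penalty that zeroes every slope down to
#'   `lambda_min_ratio` times that value.
#' @return An object of class `risk_fit` with elements `route`,
#'   `intercept`, `coefficients` (named, zeros kept), `penalty`,
#'   `selection` (per-penalty CV curve), and `prevalence`.
#' @seealso [fit_prespecified()] for the prespecified-variables route,
#'   [score()] to turn a fit into per-patient risk scores.
#' @export
fit_lasso <- function(data, folds = 10, seed = 1, lambda = NULL,
                      nlambda = 100, lambda_min_ratio = 0.001) {
  xy <- risk_design(data)
  X <- xy$X; y <- xy$y

  # path down from just above the smallest all-null penalty; covariates
  # standardized with the 1/n variance convention used by the
  # coordinate-descent solver. The 25% headroom keeps the null model inside
  # the path for every cross-validation fold (fold-wise lambda_max can
  # exceed the full-sample value), so the one-SE rule can reach it.
  n <- length(y)
  Xs <- scale(X, scale = apply(X, 2, function(v) sqrt(mean((v - mean(v))^2))))
  lambda_max <- max(abs(crossprod(Xs, y - mean(y)))) / n
  path <- exp(seq(log(1.25 * lambda_max), log(lambda_min_ratio * lambda_max),
                  length.out = nlambda))

  if (!is.null(lambda)) {
    stopifnot(lambda >= 0)
    fit <- glmnet::glmnet(X, y, family = "binomial",
                          lambda = sort(unique(c(path, lambda)),
                                        decreasing = TRUE),
                          thresh = 1e-12)
    cf <- as.numeric(stats::coef(fit, s = lambda, exact = TRUE, x = X, y = y,
                                 family = "binomial", thresh = 1e-12))
    return(new_risk_fit(route = "lasso", intercept = cf[1],
                        coefficients = stats::setNames(cf[-1], colnames(X)),
                        penalty = lambda, selection = NULL,
                        prevalence = mean(y)))
  }

  if (min(table(y)) < folds) {
    abort_ipdnmr("Too few patients in the rarer outcome class to give every fold both classes.",
                 "ipdnmr_fold_class")
  }
  foldid <- stratified_folds(y, folds, seed)
  cv <- glmnet::cv.glmnet(X, y, family = "binomial", type.measure = "auc",
                          foldid = foldid, lambda = path)
  cf <- as.numeric(stats::coef(cv, s = "lambda.1se"))
  selection <- tibble::tibble(lambda = cv$lambda, cv_auc = cv$cvm,
                              cv_auc_se = cv$cvsd, nonzero = cv$nzero)
  new_risk_fit(route = "lasso", intercept = cf[1],
               coefficients = stats::setNames(cf[-1], colnames(X)),
               penalty = cv$lambda.1se, selection = selection,
               prevalence = mean(y),
               extra = list(cv_folds = folds, seed = seed,
                            lambda_min = cv$lambda.min))
}

# outcome-stratified fold assignment, deterministic in the seed
stratified_folds <- function(y, folds, seed) {
  foldid <- integer(length(y))
  set.seed(seed)
  for (cls in unique(y)) {
    idx <- which(y == cls)
    foldid[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }
  foldid
}

risk_design <- function(data) {
  stopifnot(inherits(data, "ipd_tbl"))
  covs <- ipd_covariates(data)
  if (length(covs) == 0) abort_ipdnmr("No covariates.", "ipdnmr_no_covariates")
  X <- as.matrix(data[, covs])
  y <- data$outcome
  if (anyNA(X) || anyNA(y)) {
    abort_ipdnmr("Risk models require complete-case data; run complete_case() first.",
                 "ipdnmr_incomplete")
  }
  if (length(unique(y)) < 2) {
    abort_ipdnmr("Outcome has a single class.", "ipdnmr_single_class")
  }
  const <- apply(X, 2, function(col) stats::sd(col) == 0)
  if (any(const)) {
    abort_ipdnmr(paste0("Constant covariate(s): ",
                        paste(covs[const], collapse = ", ")),
                 "ipdnmr_constant_covariate")
  }
  list(X = X, y = y)
}

new_risk_fit <- function(route, intercept, coefficients, penalty, selection,
                         prevalence, se = NULL, extra = list()) {
  structure(c(list(route = route, intercept = intercept,
                   coefficients = coefficients, penalty = penalty,
                   selection = selection, prevalence = prevalence,
                   se = se), extra),
            class = "risk_fit")
}

#' Fit the baseline-risk model with prespecified variables
#'
#' The second stage-1 route: no variable selection. A fixed set of
#' previously identified prognostic factors is entered into the logistic
#' model and the coefficients are shrunk by ridge-type penalized maximum
#' likelihood, maximizing `loglik - (penalty/2) * sum(beta_k^2)` over
#' standardized slopes (the intercept is unpenalized). The penalty is chosen
#' over `penalty_grid` as the value maximizing a modified Akaike information
#' criterion,
#' `LR chi-square(penalty) - 2 * edf(penalty)`, where the effective degrees
#' of freedom are `edf = trace(I_unpen %*% solve(I_pen)) - 1` (unpenalized
#' information times inverse penalized information, at the penalized
#' estimate; the constant intercept df is excluded). Standard errors come
#' from the sandwich form `solve(I_pen) %*% I_unpen %*% solve(I_pen)`.
#'
#' @param data A complete-case `ipd_tbl`.
#' @param variables Character vector naming the prespecified covariates.
#' @param penalty_grid Candidate ridge penalties (on the standardized
#'   scale); 0 gives the unpenalized maximum-likelihood fit.
#' @return A `risk_fit` (see [fit_lasso()]) whose `selection` element holds
#'   the penalty trace (penalty, effective df, modified AIC); `se` holds
#'   standard errors on the original scale.
#' @export
fit_prespecified <- function(data, variables = NULL,
                             penalty_grid = c(0, 2^seq(-2, 10))) {
  covs <- ipd_covariates(data)
  variables <- variables %||% covs
  miss <- setdiff(variables, covs)
  if (length(miss) > 0) {
    abort_ipdnmr(paste0("Prespecified variable(s) not in the table: ",
                        paste(miss, collapse = ", ")),
                 "ipdnmr_missing_column")
  }
  xy <- risk_design(data[, c("study", "treatment", "outcome", variables)] |>
                      restore_ipd(data, covariates = variables))
  X <- xy$X; y <- xy$y

  fits <- lapply(penalty_grid, function(lam) pml_logistic(X, y, lam))
  ll_null <- bernoulli_loglik(y, rep(logit(mean(y)), length(y)))
  trace <- tibble::tibble(
    penalty = penalty_grid,
    loglik = vapply(fits, `[[`, numeric(1), "loglik"),
    edf = vapply(fits, `[[`, numeric(1), "edf"),
    converged = vapply(fits, `[[`, logical(1), "converged")
  )
  trace$lr_chisq <- 2 * (trace$loglik - ll_null)
  trace$modified_aic <- trace$lr_chisq - 2 * trace$edf
  if (any(!trace$converged)) {
    warning("Penalized ML did not converge at penalty = ",
            paste(trace$penalty[!trace$converged], collapse = ", "),
            " (possible separation); those penalties are not considered.")
  }
  ok <- which(trace$converged)
  best <- ok[which.max(trace$modified_aic[ok])]
  chosen <- fits[[best]]
  new_risk_fit(route = "prespecified", intercept = chosen$intercept,
               coefficients = chosen$coefficients,
               penalty = penalty_grid[best], selection = trace,
               prevalence = mean(y), se = chosen$se)
}

# ridge-penalized logistic regression by Newton-Raphson on standardized
# covariates; returns original-scale coefficients, SEs and effective df
pml_logistic <- function(X, y, lambda, max_iter = 100, tol = 1e-10) {
  n <- nrow(X); p <- ncol(X)
  mu <- colMeans(X); s <- apply(X, 2, stats::sd)
  Xs <- sweep(sweep(X, 2, mu), 2, s, "/")
  Z <- cbind(`(Intercept)` = 1, Xs)
  pen <- c(0, rep(lambda, p))
  theta <- c(logit(mean(y)), rep(0, p))
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(Z %*% theta)
    pr <- inv_logit(eta)
    w <- pmax(pr * (1 - pr), 1e-10)
    grad <- drop(crossprod(Z, y - pr)) - pen * theta
    H <- crossprod(Z, Z * w) + diag(pen, p + 1)
    step <- tryCatch(solve(H, grad), error = function(e) NULL)
    if (is.null(step)) break
    # dampen huge steps (separation at small penalties)
    if (max(abs(step)) > 10) step <- step * 10 / max(abs(step))
    theta <- theta + step
    if (max(abs(step)) < tol) { converged <- TRUE; break }
  }
  eta <- drop(Z %*% theta)
  pr <- inv_logit(eta)
  w <- pmax(pr * (1 - pr), 1e-10)
  info_unpen <- crossprod(Z, Z * w)
  info_pen <- info_unpen + diag(pen, p + 1)
  inv_pen <- solve(info_pen)
  edf <- sum(diag(inv_pen %*% info_unpen)) - 1
  V_std <- inv_pen %*% info_unpen %*% inv_pen
  # map standardized-scale coefficients back to the original scale
  Tmat <- diag(1 / c(1, s))
  Tmat[1, -1] <- -mu / s
  theta_orig <- drop(Tmat %*% theta)
  V_orig <- Tmat %*% V_std %*% t(Tmat)
  nm <- colnames(X)
  list(intercept = theta_orig[1],
       coefficients = stats::setNames(theta_orig[-1], nm),
       se = stats::setNames(sqrt(diag(V_orig))[-1], nm),
       loglik = bernoulli_loglik(y, eta),
       edf = edf, converged = converged)
}

#' Per-patient baseline risk scores
#'
#' Applies a fitted stage-1 model to an IPD table, producing the logit
#' baseline risk `logit_risk = b0 + sum(b_k * x_k)` and the risk
#' `inv_logit(logit_risk)` for every patient, together with per-study means
#' of the logit risk — the centering constants used by the stage-2
#' meta-regression.
#'
#' @param data An `ipd_tbl` whose covariates include every coefficient name
#'   in `fit`, with no missing values among them.
#' @param fit A `risk_fit` from [fit_lasso()] or [fit_prespecified()].
#' @return A tibble of class `risk_scores` with columns `study`,
#'   `treatment`, `outcome`, `logit_risk`, `risk` (same row order as
#'   `data`); per-study means are available via [study_mean_logit_risk()].
#' @export
score <- function(data, fit) {
  stopifnot(inherits(data, "ipd_tbl"), inherits(fit, "risk_fit"))
  need <- names(fit$coefficients)
  miss <- setdiff(need, ipd_covariates(data))
  if (length(miss) > 0) {
    abort_ipdnmr(paste0("Covariate(s) required by the fit are absent: ",
                        paste(miss, collapse = ", ")),
                 "ipdnmr_missing_column")
  }
  X <- as.matrix(data[, need, drop = FALSE])
  if (anyNA(X)) {
    abort_ipdnmr("Missing covariate values; score() needs complete-case data.",
                 "ipdnmr_incomplete")
  }
  lp <- fit$intercept + drop(X %*% fit$coefficients)
  out <- tibble::tibble(study = data$study, treatment = data$treatment,
                        outcome = data$outcome,
                        logit_risk = lp, risk = inv_logit(lp))
  means <- out |>
    dplyr::group_by(.data$study) |>
    dplyr::summarise(mean_logit_risk = mean(.data$logit_risk), .groups = "drop")
  structure(out, study_means = means, route = fit$route,
            class = c("risk_scores", class(out)))
}

#' @rdname score
#' @param scores A `risk_scores` tibble.
#' @export
study_mean_logit_risk <- function(scores) attr(scores, "study_means")

#' @export
print.risk_fit <- function(x, ...) {
  nz <- sum(x$coefficients != 0)
  cat("<baseline risk model> route:", x$route,
      sprintf("| penalty %.4g | %d/%d nonzero slopes | prevalence %.3f\n",
              x$penalty, nz, length(x$coefficients), x$prevalence))
  invisible(x)
}

#' Tidiers for stage-1 risk model fits
#'
#' @param x A `risk_fit`.
#' @param ... Unused.
#' @return `tidy()`: one row per model term with `estimate` (original scale)
#'   and, for the penalized-ML route, `std.error`. `glance()`: a one-row
#'   model summary.
#' @method tidy risk_fit
#' @export
tidy.risk_fit <- function(x, ...) {
  out <- tibble::tibble(term = c("(Intercept)", names(x$coefficients)),
                        estimate = c(x$intercept, unname(x$coefficients)))
  if (!is.null(x$se)) out$std.error <- c(NA_real_, unname(x$se))
  out
}

#' @rdname tidy.risk_fit
#' @method glance risk_fit
#' @export
glance.risk_fit <- function(x, ...) {
  tibble::tibble(route = x$route, penalty = x$penalty,
                 n_terms = length(x$coefficients),
                 n_nonzero = sum(x$coefficients != 0),
                 prevalence = x$prevalence)
}
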