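test_that("unpenalized prespecified fit matches the closed-form cell logits", {
  # 10/40 events at x = 0, 30/40 at x = 1:
  # slope = logit(0.75) - logit(0.25), intercept = logit(0.25)
  df <- data.frame(study = rep(c("s1", "s2"), 40),
                   treatment = rep(c("A", "B"), each = 40),
                   outcome = c(rep(1, 10), rep(0, 30), rep(1, 30), rep(0, 10)),
                   x = rep(c(0, 1), each = 40))
  fit <- fit_prespecified(ipd_table(df), penalty_grid = 0)
  expect_equal(unname(fit$coefficients["x"]), 2.197225, tolerance = 1e-6)
  expect_equal(fit$intercept, -1.098612, tolerance = 1e-6)
})

test_that("infinite shrinkage collapses slopes to zero and the intercept to the prevalence", {
  tbl <- make_two_study_ipd(n = 400, seed = 2)
  fit <- fit_prespecified(tbl, penalty_grid = 1e7)
  expect_lt(max(abs(fit$coefficients)), 1e-3)
  expect_equal(fit$intercept, logit(mean(tbl$outcome)), tolerance = 1e-3)
})

test_that("penalized ML with modified-AIC tuning recovers known coefficients", {
  set.seed(31)
  n <- 20000
  X <- matrix(rnorm(n * 5), n, 5, dimnames = list(NULL, paste0("x", 1:5)))
  beta <- c(0.6, -0.4, 0.25, 0, -0.15)
  df <- data.frame(study = rep(c("s1", "s2"), each = n / 2),
                   treatment = rep(c("A", "B"), n / 2),
                   outcome = rbinom(n, 1, plogis(-0.5 + X %*% beta)), X)
  fit <- fit_prespecified(ipd_table(df))
  expect_true(all(abs(fit$coefficients - beta) < 3 * fit$se))
  # the penalty trace explored the grid and picked its maximizer
  expect_equal(fit$penalty,
               fit$selection$penalty[which.max(fit$selection$modified_aic)])
})

test_that("LASSO on pure-noise covariates selects a practically null model", {
  # With no signal the one-SE rule lands at (or next to) the null model.
  # Fold-level CV noise can leave a coefficient marginally active at the
  # chosen penalty, so the check is on the substance: a heavily penalized
  # fit whose predictions are essentially the prevalence.
  set.seed(7)
  n <- 5000
  df <- data.frame(study = rep(c("s1", "s2"), each = n / 2),
                   treatment = rep(c("A", "B"), n / 2),
                   outcome = rbinom(n, 1, 0.35),
                   x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n))
  tbl <- ipd_table(df)
  fit <- fit_lasso(tbl, seed = 5)
  expect_lt(max(abs(fit$coefficients)), 0.02)
  expect_equal(fit$intercept, logit(mean(df$outcome)), tolerance = 0.05)
  expect_lt(max(abs(score(tbl, fit)$risk - mean(df$outcome))), 0.02)
})

test_that("the zero-penalty endpoint matches unpenalized maximum likelihood", {
  tbl <- make_two_study_ipd(n = 800, seed = 9)
  fit <- fit_lasso(tbl, lambda = 0)
  g <- stats::glm(outcome ~ x1 + x2, stats::binomial(), data = tbl)
  expect_equal(unname(c(fit$intercept, fit$coefficients)),
               unname(stats::coef(g)), tolerance = 1e-4)
})

test_that("penalties at or above lambda_max zero every slope", {
  tbl <- make_two_study_ipd(n = 800, seed = 9)
  X <- as.matrix(tbl[, c("x1", "x2")])
  n <- nrow(X)
  Xs <- scale(X, scale = apply(X, 2, function(v) sqrt(mean((v - mean(v))^2))))
  lmax <- max(abs(crossprod(Xs, tbl$outcome - mean(tbl$outcome)))) / n
  for (lam in c(lmax, 2 * lmax)) {
    fit <- fit_lasso(tbl, lambda = lam)
    expect_true(all(abs(fit$coefficients) < 1e-10))
  }
})

test_that("LASSO selection is reproducible and roughly monotone in sparsity", {
  tbl <- make_two_study_ipd(n = 600, seed = 13)
  f1 <- fit_lasso(tbl, seed = 21)
  f2 <- fit_lasso(tbl, seed = 21)
  expect_identical(f1$coefficients, f2$coefficients)
  expect_identical(f1$penalty, f2$penalty)
  expect_identical(f1$selection, f2$selection)
  # active-set size does not shrink as the penalty decreases (up to jitter)
  nz <- f1$selection$nonzero[order(f1$selection$lambda, decreasing = TRUE)]
  expect_lte(sum(diff(nz) < 0), 2)
  expect_equal(unname(nz[1]), 0)
})

test_that("degenerate inputs are rejected", {
  tbl <- make_two_study_ipd(n = 100, seed = 3)
  const <- tbl
  const$x1 <- 1
  expect_error(fit_lasso(const, seed = 1), class = "ipdnmr_constant_covariate")
  onecls <- tbl
  onecls$outcome <- 1
  expect_error(fit_lasso(onecls, seed = 1), class = "ipdnmr_single_class")
  expect_error(fit_prespecified(tbl, variables = "nope"),
               class = "ipdnmr_missing_column")
})

test_that("scoring applies the linear predictor and records study means", {
  df <- data.frame(study = c("s1", "s1", "s2", "s2"),
                   treatment = c("A", "B", "A", "B"),
                   outcome = c(0, 1, 1, 0), x = c(2, 2, 2, 2))
  tbl <- ipd_table(df)
  flat <- ipdnmr:::new_risk_fit("prespecified", intercept = -0.5,
                                coefficients = c(x = 0), penalty = 0,
                                selection = NULL, prevalence = 0.5)
  sc <- score(tbl, flat)
  expect_equal(sc$logit_risk, rep(-0.5, 4))
  expect_equal(study_mean_logit_risk(sc)$mean_logit_risk, c(-0.5, -0.5))

  flat$intercept <- 0
  flat$coefficients["x"] <- 0.3
  sc2 <- score(tbl, flat)
  expect_equal(sc2$logit_risk[1], 0.6)
  expect_equal(sc2$risk[1], 0.6456563, tolerance = 1e-6)
})

test_that("mean fitted risk equals observed prevalence for the ML fit", {
  tbl <- make_two_study_ipd(n = 1000, seed = 17)
  fit <- fit_lasso(tbl, lambda = 0)
  sc <- score(tbl, fit)
  expect_equal(mean(sc$risk), mean(tbl$outcome), tolerance = 1e-6)
  # and stays close for the penalized routes
  fitp <- fit_prespecified(tbl)
  expect_equal(mean(score(tbl, fitp)$risk), mean(tbl$outcome), tolerance = 0.01)
})

test_that("the score is affine in the covariates", {
  tbl <- make_two_study_ipd(n = 300, seed = 23)
  fit <- fit_prespecified(tbl)
  sc <- score(tbl, fit)
  mean_patient <- tbl[1, ]
  mean_patient$x1 <- mean(tbl$x1)
  mean_patient$x2 <- mean(tbl$x2)
  sc_mean <- score(restore_ipd_for_test(mean_patient, tbl), fit)
  expect_equal(sc_mean$logit_risk, mean(sc$logit_risk))
})
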