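test_that("the linear predictor follows the arm-level mean structure", {
  expect_equal(linear_predictor(-0.5, 0, 0, 0, 0, TRUE), -0.5)
  expect_equal(inv_logit(linear_predictor(-0.5, 0, 0, 0, 0, TRUE)), 0.37754,
               tolerance = 1e-4)
  expect_equal(linear_predictor(-0.5, -1, 2, 0.5, 1, FALSE), 1.0)
  expect_equal(inv_logit(1.0), 0.7310586, tolerance = 1e-6)
  # effect modification vanishes at the study-mean risk
  expect_equal(linear_predictor(0.3, -0.9, 1.26, 0.25, 0, FALSE), 0.3 - 0.9)
})

test_that("reduce_to_nma disables the risk-score terms idempotently", {
  spec <- nmr_spec("CTRL", seed = 1)
  red <- reduce_to_nma(spec)
  expect_false(red$include_interaction)
  expect_identical(reduce_to_nma(red), red)
  expect_identical(red[setdiff(names(red), "include_interaction")],
                   spec[setdiff(names(spec), "include_interaction")])
})

test_that("two identical arms yield a null treatment effect", {
  # identical arms with exactly 2000/5000 events each: the empirical
  # log-OR is 0, so any posterior displacement is the sampler's own
  df <- data.frame(study = "trial",
                   treatment = rep(c("CTRL", "ACT"), each = 5000),
                   outcome = rep(rep(c(1, 0), c(2000, 3000)), 2),
                   x = 0)
  tbl <- ipd_table(df, reference = "CTRL")
  spec <- reduce_to_nma(fast_spec("CTRL", seed = 4))
  fit <- fit_nmr(tbl, rep(0, nrow(tbl)), spec)
  expect_lt(abs(mean(fit$draws$`delta[ACT]`)), 0.1)
})

test_that("the interaction-free model matches the closed-form 2x2 log-OR", {
  tbl <- sim_two_arm(4000, 0.40, 0.25, seed = 31)
  spec <- reduce_to_nma(fast_spec("CTRL", seed = 8))
  fit <- fit_nmr(tbl, rep(0, nrow(tbl)), spec)
  expect_lt(abs(mean(fit$draws$`delta[ACT]`) - log_or_2x2(tbl, "ACT")), 0.05)
})

test_that("fitting the full model on constant scores equals the reduced model", {
  tbl <- sim_two_arm(3000, 0.45, 0.30, seed = 41)
  sc <- rep(-0.4, nrow(tbl))
  full <- fit_nmr(tbl, sc, fast_spec("CTRL", seed = 2))
  red <- fit_nmr(tbl, sc, reduce_to_nma(fast_spec("CTRL", seed = 2)))
  expect_lt(abs(mean(full$draws$`delta[ACT]`) - mean(red$draws$`delta[ACT]`)),
            0.05)
})

test_that("derived contrasts obey consistency exactly for every draw", {
  sim <- simulate_ipd(default_ms_like_config(5))
  spec <- fast_spec("Placebo", seed = 5, iterations = 2000, burn_in = 400)
  fit <- fit_nmr(sim$data, sim$truth$logit_risk, spec)
  d <- fit$draws
  ct <- relative_effect(fit, "Natalizumab", vs = "GlatiramerAcetate")
  expect_identical(ct$log_or,
                   d$`delta[Natalizumab]` - d$`delta[GlatiramerAcetate]`)
  expect_identical(ct$interaction,
                   d$`gamma[Natalizumab]` - d$`gamma[GlatiramerAcetate]`)
  # vs the reference the contrast is the basic parameter itself
  expect_identical(relative_effect(fit, "Natalizumab")$log_or,
                   d$`delta[Natalizumab]`)
  # draw-count bookkeeping: chains x (iterations - burn_in) / thin
  expect_equal(nrow(d), spec$chains * (spec$iterations - spec$burn_in) / spec$thin)
})

test_that("within-study centering removes any constant score shift", {
  sim <- simulate_ipd(default_ms_like_config(6))
  tbl <- sim$data
  sc <- sim$truth$logit_risk
  spec <- fast_spec("Placebo", seed = 9, iterations = 1500, burn_in = 300)
  f1 <- fit_nmr(tbl, sc, spec)
  sc_shift <- sc + ifelse(tbl$study == "TRIAL2", 5, 0)
  f2 <- fit_nmr(tbl, sc_shift, spec)
  expect_equal(f1$draws, f2$draws)
})

test_that("a tight prior dominates the likelihood", {
  tbl <- sim_two_arm(1000, 0.45, 0.25, seed = 51)
  spec <- fast_spec("CTRL", prior_variance = 1e-6, seed = 3,
                    iterations = 1500, burn_in = 300)
  fit <- fit_nmr(tbl, rep(0, nrow(tbl)), reduce_to_nma(spec))
  expect_lt(abs(mean(fit$draws$`delta[ACT]`)), 0.01)
})

test_that("disconnected networks and single-arm studies are rejected", {
  df <- data.frame(study = rep(c("s1", "s2"), each = 4),
                   treatment = c("A", "A", "B", "B", "C", "C", "D", "D"),
                   outcome = rep(c(0, 1), 4), x = 0)
  tbl <- ipd_table(df, reference = "A")
  expect_error(fit_nmr(tbl, rep(0, 8), fast_spec("A")),
               class = "ipdnmr_disconnected")

  df2 <- df
  df2$treatment <- rep(c("A", "B"), each = 4)
  tbl2 <- ipd_table(df2, reference = "A", external = TRUE)
  expect_error(fit_nmr(tbl2, rep(0, 8), fast_spec("A")),
               class = "ipdnmr_single_arm")
})

test_that("the random-effects options estimate the same means on homogeneous data", {
  sim <- simulate_ipd(default_ms_like_config(10))
  spec <- fast_spec("Placebo", effect_model = "random", seed = 11,
                    iterations = 2500, burn_in = 500)
  fit <- fit_nmr(sim$data, sim$truth$logit_risk, spec)
  expect_true(all(c("sigma_d", "delta[Natalizumab]",
                    "d[TRIAL1:Natalizumab]") %in% names(fit$draws)))
  sd_post <- fit$draws$sigma_d
  expect_true(all(sd_post > 0 & sd_post < 5))
  # data are generated without between-study heterogeneity, so the
  # random-effects mean should land near the common-effects estimate
  common <- fit_nmr(sim$data, sim$truth$logit_risk,
                    fast_spec("Placebo", seed = 11, iterations = 2500,
                              burn_in = 500))
  expect_lt(abs(mean(fit$draws$`delta[DimethylFumarate]`) -
                  mean(common$draws$`delta[DimethylFumarate]`)), 0.25)
})

test_that("the posterior agrees with an independent Gibbs sampler (JAGS)", {
  tbl <- sim_two_arm(1500, 0.45, 0.30, seed = 61)
  set.seed(61)
  sc <- rnorm(nrow(tbl), 0, 0.6)  # an informative patient-level score
  fit <- fit_nmr(tbl, sc, fast_spec("CTRL", seed = 13, iterations = 6000,
                                    burn_in = 1000, thin = 5))

  model <- "
  model {
    for (i in 1:n) {
      y[i] ~ dbern(p[i])
      logit(p[i]) <- u + act[i] * delta + (g0 + act[i] * g1) * c[i]
    }
    u ~ dnorm(0, 0.001)
    delta ~ dnorm(0, 0.001)
    g0 ~ dnorm(0, 0.001)
    g1 ~ dnorm(0, 0.001)
  }"
  cc <- sc - mean(sc)
  jm <- rjags::jags.model(
    textConnection(model),
    data = list(y = tbl$outcome, act = as.numeric(tbl$treatment == "ACT"),
                c = cc, n = nrow(tbl)),
    inits = list(.RNG.name = "base::Mersenne-Twister", .RNG.seed = 7),
    n.chains = 1, quiet = TRUE)
  js <- rjags::coda.samples(jm, c("delta", "g0", "g1"), n.iter = 6000)
  jmean <- colMeans(as.matrix(js))
  expect_lt(abs(mean(fit$draws$`delta[ACT]`) - jmean[["delta"]]), 0.05)
  expect_lt(abs(mean(fit$draws$gamma0) - jmean[["g0"]]), 0.05)
  expect_lt(abs(mean(fit$draws$`gamma[ACT]`) - jmean[["g1"]]), 0.08)
})
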