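test_that("the anchor reduces to the event-rate logit under constant scores", {
  df <- data.frame(study = "ext", treatment = "CTRL",
                   outcome = rep(c(1, 0), c(44, 56)), x = 0)
  tbl <- ipd_table(df, reference = "CTRL", external = TRUE)
  anchor <- estimate_anchor(tbl, rep(1.3, 100))
  expect_equal(anchor$alpha, logit(0.44), tolerance = 1e-8)
  expect_equal(anchor$mean_logit_risk, 1.3)

  # duplicating the population changes nothing
  tbl2 <- restore_ipd_for_test(rbind(tbl, tbl), tbl)
  anchor2 <- estimate_anchor(tbl2, rep(1.3, 200))
  expect_equal(anchor2$alpha, anchor$alpha)
  expect_equal(anchor2$mean_logit_risk, anchor$mean_logit_risk)
})

test_that("anchoring on pooled reference arms recovers the pooled log-odds", {
  set.seed(71)
  df <- data.frame(study = rep(c("s1", "s2"), each = 300),
                   treatment = "CTRL",
                   outcome = rbinom(600, 1, 0.42), x = 0)
  tbl <- ipd_table(df, reference = "CTRL", external = TRUE)
  anchor <- estimate_anchor(tbl, rep(0, 600))
  expect_equal(anchor$alpha, logit(mean(df$outcome)), tolerance = 1e-8)
})

test_that("anchor input validation", {
  df <- data.frame(study = "s", treatment = c("CTRL", "ACT"),
                   outcome = c(0, 1), x = 0)
  tbl <- ipd_table(df, reference = "CTRL")
  expect_error(estimate_anchor(tbl, c(0, 0)), class = "ipdnmr_reference")
  df2 <- data.frame(study = "s", treatment = "CTRL", outcome = c(1, 1), x = 0)
  tbl2 <- ipd_table(df2, reference = "CTRL", external = TRUE)
  expect_error(estimate_anchor(tbl2, c(0, 0)), class = "ipdnmr_single_class")
})

test_that("patient predictions evaluate the anchored equation", {
  post <- nmr_posterior(
    data.frame(`delta[N]` = -1.22, gamma0 = 1.26, `gamma[N]` = -0.26,
               check.names = FALSE),
    treatments = c("Placebo", "N"), reference = "Placebo")
  anchor <- list(alpha = logit(0.37), mean_logit_risk = 0)
  # at the mean risk on the reference: inverse-logit(alpha) exactly
  ref <- predict_patient(0, "Placebo", anchor, post)
  expect_equal(ref$estimate, 0.37)
  expect_equal(ref$conf.low, ref$conf.high)
  # plug-in evaluation with published point estimates
  act <- predict_patient(0, "N", anchor, post)
  expect_equal(act$estimate, 0.1477678, tolerance = 1e-6)
  expect_error(predict_patient(0, "Unknown", anchor, post),
               class = "ipdnmr_treatment")
})

test_that("predictions increase with baseline risk when all slopes are positive", {
  set.seed(81)
  draws <- data.frame(`delta[B]` = rnorm(200, -0.5, 0.2),
                      gamma0 = runif(200, 0.8, 1.6),
                      `gamma[B]` = runif(200, 0.1, 0.5),
                      check.names = FALSE)
  post <- nmr_posterior(draws, treatments = c("A", "B"), reference = "A")
  anchor <- list(alpha = -0.2, mean_logit_risk = 0)
  grid <- seq(-2, 2, length.out = 9)
  preds <- predict_patient(grid, rep("B", 9), anchor, post)$estimate
  expect_true(all(diff(preds) > 0))
})

test_that("the reported odds ratio equals exp(delta + gamma * c) per draw", {
  set.seed(91)
  draws <- data.frame(`delta[B]` = rnorm(100, -0.9, 0.3),
                      gamma0 = rnorm(100, 1.2, 0.2),
                      `gamma[B]` = rnorm(100, 0.25, 0.2),
                      check.names = FALSE)
  post <- nmr_posterior(draws, treatments = c("A", "B"), reference = "A")
  anchor <- list(alpha = -0.4, mean_logit_risk = 0)
  for (cc in c(0, 1)) {
    pb <- ipdnmr:::patient_prob_draws(cc, "B", anchor, post)[, 1]
    pa <- ipdnmr:::patient_prob_draws(cc, "A", anchor, post)[, 1]
    or_draws <- (pb / (1 - pb)) / (pa / (1 - pa))
    expect_equal(or_draws,
                 exp(draws$`delta[B]` + draws$`gamma[B]` * cc),
                 tolerance = 1e-12)
  }
})

test_that("number needed to treat uses the ceiling convention", {
  expect_equal(nnt(0.84, 0.69), 7)
  expect_equal(nnt(0.93, 0.82), 10)
  expect_equal(nnt(0.5, 0.25), 4)
  expect_error(nnt(0.5, 0.5), class = "ipdnmr_nnt")
  expect_error(nnt(0.3, 0.5), class = "ipdnmr_nnt")
})

test_that("benefit summaries reproduce point arithmetic on a degenerate posterior", {
  # one draw, gammas zero: predictions are fixed probabilities
  post <- nmr_posterior(
    data.frame(`delta[DF]` = logit(0.84), `delta[N]` = logit(0.69),
               gamma0 = 0, check.names = FALSE),
    treatments = c("Placebo", "DF", "N"), reference = "Placebo")
  anchor <- list(alpha = 0, mean_logit_risk = 0.8)
  # one high-risk patient (baseline risk 0.69 > 0.5) at the mean score
  bt <- benefit_summary(0.8, treatments = c("DF", "N"), anchor = anchor,
                        posterior = post)
  high <- bt$pairs[bt$pairs$group == "risk > 50%", ]
  expect_equal(high$comparator, "DF")
  expect_equal(high$treatment, "N")
  expect_equal(high$benefit_pp, 15, tolerance = 1e-9)
  expect_equal(high$nnt, 7)
})

test_that("benefit summaries are permutation invariant and symmetric under ties", {
  set.seed(101)
  draws <- data.frame(`delta[B]` = rnorm(150, -0.6, 0.2),
                      `delta[C]` = rnorm(150, -0.6, 0.2),
                      gamma0 = rnorm(150, 1.0, 0.2),
                      check.names = FALSE)
  post <- nmr_posterior(draws, treatments = c("A", "B", "C"), reference = "A")
  anchor <- list(alpha = -0.3, mean_logit_risk = -0.5)
  lp <- rnorm(200, -0.5, 0.8)
  b1 <- benefit_summary(lp, anchor = anchor, posterior = post)
  b2 <- benefit_summary(sample(lp), anchor = anchor, posterior = post)
  expect_equal(b1$groups$estimate, b2$groups$estimate)
  expect_equal(b1$pairs$benefit_pp, b2$pairs$benefit_pp)

  # identical posteriors for B and C: zero differences, equal ORs
  draws$`delta[C]` <- draws$`delta[B]`
  post2 <- nmr_posterior(draws, treatments = c("A", "B", "C"), reference = "A")
  b3 <- benefit_summary(lp, anchor = anchor, posterior = post2)
  bc <- b3$pairs[b3$pairs$comparator %in% c("B", "C") &
                   b3$pairs$treatment %in% c("B", "C"), ]
  expect_true(all(abs(bc$benefit_pp) < 1e-9))
  g <- b3$groups
  expect_equal(g$or_vs_ref[g$treatment == "B"], g$or_vs_ref[g$treatment == "C"])
  expect_equal(g$or_vs_ref[g$treatment == "A"], rep(1, sum(g$treatment == "A")))
})

test_that("a single patient and treatment degenerates to predict_patient", {
  set.seed(111)
  draws <- data.frame(`delta[B]` = rnorm(100, -0.8, 0.3),
                      gamma0 = rnorm(100, 1.2, 0.3),
                      check.names = FALSE)
  post <- nmr_posterior(draws, treatments = c("A", "B"), reference = "A")
  anchor <- list(alpha = -0.2, mean_logit_risk = 0.1)
  bt <- benefit_summary(1.1, treatments = "B", anchor = anchor,
                        posterior = post)
  pp <- predict_patient(1.1, "B", anchor, post)
  expect_equal(bt$groups$estimate[bt$groups$group == "all"], pp$estimate)
  expect_equal(nrow(bt$pairs), 0)
})
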