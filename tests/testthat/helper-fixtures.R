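# shared fixtures, built in code

# a small two-study, two-arm IPD table with a logistic outcome
make_two_study_ipd <- function(n = 200, seed = 1,
                               beta = c(x1 = 0.8, x2 = -0.5), b0 = -0.4) {
  set.seed(seed)
  df <- data.frame(
    study = rep(c("s1", "s2"), each = n / 2),
    treatment = rep(c("A", "B"), n / 2),
    x1 = stats::rnorm(n),
    x2 = stats::rnorm(n)
  )
  df$outcome <- stats::rbinom(n, 1, stats::plogis(b0 + as.matrix(df[, c("x1", "x2")]) %*% beta))
  ipd_table(df)
}

# brute-force pair-counting oracle for the c-statistic
cstat_brute <- function(scores, outcomes) {
  ev <- scores[outcomes == 1]
  ne <- scores[outcomes == 0]
  tot <- 0
  for (a in ev) for (b in ne) {
    tot <- tot + (a > b) + 0.5 * (a == b)
  }
  tot / (length(ev) * length(ne))
}

# one randomized two-arm trial with fixed arm-level event probabilities
# (no covariate structure; scores are constant)
sim_two_arm <- function(n_per_arm, p_ref, p_act, seed,
                        ref = "CTRL", act = "ACT") {
  set.seed(seed)
  df <- data.frame(
    study = "trial",
    treatment = rep(c(ref, act), each = n_per_arm),
    outcome = c(stats::rbinom(n_per_arm, 1, p_ref),
                stats::rbinom(n_per_arm, 1, p_act)),
    x = 0
  )
  ipd_table(df, reference = ref)
}

# empirical log odds ratio of a two-arm table (the 2x2 oracle)
log_or_2x2 <- function(data, act) {
  a <- sum(data$outcome[data$treatment == act])
  b <- sum(data$treatment == act) - a
  c_ <- sum(data$outcome[data$treatment != act])
  d <- sum(data$treatment != act) - c_
  log(a * d / (b * c_))
}

# reattach IPD metadata after a plain-tibble subset
restore_ipd_for_test <- function(rows, from) ipdnmr:::restore_ipd(rows, from)

# short-chain sampler settings for unit tests
fast_spec <- function(reference, ..., iterations = 3000, burn_in = 500,
                      thin = 5, seed = 1) {
  nmr_spec(reference, ..., iterations = iterations, burn_in = burn_in,
           thin = thin, seed = seed)
}
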