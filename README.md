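# ipdnmr

Two-stage prediction of heterogeneous treatment effects from individual
patient data (IPD) across a network of randomized trials.

Treatments rarely work equally well for everyone. When IPD are available
from several trials comparing more than two treatments, a practical way to
estimate patient-specific benefit is to condense the baseline covariates
into a single prognostic score and let that score moderate the treatment
effects. `ipdnmr` implements this workflow for a binary outcome, end to
end, for biostatisticians and evidence-synthesis analysts:

1. **Stage 1 — baseline risk model.** A multivariable logistic model of the
   outcome, fitted on all trial arms pooled and blinded to treatment.
   Two routes: LASSO selection-plus-shrinkage tuned by 10-fold
   cross-validated AUC with the one-standard-error rule, or a prespecified
   variable set shrunk by ridge-type penalized maximum likelihood tuned by a
   modified AIC. Supporting tools: events-per-variable and minimum-sample-size
   checks, and bootstrap optimism-corrected internal validation
   (c-statistic and calibration slope, with the whole selection rerun in
   every resample).
2. **Stage 2 — Bayesian network meta-regression.** The logit risk score
   from stage 1, centered within each study, enters an IPD network
   meta-regression both as a prognostic factor and as a modifier of every
   relative treatment effect, under the consistency constraints.
3. **Prediction.** Anchored on a reference population (e.g. pooled placebo
   arms), the posterior converts a new patient's risk score into absolute
   outcome probabilities under every treatment, with risk-stratum summaries,
   odds ratios and numbers needed to treat (NNT).

## The model

For patient *i* in study *j* under treatment *t*, with baseline risk score
logit(R<sub>ij</sub>) and study baseline treatment *h<sub>j</sub>*:

```
Y_ij ~ Bernoulli(p_ijt)
logit(p_ijt) = u_j                     + g0 * c_ij                     if t = h_j
logit(p_ijt) = u_j + d_jh_jt + g0 * c_ij + g_jh_jt * c_ij              if t != h_j
```

where `c_ij = logit(R_ij) - mean_j(logit(R_ij))` is the within-study
centered risk score, the `u_j` are independent study nuisance intercepts,
and consistency ties every contrast to basic parameters versus the overall
reference: `d_jht = delta_t - delta_h`, `g_jht = gamma_t - gamma_h`
(common effects; random-effects options are available). Location parameters
get Normal(0, 1000) priors; sampling is by adaptive random-walk Metropolis
with a Laplace-informed proposal (2 chains × 10 000 iterations, 1000
burn-in, thinning 10 by default), with split-chain R-hat and effective
sample sizes reported.

Predictions for a new patient with score `logit(R)` on treatment *t* use

```
logit(p) = alpha + delta_t + (gamma0 + gamma_t) * (logit(R) - mean_logit_risk)
```

with `alpha` and `mean_logit_risk` estimated from a reference population
(`estimate_anchor()`).

## Worked example

The packaged simulator generates a three-trial, four-treatment network
(placebo-controlled, ~3600 patients, binary two-year outcome) with known
generating parameters, so the whole pipeline can be exercised without
access to patient data:

```r
library(ipdnmr)

sim    <- simulate_ipd(default_ms_like_config(seed = 1))
ipd    <- complete_case(sim$data)
fit    <- fit_prespecified(ipd)               # stage 1, penalized ML
scores <- score(ipd, fit)
c_statistic(scores$logit_risk, ipd$outcome)
#> [1] 0.7033301

spec <- nmr_spec("Placebo", seed = 1)         # stage 2
post <- fit_nmr(ipd, scores, spec)
print(tidy(post)[4:10, c("term", "estimate", "conf.low", "conf.high")], digits = 3)
#> # A tibble: 7 × 4
#>   term                     estimate conf.low conf.high
#>   <chr>                       <dbl>    <dbl>     <dbl>
#> 1 delta[DimethylFumarate]   -0.669   -0.864     -0.478
#> 2 delta[GlatiramerAcetate]  -0.722   -1.01      -0.413
#> 3 delta[Natalizumab]        -1.29    -1.61      -0.989
#> 4 gamma0                     1.03     0.874      1.19 
#> 5 gamma[DimethylFumarate]    0.0464  -0.215      0.305
#> 6 gamma[GlatiramerAcetate]   0.257   -0.0908     0.626
#> 7 gamma[Natalizumab]        -0.217   -0.556      0.121
```

`delta` are log odds ratios versus placebo at the study-mean risk score
(all three drugs reduce the odds of the outcome; the third treatment the
most), `gamma0` says a unit increase in logit risk raises the outcome odds
by a factor `exp(1.03) ≈ 2.8`, and the `gamma` terms are the (weak) effect
modifications. Predictions for a new patient with baseline risk 55%:

```r
anchor <- estimate_anchor(ipd[ipd$treatment == "Placebo", ],
                          scores$logit_risk[ipd$treatment == "Placebo"],
                          source = "pooled placebo arms")
predict_patient(logit(0.55), c("Natalizumab", "DimethylFumarate", "Placebo"),
                anchor, post)
#> # A tibble: 3 × 6
#>   logit_risk treatment         risk estimate conf.low conf.high
#>        <dbl> <chr>            <dbl>    <dbl>    <dbl>     <dbl>
#> 1      0.201 Natalizumab       0.55    0.313    0.242     0.390
#> 2      0.201 DimethylFumarate  0.55    0.513    0.454     0.572
#> 3      0.201 Placebo           0.55    0.664    0.634     0.693
```

Under placebo this patient's predicted outcome probability is 66%; the
third treatment brings it to 31%. Stratum-level absolute benefits and NNTs
come from `benefit_summary(scores, anchor = anchor, posterior = post)`;
in the high-risk stratum (baseline risk > 50%) of this simulation the
best active treatment beats the second-best by 21 percentage points
(NNT 5). `autoplot()` methods and `plot_benefit_curve()` draw the risk
distributions, posterior forest and absolute-benefit curves; `run_pipeline()`
chains every step and writes each artifact to disk, and
`inst/cli/ipdnmr.R` exposes `simulate`, `check-size` and `run-all`
subcommands for shell use.

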