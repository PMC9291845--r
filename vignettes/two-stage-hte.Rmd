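---
title: "Two-stage prediction of heterogeneous treatment effects: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage prediction of heterogeneous treatment effects: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ipdnmr)
```

## The problem and the modelling strategy

Randomized trials estimate average treatment effects, but patients differ:
a drug that prevents the outcome in one patient may add little for another.
Estimating covariate-by-treatment interactions one covariate at a time in a
meta-analysis is underpowered and invites false subgroup discoveries. The
risk-modelling alternative condenses all baseline covariates into one
dimension — the predicted *baseline risk* of the outcome, ignoring
treatment — and then asks how the relative and absolute effects of each
treatment vary along that single dimension.

`ipdnmr` implements this as two separate stages, deliberately decoupled:

* **Stage 1 (frequentist):** a penalized multivariable logistic model of
  the binary outcome on baseline covariates, fitted on all randomized
  patients pooled and blinded to treatment. Pooling all arms (rather than
  control arms only) preserves the effective sample size and, crucially,
  avoids the differential-fit artifact by which a model trained only on
  controls can make an inert treatment look beneficial in high-risk
  patients and harmful in low-risk ones.
* **Stage 2 (Bayesian):** an individual-patient-data network
  meta-regression in which the stage-1 logit risk score, centered within
  each study, acts both as a prognostic factor and as a modifier of every
  relative treatment effect.

Keeping the stages separate lets stage 1 use the mature penalization
tooling of frequentist prediction modelling, and makes stage 2 rerunnable
without refitting stage 1. The price is that stage-2 posteriors treat the
risk score as known; the uncertainty of the stage-1 coefficients is not
propagated, so downstream credible intervals are somewhat too narrow. A
joint one-stage formulation would fix this and is out of scope here.

## Stage 1: the baseline risk model

With covariates $x_{ijk}$ for patient $i$ in study $j$,

$$Y_{ij} \sim \text{Bernoulli}(R_{ij}), \qquad
\text{logit}(R_{ij}) = \beta_0 + \sum_k \beta_k x_{ijk},$$

with a single intercept and coefficient vector across studies (the
common-coefficient variant; study-specific or hierarchical coefficients are
a possible extension and the API reserves no behaviour for them). Two
fitting routes are provided.

**LASSO route** (`fit_lasso()`): selection and shrinkage by the L1
penalty. The penalty path has 100 log-spaced values, starting 25% above the
smallest full-sample penalty that zeroes every slope and descending to
0.001 of it; the headroom keeps the null model inside the path for every
cross-validation fold, whose own all-null penalty can exceed the full-sample
value. Folds (10 by default) are stratified by outcome and drawn from the
user's seed, so a fit is exactly reproducible. The criterion is
cross-validated AUC, and the chosen penalty is the largest one whose CV AUC
is within one standard error of the maximum — the usual parsimony-favouring
reading of the one-SE rule when the criterion is maximized. Covariates are
standardized internally; coefficients are reported on the original scale
and the intercept is never penalized.

**Prespecified route** (`fit_prespecified()`): no selection; a fixed set of
previously identified prognostic factors, shrunk by ridge-type penalized
maximum likelihood, maximizing $\ell(\beta) - \tfrac{\lambda}{2}\sum_k
\beta_k^2$ over standardized slopes. The penalty is chosen over a grid
(default $0, 2^{-2}, \dots, 2^{10}$) to maximize a modified AIC,

$$\text{AIC}_m(\lambda) = \chi^2_{LR}(\lambda) - 2\,\text{edf}(\lambda),
\qquad \text{edf} = \operatorname{tr}\!\left(I_{\text{unpen}}
I_{\text{pen}}^{-1}\right) - 1,$$

i.e. the likelihood-ratio statistic against the intercept-only model minus
twice the effective degrees of freedom (the trace of the unpenalized
information times the inverse penalized information, both at the penalized
estimate; the intercept's constant unit of df is excluded, which shifts the
criterion by a constant and leaves the maximizer unchanged). Standard
errors use the sandwich form $I_{\text{pen}}^{-1} I_{\text{unpen}}
I_{\text{pen}}^{-1}$. This exact trace-based definition of the effective
df, and the grid, are this package's concrete choices; "modified AIC" is
used loosely in the prediction-modelling literature.

Before fitting, `compute_epv()` and `riley_min_n()` judge whether the
sample can support the candidate model. `riley_min_n()` evaluates three
published criteria for a binary-outcome model — expected global shrinkage
at least $S$ (default 0.9), apparent-fit optimism at most 0.05, and a
precise overall-risk estimate ($\pm$0.05 with $z = 1.96$) — and takes the
maximum. The anticipated fit may be given as a Cox–Snell $R^2$ or as the
more commonly reported Nagelkerke $R^2$, converted internally via the
maximum attainable Cox–Snell value at the stated prevalence,
$R^2_{\max} = 1 - \exp(2\bar\ell_{null})$. The conversion matters: rounding
the Cox–Snell value to two decimals before applying the criteria changes
the required $n$ by tens of patients, so the unconverted Nagelkerke input
is preferred when that is what was specified.

Data preparation mirrors standard prediction-modelling practice and is
explicit rather than automatic: covariates with a missing fraction strictly
above 50% are dropped; of any covariate pair with $|r| > 0.7$ the one later
in a user-supplied priority order is dropped (the priority list stands in
for subject-matter judgement, defaulting to column order); remaining
records with any missing value are removed (complete case), which assumes
missingness unrelated to outcome risk; per-covariate log transforms are
available in the reader configuration but nothing is transformed
automatically. Categorical covariates are expanded to indicators with
alphabetically ordered levels (first level as baseline) *before*
correlation pruning, so pruning acts on the columns the model will actually
see.

Internal validation (`bootstrap_validate()`) follows the optimism-bootstrap
recipe: the entire fitting procedure, selection included, is rerun on each
of $B$ (default 500) patient-level resamples; each resampled model is
scored on its own sample and on the original sample; the averaged
difference is subtracted from the apparent c-statistic and calibration
slope. Resampling ignores study membership — a cluster bootstrap would be a
defensible alternative, but patient-level resampling matches the common
single-dataset practice and keeps the selection-rerun interpretation clean.
Degenerate resamples (single-class outcome) are redrawn, up to ten
attempts, so $B$ stays fixed.

## Stage 2: the network meta-regression

Let $h_j$ be study $j$'s baseline treatment (the overall reference when the
study includes it, otherwise its alphabetically first arm) and
$c_{ij} = \text{logit}(R_{ij}) - \overline{\text{logit}(R_{ij})}_j$ the
within-study centered risk score. Then

$$\text{logit}(p_{ijt}) =
\begin{cases}
u_j + \gamma_0\, c_{ij} & t = h_j\\
u_j + d_{jh_jt} + \gamma_0\, c_{ij} + g_{jh_jt}\, c_{ij} & t \ne h_j
\end{cases}$$

with consistency $d_{jh_jt} = \delta_t - \delta_{h_j}$ and
$g_{jh_jt} = \gamma_t - \gamma_{h_j}$, $\delta_{\text{ref}} =
\gamma_{\text{ref}} = 0$, built into the design matrix, so derived
contrasts satisfy the consistency equations *exactly for every posterior
draw* — this is a structural property, not a statistical one, and the test
suite asserts it as an identity. The $u_j$ are independent fixed-effect
nuisance intercepts (each with its own vague prior), which protects
randomization: no information flows between arms through a shared baseline
model. $\gamma_0$ is common across studies. Centering uses the mean of the
fitted scores over each study's analyzed patients; because the centering is
internal, adding any constant to a study's scores changes nothing in the
treatment parameters (also asserted exactly in the tests, by refitting with
shifted scores under the same seed).

Common effects are the default for both $d$ and $g$ — with a handful of
studies a between-study variance is barely estimable. The random-effects
options draw study contrasts around the consistency means with SDs
$\sigma_D, \sigma_G \sim \text{Uniform}(0, 5)$; multi-arm studies get
independent contrasts (the usual 0.5-correlation refinement for multi-arm
trials is not implemented).

Priors on all location parameters are Normal with mean 0 and **variance**
1000 (SD $\approx 31.6$). Samplers differ in whether the second argument of
a normal is a variance or a precision; the package treats the stated value
as a variance and exposes it (`prior_variance`), so a precision reading is
one argument away.

**Sampler.** The common-effects posterior is a Bernoulli GLM posterior, so
the package samples it with an adaptive random-walk Metropolis whose
proposal covariance is the Laplace approximation at the ridge-stabilized
mode, scaled by $2.38^2/p$ and adapted toward a 0.3 acceptance rate during
burn-in only (adaptation then stops, so retained draws come from a fixed
kernel). Chains start at $\delta = \gamma = 0$ with $u_j$ at the observed
baseline-arm log odds (continuity-corrected), jittered across chains.
Under the random-effects options the study contrasts join the Metropolis
block, the consistency means are updated by their conjugate Gibbs draws and
the SDs by Metropolis on their uniform support. Defaults are 2 chains of
10 000 iterations, 1000 burn-in, thinning 10 — i.e.
`chains * (iterations - burn_in) / thin` retained draws — with split-chain
R-hat and effective sample size per parameter and a warning when any R-hat
exceeds 1.05. The contract is distributional, not sampler-specific: the
test suite checks the posterior against a closed-form 2×2 log odds ratio
when the score terms are disabled, and against an independent Gibbs sampler
(JAGS) on a two-arm meta-regression.

## Absolute predictions, strata, NNT

For a new patient with score $\text{logit}(\tilde R)$ on treatment $t$:

$$\text{logit}(p) = \alpha + \delta_t + (\gamma_0 + \gamma_t)
(\text{logit}(\tilde R) - \overline{\text{logit}(R)}),$$

where $\alpha$ (the logit outcome probability on the reference treatment at
the population-mean score) and $\overline{\text{logit}(R)}$ come from an
anchoring population — pooled placebo arms, a registry, or the network's
own reference arms (`estimate_anchor()` fits a logistic intercept on the
centered score). The anchor is a fixed plug-in: its sampling uncertainty is
not propagated, consistent with the two-stage design, and is typically
dwarfed by the posterior spread of $\delta_t$.

`benefit_summary()` reports, per risk stratum (defaults: all patients,
baseline risk `< 0.30`, `> 0.50` — illustrative cutpoints, fully
configurable), the *marginal* predicted probability per treatment: the
average over the stratum's patients of each patient's posterior-mean
probability, rather than the probability at the stratum's mean risk. The
marginal summary answers "what fraction of this group would experience the
outcome", which is the population-level reading of absolute benefit; the
probability-at-mean-risk alternative is available through
`predict_patient()` at any chosen score. Group odds ratios versus the
reference are posterior means of $\exp(\delta_t + \gamma_t \bar c)$ at the
group's mean centered score — an algebraic identity of the prediction
equation per draw. NNTs round the reciprocal risk difference *up*
(`ceiling(1 / (risk_a - risk_b))`): an NNT is a count of treated patients,
and rounding down would overstate the benefit. NNTs are reported only where
the risk difference is positive.

## The simulator and what passing tests show

`simulate_ipd()` draws multi-trial IPD with every generating parameter
known: covariates from correlated latent normals (binary covariates by
thresholding at the configured rate), uniform randomization within each
study's arm list, the true logit risk from the stage-1 equation, and
outcomes from the stage-2 mean structure at the *true* centered score. The
centering constant is the analytic mean of the risk score under the
covariate distribution, so the generative model is exactly the model being
fitted. Missingness, when configured, is injected completely at random,
matching the complete-case assumption of the preprocessing filters.

`default_ms_like_config()` packages the study conditions used throughout
the tests: three placebo-controlled trials of 939/1417/1234 patients with
2/3/2 arms over four treatments; eight covariates with trial-to-trial
shifts in age and disability score; placebo-arm log odds 0.26/−0.36/−0.22;
active-treatment log odds ratios −0.89/−0.71/−1.22; prognostic coefficient
$\gamma_0 = 1.26$ with interactions 0.25/0.23/−0.26; and 3% missingness on
two quality-of-life covariates. These values emulate the scale of a real
relapsing–remitting multiple sclerosis trial network (overall event rate
about one third, risk-score SD about 0.6 on the logit scale).

The recovery suite fits the stage-2 model to 20 such replicates (shortened
chains, 2 × 4000 iterations) using the simulator's true scores, and asks
that each parameter's 95% credible interval cover its generating value in
at least 90% of replicates. True scores are used deliberately: the stage-2
estimands are defined with respect to the true centered score, and feeding
estimated scores would change the target through measurement-error
attenuation (visible in practice as $\hat\gamma_0$ shrinking toward
$\gamma_0 \times$ the reliability of the score). What these passing tests
show is that the estimation machinery is calibrated under its own
assumptions at a realistic scale; they cannot show that the logistic risk
model or the single-score effect-modification structure is adequate for any
particular real dataset, that complete-case filtering is harmless under
informative missingness, or how the pipeline behaves under the richer
covariate distributions of real trials.

## Numerical and design notes

* Problem sizes in the test suite are chosen to keep the full suite in the
  minutes range: recovery replicates use the packaged ~3600-patient
  network with shortened chains; oracle checks use 3–10k patients where a
  closed form is the comparator.
* The Newton solver for penalized ML caps step lengths (guarding
  separation at small penalties) and reports non-convergence per penalty;
  non-converged grid points are excluded from the modified-AIC choice with
  a warning.
* `fit_lasso(lambda = 0)` extracts exact coefficients at the unpenalized
  endpoint (tested to 1e-4 against IRLS/`glm`); penalties at or above the
  all-null threshold reproduce the null model exactly.
* Bernoulli log-likelihoods use a log1p-based form stable for extreme
  linear predictors.
* Degenerate inputs fail loudly with classed conditions: constant
  covariates, single-class outcomes, single-arm studies, disconnected
  treatment networks, non-complete-case data reaching `score()`.
* With constant scores the interaction columns vanish; those parameters
  then simply return their priors, and the fitted $\delta$ match the
  score-free model (tested). A ridge term $1/\text{prior variance}$ keeps
  the proposal covariance well-defined in that case.
* Ties in the c-statistic count one half, making it the Wilcoxon/AUC
  statistic exactly; an exhaustive pair-counting oracle confirms this on
  small fixtures.
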