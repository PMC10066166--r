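---
title: "Multilevel moderated mediation of minority stress: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multilevel moderated mediation of minority stress: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stigmamed)
```

## The scientific question

Sexual and gender minority (SGM) adults report more depression than the
general population, and minority-stress theory attributes part of that
excess to stressors operating at several levels at once: structural
(discriminatory laws and hostile public attitudes), interpersonal
(victimization), and individual (concealment versus disclosure of one's
identity). `stigmamed` implements a 1-1-1 multilevel mediation and
moderated-mediation analysis of this system: respondents (level 1) nested
in countries (level 2), with community participation as the level-1
predictor, identity disclosure and victimization as level-1 mediators,
single-item depression as the level-1 outcome, and a country-level
structural-stigma composite moderating the predictor-to-mediator paths.

## Measurement model

Raw survey items are coded deterministically:

* **Community participation (cp)** — mean of four 0/1 involvement items
  (active member/volunteer, regular contact, follows activities, financial
  supporter), so cp lies on the grid 0, 0.25, 0.5, 0.75, 1.
* **Victimization** — frequency of physical or sexual attack over five
  years, coded 0/1/2/4/8/11/15 for the seven ordered categories (the codes
  approximate category midpoints), then dichotomized to 0 = never,
  1 = at least once, because the frequency distribution is heavily skewed.
* **Identity disclosure** — openness (0 = none to 3 = all) toward eight
  target groups, averaged over the groups that apply to the respondent;
  when no group applies the score is missing and the row is removed by
  listwise deletion (a zero denominator has no defensible imputation).
* **Depression** — the single downhearted/depressed item, ordinal 0-5.
* **Covariates** — age in years, ethnic-minority status (0/1), and income
  band mapped to 1-6 and entered as numeric. Age enters as continuous
  years by default (bands discard information and are only descriptive in
  the source tables); ordinal-as-numeric income is the minimal assumption
  in the absence of a stated contrast coding.

Unknown category labels are an error, never silently coerced to missing:
silent coercion hides dialect drift between survey exports.

Subgroups are mutually exclusive and exhaustive over retained respondents:
a current trans or non-binary identity, or an affirmative trans-history
answer, classifies a respondent as a gender minority regardless of sexual
orientation; remaining heterosexual respondents and respondents under 18
are excluded; the rest are sexual minority men or women by gender item.

## The structural-stigma composite

For each country, protective laws and policies are scored 1 point when in
force nationally and 0.5 when only regional, summed over five domains
(equality and non-discrimination, family, hate crime and hate speech,
civil society space, asylum) for the sexual-orientation variant; the
gender-identity variant adds a sixth domain (legal gender recognition and
bodily integrity) that applies to gender minorities only. The policy sum
and the country's mean public-comfort attitude score (10-point scale) are
each z-scored across the included countries, averaged, and sign-inverted,
so higher scores mean more structural stigma. Two numerical choices are
deliberate:

* z-scores use the sample (n-1) standard deviation — with 28 countries the
  n versus n-1 choice moves composites in the third decimal, so it is
  fixed and documented rather than left to chance;
* the standardization population is exactly the set of countries in the
  input tables; any subsetting happens after composition, never before,
  so the composite mean over included countries is 0 (enforced to 1e-9).

The composite is invariant to positive affine rescaling of the attitude
instrument and antisymmetric under sign flips of both inputs; both
properties are tested. The itemized law table is user-supplied rather than
vendored (licensing and version drift of the annual index); tests ship a
small fixture table.

## Estimation: the three-model sequence

All level-1 predictors are decomposed into within and between components
by group-mean centering (`x_w = x - mean_j(x)`, `x_b = mean_j(x)`), and
within-level effects are the reported estimands. Three equations are
fitted per model stage — one per mediator and one for the outcome — as
separate Gaussian linear mixed models by maximum likelihood (never REML,
so likelihood-ratio tests across fixed-effect changes are valid). The
binary victimization mediator is fitted as a linear-probability mixed
model, matching the estimand of the linear-only macro tradition this
analysis follows; fitted probabilities outside [0, 1] raise a warning.
Estimation is delegated to `lme4::lmer` behind the package's model-spec
interface, with the zero-random-effect case collapsing to ordinary least
squares; `nlme` serves as an independent cross-check in the test suite.

* **Model 1**: fixed effects only in the mediator equations
  (`m ~ cp_w + cp_b + age + ethnicity + income`), and the outcome equation
  (`dep ~ cp_w + cp_b + m1_w + m1_b + m2_w + m2_b + covariates`) with a
  country random intercept.
* **Model 2**: adds to each mediator equation a random intercept and a
  random slope on `cp_w`, with *diagonal* covariance — 4 new variance
  parameters, hence the 4-df likelihood-ratio test against model 1.
* **Model 3**: adds the stigma moderator, its cross-level interaction
  `cp_w x stigma`, and the country covariates (GDP-PPP, Democracy Index,
  HDI) to each mediator equation, and stigma plus the interaction to the
  outcome equation — 12 new fixed effects, hence the 12-df test.

Two design choices here were genuinely open and deserve their rationale:

* **Diagonal random-effect covariance by default.** A free
  intercept-slope covariance is a config switch (`diagonal = FALSE`), but
  the default is diagonal because the 4-df accounting of the model-2
  comparison (two mediator equations, each adding exactly one intercept
  and one slope variance) is only coherent without covariances.
* **The outcome equation keeps a country random intercept in every model,
  including model 1.** Model 3 introduces country-level fixed effects into
  the outcome equation; if the outcome were fitted as if respondents were
  independent, any real between-country outcome variance would inflate
  the likelihood-ratio statistic for those terms by roughly the design
  effect — in null simulations the 12-df test rejected at several times
  its nominal size. With the intercept present throughout, the model-2
  comparison still adds only the 4 mediator-equation variances, and the
  size simulations hold at or below nominal. The b-paths and the direct
  effect remain fixed (no random slopes on the outcome), so indirect
  effects need no slope-covariance correction term.

LR statistics are `2 * delta-loglik` clamped at zero against the naive
chi-square reference; for the model-2 comparison the tested variances sit
on the boundary of the parameter space, so the naive reference is
anti-conservative there (no 50:50 mixture correction is applied, matching
the plain `delta-chi2(df)` reporting convention this pipeline follows).

## Derived quantities

With `a` the within a-path (model 1), `a3` the cross-level interaction
(model 3), `b` the within b-path, and `tau1^2` the model-2 random-slope
variance, the pipeline computes, per mediator:

* indirect effect `a * b`, since b is fixed;
* variance of country-specific indirect effects `tau1^2 * b^2` and its
  square root;
* index of moderated mediation `a3 * b`;
* conditional indirect effects `(a + a3 * m) * b` at moderator probes `m`.

A single `b` per subgroup — the model-1 estimate — is used in every
product, so the index is exactly the difference of conditional effects one
moderator unit apart; the printed-coefficient worked examples in the test
suite confirm the published summary tables are internally consistent with
this convention. Probes default to the respondent-weighted moderator mean
plus/minus one standard deviation; a country-level alternative and fully
explicit probes are config switches, because the probe population is a
reporting choice, not an estimation one.

**Monte-Carlo confidence intervals.** Symmetric normal-theory intervals
are inappropriate for products of coefficients, so intervals are empirical
percentiles of the transform applied to draws from a multivariate normal
centred at the estimates: 10,000 draws and 95% level by default, seeded
and reproducible, percentile (not bias-corrected) bounds. Mediator- and
outcome-equation parameters are drawn as independent blocks because the
equations share no parameters and are fitted separately; within an
equation the fitted covariance is used (the `a`-`a3` covariance matters
for conditional effects). This is an approximation to a jointly fitted
system; it leaves point estimates unchanged under independent errors.

## The synthetic generator

Real microdata of this kind are restricted, so the package ships a
generator that emulates exactly the structure the estimator assumes:
countries with a Normal moderator `W_j`, independent Normal random
intercepts and slopes, participation as the mean of four Bernoulli items
with country-varying propensity (so cp sits on its 5-point grid),
mediator linear predictors `a * cp_w + a3 * cp_w * W_j + covariates +
u0_j + u1_j * cp_w`, and an outcome with direct effect, both b-paths, and
a country intercept. Default true values sit at the magnitudes this
literature reports (a about 0.89 and 0.16, b about -0.21 and 0.47, slope
sds 0.23 and 0.06, standardized moderator); cluster count defaults to 28.
Residual and intercept scales (sigma around 0.85-1.1, tau0 0.1-0.3) are
the package's choice of realistic survey noise.

Two modes separate estimator correctness from measurement mismatch:

* **idealized** — every equation Gaussian (victimization as a Gaussian
  latent), satisfying all estimator assumptions, used for recovery,
  coverage and size simulations;
* **survey** — disclosure clipped to [0, 3], victimization Bernoulli of
  the clipped-[0, 1] linear predictor (clip rate logged, warning above
  10%), depression rounded and clipped to 0-5 — used to exercise the
  coding and IO path end to end.

What passing tests on idealized data do *not* show: robustness to the
clipping/rounding bias of bounded outcomes, to the real survey's open
web-recruitment selection, to item nonresponse, or to realistic
country-size imbalance. The generator makes no claim to emulate those.

One subtlety the recovery tests encode: the model-2 random-slope variance
consistently estimates the *total* between-country slope spread
`a3^2 * sd_W^2 + tau1^2`, because model 2 omits the moderator; only after
model 3 partials the moderator out does the slope variance target `tau1^2`
itself.

## Simulation sizes and tolerances

The verification suite uses problem sizes chosen to make each check
informative at reasonable cost: parameter recovery averages 50 idealized
replicates of 28 countries x 500 respondents (absolute fixed-effect bias
below 0.01; slope-sd within 15%); interval coverage uses 200 replicates
at 28 x 300 (nominal 95%, accepted within [0.91, 0.99]); likelihood-ratio
size uses 200 null replicates at 28 x 100 (rejection at alpha = 0.05 at
most 10%). The 0.01 bias threshold is of the same order as the
Monte-Carlo standard error that 50 replicates permit for the a-path
(whose replicate-to-replicate spread is dominated by the tau1 = 0.23
slope draws over 28 countries), so the bias check is a noise-floor check
as much as a bias check; the coverage and size checks are the sharper
instruments. Optimizer convergence follows lme4 defaults with a
Nelder-Mead retry; degenerate inputs (constant predictors, a single
cluster, incomplete rows, zero-dispersion composites) fail loudly before
fitting.

## A worked run

```{r example, eval = FALSE}
params <- generative_params(n_countries = 28, n_per_country = 300,
                            seed = 42)
dataset <- generate_synthetic(params)
result <- run_sequence(dataset$data,
                       config = mediation_config(n_draws = 10000))
print(result)
true_effects(params) # generator truth for comparison
```

`run_pipeline()` drives the same sequence from CSV inputs (raw respondent
items, itemized laws, attitude means, country covariates) to per-subgroup
JSON results, model-summary and conditional-effect TSVs, and a manifest;
outputs are byte-identical under a fixed seed, and rounding to 4 decimals
happens only at the report layer.

## Known limitations

* The victimization equation is a linear-probability model by design;
  logistic mediator models are out of scope, so mediator effects are
  probability differences and can imply out-of-range fitted values.
* Cross-equation parameter covariance is zero by construction; a jointly
  estimated system would produce slightly different interval widths.
* The naive chi-square reference for variance-component tests is
  anti-conservative at the boundary.
* Between-country (level-2) indirect effects are estimated incidentally
  but not reported as substantive output; within-level effects are the
  target.
* Published score ranges of the stigma composite depend on external
  source tables (itemized 2019 law index, attitude survey means) that the
  package does not vendor; with user-supplied tables the construction is
  reproducible, and its scale-free properties are what the tests enforce.
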