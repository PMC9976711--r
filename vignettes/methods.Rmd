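---
title: "Methods: modelling realized alcohol resistance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: modelling realized alcohol resistance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Familial and polygenic loading are strong risk factors for alcohol use
disorder (AUD), yet many adolescents at high genetic risk never develop
problems.  *Realized resistance* reframes the usual risk analysis: among
high-risk individuals, what predicts a healthier-than-expected outcome?
`alcres` operationalizes resistance for three milestones — alcohol
initiation, heavy episodic drinking (HED; five or more drinks in 24 hours)
and AUD diagnosis — and models its social-relationship predictors measured
in adolescence: mother- and father-child relationship quality, parental
monitoring, peer drinking, romantic partner drinking and social competence.

## The resistance phenotypes

For initiation and HED, resistance is a *deviance residual* from a
family-clustered Cox proportional-hazards model of onset age with the
genetic-risk indices (family history density, standardized polygenic score)
as predictors and baseline age, sex, nuisance ancestry covariates and the
two parental-data indicators as covariates.  Writing $\delta_i$ for the
event flag, $t_i$ for the event/censoring age and $\eta_i$ for the linear
predictor,

$$M_i = \delta_i - \hat\Lambda_0(t_i)\,e^{\eta_i}, \qquad
D_i = \operatorname{sign}(M_i)\sqrt{-2\left[M_i + \delta_i\log(\delta_i - M_i)\right]},$$

with the log term dropped when $\delta_i = 0$.  A positive $D_i$ means the
subject's onset came *sooner* than their genetic risk predicted — low
resistance; negative means later than expected — high resistance.  Because
$M_i \le \delta_i$, right-censored subjects always have $D_i \le 0$; this
skew is why the binary AUD milestone is instead *rule-coded*: affected (0)
when diagnosed at age 15 or older, resistant (1) when a drinker followed
through age 23 never met criteria, missing otherwise (non-drinkers, or
insufficient follow-up — subjects still inside the peak risk window must
not be misread as unaffected).

Family clustering is handled with a family-shared gamma frailty estimated
by penalized partial likelihood (`cluster_mode = "gamma_frailty"`), with a
cluster-robust ordinary Cox fit as the alternative.  The published analysis
says only "mixed effects Cox models"; the frailty family is not stated, so
gamma — the standard penalized-partial-likelihood choice — is the default
and the robust mode is retained for sensitivity.  Likewise unstated is
whether residuals condition on the estimated family effect; the default
includes the log-frailty in $\eta_i$ (`conditional = TRUE`), with the
marginal version available.  Ties use Breslow by default because it matches
the closed-form residual oracle in the tests; Efron is available.  Models
are fitted separately within each ancestry group (phenotypes derived
per-ancestry to avoid stratification artefacts) and residuals are pooled.

## Genetic-risk indices

Family history density aggregates log-transformed maximum AUD symptom
counts over first- and second-degree relatives with weights 0.5 and 0.25.
The published description does not pin the normalization or log base; the
default is the *weighted mean* $\sum_r w_r \log(1+s_r) / \sum_r w_r$ with
natural logs, and the raw weighted sum is selectable
(`fhd_form = "weighted_sum"`), as both are defensible readings of
"weighted according to degree of relatedness".  The weighted-mean default
has the property that adding an unaffected relative *dilutes* the score.
The polygenic score is standardized within ancestry group before pooling.
High genetic risk — the gate into the AUD analysis subsample — is
FHD > 0 *or* top quartile of the standardized score (interpolated 75th
percentile, ties at the cut included; subjects missing the score are
assessed on the family-history criterion only).

## Measurement models and scoring

Each instrument is scored by its stated rule (sums; reverse-coded sum for
monitoring; closeness standardizes its two differently-scaled items before
averaging).  Whether the original closeness standardization used the full
sample or subsamples is unknowable from the text; the scorer defaults to
the full analysis sample.  Sum scales require complete items (item-level
missingness in the generator only arises through whole-parent absence);
closeness averages the answered items.

Father- and mother-quality are one-factor models over the four scale
scores, estimated by casewise FIML with the factor variance fixed at 1, so
loadings are reported standardized.  With four indicators the model has
10 covariance moments and 8 free parameters: 2 degrees of freedom.  Fit is
judged by chi-square against the saturated Gaussian fit (EM-estimated under
missingness), CFI against the independence baseline, and SRMR on
standardized covariance residuals, with CFI > 0.90 and SRMR < 0.08 as the
acceptability criteria.  Factor scores use the regression method — the
conventional default where the original extraction call is unstated — via
the conditional-normal formula on each case's observed indicators.
Heywood cases (negative residual variances) are flagged, never truncated.

## Univariable models

Each predictor enters its own family-clustered model (avoiding
multicollinearity across correlated parenting measures).  For the residual
outcomes: a random-intercept linear model by ML (`lme4`), outcome
standardized, continuous predictors standardized, binary predictors (partner
drinking) left on 0/1 so the coefficient reads as an SD difference between
groups.  Ordinal peer drinking (1–4) is treated as continuous.  If the
between-family variance hits zero the fit coincides with OLS and a note is
recorded.  The published analysis used a panel-model framework whose
random- vs fixed-effects choice is not fully specified; random intercepts
are the default here.  For the AUD outcome: a family random-intercept
probit fitted in-package, the likelihood integrated by Gauss–Hermite
quadrature (15 nodes by default; the tests show 15 vs 61 nodes agree to
1e-4), with baseline age, sex, ancestry and the parental-data indicators as
covariates.  Coefficients are on the latent z scale.

## The structural equation model

The path model regresses the three mediators (peer, partner, social
competence) on the three parenting predictors (father quality, mother
quality — latents with four indicators each — and observed monitoring), and
resistance on all six upstream variables: 9 + 6 = 15 structural paths.
Exogenous predictors covary freely, as do the mediator disturbances.
Estimation is FIML in a RAM parameterization with an analytic gradient;
with no missing data the objective reduces exactly to the complete-data
Gaussian ML log-likelihood (tested to 1e-8).  Standardization uses
model-implied total variances; 95% CIs are Wald from the observed
information (numeric Jacobian of the analytic gradient), with delta-method
CIs for standardized estimates, matching the symmetric intervals reported
in this literature.  Binary endogenous variables (partner drinking, the AUD
code) are treated as continuous in the Gaussian likelihood — the single-
framework FIML approximation; a probit-link extension is left as future
work.  The SEM stage does not itself cluster on family (the univariable
models do); this mirrors the published description, which mentions
clustering only for the univariable models, and is noted as a limitation.

Multi-group moderation tests fit each group freely (independent per-group
fits; the free log-likelihood is their sum) and refit jointly with the
tagged parameters — by default all 15 structural regressions — equated
across groups, warm-started from the free solutions.  The likelihood-ratio
statistic $-2(\ell_c - \ell_f)$ is referred to chi-square with df = the
number of independent equality constraints (15 for the full structural
block, 1 for a single path).  The free baseline leaves measurement loadings
group-specific, since the source analysis constrained "regression
coefficients" only; a loadings-equality constraint is available.

## The synthetic generator: its stated world

The generator's defaults *are* the conditions stated for the motivating
cohort, and are not tuned to test outcomes:

* ~900 families averaging two adolescents (≈1,850 subjects), baseline ages
  uniform on 11–17, 49.9% female, 36.5% African-ancestry families, 62%
  completing the follow-up assessment (38% MCAR attrition on the follow-up
  block).
* Liability = family component + individual component, both Gaussian, with
  `h2_liability = 0.5` (the familiality of AUD); the polygenic score is a
  noisy proxy with `prs_r2 = 0.1` (realistic current prediction); relatives'
  symptom counts are Poisson with log-mean linear in their own liability.
* Structural paths, loadings and exogenous correlations default to the
  fitted initiation-model values (e.g. mother-quality → peer −0.17,
  father-quality → resistance −0.19, factor correlation 0.63), so SEM
  recovery tests target exactly these numbers.
* Onset ages are Weibull proportional hazards (initiation shape 4 scale 17,
  HED shape 4.5 scale 21 — medians ≈ 15.5 and 19 years, matching the
  descriptive onset ages), with HED floored at initiation, uniform
  censoring on 17–26 years, and a probit AUD diagnosis model targeting 10%
  prevalence among drinkers.
* Item responses discretize Gaussian item latents at equal- or
  stated-probability thresholds (`item_fidelity = 0.9`), since the source
  gives response formats but no distributions.

What a green test establishes, and what it does not: the generator is
multivariate Gaussian with MCAR missingness, exactly the regime where FIML
and the Cox PH law are correctly specified.  Green recovery tests therefore
establish *implementation correctness* (estimators recover their estimands
under their own assumptions), not robustness to the ordinal measurement,
informative missingness, ascertainment and gene–environment correlation of
real family studies.  The social block is deliberately independent of
liability (no gene–environment correlation), and censoring is independent
uniform rather than assessment-schedule-driven.

## Numerical choices

* SEM optimizer: `nlminb` with the analytic RAM gradient; 3 starts by
  default (first unjittered; ties broken by first convergent best
  objective); non-positive-definite implied covariances are rejected via a
  large finite penalty.
* Observed information by central differences on the analytic gradient
  (step `1e-5 * max(1, |par|)`); a pseudo-inverse fallback flags empirical
  underidentification.
* Saturated FIML fit by EM on per-pattern sufficient statistics
  (tolerance 1e-9); independence baseline in closed form.
* LRT statistics are clamped at 0 with 1e-6 slack; a constrained fit
  beating its free parent by more than that raises a convergence error.
* Variances are unbounded during optimization so Heywood cases surface as
  flags rather than silent boundary truncation.
* Degenerate inputs fail fast with informative errors: constant covariates
  are dropped from Cox fits with a message, complete separation in the
  probit names the predictor, all-censored data and non-positive times are
  rejected, out-of-range item responses name the item.

## Known limitations

Ordinal indicators are treated as continuous everywhere (no polychoric or
probit-link SEM); no left truncation, time-varying covariates or competing
risks in the survival models; MCAR (not MNAR) attrition; no genotype-level
simulation or LD structure; the SEM stage is unclustered; and the published
coefficient values themselves are not reproducible because the underlying
cohort is restricted — all checks against them are structural
(degrees of freedom, sign conventions, subsample logic) or
recovery-based on the generator's stated world.
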