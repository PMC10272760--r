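---
title: "Modelling regional brain atrophy with onset ages and progression paces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling regional brain atrophy with onset ages and progression paces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(onsetpace)
```

## The model

`onsetpace` analyses longitudinal regional neuroimaging features — cortical
thicknesses or normalized subcortical volumes, one region at a time — with a
nonlinear mixed-effects trajectory model. For subject $i$ at visit age
$t_{ij}$ the observation of one (preprocessed) regional feature is

$$y_{ij} = f\!\left(e^{\xi_i}(t_{ij} - \tau_i) + t_0\right) + \varepsilon_{ij},
\qquad \varepsilon_{ij} \sim \mathcal N(0, \sigma_\varepsilon^2),$$

where the population curve $f$ is either affine,
$f(u) = p_0 + v_0 (u - t_0)$, or logistic with asymptotes 0 and 1,

$$f(u) = \frac{1}{1 + \left(\tfrac{1}{p_0} - 1\right)
  \exp\!\left(-\tfrac{v_0 (u - t_0)}{p_0 (1 - p_0)}\right)},$$

the unique such logistic satisfying $f(t_0) = p_0$ and $f'(t_0) = v_0$.
(The implementation evaluates the algebraically identical form
$p_0 / (p_0 + (1 - p_0) e^{-g(u-t_0)})$, which returns exactly $p_0$ at
$u = t_0$ in floating point.)

Each subject deviates from the population through an affine time warp with
two random effects: the **onset age** $\tau_i \sim \mathcal N(t_0,
\sigma_\tau^2)$, the age at which the subject crosses the reference value
$p_0$, and the **log progression pace** $\xi_i \sim \mathcal N(0,
\sigma_\xi^2)$, a multiplicative rescaling of time ($e^{\xi_i} = 1.2$ means
20% faster progression than the population). These two parameters align all
subjects on a common progression timeline; they are the quantities carried
into the association analysis. The fixed effects are $(t_0, p_0, v_0,
\sigma_\varepsilon, \sigma_\tau, \sigma_\xi)$.

### Identifiability and gauges

The trajectory family is deliberately over-parametrized, and two exact or
near-exact invariances must be pinned by priors rather than by data:

* **Time reference.** The data attachment does not depend on $t_0$ at all:
  the warp argument reduces to $e^{\xi_i}(t_{ij} - \tau_i)$ relative to the
  curve's centre. $t_0$ is identified solely as the prior mean of the
  $\tau_i$; the sampler's M-step ties it to the (smoothed) mean onset age.
* **Pace scale.** Multiplying $v_0$ by $c$ while subtracting $\log c$ from
  every $\xi_i$ leaves all predictions unchanged. The zero-mean prior on
  $\xi$ resolves this.
* **Reference position.** With asymptotes fixed at 0 and 1, sliding $p_0$
  along the curve can be absorbed by a joint shift of $t_0$, all $\tau_i$
  and an adjustment of $v_0$. The data therefore barely constrain $p_0$; a
  deliberately tight hyperprior (sd 0.05 on $\mathrm{logit}\,p_0$) pins it
  at the normalized-data midpoint. This is the same gauge-fixing device as
  the zero-mean $\xi$ prior; without it the fitted $t_0$ inherits
  year-scale drift along the ridge.

Both of the first two invariances are asserted numerically in the test
suite; the third motivates the default hyperprior width.

## Preprocessing

The pipeline applies, in a fixed order:

1. **Additive field-strength bias correction.** Features extracted from 3T
   scans are systematically offset against 1.5T; within each diagnosis
   group and region, 3T values are shifted by the difference of field-wise
   means, equalizing the means exactly. Mean matching is the minimal
   additive realization of histogram alignment; the correction runs before
   anything else so that all later statistics see homogeneous data.
2. **Three-sigma outlier removal**, single pass, per region within the
   cohort, with the plain mean and sd. Removing gross outliers *before*
   taking extremes keeps the normalization asymptotes realistic.
3. **Min-max normalization** to $[0, 1]$ on the retained values — required
   by the logistic family.
4. **Orientation flip** $x \mapsto 1 - x$ for decreasing features, so the
   modelled feature increases. Cortical thicknesses and volumes decrease
   over time; rather than hard-coding that expectation, each region is
   flipped when its pooled within-subject slope is negative, which
   generalizes to feature sets of either orientation (a `flip` toggle
   forces the decision).

Every applied parameter (shifts, minima, maxima, flip flags, removed
indices) is stored in a normalization record, making the transform
reproducible on new data and invertible on retained points (round-trip
within $10^{-12}$).

The order bias-correction → outlier removal → normalization is itself a
choice the data formats do not force; it was fixed once and is exercised
end-to-end by the synthetic generator, which applies its scanner offset
before preprocessing.

## Calibration by MCMC-SAEM

Fixed effects are estimated by maximum a posteriori with a stochastic
approximation EM in which the E-step is replaced by Markov-chain sampling
of the random effects. Each iteration $k$:

* **(S)** one Metropolis-within-Gibbs sweep: every subject's $\tau_i$, then
  $\xi_i$, receives a Gaussian random-walk proposal scored against the
  complete log-posterior. Because subjects are conditionally independent,
  the sweep is evaluated for all subjects in one vectorized pass.
* **(SA)** sufficient statistics (mean and second moment of $\tau$, second
  moment of $\xi$, mean squared residual) are blended with step
  $\epsilon_k = 1$ for $k \le$ burn-in and $(k - \text{burn-in})^{-\gamma}$
  after, $\gamma \in (0.5, 1]$ as the Robbins–Monro conditions require.
* **(M)** closed-form updates: $t_0$ is the Gaussian-posterior mode given
  the smoothed $\tau$ statistics; each variance is the corresponding
  smoothed moment, blended with its hyperprior mode by a
  one-observation-weight shrinkage in log space (the weight of the prior
  relative to $N$ data contributions — negligible at cohort sizes, but it
  keeps the MAP proper on tiny inputs). $(p_0, v_0)$ take one damped Newton
  step (finite-difference gradient and Hessian on
  $(\mathrm{logit}\,p_0, \log v_0)$, ridge-regularized, step halved, capped
  in norm, and scaled by $\epsilon_k$ after burn-in) on the penalized data
  attachment given the current random effects.

Proposal sds adapt toward a 30% acceptance rate during burn-in (multiplying
by $e^{\text{rate} - 0.3}$ every 25 iterations) and are frozen afterwards.
Defaults: 2000 iterations, 1000 burn-in, $\gamma = 0.65$; a mandatory seed
makes runs exactly reproducible, and observations are canonically sorted
(subject, age, value) so input row order cannot change results. Convergence
is reported, not silently enforced: the sd of each fixed-effect trace over
the final 200 iterations is returned as a diagnostic.

Hyperpriors are weak Gaussians centred at the data-driven initialization
(sd 10 y on $t_0$, sd 1 on $\log v_0$ and each $\log\sigma$), except the
tight $p_0$ pin discussed above. Initialization: $t_0$ at the mean visit
age, $p_0 = 0.5$, $v_0$ at the pooled within-subject OLS slope (floored at
$10^{-4}$/y), $\sigma_\varepsilon$ at the pooled residual sd, $\sigma_\tau$
at the sd of visit ages, $\sigma_\xi = 0.5$, and every subject at the prior
modes.

### Individual parameters

Two estimators are exposed. Calibration returns the stochastic-
approximation means of the sampled $(\tau_i, \xi_i)$. Downstream analyses
use `personalize()`: with the fixed effects frozen, each subject's MAP is
found by quasi-Newton optimization from nine starts ($\tau \in \{t_0 \pm
\sigma_\tau, t_0\} \times \xi \in \{0, \pm\sigma_\xi\}$), ties resolved by
posterior value then smaller $|\xi|$. The MAP is deterministic, free of
Monte-Carlo noise, and measurably more accurate on synthetic cohorts, and
it applies unchanged to held-out subjects.

## Association analysis

For every region and each individual parameter, ordinary least squares
regresses the parameter on female sex (0/1), APOE-ε4 allele count (0/1/2)
and education (years) jointly, so each coefficient is the effect *after
correcting for the other covariates* — education stays in the design even
when only the sex and APOE maps are reported. Two-sided $p$-values come
from $t = \beta/\mathrm{se}$ with $n - 4$ degrees of freedom.

The regressed pace parameter is $\xi$ (log scale); multiplicative effects
are reported as $(e^{\beta} - 1) \times 100$ percent. Across regions,
$p$-values are corrected with the Benjamini–Hochberg step-up FDR; the
default family is all regions of one (parameter, covariate) map, matching
how region-wise results are presented, with a pooled alternative behind a
flag. A family-wise correction would be needlessly stringent for maps of
~150 regions. Surviving regions are rendered as signed $-\log_{10}(q)$
values, positive when the covariate is a risk factor (earlier onset:
$\beta_\tau < 0$; faster pace: $\beta_\xi > 0$), negative when protective;
$q > 0.05$ is masked. Pairwise covariate correlations are reported
alongside as a collinearity check.

## Goodness of fit

Reconstruction errors (prediction minus measurement at every visit) are
compared to the measurement noise estimated from same-day duplicate scans:
for each duplicate pair, $(y_1 - y_2)/\sqrt 2$ has the sd of a single
measurement's noise under i.i.d. Gaussian errors (all pairwise pairs are
used when a visit has more than two copies). Both distributions are
summarized by 5/25/50/75/95% quantiles, and overlap is declared when the
intersection of the two interquartile ranges covers at least half of the
wider one — nesting of a narrow noise IQR inside a wide residual IQR does
not count. Residuals are additionally audited for bias: each subject's mean
absolute residual (signed mean behind a flag) is regressed on each
covariate and acquisition factor separately.

The linear and logistic families are compared by calibrating both on the
same data and preferring the lower fitted $\sigma_\varepsilon$; agreement
within 2% is reported as a tie and resolved toward the logistic family
(bounded trajectories with realistic asymptotes). Family discrimination
needs follow-up long enough to expose curvature — over a short window every
smooth trajectory is locally affine and the comparison is uninformative —
so the evaluation scenario uses six visits two years apart.

## The synthetic cohort generator

Real inputs for this analysis are restricted-access; the generator emulates
their statistical structure so every stage is testable, and retains the
generating truth. It samples covariates (44% female, APOE-ε4 0/1/2 at
roughly 31/50/19%, education $15.5 \pm 2.8$ y), baseline ages
($74.3 \pm 7.4$ y), a uniform visit count between 2 and 7 with roughly
annual intervals (truncated at 0.1 y), random effects with covariate-driven
mean shifts, Gaussian measurement noise on the logistic trajectories, an
additive offset on the ~49% of scans flagged 3T, and same-day duplicate
acquisitions (20% of visits) with fresh noise. Default trajectory values
($t_0 = 74$ y, $p_0 = 0.5$, $v_0 = 0.05$/y, $\sigma_\tau = 7$ y,
$\sigma_\xi = 0.5$, $\sigma_\varepsilon = 0.02$ normalized units) make
cohorts traverse a visible fraction of $[0, 1]$ within follow-up. Default
covariate effects place onset 1.5 years earlier per ε4 allele and make
women's pace 23% faster; all defaults are overridable, and
`covariate_effects = NULL` yields a null cohort.

What the generator does **not** emulate: informative dropout, diagnosis
conversion, visit-schedule irregularities beyond Gaussian intervals,
non-Gaussian measurement noise, or spatial correlation between regions.
Passing recovery tests on these cohorts therefore demonstrates correctness
of the estimation machinery under the model's own assumptions, not
robustness to real-data violations of them.

## Numerical choices and test scales

* Proposal adaptation only during burn-in keeps the chain a fixed Markov
  kernel afterwards.
* The $(p_0, v_0)$ Newton step is ridge-regularized when the Hessian is
  not positive definite, halved, norm-capped at 0.2, and decays with
  $\epsilon_k$ after burn-in.
* Variance statistics are floored ($10^{-8}$, residual moment $10^{-12}$)
  so noiseless inputs cannot produce log-of-zero.
* Per-region sampler seeds are derived from the master seed and the region
  *name*, so region order and parallel scheduling cannot change results.
* Degenerate inputs are first-class: a single field strength skips bias
  correction with a message, zero spread skips outlier removal, a constant
  covariate yields `NA` coefficients with a warning, subjects reduced to
  fewer than two retained visits are excluded by the study's own selection
  rule.

Recovery checks run at deliberately desk-scale sizes chosen to keep the
whole suite fast while leaving the statistical properties measurable: the
reference recovery cohort uses one region, 200 subjects and 5 visits; the
effect-recovery cohort 500 subjects; the null-calibration check 100 regions
of 150 subjects on the generator's truth table (the OLS/FDR machinery does
not require estimated parameters, and per-region sampling would add nothing
to what the dedicated recovery checks already establish); the FDR-control
simulation 500 subjects so that discoveries are frequent enough for the
empirical false-discovery proportion to be meaningful rather than binomial
noise on a handful of hits; family selection 80 subjects with 10-year
follow-up, ten seeds per generating family.

## Known limitations

* The univariate models share no information across regions; onset ages of
  different regions live on timelines that are aligned only through the
  common covariate analysis.
* Attenuation: estimated $\tau_i$, $\xi_i$ are shrunk toward the prior
  where data are uninformative (subjects observed on a trajectory plateau),
  which biases association coefficients mildly toward zero — visible in the
  recovery checks as APOE onset shifts slightly below the injected 1.5 y.
* The additive bias correction estimates one shift per (group, region) from
  the available scans; at small cohort sizes its sampling error adds a
  common offset to all 3T measurements of a region.
* No intracranial-volume normalization is applied; volumes are assumed
  pre-normalized if desired.
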