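---
title: "Estimating subnational family-planning indicators and service-disruption scenarios"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating subnational family-planning indicators and service-disruption scenarios}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fpemsub)
```

## The estimation problem

National averages of contraceptive indicators hide large within-country
disparities, and programme implementation happens at the region and
division level. The estimation task is small-area inference from sparse,
irregular survey data: a handful of household surveys (DHS and MICS style)
observed over three decades, each giving noisy proportions of married
women of reproductive age (MWRA) using any method, using a modern method,
and with unmet need, for every administrative unit. The model must
interpolate between surveys, project beyond the last one, and quantify the
considerable uncertainty of both.

`fpemsub` implements the family-planning estimation model (FPEM/FPET)
tradition of doing this: systematic logistic-growth trends with a
time-series component capturing fluctuations around them, assembled in a
Bayesian hierarchy so that data-poor divisions borrow strength from their
region and the country.

## Model structure

Three latent processes are tracked per area $a$ on an annual grid:

1. **Total prevalence.** $P_a(t) = \mathrm{logit}^{-1}\{\mathrm{logit}\,
   L_a(t) + \varepsilon_a(t)\}$ with trend
   $L_a(t) = \tilde{P}_a\,\mathrm{logit}^{-1}\{\omega_a (t - T_a)\}$.
   The asymptote $\tilde P_a \in (0,1]$ is the plateau prevalence, the
   rate $\omega_a$ (per year) controls how fast the transition happens,
   and the midpoint $T_a$ (calendar year) is where the curve reaches half
   its plateau — a gradual rise at low prevalence, fastest growth around
   the midpoint, a slowdown near the plateau.
2. **Modern share.** The ratio of modern to total use, $R_a(t)$, follows
   its own logistic trend and AR(1) distortion, so $\mathrm{mCPR} = P R$
   and traditional use is $P(1-R)$. Working on the share rather than on
   mCPR directly keeps all accounting identities exact by construction.
3. **Unmet need.** The ratio of unmet need to non-use,
   $Z_a(t) = \mathrm{logit}^{-1}\{\alpha_a + \beta L_a(t) +
   \varepsilon^{(u)}_a(t)\}$, gives
   $\text{unmet}_{\text{any}} = (1-P)\,Z$, bounded by the non-user share
   automatically. A negative $\beta$ encodes the empirical decline of
   unmet need among non-users as overall use rises. We deliberately use
   the *trend* $L_a(t)$ (not the distorted $P_a(t)$) as the regressor:
   the relation is meant to capture the systematic association between
   prevalence and unmet need, and this choice keeps the model exactly
   linear-Gaussian in the distortions (see *Computation*). The
   free-standing `unmet_relation()` helper implements the relation for
   arbitrary prevalence inputs.

All distortions $\varepsilon$ are stationary AR(1) processes on the logit
scale, initialised from their stationary distribution (variance
$\sigma^2/(1-\rho^2)$), with a shared autocorrelation $\rho$ and
process-specific innovation SDs.

**Hierarchy.** Country-level curve parameters are fixed constants supplied
in `fpem_config()` — the convention that rates, trends and data above the
modelled level are point estimates from the most recent higher-level run.
Region parameters (on the transformed scale: logit asymptote, log rate,
midpoint, unmet intercept) are normal deviations around the country
values; division parameters around their region's. Pooling is
exchangeable; an adjacency-based spatial smoother is out of scope. The
dispersion vectors `sd_region`/`sd_division` are fixed configuration
constants rather than estimated hyperparameters: with a single country
there is little information to estimate them, and fixing them makes the
prior-dispersion → interval-width relationship a directly testable dial.

**Likelihood.** Each survey row is transformed into up to three logit-scale
observations: the total $c$, the modern share $m/c$, and the unmet ratio
$u/(1-c)$, with delta-method standard errors derived from the reported SE
or from $\sqrt{p(1-p)/n_\text{eff}}$. Observed proportions are clamped to
$[0.5/n_\text{eff},\, 1 - 0.5/n_\text{eff}]$ before the logit (the usual
continuity correction; the logit is undefined at the boundary). Non-DHS
(MICS) observations carry a variance inflation factor $\kappa \ge 1$,
estimated with a lognormal prior on $\kappa - 1$; no additive source bias
is modelled. A row reporting mCPR without either the total or traditional
use cannot be transformed and is rejected with a pointed error.

## Computation

Conditional on the trend parameters, every observation is a linear
function of a Gaussian AR(1) state plus Gaussian noise, so the states are
marginalised analytically: an area's likelihood is a product of small
multivariate-normal densities whose covariance is the stationary AR(1)
covariance at the observed years plus the diagonal sampling variances.
The sampler therefore explores only ~7 parameters per area plus 5 globals
($\rho$, three $\sigma$s, $\kappa$), using adaptive random-walk Metropolis
blocks:

* one 7-dimensional block per area, with Haario-style full-covariance
  adaptation (the asymptote/rate/midpoint posterior has strong ridges
  that diagonal proposals cannot traverse) and Robbins–Monro scale
  tuning toward 0.234 acceptance;
* a *branch translation* move shifting a region and all its divisions
  jointly — the slow direction of any hierarchical posterior;
* one global block; its proposals re-factorise the observation
  covariances, which are otherwise cached across area updates.

Posterior trajectories are reconstructed per retained draw by conditional
simulation of the AR(1) states given that draw's parameters and the
area's observations; years beyond the data revert smoothly toward the
stationary distribution, which is why projection intervals widen with the
horizon. Chains are seeded `seed + 1000·chain`, making every fit
bit-reproducible. Convergence is monitored with split-$\hat R$ per
monitored parameter; a warning is raised when any exceeds the configured
threshold (default 1.05). Defaults are 4 chains, 1000 warmup and 1000
retained draws; `thin` trades iterations for memory-neutral extra mixing.

Numerical conventions fixed for testability: posterior summaries are the
2.5th/50th/97.5th percentiles with linear interpolation between order
statistics (`quantile()` type 7); reported percentages round half-even to
one decimal; demand satisfied is defined as 0 when demand is 0; negative
required increases are reported as computed (an area already past the
target carries information), and a zero attainment probability is rendered
as the `".."` sentinel in formatted tables.

Derived indicators are always computed sample-wise and then summarised.
Summaries of ratios are not ratios of summaries — published tables whose
medians do not satisfy the ratio identity exactly illustrate why the order
matters — so `fp_posterior()` validates the identity set
(`traditional = cpr_total − mcpr`, `unmet_modern = unmet_any +
traditional`, `demand_modern = mcpr + unmet_modern`) on every array it
wraps, and the fit enforces them by construction.

## The synthetic-data generator

`simulate_true_trajectories()` draws area parameters from the same
hierarchical process the model assumes and adds AR(1) distortions, so
parameter recovery and interval calibration are well-posed questions.
Defaults describe a Cameroon-like setting: total prevalence rising from a
few percent in 1990 toward a 0.6 asymptote (about 21% by 2022), a modern
share rising from roughly 0.2 to 0.8 over the same period, unmet/non-use
ratio declining with prevalence ($\alpha = -0.4$, $\beta = -1$), $\rho =
0.8$ and logit-scale innovation SDs of 0.06–0.08. Survey designs default
to the DHS 1991/1998/2004/2011/2018 and MICS 2000/2006/2014 calendar with
effective sample sizes shrinking down the hierarchy (2000/800/250), and
MICS sampling SDs inflated ×1.5 — the estimation model's $\kappa$ is the
variance-scale analogue of this. Populations grow log-linearly with
Dirichlet shares and are apportioned so division counts sum exactly to
regions and regions to the country. Services data (per-capita health
workers, facilities, budget) drift upward at 2%/year with modest regional
effects and noise — the within-sample growth that makes a provision
elasticity estimable — and poverty rates sit around 0.375.

What the generator does *not* emulate: DHS cluster/stratification design
(only an effective sample size), source-specific additive biases,
migration shocks or census revisions in the population series, and any
real spatial autocorrelation between neighbouring divisions. Passing
tests therefore demonstrate internal statistical correctness — that the
machinery recovers the process it assumes — not that the functional forms
match any particular country's data-generating reality.

## Scenario engine

Coverage is factorised as provision × utilization:
$\text{provision} = \text{HRH} \cdot \text{FH} \cdot \text{HB}$ and
$\text{utilization} = \text{demand} \cdot (1 - \text{poverty rate})$.
Because the provision components' official units are arbitrary, indices
are normalised to 1 in the scenario start year within each region before
regression. The link is log-linear with region fixed effects,
$\ln \text{mCPR} = a_r + b \ln \text{provision} + c \ln
\text{utilization}$, fitted on the baseline projection panel (2020–2030)
and *retained* only when both predictors are significant at $p < 0.05$ —
a double screen whose null retention rate is approximately $\alpha^2$ for
independent predictors, which the test suite verifies by simulation.
Annual reductions compound multiplicatively, $(1-x)^{t-2020}$ on
provision and $(1-y)^{t-2020}$ on utilization, over the 4 × 4 grid
$\{0, 5, 10, 25\}\%$ labelled none/small/moderate/large; demand inside
utilization keeps evolving along the baseline projection while the
reduction factor compounds. The $(0,0)$ scenario reproduces the link
model's own baseline prediction exactly; it can differ from the raw
projection by the regression's residual, so both curves are exposed for
inspection (`attr(result, "baseline")` versus the `fpet_projection`
argument of `cumulative_change()`).

## Problem sizes used by the test suite

The calibration study fits 20 independent synthetic replicates of a
2-region × 3-division hierarchy with 4 surveys per area on the full
1990–2030 grid, using 2 chains × (300 warmup + 300 kept, thin 2), and
requires 95% intervals to cover the true mCPR in at least 85% of
area-years. The grid-posterior oracle reduces the model to one area with
two free parameters (total-prevalence asymptote and midpoint, distortions
off) and compares MCMC medians against an exhaustive 220 × 220 grid
posterior to within 0.01. The aggregation-consistency diagnostic is
exercised on constructed posterior arrays in which divisions share the
national truth exactly, so any flagged gap would come from the diagnostic
itself rather than from model noise; 20 such replicates must yield
$p > 0.05$ in at least 90%. These sizes are the package's chosen
desk-scale study conditions and are deliberately small enough to run
routinely.

## Limitations

* The exact transition-rate parametrisation and prior constants of the
  production FPEM are not public; the forms here are declared stand-ins
  with the same architecture. Published country-specific posterior values
  are consequently not reproduction targets for synthetic inputs.
* Exchangeable pooling ignores spatial adjacency; two neighbouring
  divisions are no more similar a priori than two distant ones.
* The source-type effect is variance-only; a systematic MICS-vs-DHS bias
  would be absorbed into wider intervals rather than corrected.
* The coverage link is a deliberately simple log-linear elasticity model
  screened on significance; it captures quantitative provision and
  utilization only, not service quality, and its scenario paths are
  hypothetical what-ifs, not forecasts.
* Reduced-MCMC settings used in tests trade some chain mixing for speed;
  production analyses should use the 4 × (1000 + 1000) defaults and heed
  the split-$\hat R$ warning.
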