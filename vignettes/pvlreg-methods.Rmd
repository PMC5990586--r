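---
title: "Bayesian regression for PVL-Delta parameters: models, priors, and numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian regression for PVL-Delta parameters: models, priors, and numerics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

Cognitive models summarize behavior through interpretable parameters, and a
recurring question is whether those parameters are related to continuous
covariates such as questionnaire scores. A common shortcut is to dichotomize
the covariate (typically at its median), split participants into a "high" and
a "low" group, and test the groups for a difference in the fitted parameters.
Dichotomization is statistically biased: with uncorrelated covariates it
wastes information and understates true effects, and with correlated
covariates it manufactures spurious ones, because the median split on one
covariate drags along group differences on every covariate correlated with
it.

`pvlreg` implements the principled alternative for the Prospect Valence
Learning model with delta learning rule (PVL-Delta) applied to the Iowa
Gambling Task (IGT): a hierarchical Bayesian regression in which covariates
predict probit-scale model parameters, with Bayes factors quantifying the
evidence for each parameter-covariate relationship. It also implements the
median-split comparison model and a simulation study that measures the bias
the regression framework avoids.

## The PVL-Delta model

On each trial the participant draws a card from one of four decks and
receives a net outcome $X(t)$ (win plus loss). Utilities follow a prospect
utility function with outcome sensitivity $A \in [0,1]$ and loss aversion
$w \in [0,5]$:

$$u(t) = \begin{cases} X(t)^A & X(t) \ge 0 \\ -w\,|X(t)|^A & X(t) < 0.
\end{cases}$$

Deck expectancies update by the delta rule with rate $a \in [0,1]$,
$Ev_k(t) = Ev_k(t-1) + a\,(u(t) - Ev_k(t-1))$ (chosen deck only), and the
next choice follows a softmax with sensitivity $\theta = 3^c - 1$,
$c \in [0,5]$. All expectancies start at zero, so trial 1 is uniform over the
four decks; its constant $\log(1/4)$ is included in the likelihood so the
simulated and fitted data-generating processes are identical. A net outcome
of exactly zero is given utility zero for every $A$ (this also resolves the
$0^0$ corner, by continuity from below in $X$).

The dealt payoffs follow the traditional fixed four-deck schedule: wins of
100 (decks A, B) or 50 (decks C, D) on every draw, and losses placed so that
each ten-draw block nets $-250$ for A and B (five medium losses, or one of
$-1250$) and $+250$ for C and D (five losses of $-50$, or one of $-250$).
The literature contains minor dialects of the within-block loss amounts and
positions; the package pins one canonical choice and its tests enforce only
the block-sum and loss-count invariants, so any conforming dialect is
interchangeable. One member of the family is avoided deliberately: flat
$-50$ losses on deck C would make every deck-C loss draw net exactly zero,
and a zero net outcome has utility zero for every $(A, w)$ — the
most-preferred deck would then carry no information about the utility
parameters. The varied $-25/-75$ dialect used here matches the original
description of deck C ("small unpredictable punishments") and keeps those
draws informative. Blocks repeat cyclically, so any number of draws can be
dealt from one deck. The initial credit of $2000 is recorded as task
metadata but enters no model equation.

## Hierarchy, regression extension, and the median-split model

Each parameter $z \in \{A, w, a, c\}$ is mapped to the real line by the
probit transform of its fraction of the upper bound $U_z \in \{1,5,1,5\}$:
$z' = \Phi^{-1}(z/U_z)$. (The transform is stated in the literature for
$(0,1)$ parameters; dividing by the upper bound first is the convention of
the published hierarchical implementations and makes the mapping a bijection
for all four parameters.) The regression model draws each participant's
probit-scale parameter from

$$z'_i \sim \mathcal{N}(\mu_{z'} + \mathbf{x}_i^\top \boldsymbol\alpha_{z'},
\sigma^2_{z'}),$$

with covariates centered at analysis time. Priors are
$\mu_{z'} \sim \mathcal{N}(0,1)$,
$\sigma^2_{z'} \sim \mathrm{InvGamma}(2, 1/2)$, and the
Jeffreys-Zellner-Siow mixture-of-g prior on the weights,
$\boldsymbol\alpha_{z'} \mid g \sim \mathcal{N}(\mathbf 0,\,
g\,\sigma^2_{z'}(\mathbf X^\top \mathbf X / N)^{-1})$ with
$g \sim \mathrm{InvGamma}(1/2, s^2/2)$. Marginally the weights follow a
multivariate Cauchy prior with scale $s$; the implied prior on each
standardized effect size $\beta_{z'j} = \alpha_{z'j} s_j / \sigma_{z'}$ is
Cauchy$(0, s)$. The default is $s = 1$; $s = 1/3$ is available for settings
where small effects are expected a priori. An intercept-only variant with
$\sigma_{z'} \sim \mathrm{Uniform}(0, 1.5)$ is provided for completeness;
the regression and median-split specs use the inverse-gamma residual prior,
which converges faster and does not change the qualitative conclusions.

The median-split model replaces the regression mean by effect coding:
$d_{ij} = +0.5$ if participant $i$ scores strictly above the median of
covariate $j$ and $-0.5$ otherwise, ties going to the lower group, and

$$z'_i \sim \mathcal{N}(\mu_{z'} + \boldsymbol\delta_{z'}^\top \mathbf d_i\,
\sigma_{z'},\ \sigma^2_{z'}),$$

with independent Cauchy$(0, s)$ priors on the standardized group differences
$\delta_{z'j}$.

Design choices worth noting:

* `crossprod(X)/N` uses the denominator-$N$ covariate standard deviation, so
  for one covariate it equals $s_x^2$ exactly.
* Covariates are centered, not standardized; the covariate scale $s_j$
  enters through the standardized effect size instead. Which of the two
  conventions the original analyses used is not documented; centering alone
  keeps the weights interpretable in covariate units.
* The generating table used by the synthetic-data module reads the printed
  group-level spread column as a standard deviation, matching its symbol;
  because the underlying adjustment was stated in terms of variances, a
  `sd_as_variance` switch is provided for sensitivity analysis.

## Bayes factors

Evidence for a relationship is the Bayes factor of
$\mathcal H_1: \beta_{z'j} \sim \mathcal{C}(0, s)$ against
$\mathcal H_0: \beta_{z'j} = 0$, computed by the Savage-Dickey density
ratio: prior density at zero, $1/(\pi s)$, divided by the posterior density
at zero. The posterior density is estimated from pooled post-burn-in draws
by a log-spline-type smooth fit — a penalized cubic-spline Poisson
regression of binned counts on bin midpoints, so the log-density is a smooth
spline — with a Sheather-Jones kernel estimate as recorded fallback. The
binning grid always covers zero, so a posterior far from the null yields a
smoothly decaying (not blindly extrapolated) estimate. The estimator is
benchmarked to recover the standard normal density at zero within 0.01 from
$10^5$ draws. With several covariates the prior density at zero keeps the
$1/(\pi s)$ convention of the marginal Cauchy statement; for strongly
correlated designs the exact marginal prior of a single weight is somewhat
wider, a known approximation shared with the original analyses.

A third estimator, `"conditional"`, exploits the model's structure: given
everything else, the regression weights (and the standardized group
differences of the median-split model) are exactly Gaussian, so the marginal
posterior density at the null is the posterior expectation of a known
Gaussian density. Averaging that conditional density over the retained draws
(Rao-Blackwellization) gives an estimate with far lower Monte-Carlo variance
than any smooth fit to the draws themselves — at desk-scale chain lengths
the smooth-fit estimate of a regression effect's density at zero can wobble
by more than a log unit, which is why the simulation-study paths use the
conditional estimator. The estimators agree closely on well-mixed chains
and every Bayes-factor table records which one produced it.

Density-ratio Bayes factors saturate: once $|\log \mathrm{BF}|$ exceeds
roughly 5, the posterior density at the null sits many posterior standard
deviations in the tail, where any smooth estimator is extrapolating;
estimates there are order-of-magnitude statements, not precise ratios. A
posterior density estimate of exactly zero is reported as an infinite Bayes
factor with a `saturated` flag.

For the plain linear model (no cognitive likelihood) the package also
computes the analytic JZS Bayes factor by one-dimensional quadrature over
$g$ of
$(1 + Ng)^{(N-1-P)/2}\,(1 + Ng(1 - R^2))^{-(N-1)/2}$
against the $\mathrm{InvGamma}(1/2, s^2/2)$ density, on the log-$g$ scale
after centering at the integrand mode. This is the independent oracle the
Savage-Dickey path is validated against: on linear data with matched
reference (Jeffreys) priors on the intercept and residual variance the two
routes agree within 0.05 in log Bayes factor in the moderate-evidence regime
($|\log \mathrm{BF}| \lesssim 4$).

## Posterior computation

The sampler is a hybrid designed around the structure of the model:

* Group-level quantities are conjugate given the probit-scale parameters and
  are Gibbs-sampled exactly: $\boldsymbol\alpha \mid g, \sigma^2$ is
  multivariate normal, $\mu$, $\sigma^2$ and $g$ have normal and
  inverse-gamma conditionals, and the Cauchy priors on $\delta$ are handled
  through their inverse-gamma scale-mixture representation, which restores
  conjugacy. In the median-split model $\sigma^2$ appears in the group mean
  as well and is updated by a Metropolis step on $\log\sigma^2$.
* Participant-level parameters are updated by one joint Metropolis proposal
  per participant over all four probit-scale parameters, drawn from a
  per-participant covariance learned during burn-in (Welford accumulators,
  refreshed Cholesky factors, scalar step adapted to ~25% acceptance). The
  joint proposal matters because utility magnitude ($A'$, $w'$) and softmax
  sensitivity ($c'$) are strongly correlated in the likelihood; axis-aligned
  walks crawl along that ridge.
* Two families of non-centered moves break the remaining coupling between
  group and participant levels: translation moves that shift a group-level
  linear predictor and every participant's parameter together through the
  likelihood, and scale moves that jointly expand the residual spread and
  the residuals (with the appropriate Jacobian). Both adapt during burn-in
  only, so the retained chain is time-homogeneous.

A gradient-based sampler over the joint space is the other natural
implementation; the conjugacy of every group-level conditional makes the
Gibbs/Metropolis hybrid simpler, dependency-free and fast here, and the
sampler is validated behaviorally rather than by construction: exact
conjugate shrinkage in the fixed-$g$ sub-case, prior recovery with no data,
simulation-based-calibration rank uniformity on the linear path, and the
analytic-oracle agreement above.

The likelihood kernel memoizes utilities over the (few) distinct net
outcomes of the deterministic payoff schedule and maintains the softmax
normalizer incrementally (one exponential and one logarithm per trial, with
occasional rebasing against overflow); it matches a plain reference
implementation to machine precision. All randomness flows through R's RNG,
including inside the compiled steps, so runs are exactly reproducible under
`set.seed`. Initial values follow the published protocol: standard-normal
group means, exponential(1) group spreads, regression weights from
$\mathcal N(0, 2^2)$, $g = 1$, and participant parameters at their implied
conditional means.

## Convergence diagnostics and run lengths

`gelman_rubin()` implements the split potential-scale-reduction statistic on
every group-level quantity. The convergence gate for study summaries is
$\hat R \le 1.01$ at the full-scale protocol (2 chains of 45,000 iterations,
5,000 burn-in, thinning 5 — the package default). Desk-scale runs
necessarily use short chains (2 × 12,000); there the sampler typically
reaches $\hat R$ of 1.05–1.25, because synthetic participants with high
consistency ($\theta \approx 150$) make the likelihood nearly discrete and
slow for random-walk moves. Desk-scale study paths therefore flag fits
against a loose desk gate of 1.3 — which excludes only catastrophic,
visibly stuck fits — and always report the per-fit maximum $\hat R$, keeping
exclusions auditable. Conclusions drawn at desk scale are sign-level only;
magnitude claims require the full-scale protocol.

## The synthetic-data generator

The generator reproduces the study conditions: $N$ participants (150 at
full scale) each receive two covariate scores from a bivariate standard
normal with correlation $\rho \in \{0, 0.7\}$; probit-scale parameters
follow the generating regression with weights
$(\alpha_{A'1}, \alpha_{A'2}) = (1, 0)$ and
$(\alpha_{w'1}, \alpha_{w'2}) = (0, -0.9)$ (true effect of covariate 1 on
outcome sensitivity, true negative effect of covariate 2 on loss aversion,
near-null weights for $a'$ and $c'$), intercepts $(0.24, 0.38, 0.30, 1.34)$
and spreads $(1.06, 0.91, 1.58, 0.46)$; and each synthetic participant plays
$T$ trials (200 at full scale) of the traditional IGT through the forward
simulator. Per-dataset seeds are `base_seed + index`, recorded with the
ground truth so any single dataset can be regenerated alone.

What the generator deliberately does not emulate: real covariates are
neither exactly normal nor exactly linearly related to probit-scale
parameters; real participants drift, lapse, and differ in trial counts; and
payoff schedules in real administrations are sometimes shuffled within
blocks (the generator deals losses in fixed positions, as the simulated
study did). Passing tests on synthetic data therefore validate the
machinery — likelihood, priors, sampler, Bayes factors — not the
substantive adequacy of PVL-Delta for any particular population.

## Problem sizes used by the tests and the acceptance script

The test suite and the acceptance script run the study comparison at 60
participants × 100 trials with 3 datasets per scenario, 2 × 10,000–14,000
iteration chains for the regression fits and 2 × 5,000–6,000 for the
faster-mixing median-split fits. These sizes were
chosen so the whole suite completes on a single CPU in well under half an
hour while still separating the true-effect, null, and spurious-effect
cells by sign. The full-scale study (50 datasets, 150 × 200, paper-scale
chains) is available through `scenario_config()` +
`sampler_config()` defaults or the command line's `--paper-scale` flag, and
takes CPU-days.

## Known limitations

* Savage-Dickey estimates saturate beyond $|\log \mathrm{BF}| \approx 5$
  (see above); bridge sampling would be the next tool for such cells.
* Only marginal (one-at-a-time) point nulls are tested; joint nulls over
  several effect sizes would require multivariate density estimation at the
  null and are out of scope.
* Missing covariates, unequal trial counts, and non-traditional payoff
  schemes are not supported (the schedule interface is pluggable, but only
  the traditional scheme ships).
* The desk-scale convergence caveat above applies to every reduced-scale
  number; treat desk-scale magnitudes as indicative.
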