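---
title: "Spatiotemporal relative-risk modelling of climate and sentiment: methods"
author: "climsent authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatiotemporal relative-risk modelling of climate and sentiment: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(climsent)
```

## The model

`climsent` analyses weekly counts of negative-sentiment documents on a
network of regions. Write $NTw(i,t)$ for the number of negative documents in
region $i$ during week $t$ and $TTW(i,t)$ for the total number of documents
in that cell. The model is a Poisson relative-risk regression of the kind
used in disease mapping:

$$NTw(i,t) \sim \mathrm{Poisson}\big(\mu(i,t)\big), \qquad
\mu(i,t) = \theta_{tot}\, TTW(i,t)\, \mathrm{relrisk}(i,t),$$

where $\theta_{tot}$ is the dataset-wide proportion of negative documents
(`compute_theta_tot()`), $TTW$ enters as an exposure offset, and the log
relative risk is additive in a latent space-time field and categorized
covariate effects:

$$\log \mathrm{relrisk}(i,t) = \beta_0 + u(i,t)
 + f_{temp}[c_T(i,t)] + f_{prec}[c_P(i,t)]
 \;(+\, f_{int}[c_T, c_P]).$$

Here $c_T$ and $c_P$ are the temperature and precipitation categories of the
cell. The blocks get Gaussian Markov random field priors:

* the space-time field $u$ is separable, intrinsic CAR (Besag,
  $Q_s = \tau(D - A)$ on the neighbourhood graph, unscaled) in space times a
  stationary AR1 in time, i.e. precision $Q_s \otimes Q_t$. Both "independent
  in space" and "independent in time" variants are available
  (`risk_config(spatial=, temporal=)`); the default is ICAR space with AR1
  time.
* each covariate effect vector ($f_{temp}$, 4 levels; $f_{prec}$, 3 levels)
  gets a chain prior over consecutive levels: independent levels by default,
  optionally an AR chain.
* the optional temperature-by-precipitation interaction gets an intrinsic CAR
  prior on the $4\times3$ category lattice.

The Poisson assumption treats counts as conditionally independent given the
latent surface; all dependence is carried by the mean. Overdispersion beyond
the latent field is not modelled.

## Identifiability and the weekly level

With a global intercept, intrinsic blocks need sum-to-zero constraints, and
covariate effect vectors are only identified up to their mean. The package
reports every effect vector centered (effects are contrasts against the
average category, not against a named reference level; the convention is
recorded in the output metadata).

For the field, two conventions are exposed (`risk_config(field_constraint=)`):

* `"global"` (default): the field is decomposed into a slice-centered part
  (every weekly spatial slice sums to zero) plus an explicit weekly-level
  block $g(t)$ with a flat prior and a single sum-to-zero constraint. This is
  an exact sparse reparameterization of an intrinsic field carrying one
  overall constraint. Week-specific shocks shared by many regions — an
  extreme event, a holiday, a news cycle — are absorbed by $g$ instead of
  being forced out of the model.
* `"per_slice"`: no weekly level; every weekly slice of the field sums to
  zero, so the field carries pure within-week spatial contrasts.

The choice matters for what each analysis estimates best. Under
`"per_slice"`, categorized covariate effects are identified from the full
(mostly seasonal, region-shared) covariate signal and are sharpest; but any
region-average component of an unmodelled shock is unrepresentable, which
biases event-window contrasts downward by the exposed-share of the effect.
Under `"global"`, event contrasts are nearly unbiased, while covariate
effects lose some precision to their partial confounding with the free
weekly level (roughly a 30% increase in posterior sd at the default
synthetic scale). We therefore default to `"global"` and recommend
`"per_slice"` when the covariate effect curves are the primary target.

Zero-exposure cells are dropped from the likelihood ($\mu = 0$ would be
degenerate) but kept in the field, which smooths across them.

## Fitting: constrained Gaussian approximation with empirical Bayes

The fitter is deterministic and sampling-free:

1. **Inner loop.** For fixed hyperparameters, the joint log-posterior is
   maximized over all latents by Newton iteration with backtracking line
   search. Each step solves its equality-constrained quadratic subproblem
   exactly by conditioning by kriging on the orthonormalized constraint rows;
   a penalty $\kappa\, C'C$ is folded into the Hessian before factorization
   (the constrained optimum and covariance are invariant to it) to remove the
   structurally flat intercept/field-level direction that would otherwise
   make the kriging system ill-conditioned. The posterior is then
   approximated by a Gaussian centered at the mode with covariance the
   inverse negative Hessian restricted to the constraint subspace. Posterior
   standard deviations and all reported intervals come from this Gaussian;
   no simplified-Laplace correction is applied (Poisson likelihoods at the
   count sizes targeted here are close to Gaussian in the latents).
2. **Outer loop.** The field precision $\tau$ is chosen by maximizing the
   Laplace-approximate log marginal likelihood over a 7-point logarithmic
   grid from $10^2$ to $10^5$ (empirical Bayes), warm-starting each Newton
   run. The $\tau$ hyperprior is the log-gamma form with shape 1 and rate
   $5\times10^{-5}$. Other hyperparameters are fixed by configuration:
   effect-block precisions default to 1 (prior sd 1 on the log-RR scale,
   essentially noninformative at percent-scale effects), and the AR1
   correlation defaults to $\rho = 0.5$.

The default $\rho = 0.5$ is a deliberate smoothness-versus-robustness
choice: strong temporal priors ($\rho \ge 0.9$) suppress abrupt event-scale
excursions of the field and smear them across window boundaries, degrading
event contrasts; weak temporal pooling costs a little efficiency on smooth
seasonal structure. Users fitting smooth fields with no interest in abrupt
events may raise $\rho$.

Numerical choices: Newton stops when the step max-norm falls below
$10^{-10}$ (cap 50 iterations, error with diagnostics on non-convergence); a
ridge of $10^{-8}$ stabilizes the Hessian; constraints are re-projected to
machine precision each step. Hyperparameter uncertainty is **not**
propagated (pure empirical Bayes), so intervals are slightly narrow when the
marginal likelihood surface is flat.

## Reported surfaces

* `effect_summary()` — per category level: posterior mean and
  $\pm 1.96\,\mathrm{sd}$ interval on the log-RR scale, transformed
  monotonically to percent relative risk ($e^x - 1$), plus the occupancy
  histogram of observed cells per level.
* `rr_difference()` — for each region, the posterior difference of mean log
  relative risk between the during- and before-event windows (28-day windows,
  inclusive endpoints; defaults are the July 2021 flood calendar). The
  variance is propagated through the full joint Gaussian covariance of all
  involved coordinates; a region is flagged when the 95% interval excludes
  zero. The contrast is computed inside a single fit, not by fitting the
  windows separately, so the uncertainty of shared components is handled
  coherently.

## The synthetic-data generator

The generator (`simulate_climate()`, `simulate_panel()`,
`simulate_bundle()`) is first-class, tested code: it produces the known-truth
test bed for everything above. Its defaults define the package's reference
study conditions:

* 13 regions (German federal states with the city states merged into their
  surrounds), 187 weeks from 2019-01-01; the July 2021 flood calendar's
  three windows align exactly with 7-day bins anchored at that origin
  (weeks 126–129, 130–133, 134–137).
* weekly temperature: a yearly sinusoid (mean 12 °C, amplitude 10 °C, trough
  mid-January) plus fixed regional offsets (sd 0.8 °C) and weekly noise (sd
  1.8 °C), clipped to $[-1, 24]$ °C — this populates all four temperature
  categories, with roughly 8–10% of cells in the warmest one.
* weekly precipitation: Gamma(shape 2, scale 0.008) clipped to $[0, 0.07]$
  in the covariate's native unit; the planted event adds 0.04 to four
  contiguous western regions (NW, RP, SL, HE) for the four during-flood
  weeks, pushing those cells into the high category. Clipping (not
  rejection) keeps the number of draws per cell fixed, so output is
  reproducible cell-by-cell.
* exposures $TTW$: negative binomial with mean 6000 (about 14.8M documents
  spread over 13 regions and 187 weeks) and size 5 (heavy-tailed weekly
  volumes), floored at 1 unless zeros are requested.
* the latent field is drawn from the constrained ICAR$\times$AR1 prior with
  $\tau = 24000$ and $\rho = 0.98$, calibrated once so the field's marginal
  sd is about 2% on the log-RR scale with slowly drifting regional baselines
  (correlation half-life about 34 weeks) — the scale of residual
  regional-seasonal sentiment variation the model is meant to absorb.
* ground-truth covariate effects default to scaled echoes of effect sizes a
  weekly climate signal could plausibly carry (fractions of a percent up to
  2%); the vectors are mean-centered at construction so they satisfy the
  same identifiability convention under which effects are reported, with
  the removed mean absorbed into the baseline rate. The default event bump
  is $\log(1.10)$.
* counts are unbounded Poisson draws; the rare cell with $NTw > TTW$ is
  redrawn (at $\theta_{tot} \approx 0.1$ this touches a few cells per
  million), keeping the panel invariant $0 \le NTw \le TTW$.

What the generator does **not** emulate: real geography (the graph is the
true adjacency but climate is exchangeable across regions apart from random
offsets), spatially correlated weather, text at realistic scale or
vocabulary, non-stationary posting behaviour, and classifier error
structure. Passing recovery tests therefore demonstrates that the inference
machinery is correct and calibrated under the stated generative model — not
that the pipeline is robust to the additional misspecifications of real
social-media data.

## Text pipeline

`clean_text()` implements the normalization chain (lowercase; URLs, handles,
HTML tags, digits, punctuation and symbols removed; hashtag markers dropped
but the bare word kept, configurable; whitespace collapsed) and is
idempotent. Tokenization is whitespace-based with exact stopword removal.
The sentiment scorer is a transparent majority-rule lexicon with optional
prefix stems (`term*`), and ties — including empty documents — are neutral:
a symmetric, conservative rule. It is a pluggable stand-in for external
classifiers; documents labelled by any model can enter `aggregate_panel()`
directly, because the statistics downstream, not the classifier, are the
package's contribution. The shipped German lexicon is synthetic demo
vocabulary, not a validated dictionary. Language filtering is out of scope:
a predicate hook is provided and documents are otherwise assumed
pre-filtered.

Weeks are fixed 7-day bins anchored at a configured origin (default
2019-01-01), not ISO calendar weeks: fixed bins keep 28-day event windows
exact, and the default origin makes the flood windows align with whole
weeks. Exact duplicates (same document id) are counted once; out-of-window
documents are skipped with a logged count; unknown regions are an error.

## Covariate conventions

Category intervals are left-closed/right-open with the first category
unbounded below and the last unbounded above. This single convention
reconciles the stated band edges ("below 0.01", "0.035 and higher") and
gives every finite value — including temperatures below the first printed
band edge — exactly one category. Weekly covariate construction from daily
series defaults to the mean for both temperature and precipitation (the
0–0.07 precipitation range is the scale of a grid-native mean quantity, not
of weekly totals in mm); a sum reducer is available. The unit of
precipitation is treated agnostically throughout: breaks, ranges and
boosts are all in the covariate's native unit.

## Problem sizes used in validation

The test suite exercises the fitter at the reference scale: a 16-region
lattice over 150 weeks with mean exposure 5000 for covariate-effect recovery
(50 replicates), and the 13-region, 187-week default study for the event
contrast (20 replicates). A single fit at these sizes takes a few seconds;
the replicate studies dominate the suite's runtime.

## Known limitations

* Empirical-Bayes intervals ignore hyperparameter uncertainty; full
  integration over hyperparameters (as INLA performs) is out of scope.
* A Gaussian field prior shrinks abrupt localized excursions: in the event
  recovery study about 80% of the injected bump is recovered in exposed
  regions, and the remainder leaks as a ~1% upward bias into all regions'
  window contrasts, which together with real seasonal covariate differences
  makes some unexposed regions genuinely cross the significance line. Event
  contrasts should be read as conservative for exposed regions and
  anti-conservative for their complement.
* The Poisson likelihood carries no extra-Poisson dispersion beyond the
  latent field.
* `log_posterior()`/`fit_risk_model()` assume every cell with exposure has
  complete climate; there is no missing-covariate machinery.
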