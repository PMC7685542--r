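---
title: "Spatio-temporal mapping of routine anaemia counts: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatio-temporal mapping of routine anaemia counts: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(anaemap)
```

## The problem

Routine health-information systems report, per administrative area and
quarter, the number of pregnant women presenting at antenatal care (ANC)
with anaemia (haemoglobin below 11 g/dL) together with the number of new
ANC clients. These counts are noisy, area sizes and facility utilisation
differ wildly, and policy questions are asked at a spatial resolution
(sub-county) where raw rates are unstable. `anaemap` provides small-area
estimation for such panels: smoothed prevalence per area and quarter with
honest uncertainty, WHO public-health severity classification, and
stratified summaries by malaria endemicity zone.

## Model

Let $y_{it}$ be the count in area $i = 1,\dots,I$ and quarter
$t = 1,\dots,T$, and $N_{it}$ the number of new ANC clients. Expected
counts are built by internal standardisation,
$E_{it} = N_{it}\,\bar r$ with $\bar r = \sum y / \sum N$ over observed
cells, so that $\sum E = \sum y$ and the intercept is centred at zero.
Counts are modelled as overdispersed around $E_{it}\pi_{it}$:

$$y_{it} \mid \pi_{it} \sim \mathrm{NegBin}\!\left(E_{it}\pi_{it},\, r\right),
\qquad \operatorname{Var}[y] = \mu(1 + r\mu),$$

so the Poisson model is recovered as $r \to 0$ (the `size` parameter of
the usual parameterisation is $1/r$). The log relative risk decomposes as

$$\log \pi_{it} = \alpha + u_i + v_i + \xi_t + \nu_{it},$$

with

* $u$: structured spatial effect with an intrinsic conditional
  autoregressive (ICAR) prior on the areal adjacency graph — the kernel
  penalises $\tfrac{\tau_u}{2}\sum_{i\sim j}(u_i-u_j)^2$ and is flat along
  per-component constants; together with the unstructured iid normal $v$
  this is the Besag–York–Mollié (BYM) convolution;
* $\xi$: stationary first-order autoregressive quarterly effect,
  $\xi_t \mid \xi_{t-1} \sim N(\rho\,\xi_{t-1}, 1/\tau_\xi)$ with
  $\xi_1 \sim N(0, 1/(\tau_\xi(1-\rho^2)))$, $|\rho|<1$;
* $\nu$: independent $N(0, 1/\tau_\nu)$ space–time interaction
  (Knorr-Held type I — no structure is imposed because none is
  identified by quarterly panels of this length).

Modelled prevalence for a cell is $E_{it}\pi_{it}/N_{it}$; year-level
prevalence per area pools counts,
$(\sum_{t \in \text{year}} E_{it}\pi_{it}) / (\sum_{t} N_{it})$, so
quarters are weighted by client volume rather than averaged.

### Design choices that were genuinely open

* **Standardisation**: a single global crude rate (not per-quarter) is
  used for $E$, so temporal signal stays in $\xi_t$ rather than being
  absorbed into the offset.
* **Temporal indexing**: $\xi$ runs over all $T$ quarters with an AR(1)
  prior; the quarter-of-year mapping is kept only for reporting. A
  4-level seasonal effect would conflate trend and season over a 4-year
  window.
* **Islands** (areas with no neighbours): their structured effect is
  pinned at zero and the unstructured term absorbs their variation, the
  behaviour users of classic disease-mapping software expect.
* **Identifiability**: $u$ is recentred to sum to zero per graph
  component after every sweep, with the subtracted mean absorbed into
  $\alpha$. $v$, $\xi$ and $\nu$ keep proper priors and are not
  constrained; their means trade off against $\alpha$ only through those
  priors, which is reflected honestly in $\alpha$'s posterior spread.
* **Prevalence definition**: the paper-style "prevalence" is taken as
  modelled mean over denominator. Values above 1 are possible (the count
  model is unbounded) and are flagged with warnings and capped only at
  classification time.

## Priors

Following long-standing practice for this model family, precisions get
Gamma(shape, rate) priors, the intercept is flat, any regression
coefficients would get $N(0, 10^2)$ (the shipped model is
covariate-free), $\rho$ is Uniform($-1,1$), and $1/r$ gets a Gamma prior.
The package default is the historical Gamma(0.5, 0.0005) convention.

That default deserves a warning, and it is the reason the simulation
studies in this package use a different, documented configuration. On the
log scale Gamma(0.5, 0.0005) concentrates near $\tau \approx 10^3$, and
the implied prior on $r$ piles up near $r \approx 0.002$. When a variance
component is only weakly identified — and two pairs here are weakly
identified by construction: the BYM split ($u$ vs $v$) and the
overdispersion split ($r$ vs $\nu$, which compete to explain
extra-Poisson cell noise) — the prior decides, and that default decides
badly. For
parameter-recovery and validation studies the package therefore uses
`prior_config(0.1, 0.1, 0.1, 0.1)`: Gamma(0.1, 0.1) is approximately flat
in $\log\tau$ (and $\log(1/r)$) across several orders of magnitude around
1, so weakly identified splits yield wide, honest intervals instead of
prior-driven point masses. Both configurations are one argument away from
the user.

## Sampler

`run_mcmc()` is a Metropolis-within-Gibbs sampler with the sweep order:
site-wise $u$ updates proposing from the ICAR full conditional (neighbour
mean, precision $\tau_u m_i$) and accepting on the negative binomial
likelihood ratio; sum-to-zero recentring of $u$ with compensation into
$\alpha$; random-walk updates for $v$, $\xi$, $\nu$ and $\alpha$;
a random walk on $\mathrm{logit}((\rho+1)/2)$; conjugate Gibbs draws for
the four precisions from their Gamma full conditionals (the ICAR
quadratic form has rank $I - c$ for $c$ graph components); and a random
walk on $\log r$. Proposal scales adapt toward 44% acceptance during
burn-in only, so the post-burn-in kernel is fixed and detailed balance
holds for every retained draw.

Four additional moves are interleaved, each leaving the linear predictor
— and hence the likelihood — untouched and accepted on prior ratios
alone:

1. $u_i \mathrel{+}= c,\; v_i \mathrel{-}= c$ (BYM split),
2. $v_i \mathrel{+}= c,\; \nu_{i\cdot} \mathrel{-}= c$ (area-persistent
   interaction content into the unstructured effect),
3. $\xi_t \mathrel{+}= c,\; \nu_{\cdot t} \mathrel{-}= c$ (time-persistent
   content into the temporal effect),
4. $\xi \mathrel{+}= c\mathbf{1},\; \alpha \mathrel{-}= c$ (temporal level
   against the intercept).

Without them, the 240-cell interaction surface absorbs area- and
time-persistent variance early in the run and single-site sweeps return
it only geometrically slowly; with them, desk-scale chains mix across the
weakly identified splits. Blocks with no likelihood contribution (missing
cells, empty areas or quarters, or a fully missing panel) are drawn
exactly from their prior full conditionals, which is what makes the
prior-recovery check below possible.

The hot loop is compiled (Rcpp) and uses R's RNG throughout, so a fit is
bit-identical given (inputs, configuration, seed); chain $k$ seeds at
`seed + k - 1`.

### Initialisation and degenerate inputs

Chains start at $\alpha = \log(\sum y / \sum E)$ (zero under internal
standardisation), effects jittered $N(0, 0.1^2)$, precisions 1,
$\rho = 0$, $r = 0.5$. A non-finite log posterior at the start aborts
with a state dump. An all-missing panel is allowed (the likelihood is
empty and the sampler explores the prior); the intercept and $r$
likelihood updates are skipped in that case.

## What the synthetic generator emulates — and what it does not

`generate_panel()` simulates exactly the assumed data-generating process
on a rook-contiguity lattice: a constrained ICAR draw via the spectral
decomposition of the graph Laplacian (exact for lattices up to the
national scale of a few hundred areas), iid $v$ and $\nu$, stationary
AR(1) $\xi$, log-normal denominators (median 800 clients/quarter, floored
at 20, echoing facility-volume heterogeneity), and negative binomial
counts. Default size is 30 areas by 8 quarters; a preset matches the
national panel's 290 by 16. Zones are assigned in contiguous lattice
blocks. All realised effect vectors are mean-centred so that ground truth
is exactly expressible in the fitted parameterisation; because the
pipeline re-standardises $E$ from the realised panel, the recoverable
intercept is the returned `alpha_offset`
$= \alpha + \log(\text{base rate}) - \log(\text{realised crude rate})$,
not the nominal $\alpha$.

The generator does *not* emulate reporting-completeness artefacts of real
routine data beyond a missing-completely-at-random cell rate: no
strike-period under-reporting, no facility-level entry errors, no
boundary changes. Passing recovery tests therefore certifies the
estimator under its own assumptions, not robustness to systematic
surveillance bias.

The generator's tails can produce cells with more cases than new clients
(as real routine extracts do); the panel container keeps such cells and
raises a data-quality warning rather than failing.

## Validation and diagnostics

* **Holdout**: `holdout_validate()` masks a seeded uniform sample of
  observed cells entirely (count and denominator), refits once, and
  compares posterior-predictive medians (cell mean pushed through the
  negative binomial) with the held-out counts; Pearson (and Spearman)
  correlations are reported. The full-protocol preset holds out 500
  cells; simulation studies use 50.
* **Convergence**: split-$\hat R$ (each chain halved) is the default,
  being more conservative than the classic statistic, which remains
  available via `split = FALSE`. `effective_sample_size()` uses Geyer's
  initial positive sequence. Constant chains return `NA` rather than a
  number.
* **Prior recovery**: on an all-missing panel the sampler's precision
  marginals are compared with their Gamma prior by Kolmogorov–Smirnov
  test. This check uses a Gamma(2, 1) prior and heavy thinning (5,000
  draws kept from 750,000 sweeps on a 4-area panel): the KS test assumes
  independent draws, and no desk-scale chain traverses the default
  prior's twelve orders of magnitude with near-iid quality — the check
  targets the sampler's invariant measure, not that particular prior.

## Problem sizes used by the shipped studies

The packaged simulation studies run at desk scale, chosen so the full
suite completes comfortably on one CPU: recovery uses 20 replicate
30×8 panels at truth $\alpha = 0.2$, $\rho = 0.6$, $r = 0.3$, all
precisions 4, each fitted with 2 chains × 10,000 iterations (4,000
burn-in); the holdout study masks 50 of 240 cells of a strong-signal
panel (large denominators, small overdispersion). The documented
full-scale protocol — 2 chains × 71,000 iterations, 4,000 burn-in, 500
held-out cells on a 290×16 panel — is available through
`mcmc_config()` defaults and the `"paper"` generator preset.

## Known limitations

* The BYM split and the $r$-vs-$\nu$ split are weakly identified; under
  diffuse priors their posteriors are wide by design. Report the
  convolution $u + v$ and total extra-Poisson variance when a point
  decomposition is not needed.
* $\alpha$'s marginal posterior includes the temporal-level uncertainty
  inherited from the AR(1) prior; with short panels and $\rho$ near 1 it
  is wide. This is a property of the parameterisation, not a mixing
  failure.
* Percentages derived from *observed* totals are reported as point
  values; uncertainty intervals are attached only to model-based
  quantities, since observed counts carry no sampling model here.
* Queen contiguity from GeoJSON matches polygons on shared vertices
  (after coordinate rounding); topologically sloppy boundary files with
  non-coincident vertices along shared borders should be cleaned first
  or supplied as an explicit edge list.
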