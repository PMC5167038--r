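---
title: "Density and space use over a mast-driven rodent cycle: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Density and space use over a mast-driven rodent cycle: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mastsecr)
```

`mastsecr` estimates population density and space use of small mammals from
multi-catch live-trapping grids, and tests whether the density–space-use
relationship differs between the peak (first summer after masting, FSA) and
crash (second summer, SSA) phases of a masting-driven population cycle.
This vignette documents the models, the numerical choices, and the
assumptions behind the synthetic-data generator used by the test suite.

## The SECR observation model

Each animal occupies a latent activity centre $\mathbf{x}$; centres follow
a homogeneous Poisson process with intensity $D$ (animals/ha). A trap at
distance $d$ from $\mathbf{x}$ accrues per-occasion detection hazard

$$\lambda(d) = \lambda_0 \exp\!\left(-\frac{d^2}{2\sigma^2}\right),$$

the half-normal curve. $\sigma$ (metres) is the spatial scale of detection
and serves as a model-based index of home-range size; $\lambda_0$ is the
hazard for a trap at the centre itself.

**$\lambda_0$ is a hazard, not a probability.** Field descriptions often
call $\lambda_0$ the "probability of detection at the activity centre".
We deliberately treat it as the cumulative hazard of the half-normal hazard
function: with several traps competing for one animal, per-trap
"probabilities" cannot be combined coherently, whereas hazards add. For a
multi-catch trap array with per-trap hazards $h_k$ and total
$H = \sum_k h_k$, one occasion yields

$$P(\text{caught in } k) = \frac{h_k}{H}\left(1 - e^{-H}\right), \qquad
  P(\text{not caught}) = e^{-H},$$

the competing-risks multinomial. When hazards are small,
$1 - e^{-\lambda_0} \approx \lambda_0$, so the two readings agree in the
sparse-detection limit. A global behavioural response multiplies
$\lambda_0$ by $b$ from the occasion after an animal's first capture
*within a session*; it resets between sessions because sessions are
modelled as independent populations.

## Likelihood and habitat mask

The probability that an animal centred at $\mathbf{x}$ is detected at least
once in $K$ occasions is $p_\cdot(\mathbf{x}) = 1 - e^{-K H(\mathbf{x})}$
(naive $\lambda_0$: the behavioural response cannot act before a first
capture). Integrals over the plane are discretised on a habitat mask: a
regular grid of cells within a buffer of the trap array. With cell area $c$
(ha), mask points $\mathbf{x}_m$, $n$ detected animals with histories
$\omega_i$, the full (Poisson-$n$) log-likelihood of one session is

$$\log L = -D\,a(\theta) + n \log D +
  \sum_{i=1}^{n} \log\Big[c \sum_m \Pr(\omega_i \mid \mathbf{x}_m)\Big]
  - \log n!,$$

with effective sampled area $a(\theta) = c \sum_m p_\cdot(\mathbf{x}_m)$.
$\Pr(\omega_i \mid \mathbf{x})$ multiplies the competing-risks terms over
occasions, switching the hazard scale to $b\lambda_0$ after the first
capture. Including $-\log n!$ keeps log-likelihoods comparable across model
structures, which AICc ranking requires. Multi-session models share or
split $D$, $\sigma$ and $\lambda_0$ across sessions according to the model
structure; animals are never linked across sessions.

Numerical choices:

* **Optimisation.** All parameters are log-transformed and maximised with
  BFGS using an analytic gradient of the likelihood (verified in the test
  suite against central differences); convergence tolerance `reltol = 1e-8`
  on the objective. Wald standard errors come from the inverse numerical
  Hessian at the optimum.
* **Starting values.** $\sigma_0$ = half the mean recapture displacement
  (fallback: half the mask spacing), $\lambda_0 = 0.3$, $b = 1$, and
  $D_0 = n / a(\sigma_0, \lambda_0)$ — the detected count over the
  effective sampled area implied by the starting detection parameters.
  Starting $D$ from $n$ over the whole mask area instead routinely placed
  the optimiser in a poor basin on sparse sessions.
* **Mask.** Default buffer 100 m (generous for $\sigma \approx 12$ m;
  detection hazard at 100 m is below $10^{-14}$ of its central value) and
  default spacing 10 m, equal to the trap spacing. The spacing should stay
  well below $\sigma$ — midpoint integration of a kernel that varies on the
  scale of $\sigma$ degrades once cells approach that scale — and the test
  suite checks that refining from 10 m to 5 m changes the negative
  log-likelihood by less than 0.1 at study scale. Where this package's own
  simulation suites trade mask resolution for problem size, they use 15-m
  masks against $\sigma \ge 11$ m, and reserve 20-m masks for model-ranking
  exercises where only likelihood differences matter.
* **Degenerate inputs.** A session with zero detected animals has an exact
  likelihood ($-\log L = D\,a(\theta)$) and is accepted in pooled fits, but
  a session-specific density for an empty session is refused with an error
  naming the session. Non-convergence is flagged on the fit, not raised.

## Model selection

Candidate structures let $D$ and $\sigma$ be constant or session-specific
and $\lambda_0$ be constant, session-specific, or constant with a
behavioural response — $2 \times 2 \times 3 = 12$ models in a fixed order.
This is one defensible reading of a "12 models from all combinations of
three parameters" design (a fully crossed four-level $\lambda_0$ axis would
give 16 models, a two-level one 8), so every function that consumes a model
set also accepts a user-supplied list of structures. Ranking uses AICc with
effective sample size $n$ = the number of distinct individuals detected
(standard SECR practice); models with $n \le K + 1$ are excluded from
ranking with a warning rather than given a meaningless correction. Ties are
broken by fewer parameters, then input order.

## Overlap statistics

$k = \sigma\sqrt{D}$ in consistent units; with $D$ per hectare and $\sigma$
in metres, $k = \sigma\sqrt{D}/100$, which is dimensionless and zero only
at zero density. Constant $k$ is equivalent to
$\log \sigma = \log(100k) - 0.5 \log D$: home-range size shrinking with the
square root of density at a fixed degree of neighbour overlap. The derived
quantity $S_{95} = 6\pi k^2$ estimates how many individuals occur at any
time within one animal's 95% home range (a circle of radius
$\sqrt{6}\sigma$ under the half-normal model).

Phase-level $S_{95}$ is reported **both** ways — $6\pi(\bar k)^2$ from the
phase-mean $k$, and the phase mean of per-session $6\pi k^2$ — because the
square and the average do not commute (Jensen's inequality); with
session-to-session variation in $k$ the session-averaged convention is
systematically the larger. Exposing both avoids silently choosing one.

## The mixed-model stage

Per-session estimates $(\hat D_p, \hat\sigma_p)$ are treated as data in two
Gaussian linear mixed models with a random intercept per study site,
estimated by maximum likelihood (not REML, so likelihoods remain comparable
across fixed-effect structures; Wald tests use the ML covariance):

* density model: $\log \hat D \sim \text{phase} \times \text{sex} +
  \text{month} + (1 \mid \text{site})$;
* space-use model: $\log \hat\sigma \sim (\log \hat D + \text{phase} +
  \text{sex})^2 + \text{month} + (1 \mid \text{site})$ (all two-way
  interactions).

Month enters as a centred numeric covariate (June = 6 … September = 9);
the design gives no reason to spend three degrees of freedom on a
four-level factor, and the density model includes month for symmetry with
the space-use model. Reference levels are SSA and female, so the phase main
effect reads as the FSA offset. Terms are tested with Wald Type II
chi-squares (each term adjusted for all others except higher-order terms
containing it), computed via `car::Anova` on the `lme4` fit — the standard
tooling for exactly this model class.

Two caveats are deliberate properties of the procedure, not oversights.
First, the estimation uncertainty of $\hat D$ and $\hat\sigma$ is ignored
by the second stage; because the errors in $\log\hat D$ are substantial for
sparse crash-phase sessions, the fitted $\log D$ slope attenuates towards
zero relative to the generating $-0.5$, and the negatively correlated
errors of $\log\hat\sigma$ and $\log\hat D$ push the other way. Second,
session estimates based on very few individuals are uninformative about
$\sigma$ and can leverage the regression; the pipeline therefore excludes
sessions with fewer than 3 detected individuals from the second stage.

## The synthetic-data generator

`mast_cycle_scenario()` emulates the statistical structure the analysis
assumes: for every site × year × month × sex cell it draws a true density
from a lognormal matched (on the natural scale) to the phase- and
sex-specific mean and SD, sets $\sigma = 100 k_{\text{phase}}/\sqrt{D}$ so
the overlap index is exactly the configured phase value, and simulates
multi-catch trapping by the same competing-risks mechanism the likelihood
assumes. Defaults encode the study design this package targets: 8 sites,
8×8 grids at 10-m spacing, five-night sessions June–September over two FSA
years (2010, 2012) and two SSA years (2011, 2013) following mast autumns
2009 and 2011; FSA densities near 22–28 animals/ha and SSA densities near
5–6 with large right skew (hence the lognormal); overlap $k$ 0.54/0.58
(FSA females/males) versus 0.30/0.37 (SSA). No $\lambda_0$ or $b$ is
reported for the real system, so the generator uses $\lambda_0 = 0.5$ and
$b = 1$ as neutral defaults, with a trap-happy $b = 1.5$ variant for
model-selection exercises. The simulation region pads the trap bounding box
by 150 m — wider than the 100-m analysis buffer — so edge animals are
representable; true densities refer to that region.

What the generator does *not* emulate, and hence what passing tests cannot
show about field data: spatial clumping of activity centres (kinship
structure), within-season demography (births, deaths, dispersal between
monthly sessions), heterogeneous detection among individuals, trap
saturation (multi-catch traps never fill), and any direct effect of food on
behaviour. Recovery results under the generator demonstrate the estimator
and pipeline are consistent with their own assumptions — the classical
simulation check — not that those assumptions hold in the forest.

## Problem sizes used by the simulation suites

The test suite scales the study down so the checks measure properties, not
patience; sizes were fixed by pilot power calculations and then frozen:

* parameter recovery: 100 single sessions at $D = 25$/ha, $\sigma = 12$ m,
  $\lambda_0 = 0.5$ on the 8×8 design with the default 10-m mask;
* simulator–likelihood consistency: one pooled fit of 50 sessions on a
  12×12 grid at $D = 50$/ha (about 6 400 individuals), sized so a 2%
  agreement check sits several Monte-Carlo standard errors from the truth;
* structure recovery: 50 replicates of 8 alternating-phase sessions with a
  trap-happy response, 20-m mask;
* phase-effect recovery: 20 replicates of an 8-site, one-FSA-year,
  one-SSA-year study, 15-m mask, site-level fits sharing $\lambda_0$ across
  sessions (the best-supported structure in this design).

## Known limitations

Homogeneous density only (no density surfaces or covariates); multi-catch
competing-risks detectors only — data from true single-catch traps are
analysed under the multi-catch approximation, a deliberate and standard
choice whose $D$ and $\sigma$ estimates are robust to that
misspecification; closed populations within sessions; no errors-in-variables
treatment in the second stage; Euclidean planar distances in metres (no
geodesy).
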