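# mastsecr

Spatially explicit capture–recapture (SECR) analysis of small-mammal
live-trapping grids across a masting-driven population cycle.

Granivorous rodents such as the yellow-necked mouse erupt after beech mast
autumns: the first summer after masting (FSA) is a population peak, the
second (SSA) a crash. `mastsecr` implements the full analysis chain needed
to ask whether the relationship between population density and individual
space use differs between the two phases:

1. **SECR estimation.** Animals occupy latent activity centres distributed
   as a uniform Poisson process with density *D* (animals/ha). A trap at
   distance *d* from an animal's centre accumulates detection hazard
   λ(d) = λ₀·exp(−d²/2σ²) per night; multi-catch traps compete for the
   animal, so it enters trap *k* with probability
   (h_k/H)(1 − e^(−H)), H = Σ h_k. The full (Poisson-n) likelihood
   integrates each capture history over a discretised habitat mask and
   yields maximum-likelihood estimates of *D*, σ (the spatial scale of
   detection — a model-based index of home-range size), λ₀, and optionally
   a global behavioural response *b* after first capture.
2. **Model selection.** Candidate structures let *D*, σ and λ₀ be constant
   or session-specific; AICc, Akaike weights and evidence ratios rank them.
3. **Home-range overlap.** k = σ√D (dimensionless with *D* per m²;
   `k = sigma * sqrt(D) / 100` in ha/metre units) and S₉₅ = 6πk², the
   expected number of individuals inside one animal's 95% home range.
4. **Mixed-model stage.** Session-level estimates feed Gaussian GLMMs
   (random site intercept, ML): log D ~ mast phase × sex + month, and
   log σ ~ (log D + phase + sex)² + month, with Wald Type II tests. Under
   constant within-phase overlap, log σ = log(100k) − 0.5·log D, so the
   log D slope has −0.5 as its reference value and the phase coefficient
   measures log(k_FSA/k_SSA).
5. **Synthetic data.** A generator emulates the whole design — 8 sites,
   8×8 grids at 10-m spacing, 5-night monthly sessions June–September over
   FSA/SSA years — with phase-and-sex-specific lognormal densities and
   phase-specific overlap k.

## Worked example

```r
library(mastsecr)

traps <- make_grid(8, 8, 10)                  # 64-trap grid, 10-m spacing
mask  <- build_mask(traps, buffer = 100, spacing = 10)

set.seed(42)
sim <- simulate_session(D = 25, detection_params(lambda0 = 0.5, sigma = 12),
                        traps, K = 5)
fit <- fit_secr(sim$session, traps, mask)
fit
```

```
SECR fit: D ~ constant, sigma ~ constant, lambda0 ~ (.)
  1 sessions, 42 individuals, logLik -639.884, 3 parameters
 parameter group log_estimate  log_se estimate
         D   all        3.276 0.16965  26.4666
     sigma   all        2.653 0.06706  14.1995
   lambda0   all       -1.073 0.18165   0.3418
```

One five-night session detected 42 animals; the fit estimates about 26.5
animals/ha (truth 25) with a spatial scale of 14.2 m (truth 12) — single
sessions are noisy; pooling sessions or sharing λ₀ across sessions tightens
them. Derived overlap:

```r
k_index(26.4666, 14.1995)   # 0.7305  overlap index sigma * sqrt(D) / 100
s95(0.7305)                 # 10.06   expected neighbours in a 95% home range
```

A full study, end to end:

```r
cfg <- scenario_config(seed = 1)        # the 8-site, 4-year default design
sc  <- mast_cycle_scenario(cfg)
write_bundle(sc, "study")
bundle <- read_bundle("study")
trap_nights(bundle)                     # 40960 trap nights of effort
res <- run_pipeline(bundle, "results")  # model tables, overlap, GLMM TSVs
```

A thin command-line front end with `simulate`, `fit`, `select`, `overlap`,
`glmm` and `pipeline` subcommands is installed at `inst/cli/mastsecr`.

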