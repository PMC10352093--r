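---
title: "Search-encounter SECR: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Search-encounter SECR: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Fenced reserves hold closed populations of large carnivores whose
management (translocation, contraception, removal) hinges on credible
estimates of abundance, density, sex structure and space use. Individuals
are identifiable from photographs (whisker-spot patterns and scars), but
sampling is *unstructured*: a vehicle searches the road network daily and
records every identified encounter, rather than operating a fixed trap
array. `sesecr` implements the full analysis chain for such
search-encounter data: discretisation of the reserve and the search tracks
into a trap grid, a Bayesian spatially explicit capture–recapture (SECR)
model with search effort as a detection covariate, convergence and
goodness-of-fit diagnostics, derived management quantities, and a
rarefaction experiment that converts the question "how many kilometres must
we drive next year?" into measured precision and bias.

## The model

The reserve interior is gridded into pixels of area $a$ (default
0.5 km^2^). Each pixel is simultaneously a candidate *activity centre*
location and a *trap*; one calendar day is one sampling occasion. The data
are a binary array $y_{ijk}$ (individual $i$ seen in pixel $j$ on day $k$)
and an effort matrix $e_{jk}$ (km driven in pixel $j$ on day $k$).

The population is embedded in an augmented set of $M$ pseudo-individuals
with inclusion indicators $z_i \sim \mathrm{Bern}(\psi)$, sexes
$\mathrm{sex}_i \sim \mathrm{Bern}(\psi_{\mathrm{sex}})$ and activity
centres $s_i$ uniform over the pixel set. Abundance is
$N_{\mathrm{super}} = \sum_i z_i$ and density is
$N_{\mathrm{super}}$ divided by the state-space area (pixel count
$\times a$) — the discretised area, not the nominal park area, so the
identity $D \cdot A / 100 = N$ holds exactly draw by draw.

Detection follows a complementary log-log (hazard) model:

$$\mathrm{cloglog}\,\pi_{ijk} = \log \lambda_0
  + \beta_{\mathrm{eff}} \log e_{jk}
  + \beta_{\mathrm{sex}} \cdot \mathrm{male}_i
  - \left( \frac{d(s_i, j)^2}{2\sigma^2_{\mathrm{sex}_i}} \right)^\theta,
  \qquad \theta = 1,$$

i.e. a half-normal decay of the encounter hazard with distance from the
activity centre, a log-linear effort effect (an elasticity on the hazard
scale), and a male offset. The five candidate models toggle which pieces
are sex-specific: Model 1 (both $\lambda_0$ and $\sigma$), Model 2
($\sigma$ only), Model 3 (neither), Model 4 ($\lambda_0$ only), and
Model 5, a nonspatial effort-corrected benchmark in which the distance
term is dropped, the capture history collapses to individual × occasion,
and the covariate is the total km searched that day. Model 5 is the
minimal interpretation consistent with "conventional capture–recapture
corrected for effort"; it exists to show what ignoring space costs, not to
be reported.

**Zero effort.** An unsearched pixel-day cannot produce a detection, so
$\pi = 0$ there rather than evaluating $\log 0$. Detections reported
opportunistically (tip-offs) can still land in unsearched cells; those
pixels join the trap set and the cell receives a configurable effort floor
(`effort_floor_km`, default 0.1 km — about one minute of driving) so the
observed detection has positive likelihood. This is our resolution of a
genuinely open point; the floor only ever touches cells that hold a
detection, so the effort matrix used for conservation checks is unchanged.

**Priors.** The source protocol inherits priors from earlier code without
stating them, so `sesecr` uses explicit vague proper ones:
$\log\lambda_0, \beta_\cdot \sim N(0, 10^2)$,
$\sigma \sim U(0, \mathrm{diameter})$, $\psi, \psi_{\mathrm{sex}} \sim
\mathrm{Beta}(1,1)$. With ~180 detections these are numerically inert;
they guarantee a proper posterior for arbitrarily sparse rarefied subsets.

## Sampler

`secr_fit()` runs Metropolis-within-Gibbs per sweep in a fixed order:
continuous parameters, then $z$, sexes, activity centres, then the
conjugate $\psi$ and $\psi_{\mathrm{sex}}$ draws. $\lambda_0$ and the
$\sigma$s use log-scale Gaussian random walks (the $\sigma$ walk carries
its Jacobian against the uniform prior; the $\lambda_0$ walk needs none
because its prior is placed on the log scale); the $\beta$s use plain
Gaussian walks. Activity centres propose uniformly among pixels within
$3\max(\sigma_f,\sigma_m)$ km; off-state-space proposals are rejected,
which preserves symmetry. The likelihood factorises so that one sweep
costs $O(M + GJ_{\sigma\text{-moves}} + \#\mathrm{detections})$; a full
31,000 × 4-chain protocol at survey scale (~1,000 pixels, 90 occasions,
$M = 200$) runs in hours on one CPU, and the scaled test worlds in tens of
seconds.

Proposal scales adapt during burn-in only (targeting 20–40% acceptance,
windows of 50 sweeps) and freeze afterwards, so retained draws satisfy
detailed balance. Initial values are overdispersed across chains: detected
individuals start at their detection centroid with $\sigma$ from the RMS
spread of their detections (fallback 2 km), and $\lambda_0$, $\psi$, the
$\beta$s are jittered per chain. Chain seeds derive deterministically from
the master seed; identical inputs and seed give bit-identical output.

## Diagnostics

* **Convergence**: the classical (non-split) Gelman–Rubin factor per
  parameter, gated at 1.05 for full-data fits and 1.1 for sparse rarefied
  subsets. `sampler_config(extra_discard = )` reproduces the practice of
  discarding additional initial draws post hoc when needed.
* **Goodness of fit**: a posterior predictive check on *individual
  encounters*. The exact discrepancy in the original protocol is not
  published, so we use the Freeman–Tukey statistic on per-individual total
  encounter counts — the standard choice for this family — with replicates
  simulated conditional on each retained draw's latent state. The model is
  rejected when the tail probability leaves (0.15, 0.85).
* **Parameter redundancy**: the visual inspection of pairs plots is
  replaced by a screen on posterior correlations, flagging $|\rho| > 0.9$
  (configurable).
* **Intervals**: HPD intervals are the shortest contiguous window holding
  $\lceil \gamma n \rceil$ sorted draws, first window on ties.

## Derived quantities

Density draws are $N/A \times 100$; the sex ratio is
$(1-\psi_{\mathrm{sex}})/\psi_{\mathrm{sex}}$ females per male; the 95%
home-range area is $\pi \sigma^2 \cdot 5.99$ per draw (5.99 being
$\chi^2_{2,0.95}$), summarised as the posterior mean of the transform —
which, by Jensen's inequality, exceeds the transform of the posterior mean
by a few percent. The pixel density surface is the posterior mean count of
included activity centres per pixel and sums exactly to the posterior mean
of $N_{\mathrm{super}}$.

## Rarefaction

`run_rarefaction()` accumulates whole chronological survey days until each
effort target is reached (field teams drive complete circuits, so days are
never cut), rebuilds effort and captures from scratch for each prefix, and
refits. Model 1 is used unless either sex retains fewer than 2 recaptures
— an explicit version of the judgement call made when a sparse subset
cannot support sex-specific parameters — in which case Model 3 is fitted.
Each subset is scored by CV (posterior SD over mean) and relative bias
against the full-data fit for $\sigma$ (per sex), $\psi_{\mathrm{sex}}$,
$N_{\mathrm{super}}$ and $D$; a subset is *adequate* when every CV < 20%
and every |RB| < 15%. The full-effort subset is its own reference, so its
RB is identically zero — deliberately, as the experiment measures
degradation relative to the best available estimate, not truth.

## The synthetic world

`scenario()` defaults encode the survey the pipeline targets: a ~500 km^2^
fenced polygon, 0.5 km^2^ pixels, 90 daily searches of 78.5 km
(~7,065 km total), 44 individuals with uniform activity centres,
$\lambda_0 = 0.005$, $\beta_{\mathrm{eff}} = 0.79$,
$\beta_{\mathrm{sex}} = -0.13$, $\sigma_F = 3.19$, $\sigma_M = 3.85$ km,
53% males. Tracks are bounded correlated random walks emitted as ~0.1 km
spaced GPS points; they emulate coverage intensity, not an actual road
network, and the generator makes no attempt at territoriality, social
structure (prides share centres in reality), habitat-driven density
variation or misidentification. A green recovery test therefore
establishes that the estimator inverts its own generating model at
realistic data densities — not that field data meet those assumptions.

`scenario_recovery()` is the scaled world used by the tests (~150 km^2^,
~290 pixels, 25 occasions of 60 km, $N = 40$, $\lambda_0 = 0.01$,
$\sigma$ = 2/3 km): search intensity per km^2^ and detections per
individual (~4) match the full-scale default while one Model-1 fit
(3 × 5,000 sweeps) takes ~1 minute.

## Numerical choices and edge cases

* Grid origin anchors at the boundary bounding-box lower-left corner;
  pixels are retained iff their centroid is inside the polygon
  (determinism; note a square park therefore yields slightly fewer pixels
  than area/`pixel_area` because edge pixels cannot be fractional).
* Track segments are split exactly at grid lines, so effort is conserved
  to floating-point accuracy (tested at 10^-6^ km); pieces outside the
  retained pixels are clipped and reported, never silently lost.
* Coordinates are projected once to a local equirectangular km frame
  (adequate below ~50 km extents; no geodesy library is required). Any
  metric projection is acceptable — $\sigma$ and effort are in km.
* `log(1 - pi)` is computed as `-h` and `log(pi)` as `log(-expm1(-h))` on
  the hazard scale, keeping tiny probabilities exact.
* A detection with $z_i = 0$ or $\pi = 0$ returns `-Inf` flagged, and
  initialisation retries (then aborts) if a chain starts at zero
  likelihood.
* Multiple same-day same-pixel sightings collapse to one binary entry;
  days without any track are dropped (occasions without effort are
  uninformative under the effort model).

## Known limitations

* Demographic and geographic closure is assumed over the survey window;
  there is no open-population machinery.
* Independence of individuals is assumed; pride structure will make
  detections overdispersed, which the goodness-of-fit check can flag but
  the model cannot absorb.
* Effort is km driven; time-of-day, habitat visibility and observer
  effects are not modelled (deliberately out of scope).
* The nonspatial Model 5 shares the likelihood machinery but discards
  spatial recaptures; its density requires an externally supplied area and
  it is included for comparison only.
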