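# sesecr — Bayesian search-encounter spatial capture–recapture

`sesecr` estimates the density, abundance, sex ratio and home-range size
of individually identifiable animals in fenced reserves from
*unstructured search-encounter* surveys: a vehicle drives the reserve
daily logging its GPS track, and every photographic identification of an
individual becomes a spatially referenced detection. It is aimed at
ecologists and reserve managers who need defensible population estimates
for large carnivores (the design case is lions in a ~500 km² fenced park)
and a quantitative answer to "how much search effort is enough?".

## The model

The reserve is gridded into 0.5 km² pixels that act both as candidate
activity-centre locations and as "traps"; one day is one occasion. With
data augmentation (`z_i ~ Bern(ψ)`, `N_super = Σ z_i`, centres `s_i`
uniform over pixels, sexes `~ Bern(ψ_sex)`), detection is a complementary
log-log hazard model with a half-normal distance kernel and search effort
as a covariate:

    cloglog π_ijk = log λ0 + β_eff · log(effort_jk) + β_sex · male_i
                    − d(s_i, j)² / (2 σ²_sex)

Five candidate models toggle the sex-specificity of `λ0` and `σ`
(Model 5 is a nonspatial effort-corrected benchmark). Fitting is
Metropolis-within-Gibbs MCMC; diagnostics include Gelman–Rubin r-hat, a
posterior predictive Bayesian p-value on individual encounter counts
(reject outside .15–.85), HPD intervals and a parameter-redundancy
screen. A rarefaction module refits the model to chronological effort
prefixes and scores precision (CV) and relative bias against the
full-data estimate. A synthetic-data generator produces parks, tracks,
populations and detections with the assumed structure, so the whole
pipeline is testable offline.

## Worked example

```r
library(sesecr)

# a ~150 km² fenced reserve, 25 daily searches of 60 km, 40 lions
sim <- simulate_survey(scenario_recovery(), seed = 42)
print(sim$space)
print(sim$effort)
print(sim$ch)

fit <- secr_fit(sim$ch, sim$space, spec = model_spec(1), M = 100,
                config = sampler_config(n_iter = 5000, burn_in = 1000,
                                        n_chains = 3, seed = 42))
rep <- diagnose(fit, sim$ch, sim$space, seed = 42)
print(rep)
print(derived_summary(fit))
```

Output (about one minute of sampling):

```
state_space: 289 pixels of 0.50 km^2 (total 144.5 km^2), grid 18 x 18
effort_matrix: 289 traps x 25 occasions, 1440.3 km searched (59.73 km clipped off)
capture_history: 35 individuals (16 F / 19 M), 289 traps, 25 occasions
  133 detections, 98 recaptures, 3.8 average spatial recaptures
convergence: max r-hat 1.0384 (threshold 1.05) -> converged
goodness of fit: Bayesian p = 0.637 -> adequate
Model 1 posterior summaries (n = 35 detected, M = 100, area 144.5 km^2)
 parameter     mean       sd hpd_lower hpd_upper
   lambda0  0.01072 0.003125  0.004797   0.01666
  beta_eff  0.82023 0.156706  0.528026   1.14281
  beta_sex  0.26348 0.346752 -0.339142   0.99379
   sigma_f  2.04492 0.271307  1.561793   2.61206
   sigma_m  2.97124 0.263552  2.474162   3.48408
       psi  0.38846 0.053333  0.286884   0.49473
   psi_sex  0.50379 0.082124  0.348260   0.66523
   N_super 38.60450 2.535504 35.000000  44.00000
         D 26.71592 1.754674 24.221453  30.44983
home range: F 80 km^2 (PSD 22.0), M 167 km^2 (PSD 30.3)
sex ratio 1.0F:1M; detected ~91% of estimated individuals
```

The generating truth was `N = 40`, `λ0 = 0.01`, `σ_F = 2`, `σ_M = 3`,
equal sexes: every generating parameter sits inside its 95% HPD. `N_super`
counts individuals over the whole state space, `D` is per 100 km² of
state-space area (so `D · area / 100 = N` exactly per draw), and the home
ranges are posterior means of `π σ² · 5.99` (the 95% half-normal range).

The same stages are scriptable end to end (JSON config with a `scenario`
block, or `paths` pointing at boundary GeoJSON, track and sighting CSVs):

```sh
Rscript -e 'sesecr::sesecr_cli()' simulate --config run.json --out out
Rscript -e 'sesecr::sesecr_cli()' prepare  --config run.json --out out
Rscript -e 'sesecr::sesecr_cli()' fit      --config run.json --out out --model all
Rscript -e 'sesecr::sesecr_cli()' diagnose --config run.json --out out
Rscript -e 'sesecr::sesecr_cli()' rarefy   --config run.json --out out
Rscript -e 'sesecr::sesecr_cli()' report   --config run.json --out out
```

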