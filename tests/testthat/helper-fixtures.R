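# Shared fixtures, built once per test run and memoised.

.fix <- new.env()
memo_fixture <- function(key, fn) {
  if (is.null(.fix[[key]])) .fix[[key]] <- fn()
  .fix[[key]]
}

# A very small world: handful of pixels, strong detection, for oracle tests.
tiny_survey <- function() memo_fixture("tiny", function() {
  simulate_survey(scenario_recovery(area_km2 = 8, n_days = 3, km_per_day = 6,
                                    N_true = 6, lambda0 = 0.3),
                  seed = 5)
})

# A small but non-trivial world for MCMC-backed tests.
small_survey <- function(seed = 11) memo_fixture(paste0("small", seed), function() {
  simulate_survey(scenario_recovery(area_km2 = 60, n_days = 12, km_per_day = 30,
                                    N_true = 25, lambda0 = 0.02,
                                    sigma_f = 1.5, sigma_m = 2),
                  seed = seed)
})

# One short Model 1 fit on the small world, reused by derived/diagnostic tests.
fixture_fit <- function() memo_fixture("fit1", function() {
  sim <- small_survey()
  secr_fit(sim$ch, sim$space, spec = model_spec(1), M = 60,
           config = sampler_config(n_iter = 1000, burn_in = 300, n_chains = 2,
                                   seed = 99, n_snapshots = 80))
})

# Deterministic sightings table: n_f females / n_m males with the requested
# per-sex detection totals, spread over distinct pixel-days of `sim`.
make_records <- function(sim, n_f, n_m, det_f, det_m) {
  eff <- sim$effort
  pos <- which(eff$values > 0, arr.ind = TRUE)
  stopifnot(nrow(pos) >= det_f + det_m)
  counts <- c(stats::rmultinom(1, det_f - n_f, rep(1, n_f))[, 1] + 1,
              stats::rmultinom(1, det_m - n_m, rep(1, n_m))[, 1] + 1)
  ids <- c(sprintf("F%02d", seq_len(n_f)), sprintf("M%02d", seq_len(n_m)))
  sexes <- c(rep("female", n_f), rep("male", n_m))
  i <- rep(seq_along(ids), counts)
  cell <- seq_len(length(i)) # distinct pixel-day per detection: no collapse
  data.frame(day = eff$occasion_dates[pos[cell, 2]],
             x_km = eff$trap_xy[pos[cell, 1], 1],
             y_km = eff$trap_xy[pos[cell, 1], 2],
             individual_id = ids[i], sex = sexes[i],
             age_class = "older", id_quality = "adequate",
             stringsAsFactors = FALSE)
}
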