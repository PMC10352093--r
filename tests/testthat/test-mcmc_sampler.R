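test_that("configuration and augmentation are validated", {
  expect_error(sampler_config(n_iter = 100, burn_in = 100), "invalid-config")
  expect_error(sampler_config(n_chains = 0), "invalid-config")
  sim <- tiny_survey()
  expect_error(secr_fit(sim$ch, sim$space, M = dim(sim$ch$y)[1],
                        config = sampler_config(n_iter = 50, burn_in = 10,
                                                n_chains = 1)),
               "M must exceed")
})

test_that("identical seed and inputs give bit-identical samples", {
  sim <- tiny_survey()
  cfg <- sampler_config(n_iter = 150, burn_in = 50, n_chains = 2, seed = 3,
                        n_snapshots = 10)
  f1 <- secr_fit(sim$ch, sim$space, M = 20, config = cfg)
  f2 <- secr_fit(sim$ch, sim$space, M = 20, config = cfg)
  expect_identical(f1$chains, f2$chains)
  expect_identical(f1$tally, f2$tally)
  f3 <- secr_fit(sim$ch, sim$space, M = 20,
                 config = sampler_config(n_iter = 150, burn_in = 50,
                                         n_chains = 2, seed = 4))
  expect_false(identical(f1$chains, f3$chains))
})

test_that("psi update is the conjugate Beta draw", {
  st <- augmented_state(200, z = c(rep(1L, 44), rep(0L, 156)),
                        sex = rep(0:1, 100), s = rep(1L, 200),
                        psi = 0.5, psi_sex = 0.5, n = 0L)
  set.seed(1)
  draws <- replicate(4000, update_psi(st)$psi)
  a <- 45; b <- 157 # Beta(1 + 44, 1 + 156)
  expect_equal(mean(draws), a / (a + b), tolerance = 0.01)
  expect_equal(var(draws), a * b / ((a + b)^2 * (a + b + 1)), tolerance = 0.1)
  # Sum z = 0 edge: Beta(1, 1 + M)
  st0 <- st; st0$z[] <- 0L
  d0 <- replicate(2000, update_psi(st0)$psi)
  expect_equal(mean(d0), 1 / 202, tolerance = 0.1)
})

test_that("psi_sex update counts sexes over included individuals only", {
  st <- augmented_state(50, z = c(rep(1L, 20), rep(0L, 30)),
                        sex = c(rep(1L, 12), rep(0L, 8), rep(1L, 30)),
                        s = rep(1L, 50), psi = 0.4, psi_sex = 0.5, n = 0L)
  set.seed(2)
  draws <- replicate(3000, update_psi_sex(st)$psi_sex)
  expect_equal(mean(draws), 13 / 22, tolerance = 0.01) # Beta(1+12, 1+8)
})

test_that("z update matches the two-state enumeration", {
  sim <- tiny_survey()
  ch <- sim$ch; n <- dim(ch$y)[1]
  spec <- model_spec(1)
  dat <- secr_data(ch, ch$effort, sim$space, spec)
  pars <- detection_params(0.15, beta_eff = 0.5, beta_sex = 0.2,
                           sigma_f = 1, sigma_m = 1.4)
  parts <- sesecr:::.make_parts(dat, pars)
  M <- n + 1L
  set.seed(9)
  g <- sample.int(nrow(sim$space$pixels), 1)
  st <- augmented_state(M, z = c(rep(1L, n), 0L),
                        sex = c(as.integer(ch$sexes == "male"), 0L),
                        s = c(rep(1L, n), g), psi = 0.35, psi_sex = 0.5, n = n)
  # oracle: q = prod over searched cells of (1 - pi) via detection_prob
  pos <- which(ch$effort$values > 0, arr.ind = TRUE)
  dists <- sqrt((sim$space$pixels$x_km[g] - ch$effort$trap_xy[pos[, 1], 1])^2 +
                (sim$space$pixels$y_km[g] - ch$effort$trap_xy[pos[, 1], 2])^2)
  q <- prod(1 - detection_prob(pars, dists, ch$effort$values[pos], 0))
  p1 <- 0.35 * q / (0.35 * q + 0.65)
  zdraws <- replicate(3000, update_z(dat, parts, pars, st)$z[M])
  expect_equal(mean(zdraws), p1, tolerance = 0.03)
  # all pi = 0 (lambda0 -> 0): P(z = 1) -> psi
  tiny <- detection_params(1e-300, sigma_f = 1, sigma_m = 1)
  ptiny <- sesecr:::.make_parts(dat, tiny)
  z2 <- replicate(2000, update_z(dat, ptiny, tiny, st)$z[M])
  expect_equal(mean(z2), 0.35, tolerance = 0.035)
  # psi ~ 0: augmented z stay off
  st3 <- st; st3$psi <- 1e-12
  expect_equal(sum(replicate(50, update_z(dat, parts, pars, st3)$z[M])), 0)
  # detected individuals always keep z = 1
  expect_true(all(replicate(20, all(update_z(dat, parts, pars, st)$z[1:n] == 1L))))
})

test_that("sex update reduces to psi_sex under sex symmetry, fixes detected sexes", {
  sim <- tiny_survey()
  ch <- sim$ch; n <- dim(ch$y)[1]
  dat <- secr_data(ch, ch$effort, sim$space, model_spec(3))
  pars <- detection_params(0.1, beta_eff = 0.5, beta_sex = 0,
                           sigma_f = 1.2, sigma_m = 1.2)
  parts <- sesecr:::.make_parts(dat, pars)
  M <- n + 2L
  st <- augmented_state(M, z = c(rep(1L, n), 1L, 0L),
                        sex = c(as.integer(ch$sexes == "male"), 0L, 0L),
                        s = rep(1L, M), psi = 0.5, psi_sex = 0.62, n = n)
  set.seed(4)
  draws <- replicate(3000, update_sex(dat, parts, pars, st)$sex[(n + 1):M])
  expect_equal(mean(draws[1, ]), 0.62, tolerance = 0.03) # included, symmetric
  expect_equal(mean(draws[2, ]), 0.62, tolerance = 0.03) # excluded: prior only
  expect_true(all(replicate(20, identical(update_sex(dat, parts, pars, st)$sex[1:n],
                                          st$sex[1:n]))))
})

test_that("activity-centre occupancy matches the enumerated posterior on a toy", {
  # thin 5-pixel strip; one detected individual seen once in the end pixel
  delta <- sqrt(0.5)
  b <- park_boundary(cbind(c(0, 5 * delta, 5 * delta, 0), c(0, 0, delta, delta)))
  space <- build_state_space(b, 0.5)
  expect_equal(nrow(space$pixels), 5L)
  d <- as.Date("2020-01-01")
  tr <- track_log(d, cbind(seq(0.05, 5 * delta - 0.05, length.out = 50),
                           rep(delta / 2, 50)))
  eff <- compute_effort(list(tr), space)
  rec <- data.frame(day = d, x_km = space$pixels$x_km[1],
                    y_km = space$pixels$y_km[1], individual_id = "A",
                    sex = "female", age_class = "older", id_quality = "adequate")
  ch <- build_capture_history(rec, eff, space)
  dat <- secr_data(ch, ch$effort, space, model_spec(3))
  pars <- detection_params(0.4, beta_eff = 0, sigma_f = 0.8, sigma_m = 0.8)
  parts <- sesecr:::.make_parts(dat, pars)
  st <- augmented_state(1L, z = 1L, sex = 0L, s = 3L, psi = 0.5, psi_sex = 0.5,
                        n = 1L)
  # enumeration oracle: posterior over the 5 pixels, flat prior
  lp <- vapply(1:5, function(g) {
    st2 <- st; st2$s <- g
    as.numeric(log_likelihood(ch, ch$effort, st2, pars, model_spec(3), space)) }, 0)
  post <- exp(lp - max(lp)); post <- post / sum(post)
  set.seed(12)
  occ <- integer(5)
  # r_prop = 1.5 keeps the proposal acceptance workable on the thin strip;
  # 30k sweeps give an effective sample size justifying a 0.025 tolerance
  for (it in 1:30000) {
    st <- update_activity_centres(dat, parts, pars, st, r_prop = 1.5)$state
    occ[st$s] <- occ[st$s] + 1L
  }
  expect_lt(max(abs(occ / 30000 - post)), 0.025)
})

test_that("undetected excluded individuals walk to a uniform distribution", {
  sim <- tiny_survey()
  dat <- secr_data(sim$ch, sim$effort, sim$space, model_spec(3))
  pars <- detection_params(0.1, sigma_f = 1, sigma_m = 1)
  parts <- sesecr:::.make_parts(dat, pars)
  n <- dim(sim$ch$y)[1]
  G <- nrow(sim$space$pixels)
  M <- n + 30L
  st <- augmented_state(M, z = c(rep(1L, n), rep(0L, 30)),
                        sex = rep(0L, M), s = rep(1L, M),
                        psi = 0.5, psi_sex = 0.5, n = n)
  set.seed(5)
  counts <- numeric(G)
  for (it in 1:1500) {
    st <- update_activity_centres(dat, parts, pars, st, r_prop = 3)$state
    tt <- tabulate(st$s[(n + 1):M], G)
    counts <- counts + tt
  }
  # chi-square statistic against uniform
  expe <- sum(counts) / G
  chi2 <- sum((counts - expe)^2 / expe)
  # draws are autocorrelated so compare against a generous multiple of df
  expect_lt(chi2 / (30 * 1500 / 40), G * 3)
  expect_true(all(counts > 0))
})

test_that("vanishing proposal scale drives Metropolis acceptance to one", {
  sim <- tiny_survey()
  dat <- secr_data(sim$ch, sim$effort, sim$space, model_spec(1))
  n <- dim(sim$ch$y)[1]
  pars <- detection_params(0.2, beta_eff = 0.3, beta_sex = 0.1,
                           sigma_f = 1, sigma_m = 1.3)
  parts <- sesecr:::.make_parts(dat, pars)
  st <- augmented_state(n, z = rep(1L, n),
                        sex = as.integer(sim$ch$sexes == "male"),
                        s = match(sim$ch$trap_ids[1], sim$space$pixels$pixel_id) +
                          integer(n), psi = 0.5, psi_sex = 0.5, n = n)
  sc <- c(lambda0 = 1e-9, beta_eff = 1e-9, beta_sex = 1e-9,
          sigma_f = 1e-9, sigma_m = 1e-9, sigma = 1e-9)
  set.seed(6)
  acc <- replicate(40, mean(update_continuous(dat, parts, pars, st, sc)$accepted))
  expect_gt(mean(acc), 0.999)
})

test_that("short fit keeps posterior draws inside their supports", {
  fit <- fixture_fit()
  N <- posterior_draws(fit, "N_super")
  expect_true(all(N >= fit$n & N <= fit$M))
  expect_true(all(posterior_draws(fit, "lambda0") > 0))
  expect_true(all(posterior_draws(fit, "sigma_f") > 0))
  psi <- posterior_draws(fit, "psi")
  expect_true(all(psi > 0 & psi < 1))
  expect_equal(sum(fit$tally), sum(N))
})

test_that("Model 1 fitted to sexless data centres beta_sex near zero", {
  sim <- small_survey() # generated with beta_sex = 0, but sigma_f != sigma_m
  sim2 <- memo_fixture("sym", function()
    simulate_survey(scenario_recovery(area_km2 = 60, n_days = 12, km_per_day = 30,
                                      N_true = 25, lambda0 = 0.02,
                                      sigma_f = 1.7, sigma_m = 1.7), seed = 13))
  fit <- secr_fit(sim2$ch, sim2$space, spec = model_spec(1), M = 60,
                  config = sampler_config(n_iter = 1200, burn_in = 400,
                                          n_chains = 2, seed = 21))
  bs <- posterior_draws(fit, "beta_sex")
  expect_lt(abs(mean(bs)), 2 * sd(bs) + 0.2)
  sf <- mean(posterior_draws(fit, "sigma_f"))
  sm <- mean(posterior_draws(fit, "sigma_m"))
  expect_lt(abs(sf - sm) / sf, 0.4)
})
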