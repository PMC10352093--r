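test_that("model specifications match the candidate set", {
  m <- lapply(1:5, model_spec)
  expect_true(m[[1]]$lambda0_sex_specific && m[[1]]$sigma_sex_specific)
  expect_true(!m[[2]]$lambda0_sex_specific && m[[2]]$sigma_sex_specific)
  expect_true(!m[[3]]$lambda0_sex_specific && !m[[3]]$sigma_sex_specific)
  expect_true(m[[4]]$lambda0_sex_specific && !m[[4]]$sigma_sex_specific)
  expect_false(m[[5]]$spatial)
  expect_true(all(vapply(m, function(x) x$theta == 1, TRUE)))
  expect_error(model_spec(6), "1..5")
})

test_that("distance kernel is the half-normal exponent at theta = 1", {
  expect_equal(distance_kernel(0, 2), 0)
  expect_equal(distance_kernel(1, 1), 0.5)
  expect_equal(distance_kernel(2, 1), 2)
  expect_equal(distance_kernel(3, 2, theta = 2), (9 / 8)^2)
  expect_error(distance_kernel(1, 0), "sigma")
})

test_that("detection probability follows the cloglog closed form", {
  p <- detection_params(lambda0 = 0.005, beta_eff = 0, sigma_f = 1)
  expect_equal(detection_prob(p, d = 0, effort_km = 1, male = 0),
               1 - exp(-0.005), tolerance = 1e-10)
  p2 <- detection_params(lambda0 = 0.005, beta_eff = 0.79, sigma_f = 1)
  expect_equal(detection_prob(p2, d = 0, effort_km = exp(1), male = 0),
               1 - exp(-0.005 * exp(0.79)), tolerance = 1e-10)
  # zero effort means no functioning trap
  expect_equal(detection_prob(p2, d = 0, effort_km = 0, male = 1), 0)
  # pi ~ lambda0 to second order at d = 0, unit effort
  expect_lt(abs(detection_prob(p, 0, 1, 0) - 0.005), 0.005^2)
})

test_that("detection probability is monotone in distance and effort", {
  p <- detection_params(lambda0 = 0.05, beta_eff = 0.8, beta_sex = 0.3,
                        sigma_f = 1.5, sigma_m = 2.5)
  d <- seq(0, 6, by = 0.5)
  for (male in 0:1) {
    pd <- detection_prob(p, d, effort_km = 2, male = male)
    expect_true(all(diff(pd) <= 0))
  }
  eff <- seq(0.1, 5, by = 0.1)
  pe <- detection_prob(p, d = 1, effort_km = eff, male = 0)
  expect_true(all(diff(pe) >= 0))
  # males decay slower here because sigma_m > sigma_f
  expect_gt(detection_prob(p, 3, 1, 1), detection_prob(p, 3, 1, 0) * exp(0))
})

test_that("log likelihood matches the brute-force triple loop to 1e-10", {
  sim <- tiny_survey()
  ch <- sim$ch; space <- sim$space
  n <- dim(ch$y)[1]
  expect_lte(dim(ch$y)[2], 20) # J <= 20, K <= 5, M <= 10 instances
  expect_lte(dim(ch$y)[3], 5)
  set.seed(31)
  for (mid in 1:5) {
    spec <- model_spec(mid)
    for (rep in 1:3) {
      M <- n + sample(1:4, 1)
      st <- augmented_state(M, z = c(rep(1L, n), rbinom(M - n, 1, 0.5)),
                            sex = c(as.integer(ch$sexes == "male"),
                                    rbinom(M - n, 1, 0.5)),
                            s = sample.int(nrow(space$pixels), M, replace = TRUE),
                            psi = runif(1, 0.2, 0.8),
                            psi_sex = runif(1, 0.2, 0.8), n = n)
      sf <- runif(1, 0.8, 2)
      sm <- if (spec$sigma_sex_specific) runif(1, 0.8, 2.5) else sf
      pars <- detection_params(exp(runif(1, -3, -0.5)),
                               beta_eff = runif(1, -0.5, 1),
                               beta_sex = if (spec$lambda0_sex_specific) runif(1, -1, 1) else 0,
                               sigma_f = sf, sigma_m = sm)
      ll <- log_likelihood(ch, ch$effort, st, pars, spec, space)
      expect_equal(as.numeric(ll),
                   oracle_loglik(ch, ch$effort, st, pars, spec, space),
                   tolerance = 1e-10)
    }
  }
})

test_that("sampler's factorised likelihood agrees with the reference", {
  sim <- tiny_survey()
  ch <- sim$ch; space <- sim$space
  n <- dim(ch$y)[1]
  set.seed(7)
  for (mid in c(1, 3, 5)) {
    spec <- model_spec(mid)
    M <- n + 3
    st <- augmented_state(M, z = c(rep(1L, n), rbinom(3, 1, 0.5)),
                          sex = c(as.integer(ch$sexes == "male"), rbinom(3, 1, 0.5)),
                          s = sample.int(nrow(space$pixels), M, replace = TRUE),
                          psi = 0.4, psi_sex = 0.5, n = n)
    pars <- detection_params(0.2, beta_eff = 0.6,
                             beta_sex = if (spec$lambda0_sex_specific) -0.2 else 0,
                             sigma_f = 1.2,
                             sigma_m = if (spec$sigma_sex_specific) 1.7 else 1.2)
    dat <- secr_data(ch, ch$effort, space, spec)
    parts <- sesecr:::.make_parts(dat, pars)
    lat_mass <- sum(dbinom(st$z, 1, st$psi, log = TRUE)) +
      sum(dbinom(st$sex[st$z == 1], 1, st$psi_sex, log = TRUE))
    expect_equal(sesecr:::.ll_y(dat, parts, pars, st) + lat_mass,
                 as.numeric(log_likelihood(ch, ch$effort, st, pars, spec, space)),
                 tolerance = 1e-10)
  }
})

test_that("Model 3 and Model 1 likelihoods coincide when sex effects vanish", {
  sim <- tiny_survey()
  ch <- sim$ch; n <- dim(ch$y)[1]
  set.seed(2)
  M <- n + 3
  st <- augmented_state(M, z = c(rep(1L, n), 1L, 0L, 1L),
                        sex = c(as.integer(ch$sexes == "male"), 1L, 0L, 1L),
                        s = sample.int(nrow(sim$space$pixels), M, replace = TRUE),
                        psi = 0.5, psi_sex = 0.4, n = n)
  pars <- detection_params(0.1, beta_eff = 0.5, beta_sex = 0,
                           sigma_f = 1.5, sigma_m = 1.5)
  expect_equal(log_likelihood(ch, ch$effort, st, pars, model_spec(1), sim$space),
               log_likelihood(ch, ch$effort, st, pars, model_spec(3), sim$space))
})

test_that("empty capture history with all z = 0 gives M log(1 - psi)", {
  sim <- tiny_survey()
  y0 <- array(0L, dim = c(1, dim(sim$ch$y)[2], dim(sim$ch$y)[3]))
  ch0 <- sesecr:::.new_capture_history(y0, "ghost", "female", sim$effort)
  M <- 12
  st <- augmented_state(M, z = rep(0L, M), sex = rep(0L, M),
                        s = rep(1L, M), psi = 0.3, psi_sex = 0.5, n = 0L)
  pars <- detection_params(0.01, sigma_f = 1)
  expect_equal(as.numeric(log_likelihood(ch0, sim$effort, st, pars,
                                         model_spec(1), sim$space)),
               M * log(1 - 0.3), tolerance = 1e-12)
})

test_that("raising effort on undetected cells lowers the likelihood (beta_eff > 0)", {
  sim <- tiny_survey()
  ch <- sim$ch; n <- dim(ch$y)[1]
  st <- augmented_state(n, z = rep(1L, n),
                        sex = as.integer(ch$sexes == "male"),
                        s = vapply(seq_len(n), function(i)
                          which.max(apply(ch$y[i, , , drop = FALSE], 2, sum)), 0L),
                        psi = 0.5, psi_sex = 0.5, n = n)
  st$s <- match(ch$trap_ids[st$s], sim$space$pixels$pixel_id)
  pars <- detection_params(0.1, beta_eff = 0.8, sigma_f = 1.2, sigma_m = 1.2)
  ll1 <- log_likelihood(ch, ch$effort, st, pars, model_spec(3), sim$space)
  eff2 <- ch$effort
  miss <- apply(ch$y, c(2, 3), max) == 0L
  eff2$values[miss] <- eff2$values[miss] * 2
  ll2 <- log_likelihood(ch, eff2, st, pars, model_spec(3), sim$space)
  expect_lt(as.numeric(ll2), as.numeric(ll1))
})

test_that("a detection with z = 0 is impossible (log-zero sentinel)", {
  sim <- tiny_survey()
  ch <- sim$ch; n <- dim(ch$y)[1]
  st <- augmented_state(n, z = c(0L, rep(1L, n - 1)),
                        sex = as.integer(ch$sexes == "male"),
                        s = rep(1L, n), psi = 0.5, psi_sex = 0.5, n = 0L)
  pars <- detection_params(0.1, sigma_f = 1, sigma_m = 1)
  ll <- log_likelihood(ch, ch$effort, st, pars, model_spec(3), sim$space)
  expect_identical(as.numeric(ll), -Inf)
  expect_true(isTRUE(attr(ll, "flagged")))
})
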