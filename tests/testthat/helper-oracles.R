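# Independent brute-force oracles. These deliberately use plain scalar
# loops and arithmetic, not the package's vectorised code paths.

# Complete-data log likelihood by explicit triple loop.
oracle_loglik <- function(ch, effort, state, params, spec, space) {
  n <- dim(ch$y)[1L]; J <- dim(ch$y)[2L]; K <- dim(ch$y)[3L]
  ll <- 0
  for (i in seq_len(state$M)) {
    zi <- state$z[i]
    ll <- ll + log(if (zi == 1) state$psi else 1 - state$psi)
    if (zi == 1)
      ll <- ll + log(if (state$sex[i] == 1) state$psi_sex else 1 - state$psi_sex)
    if (spec$spatial) {
      sx <- space$pixels$x_km[state$s[i]]
      sy <- space$pixels$y_km[state$s[i]]
      sig <- if (state$sex[i] == 1) params$sigma_m else params$sigma_f
      for (j in seq_len(J)) {
        d2 <- (sx - effort$trap_xy[j, 1])^2 + (sy - effort$trap_xy[j, 2])^2
        for (k in seq_len(K)) {
          e <- effort$values[j, k]
          pi_ <- 0
          if (e > 0) {
            eta <- log(params$lambda0) + params$beta_eff * log(e) +
              params$beta_sex * state$sex[i] - (d2 / (2 * sig^2))^spec$theta
            pi_ <- 1 - exp(-exp(eta))
          }
          pz <- zi * pi_
          y <- if (i <= n) ch$y[i, j, k] else 0L
          ll <- ll + (if (y == 1L) log(pz) else log(1 - pz))
        }
      }
    } else {
      for (k in seq_len(K)) {
        e <- sum(effort$values[, k])
        pi_ <- 0
        if (e > 0) {
          eta <- log(params$lambda0) + params$beta_eff * log(e) +
            params$beta_sex * state$sex[i]
          pi_ <- 1 - exp(-exp(eta))
        }
        pz <- zi * pi_
        y <- if (i <= n) max(ch$y[i, , k]) else 0L
        ll <- ll + (if (y == 1L) log(pz) else log(1 - pz))
      }
    }
  }
  ll
}

# Shortest HPD window by exhaustive scan over all candidate windows.
oracle_hpd <- function(draws, mass) {
  x <- sort(draws)
  n <- length(x)
  m <- ceiling(mass * n)
  best <- c(-Inf, Inf)
  for (i in seq_len(n - m + 1L)) {
    lo <- x[i]; hi <- x[i + m - 1L]
    if (hi - lo < best[2L] - best[1L]) best <- c(lo, hi)
  }
  best
}

# Capture-history summaries by naive re-scan of the binary tensor.
oracle_capture_counts <- function(ch) {
  n <- dim(ch$y)[1L]
  dets <- 0; traps_hit <- numeric(n)
  for (i in seq_len(n)) {
    for (j in seq_len(dim(ch$y)[2L])) {
      row <- 0
      for (k in seq_len(dim(ch$y)[3L])) {
        dets <- dets + ch$y[i, j, k]
        row <- row + ch$y[i, j, k]
      }
      if (row > 0) traps_hit[i] <- traps_hit[i] + 1
    }
  }
  list(detections = dets, avg_spatial_recaptures = mean(traps_hit))
}
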