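#' Gelman-Rubin potential scale reduction factor
#'
#' Classical (non-split, two-stage) estimator from between- and
#' within-chain variances. Invariant to an affine transformation applied to
#' all chains jointly and to permutation of draws within chains.
#'
#' @param chains list of numeric vectors (>= 2 chains, each >= 2 draws), or
#'   a matrix with one chain per column.
#' @return The PSRF (r-hat); `NA` with attribute `degenerate = TRUE` when
#'   the pooled within-chain variance is zero.
#' @export
gelman_rubin <- function(chains) {
  if (is.matrix(chains)) chains <- lapply(seq_len(ncol(chains)), function(j) chains[, j])
  m <- length(chains)
  if (m < 2L) stop("gelman_rubin needs at least 2 chains")
  nlen <- vapply(chains, length, 0L)
  if (any(nlen < 2L)) stop("each chain needs at least 2 draws")
  n <- min(nlen)
  chains <- lapply(chains, function(x) x[seq_len(n)])
  W <- mean(vapply(chains, stats::var, 0))
  if (W == 0) return(structure(NA_real_, degenerate = TRUE))
  B <- n * stats::var(vapply(chains, mean, 0))
  vhat <- (n - 1) / n * W + B / n
  sqrt((vhat + B / (m * n)) / W)
}

#' r-hat for every monitored parameter of a fit
#'
#' @param fit a [secr_fit()] result (>= 2 chains).
#' @param threshold convergence gate (1.05 for full-data fits; 1.1 is
#'   conventional for sparse rarefied subsets).
#' @return Named vector of r-hat values with attribute `converged`.
#' @export
rhat <- function(fit, threshold = 1.05) {
  if (length(fit$chains) < 2L)
    stop("Gelman-Rubin diagnostic needs at least 2 chains; refit with n_chains >= 2")
  vals <- vapply(fit$param_names, function(p) {
    r <- gelman_rubin(lapply(fit$chains, function(m) m[, p]))
    if (is.na(r)) 1 else r # degenerate (constant) parameter: trivially converged
  }, 0)
  structure(vals, converged = all(vals < threshold), threshold = threshold)
}

#' Freeman-Tukey discrepancy on per-individual encounter totals
#'
#' @param e observed (or replicated) encounter counts.
#' @param mu expected encounter counts.
#' @return `sum((sqrt(e) - sqrt(mu))^2)`.
#' @export
freeman_tukey <- function(e, mu) sum((sqrt(e) - sqrt(mu))^2)

#' Posterior predictive Bayesian p-value
#'
#' For each retained latent snapshot (parameters plus `z`, `sex`, `s`),
#' replicate capture data are simulated conditional on that draw's latent
#' state, and the Freeman-Tukey discrepancy on per-individual total
#' encounter counts is compared between observed and replicated data:
#' `p = P(T_rep >= T_obs)`. Values outside (0.15, 0.85) indicate misfit.
#'
#' @param fit a [secr_fit()] result (snapshots must be present).
#' @param ch the capture history the model was fitted to.
#' @param effort aligned effort matrix (default `ch$effort`).
#' @param space the state space.
#' @param n_rep number of snapshots used (default: all available; a warning
#'   is given below 50).
#' @param seed RNG seed for the replicate simulations.
#' @return List of class `bayes_p`: `p`, `gof_pass` (0.15 < p < 0.85),
#'   `T_obs`, `T_rep` (vectors over draws), `n_rep`.
#' @export
bayesian_p_value <- function(fit, ch, effort = ch$effort, space,
                             n_rep = NULL, seed = 1) {
  snaps <- fit$snapshots
  if (!length(snaps)) stop("fit carries no latent snapshots")
  if (is.null(n_rep)) n_rep <- length(snaps)
  if (n_rep > length(snaps)) n_rep <- length(snaps)
  if (n_rep < 50L) warning("fewer than 50 replicate draws: p-value is unstable")
  use <- unique(round(seq(1L, length(snaps), length.out = n_rep)))
  dat <- secr_data(ch, effort, space, fit$spec)
  e_obs_det <- dat$det_counts
  set.seed(seed)
  Tobs <- Trep <- numeric(length(use))
  for (u in seq_along(use)) {
    sn <- snaps[[use[u]]]
    pr <- sn$params
    incl <- which(sn$z == 1L)
    # per included individual: detection probability over all searched cells
    effq <- exp(pr$beta_eff * dat$leff)
    male <- sn$sex[incl] == 1L
    sig <- ifelse(male, pr$sigma_m, pr$sigma_f)
    g <- sn$s[incl]
    D2c <- dat$D2[g, dat$ej, drop = FALSE] # |incl| x C, row-wise sigma below
    Kcells <- exp(sweep(-D2c, 1L, 2 * sig^2, "/"))
    H <- pr$lambda0 * exp(pr$beta_sex * male) *
      sweep(Kcells, 2L, effq, "*")
    P <- -expm1(-H)
    mu <- rowSums(P)
    e_obs <- numeric(length(incl))
    det_in <- incl[incl <= dat$n]
    e_obs[match(det_in, incl)] <- e_obs_det[det_in]
    e_rep <- rowSums(matrix(stats::rbinom(length(P), 1L, as.vector(P)),
                            nrow = nrow(P)))
    Tobs[u] <- freeman_tukey(e_obs, mu)
    Trep[u] <- freeman_tukey(e_rep, mu)
  }
  p <- mean(Trep >= Tobs)
  structure(list(p = p, gof_pass = (p > 0.15 && p < 0.85),
                 T_obs = Tobs, T_rep = Trep, n_rep = length(use)),
            class = "bayes_p")
}

#' @export
print.bayes_p <- function(x, ...) {
  cat(sprintf("Bayesian p-value = %.3f over %d draws (%s)\n", x$p, x$n_rep,
              if (x$gof_pass) "adequate: within .15-.85" else "MISFIT: outside .15-.85"))
  invisible(x)
}

#' Highest posterior density interval
#'
#' Shortest contiguous interval containing `ceiling(mass * n)` of the
#' sorted draws; on ties the smallest lower endpoint wins.
#'
#' @param draws numeric vector (>= 10 draws).
#' @param mass interval mass in (0, 1), default 0.95.
#' @return `c(lower, upper)`.
#' @examples
#' hpd_interval(1:100, 0.95) # c(1, 95)
#' @export
hpd_interval <- function(draws, mass = 0.95) {
  if (!is.numeric(mass) || length(mass) != 1L || mass <= 0 || mass >= 1)
    stop("mass must be in (0, 1)")
  n <- length(draws)
  if (n < 10L) stop("hpd_interval needs at least 10 draws")
  x <- sort(draws)
  m <- ceiling(mass * n)
  if (m >= n) return(c(x[1L], x[n]))
  i <- seq_len(n - m + 1L)
  w <- x[i + m - 1L] - x[i]
  k <- which.min(w) # which.min returns the first (smallest lower endpoint)
  c(x[k], x[k + m - 1L])
}

#' Pairwise posterior correlations and redundancy flags
#'
#' Strongly correlated posterior pairs signal parameter redundancy (the
#' data cannot separate them); the screen here replaces a visual check of
#' pairs plots with a configurable absolute-correlation threshold.
#'
#' @param draws matrix of posterior draws (columns = parameters), or a
#'   [secr_fit()] whose monitored parameters are used.
#' @param threshold flag pairs with `|rho| > threshold` (default 0.9).
#' @return List: `corr` (symmetric matrix), `flagged` (data frame of pairs).
#' @export
parameter_redundancy <- function(draws, threshold = 0.9) {
  if (inherits(draws, "secr_fit")) {
    fit <- draws
    draws <- do.call(rbind, fit$chains)[, fit$param_names, drop = FALSE]
  }
  draws <- as.matrix(draws)
  if (ncol(draws) < 2L) stop("need at least 2 parameters")
  ok <- apply(draws, 2L, function(x) stats::sd(x) > 0)
  corr <- diag(1, ncol(draws))
  dimnames(corr) <- list(colnames(draws), colnames(draws))
  if (sum(ok) >= 2L) corr[ok, ok] <- stats::cor(draws[, ok, drop = FALSE])
  ut <- which(upper.tri(corr) & abs(corr) > threshold, arr.ind = TRUE)
  flagged <- data.frame(param1 = rownames(corr)[ut[, 1L]],
                        param2 = colnames(corr)[ut[, 2L]],
                        rho = corr[ut])
  list(corr = corr, flagged = flagged, threshold = threshold)
}

#' Full diagnostics report for a fitted model
#'
#' @param fit a [secr_fit()] (>= 2 chains).
#' @param ch,space data the model was fitted to (for the posterior
#'   predictive check).
#' @param rhat_threshold convergence gate (default 1.05).
#' @param mass HPD mass (default 0.95).
#' @param n_rep snapshots for the Bayesian p-value (default all).
#' @param seed RNG seed for replicates.
#' @return Object of class `diagnostics_report`: `rhat`, `converged`,
#'   `bayesian_p`, `gof_pass`, `hpd` (matrix), `pairwise_corr`, `flagged`.
#' @export
diagnose <- function(fit, ch, space, rhat_threshold = 1.05, mass = 0.95,
                     n_rep = NULL, seed = 1) {
  rh <- rhat(fit, threshold = rhat_threshold)
  bp <- bayesian_p_value(fit, ch, space = space, n_rep = n_rep, seed = seed)
  hpd <- t(vapply(fit$param_names,
                  function(p) hpd_interval(posterior_draws(fit, p), mass),
                  numeric(2L)))
  colnames(hpd) <- c("lower", "upper")
  pr <- parameter_redundancy(fit)
  structure(list(rhat = rh, converged = attr(rh, "converged"),
                 rhat_threshold = rhat_threshold,
                 bayesian_p = bp$p, gof_pass = bp$gof_pass,
                 hpd = hpd, pairwise_corr = pr$corr, flagged = pr$flagged),
            class = "diagnostics_report")
}

#' @export
print.diagnostics_report <- function(x, ...) {
  cat(sprintf("convergence: max r-hat %.4f (threshold %.2f) -> %s\n",
              max(x$rhat), x$rhat_threshold,
              if (x$converged) "converged" else "NOT converged"))
  cat(sprintf("goodness of fit: Bayesian p = %.3f -> %s\n", x$bayesian_p,
              if (x$gof_pass) "adequate" else "rejected"))
  if (nrow(x$flagged))
    cat(sprintf("redundancy flags: %s\n",
                paste(sprintf("%s~%s (%.2f)", x$flagged$param1, x$flagged$param2,
                              x$flagged$rho), collapse = ", ")))
  invisible(x)
}
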