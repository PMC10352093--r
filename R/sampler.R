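#' MCMC sampler configuration
#'
#' Defaults follow a long-run protocol for a full survey analysis (31,000
#' iterations, 4 chains, 1,000 burn-in); tests and rarefaction subsets use
#' shorter runs.
#'
#' @param n_iter iterations per chain (> `burn_in`).
#' @param burn_in initial iterations discarded (>= 0); proposal-scale
#'   adaptation, when enabled, happens only here.
#' @param n_chains number of independent chains (>= 1).
#' @param thin keep every `thin`-th post-burn-in draw.
#' @param seed master seed; per-chain streams are derived from it.
#' @param proposal_scales optional named numeric overriding the initial
#'   random-walk scales (`lambda0`, `beta_eff`, `beta_sex`, `sigma_f`,
#'   `sigma_m`, `sigma`).
#' @param adapt adapt proposal scales during burn-in (target 20--40%
#'   acceptance), frozen afterwards so detailed balance holds for retained
#'   draws.
#' @param n_snapshots approximate number of full latent-state snapshots
#'   (`z`, `sex`, `s` and parameters) retained per chain for posterior
#'   predictive checks.
#' @param extra_discard additional post-hoc iterations dropped after
#'   burn-in (used when convergence diagnostics demand it).
#' @return Object of class `sampler_config`.
#' @export
sampler_config <- function(n_iter = 31000, burn_in = 1000, n_chains = 4,
                           thin = 1, seed = 1, proposal_scales = NULL,
                           adapt = TRUE, n_snapshots = 100, extra_discard = 0) {
  if (n_iter <= burn_in + extra_discard)
    stop("invalid-config: n_iter must exceed burn_in (+ extra_discard)")
  if (burn_in < 0 || n_chains < 1 || thin < 1)
    stop("invalid-config: burn_in >= 0, n_chains >= 1, thin >= 1 required")
  structure(list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 n_chains = as.integer(n_chains), thin = as.integer(thin),
                 seed = as.integer(seed), proposal_scales = proposal_scales,
                 adapt = isTRUE(adapt), n_snapshots = as.integer(n_snapshots),
                 extra_discard = as.integer(extra_discard)),
            class = "sampler_config")
}

#' Precompute the sampler's data structures
#'
#' Factorises the detection likelihood for fast evaluation: for an included
#' individual with centre pixel `g` the expected encounter hazard summed
#' over all searched cells is `lambda0 * exp(beta_sex * male) * W_sex[g]`
#' with `W_sex = exp(-D2 / (2 sigma_sex^2)) %*% E` and
#' `E_j = sum_k effort_jk^beta_eff` (zero-effort cells excluded). Observed
#' detection cells are stored sparsely. For the nonspatial Model 5 the data
#' collapse to one pseudo-trap per occasion carrying the total searched km.
#'
#' @param ch capture history.
#' @param effort aligned effort matrix (defaults to `ch$effort`).
#' @param space state space.
#' @param spec model specification.
#' @return An environment of class `secr_data` (treated as read-only by the
#'   update functions, except for an internal proposal-offset cache).
#' @export
secr_data <- function(ch, effort = ch$effort, space, spec) {
  stopifnot(inherits(ch, "capture_history"), inherits(spec, "model_spec"))
  dat <- new.env(parent = emptyenv())
  dat$spec <- spec
  dat$n <- dim(ch$y)[1L]
  dat$det_sex <- as.integer(ch$sexes == "male")
  if (spec$spatial) {
    vals <- effort$values
    dat$J <- nrow(vals); dat$K <- ncol(vals)
    dat$G <- nrow(space$pixels)
    dat$D2 <- pixel_dist2(space, effort$trap_ids)
    pos <- which(vals > 0, arr.ind = TRUE)
    dat$ej <- pos[, 1L]; dat$ek <- pos[, 2L]; dat$leff <- log(vals[pos])
    idx <- which(ch$y == 1L, arr.ind = TRUE)
    dat$di <- idx[, 1L]; dat$dj <- idx[, 2L]; dat$dk <- idx[, 3L]
    cell_eff <- vals[cbind(dat$dj, dat$dk)]
    if (any(cell_eff <= 0))
      stop("detection in a zero-effort cell; apply an effort floor in build_capture_history")
    dat$dleff <- log(cell_eff)
    dat$pix_row <- space$pixels$row; dat$pix_col <- space$pixels$col
    dat$id_grid <- space$id_grid; dat$nx <- space$nx; dat$ny <- space$ny
    dat$delta <- space$delta
    dat$sigma_max <- sqrt(diff(range(space$pixels$x_km))^2 +
                          diff(range(space$pixels$y_km))^2)
    dat$trap_xy <- effort$trap_xy
    dat$sp_x <- space$pixels$x_km; dat$sp_y <- space$pixels$y_km
  } else {
    ek_tot <- colSums(effort$values)
    dat$J <- 1L; dat$K <- length(ek_tot); dat$G <- 1L
    dat$D2 <- matrix(0, 1L, 1L)
    pos <- which(ek_tot > 0)
    dat$ej <- rep(1L, length(pos)); dat$ek <- pos; dat$leff <- log(ek_tot[pos])
    y5 <- apply(ch$y, c(1L, 3L), max)
    idx <- which(y5 == 1L, arr.ind = TRUE)
    dat$di <- idx[, 1L]; dat$dj <- rep(1L, nrow(idx)); dat$dk <- idx[, 2L]
    if (any(ek_tot[dat$dk] <= 0)) stop("detection on an occasion with zero total effort")
    dat$dleff <- log(ek_tot[dat$dk])
    dat$sigma_max <- Inf
    dat$delta <- 1
  }
  dat$dmale <- dat$det_sex[dat$di]
  dat$det_counts <- tabulate(dat$di, dat$n)
  dat$offset_cache <- list()
  class(dat) <- c("secr_data", class(dat))
  dat
}

# ---- likelihood parts -------------------------------------------------------

.make_E <- function(dat, beta_eff) {
  E <- numeric(dat$J)
  sums <- rowsum(exp(beta_eff * dat$leff), dat$ej)
  E[as.integer(rownames(sums))] <- sums
  E
}

.make_K <- function(dat, sigma) exp(-dat$D2 / (2 * sigma^2))

# parts: E (J), Kf/Km (G x J), Wf/Wm (G); keyed to current params
.make_parts <- function(dat, params) {
  E <- .make_E(dat, params$beta_eff)
  Kf <- .make_K(dat, params$sigma_f)
  Km <- if (params$sigma_m == params$sigma_f) Kf else .make_K(dat, params$sigma_m)
  list(E = E, Kf = Kf, Km = Km,
       Wf = as.vector(Kf %*% E), Wm = as.vector(Km %*% E))
}

.det_h <- function(dat, params, s) {
  if (!length(dat$di)) return(numeric(0))
  g <- if (dat$spec$spatial) s[dat$di] else rep(1L, length(dat$di))
  sig <- ifelse(dat$dmale == 1L, params$sigma_m, params$sigma_f)
  params$lambda0 * exp(params$beta_sex * dat$dmale + params$beta_eff * dat$dleff -
                       dat$D2[cbind(g, dat$dj)] / (2 * sig^2))
}

# Detection-data log likelihood given latent state (z/sex/s) and params.
.ll_y <- function(dat, parts, params, state) {
  incl <- which(state$z == 1L)
  male <- state$sex[incl] == 1L
  sidx <- if (dat$spec$spatial) state$s else rep(1L, state$M)
  lam_tot <- params$lambda0 *
    (sum(parts$Wf[sidx[incl[!male]]]) +
     exp(params$beta_sex) * sum(parts$Wm[sidx[incl[male]]]))
  h <- .det_h(dat, params, state$s)
  ll <- -lam_tot
  if (length(h)) {
    lp1 <- log(-expm1(-h))
    if (any(!is.finite(lp1))) return(-Inf)
    ll <- ll + sum(lp1 + h)
  }
  ll
}

.log_prior <- function(dat, params) {
  spec <- dat$spec
  lp <- stats::dnorm(log(params$lambda0), 0, 10, log = TRUE) +
    stats::dnorm(params$beta_eff, 0, 10, log = TRUE)
  if (spec$lambda0_sex_specific)
    lp <- lp + stats::dnorm(params$beta_sex, 0, 10, log = TRUE)
  if (spec$spatial &&
      (params$sigma_f <= 0 || params$sigma_f >= dat$sigma_max ||
       params$sigma_m <= 0 || params$sigma_m >= dat$sigma_max))
    return(-Inf)
  lp
}

# ---- Metropolis / Gibbs updates --------------------------------------------

#' Metropolis update of the continuous detection parameters
#'
#' Log-scale Gaussian random walks for `lambda0` and the sigmas (the prior
#' on `log(lambda0)` is Normal, so that walk needs no Jacobian; the sigma
#' walk carries the `sigma'/sigma` Jacobian against its Uniform prior),
#' plain Gaussian walks for the betas. Shared-sigma models update one sigma
#' applied to both sexes; parameters a model fixes at zero are skipped.
#'
#' @param dat a [secr_data()] environment.
#' @param parts current likelihood parts (from the previous accepted state).
#' @param params current [detection_params()].
#' @param state current [augmented_state()].
#' @param scales named proposal scales.
#' @return List `params`, `parts`, `ll` (detection log likelihood at exit)
#'   and `accepted` (named logical).
#' @export
update_continuous <- function(dat, parts, params, state, scales) {
  spec <- dat$spec
  active <- c("lambda0", "beta_eff",
              if (spec$lambda0_sex_specific) "beta_sex",
              if (spec$spatial) (if (spec$sigma_sex_specific) c("sigma_f", "sigma_m") else "sigma"))
  cur_ll <- .ll_y(dat, parts, params, state)
  accepted <- stats::setNames(logical(length(active)), active)
  for (p in active) {
    prop <- params; parts2 <- parts; lratio_extra <- 0
    if (p == "lambda0") {
      u <- log(params$lambda0); u2 <- u + stats::rnorm(1L, 0, scales[["lambda0"]])
      prop$lambda0 <- exp(u2)
      lratio_extra <- stats::dnorm(u2, 0, 10, log = TRUE) -
        stats::dnorm(u, 0, 10, log = TRUE)
    } else if (p == "beta_eff") {
      prop$beta_eff <- params$beta_eff + stats::rnorm(1L, 0, scales[["beta_eff"]])
      parts2$E <- .make_E(dat, prop$beta_eff)
      parts2$Wf <- as.vector(parts2$Kf %*% parts2$E)
      parts2$Wm <- as.vector(parts2$Km %*% parts2$E)
      lratio_extra <- stats::dnorm(prop$beta_eff, 0, 10, log = TRUE) -
        stats::dnorm(params$beta_eff, 0, 10, log = TRUE)
    } else if (p == "beta_sex") {
      prop$beta_sex <- params$beta_sex + stats::rnorm(1L, 0, scales[["beta_sex"]])
      lratio_extra <- stats::dnorm(prop$beta_sex, 0, 10, log = TRUE) -
        stats::dnorm(params$beta_sex, 0, 10, log = TRUE)
    } else { # sigma walks (log scale, Uniform(0, sigma_max) prior + Jacobian)
      which_s <- if (p == "sigma") c("sigma_f", "sigma_m") else p
      mult <- exp(stats::rnorm(1L, 0, scales[[p]]))
      for (ps in which_s) prop[[ps]] <- params[[ps]] * mult
      if (any(unlist(prop[which_s]) >= dat$sigma_max)) next # prior mass zero
      if ("sigma_f" %in% which_s) {
        parts2$Kf <- .make_K(dat, prop$sigma_f)
        parts2$Wf <- as.vector(parts2$Kf %*% parts2$E)
      }
      if ("sigma_m" %in% which_s) {
        parts2$Km <- if (prop$sigma_m == prop$sigma_f && !is.null(parts2$Kf) &&
                         "sigma_f" %in% which_s) parts2$Kf else .make_K(dat, prop$sigma_m)
        parts2$Wm <- as.vector(parts2$Km %*% parts2$E)
      }
      lratio_extra <- length(which_s) * 0 + log(mult) # d sigma'/d u Jacobian
    }
    ll2 <- .ll_y(dat, parts2, prop, state)
    if (is.finite(ll2)) {
      lacc <- ll2 - cur_ll + lratio_extra
      if (log(stats::runif(1L)) < lacc) {
        params <- prop; parts <- parts2; cur_ll <- ll2
        accepted[p] <- TRUE
        next
      }
    }
  }
  list(params = params, parts = parts, ll = cur_ll, accepted = accepted)
}

#' Gibbs update of the inclusion indicators z
#'
#' Detected individuals stay included. For an augmented pseudo-individual,
#' `P(z = 1 | .) = psi * q / (psi * q + 1 - psi)` where `q = exp(-Lambda)`
#' is its probability of an all-zero encounter history given inclusion.
#'
#' @inheritParams update_continuous
#' @return Updated state.
#' @export
update_z <- function(dat, parts, params, state) {
  if (state$M <= dat$n) return(state)
  aug <- (dat$n + 1L):state$M
  male <- state$sex[aug] == 1L
  saug <- if (dat$spec$spatial) state$s[aug] else rep(1L, length(aug))
  W <- ifelse(male, parts$Wm[saug], parts$Wf[saug])
  lam <- params$lambda0 * exp(params$beta_sex * male) * W
  q <- exp(-lam)
  p1 <- state$psi * q / (state$psi * q + 1 - state$psi)
  state$z[aug] <- stats::rbinom(length(aug), 1L, p1)
  state
}

#' Gibbs update of the latent sexes
#'
#' Sexes of detected individuals are data and never move. For augmented
#' individuals the two sexes are weighted by `psi_sex` and, when included,
#' by the all-zero encounter likelihood each sex implies.
#'
#' @inheritParams update_continuous
#' @return Updated state.
#' @export
update_sex <- function(dat, parts, params, state) {
  if (state$M <= dat$n) return(state)
  aug <- (dat$n + 1L):state$M
  z <- state$z[aug]
  saug <- if (dat$spec$spatial) state$s[aug] else rep(1L, length(aug))
  lamF <- params$lambda0 * parts$Wf[saug]
  lamM <- params$lambda0 * exp(params$beta_sex) * parts$Wm[saug]
  lwM <- log(state$psi_sex) - z * lamM
  lwF <- log1p(-state$psi_sex) - z * lamF
  pM <- 1 / (1 + exp(lwF - lwM))
  state$sex[aug] <- stats::rbinom(length(aug), 1L, pM)
  state
}

.prop_offsets <- function(dat, r_prop) {
  key <- as.character(max(1L, as.integer(ceiling(r_prop / dat$delta))))
  off <- dat$offset_cache[[key]]
  if (is.null(off)) {
    m <- as.integer(key)
    g <- expand.grid(dr = -m:m, dc = -m:m, KEEP.OUT.ATTRS = FALSE)
    g <- g[g$dr^2 + g$dc^2 <= m^2 & !(g$dr == 0 & g$dc == 0), ]
    off <- as.matrix(g)
    dat$offset_cache[[key]] <- off
  }
  off
}

#' Metropolis update of the activity centres
#'
#' Each individual proposes a pixel uniformly within `r_prop` km of its
#' current pixel (a symmetric proposal on the grid); proposals landing
#' outside the state space are rejected. The acceptance ratio involves only
#' that individual's detection likelihood, so all M individuals are updated
#' in one vectorised pass. Undetected, excluded individuals random-walk
#' freely (uniform stationary distribution over the state space).
#'
#' @inheritParams update_continuous
#' @param r_prop proposal radius in km (default 3 x the larger sigma).
#' @return List `state`, `acc_rate`.
#' @export
update_activity_centres <- function(dat, parts, params, state,
                                    r_prop = 3 * max(params$sigma_f, params$sigma_m)) {
  if (!dat$spec$spatial) return(list(state = state, acc_rate = NA_real_))
  off <- .prop_offsets(dat, r_prop)
  M <- state$M
  pick <- sample.int(nrow(off), M, replace = TRUE)
  nrow_ <- dat$pix_row[state$s] + off[pick, 1L]
  ncol_ <- dat$pix_col[state$s] + off[pick, 2L]
  ok <- nrow_ >= 1L & nrow_ <= dat$ny & ncol_ >= 1L & ncol_ <= dat$nx
  gnew <- rep(NA_integer_, M)
  gnew[ok] <- dat$id_grid[cbind(nrow_[ok], ncol_[ok])]
  ok <- ok & !is.na(gnew)
  delta_ll <- numeric(M)
  z1 <- state$z == 1L
  male <- state$sex == 1L
  mv <- z1 & ok
  if (any(mv)) {
    W <- ifelse(male[mv], parts$Wm[gnew[mv]] - parts$Wm[state$s[mv]],
                          parts$Wf[gnew[mv]] - parts$Wf[state$s[mv]])
    delta_ll[mv] <- -params$lambda0 * exp(params$beta_sex * male[mv]) * W
  }
  if (length(dat$di)) {
    cell_ok <- ok[dat$di]
    if (any(cell_ok)) {
      di <- dat$di[cell_ok]; dj <- dat$dj[cell_ok]
      sig <- ifelse(dat$dmale[cell_ok] == 1L, params$sigma_m, params$sigma_f)
      base <- params$lambda0 * exp(params$beta_sex * dat$dmale[cell_ok] +
                                   params$beta_eff * dat$dleff[cell_ok])
      h_old <- base * exp(-dat$D2[cbind(state$s[di], dj)] / (2 * sig^2))
      h_new <- base * exp(-dat$D2[cbind(gnew[di], dj)] / (2 * sig^2))
      term <- function(h) ifelse(h > 0, log(-expm1(-h)) + h, -Inf)
      dterm <- term(h_new) - term(h_old)
      agg <- rowsum(dterm, di)
      delta_ll[as.integer(rownames(agg))] <-
        delta_ll[as.integer(rownames(agg))] + agg[, 1L]
    }
  }
  acc <- ok & (log(stats::runif(M)) < delta_ll)
  state$s[acc] <- gnew[acc]
  list(state = state, acc_rate = mean(acc))
}

#' Conjugate Gibbs update of psi
#'
#' With a Beta(1, 1) prior, `psi ~ Beta(1 + sum(z), 1 + M - sum(z))`.
#' @inheritParams update_continuous
#' @return Updated state.
#' @export
update_psi <- function(state) {
  nz <- sum(state$z)
  state$psi <- stats::rbeta(1L, 1 + nz, 1 + state$M - nz)
  state
}

#' Conjugate Gibbs update of psi_sex
#'
#' Counting sexes over included (`z = 1`) individuals:
#' `psi_sex ~ Beta(1 + males, 1 + females)`.
#' @inheritParams update_continuous
#' @return Updated state.
#' @export
update_psi_sex <- function(state) {
  incl <- state$z == 1L
  nm <- sum(state$sex[incl])
  nf <- sum(incl) - nm
  state$psi_sex <- stats::rbeta(1L, 1 + nm, 1 + nf)
  state
}

# ---- initialisation ---------------------------------------------------------

.init_sigma <- function(dat, ch, sex_value) {
  # RMS spread of each individual's detections around its centroid, pooled
  ids <- which(dat$det_sex == sex_value | is.na(sex_value))
  sq <- c()
  for (i in ids) {
    cells <- which(dat$di == i)
    if (length(cells) < 2L) next
    xy <- dat$trap_xy[dat$dj[cells], , drop = FALSE]
    sq <- c(sq, (xy[, 1L] - mean(xy[, 1L]))^2 + (xy[, 2L] - mean(xy[, 2L]))^2)
  }
  if (length(sq) && mean(sq) > 0) sqrt(mean(sq)) else 2
}

.init_chain <- function(dat, ch, M, overdisperse = TRUE) {
  spec <- dat$spec
  jit <- function(sd) if (overdisperse) stats::rnorm(1L, 0, sd) else 0
  sf <- 2; sm <- 2
  if (spec$spatial) {
    sf <- if (spec$sigma_sex_specific) .init_sigma(dat, ch, 0L) * exp(jit(0.2))
          else .init_sigma(dat, ch, NA) * exp(jit(0.2))
    sm <- if (spec$sigma_sex_specific) .init_sigma(dat, ch, 1L) * exp(jit(0.2)) else sf
    cap <- dat$sigma_max * 0.45
    sf <- min(max(sf, 0.2), cap); sm <- min(max(sm, 0.2), cap)
    if (!spec$sigma_sex_specific) sm <- sf
  }
  params <- detection_params(lambda0 = 0.01 * exp(jit(0.5)),
                             beta_eff = jit(0.3),
                             beta_sex = if (spec$lambda0_sex_specific) jit(0.3) else 0,
                             sigma_f = sf, sigma_m = sm)
  psi0 <- min(max((dat$n + 1) / M + jit(0.1), 0.05), 0.9)
  z <- c(rep(1L, dat$n), stats::rbinom(M - dat$n, 1L, psi0))
  pm <- min(max(mean(dat$det_sex) + jit(0.1), 0.1), 0.9)
  sex <- c(dat$det_sex, stats::rbinom(M - dat$n, 1L, pm))
  if (dat$spec$spatial) {
    s <- integer(M)
    for (i in seq_len(dat$n)) {
      cells <- which(dat$di == i)
      xy <- dat$trap_xy[dat$dj[cells], , drop = FALSE]
      cx <- mean(xy[, 1L]); cy <- mean(xy[, 2L])
      # nearest state-space pixel to the detection centroid
      s[i] <- which.min((dat$sp_x - cx)^2 + (dat$sp_y - cy)^2)
    }
    if (M > dat$n) s[(dat$n + 1L):M] <- sample.int(dat$G, M - dat$n, replace = TRUE)
  } else {
    s <- rep(1L, M)
  }
  state <- augmented_state(M, z, sex, s, psi = psi0, psi_sex = pm, n = dat$n)
  list(params = params, state = state)
}

.default_scales <- function() {
  c(lambda0 = 0.4, beta_eff = 0.15, beta_sex = 0.3,
    sigma_f = 0.12, sigma_m = 0.12, sigma = 0.1)
}

.run_chain <- function(dat, ch, M, cfg, chain_seed) {
  set.seed(chain_seed)
  scales <- .default_scales()
  if (!is.null(cfg$proposal_scales))
    scales[names(cfg$proposal_scales)] <- cfg$proposal_scales
  init <- NULL
  for (try in 1:5) {
    cand <- .init_chain(dat, ch, M)
    parts <- .make_parts(dat, cand$params)
    if (is.finite(.ll_y(dat, parts, cand$params, cand$state))) { init <- cand; break }
  }
  if (is.null(init)) stop("could not find a finite-likelihood initial state")
  params <- init$params; state <- init$state
  first_keep <- cfg$burn_in + cfg$extra_discard + 1L
  keep_iter <- seq.int(first_keep, cfg$n_iter, by = cfg$thin)
  n_keep <- length(keep_iter)
  out <- matrix(NA_real_, nrow = n_keep, ncol = 8L,
                dimnames = list(NULL, c("lambda0", "beta_eff", "beta_sex",
                                        "sigma_f", "sigma_m", "psi", "psi_sex",
                                        "N_super")))
  tally <- numeric(dat$G)
  snap_at <- unique(keep_iter[round(seq(1L, n_keep,
                                        length.out = min(cfg$n_snapshots, n_keep)))])
  snapshots <- vector("list", length(snap_at))
  acc_tot <- c(.default_scales() * 0, s = 0)
  acc_n <- 0L
  win_acc <- acc_tot; win_n <- 0L
  row <- 0L; snap_i <- 0L
  for (it in seq_len(cfg$n_iter)) {
    up <- update_continuous(dat, parts, params, state, scales)
    params <- up$params; parts <- up$parts
    state <- update_z(dat, parts, params, state)
    state <- update_sex(dat, parts, params, state)
    sup <- update_activity_centres(dat, parts, params, state)
    state <- sup$state
    state <- update_psi(state)
    state <- update_psi_sex(state)
    accv <- c(rep(0, 6), s = 0)
    names(accv) <- names(acc_tot)
    accv[names(up$accepted)] <- as.numeric(up$accepted)
    accv["s"] <- if (is.na(sup$acc_rate)) 0 else sup$acc_rate
    if (it <= cfg$burn_in) {
      if (cfg$adapt) {
        win_acc <- win_acc + accv; win_n <- win_n + 1L
        if (win_n == 50L) {
          rate <- win_acc / win_n
          for (p in intersect(names(scales), names(rate))) {
            if (rate[p] > 0.4) scales[p] <- scales[p] * 1.3
            else if (rate[p] < 0.2) scales[p] <- scales[p] / 1.3
          }
          win_acc[] <- 0; win_n <- 0L
        }
      }
    } else {
      acc_tot <- acc_tot + accv; acc_n <- acc_n + 1L
    }
    if (it >= first_keep && ((it - first_keep) %% cfg$thin == 0L)) {
      row <- row + 1L
      out[row, ] <- c(params$lambda0, params$beta_eff, params$beta_sex,
                      if (dat$spec$spatial) params$sigma_f else NA_real_,
                      if (dat$spec$spatial) params$sigma_m else NA_real_,
                      state$psi, state$psi_sex, sum(state$z))
      on <- state$s[state$z == 1L]
      if (length(on)) tally <- tally + tabulate(on, dat$G)
      if (snap_i < length(snap_at) && it == snap_at[snap_i + 1L]) {
        snap_i <- snap_i + 1L
        snapshots[[snap_i]] <- list(params = params, z = state$z,
                                    sex = state$sex, s = state$s)
      }
    }
  }
  list(draws = out, tally = tally, n_tally = n_keep,
       snapshots = snapshots[seq_len(snap_i)],
       acceptance = acc_tot / max(acc_n, 1L), scales = scales,
       seed = chain_seed)
}

#' Fit a search-encounter SECR model by MCMC
#'
#' Metropolis-within-Gibbs over the detection parameters and the latent
#' augmented state. Per sweep: continuous parameters, then inclusion
#' indicators `z`, latent sexes, activity centres, then the conjugate
#' `psi`/`psi_sex` draws. Chains are independent with seeds derived from
#' the master seed; identical inputs, configuration and seed give
#' bit-identical samples.
#'
#' @param ch capture history from [build_capture_history()] (or the
#'   simulator).
#' @param space state space.
#' @param spec a [model_spec()] (default Model 1).
#' @param M data-augmentation size (default 200; must exceed the number of
#'   detected individuals).
#' @param config a [sampler_config()].
#' @param effort aligned effort matrix (default `ch$effort`).
#' @return Object of class `secr_fit`: per-chain draw matrices (`chains`),
#'   summed activity-centre pixel tallies (`tally`, over included
#'   individuals and retained draws), latent `snapshots`, acceptance rates,
#'   and metadata (`spec`, `config`, `M`, `n`, `area_km2`, `param_names`).
#' @export
secr_fit <- function(ch, space, spec = model_spec(1), M = 200,
                     config = sampler_config(), effort = ch$effort) {
  stopifnot(inherits(config, "sampler_config"))
  n <- dim(ch$y)[1L]
  if (M <= n) stop("invalid-config: M must exceed the number of detected individuals")
  dat <- secr_data(ch, effort, space, spec)
  set.seed(config$seed)
  seeds <- sample.int(2147483646L, config$n_chains)
  chains <- lapply(seeds, function(sd) .run_chain(dat, ch, M, cfg = config, chain_seed = sd))
  free <- c("lambda0", "beta_eff",
            if (spec$lambda0_sex_specific) "beta_sex",
            if (spec$spatial) (if (spec$sigma_sex_specific) c("sigma_f", "sigma_m") else "sigma_f"),
            "psi", "psi_sex", "N_super")
  structure(list(chains = lapply(chains, `[[`, "draws"),
                 tally = Reduce(`+`, lapply(chains, `[[`, "tally")),
                 n_tally_draws = sum(vapply(chains, `[[`, 0, "n_tally")),
                 snapshots = unlist(lapply(chains, `[[`, "snapshots"),
                                    recursive = FALSE),
                 acceptance = lapply(chains, `[[`, "acceptance"),
                 chain_seeds = seeds,
                 spec = spec, config = config, M = M, n = n,
                 area_km2 = space$total_area_km2,
                 param_names = free),
            class = "secr_fit")
}

#' Pooled posterior draws of one parameter
#' @param fit a [secr_fit()] result.
#' @param param column name (e.g. `"N_super"`).
#' @return Numeric vector over all chains.
#' @export
posterior_draws <- function(fit, param) {
  unlist(lapply(fit$chains, function(m) m[, param]), use.names = FALSE)
}

#' @export
print.secr_fit <- function(x, ...) {
  cat(sprintf("secr_fit: Model %d, %d chains x %d retained draws, n = %d, M = %d\n",
              x$spec$model_id, length(x$chains), nrow(x$chains[[1L]]), x$n, x$M))
  for (p in x$param_names) {
    d <- posterior_draws(x, p)
    cat(sprintf("  %-9s mean %8.4f  sd %7.4f\n", p, mean(d), stats::sd(d)))
  }
  invisible(x)
}
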