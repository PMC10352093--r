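#' Chronological whole-day rarefaction of search tracks
#'
#' Whole-day tracks are accumulated in chronological order until the
#' cumulative driven length reaches `target_km`; the day that crosses the
#' threshold is kept whole (real surveys start and end at a base, so days
#' are not cut). A target at or beyond the total returns the full set with
#' a warning.
#'
#' @param tracks list of [track_log()].
#' @param target_km positive target search effort in km.
#' @return The retained tracks (chronological order), with attributes
#'   `realised_km` and `target_km`.
#' @export
rarefy_tracks <- function(tracks, target_km) {
  if (!is.numeric(target_km) || target_km <= 0) stop("target_km must be > 0")
  days <- as.Date(vapply(tracks, function(t) as.character(t$day), ""))
  ord <- order(days)
  tracks <- tracks[ord]
  lens <- vapply(tracks, track_length, 0)
  cum <- cumsum(lens)
  if (target_km >= cum[length(cum)]) {
    if (target_km > cum[length(cum)])
      warning("target exceeds total track length; returning the full set")
    keep <- length(tracks)
  } else {
    keep <- which(cum >= target_km)[1L]
  }
  out <- tracks[seq_len(keep)]
  attr(out, "realised_km") <- cum[keep]
  attr(out, "target_km") <- target_km
  out
}

#' Coefficient of variation of an estimate
#' @param estimate_mean posterior mean (nonzero).
#' @param estimate_sd posterior SD.
#' @return `sd / |mean|`.
#' @export
cv <- function(estimate_mean, estimate_sd) {
  if (any(estimate_mean == 0)) stop("cv undefined for a zero mean")
  estimate_sd / abs(estimate_mean)
}

#' Relative bias of an estimate against a reference
#' @param estimate estimate from a reduced data set.
#' @param reference estimate from the full data set (nonzero).
#' @return `(estimate - reference) / reference`.
#' @export
relative_bias <- function(estimate, reference) {
  if (any(reference == 0)) stop("relative_bias undefined for a zero reference")
  (estimate - reference) / reference
}

#' Effort-rarefaction experiment
#'
#' Refits the model to chronological effort prefixes and scores each subset
#' against the full-data fit: the coefficient of variation (precision) and
#' relative bias of the spatial scale(s), `psi_sex`, `N_super` and density.
#' The sex-specific Model 1 is used unless a subset leaves either sex with
#' fewer than 2 recaptures, in which case the sexless Model 3 is fitted
#' instead. A subset is `adequate` when every scored parameter has
#' CV < 20% and |RB| < 15%.
#'
#' @param tracks full list of [track_log()].
#' @param records filtered sighting records (output `kept` of
#'   [filter_sightings()]).
#' @param space state space.
#' @param increments_km effort targets in km (the full total is appended as
#'   the reference subset when not already included).
#' @param config a [sampler_config()] used for every subset fit (override
#'   per subset via `overrides`).
#' @param M data-augmentation size.
#' @param overrides optional named list (names = target km) of
#'   [sampler_config()] objects for individual subsets (e.g. longer runs
#'   for the sparsest data).
#' @param effort_floor_km passed to [build_capture_history()].
#' @param min_sex_recaptures fallback trigger: fewer recaptures than this
#'   for either sex switches the subset to Model 3 (default 2).
#' @return Object of class `rarefaction_result`: `table` (one row per
#'   subset: target/realised km, capture summaries, model used, per-
#'   parameter mean/CV/RB, `adequate`), `fits` (list of `secr_fit`),
#'   `reference_km`.
#' @export
run_rarefaction <- function(tracks, records, space, increments_km,
                            config = sampler_config(), M = 200,
                            overrides = NULL, effort_floor_km = 0.1,
                            min_sex_recaptures = 2L) {
  total <- sum(vapply(tracks, track_length, 0))
  increments_km <- sort(unique(increments_km))
  if (max(increments_km) < total) increments_km <- c(increments_km, total)
  params_scored <- c("sigma_f", "sigma_m", "psi_sex", "N_super", "D")
  rows <- list(); fits <- list()
  for (tk in increments_km) {
    sub <- suppressWarnings(rarefy_tracks(tracks, tk))
    eff <- compute_effort(sub, space)
    keep <- as.Date(records$day) %in% eff$occasion_dates
    rec <- records[keep, , drop = FALSE]
    if (nrow(rec) == 0L) {
      warning(sprintf("subset %g km holds no detections; fit skipped", tk))
      next
    }
    ch <- build_capture_history(rec, eff, space, effort_floor_km = effort_floor_km)
    sm <- summarize_captures(ch)
    if (sm$recaptures == 0L) {
      warning(sprintf("subset %g km has zero recaptures; fit skipped", tk))
      next
    }
    use_model3 <- sm$recaptures_female < min_sex_recaptures ||
      sm$recaptures_male < min_sex_recaptures
    spec <- model_spec(if (use_model3) 3 else 1)
    cfg <- config
    if (!is.null(overrides)) {
      ov <- overrides[[as.character(tk)]]
      if (!is.null(ov)) cfg <- ov
    }
    fit <- secr_fit(ch, space, spec = spec, M = M, config = cfg)
    est <- list(sigma_f = posterior_draws(fit, "sigma_f"),
                sigma_m = posterior_draws(fit, "sigma_m"),
                psi_sex = posterior_draws(fit, "psi_sex"),
                N_super = posterior_draws(fit, "N_super"),
                D = density_draws(posterior_draws(fit, "N_super"), fit$area_km2))
    row <- data.frame(target_km = tk,
                      realised_km = attr(sub, "realised_km"),
                      n_individuals = sm$n_individuals,
                      n_recaptures = sm$recaptures,
                      avg_spatial_recaptures = sm$avg_spatial_recaptures,
                      model_used = spec$model_id)
    for (p in params_scored) {
      row[[paste0(p, "_mean")]] <- mean(est[[p]])
      row[[paste0(p, "_cv")]] <- cv(mean(est[[p]]), stats::sd(est[[p]]))
    }
    rows[[length(rows) + 1L]] <- row
    fits[[as.character(tk)]] <- fit
  }
  if (!length(rows)) stop("no subset could be fitted")
  tab <- do.call(rbind, rows)
  ref <- tab[nrow(tab), ] # largest increment = full data
  for (p in params_scored) {
    tab[[paste0(p, "_rb")]] <- relative_bias(tab[[paste0(p, "_mean")]],
                                             ref[[paste0(p, "_mean")]])
  }
  cvs <- as.matrix(tab[, paste0(params_scored, "_cv")])
  rbs <- as.matrix(tab[, paste0(params_scored, "_rb")])
  tab$adequate <- apply(cvs < 0.20, 1L, all) & apply(abs(rbs) < 0.15, 1L, all)
  structure(list(table = tab, fits = fits,
                 reference_km = ref$realised_km),
            class = "rarefaction_result")
}

#' @export
print.rarefaction_result <- function(x, ...) {
  cat(sprintf("rarefaction over %d subsets (reference %.0f km)\n",
              nrow(x$table), x$reference_km))
  cols <- c("target_km", "realised_km", "n_individuals", "n_recaptures",
            "model_used", "N_super_mean", "D_cv", "D_rb", "adequate")
  print(format(x$table[, cols], digits = 3), row.names = FALSE)
  invisible(x)
}
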