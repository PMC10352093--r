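#' Density draws from abundance draws
#'
#' @param N_draws posterior draws of `N_super`.
#' @param area_km2 state-space area (> 0).
#' @return Draws of density per 100 km^2 (`N / area * 100`).
#' @export
density_draws <- function(N_draws, area_km2) {
  if (!is.numeric(area_km2) || area_km2 <= 0) stop("area_km2 must be > 0")
  N_draws / area_km2 * 100
}

#' Sex ratio (females per male) from psi_sex
#'
#' `psi_sex` is the probability an included individual is male, so the
#' ratio of females to males is `(1 - psi_sex) / psi_sex`.
#'
#' @param psi_sex posterior mean of psi_sex, strictly inside (0, 1).
#' @return Females per male (raw value; round to one decimal for the
#'   conventional "x females : 1 male" statement, see [sex_ratio_label()]).
#' @export
sex_ratio <- function(psi_sex) {
  if (!is.numeric(psi_sex) || psi_sex <= 0 || psi_sex >= 1)
    stop("psi_sex must be strictly inside (0, 1)")
  (1 - psi_sex) / psi_sex
}

#' Format a sex ratio as "x:1" females per male, one decimal
#' @param psi_sex posterior mean of psi_sex.
#' @return Character, e.g. `"0.9F:1M"`.
#' @export
sex_ratio_label <- function(psi_sex) {
  sprintf("%.1fF:1M", round(sex_ratio(psi_sex), 1))
}

#' Home-range area draws from spatial-scale draws
#'
#' The 95% home-range area implied by a half-normal activity model is
#' `pi * sigma^2 * 5.99` (5.99 being the 0.95 quantile of a chi-square
#' with 2 df). Summaries should be taken over the transformed draws
#' (posterior mean of the transform), which by Jensen's inequality exceeds
#' the transform of the posterior mean.
#'
#' @param sigma_draws posterior draws of sigma (km, > 0).
#' @return Draws of home-range area (km^2).
#' @export
home_range_draws <- function(sigma_draws) {
  if (any(sigma_draws <= 0)) stop("sigma draws must be > 0")
  pi * sigma_draws^2 * 5.99
}

#' Posterior mean activity-centre count per pixel
#'
#' @param fit a [secr_fit()] of a spatial model.
#' @param space the state space used in the fit.
#' @return Data frame `pixel_id`, `x_km`, `y_km`, `mean_count`; the column
#'   sums to the posterior mean of `N_super` (conservation of individuals).
#' @export
pixel_density_map <- function(fit, space) {
  if (!fit$spec$spatial) stop("pixel map undefined for the nonspatial model")
  if (!fit$n_tally_draws) stop("fit carries no pixel tallies")
  data.frame(pixel_id = space$pixels$pixel_id,
             x_km = space$pixels$x_km, y_km = space$pixels$y_km,
             mean_count = fit$tally / fit$n_tally_draws)
}

#' Fraction of the population actually detected
#'
#' @param n_detected number of identified individuals.
#' @param N_mean posterior mean abundance (>= n_detected).
#' @return Percentage, rounded to the nearest integer.
#' @export
detected_fraction <- function(n_detected, N_mean) {
  if (n_detected <= 0 || N_mean < n_detected)
    stop("need N_mean >= n_detected > 0")
  round(100 * n_detected / N_mean)
}

#' Management summary of a fitted model
#'
#' Posterior mean, SD and HPD interval for every monitored parameter plus
#' the derived density, home ranges, sex ratio and detected fraction.
#'
#' @param fit a [secr_fit()].
#' @param mass HPD mass (default 0.95).
#' @return Object of class `derived_summary`: `table` (one row per
#'   parameter: mean, sd, hpd_lower, hpd_upper), `home_range_f_km2`,
#'   `home_range_m_km2` (each mean + psd), `sex_ratio_f_per_m`,
#'   `detected_fraction_pct`, `area_km2`, `n`, `M`.
#' @export
derived_summary <- function(fit, mass = 0.95) {
  rows <- fit$param_names
  tab <- do.call(rbind, lapply(rows, function(p) {
    d <- posterior_draws(fit, p)
    h <- hpd_interval(d, mass)
    data.frame(parameter = p, mean = mean(d), sd = stats::sd(d),
               hpd_lower = h[1L], hpd_upper = h[2L])
  }))
  Nd <- posterior_draws(fit, "N_super")
  Dd <- density_draws(Nd, fit$area_km2)
  h <- hpd_interval(Dd, mass)
  tab <- rbind(tab, data.frame(parameter = "D", mean = mean(Dd), sd = stats::sd(Dd),
                               hpd_lower = h[1L], hpd_upper = h[2L]))
  hr_f <- hr_m <- c(mean = NA_real_, psd = NA_real_)
  if (fit$spec$spatial) {
    hf <- home_range_draws(posterior_draws(fit, "sigma_f"))
    hm <- home_range_draws(posterior_draws(fit, "sigma_m"))
    hr_f <- c(mean = mean(hf), psd = stats::sd(hf))
    hr_m <- c(mean = mean(hm), psd = stats::sd(hm))
  }
  psx <- mean(posterior_draws(fit, "psi_sex"))
  structure(list(table = tab,
                 home_range_f_km2 = hr_f, home_range_m_km2 = hr_m,
                 sex_ratio_f_per_m = sex_ratio(psx),
                 detected_fraction_pct = detected_fraction(fit$n, mean(Nd)),
                 area_km2 = fit$area_km2, n = fit$n, M = fit$M,
                 model_id = fit$spec$model_id),
            class = "derived_summary")
}

#' @export
print.derived_summary <- function(x, digits = 4, ...) {
  cat(sprintf("Model %d posterior summaries (n = %d detected, M = %d, area %.1f km^2)\n",
              x$model_id, x$n, x$M, x$area_km2))
  print(format(x$table, digits = digits), row.names = FALSE)
  if (!is.na(x$home_range_m_km2["mean"]))
    cat(sprintf("home range: F %.0f km^2 (PSD %.1f), M %.0f km^2 (PSD %.1f)\n",
                x$home_range_f_km2["mean"], x$home_range_f_km2["psd"],
                x$home_range_m_km2["mean"], x$home_range_m_km2["psd"]))
  cat(sprintf("sex ratio %s; detected ~%d%% of estimated individuals\n",
              sex_ratio_label(1 / (1 + x$sex_ratio_f_per_m)),
              x$detected_fraction_pct))
  invisible(x)
}
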