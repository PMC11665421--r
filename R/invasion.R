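# Invasion kinetics: normalized radius trajectories, onset time,
# saturation detection, and power-law expansion-rate fitting.

#' Metrics parameters
#'
#' @param onset_threshold normalized-radius value defining invasion onset
#'   (default 1.1, i.e. a 10 percent radius increase).
#' @param saturation_rel_rate relative growth rate (per hour) below which the
#'   trajectory counts as saturated (default 0.01).
#' @param saturation_run minimum duration (hours) the rate must stay below
#'   `saturation_rel_rate` to call a plateau (default 3).
#' @param interval_confidence confidence level of the slope interval
#'   (default 0.95).
#' @return list of class `uj_metrics_params`.
#' @export
metrics_params <- function(onset_threshold = 1.1,
                           saturation_rel_rate = 0.01,
                           saturation_run = 3,
                           interval_confidence = 0.95) {
  stopifnot(onset_threshold > 1, saturation_rel_rate > 0,
            saturation_run > 0, interval_confidence > 0,
            interval_confidence < 1)
  structure(list(onset_threshold = onset_threshold,
                 saturation_rel_rate = saturation_rel_rate,
                 saturation_run = saturation_run,
                 interval_confidence = interval_confidence),
            class = "uj_metrics_params")
}

#' Normalize an effective-radius time series
#'
#' Divides the effective circular radius by its value at the first time
#' point, removing variation in initial spheroid size.
#'
#' @param times times in hours, strictly increasing.
#' @param r_eff effective circular radii in micrometers; `r_eff[1]` must be
#'   positive.
#' @return Object of class `uj_trajectory` with `times`, `r_eff` and
#'   `r_norm` (with `r_norm[1] == 1` exactly).
#' @export
normalize_radius <- function(times, r_eff) {
  stopifnot(length(times) == length(r_eff), length(times) >= 1)
  if (length(times) > 1 && any(diff(times) <= 0))
    uj_stop("InvalidTrajectory", "times must be strictly increasing")
  if (!is.finite(r_eff[1]) || r_eff[1] <= 0)
    uj_stop("ZeroInitialRadius", "initial effective radius must be > 0")
  structure(list(times = as.numeric(times), r_eff = as.numeric(r_eff),
                 r_norm = as.numeric(r_eff) / r_eff[1]),
            class = "uj_trajectory")
}

#' Invasion onset time
#'
#' First time the normalized radius reaches `onset_threshold`, linearly
#' interpolated between the bracketing samples ("reaches" is inclusive).
#'
#' @param traj a [normalize_radius()] trajectory.
#' @param params a [metrics_params()].
#' @return Onset time in hours, or `NA_real_` when the threshold is never
#'   reached (no measurable invasion).
#' @export
onset_time <- function(traj, params = metrics_params()) {
  stopifnot(inherits(traj, "uj_trajectory"), length(traj$times) >= 2)
  thr <- params$onset_threshold
  r <- traj$r_norm; t <- traj$times
  hit <- which(r >= thr)
  if (length(hit) == 0) return(NA_real_)
  i <- hit[1]
  if (r[i] == thr || i == 1) return(t[i])
  t[i - 1] + (thr - r[i - 1]) / (r[i] - r[i - 1]) * (t[i] - t[i - 1])
}

#' Saturation time of a normalized-radius trajectory
#'
#' Finds the earliest time after which the relative per-hour increase of the
#' normalized radius stays below `saturation_rel_rate` for at least
#' `saturation_run` hours. Brief above-threshold excursions shorter than
#' `saturation_run` are treated as noise and do not interrupt a plateau.
#' Returns the final time point when the trajectory never saturates (the
#' fit window then extends to the end of the assay).
#'
#' @param traj a [normalize_radius()] trajectory with at least 3 points.
#' @param params a [metrics_params()].
#' @param after ignore any plateau starting before this time (hours); used
#'   to skip the flat pre-onset part of the trajectory when determining the
#'   fit window.
#' @return Saturation time in hours.
#' @export
saturation_time <- function(traj, params = metrics_params(), after = 0) {
  stopifnot(inherits(traj, "uj_trajectory"), length(traj$times) >= 3)
  keep <- traj$times >= after
  if (sum(keep) < 3) return(traj$times[length(traj$times)])
  t <- traj$times[keep]; r <- traj$r_norm[keep]
  dt <- diff(t)
  rate <- diff(r) / (head(r, -1) * dt)  # relative increase per hour
  high <- rate >= params$saturation_rel_rate
  # suppress high runs shorter than saturation_run
  rl <- rle(high)
  dur <- numeric(length(rl$lengths))
  pos <- cumsum(c(1, rl$lengths))
  for (k in seq_along(rl$lengths)) {
    idx <- seq(pos[k], pos[k + 1] - 1)
    dur[k] <- sum(dt[idx])
  }
  rl$values[rl$values & dur < params$saturation_run] <- FALSE
  high <- inverse.rle(rl)
  rl <- rle(high)
  pos <- cumsum(c(1, rl$lengths))
  for (k in seq_along(rl$lengths)) {
    if (rl$values[k]) next
    idx <- seq(pos[k], pos[k + 1] - 1)
    if (sum(dt[idx]) >= params$saturation_run) return(t[pos[k]])
  }
  t[length(t)]
}

#' Power-law expansion rate
#'
#' Ordinary-least-squares slope of `log(r_norm)` against `log(t)` over the
#' samples inside the fit window, i.e. the exponent alpha of
#' `r_norm ~ A t^alpha`. Samples at `t = 0` are excluded (log undefined).
#'
#' @param traj a [normalize_radius()] trajectory.
#' @param window numeric length-2 `[t_start, t_end]` in hours (inclusive).
#' @param params a [metrics_params()]; sets the confidence level of the
#'   interval.
#' @return list with `alpha`, `alpha_interval` (symmetric t-based OLS
#'   confidence interval; zero-width for a perfect fit), `intercept` (log A),
#'   `n` and `window`.
#' @export
fit_expansion_rate <- function(traj, window, params = metrics_params()) {
  stopifnot(inherits(traj, "uj_trajectory"), length(window) == 2)
  sel <- traj$times >= window[1] & traj$times <= window[2] & traj$times > 0
  t <- traj$times[sel]; r <- traj$r_norm[sel]
  if (length(t) < 3)
    uj_stop("InsufficientData", "need at least 3 samples with t > 0 in window")
  if (any(r <= 0))
    uj_stop("NonPositiveValues", "r_norm must be positive within the fit window")
  x <- log(t); y <- log(r)
  n <- length(x)
  xbar <- mean(x); ybar <- mean(y)
  sxx <- sum((x - xbar)^2)
  alpha <- sum((x - xbar) * (y - ybar)) / sxx
  inter <- ybar - alpha * xbar
  res <- y - (inter + alpha * x)
  se <- sqrt(sum(res^2) / (n - 2) / sxx)
  tq <- qt(1 - (1 - params$interval_confidence) / 2, df = n - 2)
  list(alpha = alpha,
       alpha_interval = c(alpha - tq * se, alpha + tq * se),
       intercept = inter, se = se, n = n, window = as.numeric(window))
}

#' Aggregate replicate trajectories
#'
#' Pointwise mean and standard deviation of the normalized radius across
#' replicates. Replicates not sampled on the reference grid (the first
#' trajectory's times) are resampled by linear interpolation.
#'
#' @param trajs list of [normalize_radius()] trajectories.
#' @return Object of class `uj_mean_trajectory`: `times`, `mean`, `sd`, `n`,
#'   plus a `uj_trajectory` view (`as_trajectory`) of the mean curve for
#'   onset/slope analysis.
#' @export
aggregate_replicates <- function(trajs) {
  if (length(trajs) == 0) uj_stop("EmptyInput", "no trajectories supplied")
  stopifnot(all(vapply(trajs, inherits, logical(1), "uj_trajectory")))
  grid <- trajs[[1]]$times
  vals <- vapply(trajs, function(tr) {
    if (identical(tr$times, grid)) tr$r_norm
    else approx(tr$times, tr$r_norm, xout = grid, rule = 2)$y
  }, numeric(length(grid)))
  vals <- matrix(vals, nrow = length(grid))
  m <- rowMeans(vals)
  s <- apply(vals, 1, sd)
  structure(list(times = grid, mean = m, sd = s, n = length(trajs),
                 as_trajectory = structure(
                   list(times = grid, r_eff = m, r_norm = m / m[1]),
                   class = "uj_trajectory")),
            class = "uj_mean_trajectory")
}

#' Summarize invasion kinetics of one trajectory
#'
#' Convenience wrapper: onset by threshold crossing, saturation detection,
#' and a power-law fit over `[t_ons, t_sat]`. When onset is undefined (the
#' threshold is never reached) no rate is fitted.
#'
#' @param traj a [normalize_radius()] trajectory.
#' @param params a [metrics_params()].
#' @return list of class `uj_invasion_summary`: `t_ons`, `alpha`,
#'   `alpha_interval`, `fit_window`, `r_norm_final`.
#' @export
summarize_invasion <- function(traj, params = metrics_params()) {
  t_ons <- onset_time(traj, params)
  r_final <- traj$r_norm[length(traj$r_norm)]
  if (is.na(t_ons)) {
    return(structure(list(t_ons = NA_real_, alpha = NA_real_,
                          alpha_interval = c(NA_real_, NA_real_),
                          fit_window = c(NA_real_, NA_real_),
                          r_norm_final = r_final),
                     class = "uj_invasion_summary"))
  }
  t_sat <- saturation_time(traj, params, after = t_ons)
  window <- c(t_ons, max(t_sat, t_ons))
  fit <- tryCatch(fit_expansion_rate(traj, window, params),
                  InsufficientData = function(e) NULL)
  structure(list(
    t_ons = t_ons,
    alpha = if (is.null(fit)) NA_real_ else fit$alpha,
    alpha_interval = if (is.null(fit)) c(NA_real_, NA_real_) else fit$alpha_interval,
    fit_window = window,
    r_norm_final = r_final
  ), class = "uj_invasion_summary")
}
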