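# Ground-truthed synthetic inputs: spheroid time-lapses, fiber networks,
# and advancing dye fronts. The generators reproduce the phenomenology the
# analysis assumes (onset-delayed power-law growth, angular protrusion
# bumps, disseminating cell blobs, noisy fiber stacks, sigmoidal fronts),
# not any cell-level mechanism.

#' Spheroid time-lapse simulation parameters
#'
#' Defaults emulate a control melanoma spheroid in a dense gel: initial
#' radius 100 um (assay spheroids average about 200 um diameter), onset at
#' 11.5 hrs, power-law exponent 0.29, hourly frames over 24 hrs, 2 percent
#' noise.
#'
#' @param r0 initial spheroid radius in micrometers.
#' @param t_ons_true ground-truth invasion onset in hours: the time at which
#'   the noiseless normalized radius crosses `onset_threshold`. Motion
#'   starts earlier, at `t0 = t_ons_true * onset_threshold^(-1/alpha_true)`,
#'   so that the operational (threshold) onset matches this parameter.
#' @param alpha_true power-law exponent of the normalized radius after
#'   motion start (0 = no invasion).
#' @param n_protrusions number of angular protrusion bumps.
#' @param protrusion_growth protrusion elongation rate in um/hr after motion
#'   start.
#' @param cell_emission_rate expected dissociated cells per hour after
#'   onset (Poisson).
#' @param noise_sd additive Gaussian noise, as a fraction of the intensity
#'   dynamic range.
#' @param pixel_size micrometers per pixel.
#' @param interval hours between frames.
#' @param duration total assay duration in hours.
#' @param onset_threshold normalized-radius threshold defining the onset.
#' @param seed RNG seed.
#' @return list of class `uj_spheroid_sim_params`.
#' @export
spheroid_sim_params <- function(r0 = 100, t_ons_true = 11.5, alpha_true = 0.29,
                                n_protrusions = 0, protrusion_growth = 0,
                                cell_emission_rate = 0, noise_sd = 0.02,
                                pixel_size = 1, interval = 1, duration = 24,
                                onset_threshold = 1.1, seed = 1) {
  if (r0 <= 0 || alpha_true < 0 || duration < interval || interval <= 0 ||
      pixel_size <= 0 || noise_sd < 0 || n_protrusions < 0 ||
      protrusion_growth < 0 || cell_emission_rate < 0 || t_ons_true <= 0)
    uj_stop("InvalidParams", "invalid spheroid simulation parameters")
  structure(as.list(environment()), class = "uj_spheroid_sim_params")
}

# Noiseless forward model of the normalized radius. Motion starts at t0 and
# follows (t/t0)^alpha, so the threshold crossing sits exactly at t_ons.
spheroid_radius_law <- function(times, t_ons, alpha, threshold = 1.1) {
  if (alpha <= 0) return(rep(1, length(times)))
  t0 <- t_ons * threshold^(-1 / alpha)
  ifelse(times <= t0, 1, (times / t0)^alpha)
}

#' Simulate a bright-field spheroid invasion time-lapse
#'
#' Renders a dark spheroid disk (with a faint halo) on a bright background.
#' After motion start the body radius follows the power law of
#' [spheroid_radius_law()], protrusions grow as Gaussian angular bumps, and
#' dissociated cells are emitted as a Poisson process and rendered as small
#' dark blobs placed clear of the final spheroid outline so ground-truth
#' counts are unambiguous.
#'
#' @param params a [spheroid_sim_params()].
#' @return list: `movie` (a [timelapse()]), `truth` (list with `times`,
#'   `r_norm_true`, `r_eff_true_um`, `protrusion_length_um`,
#'   `n_cells_cum`, `t_ons_true`, `alpha_true`, `motion_start_hrs`).
#' @export
simulate_spheroid_timelapse <- function(params = spheroid_sim_params()) {
  stopifnot(inherits(params, "uj_spheroid_sim_params"))
  set.seed(params$seed)
  p <- params
  times <- seq(0, p$duration, by = p$interval)
  r_norm <- spheroid_radius_law(times, p$t_ons_true, p$alpha_true,
                                p$onset_threshold)
  r_body_px <- p$r0 * r_norm / p$pixel_size
  t0 <- if (p$alpha_true > 0) p$t_ons_true * p$onset_threshold^(-1 / p$alpha_true) else Inf
  prot_len_um <- pmax(0, (times - t0)) * p$protrusion_growth
  if (p$n_protrusions == 0) prot_len_um[] <- 0

  prot_theta <- if (p$n_protrusions > 0) runif(p$n_protrusions, 0, 2 * pi) else numeric(0)
  sd_theta <- 7.5 * pi / 180  # 15 degree bump width
  bump_profile <- function(theta, amp) {
    out <- 0
    for (th in prot_theta) {
      dth <- abs(((theta - th + pi) %% (2 * pi)) - pi)
      out <- out + amp * exp(-0.5 * (dth / sd_theta)^2)
    }
    out
  }

  # canvas large enough for the body plus summed (possibly overlapping)
  # protrusion bumps at the final frame, with room for emitted cells
  theta_grid <- seq(0, 2 * pi, length.out = 720)
  bump_max_px <- if (length(prot_theta)) {
    max(bump_profile(theta_grid, max(prot_len_um) / p$pixel_size))
  } else 0
  max_extent <- max(r_body_px) + bump_max_px
  half <- ceiling(max_extent + 60)
  size <- max(2L * as.integer(half), 64L)
  ctr <- (size + 1) / 2
  rows <- matrix(seq_len(size), size, size) - ctr
  cols <- matrix(seq_len(size), size, size, byrow = TRUE) - ctr
  dist <- sqrt(rows^2 + cols^2)
  ang <- atan2(rows, cols)

  # Poisson cell emission after onset; cells persist once emitted
  n_new <- integer(length(times))
  for (i in seq_along(times)[-1]) {
    exposed <- max(0, min(times[i], p$duration) - max(times[i - 1], p$t_ons_true))
    n_new[i] <- if (exposed > 0) rpois(1, p$cell_emission_rate * exposed) else 0L
  }
  n_cum <- cumsum(n_new)

  # place cells outside the final spheroid outline (body + protrusions)
  final_body <- r_body_px[length(times)]
  cell_r_px <- 5
  cell_pos <- matrix(numeric(0), 0, 2)
  total_cells <- n_cum[length(n_cum)]
  if (total_cells > 0) {
    tries <- 0
    while (nrow(cell_pos) < total_cells && tries < 2000) {
      tries <- tries + 1
      th <- runif(1, 0, 2 * pi)
      outline <- final_body
      if (length(prot_theta))
        outline <- outline + bump_profile(th, max(prot_len_um) / p$pixel_size)
      # clearance: morphological closing in the detector (dilate + erode by
      # 5 px) merges structures closer than ~2 x dilation_radius, so blobs
      # are kept well apart from the body and from each other
      lo <- outline + 25 + cell_r_px
      hi <- half - 14
      if (lo >= hi) next
      rr <- runif(1, lo, hi)
      pos <- c(rr * sin(th), rr * cos(th))
      if (nrow(cell_pos) > 0 &&
          min(sqrt((cell_pos[, 1] - pos[1])^2 + (cell_pos[, 2] - pos[2])^2)) < 25)
        next
      cell_pos <- rbind(cell_pos, pos)
    }
    total_cells <- nrow(cell_pos)
    n_cum <- pmin(n_cum, total_cells)
  }

  bg <- 0.85; fg <- 0.15
  frames <- vector("list", length(times))
  for (i in seq_along(times)) {
    R <- r_body_px[i]
    radius_map <- R
    if (length(prot_theta) && prot_len_um[i] > 0)
      radius_map <- R + bump_profile(ang, prot_len_um[i] / p$pixel_size)
    img <- bg - (bg - fg) * stats::plogis((radius_map - dist) / 0.8)
    img <- img + 0.06 * exp(-((dist - radius_map - 2.5) / 1.5)^2)
    if (n_cum[i] > 0) {
      for (k in seq_len(n_cum[i])) {
        dcell <- sqrt((rows - cell_pos[k, 1])^2 + (cols - cell_pos[k, 2])^2)
        img <- img - (bg - fg) * stats::plogis((cell_r_px - dcell) / 0.6) *
          (1 - stats::plogis((radius_map - dist) / 0.8))
      }
    }
    if (p$noise_sd > 0) img <- img + rnorm(length(img), 0, p$noise_sd * (bg - fg))
    frames[[i]] <- bf_frame(matrix(img, size, size), p$pixel_size, times[i])
  }
  list(movie = timelapse(frames, p$interval),
       truth = list(times = times, r_norm_true = r_norm,
                    r_eff_true_um = p$r0 * r_norm,
                    protrusion_length_um = prot_len_um,
                    n_cells_cum = n_cum,
                    t_ons_true = if (p$alpha_true > 0) p$t_ons_true else NA_real_,
                    alpha_true = p$alpha_true,
                    motion_start_hrs = t0))
}

#' Simulate a noisy normalized-radius trajectory
#'
#' Lightweight trajectory-level generator (no image rendering):
#' `r_eff(t) = r0 * law(t) * (1 + eps)`, with `eps ~ N(0, noise_sd)`
#' multiplicative noise. With `calibrate_onset = FALSE` the power law is
#' anchored at the motion start (`r_norm(t_start) = 1`, i.e.
#' `r_norm = (t/t_start)^alpha` afterwards); with `TRUE` the anchor is
#' shifted so the noiseless threshold crossing occurs at `t_start`.
#'
#' @param times sample times in hours.
#' @param t_start motion-start (or calibrated onset) time in hours.
#' @param alpha power-law exponent.
#' @param noise_sd multiplicative noise standard deviation.
#' @param r0 initial radius in micrometers.
#' @param calibrate_onset see description.
#' @param onset_threshold threshold used when `calibrate_onset = TRUE`.
#' @return list: `times`, `r_eff` (noisy, um), `r_norm_true`.
#' @export
simulate_radius_trajectory <- function(times, t_start, alpha, noise_sd = 0.02,
                                       r0 = 100, calibrate_onset = FALSE,
                                       onset_threshold = 1.1) {
  stopifnot(t_start > 0, alpha >= 0, noise_sd >= 0)
  law <- if (calibrate_onset) {
    spheroid_radius_law(times, t_start, alpha, onset_threshold)
  } else if (alpha <= 0) {
    rep(1, length(times))
  } else {
    ifelse(times <= t_start, 1, (times / t_start)^alpha)
  }
  r <- r0 * law
  if (noise_sd > 0) r <- r * (1 + rnorm(length(r), 0, noise_sd))
  list(times = times, r_eff = r, r_norm_true = law)
}

#' Fiber network simulation parameters
#'
#' @param volume_shape integer length-3 `(z, rows, cols)`.
#' @param fiber_count number of straight fibers thrown into the volume.
#' @param fiber_radius fiber radius in pixels.
#' @param intensity_noise_sd additive Gaussian noise level.
#' @param seed RNG seed.
#' @return list of class `uj_fiber_sim_params`.
#' @export
fiber_sim_params <- function(volume_shape = c(5, 128, 128), fiber_count = 40,
                             fiber_radius = 1.5, intensity_noise_sd = 0.05,
                             seed = 1) {
  if (length(volume_shape) != 3 || any(volume_shape < 1) || fiber_count < 0 ||
      fiber_radius <= 0 || intensity_noise_sd < 0)
    uj_stop("InvalidParams", "invalid fiber simulation parameters")
  structure(list(volume_shape = as.integer(volume_shape),
                 fiber_count = as.integer(fiber_count),
                 fiber_radius = fiber_radius,
                 intensity_noise_sd = intensity_noise_sd, seed = seed),
            class = "uj_fiber_sim_params")
}

#' Simulate a confocal reflectance stack of a random fiber network
#'
#' Straight 3D line segments with isotropic random orientation are rendered
#' as bright tubes of radius `fiber_radius` on a dark background, lightly
#' blurred, with additive Gaussian noise.
#'
#' @param params a [fiber_sim_params()].
#' @param pixel_size_xy lateral pixel size in micrometers.
#' @param z_step axial step in micrometers.
#' @return list: `stack` (a [confocal_stack()]), `coverage` (ground-truth
#'   fiber area fraction of the binary maximum projection).
#' @export
simulate_fiber_stack <- function(params = fiber_sim_params(),
                                 pixel_size_xy = 0.2, z_step = 2) {
  stopifnot(inherits(params, "uj_fiber_sim_params"))
  set.seed(params$seed)
  dims <- params$volume_shape  # (z, rows, cols)
  nz <- dims[1]; nr <- dims[2]; nc <- dims[3]
  vox <- array(0, dim = c(nr, nc, nz))
  rowg <- matrix(seq_len(nr), nr, nc)
  colg <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  for (f in seq_len(params$fiber_count)) {
    p0 <- c(runif(1, 1, nr), runif(1, 1, nc), runif(1, 1, nz))
    u <- rnorm(3); u[3] <- u[3] * nz / max(nr, nc)  # mildly in-plane
    u <- u / sqrt(sum(u^2))
    for (z in seq_len(nz)) {
      # distance from voxel (r, c, z) to the infinite line p0 + s*u
      dr <- rowg - p0[1]; dc <- colg - p0[2]; dz <- z - p0[3]
      s <- dr * u[1] + dc * u[2] + dz * u[3]
      d2 <- (dr - s * u[1])^2 + (dc - s * u[2])^2 + (dz - s * u[3])^2
      vox[, , z] <- pmax(vox[, , z], as.numeric(d2 <= params$fiber_radius^2))
    }
  }
  proj <- apply(vox, c(1, 2), max)
  coverage <- mean(proj > 0)
  for (z in seq_len(nz)) {
    sl <- img_gaussian(vox[, , z], 0.8)
    if (params$intensity_noise_sd > 0)
      sl <- sl + rnorm(length(sl), 0, params$intensity_noise_sd)
    vox[, , z] <- sl
  }
  list(stack = confocal_stack(vox, pixel_size_xy, z_step),
       coverage = coverage)
}

#' Dye-front simulation parameters
#'
#' Defaults match the permeability assay geometry: 0.62 um pixels, 30 s
#' frame interval, 20 mbar (2000 Pa) pressure difference over a 1 mm gel
#' channel, water-like viscosity.
#'
#' @param velocity_true front velocity in m/s.
#' @param pixel_size pixel size in micrometers.
#' @param interval frame interval in seconds.
#' @param n_frames number of frames.
#' @param noise_sd additive intensity noise.
#' @param shape image size `(rows, cols)`; flow runs along rows.
#' @param front_width_px sigmoidal front width in pixels.
#' @param start_px initial front position in pixels.
#' @param delta_P pressure difference in pascal.
#' @param channel_length channel length in meters.
#' @param viscosity dynamic viscosity in pascal-seconds.
#' @param seed RNG seed.
#' @return list of class `uj_front_sim_params`.
#' @export
front_sim_params <- function(velocity_true = 2e-7, pixel_size = 0.62,
                             interval = 30, n_frames = 11, noise_sd = 0.01,
                             shape = c(200, 64), front_width_px = 3,
                             start_px = 20, delta_P = 2000,
                             channel_length = 1e-3, viscosity = 1e-3,
                             seed = 1) {
  if (velocity_true < 0 || pixel_size <= 0 || interval <= 0 || n_frames < 1 ||
      noise_sd < 0 || any(shape < 8))
    uj_stop("InvalidParams", "invalid front simulation parameters")
  structure(as.list(environment()), class = "uj_front_sim_params")
}

#' Simulate an advancing dye front
#'
#' Frames show a bright dye phase behind a sigmoidal front advancing along
#' the row axis at constant velocity, with additive Gaussian noise.
#'
#' @param params a [front_sim_params()].
#' @return list: `series` (a [front_series()] carrying the pressure /
#'   geometry metadata), `velocity_true` (m/s).
#' @export
simulate_dye_front <- function(params = front_sim_params()) {
  stopifnot(inherits(params, "uj_front_sim_params"))
  set.seed(params$seed)
  p <- params
  nr <- p$shape[1]; nc <- p$shape[2]
  px_per_s <- p$velocity_true / (p$pixel_size * 1e-6)
  frames <- lapply(seq_len(p$n_frames) - 1L, function(k) {
    pos <- p$start_px + px_per_s * p$interval * k
    prof <- stats::plogis((pos - seq_len(nr)) / p$front_width_px)
    img <- matrix(prof, nr, nc)
    if (p$noise_sd > 0) img <- img + rnorm(length(img), 0, p$noise_sd)
    img
  })
  list(series = front_series(frames, p$pixel_size, p$interval, p$delta_P,
                             p$channel_length, p$viscosity),
       velocity_true = p$velocity_true)
}
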