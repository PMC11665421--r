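# Hydrogel confinement characterization: bubble-method pore sizes from
# confocal reflectance stacks, void fraction from maximum-intensity
# projections, Darcy permeability from dye-front tracking, and the
# shear-to-Young's modulus conversion.

#' Construct a confocal reflectance stack
#'
#' @param voxels 3D numeric array indexed `[row, col, z]` (a single matrix is
#'   promoted to one slice).
#' @param pixel_size_xy lateral pixel size in micrometers.
#' @param z_step axial step in micrometers.
#' @return object of class `uj_stack`.
#' @export
confocal_stack <- function(voxels, pixel_size_xy, z_step = 2) {
  if (is.matrix(voxels)) voxels <- array(voxels, dim = c(dim(voxels), 1))
  stopifnot(is.array(voxels), length(dim(voxels)) == 3,
            pixel_size_xy > 0, z_step > 0, dim(voxels)[3] >= 1)
  structure(list(voxels = voxels, pixel_size_xy = pixel_size_xy,
                 z_step = z_step),
            class = "uj_stack")
}

#' Pore-size analysis parameters
#'
#' @param tv_weight denoising strength of the total-variation filter.
#' @param local_threshold_block side length (pixels, odd) of the local-mean
#'   threshold window.
#' @param edm_gauss_sigma standard deviation (pixels) of the Gaussian applied
#'   to the Euclidean distance map before peak finding (default 5).
#' @param min_separation minimum distance (pixels) between retained maxima;
#'   defaults to `edm_gauss_sigma`.
#' @param threshold_offset_frac fraction of the global intensity range added
#'   to the local mean before binarization; guards against speckle in
#'   fiber-free regions while keeping exactly uniform slices all-fiber.
#' @return list of class `uj_pore_params`.
#' @export
pore_size_params <- function(tv_weight = 0.1,
                             local_threshold_block = 51,
                             edm_gauss_sigma = 5,
                             min_separation = edm_gauss_sigma,
                             threshold_offset_frac = 0.02) {
  stopifnot(tv_weight > 0, local_threshold_block > 0, edm_gauss_sigma > 0,
            min_separation >= 0, threshold_offset_frac >= 0)
  structure(list(tv_weight = tv_weight,
                 local_threshold_block = as.integer(local_threshold_block),
                 edm_gauss_sigma = edm_gauss_sigma,
                 min_separation = min_separation,
                 threshold_offset_frac = threshold_offset_frac),
            class = "uj_pore_params")
}

#' Total-variation (ROF) denoising
#'
#' Chambolle's dual projection algorithm for the Rudin-Osher-Fatemi model;
#' `weight` plays the role of the regularization strength (larger = smoother).
#'
#' @param img numeric matrix.
#' @param weight regularization weight.
#' @param n_iter number of projection iterations.
#' @return denoised matrix of the same size.
#' @export
tv_denoise <- function(img, weight = 0.1, n_iter = 60) {
  stopifnot(is.matrix(img), weight > 0)
  nr <- nrow(img); nc <- ncol(img)
  p1 <- matrix(0, nr, nc); p2 <- matrix(0, nr, nc)
  tau <- 0.25
  grad <- function(u) {
    g1 <- rbind(u[-1, , drop = FALSE] - u[-nr, , drop = FALSE], rep(0, nc))
    g2 <- cbind(u[, -1, drop = FALSE] - u[, -nc, drop = FALSE], rep(0, nr))
    list(g1, g2)
  }
  divergence <- function(p1, p2) {
    d1 <- rbind(p1[1, , drop = FALSE],
                p1[-c(1, nr), , drop = FALSE] - p1[-c(nr - 1, nr), , drop = FALSE],
                -p1[nr - 1, , drop = FALSE])
    d2 <- cbind(p2[, 1, drop = FALSE],
                p2[, -c(1, nc), drop = FALSE] - p2[, -c(nc - 1, nc), drop = FALSE],
                -p2[, nc - 1, drop = FALSE])
    d1 + d2
  }
  for (it in seq_len(n_iter)) {
    u <- divergence(p1, p2) - img / weight
    g <- grad(u)
    denom <- 1 + tau * sqrt(g[[1]]^2 + g[[2]]^2)
    p1 <- (p1 + tau * g[[1]]) / denom
    p2 <- (p2 + tau * g[[2]]) / denom
  }
  img - weight * divergence(p1, p2)
}

# Local-mean binarization; fibers are bright. `>=` keeps exactly uniform
# slices all-fiber (no void), which the bubble method reports as such.
binarize_fibers <- function(img, params) {
  off <- params$threshold_offset_frac * diff(range(img))
  img >= mean_filter(img, params$local_threshold_block %/% 2L) + off
}

#' Bubble-method pore sizes from a confocal reflectance stack
#'
#' Per slice: total-variation denoising, local-mean binarization into fiber
#' and void phases, exact Euclidean distance map of the void phase (distance
#' to the nearest fiber), Gaussian smoothing of the map (sigma =
#' `edm_gauss_sigma`), and local-maximum detection with plateau merging and
#' a minimum separation. Each retained maximum marks a pore; the unsmoothed
#' distance there is half the local pore size. Maxima touching the image
#' border are discarded (pores truncated by the field of view). Results are
#' pooled across slices.
#'
#' @param stack a [confocal_stack()].
#' @param params a [pore_size_params()].
#' @return list of class `uj_pore_sizes`: `pore_diameters` (micrometers),
#'   `mean`, `sd`, `n_maxima`.
#' @export
bubble_pore_sizes <- function(stack, params = pore_size_params()) {
  stopifnot(inherits(stack, "uj_stack"), inherits(params, "uj_pore_params"))
  nz <- dim(stack$voxels)[3]
  diameters <- numeric(0)
  any_void <- FALSE
  for (z in seq_len(nz)) {
    slice <- stack$voxels[, , z]
    # normalize contrast so binarization (and tv_weight) are invariant to
    # intensity rescaling of the stack
    rng <- range(slice)
    if (diff(rng) > 0) slice <- (slice - rng[1]) / diff(rng)
    den <- tv_denoise(slice, params$tv_weight)
    fiber <- binarize_fibers(den, params)
    void <- !fiber
    if (!any(void)) next
    any_void <- TRUE
    edm <- distance_transform(fiber)
    if (!any(is.finite(edm))) next  # no fiber at all: pore size unbounded
    sm <- img_gaussian(edm, params$edm_gauss_sigma)
    interior <- matrix(FALSE, nrow(slice), ncol(slice))
    interior[-c(1, nrow(slice)), -c(1, ncol(slice))] <- TRUE
    peaks <- local_maxima(sm, min_separation = params$min_separation,
                          mask = void & interior)
    if (nrow(peaks) == 0) next
    vals <- edm[cbind(peaks$row, peaks$col)]
    vals <- vals[vals > 0]
    diameters <- c(diameters, 2 * vals * stack$pixel_size_xy)
  }
  if (!any_void)
    uj_stop("EmptyVoidPhase", "binarization produced no void pixels")
  if (length(diameters) == 0)
    uj_stop("NoMaxima", "no local maximum survived peak filtering")
  structure(list(pore_diameters = diameters,
                 mean = mean(diameters),
                 sd = if (length(diameters) > 1) sd(diameters) else 0,
                 n_maxima = length(diameters)),
            class = "uj_pore_sizes")
}

#' Void fraction of a hydrogel stack
#'
#' Maximum-intensity projection along z, contrast stretch, Otsu
#' binarization (white = fibers, black = voids), then the black-to-white
#' pixel ratio plus the conventional void fraction
#' `n_black / (n_black + n_white)`.
#'
#' @param stack a [confocal_stack()], or a single binary/grayscale matrix.
#' @return list: `ratio_black_white`, `fraction_void`, `n_black`, `n_white`.
#'   When no pixel is classified as fiber an `AllVoid` error is raised (its
#'   condition carries `fraction_void = 1`).
#' @export
void_fraction <- function(stack) {
  if (is.matrix(stack)) stack <- confocal_stack(stack, 1)
  stopifnot(inherits(stack, "uj_stack"))
  mip <- apply(stack$voxels, c(1, 2), max)
  rng <- range(mip)
  if (diff(rng) == 0) {
    # uniform projection: nothing separable from background
    uj_stop("AllVoid", "projection is uniform; no fiber phase detected",
            data = list(fraction_void = 1, n_black = length(mip), n_white = 0L))
  }
  mip <- (mip - rng[1]) / diff(rng)
  thr <- otsu_threshold(mip)
  white <- mip > thr
  n_white <- sum(white); n_black <- sum(!white)
  if (n_white == 0)
    uj_stop("AllVoid", "no fiber pixels after binarization",
            data = list(fraction_void = 1, n_black = n_black, n_white = 0L))
  list(ratio_black_white = n_black / n_white,
       fraction_void = n_black / (n_black + n_white),
       n_black = n_black, n_white = n_white)
}

#' Construct a dye-front time series
#'
#' @param frames list of numeric matrices (fluorescence images), or a 3D
#'   array `[row, col, frame]`; the dye advances along increasing row index.
#' @param pixel_size pixel size in micrometers.
#' @param interval time between frames in seconds.
#' @param delta_P pressure difference across the gel channel in pascal.
#' @param channel_length gel channel length in meters.
#' @param viscosity fluid dynamic viscosity in pascal-seconds (default
#'   1e-3, water at room temperature).
#' @return object of class `uj_front_series`.
#' @export
front_series <- function(frames, pixel_size, interval,
                         delta_P, channel_length, viscosity = 1e-3) {
  if (is.array(frames) && length(dim(frames)) == 3)
    frames <- lapply(seq_len(dim(frames)[3]), function(k) frames[, , k])
  stopifnot(is.list(frames), length(frames) >= 1, pixel_size > 0,
            interval > 0)
  if (delta_P <= 0 || channel_length <= 0 || viscosity <= 0)
    uj_stop("InvalidPhysical", "delta_P, channel_length and viscosity must be > 0")
  structure(list(frames = frames, pixel_size = pixel_size,
                 interval = interval, delta_P = delta_P,
                 channel_length = channel_length, viscosity = viscosity),
            class = "uj_front_series")
}

#' Track an advancing dye front
#'
#' For each frame the transverse mean intensity is computed along the flow
#' axis; the front position is the first distance at which the
#' background-subtracted profile drops to at most epsilon (two background
#' noise standard deviations, estimated from the far field of the first
#' frame), sub-pixel interpolated. The velocity is the mean of successive
#' displacements divided by the frame interval.
#'
#' Epsilon is two background-noise standard deviations, floored at 2
#' percent of the front amplitude: crossing the raw noise level in the far
#' logistic tail is numerically ill-conditioned (the profile slope there is
#' of the order of the noise), while a small amplitude-relative floor sits
#' on the steep part of the front and only shifts every frame's position by
#' the same constant, which cancels in the velocity.
#'
#' @param series a [front_series()] with at least 2 frames.
#' @return list of class `uj_front_track`: `front_positions` (meters),
#'   `velocity` (m/s). A `NonMonotonicFront` warning is raised when the
#'   front regresses by more than one pixel. A `NoFront` error is raised
#'   when the frames are uniformly saturated (no dye-free far field) or the
#'   profile never drops to the background level.
#' @export
track_dye_front <- function(series) {
  stopifnot(inherits(series, "uj_front_series"), length(series$frames) >= 2)
  n_ahead <- max(5L, ceiling(nrow(series$frames[[1]]) * 0.1))
  prof1 <- rowMeans(series$frames[[1]])
  far <- tail(prof1, n_ahead)
  bg <- mean(far)
  amplitude <- max(prof1) - bg
  noise <- sd(far)
  if (!is.finite(noise)) noise <- 0
  if (amplitude <= max(4 * noise, 1e-9))
    uj_stop("NoFront", "frames are uniformly saturated; no dye front present")
  eps <- max(2 * noise, 0.02 * amplitude)
  pos_px <- vapply(series$frames, function(f) {
    prof <- rowMeans(f) - bg
    below <- which(prof <= eps)
    if (length(below) == 0)
      uj_stop("NoFront", "intensity profile never drops to background level")
    i <- below[1]
    if (i == 1) return(0)
    # sub-pixel: linear interpolation of the crossing of level eps
    frac <- (prof[i - 1] - eps) / (prof[i - 1] - prof[i])
    (i - 2) + frac  # 0-based pixel position
  }, numeric(1))
  if (any(diff(pos_px) < -1))
    uj_warn("NonMonotonicFront", "front position regressed by more than one pixel")
  positions <- pos_px * series$pixel_size * 1e-6
  velocity <- mean(diff(positions)) / series$interval
  structure(list(front_positions = positions, velocity = velocity),
            class = "uj_front_track")
}

#' Hydraulic permeability from Darcy's law
#'
#' Inverts `v = delta_P * K / (L * mu)` for the permeability `K`.
#'
#' @param v flow velocity in m/s (>= 0).
#' @param delta_P pressure difference in pascal.
#' @param L channel length in meters.
#' @param mu dynamic viscosity in pascal-seconds.
#' @return permeability K in m^2.
#' @export
permeability_from_velocity <- function(v, delta_P, L, mu = 1e-3) {
  if (any(v < 0)) uj_stop("InvalidPhysical", "velocity must be >= 0")
  if (any(delta_P <= 0) || any(L <= 0) || any(mu <= 0))
    uj_stop("InvalidPhysical", "delta_P, L and mu must be > 0")
  v * L * mu / delta_P
}

#' Pore size from permeability
#'
#' The square root of the hydraulic permeability, taken literally as the
#' characteristic pore size with no geometric prefactor. Note the scale:
#' sqrt(2.36e-16 m^2) = 1.536e-8 m, i.e. 15.4 nm; reports quoting "1.54 nm"
#' for this permeability are using units of 1e-8 m.
#'
#' @param K permeability in m^2 (>= 0).
#' @return pore size in meters; attributes `nm` and `per_1e8_m` give the
#'   value in nanometers and in units of 1e-8 m.
#' @export
pore_size_from_permeability <- function(K) {
  if (any(K < 0)) uj_stop("NegativePermeability", "K must be >= 0")
  p <- sqrt(K)
  attr(p, "nm") <- as.numeric(p) * 1e9
  attr(p, "per_1e8_m") <- as.numeric(p) * 1e8
  p
}

#' Full permeability analysis of a dye-front series
#'
#' @param series a [front_series()].
#' @return list of class `uj_permeability`: `front_positions`, `velocity`,
#'   `K` (m^2), `pore_size` (m, `sqrt(K)`).
#' @export
darcy_permeability <- function(series) {
  tr <- track_dye_front(series)
  K <- permeability_from_velocity(tr$velocity, series$delta_P,
                                  series$channel_length, series$viscosity)
  structure(list(front_positions = tr$front_positions,
                 velocity = tr$velocity, K = K,
                 pore_size = as.numeric(pore_size_from_permeability(K))),
            class = "uj_permeability")
}

#' Young's modulus from the shear storage modulus
#'
#' `E = 2 G (1 + nu)`; for an incompressible gel (`nu = 0.5`) the Young's
#' modulus is three times the storage modulus.
#'
#' @param G shear storage modulus in pascal (>= 0).
#' @param poisson Poisson's ratio in `[0, 0.5]`.
#' @return Young's modulus in pascal.
#' @export
youngs_modulus <- function(G, poisson = 0.5) {
  if (any(G < 0)) uj_stop("InvalidPhysical", "G must be >= 0")
  if (any(poisson < 0) || any(poisson > 0.5))
    uj_stop("InvalidPoisson", "Poisson's ratio must be in [0, 0.5]")
  2 * G * (1 + poisson)
}
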