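# Polar-coordinate protrusion detection and unjamming-phase classification.
#
# The boundary is resampled on uniform angular bins around the centroid;
# multicellular protrusions appear as contiguous runs where the boundary
# radius exceeds the mean radius. The classification uses the two endpoint
# criteria of the assay: more than `cell_count_cutoff` net dissociated
# cells means gas-like; otherwise a mean protrusion length above
# `length_cutoff` means liquid-like; otherwise solid-like. Both inequalities
# are strict, so boundary values map to the lower (more jammed) phase.

#' Classification parameters
#'
#' @param length_cutoff mean protrusion length (micrometers) above which a
#'   spheroid is liquid-like; 25 um by default because intact spheroids at
#'   t = 0 occasionally show apparent protrusions up to that length.
#' @param cell_count_cutoff net dissociated-cell count above which a
#'   spheroid is gas-like (default 10).
#' @param theta_bins number of uniform angular bins (default 360).
#' @param min_prominence smallest peak height (micrometers) above the mean
#'   radius retained as a protrusion; suppresses pixel noise. The 25 um
#'   cutoff makes the classification insensitive to this choice.
#' @return list of class `uj_class_params`.
#' @export
classification_params <- function(length_cutoff = 25,
                                  cell_count_cutoff = 10,
                                  theta_bins = 360,
                                  min_prominence = 5) {
  stopifnot(length_cutoff > 0, cell_count_cutoff > 0, theta_bins > 0,
            min_prominence >= 0)
  structure(list(length_cutoff = length_cutoff,
                 cell_count_cutoff = cell_count_cutoff,
                 theta_bins = as.integer(theta_bins),
                 min_prominence = min_prominence),
            class = "uj_class_params")
}

#' Polar boundary profile of a segmented spheroid
#'
#' Converts the exterior contour to polar coordinates (theta, r). Radii are
#' measured from the center of the largest inscribed disk (the maximum of
#' the mask's distance transform), not the area centroid: long protrusions
#' drag the area centroid toward themselves, which would depress their
#' measured length and create phantom peaks on the opposite side. Each
#' angular bin records the outermost contour point falling in the bin, so
#' overhanging protrusions are measured at full extent; empty bins are
#' filled by circular linear interpolation from their neighbours.
#'
#' @param seg a [segment_spheroid()] result.
#' @param theta_bins number of uniform bins over `[0, 2*pi)`.
#' @return Object of class `uj_polar_profile`: `theta` (bin centers,
#'   radians), `r` (micrometers), `r_mean`, `center` (0-based row/col).
#' @export
polar_profile <- function(seg, theta_bins = 360) {
  stopifnot(inherits(seg, "uj_segmentation"))
  if (is.null(seg$contour) || nrow(seg$contour) < 3 || seg$area_px <= 0)
    uj_stop("DegenerateContour", "contour encloses no area")
  edt <- distance_transform(!seg$mask)
  deep <- edt >= max(edt) - 0.5
  center <- c(mean(row(seg$mask)[deep]) - 1, mean(col(seg$mask)[deep]) - 1)
  dr <- seg$contour[, "row"] - center[1]
  dc <- seg$contour[, "col"] - center[2]
  # angle measured from +col axis, counterclockwise with +row pointing down
  ang <- atan2(dr, dc) %% (2 * pi)
  rad <- sqrt(dr^2 + dc^2) * seg$pixel_size
  bin <- floor(ang / (2 * pi) * theta_bins) + 1L
  bin[bin > theta_bins] <- theta_bins
  r <- rep(NA_real_, theta_bins)
  mx <- tapply(rad, bin, max)
  r[as.integer(names(mx))] <- mx
  if (anyNA(r)) {
    if (all(is.na(r))) uj_stop("DegenerateContour", "no boundary points binned")
    # circular linear interpolation across empty bins
    idx <- which(!is.na(r))
    n <- theta_bins
    xi <- c(idx - n, idx, idx + n)
    yi <- rep(r[idx], 3)
    r[is.na(r)] <- approx(xi, yi, xout = which(is.na(r)))$y
  }
  theta <- (seq_len(theta_bins) - 0.5) * 2 * pi / theta_bins
  structure(list(theta = theta, r = r, r_mean = mean(r), center = center),
            class = "uj_polar_profile")
}

#' Detect protrusions as peaks of the polar profile
#'
#' Maximal contiguous angular runs with `r > r_mean` (circular, so a run may
#' wrap through theta = 0) each yield one protrusion of length
#' `max(r in run) - r_mean`. Runs with peak height below `min_prominence`
#' are discarded.
#'
#' @param profile a [polar_profile()].
#' @param params a [classification_params()].
#' @return data.frame with one row per protrusion: `theta_start`,
#'   `theta_end`, `peak_theta` (radians), `length` (micrometers). Zero rows
#'   when the boundary never exceeds the mean radius.
#' @export
detect_protrusions <- function(profile, params = classification_params()) {
  stopifnot(inherits(profile, "uj_polar_profile"))
  r <- profile$r; theta <- profile$theta
  n <- length(r)
  above <- r > profile$r_mean
  empty <- data.frame(theta_start = numeric(), theta_end = numeric(),
                      peak_theta = numeric(), length = numeric())
  if (!any(above)) return(empty)
  if (all(above)) {
    # pathological: everything above the mean is impossible unless flat
    return(empty)
  }
  # rotate so the sequence starts in a below-mean bin; runs then never wrap
  start <- which(!above)[1]
  ord <- c(seq(start, n), seq_len(start - 1))
  ab <- above[ord]
  rl <- rle(ab)
  ends <- cumsum(rl$lengths)
  begins <- c(1, head(ends, -1) + 1)
  out <- empty
  for (k in seq_along(rl$values)) {
    if (!rl$values[k]) next
    run <- ord[begins[k]:ends[k]]
    peak <- run[which.max(r[run])]
    len <- r[peak] - profile$r_mean
    if (len < params$min_prominence) next
    out <- rbind(out, data.frame(theta_start = theta[run[1]],
                                 theta_end = theta[run[length(run)]],
                                 peak_theta = theta[peak],
                                 length = len))
  }
  out
}

#' Net dissociated-cell count
#'
#' Cells already present at t = 0 are subtracted from the endpoint count;
#' the result is floored at zero.
#'
#' @param count_end dissociated-cell count at the assay endpoint.
#' @param count_t0 count at t = 0.
#' @return non-negative integer.
#' @export
net_dissociated_count <- function(count_end, count_t0) {
  stopifnot(count_end >= 0, count_t0 >= 0)
  max(as.integer(count_end) - as.integer(count_t0), 0L)
}

#' Classify the unjamming phase of a spheroid
#'
#' Gas-like when the net dissociated-cell count exceeds `cell_count_cutoff`
#' (this takes precedence in the single label); otherwise liquid-like when
#' the mean protrusion length exceeds `length_cutoff`; otherwise solid-like.
#' When both criteria are met the spheroid is labelled gas with
#' `coexistence = TRUE` (a liquid phase of long protrusions coexisting with
#' a gas phase of disseminated cells).
#'
#' @param mean_len mean protrusion length in micrometers.
#' @param net_count net dissociated-cell count.
#' @param params a [classification_params()].
#' @return list of class `uj_phase_call`: `label` (one of `"solid"`,
#'   `"liquid"`, `"gas"`), `mean_protrusion_length`, `net_cell_count`,
#'   `coexistence`.
#' @export
classify_phase <- function(mean_len, net_count, params = classification_params()) {
  stopifnot(mean_len >= 0, net_count >= 0)
  gas <- net_count > params$cell_count_cutoff
  liquid <- mean_len > params$length_cutoff
  label <- if (gas) "gas" else if (liquid) "liquid" else "solid"
  structure(list(label = label,
                 mean_protrusion_length = mean_len,
                 net_cell_count = as.integer(net_count),
                 coexistence = gas && liquid),
            class = "uj_phase_call")
}

#' Endpoint phase analysis of a tracked time-lapse
#'
#' Builds the polar profile of the final segmented frame, measures mean
#' protrusion length (average over detected protrusions), subtracts the
#' t = 0 dissociated-cell count from the endpoint count, and classifies the
#' unjamming phase.
#'
#' @param track a [track_timelapse()] result.
#' @param params a [classification_params()].
#' @return list: `phase` (a `uj_phase_call`), `protrusions` (data.frame),
#'   `profile` (the endpoint `uj_polar_profile`).
#' @export
phase_from_track <- function(track, params = classification_params()) {
  stopifnot(inherits(track, "uj_track"))
  ok <- which(!vapply(track, is.null, logical(1)))
  if (length(ok) == 0) uj_stop("AllFramesFailed", "no segmented frames")
  first <- track[[ok[1]]]
  last <- track[[ok[length(ok)]]]
  profile <- polar_profile(last$segmentation, params$theta_bins)
  prot <- detect_protrusions(profile, params)
  mean_len <- if (nrow(prot) == 0) 0 else mean(prot$length)
  net <- net_dissociated_count(last$cells$count, first$cells$count)
  list(phase = classify_phase(mean_len, net, params),
       protrusions = prot, profile = profile)
}
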