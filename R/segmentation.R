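# Bright-field spheroid segmentation.
#
# The detector follows the classic gradient-mask recipe used for
# low-contrast bright-field objects: derivative-of-Gaussian edge magnitude,
# threshold, dilate, fill holes, erode back (morphological closing), keep
# the largest component, then refine the boundary with a half-maximum
# intensity threshold estimated from the object core and the surrounding
# background. The refinement removes the systematic outward bias of the
# thresholded gradient band so that the effective circular radius is
# accurate to well under a pixel for smooth boundaries.

#' Construct a single image frame
#'
#' @param pixels numeric matrix of intensities (rows x cols), at least 64x64.
#' @param pixel_size physical pixel size in micrometers.
#' @param time acquisition time in hours since embedding.
#' @return An object of class `uj_frame`.
#' @export
bf_frame <- function(pixels, pixel_size, time = 0) {
  stopifnot(is.matrix(pixels), is.numeric(pixels))
  if (nrow(pixels) < 64 || ncol(pixels) < 64)
    uj_stop("InvalidFrame", "frame must be at least 64x64 pixels")
  if (!is.numeric(pixel_size) || pixel_size <= 0)
    uj_stop("InvalidFrame", "pixel_size must be > 0")
  if (time < 0) uj_stop("InvalidFrame", "time must be >= 0")
  structure(list(pixels = pixels, pixel_size = pixel_size, time = time),
            class = "uj_frame")
}

#' Construct a time-lapse of frames
#'
#' @param frames list of [bf_frame()] objects with strictly increasing times and
#'   a common pixel size.
#' @param interval nominal time between frames in hours.
#' @return An object of class `uj_timelapse`.
#' @export
timelapse <- function(frames, interval) {
  if (length(frames) == 0) uj_stop("InvalidTimeLapse", "no frames")
  times <- vapply(frames, function(f) f$time, numeric(1))
  if (length(times) > 1 && any(diff(times) <= 0))
    uj_stop("InvalidTimeLapse", "frame times must be strictly increasing")
  px <- vapply(frames, function(f) f$pixel_size, numeric(1))
  if (length(unique(px)) != 1)
    uj_stop("InvalidTimeLapse", "pixel_size must be constant across frames")
  structure(list(frames = frames, interval = interval, times = times),
            class = "uj_timelapse")
}

#' Segmentation parameters
#'
#' @param gradient_sigma scale (pixels) of the derivative-of-Gaussian edge
#'   filter.
#' @param edge_threshold gradient-magnitude cutoff, or `"auto"` for Otsu's
#'   threshold on the gradient image. Bright-field contrast varies between
#'   image sets, so the automatic value can be overridden per dataset.
#' @param dilation_radius radius (pixels) of the dilation used to close the
#'   gradient mask before hole filling; also the exclusion margin around the
#'   spheroid when counting dissociated cells.
#' @param min_spheroid_area smallest component area (pixels^2) accepted as a
#'   spheroid body.
#' @param cell_area_range numeric length-2, area range (pixels^2) accepted as
#'   a single dissociated cell.
#' @param border_margin distance (pixels) from the image border below which a
#'   spheroid is flagged as wall-contacting.
#' @param sharpen_amount optional unsharp-mask strength applied before edge
#'   detection (0 disables; the acquisition-side sharpening some pipelines
#'   apply is not needed for synthetic data).
#' @return A list of class `uj_seg_params`.
#' @export
seg_params <- function(gradient_sigma = 2,
                       edge_threshold = "auto",
                       dilation_radius = 5,
                       min_spheroid_area = 2000,
                       cell_area_range = c(10, 500),
                       border_margin = 10,
                       sharpen_amount = 0) {
  stopifnot(gradient_sigma > 0, dilation_radius > 0, min_spheroid_area > 0,
            length(cell_area_range) == 2, all(cell_area_range > 0),
            cell_area_range[1] < cell_area_range[2], border_margin > 0)
  if (cell_area_range[1] >= min_spheroid_area)
    uj_stop("InvalidParams", "cell_area_range minimum must be < min_spheroid_area")
  if (!identical(edge_threshold, "auto") &&
      (!is.numeric(edge_threshold) || edge_threshold <= 0))
    uj_stop("InvalidParams", "edge_threshold must be 'auto' or a positive number")
  structure(list(gradient_sigma = gradient_sigma,
                 edge_threshold = edge_threshold,
                 dilation_radius = dilation_radius,
                 min_spheroid_area = min_spheroid_area,
                 cell_area_range = cell_area_range,
                 border_margin = border_margin,
                 sharpen_amount = sharpen_amount),
            class = "uj_seg_params")
}

# Gradient-mask closing shared by the spheroid and cell detectors.
closed_gradient_mask <- function(img, params) {
  if (params$sharpen_amount > 0)
    img <- img + params$sharpen_amount * (img - img_gaussian(img, params$gradient_sigma))
  g <- img_gradmag(img, params$gradient_sigma)
  thr <- if (identical(params$edge_threshold, "auto")) {
    otsu_threshold(g)
  } else {
    params$edge_threshold
  }
  edges <- g > thr
  if (!any(edges)) return(edges)
  binary_erode(fill_holes(binary_dilate(edges, params$dilation_radius)),
               params$dilation_radius)
}

# Sub-pixel-ish exterior contour: midpoints of exposed 4-neighbour pixel
# faces, ordered by angle around the centroid (adequate for the star-shaped
# masks this assay produces). Coordinates are 0-based (row, col).
trace_contour <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  pts <- list()
  shift <- function(dr, dc) {
    ridx <- pmin(pmax(seq_len(nr) + dr, 1L), nr)
    cidx <- pmin(pmax(seq_len(nc) + dc, 1L), nc)
    out <- mask[ridx, cidx]
    # pixels at the image border are exposed
    if (dr == -1) out[1, ] <- FALSE
    if (dr ==  1) out[nr, ] <- FALSE
    if (dc == -1) out[, 1] <- FALSE
    if (dc ==  1) out[, nc] <- FALSE
    out
  }
  for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
    exposed <- mask & !shift(d[1], d[2])
    if (any(exposed)) {
      r <- row(mask)[exposed] - 1 + d[1] * 0.5
      c <- col(mask)[exposed] - 1 + d[2] * 0.5
      pts[[length(pts) + 1]] <- cbind(r, c)
    }
  }
  pts <- do.call(rbind, pts)
  ctr <- c(mean(row(mask)[mask]) - 1, mean(col(mask)[mask]) - 1)
  ang <- atan2(pts[, 1] - ctr[1], pts[, 2] - ctr[2])
  pts <- pts[order(ang), , drop = FALSE]
  colnames(pts) <- c("row", "col")
  pts
}

#' Segment the spheroid body in one bright-field frame
#'
#' Detects the single dominant dark object: edge magnitude from a
#' derivative-of-Gaussian filter is thresholded (Otsu by default), the
#' binary gradient mask is dilated, hole-filled and eroded back, the
#' largest sufficiently large component is kept and its boundary is refined
#' with a half-maximum intensity threshold so the reported effective
#' circular radius is unbiased.
#'
#' @param fr a [bf_frame()].
#' @param params a [seg_params()].
#' @return An object of class `uj_segmentation` with elements `mask`
#'   (logical matrix), `contour` (n x 2 matrix, 0-based row/col pixels),
#'   `centroid` (0-based row/col), `area` (um^2), `r_eff` (um, equal to
#'   `sqrt(area/pi)`), `area_px`, `pixel_size`, `time` and `border_flag`.
#'   A `BorderContact` warning (with the flag set) is raised when the mask
#'   comes within `border_margin` pixels of the image border.
#' @export
segment_spheroid <- function(fr, params = seg_params()) {
  stopifnot(inherits(fr, "uj_frame"), inherits(params, "uj_seg_params"))
  img <- fr$pixels
  closed <- closed_gradient_mask(img, params)
  if (!any(closed))
    uj_stop("NoObjectFound", "no edges detected in frame")
  lab <- label_components(closed, 8L)
  areas <- tabulate(lab[lab > 0])
  big <- which(areas >= params$min_spheroid_area)
  if (length(big) == 0)
    uj_stop("NoObjectFound",
            sprintf("largest component (%d px^2) below min_spheroid_area", max(areas)))
  body <- lab == big[which.max(areas[big])]

  # half-maximum intensity refinement
  smooth <- img_gaussian(img, params$gradient_sigma)
  core <- binary_erode(body, params$dilation_radius + params$gradient_sigma)
  if (!any(core)) core <- body
  far <- !binary_dilate(body, 3 * params$gradient_sigma)
  if (!any(far)) far <- !body
  mu_in <- mean(smooth[core]); mu_out <- mean(smooth[far])
  level <- (mu_in + mu_out) / 2
  # the closing erosion trims features thinner than ~2x dilation_radius
  # (protrusion tips); widening the refinement region by that radius lets
  # the intensity threshold recover them
  region <- binary_dilate(body, params$dilation_radius + 2 * params$gradient_sigma)
  refined <- if (mu_in < mu_out) smooth < level else smooth > level
  refined <- refined & region
  refined <- fill_holes(refined)
  lab2 <- label_components(refined, 8L)
  if (any(lab2 > 0)) {
    areas2 <- tabulate(lab2[lab2 > 0])
    refined <- lab2 == which.max(areas2)
  } else {
    refined <- body
  }

  area_px <- sum(refined)
  area <- area_px * fr$pixel_size^2
  ctr <- c(mean(row(refined)[refined]) - 1, mean(col(refined)[refined]) - 1)
  m <- params$border_margin
  edge_band <- matrix(FALSE, nrow(img), ncol(img))
  edge_band[c(seq_len(m), nrow(img) - seq_len(m) + 1L), ] <- TRUE
  edge_band[, c(seq_len(m), ncol(img) - seq_len(m) + 1L)] <- TRUE
  border_flag <- any(refined & edge_band)

  seg <- structure(list(
    mask = refined,
    contour = trace_contour(refined),
    centroid = ctr,
    area = area,
    r_eff = sqrt(area / pi),
    area_px = area_px,
    pixel_size = fr$pixel_size,
    time = fr$time,
    border_flag = border_flag,
    closed_mask = closed
  ), class = "uj_segmentation")
  if (border_flag)
    uj_warn("BorderContact", "spheroid mask touches the image border margin")
  seg
}

#' @export
print.uj_segmentation <- function(x, ...) {
  cat(sprintf("uj_segmentation: area %.0f um^2, r_eff %.2f um, centroid (%.1f, %.1f)%s\n",
              x$area, x$r_eff, x$centroid[1], x$centroid[2],
              if (x$border_flag) " [border contact]" else ""))
  invisible(x)
}

#' Detect dissociated single cells in a frame
#'
#' Connected components of the closed gradient mask whose area falls in
#' `cell_area_range` and that do not overlap the spheroid mask dilated by
#' `dilation_radius` are counted as dissociated cells. Components touching
#' the dilated spheroid are discarded: cells near the boundary cannot be
#' reliably called dissociated, so counts are conservative.
#'
#' @param fr the [bf_frame()] the segmentation came from.
#' @param spheroid the [segment_spheroid()] result for that frame.
#' @param params a [seg_params()].
#' @return An object of class `uj_cells`: `centroids` (n x 2 matrix, 0-based
#'   row/col) and `count`.
#' @export
detect_dissociated_cells <- function(fr, spheroid, params = seg_params()) {
  stopifnot(inherits(fr, "uj_frame"), inherits(spheroid, "uj_segmentation"))
  closed <- spheroid$closed_mask
  if (is.null(closed)) closed <- closed_gradient_mask(fr$pixels, params)
  keepout <- binary_dilate(spheroid$mask, params$dilation_radius)
  lab <- label_components(closed, 8L)
  n <- max(lab)
  centroids <- NULL
  if (n > 0) {
    areas <- tabulate(lab[lab > 0], nbins = n)
    touches <- unique(lab[keepout & lab > 0])
    ok <- setdiff(which(areas >= params$cell_area_range[1] &
                          areas <= params$cell_area_range[2]), touches)
    if (length(ok)) {
      sel <- lab %in% ok
      rows <- tapply(row(lab)[sel] - 1, lab[sel], mean)
      cols <- tapply(col(lab)[sel] - 1, lab[sel], mean)
      centroids <- cbind(row = as.numeric(rows), col = as.numeric(cols))
    }
  }
  if (is.null(centroids)) centroids <- matrix(numeric(0), 0, 2,
                                              dimnames = list(NULL, c("row", "col")))
  structure(list(centroids = centroids, count = nrow(centroids)),
            class = "uj_cells")
}

#' Segment every frame of a time-lapse
#'
#' Applies [segment_spheroid()] and [detect_dissociated_cells()] to each
#' frame with the same parameters. Frames where segmentation fails are
#' recorded as gaps (`NULL`), not errors.
#'
#' @param movie a [timelapse()].
#' @param params a [seg_params()].
#' @return A list of class `uj_track`, one element per frame, each either
#'   `NULL` (gap) or `list(segmentation =, cells =)`. Use
#'   [as.data.frame.uj_track()] for a tidy per-frame table.
#' @export
track_timelapse <- function(movie, params = seg_params()) {
  stopifnot(inherits(movie, "uj_timelapse"))
  out <- lapply(movie$frames, function(fr) {
    seg <- withCallingHandlers(
      tryCatch(segment_spheroid(fr, params), unjamr_error = function(e) NULL),
      BorderContact = function(w) invokeRestart("muffleWarning")
    )
    if (is.null(seg)) return(NULL)
    list(segmentation = seg, cells = detect_dissociated_cells(fr, seg, params))
  })
  if (all(vapply(out, is.null, logical(1))))
    uj_stop("AllFramesFailed", "no frame could be segmented")
  structure(out, class = "uj_track", times = movie$times)
}

#' Per-frame results table of a tracked time-lapse
#'
#' @param x a `uj_track` from [track_timelapse()].
#' @param ... unused.
#' @return data.frame with one row per frame: `frame_index`, `time_hrs`,
#'   `area_um2`, `r_eff_um`, `centroid_row`, `centroid_col`, `n_cells`,
#'   `border_flag`; gap frames carry `NA`s.
#' @export
as.data.frame.uj_track <- function(x, ...) {
  times <- attr(x, "times")
  rows <- lapply(seq_along(x), function(i) {
    e <- x[[i]]
    if (is.null(e)) {
      data.frame(frame_index = i, time_hrs = times[i], area_um2 = NA_real_,
                 r_eff_um = NA_real_, centroid_row = NA_real_,
                 centroid_col = NA_real_, n_cells = NA_integer_,
                 border_flag = NA)
    } else {
      s <- e$segmentation
      data.frame(frame_index = i, time_hrs = times[i], area_um2 = s$area,
                 r_eff_um = s$r_eff, centroid_row = s$centroid[1],
                 centroid_col = s$centroid[2], n_cells = e$cells$count,
                 border_flag = s$border_flag)
    }
  })
  do.call(rbind, rows)
}
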