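#' @useDynLib unjamr, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats approx coef dnorm lm median qt rnorm rpois runif sd
#' @importFrom utils head tail write.csv
NULL

# ---- low-level image utilities (internal) -----------------------------------
# Images are plain numeric matrices indexed (row, col), 0-based coordinates
# only at reporting boundaries; intensities are arbitrary (usually [0, 1]).

gaussian_kernel_1d <- function(sigma, derivative = FALSE) {
  radius <- max(1L, ceiling(3 * sigma))
  x <- seq(-radius, radius)
  g <- exp(-x^2 / (2 * sigma^2))
  g <- g / sum(g)
  if (derivative) {
    k <- -x / sigma^2 * g
    # enforce exact zero response to constants
    k - mean(k)
  } else {
    g
  }
}

# Separable convolution with replicate padding, same-size output.
convolve_sep <- function(img, krow, kcol = krow) {
  img <- conv_1d(img, krow, along = "row")
  conv_1d(img, kcol, along = "col")
}

conv_1d <- function(img, kernel, along = c("row", "col")) {
  along <- match.arg(along)
  radius <- (length(kernel) - 1L) / 2L
  n <- if (along == "row") nrow(img) else ncol(img)
  out <- matrix(0, nrow(img), ncol(img))
  for (j in seq_along(kernel)) {
    off <- j - 1L - radius
    idx <- pmin(pmax(seq_len(n) + off, 1L), n)  # replicate edges
    shifted <- if (along == "row") img[idx, , drop = FALSE] else img[, idx, drop = FALSE]
    out <- out + kernel[j] * shifted
  }
  out
}

img_gaussian <- function(img, sigma) {
  if (sigma <= 0) return(img)
  k <- gaussian_kernel_1d(sigma)
  convolve_sep(img, k)
}

# Gradient magnitude via derivative-of-Gaussian filters.
img_gradmag <- function(img, sigma) {
  g <- gaussian_kernel_1d(sigma)
  dg <- gaussian_kernel_1d(sigma, derivative = TRUE)
  gy <- conv_1d(conv_1d(img, dg, "row"), g, "col")
  gx <- conv_1d(conv_1d(img, g, "row"), dg, "col")
  sqrt(gx^2 + gy^2)
}

# Otsu's threshold on a numeric vector (maximizes between-class variance).
otsu_threshold <- function(x, n_bins = 256L) {
  x <- x[is.finite(x)]
  rng <- range(x)
  if (diff(rng) == 0) return(rng[1])
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  h <- tabulate(findInterval(x, breaks, all.inside = TRUE), nbins = n_bins)
  p <- h / sum(h)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  sigma_b <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  sigma_b[!is.finite(sigma_b)] <- 0
  mids[which.max(sigma_b)]
}

label_components <- function(mask, connectivity = 8L) {
  storage.mode(mask) <- "logical"
  cpp_label(mask, as.integer(connectivity))
}

distance_transform <- function(sites) {
  storage.mode(sites) <- "logical"
  cpp_edt(sites)
}

binary_dilate <- function(mask, radius) {
  if (radius <= 0) return(mask)
  distance_transform(mask) <= radius
}

binary_erode <- function(mask, radius) {
  if (radius <= 0) return(mask)
  distance_transform(!mask) > radius
}

# Fill holes: background components (4-connected) not touching the border
# become foreground.
fill_holes <- function(mask) {
  lab <- label_components(!mask, connectivity = 4L)
  border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  border <- border[border > 0]
  hole <- lab > 0 & !(lab %in% border)
  mask | hole
}

# Box mean filter via integral image; window is (2r+1)^2 clipped at edges.
mean_filter <- function(img, radius) {
  nr <- nrow(img); nc <- ncol(img)
  ii <- rbind(0, apply(img, 2, cumsum))
  ii <- cbind(0, t(apply(ii, 1, cumsum)))
  r1 <- pmax(seq_len(nr) - radius, 1L); r2 <- pmin(seq_len(nr) + radius, nr)
  c1 <- pmax(seq_len(nc) - radius, 1L); c2 <- pmin(seq_len(nc) + radius, nc)
  sums <- ii[r2 + 1L, c2 + 1L] - ii[r1, c2 + 1L] - ii[r2 + 1L, c1] + ii[r1, c1]
  counts <- outer(r2 - r1 + 1L, c2 - c1 + 1L)
  sums / counts
}

# Local maxima of a numeric matrix: pixels >= all 8 neighbours (plateaus
# merged to their centroid), then a greedy minimum-separation filter keeping
# the larger value. Returns a data.frame(row, col, value).
local_maxima <- function(img, min_separation = 0, mask = NULL) {
  nr <- nrow(img); nc <- ncol(img)
  is_max <- matrix(TRUE, nr, nc)
  shifts <- expand.grid(dr = -1:1, dc = -1:1)
  shifts <- shifts[!(shifts$dr == 0 & shifts$dc == 0), ]
  for (k in seq_len(nrow(shifts))) {
    ridx <- pmin(pmax(seq_len(nr) + shifts$dr[k], 1L), nr)
    cidx <- pmin(pmax(seq_len(nc) + shifts$dc[k], 1L), nc)
    is_max <- is_max & (img >= img[ridx, cidx])
  }
  if (!is.null(mask)) is_max <- is_max & mask
  if (!any(is_max)) return(data.frame(row = integer(), col = integer(), value = numeric()))
  # merge plateaus (connected runs of equal-valued maxima) at their centroid
  lab <- label_components(is_max, connectivity = 8L)
  ks <- sort(unique(lab[lab > 0]))
  rows <- row(img)[is_max]; cols <- col(img)[is_max]; labs <- lab[is_max]
  vals <- img[is_max]
  peaks <- data.frame(
    row = round(tapply(rows, labs, mean)),
    col = round(tapply(cols, labs, mean)),
    value = as.numeric(tapply(vals, labs, max))
  )
  peaks <- peaks[order(-peaks$value), , drop = FALSE]
  if (min_separation > 0 && nrow(peaks) > 1) {
    keep <- rep(TRUE, nrow(peaks))
    for (i in seq_len(nrow(peaks))[-1]) {
      d <- sqrt((peaks$row[seq_len(i - 1)][keep[seq_len(i - 1)]] - peaks$row[i])^2 +
                  (peaks$col[seq_len(i - 1)][keep[seq_len(i - 1)]] - peaks$col[i])^2)
      if (length(d) && any(d < min_separation)) keep[i] <- FALSE
    }
    peaks <- peaks[keep, , drop = FALSE]
  }
  rownames(peaks) <- NULL
  peaks
}

# ---- classed conditions -----------------------------------------------------

uj_stop <- function(class, message, data = list(), call. = NULL) {
  cond <- structure(
    class = c(class, "unjamr_error", "error", "condition"),
    c(list(message = message, call = call.), list(data = data))
  )
  stop(cond)
}

uj_warn <- function(class, message, data = list()) {
  cond <- structure(
    class = c(class, "unjamr_warning", "warning", "condition"),
    c(list(message = message, call = NULL), list(data = data))
  )
  warning(cond)
}
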