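# Fixtures are rendered in code; oracles are deliberately naive pure-R
# implementations, independent of the package's compiled paths.

# Soft-edged dark disk on bright background, optionally with extra dark
# blobs (cells) given as data.frame(row, col, r) in pixel coordinates.
make_disk_frame <- function(R, size = 2 * R + 80, noise_sd = 0,
                            px = 1, center = NULL, blobs = NULL,
                            offset = 0, time = 0) {
  if (is.null(center)) center <- c((size + 1) / 2, (size + 1) / 2)
  rows <- matrix(seq_len(size), size, size)
  cols <- matrix(seq_len(size), size, size, byrow = TRUE)
  d <- sqrt((rows - center[1])^2 + (cols - center[2])^2)
  img <- 0.85 - 0.7 * stats::plogis((R - d) / 0.8)
  if (!is.null(blobs)) {
    for (k in seq_len(nrow(blobs))) {
      db <- sqrt((rows - blobs$row[k])^2 + (cols - blobs$col[k])^2)
      img <- img - 0.7 * stats::plogis((blobs$r[k] - db) / 0.6) *
        (1 - stats::plogis((R - d) / 0.8))
    }
  }
  if (noise_sd > 0) img <- img + rnorm(length(img), 0, noise_sd)
  bf_frame(img + offset, px, time)
}

# Ellipse with semi-axes (a, b) in pixels (a along rows).
make_ellipse_frame <- function(a, b, size = 2 * max(a, b) + 80, px = 1) {
  ctr <- (size + 1) / 2
  rows <- matrix(seq_len(size), size, size) - ctr
  cols <- matrix(seq_len(size), size, size, byrow = TRUE) - ctr
  u <- sqrt((rows / a)^2 + (cols / b)^2)
  img <- 0.85 - 0.7 * stats::plogis((1 - u) * min(a, b) / 0.8)
  bf_frame(img, px, 0)
}

# Brute-force 4/8-connected component labeling by repeated flood fill
# using only base R (the oracle for cpp_label).
oracle_label <- function(mask, connectivity = 8) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nb <- if (connectivity == 8) {
    cbind(c(-1, 1, 0, 0, -1, -1, 1, 1), c(0, 0, -1, 1, -1, 1, -1, 1))
  } else cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  cur <- 0L
  for (c0 in seq_len(nc)) for (r0 in seq_len(nr)) {
    if (!mask[r0, c0] || lab[r0, c0] != 0L) next
    cur <- cur + 1L
    queue <- list(c(r0, c0)); lab[r0, c0] <- cur
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (k in seq_len(nrow(nb))) {
        r <- p[1] + nb[k, 1]; c <- p[2] + nb[k, 2]
        if (r < 1 || r > nr || c < 1 || c > nc) next
        if (mask[r, c] && lab[r, c] == 0L) {
          lab[r, c] <- cur
          queue[[length(queue) + 1]] <- c(r, c)
        }
      }
    }
  }
  lab
}

# O(n^2) brute-force Euclidean distance to the nearest TRUE pixel.
oracle_edt <- function(sites) {
  nr <- nrow(sites); nc <- ncol(sites)
  pr <- row(sites)[sites]; pc <- col(sites)[sites]
  out <- matrix(Inf, nr, nc)
  if (length(pr) == 0) return(out)
  for (c in seq_len(nc)) for (r in seq_len(nr)) {
    out[r, c] <- sqrt(min((pr - r)^2 + (pc - c)^2))
  }
  out
}

# Brute-force scan for maximal circular runs with r > mean(r); returns peak
# heights (the oracle for detect_protrusions, ignoring prominence).
oracle_runs <- function(r) {
  n <- length(r); m <- mean(r)
  above <- r > m
  if (!any(above) || all(above)) return(numeric(0))
  start <- which(!above)[1]
  ord <- c(seq(start, n), seq_len(start - 1))
  lens <- numeric(0)
  in_run <- FALSE; best <- -Inf
  for (i in ord) {
    if (above[i]) {
      in_run <- TRUE
      best <- max(best, r[i])
    } else if (in_run) {
      lens <- c(lens, best - m)
      in_run <- FALSE; best <- -Inf
    }
  }
  if (in_run) lens <- c(lens, best - m)
  lens
}

# Run-length oracle for the saturation rule: earliest low-run start after
# deleting short high runs; final time if none qualifies.
oracle_saturation <- function(times, r, thr, run) {
  dt <- diff(times)
  rate <- diff(r) / (r[-length(r)] * dt)
  high <- rate >= thr
  # delete high runs shorter than `run`
  i <- 1
  while (i <= length(high)) {
    if (high[i]) {
      j <- i
      while (j < length(high) && high[j + 1]) j <- j + 1
      if (sum(dt[i:j]) < run) high[i:j] <- FALSE
      i <- j + 1
    } else i <- i + 1
  }
  i <- 1
  while (i <= length(high)) {
    if (!high[i]) {
      j <- i
      while (j < length(high) && !high[j + 1]) j <- j + 1
      if (sum(dt[i:j]) >= run) return(times[i])
      i <- j + 1
    } else i <- i + 1
  }
  times[length(times)]
}

# Build a polar profile object directly (for analytic protrusion cases).
make_profile <- function(r) {
  n <- length(r)
  structure(list(theta = (seq_len(n) - 0.5) * 2 * pi / n, r = r,
                 r_mean = mean(r)),
            class = "uj_polar_profile")
}

# A valid 24-condition table (2 cell lines x 4 matrices x 3 treatments)
# where onset decreases with pore size and dense matrices stay solid.
make_condition_table <- function() {
  grid <- expand.grid(
    cell_line = c("MV3", "A549"),
    matrix_id = c("collagen-2.4", "collagen-8", "gelma-30", "gelma-50"),
    treatment = c("control", "tgfb", "mmpi"),
    stringsAsFactors = FALSE
  )
  pore <- c("collagen-2.4" = 8, "collagen-8" = 4, "gelma-30" = 0.0015,
            "gelma-50" = 0.0011)
  grid$pore_size <- pore[grid$matrix_id]
  grid$concentration_mg_ml <- as.numeric(sub(".*-", "", grid$matrix_id))
  grid$matrix <- sub("-.*", "", grid$matrix_id)
  base_mmp1 <- ifelse(grid$cell_line == "MV3", 1.0, 0.3)
  tr_fac <- c(control = 1, tgfb = 1.8, mmpi = 0.5)
  grid$mmp1 <- base_mmp1 * tr_fac[grid$treatment] +
    seq_len(nrow(grid)) * 1e-4  # break ties deterministically
  grid$mmp2 <- grid$mmp1 * 0.7
  grid$vim <- ifelse(grid$cell_line == "MV3", 1.2, 0.4)
  grid$ecad <- ifelse(grid$cell_line == "MV3", 0.1, 1.0)
  # onset longer in smaller pores; no invasion in the densest gel
  grid$t_ons_hrs <- ifelse(grid$matrix_id == "gelma-50", NA,
                           3 + 20 * (1 - grid$pore_size / 8))
  grid$alpha <- ifelse(is.na(grid$t_ons_hrs), NA, 0.1 + 0.2 * grid$mmp1 / 2)
  grid$phase_label <- ifelse(is.na(grid$t_ons_hrs), "solid",
                      ifelse(grid$mmp1 > 1.5, "gas",
                      ifelse(grid$mmp1 > 0.5, "liquid", "solid")))
  grid[c("cell_line", "matrix", "concentration_mg_ml", "treatment",
         "pore_size", "mmp1", "mmp2", "vim", "ecad", "t_ons_hrs",
         "alpha", "phase_label")]
}
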