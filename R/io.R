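# Plain-text image interchange (ASCII PGM, "P2") and CSV export. The
# analysis itself works on numeric matrices; PGM keeps fixtures and QC
# output human-readable and dependency-free.

#' Read an ASCII PGM (P2) image
#'
#' @param path file path.
#' @return numeric matrix scaled to `[0, 1]`.
#' @export
read_pgm <- function(path) {
  tok <- scan(path, what = character(), quiet = TRUE, comment.char = "#")
  if (tok[1] != "P2") uj_stop("InvalidFormat", "not an ASCII PGM (P2) file")
  nc <- as.integer(tok[2]); nr <- as.integer(tok[3])
  maxval <- as.numeric(tok[4])
  vals <- as.numeric(tok[-(1:4)])
  if (length(vals) != nr * nc) uj_stop("InvalidFormat", "pixel count mismatch")
  matrix(vals, nr, nc, byrow = TRUE) / maxval
}

#' Write an ASCII PGM (P2) image
#'
#' @param img numeric matrix; rescaled to 0..`maxval`.
#' @param path file path.
#' @param maxval maximum gray value.
#' @return invisibly, `path`.
#' @export
write_pgm <- function(img, path, maxval = 255L) {
  rng <- range(img)
  z <- if (diff(rng) == 0) matrix(0L, nrow(img), ncol(img))
       else round((img - rng[1]) / diff(rng) * maxval)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(img), nrow(img)), as.character(maxval)), con)
  write(t(z), con, ncolumns = ncol(img))
  invisible(path)
}

#' Write the per-frame tracking table to CSV
#'
#' @param track a [track_timelapse()] result.
#' @param path output file.
#' @return invisibly, the data.frame written.
#' @export
write_track_csv <- function(track, path) {
  df <- as.data.frame(track)
  write.csv(df, path, row.names = FALSE)
  invisible(df)
}
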