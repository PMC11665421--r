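# Condition-level assembly: heatmaps of onset time / expansion rate against
# pore size and EMT-marker level, and the unjamming phase-diagram grid.
# Marker levels (GAPDH-normalized Western-blot densitometry) are inputs,
# not computed here.

MARKERS <- c("mmp1", "mmp2", "vim", "ecad")

#' Build and validate a condition table
#'
#' One row per experimental condition. Checks key uniqueness and internal
#' consistency: an expansion rate without a defined onset is contradictory
#' (the fit window starts at the onset).
#'
#' @param records data.frame with columns `cell_line`, `matrix`,
#'   `concentration_mg_ml`, `treatment`, `pore_size` (micrometers or other
#'   consistent unit), marker columns `mmp1`, `mmp2`, `vim`, `ecad`
#'   (GAPDH-normalized, dimensionless), `t_ons_hrs` (`NA` = no invasion),
#'   `alpha`, `phase_label` (`"solid"`, `"liquid"` or `"gas"`).
#' @return the validated data.frame, class `uj_condition_table`.
#' @export
build_condition_table <- function(records) {
  stopifnot(is.data.frame(records))
  needed <- c("cell_line", "matrix", "concentration_mg_ml", "treatment",
              "pore_size", MARKERS, "t_ons_hrs", "alpha", "phase_label")
  missing <- setdiff(needed, names(records))
  if (length(missing))
    uj_stop("InvalidRecord", paste("missing columns:", paste(missing, collapse = ", ")))
  key <- paste(records$cell_line, records$matrix,
               records$concentration_mg_ml, records$treatment, sep = "|")
  if (anyDuplicated(key))
    uj_stop("DuplicateCondition",
            paste("duplicated condition:", key[duplicated(key)][1]))
  if (any(records$pore_size <= 0, na.rm = TRUE))
    uj_stop("InvalidRecord", "pore_size must be > 0")
  for (m in MARKERS)
    if (any(records[[m]] < 0, na.rm = TRUE))
      uj_stop("InvalidRecord", paste(m, "levels must be >= 0"))
  bad <- !is.na(records$alpha) & is.na(records$t_ons_hrs)
  if (any(bad))
    uj_stop("InconsistentRecord",
            "expansion rate present without a defined onset time")
  if (!all(records$phase_label %in% c("solid", "liquid", "gas", NA)))
    uj_stop("InvalidRecord", "phase_label must be solid/liquid/gas")
  structure(records, class = c("uj_condition_table", "data.frame"))
}

rank_conditions <- function(table, x_marker) {
  # deterministic, permutation-invariant ranking: marker level (or pore
  # size), remaining ties broken by the full condition key
  ord_x <- order(table[[x_marker]], table$cell_line, table$treatment,
                 table$matrix, table$concentration_mg_ml)
  ord_y <- order(table$pore_size, table$matrix, table$concentration_mg_ml,
                 table$cell_line, table$treatment)
  list(x = ord_x, y = ord_y)
}

#' Heatmap grid of an invasion metric
#'
#' Ranks conditions along x by the chosen EMT-marker level and along y by
#' hydrogel pore size and fills a grid with the chosen metric. Conditions
#' whose onset is undefined (no invasion within the assay window) become
#' distinguished no-invasion cells carrying no numeric value.
#'
#' @param table a [build_condition_table()].
#' @param metric `"onset"` (hours) or `"rate"` (the power-law exponent).
#' @param x_marker one of `"mmp1"`, `"mmp2"`, `"vim"`, `"ecad"`.
#' @return list of class `uj_heatmap`: `values` (matrix, rows = conditions
#'   sorted by pore size, cols sorted by marker level; each input condition
#'   occupies exactly one diagonal-free cell keyed by its x and y rank),
#'   `no_invasion` (logical matrix), `x_levels`, `y_levels`, `metric`.
#' @export
heatmap_grid <- function(table, metric = c("onset", "rate"),
                         x_marker = c("mmp1", "mmp2", "vim", "ecad")) {
  stopifnot(inherits(table, "uj_condition_table"))
  metric <- match.arg(metric)
  if (!x_marker[1] %in% MARKERS) uj_stop("UnknownMarker", paste("unknown marker:", x_marker[1]))
  x_marker <- match.arg(x_marker)
  n <- nrow(table)
  rk <- rank_conditions(table, x_marker)
  xi <- match(seq_len(n), rk$x)  # column index per record
  yi <- match(seq_len(n), rk$y)  # row index per record
  vals <- matrix(NA_real_, n, n)
  noinv <- matrix(FALSE, n, n)
  occupied <- matrix(FALSE, n, n)
  v <- if (metric == "onset") table$t_ons_hrs else table$alpha
  for (i in seq_len(n)) {
    occupied[yi[i], xi[i]] <- TRUE
    if (is.na(table$t_ons_hrs[i])) noinv[yi[i], xi[i]] <- TRUE
    else vals[yi[i], xi[i]] <- v[i]
  }
  structure(list(values = vals, no_invasion = noinv, occupied = occupied,
                 x_levels = table[[x_marker]][rk$x],
                 y_levels = table$pore_size[rk$y],
                 x_marker = x_marker, metric = metric,
                 record_index = cbind(row = yi, col = xi)),
            class = "uj_heatmap")
}

#' Unjamming phase-diagram grid
#'
#' Orders conditions by pore size (y) and marker level (x, MMP1 by default)
#' and places each condition's phase label in its cell.
#'
#' @param table a [build_condition_table()]; every record must carry a
#'   phase label.
#' @param x_marker marker used for the x ranking (default `"mmp1"`).
#' @return list of class `uj_phase_diagram`: `labels` (character matrix
#'   with `NA` in unoccupied cells), `x_levels`, `y_levels`,
#'   `record_index`.
#' @export
phase_diagram_grid <- function(table, x_marker = "mmp1") {
  stopifnot(inherits(table, "uj_condition_table"))
  if (!x_marker %in% MARKERS) uj_stop("UnknownMarker", paste("unknown marker:", x_marker))
  if (any(is.na(table$phase_label)))
    uj_stop("MissingPhase", "every record needs a phase label")
  n <- nrow(table)
  rk <- rank_conditions(table, x_marker)
  xi <- match(seq_len(n), rk$x)
  yi <- match(seq_len(n), rk$y)
  labels <- matrix(NA_character_, n, n)
  for (i in seq_len(n)) labels[yi[i], xi[i]] <- table$phase_label[i]
  structure(list(labels = labels,
                 x_levels = table[[x_marker]][rk$x],
                 y_levels = table$pore_size[rk$y],
                 x_marker = x_marker,
                 record_index = cbind(row = yi, col = xi)),
            class = "uj_phase_diagram")
}

#' Render a heatmap or phase diagram
#'
#' Simple base-graphics rendering for QC; no-invasion cells are drawn black,
#' numeric cells on a linear scale between the observed minimum and maximum.
#'
#' @param x a `uj_heatmap` or `uj_phase_diagram`.
#' @param ... passed to [graphics::image()].
#' @return invisibly, the matrix that was drawn.
#' @export
plot.uj_heatmap <- function(x, ...) {
  v <- x$values
  rng <- range(v, na.rm = TRUE)
  z <- (v - rng[1]) / max(diff(rng), .Machine$double.eps)
  z[x$no_invasion] <- NA
  graphics::image(t(z[nrow(z):1, , drop = FALSE]),
                  col = grDevices::hcl.colors(64, "viridis"),
                  axes = FALSE, ...)
  invisible(z)
}

#' @rdname plot.uj_heatmap
#' @export
plot.uj_phase_diagram <- function(x, ...) {
  lv <- c(solid = 1, liquid = 2, gas = 3)
  z <- matrix(lv[x$labels], nrow(x$labels))
  graphics::image(t(z[nrow(z):1, , drop = FALSE]),
                  col = c("#3B6FB6", "#C73B3B", "#E8C12E"),
                  zlim = c(1, 3), axes = FALSE, ...)
  invisible(z)
}
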