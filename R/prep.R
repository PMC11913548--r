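#' Deduplicate presences to the modeling grid
#'
#' Rasterizes presence points to the modeling resolution so at most one
#' presence occupies each cell; retained points are snapped to their cell
#' centers. Reduces the spatial aggregation typical of opportunistic
#' occurrence records.
#'
#' @param points Tibble with `x`, `y` (projected meters, grid CRS).
#' @param grid The modeling `gs_grid`.
#' @return Tibble of cell-center points, one per occupied cell; empty input
#'   gives an empty output.
#' @export
dedup_to_grid <- function(points, grid) {
  if (nrow(points) == 0) return(tibble::tibble(x = numeric(0), y = numeric(0)))
  rc <- cells_from_xy(grid, points$x, points$y)
  keep <- !is.na(rc$cell) & !duplicated(rc$cell)
  ctr <- xy_from_cells(grid, rc$row[keep], rc$col[keep])
  tibble::tibble(x = ctr$x, y = ctr$y)
}

#' Spatially thin presences on a coarse stratification grid
#'
#' Within every cell of a uniform coarse grid (default 1000 m), at most
#' `max_per_cell` points are retained; when a cell holds more, the retained
#' subset is drawn uniformly without replacement. Run after
#' [dedup_to_grid()].
#'
#' @param points Deduplicated presence tibble (`x`, `y`).
#' @param coarse_cell_m Coarse grid resolution (m).
#' @param max_per_cell Maximum points kept per coarse cell.
#' @param seed Integer seed for the random subsets.
#' @param origin_x,origin_y Origin of the coarse grid; defaults to the
#'   point-cloud's north-west bounding corner so thinning is
#'   self-contained.
#' @return A `gs_thinning` list: `points` (retained tibble), `n_before`,
#'   `n_after`, `seed`, `coarse_cell_m`, `max_per_cell`.
#' @export
thin_stratified <- function(points, coarse_cell_m = 1000, max_per_cell = 4,
                            seed = 1, origin_x = NULL, origin_y = NULL) {
  n_before <- nrow(points)
  if (n_before == 0) {
    return(structure(list(points = points, n_before = 0L, n_after = 0L,
                          seed = seed, coarse_cell_m = coarse_cell_m,
                          max_per_cell = max_per_cell),
                     class = "gs_thinning"))
  }
  ox <- origin_x %||% min(points$x)
  oy <- origin_y %||% max(points$y)
  set.seed(seed)
  cell <- paste(floor((points$x - ox) / coarse_cell_m),
                floor((oy - points$y) / coarse_cell_m))
  keep <- unlist(lapply(split(seq_len(n_before), cell), function(idx) {
    if (length(idx) <= max_per_cell) idx else sample(idx, max_per_cell)
  }), use.names = FALSE)
  keep <- sort(keep)
  structure(list(points = points[keep, , drop = FALSE],
                 n_before = as.integer(n_before),
                 n_after = length(keep), seed = seed,
                 coarse_cell_m = coarse_cell_m,
                 max_per_cell = max_per_cell),
            class = "gs_thinning")
}

#' @export
print.gs_thinning <- function(x, ...) {
  cat(sprintf("<gs_thinning> %d -> %d points (max %d per %g m cell, seed %s)\n",
              x$n_before, x$n_after, x$max_per_cell, x$coarse_cell_m,
              format(x$seed)))
  invisible(x)
}

#' Build a sampling-effort bias raster by kernel density estimation
#'
#' A two-dimensional Gaussian KDE of the effort points (records of other
#' readily reported species, which proxy search effort) evaluated at every
#' cell center, with Scott's-rule bandwidth per axis, rescaled to (0, 1] by
#' its maximum. A strictly positive floor keeps every cell drawable as a
#' pseudo-absence stratum. Higher effort means a higher pseudo-absence
#' weight.
#'
#' @param effort_points Tibble with `x`, `y` (>= 1 row).
#' @param grid The modeling `gs_grid`.
#' @param bandwidth Optional numeric of length 1 or 2 (m) overriding
#'   Scott's rule.
#' @param floor_value Positive floor added before rescaling (default 1e-6).
#' @return A `gs_raster` named `"bias"` with values in (0, 1]; the
#'   bandwidth actually used is stored in `attr(, "bandwidth")`.
#' @export
build_bias_raster <- function(effort_points, grid, bandwidth = NULL,
                              floor_value = 1e-6) {
  n <- nrow(effort_points)
  if (n == 0) stop("at least one effort point is required", call. = FALSE)
  if (is.null(bandwidth)) {
    # Scott's rule per axis: sigma * n^(-1/6) for a 2-D KDE
    bw <- c(stats::sd(effort_points$x), stats::sd(effort_points$y)) * n^(-1 / 6)
    bw[!is.finite(bw) | bw <= 0] <- grid$cell_size  # degenerate spreads
  } else {
    bw <- rep(bandwidth, length.out = 2)
  }
  cc <- cell_centers(grid)
  dens <- numeric(nrow(cc))
  for (i in seq_len(n)) {
    dens <- dens + stats::dnorm(cc$x, effort_points$x[i], bw[1]) *
      stats::dnorm(cc$y, effort_points$y[i], bw[2])
  }
  dens <- dens / n + floor_value
  dens <- dens / max(dens)
  out <- raster_layer(grid, matrix(dens, grid$n_rows, grid$n_cols), "bias")
  attr(out, "bandwidth") <- bw
  out
}

#' One-call occurrence preparation
#'
#' Chains [dedup_to_grid()], [thin_stratified()] and [build_bias_raster()]
#' under one configuration.
#'
#' @param occurrences Raw occurrence tibble (`x`, `y`).
#' @param effort_points Effort tibble (`x`, `y`).
#' @param grid Modeling `gs_grid`.
#' @param config A `gs_config`.
#' @return List with `presences` (thinned tibble), `thinning`
#'   (`gs_thinning`), and `bias` (`gs_raster`).
#' @export
prep_occurrences <- function(occurrences, effort_points, grid,
                             config = pipeline_config()) {
  dedup <- dedup_to_grid(occurrences, grid)
  thin <- thin_stratified(dedup, coarse_cell_m = config$thinning_grid_size,
                          max_per_cell = config$thinning_max_per_cell,
                          seed = config$random_seed)
  bias <- build_bias_raster(effort_points, grid)
  list(presences = thin$points, thinning = thin, bias = bias)
}
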