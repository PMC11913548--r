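#' Define a raster analysis grid
#'
#' A grid is the georeferencing contract shared by every layer in an
#' analysis: all rasters, point assignments and polygon rasterizations refer
#' to the same lattice. Coordinates are projected meters. The origin is the
#' north-west (top-left) corner of the lattice; row 1 / column 1 is the
#' north-west cell and rows increase southwards. Cells are half-open: a point
#' lying exactly on a cell's eastern or southern edge belongs to the next
#' cell.
#'
#' @param origin_x,origin_y Projected coordinates (m) of the north-west
#'   corner of the grid.
#' @param cell_size Cell edge length in meters (> 0). The modeling default
#'   throughout the pipeline is 250 m.
#' @param n_rows,n_cols Lattice dimensions (>= 1).
#' @param crs Free-text tag for the projected CRS. All layers in one
#'   analysis must carry an identical tag; geographic (degree) inputs are
#'   rejected by the readers rather than silently reprojected.
#' @param nodata Sentinel value used on disk for missing cells.
#' @return An object of class `gs_grid`.
#' @export
raster_grid <- function(origin_x, origin_y, cell_size, n_rows, n_cols,
                        crs = "local-meters", nodata = -9999) {
  stopifnot(is.numeric(cell_size), cell_size > 0,
            n_rows >= 1, n_cols >= 1)
  structure(
    list(origin_x = as.numeric(origin_x), origin_y = as.numeric(origin_y),
         cell_size = as.numeric(cell_size),
         n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
         crs = as.character(crs), nodata = as.numeric(nodata)),
    class = "gs_grid")
}

#' @export
print.gs_grid <- function(x, ...) {
  cat(sprintf("<gs_grid> %d x %d cells @ %g m, NW corner (%g, %g), crs '%s'\n",
              x$n_rows, x$n_cols, x$cell_size, x$origin_x, x$origin_y, x$crs))
  invisible(x)
}

#' Test two grids for exact equality
#'
#' Layers may only be combined when their grids agree bitwise in every
#' field.
#'
#' @param a,b `gs_grid` objects.
#' @return Logical scalar.
#' @export
grid_equal <- function(a, b) {
  stopifnot(inherits(a, "gs_grid"), inherits(b, "gs_grid"))
  isTRUE(all.equal(a$origin_x, b$origin_x, tolerance = 0)) &&
    isTRUE(all.equal(a$origin_y, b$origin_y, tolerance = 0)) &&
    a$cell_size == b$cell_size &&
    a$n_rows == b$n_rows && a$n_cols == b$n_cols &&
    a$crs == b$crs
}

stop_if_grid_mismatch <- function(a, b, what = "layer") {
  if (!grid_equal(a, b)) {
    stop("grid mismatch: ", what,
         " is not on the analysis grid (origin/cell size/dimensions/crs ",
         "must be identical)", call. = FALSE)
  }
  invisible(TRUE)
}

#' Construct a raster layer on a grid
#'
#' @param grid A `gs_grid`.
#' @param values Numeric matrix (`n_rows` x `n_cols`) or a single value to
#'   fill. Missing cells are `NA` in memory; the grid's nodata sentinel is
#'   only used on disk.
#' @param name Layer name.
#' @return An object of class `gs_raster`.
#' @export
raster_layer <- function(grid, values, name = "layer") {
  stopifnot(inherits(grid, "gs_grid"))
  if (length(values) == 1L) {
    values <- matrix(as.numeric(values), grid$n_rows, grid$n_cols)
  }
  values <- as.matrix(values)
  if (nrow(values) != grid$n_rows || ncol(values) != grid$n_cols) {
    stop("value lattice is ", nrow(values), "x", ncol(values),
         " but grid is ", grid$n_rows, "x", grid$n_cols, call. = FALSE)
  }
  storage.mode(values) <- "double"
  structure(list(grid = grid, values = values, name = as.character(name)),
            class = "gs_raster")
}

#' @export
print.gs_raster <- function(x, ...) {
  v <- x$values[!is.na(x$values)]
  cat(sprintf("<gs_raster> '%s' %d x %d @ %g m; %d nodata cells",
              x$name, x$grid$n_rows, x$grid$n_cols, x$grid$cell_size,
              sum(is.na(x$values))))
  if (length(v)) cat(sprintf("; range [%.4g, %.4g]", min(v), max(v)))
  cat("\n")
  invisible(x)
}

#' Map point coordinates to grid cells
#'
#' Half-open cell convention: `col = floor((x - origin_x) / cell_size) + 1`,
#' `row = floor((origin_y - y) / cell_size) + 1`. Points outside the lattice
#' get `NA` row/col.
#'
#' @param grid A `gs_grid`.
#' @param x,y Numeric vectors of projected coordinates (m).
#' @return A tibble with columns `row`, `col`, `cell` (1-based column-major
#'   index, `NA` off-grid).
#' @export
cells_from_xy <- function(grid, x, y) {
  col <- floor((x - grid$origin_x) / grid$cell_size) + 1
  row <- floor((grid$origin_y - y) / grid$cell_size) + 1
  off <- col < 1 | col > grid$n_cols | row < 1 | row > grid$n_rows
  row[off] <- NA_integer_
  col[off] <- NA_integer_
  tibble::tibble(row = as.integer(row), col = as.integer(col),
                 cell = as.integer(row + (col - 1L) * grid$n_rows))
}

#' Cell-center coordinates for grid cells
#'
#' @param grid A `gs_grid`.
#' @param row,col Integer vectors (recycled).
#' @return A tibble with columns `x`, `y` of the cell centers.
#' @export
xy_from_cells <- function(grid, row, col) {
  tibble::tibble(
    x = grid$origin_x + (col - 0.5) * grid$cell_size,
    y = grid$origin_y - (row - 0.5) * grid$cell_size)
}

#' All cell centers of a grid
#'
#' @param grid A `gs_grid`.
#' @return Tibble with `row`, `col`, `x`, `y` in column-major order.
#' @export
cell_centers <- function(grid) {
  rc <- expand.grid(row = seq_len(grid$n_rows), col = seq_len(grid$n_cols))
  dplyr::bind_cols(tibble::as_tibble(rc), xy_from_cells(grid, rc$row, rc$col))
}

#' Extract raster values at point locations
#'
#' @param layer A `gs_raster`.
#' @param x,y Coordinates (m); must fall on the lattice.
#' @return Numeric vector of cell values (`NA` for off-grid points or
#'   nodata cells).
#' @export
extract_values <- function(layer, x, y) {
  rc <- cells_from_xy(layer$grid, x, y)
  out <- rep(NA_real_, length(x))
  ok <- !is.na(rc$cell)
  out[ok] <- layer$values[cbind(rc$row[ok], rc$col[ok])]
  out
}

#' @importFrom tibble as_tibble
#' @export
as_tibble.gs_raster <- function(x, ...) {
  cc <- cell_centers(x$grid)
  cc$value <- as.vector(x$values)
  cc$layer <- x$name
  cc
}

#' A named stack of co-registered covariate rasters
#'
#' All layers must share one grid. The stack records per-covariate training
#' ranges (min/max over non-missing cells) used later for extrapolation
#' flagging.
#'
#' @param layers Named list of `gs_raster` objects (names override layer
#'   names if given).
#' @return An object of class `gs_stack`.
#' @export
covariate_stack <- function(layers) {
  stopifnot(length(layers) >= 1)
  if (is.null(names(layers)) || any(!nzchar(names(layers)))) {
    names(layers) <- vapply(layers, function(l) l$name, character(1))
  }
  g <- layers[[1]]$grid
  for (l in layers) stop_if_grid_mismatch(g, l$grid, paste0("layer '", l$name, "'"))
  ranges <- purrr::map_dfr(names(layers), function(nm) {
    v <- layers[[nm]]$values
    v <- v[!is.na(v)]
    tibble::tibble(covariate = nm,
                   min = if (length(v)) min(v) else NA_real_,
                   max = if (length(v)) max(v) else NA_real_,
                   mean = if (length(v)) mean(v) else NA_real_,
                   sd = if (length(v)) stats::sd(v) else NA_real_)
  })
  structure(list(grid = g, layers = layers, ranges = ranges),
            class = "gs_stack")
}

#' @export
print.gs_stack <- function(x, ...) {
  cat(sprintf("<gs_stack> %d layers on %d x %d grid @ %g m:\n",
              length(x$layers), x$grid$n_rows, x$grid$n_cols,
              x$grid$cell_size))
  cat(" ", paste(names(x$layers), collapse = ", "), "\n")
  invisible(x)
}

#' @export
`[[.gs_stack` <- function(x, i) x$layers[[i]]

#' @export
names.gs_stack <- function(x) names(x$layers)

#' Covariate values at point locations, one column per layer
#'
#' @param stack A `gs_stack`.
#' @param points Data frame with `x`, `y` columns (m).
#' @param covariates Optional character vector restricting the layers.
#' @return The input points with one extra column per covariate.
#' @export
stack_extract <- function(stack, points, covariates = NULL) {
  nms <- covariates %||% names(stack$layers)
  vals <- purrr::map(nms, function(nm) extract_values(stack$layers[[nm]],
                                                      points$x, points$y))
  names(vals) <- nms
  dplyr::bind_cols(tibble::as_tibble(points), tibble::as_tibble(vals))
}

#' Covariate matrix over all grid cells
#'
#' @param stack A `gs_stack`.
#' @param covariates Optional layer subset.
#' @return Tibble with `row`, `col`, `x`, `y` and one column per covariate,
#'   in column-major cell order.
#' @export
stack_table <- function(stack, covariates = NULL) {
  nms <- covariates %||% names(stack$layers)
  out <- cell_centers(stack$grid)
  for (nm in nms) out[[nm]] <- as.vector(stack$layers[[nm]]$values)
  out
}

#' Aggregate a fine raster onto a coarser grid
#'
#' Each target cell takes the mean (or max) of the source cells whose
#' centers fall inside it. Used to carry the 30 m movement surface onto the
#' 250 m modeling grid.
#'
#' @param layer A `gs_raster` on a finer grid.
#' @param target A `gs_grid` with the same CRS.
#' @param fun `"mean"` (default) or `"max"`.
#' @return A `gs_raster` on `target`.
#' @export
aggregate_to_grid <- function(layer, target, fun = c("mean", "max")) {
  fun <- match.arg(fun)
  if (layer$grid$crs != target$crs) stop("CRS mismatch in aggregation", call. = FALSE)
  cc <- cell_centers(layer$grid)
  rc <- cells_from_xy(target, cc$x, cc$y)
  v <- as.vector(layer$values)
  ok <- !is.na(rc$cell) & !is.na(v)
  agg <- tapply(v[ok], rc$cell[ok], if (fun == "mean") mean else max)
  out <- matrix(NA_real_, target$n_rows, target$n_cols)
  out[as.integer(names(agg))] <- as.numeric(agg)
  raster_layer(target, out, name = layer$name)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
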