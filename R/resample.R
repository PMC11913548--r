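# Resampling between co-registered grids. Continuous covariates use the
# bilinear kernel; downscaled climate layers use a separable natural cubic
# spline. Both operate in cell-center index space; target centers outside
# the source center hull are clamped to the nearest valid source position
# (nearest-valid edge padding).

source_index_coords <- function(src_grid, target) {
  if (src_grid$crs != target$crs) {
    stop("CRS mismatch between source and target grids", call. = FALSE)
  }
  if (target$cell_size > 10 * src_grid$cell_size) {
    warning("target grid is more than 10x coarser than source; ",
            "consider aggregating instead", call. = FALSE)
  }
  cx <- (target$origin_x + (seq_len(target$n_cols) - 0.5) * target$cell_size -
           src_grid$origin_x) / src_grid$cell_size + 0.5
  ry <- (src_grid$origin_y -
           (target$origin_y - (seq_len(target$n_rows) - 0.5) * target$cell_size)) /
    src_grid$cell_size + 0.5
  list(col = pmin(pmax(cx, 1), src_grid$n_cols),
       row = pmin(pmax(ry, 1), src_grid$n_rows))
}

#' Resample a raster onto a target grid by bilinear interpolation
#'
#' The standard kernel for continuous covariates. Exact for spatially
#' constant layers and, away from the clamped edge band, for linear fields.
#' Missing source cells are handled by renormalizing the weights of the
#' available neighbors; a target cell whose four neighbors are all missing
#' is missing.
#'
#' @param layer Source `gs_raster`.
#' @param target Target `gs_grid` (same CRS).
#' @return A `gs_raster` on `target`.
#' @export
resample_bilinear <- function(layer, target) {
  idx <- source_index_coords(layer$grid, target)
  m <- layer$values
  nr <- nrow(m); nc <- ncol(m)
  r0 <- pmin(pmax(floor(idx$row), 1), nr); r1 <- pmin(r0 + 1, nr)
  c0 <- pmin(pmax(floor(idx$col), 1), nc); c1 <- pmin(c0 + 1, nc)
  fr <- idx$row - r0
  fc <- idx$col - c0
  out <- matrix(NA_real_, target$n_rows, target$n_cols)
  for (j in seq_len(target$n_cols)) {
    v00 <- m[cbind(r0, rep(c0[j], length(r0)))]
    v10 <- m[cbind(r1, rep(c0[j], length(r1)))]
    v01 <- m[cbind(r0, rep(c1[j], length(r0)))]
    v11 <- m[cbind(r1, rep(c1[j], length(r1)))]
    w00 <- (1 - fr) * (1 - fc[j]); w10 <- fr * (1 - fc[j])
    w01 <- (1 - fr) * fc[j];       w11 <- fr * fc[j]
    vals <- cbind(v00, v10, v01, v11)
    wts <- cbind(w00, w10, w01, w11)
    wts[is.na(vals)] <- 0
    vals[is.na(vals)] <- 0
    tot <- rowSums(wts)
    res <- ifelse(tot > 0, rowSums(vals * wts) / tot, NA_real_)
    out[, j] <- res
  }
  raster_layer(target, out, name = layer$name)
}

#' Resample a raster onto a target grid by separable cubic spline
#'
#' Used for climate layers. A natural cubic spline is fit along each source
#' row and evaluated at the target column positions, then along each
#' resulting column at the target row positions. Natural end conditions
#' reproduce linear fields exactly. Missing source cells are not supported
#' (climate layers are complete).
#'
#' @inheritParams resample_bilinear
#' @return A `gs_raster` on `target`.
#' @export
resample_cubic_spline <- function(layer, target) {
  if (anyNA(layer$values)) {
    stop("cubic-spline resampling requires a complete source layer",
         call. = FALSE)
  }
  idx <- source_index_coords(layer$grid, target)
  m <- layer$values
  nr <- nrow(m); nc <- ncol(m)
  # along columns (x direction) first
  m1 <- matrix(NA_real_, nr, target$n_cols)
  if (nc == 1) {
    m1[] <- m[, 1]
  } else {
    for (i in seq_len(nr)) {
      f <- stats::splinefun(seq_len(nc), m[i, ], method = "natural")
      m1[i, ] <- f(idx$col)
    }
  }
  out <- matrix(NA_real_, target$n_rows, target$n_cols)
  if (nr == 1) {
    out[] <- rep(m1[1, ], each = target$n_rows)
  } else {
    for (j in seq_len(target$n_cols)) {
      f <- stats::splinefun(seq_len(nr), m1[, j], method = "natural")
      out[, j] <- f(idx$row)
    }
  }
  raster_layer(target, out, name = layer$name)
}
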