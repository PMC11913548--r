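#' Read a single-band georeferenced raster (ESRI ASCII grid)
#'
#' Rasters are stored in the plain-text ESRI ASCII grid format (`ncols` /
#' `nrows` / `xllcorner` / `yllcorner` / `cellsize` / `NODATA_value` header
#' followed by north-to-south rows). The format carries no CRS, so an
#' optional sidecar file `<path>.crs` holding the CRS tag is honored; absent
#' a sidecar the tag defaults to `"local-meters"`. Inputs whose CRS tag
#' looks geographic (contains "4326" or "longlat") are rejected: the
#' pipeline works in one projected CRS in meters and never silently
#' reprojects.
#'
#' @param path File path of the `.asc` raster.
#' @param expected_grid Optional `gs_grid`; if supplied and the file's grid
#'   differs in any field the read fails rather than silently adapting.
#' @param name Layer name (defaults to the file stem).
#' @return A `gs_raster`.
#' @export
read_raster <- function(path, expected_grid = NULL, name = NULL) {
  if (!file.exists(path)) stop("raster file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (i <= length(lines)) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(parts) == 2 && tolower(parts[1]) %in%
        c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize",
          "nodata_value")) {
      hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
      i <- i + 1L
    } else break
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr))) {
    stop("malformed ASCII grid header in ", path, call. = FALSE)
  }
  nodata <- hdr[["nodata_value"]] %||% -9999
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  if (length(vals) != nr * nc) {
    stop("ASCII grid body has ", length(vals), " values, expected ",
         nr * nc, call. = FALSE)
  }
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == nodata] <- NA_real_
  if (all(is.na(m))) stop("raster band is entirely nodata: ", path, call. = FALSE)
  crs <- "local-meters"
  crs_file <- paste0(path, ".crs")
  if (file.exists(crs_file)) crs <- trimws(readLines(crs_file, n = 1))
  if (grepl("4326|longlat|degrees", crs, ignore.case = TRUE)) {
    stop("geographic CRS rejected (analysis requires projected meters): ",
         crs, call. = FALSE)
  }
  grid <- raster_grid(origin_x = hdr$xllcorner,
                      origin_y = hdr$yllcorner + nr * hdr$cellsize,
                      cell_size = hdr$cellsize, n_rows = nr, n_cols = nc,
                      crs = crs, nodata = nodata)
  if (!is.null(expected_grid)) stop_if_grid_mismatch(expected_grid, grid, path)
  raster_layer(grid, m,
               name = name %||% sub("\\.asc$", "", basename(path)))
}

#' Write a raster as an ESRI ASCII grid
#'
#' Values are written at full double precision so write-then-read is an
#' exact round trip. The CRS tag is written to a `<path>.crs` sidecar.
#'
#' @param layer A `gs_raster`.
#' @param path Destination path (conventionally `.asc`).
#' @return `path`, invisibly.
#' @export
write_raster <- function(layer, path) {
  g <- layer$grid
  hdr <- c(sprintf("ncols %d", g$n_cols),
           sprintf("nrows %d", g$n_rows),
           sprintf("xllcorner %.17g", g$origin_x),
           sprintf("yllcorner %.17g", g$origin_y - g$n_rows * g$cell_size),
           sprintf("cellsize %.17g", g$cell_size),
           sprintf("NODATA_value %.17g", g$nodata))
  m <- layer$values
  m[is.na(m)] <- g$nodata
  body <- apply(m, 1, function(r) paste(sprintf("%.17g", r), collapse = " "))
  writeLines(c(hdr, body), path)
  writeLines(g$crs, paste0(path, ".crs"))
  invisible(path)
}

#' Read a point table (occurrences, telemetry fixes, or effort points)
#'
#' @param path CSV path with projected-meter `x`, `y` columns. Telemetry
#'   additionally requires `animal_id` and a numeric `timestamp` (seconds).
#' @param schema One of `"occurrence"`, `"telemetry"`, `"effort"`.
#' @return A validated tibble; telemetry is sorted by animal then timestamp
#'   and must have strictly increasing timestamps within each animal.
#' @export
read_points <- function(path, schema = c("occurrence", "telemetry", "effort")) {
  schema <- match.arg(schema)
  if (!file.exists(path)) stop("point file not found: ", path, call. = FALSE)
  df <- tibble::as_tibble(utils::read.csv(path))
  validate_points(df, schema)
}

#' @rdname read_points
#' @param points A point tibble to validate without reading from disk.
#' @export
validate_points <- function(points, schema = c("occurrence", "telemetry", "effort")) {
  schema <- match.arg(schema)
  need <- c("x", "y")
  if (schema == "telemetry") need <- c(need, "animal_id", "timestamp")
  missing_cols <- setdiff(need, names(points))
  if (length(missing_cols)) {
    stop("point table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  points <- tibble::as_tibble(points)
  if (schema == "telemetry") {
    points <- dplyr::arrange(points, .data$animal_id, .data$timestamp)
    dup <- points |>
      dplyr::group_by(.data$animal_id) |>
      dplyr::filter(duplicated(.data$timestamp)) |>
      dplyr::ungroup()
    if (nrow(dup)) {
      stop("duplicate timestamps within animal(s): ",
           paste(unique(dup$animal_id), collapse = ", "), call. = FALSE)
    }
  }
  points
}

#' Write a point table to CSV
#'
#' @param points A tibble.
#' @param path Destination CSV path.
#' @return `path`, invisibly.
#' @export
write_points <- function(points, path) {
  utils::write.csv(points, path, row.names = FALSE)
  invisible(path)
}

#' Read polygons with protection categories from GeoJSON
#'
#' Only `Polygon` (single outer ring) and `MultiPolygon` features are
#' supported; multipolygons are split into one row per part. Feature
#' properties become columns (`category` is expected for protection
#' layers).
#'
#' @param path GeoJSON path.
#' @return A `gs_polygons` tibble with columns `poly_id`, any property
#'   columns, and a `geometry` list-column of two-column coordinate
#'   matrices (outer rings, not closed).
#' @export
read_polygons <- function(path) {
  if (!file.exists(path)) stop("polygon file not found: ", path, call. = FALSE)
  gj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(gj$features)) stop("not a GeoJSON FeatureCollection: ", path, call. = FALSE)
  rows <- list()
  for (f in gj$features) {
    props <- f$properties %||% list()
    geom <- f$geometry
    rings <- switch(geom$type,
                    Polygon = list(geom$coordinates[[1]]),
                    MultiPolygon = lapply(geom$coordinates, function(p) p[[1]]),
                    stop("unsupported geometry type: ", geom$type, call. = FALSE))
    for (ring in rings) {
      m <- do.call(rbind, lapply(ring, function(pt) c(pt[[1]], pt[[2]])))
      # drop closing vertex if the ring is closed
      if (nrow(m) > 1 && all(m[1, ] == m[nrow(m), ])) m <- m[-nrow(m), , drop = FALSE]
      rows[[length(rows) + 1L]] <- c(props, list(geometry = list(m)))
    }
  }
  out <- purrr::map_dfr(rows, function(r) {
    tibble::as_tibble(r[names(r) != "geometry"])
  })
  out$geometry <- lapply(rows, function(r) r$geometry[[1]])
  out <- dplyr::mutate(out, poly_id = dplyr::row_number(), .before = 1)
  class(out) <- c("gs_polygons", class(out))
  out
}

#' Write polygons to GeoJSON
#'
#' @param polys A `gs_polygons` tibble (or any tibble with a `geometry`
#'   list-column of coordinate matrices and property columns).
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_polygons <- function(polys, path) {
  prop_cols <- setdiff(names(polys), c("geometry", "poly_id"))
  features <- lapply(seq_len(nrow(polys)), function(i) {
    m <- polys$geometry[[i]]
    ring <- lapply(seq_len(nrow(m)), function(j) c(m[j, 1], m[j, 2]))
    ring[[length(ring) + 1L]] <- ring[[1]]  # close the ring
    props <- as.list(polys[i, prop_cols, drop = FALSE])
    list(type = "Feature",
         properties = props,
         geometry = list(type = "Polygon", coordinates = list(ring)))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Polygon area by the shoelace formula
#'
#' @param geometry A two-column coordinate matrix (outer ring, open).
#' @return Area in square meters (always positive).
#' @export
polygon_area <- function(geometry) {
  x <- geometry[, 1]; y <- geometry[, 2]
  n <- length(x)
  j <- c(n, seq_len(n - 1))
  abs(sum(x[j] * y - x * y[j])) / 2
}

#' Append a timestamped line to a plain-text run log
#'
#' @param ... Message parts pasted together.
#' @param file Optional log file; `NULL` logs via [message()].
#' @return The formatted line, invisibly.
#' @export
log_line <- function(..., file = NULL) {
  line <- sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                  paste0(...))
  if (is.null(file)) message(line) else cat(line, "\n", file = file,
                                            append = TRUE, sep = "")
  invisible(line)
}
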