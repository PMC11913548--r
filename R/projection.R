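# Decadal climate preparation, delta-method downscaling, extrapolation
# flagging, future suitability prediction, and the dispersal-constrained
# occupiable-habitat update.

#' Replace layers in a stack
#'
#' Returns a new stack with the named layers swapped (grids must match);
#' used to substitute future climate layers while keeping the static
#' covariates. The SDM covariate attribute is preserved.
#'
#' @param stack A `gs_stack`.
#' @param replacements Named list of `gs_raster` layers.
#' @return A `gs_stack`.
#' @export
replace_layers <- function(stack, replacements) {
  layers <- stack$layers
  for (nm in names(replacements)) {
    stop_if_grid_mismatch(stack$grid, replacements[[nm]]$grid, nm)
    layers[[nm]] <- replacements[[nm]]
  }
  out <- covariate_stack(layers)
  attr(out, "sdm_covariates") <- attr(stack, "sdm_covariates")
  out
}

#' Decadal climate covariates from a monthly series
#'
#' Winter precipitation is the mean over the decade of the November-March
#' totals (the winter beginning in each year of the decade); average spring
#' temperature is the mean over the decade of the March-May means. The
#' decade covers exactly the ten years starting at `decade_start_year`.
#'
#' @param monthly_series Tibble with columns `year`, `month`, `variable`
#'   (`"temperature"` or `"precipitation"`), and `layer` (list of
#'   `gs_raster` on one grid).
#' @param decade_start_year First year of the decade.
#' @return List with `spring_temp` and `winter_precip` (`gs_raster`).
#' @export
decadal_average <- function(monthly_series, decade_start_year) {
  years <- decade_start_year + 0:9
  g <- monthly_series$layer[[1]]$grid
  get_layer <- function(variable, year, month) {
    i <- which(monthly_series$variable == variable &
                 monthly_series$year == year & monthly_series$month == month)
    if (length(i) != 1) {
      stop("monthly series is missing ", variable, " for ", year, "-", month,
           call. = FALSE)
    }
    monthly_series$layer[[i]]$values
  }
  spring <- Reduce(`+`, lapply(years, function(y) {
    (get_layer("temperature", y, 3) + get_layer("temperature", y, 4) +
       get_layer("temperature", y, 5)) / 3
  })) / 10
  winter <- Reduce(`+`, lapply(years, function(y) {
    get_layer("precipitation", y, 11) + get_layer("precipitation", y, 12) +
      get_layer("precipitation", y + 1, 1) +
      get_layer("precipitation", y + 1, 2) + get_layer("precipitation", y + 1, 3)
  })) / 10
  list(spring_temp = raster_layer(g, spring, "spring_temp"),
       winter_precip = raster_layer(g, winter, "winter_precip"))
}

#' Delta-method downscaling of a coarse climate forecast
#'
#' Temperature: the coarse anomaly (future minus baseline) is interpolated
#' to the fine grid and added to the fine reference climatology.
#' Precipitation: the coarse ratio (future over baseline, baseline floored
#' at `eps`, ratio clipped to \[0.1, 10\]) is interpolated and multiplied
#' onto the reference. Cells whose baseline needed the floor are counted in
#' `attr(, "n_floored")`.
#'
#' @param coarse_future,coarse_baseline `gs_raster` layers on one coarse
#'   grid.
#' @param fine_reference `gs_raster` reference climatology on the fine
#'   grid.
#' @param method `"additive"` (temperature) or `"ratio"` (precipitation).
#' @param eps Baseline floor for the ratio method.
#' @return A `gs_raster` on the fine grid.
#' @export
delta_downscale <- function(coarse_future, coarse_baseline, fine_reference,
                            method = c("additive", "ratio"), eps = 1e-6) {
  method <- match.arg(method)
  stop_if_grid_mismatch(coarse_future$grid, coarse_baseline$grid, "baseline")
  n_floored <- 0L
  if (method == "additive") {
    delta <- raster_layer(coarse_future$grid,
                          coarse_future$values - coarse_baseline$values)
    fine_delta <- resample_bilinear(delta, fine_reference$grid)
    out_vals <- fine_reference$values + fine_delta$values
  } else {
    base <- coarse_baseline$values
    n_floored <- sum(base < eps, na.rm = TRUE)
    ratio <- coarse_future$values / pmax(base, eps)
    ratio <- pmin(pmax(ratio, 0.1), 10)
    fine_ratio <- resample_bilinear(raster_layer(coarse_future$grid, ratio),
                                    fine_reference$grid)
    out_vals <- fine_reference$values * fine_ratio$values
  }
  out <- raster_layer(fine_reference$grid, out_vals, fine_reference$name)
  attr(out, "n_floored") <- n_floored
  out
}

#' Flag cells outside the training covariate ranges
#'
#' A cell is flagged when any covariate falls outside the range observed in
#' training: model predictions there extrapolate and are uncertain (but not
#' automatically unsuitable).
#'
#' @param stack A `gs_stack` of (future) covariates.
#' @param training_ranges Tibble with `covariate`, `min`, `max` (e.g. a
#'   `gs_ensemble$training_ranges`).
#' @return List with `mask` (`gs_raster` 0/1) and `report` (tibble:
#'   `covariate`, `flagged_fraction`).
#' @export
flag_extrapolation <- function(stack, training_ranges) {
  g <- stack$grid
  flagged <- matrix(FALSE, g$n_rows, g$n_cols)
  rows <- list()
  for (i in seq_len(nrow(training_ranges))) {
    nm <- training_ranges$covariate[i]
    if (!nm %in% names(stack$layers)) next
    v <- stack$layers[[nm]]$values
    f <- !is.na(v) & (v < training_ranges$min[i] | v > training_ranges$max[i])
    flagged <- flagged | f
    rows[[length(rows) + 1L]] <- tibble::tibble(
      covariate = nm, flagged_fraction = mean(f, na.rm = TRUE))
  }
  list(mask = raster_layer(g, flagged + 0, "extrapolation"),
       report = dplyr::bind_rows(rows))
}

#' Project ensemble suitability onto a (future) covariate stack
#'
#' Applies the fitted ensemble with the same threshold as the fitting
#' period; the extrapolation mask for the stack is carried alongside.
#'
#' @param ensemble A `gs_ensemble` with its threshold set.
#' @param stack Covariate stack for the projection period.
#' @return List: `mean`, `se`, `binary` (`gs_raster`s) and `extrapolation`
#'   (from [flag_extrapolation()]).
#' @export
project_suitability <- function(ensemble, stack) {
  pred <- ensemble_predict(ensemble, stack)
  pred$extrapolation <- flag_extrapolation(stack, ensemble$training_ranges)
  pred
}

#' Movement cutoff at the SDM locality points
#'
#' The empirical percentile (linear-interpolation convention) of the
#' movement prediction extracted at the presence points used for the SDM;
#' the default 1st percentile defines where movement is implausibly low.
#'
#' @param movement A `gs_raster` movement surface.
#' @param sdm_presences Presence tibble (`x`, `y`).
#' @param percentile Percentile in \[0, 1\] (default 0.01).
#' @return The cutoff value.
#' @export
movement_cutoff_at_localities <- function(movement, sdm_presences,
                                          percentile = 0.01) {
  v <- extract_values(movement, sdm_presences$x, sdm_presences$y)
  v <- v[!is.na(v)]
  if (!length(v)) stop("no locality falls on a valid movement cell", call. = FALSE)
  as.numeric(stats::quantile(v, percentile, type = 7))
}

# Binary dilation of a logical matrix by a Euclidean disk of radius
# `radius_cells` (center-to-center distance, <= convention).
dilate_disk <- function(mask, radius_cells) {
  nr <- nrow(mask); nc <- ncol(mask)
  if (radius_cells^2 >= (nr - 1)^2 + (nc - 1)^2) {
    return(matrix(any(mask), nr, nc))
  }
  r <- floor(radius_cells)
  out <- matrix(FALSE, nr, nc)
  for (di in -r:r) for (dj in -r:r) {
    if (di * di + dj * dj > radius_cells^2) next
    lo_r <- max(1, 1 - di); hi_r <- min(nr, nr - di)
    lo_c <- max(1, 1 - dj); hi_c <- min(nc, nc - dj)
    if (lo_r > hi_r || lo_c > hi_c) next
    src_r <- lo_r:hi_r
    src_c <- lo_c:hi_c
    out[src_r + di, src_c + dj] <- out[src_r + di, src_c + dj] |
      mask[src_r, src_c]
  }
  out
}

#' One decade of the dispersal-constrained occupancy update
#'
#' Newly suitable habitat is current suitable habitat not previously
#' occupiable. A new cell is reachable when its center lies within the
#' dispersal radius of a previously occupiable cell center, its movement
#' value is at or above the movement cutoff, and its impervious fraction is
#' at or below the impervious ceiling. Occupiable habitat persists where it
#' stays suitable and grows by the reachable cells:
#' `O = (O_prev & S) | R`.
#'
#' @param prior_occupiable `gs_raster` (0/1) of the previous decade's
#'   occupiable mask.
#' @param suitable `gs_raster` (0/1) of current binary suitability.
#' @param movement `gs_raster` movement surface on the same grid (aggregate
#'   a finer surface first with [aggregate_to_grid()]).
#' @param movement_cutoff Cutoff from [movement_cutoff_at_localities()].
#' @param impervious `gs_raster` impervious fraction.
#' @param config A `gs_config` (`dispersal_radius_m`, `impervious_cutoff`).
#' @return List of 0/1 `gs_raster`s `suitable`, `newly_suitable`,
#'   `reachable`, `occupiable` and a one-row `areas` tibble (hectares).
#' @export
occupiable_update <- function(prior_occupiable, suitable, movement,
                              movement_cutoff, impervious,
                              config = pipeline_config()) {
  g <- suitable$grid
  for (l in list(prior_occupiable, movement, impervious)) {
    stop_if_grid_mismatch(g, l$grid, l$name)
  }
  O_prev <- !is.na(prior_occupiable$values) & prior_occupiable$values > 0
  S <- !is.na(suitable$values) & suitable$values > 0
  N <- S & !O_prev
  within_reach <- dilate_disk(O_prev, config$dispersal_radius_m / g$cell_size)
  mv_ok <- !is.na(movement$values) & movement$values >= movement_cutoff
  imp_ok <- !is.na(impervious$values) & impervious$values <= config$impervious_cutoff
  R <- N & within_reach & mv_ok & imp_ok
  O <- (O_prev & S) | R
  ha <- g$cell_size^2 / 1e4
  lay <- function(m, nm) raster_layer(g, m + 0, nm)
  list(suitable = lay(S, "suitable"),
       newly_suitable = lay(N, "newly_suitable"),
       reachable = lay(R, "reachable"),
       occupiable = lay(O, "occupiable"),
       areas = tibble::tibble(suitable_ha = sum(S) * ha,
                              newly_suitable_ha = sum(N) * ha,
                              reachable_ha = sum(R) * ha,
                              occupiable_ha = sum(O) * ha))
}

#' Run the decadal occupiable-habitat projection
#'
#' For each scenario: predicts binary suitability for every decade with the
#' fitted ensemble (fixed threshold), initializes the occupiable mask as
#' decade-0 suitability minus heavily impervious cells, and iterates
#' [occupiable_update()] through the final decade. The summary ratio is the
#' final occupiable area over the initial occupiable area.
#'
#' @param ensemble A fitted `gs_ensemble`.
#' @param base_stack Baseline landscape stack.
#' @param climate_series Tibble from [make_future_climate()] (columns
#'   `scenario`, `decade`, `spring_temp`, `winter_precip`).
#' @param movement `gs_raster` movement surface on the modeling grid.
#' @param impervious `gs_raster` impervious fraction on the modeling grid.
#' @param sdm_presences Presences used for the SDM (set the movement
#'   cutoff).
#' @param config A `gs_config`.
#' @return A `gs_occupiable`: `series` (tibble: `scenario`, `decade`,
#'   areas in hectares, `extrapolated_fraction`), `ratios` (tibble:
#'   `scenario`, `ratio`), `masks` (per scenario/decade lists).
#' @export
run_decadal_projection <- function(ensemble, base_stack, climate_series,
                                   movement, impervious, sdm_presences,
                                   config = pipeline_config()) {
  cutoff <- movement_cutoff_at_localities(movement, sdm_presences,
                                          config$movement_percentile)
  ha <- base_stack$grid$cell_size^2 / 1e4
  series <- list(); ratios <- list(); masks <- list()
  for (sc in unique(climate_series$scenario)) {
    dec <- dplyr::filter(climate_series, .data$scenario == sc) |>
      dplyr::arrange(.data$decade)
    O_prev <- NULL
    for (i in seq_len(nrow(dec))) {
      st <- replace_layers(base_stack,
                           list(spring_temp = dec$spring_temp[[i]],
                                winter_precip = dec$winter_precip[[i]]))
      proj <- project_suitability(ensemble, st)
      S <- proj$binary
      ex_frac <- mean(proj$extrapolation$mask$values, na.rm = TRUE)
      if (is.null(O_prev)) {
        ok_imp <- !is.na(impervious$values) &
          impervious$values <= config$impervious_cutoff
        O0 <- (!is.na(S$values) & S$values > 0) & ok_imp
        upd <- list(
          suitable = S,
          newly_suitable = raster_layer(S$grid, 0, "newly_suitable"),
          reachable = raster_layer(S$grid, 0, "reachable"),
          occupiable = raster_layer(S$grid, O0 + 0, "occupiable"),
          areas = tibble::tibble(
            suitable_ha = sum(S$values > 0, na.rm = TRUE) * ha,
            newly_suitable_ha = 0, reachable_ha = 0,
            occupiable_ha = sum(O0) * ha))
      } else {
        upd <- occupiable_update(O_prev, S, movement, cutoff, impervious,
                                 config)
      }
      O_prev <- upd$occupiable
      series[[length(series) + 1L]] <- dplyr::bind_cols(
        tibble::tibble(scenario = sc, decade = dec$decade[i]),
        upd$areas, tibble::tibble(extrapolated_fraction = ex_frac))
      masks[[sc]][[as.character(dec$decade[i])]] <- upd
    }
    sc_series <- dplyr::bind_rows(series) |>
      dplyr::filter(.data$scenario == sc)
    first_area <- sc_series$occupiable_ha[1]
    last_area <- sc_series$occupiable_ha[nrow(sc_series)]
    ratios[[length(ratios) + 1L]] <- tibble::tibble(
      scenario = sc,
      ratio = if (first_area > 0) last_area / first_area else NA_real_)
  }
  structure(list(series = dplyr::bind_rows(series),
                 ratios = dplyr::bind_rows(ratios),
                 movement_cutoff = cutoff, masks = masks),
            class = "gs_occupiable")
}

#' @export
print.gs_occupiable <- function(x, ...) {
  cat("<gs_occupiable> occupiable-habitat series\n")
  print(x$ratios)
  invisible(x)
}

#' Plot an occupiable-habitat series
#'
#' Occupiable habitat as solid lines, newly suitable dotted, reachable
#' dashed; one colour per scenario.
#'
#' @param object A `gs_occupiable`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gs_occupiable <- function(object, ...) {
  long <- object$series |>
    tidyr::pivot_longer(c("occupiable_ha", "newly_suitable_ha", "reachable_ha"),
                        names_to = "quantity", values_to = "hectares") |>
    dplyr::mutate(quantity = factor(
      .data$quantity,
      levels = c("occupiable_ha", "newly_suitable_ha", "reachable_ha"),
      labels = c("Occupiable", "Newly suitable", "Reachable")))
  ggplot2::ggplot(long, ggplot2::aes(.data$decade, .data$hectares,
                                     colour = .data$scenario,
                                     linetype = .data$quantity)) +
    ggplot2::geom_line() +
    ggplot2::scale_linetype_manual(values = c(Occupiable = "solid",
                                              `Newly suitable` = "dotted",
                                              Reachable = "dashed")) +
    ggplot2::labs(x = "Decade", y = "Hectares", colour = "Scenario",
                  linetype = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a raster layer
#'
#' @param object A `gs_raster`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gs_raster <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object), ggplot2::aes(.data$x, .data$y,
                                                  fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_viridis_c(na.value = "white") +
    ggplot2::labs(title = object$name, x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}
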