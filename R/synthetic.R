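# Synthetic landscapes, occurrences, telemetry, climate futures and
# protection geometries. The study's real Gila monster localities are
# withheld (poaching risk), so every pipeline stage is exercised on
# generated data with a known truth: a suitability function over covariates
# that mirror the roles of the real ones (soil, texture, topography,
# washes, spring temperature, winter precipitation), spatially biased
# detection effort, biased-random-walk telemetry over a movement-preference
# surface with the fitted model's sign structure, and two decadal climate
# trajectories bracketing low- and high-change futures.

#' True generating parameters for the synthetic study system
#'
#' Coefficients act on per-covariate z-scores (standardized against the
#' landscape), so magnitudes are comparable across covariates. Defaults
#' encode the target ecology: suitability peaks on moderately sloped,
#' rugged, wash-bearing terrain at intermediate spring temperatures
#' (negative quadratic, so warming beyond the optimum degrades habitat) and
#' higher winter precipitation. The movement preference carries the sign
#' structure recovered by the movement model: quadratic (hump-shaped)
#' slope, ruggedness and shrub responses, avoidance of high topographic
#' position, attraction to suitable habitat, and negative log-distance
#' terms for roads and paths.
#'
#' @param suitability_linear,suitability_quadratic Named numeric vectors of
#'   logit-scale weights on standardized covariates.
#' @param suitability_intercept Logit-scale intercept.
#' @param detection_bias_strength Exponent (>= 0) on the effort surface in
#'   occurrence sampling; 0 removes detection bias.
#' @param climate_trend Per-scenario list with `temp` (additive deg C per
#'   decade) and `precip` (multiplicative factor per decade).
#' @param movement_linear,movement_quadratic Named weights of the
#'   movement-preference surface (log scale).
#' @return A `gs_truth` list.
#' @export
truth_params <- function(
    suitability_linear = c(coarse_fragments = 0.5, surface_texture = 0.3,
                           depth_bedrock = -0.3, pct_sand = -0.5,
                           pct_washes = 0.5, mountain_base = 0.6,
                           slope = 0.6, tpi = -0.4, ruggedness = 0.4,
                           spring_temp = 1.0, winter_precip = 0.8),
    suitability_quadratic = c(slope = -0.5, spring_temp = -1.2,
                              winter_precip = -0.3),
    suitability_intercept = -0.5,
    detection_bias_strength = 1,
    climate_trend = list(low = list(temp = 0.2, precip = 0.99),
                         high = list(temp = 0.9, precip = 0.93)),
    movement_linear = c(slope = 0.6, ruggedness = 0.2, tpi = -0.5,
                        shrub = 0.6, suitability = 0.8,
                        log_dist_road = -0.3, log_dist_path = -0.3),
    movement_quadratic = c(slope = -0.5, ruggedness = -0.3, shrub = -0.4)) {
  stopifnot(detection_bias_strength >= 0)
  structure(list(suitability_linear = suitability_linear,
                 suitability_quadratic = suitability_quadratic,
                 suitability_intercept = suitability_intercept,
                 detection_bias_strength = detection_bias_strength,
                 climate_trend = climate_trend,
                 movement_linear = movement_linear,
                 movement_quadratic = movement_quadratic),
            class = "gs_truth")
}

# Stationary Gaussian random field by spectral smoothing of white noise on
# the torus; standardized to mean 0, sd 1. Deterministic under the caller's
# RNG state.
gaussian_field <- function(n_rows, n_cols, range_cells = 10) {
  noise <- matrix(stats::rnorm(n_rows * n_cols), n_rows, n_cols)
  if (range_cells <= 0) return((noise - mean(noise)) / stats::sd(noise))
  di <- pmin(seq_len(n_rows) - 1, n_rows - (seq_len(n_rows) - 1))
  dj <- pmin(seq_len(n_cols) - 1, n_cols - (seq_len(n_cols) - 1))
  kern <- exp(-(outer(di^2, dj^2, "+")) / (2 * range_cells^2))
  f <- Re(stats::fft(stats::fft(noise) * stats::fft(kern), inverse = TRUE)) /
    (n_rows * n_cols)
  (f - mean(f)) / stats::sd(f)
}

# 3x3 neighborhood helpers with replicate (nearest-valid) padding.
pad_replicate <- function(m) {
  m <- rbind(m[1, , drop = FALSE], m, m[nrow(m), , drop = FALSE])
  cbind(m[, 1, drop = FALSE], m, m[, ncol(m), drop = FALSE])
}

neighborhood_stats <- function(m) {
  p <- pad_replicate(m)
  nr <- nrow(m); nc <- ncol(m)
  shifts <- list()
  for (di in -1:1) for (dj in -1:1) {
    shifts[[length(shifts) + 1L]] <- p[(2 + di):(nr + 1 + di),
                                       (2 + dj):(nc + 1 + dj)]
  }
  arr <- array(unlist(shifts), dim = c(nr, nc, 9))
  sum_all <- apply(arr, c(1, 2), sum)
  sumsq <- apply(arr, c(1, 2), function(v) sum(v^2))
  mean_nb <- (sum_all - m) / 8            # mean of the 8 neighbors
  sd_all <- sqrt(pmax(sumsq / 9 - (sum_all / 9)^2, 0))
  list(mean_neighbors = mean_nb, sd_window = sd_all)
}

dem_derivatives <- function(dem, cell_size) {
  p <- pad_replicate(dem)
  nr <- nrow(dem); nc <- ncol(dem)
  ctr_r <- 2:(nr + 1); ctr_c <- 2:(nc + 1)
  gx <- (p[ctr_r, ctr_c + 1] - p[ctr_r, ctr_c - 1]) / (2 * cell_size)
  gy <- (p[ctr_r + 1, ctr_c] - p[ctr_r - 1, ctr_c]) / (2 * cell_size)
  slope_deg <- atan(sqrt(gx^2 + gy^2)) * 180 / pi
  nb <- neighborhood_stats(dem)
  list(slope = slope_deg,
       tpi = dem - nb$mean_neighbors,
       ruggedness = nb$sd_window)
}

#' Generate a synthetic covariate landscape
#'
#' Produces the nine static covariates (Gaussian random fields for the
#' soil/texture/wash layers; a smooth synthetic DEM from which slope,
#' topographic position index, ruggedness and a mountain-base indicator are
#' derived) plus the two climate covariates: average spring temperature as
#' a lapse-rate function of elevation with noise, and winter precipitation
#' increasing with elevation. Additional movement-model layers (shrub
#' cover, distance to a road and to a path) and a detection-effort surface
#' concentrated near the road are included for the downstream stages.
#'
#' @param grid A `gs_grid` (>= 50 x 50 recommended).
#' @param seed Integer seed; identical seeds give bitwise-identical stacks.
#' @param relief Total DEM relief amplitude in meters (0 gives a flat DEM).
#' @param lapse_rate Temperature lapse rate in deg C per km of elevation
#'   (negative: cooler aloft).
#' @param range_cells Correlation length of the random fields, in cells.
#' @return A `gs_stack`; the SDM covariate subset is recorded in
#'   `attr(, "sdm_covariates")`.
#' @export
make_landscape <- function(grid, seed = 1, relief = 400, lapse_rate = -6.5,
                           range_cells = 8) {
  if (grid$n_rows < 2 || grid$n_cols < 2) stop("degenerate grid", call. = FALSE)
  set.seed(seed)
  nr <- grid$n_rows; nc <- grid$n_cols
  dem <- 600 + relief * gaussian_field(nr, nc, range_cells * 2)
  der <- dem_derivatives(dem, grid$cell_size)
  mountain_base <- (der$slope > 0.5 & der$slope < 10 &
                      dem > stats::quantile(dem, 0.3) &
                      dem < stats::quantile(dem, 0.8)) + 0
  coarse_fragments <- gaussian_field(nr, nc, range_cells)
  surface_texture <- gaussian_field(nr, nc, range_cells)
  depth_bedrock <- gaussian_field(nr, nc, range_cells)
  pct_sand <- gaussian_field(nr, nc, range_cells)
  pct_washes <- 0.7 * scale_field(-der$tpi) + 0.3 * gaussian_field(nr, nc, range_cells)
  shrub <- gaussian_field(nr, nc, range_cells)
  spring_temp <- 24 + lapse_rate * dem / 1000 +
    0.5 * gaussian_field(nr, nc, range_cells)
  winter_precip <- pmax(60 + 0.03 * (dem - 600) +
                          15 * gaussian_field(nr, nc, range_cells), 5)
  # one vertical road and one horizontal path crossing the landscape
  road_col <- sample.int(nc, 1)
  path_row <- sample.int(nr, 1)
  road_x <- grid$origin_x + (road_col - 0.5) * grid$cell_size
  path_y <- grid$origin_y - (path_row - 0.5) * grid$cell_size
  cc <- cell_centers(grid)
  dist_road <- matrix(abs(cc$x - road_x), nr, nc)
  dist_path <- matrix(abs(cc$y - path_y), nr, nc)
  effort <- exp(-dist_road / (6 * grid$cell_size)) +
    0.5 * exp(-dist_path / (6 * grid$cell_size)) + 0.02
  lay <- function(v, nm) raster_layer(grid, v, nm)
  layers <- list(
    dem = lay(dem, "dem"),
    coarse_fragments = lay(coarse_fragments, "coarse_fragments"),
    surface_texture = lay(surface_texture, "surface_texture"),
    depth_bedrock = lay(depth_bedrock, "depth_bedrock"),
    pct_sand = lay(pct_sand, "pct_sand"),
    pct_washes = lay(pct_washes, "pct_washes"),
    mountain_base = lay(mountain_base, "mountain_base"),
    slope = lay(der$slope, "slope"),
    tpi = lay(der$tpi, "tpi"),
    ruggedness = lay(der$ruggedness, "ruggedness"),
    spring_temp = lay(spring_temp, "spring_temp"),
    winter_precip = lay(winter_precip, "winter_precip"),
    shrub = lay(shrub, "shrub"),
    dist_road = lay(dist_road, "dist_road"),
    dist_path = lay(dist_path, "dist_path"),
    effort = lay(effort, "effort"))
  st <- covariate_stack(layers)
  attr(st, "sdm_covariates") <- c("coarse_fragments", "surface_texture",
                                  "depth_bedrock", "pct_sand", "pct_washes",
                                  "mountain_base", "slope", "tpi",
                                  "ruggedness", "spring_temp", "winter_precip")
  st
}

scale_field <- function(m) {
  s <- stats::sd(m)
  if (s == 0) return(m * 0)
  (m - mean(m)) / s
}

standardize_against <- function(values, covariate, ranges) {
  r <- ranges[ranges$covariate == covariate, ]
  if (nrow(r) == 0 || is.na(r$sd) || r$sd == 0) return(values - (r$mean %||% 0))
  (values - r$mean) / r$sd
}

#' True habitat suitability of a synthetic landscape
#'
#' Deterministic logistic transform of a linear + quadratic form in the
#' standardized covariates.
#'
#' @param stack A `gs_stack` (typically from [make_landscape()], possibly
#'   with climate layers swapped for a future decade).
#' @param truth A `gs_truth`.
#' @param reference_ranges Optional ranges tibble used for
#'   standardization; defaults to the stack's own. Supplying the baseline
#'   landscape's ranges keeps the truth function fixed when projecting
#'   future climates.
#' @return A `gs_raster` named `"true_suitability"`, values in \[0, 1\].
#' @export
true_suitability <- function(stack, truth, reference_ranges = NULL) {
  ranges <- reference_ranges %||% stack$ranges
  bad <- setdiff(union(names(truth$suitability_linear),
                       names(truth$suitability_quadratic)),
                 names(stack$layers))
  if (length(bad)) {
    stop("truth references unknown covariate(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  logit <- matrix(truth$suitability_intercept,
                  stack$grid$n_rows, stack$grid$n_cols)
  for (nm in names(truth$suitability_linear)) {
    z <- standardize_against(stack$layers[[nm]]$values, nm, ranges)
    logit <- logit + truth$suitability_linear[[nm]] * z
  }
  for (nm in names(truth$suitability_quadratic)) {
    z <- standardize_against(stack$layers[[nm]]$values, nm, ranges)
    logit <- logit + truth$suitability_quadratic[[nm]] * z^2
  }
  raster_layer(stack$grid, stats::plogis(logit), "true_suitability")
}

#' True movement-preference surface
#'
#' Exponential of the movement linear predictor over the landscape's
#' movement covariates (standardized), rescaled to \[0, 1\].
#'
#' @inheritParams true_suitability
#' @param suitability Optional `gs_raster` of habitat suitability feeding
#'   the preference (defaults to [true_suitability()]).
#' @return A `gs_raster` in \[0, 1\].
#' @export
true_movement_preference <- function(stack, truth, suitability = NULL) {
  suitability <- suitability %||% true_suitability(stack, truth)
  eta <- matrix(0, stack$grid$n_rows, stack$grid$n_cols)
  val <- function(nm) {
    if (nm == "suitability") return(scale_field(suitability$values))
    if (nm == "log_dist_road") {
      return(scale_field(log(stack$layers[["dist_road"]]$values + 30)))
    }
    if (nm == "log_dist_path") {
      return(scale_field(log(stack$layers[["dist_path"]]$values + 30)))
    }
    standardize_against(stack$layers[[nm]]$values, nm, stack$ranges)
  }
  for (nm in names(truth$movement_linear)) {
    eta <- eta + truth$movement_linear[[nm]] * val(nm)
  }
  for (nm in names(truth$movement_quadratic)) {
    eta <- eta + truth$movement_quadratic[[nm]] * val(nm)^2
  }
  p <- exp(eta)
  raster_layer(stack$grid, (p - min(p)) / (max(p) - min(p)),
               "movement_preference")
}

#' Sample biased presence points
#'
#' Cells are drawn (with replacement, so duplicate-cell records occur and
#' exercise downstream thinning) with probability proportional to
#' `suitability * effort^bias_strength`, then jittered uniformly within the
#' cell.
#'
#' @param suitability,effort `gs_raster` layers on one grid; `effort >= 0`.
#' @param n Number of occurrence records.
#' @param seed Integer seed.
#' @param bias_strength Detection-bias exponent (default from
#'   [truth_params()] is 1; 0 gives unbiased sampling).
#' @return Tibble of `x`, `y` occurrence points.
#' @export
sample_occurrences <- function(suitability, effort, n, seed = 1,
                               bias_strength = 1) {
  stop_if_grid_mismatch(suitability$grid, effort$grid, "effort layer")
  if (any(effort$values < 0, na.rm = TRUE)) stop("effort must be >= 0", call. = FALSE)
  if (n == 0) return(tibble::tibble(x = numeric(0), y = numeric(0)))
  set.seed(seed)
  w <- as.vector(suitability$values) * as.vector(effort$values)^bias_strength
  w[is.na(w)] <- 0
  if (sum(w) <= 0) stop("no cell has positive sampling weight", call. = FALSE)
  g <- suitability$grid
  cells <- sample.int(length(w), n, replace = TRUE, prob = w)
  row <- ((cells - 1L) %% g$n_rows) + 1L
  col <- ((cells - 1L) %/% g$n_rows) + 1L
  ctr <- xy_from_cells(g, row, col)
  tibble::tibble(
    x = ctr$x + stats::runif(n, -0.5, 0.5) * g$cell_size * 0.999,
    y = ctr$y + stats::runif(n, -0.5, 0.5) * g$cell_size * 0.999)
}

#' Simulate telemetry tracks as a biased random walk
#'
#' Each animal starts in a high-preference cell and proposes Gaussian
#' steps; a candidate step is accepted with probability proportional to the
#' preference at the destination relative to the current cell (Metropolis
#' rule, so the walk's stationary distribution follows the preference
#' surface). Rejected proposals leave the animal in place, producing the
#' zero-length steps the telemetry filter must handle. Fixes are
#' timestamped at a regular interval with occasional injected gaps longer
#' than 36 h.
#'
#' @param preference A `gs_raster` movement-preference surface in \[0, 1\].
#' @param n_animals,fixes_per_animal Track dimensions.
#' @param step_sd_m Per-axis standard deviation of proposed steps (m); 0
#'   means the animal never moves.
#' @param seed Integer seed; identical seeds give identical tracks.
#' @param fix_interval_hours Nominal time between fixes.
#' @param gap_rate Probability a fix is delayed by an extra 48 h.
#' @return Telemetry tibble (`animal_id`, `timestamp` seconds, `x`, `y`).
#' @export
simulate_telemetry <- function(preference, n_animals, fixes_per_animal = 800,
                               step_sd_m = 150, seed = 1,
                               fix_interval_hours = 12, gap_rate = 0.04) {
  set.seed(seed)
  g <- preference$grid
  pv <- preference$values
  pmax_val <- max(pv, na.rm = TRUE)
  xmin <- g$origin_x; xmax <- g$origin_x + g$n_cols * g$cell_size
  ymin <- g$origin_y - g$n_rows * g$cell_size; ymax <- g$origin_y
  top_cells <- which(as.vector(pv) >= stats::quantile(pv, 0.8, na.rm = TRUE))
  out <- vector("list", n_animals)
  for (a in seq_len(n_animals)) {
    start_cell <- sample(top_cells, 1)
    row <- ((start_cell - 1L) %% g$n_rows) + 1L
    col <- ((start_cell - 1L) %/% g$n_rows) + 1L
    pos <- as.numeric(xy_from_cells(g, row, col)[1, ])
    t <- 0
    xs <- numeric(fixes_per_animal); ys <- numeric(fixes_per_animal)
    ts <- numeric(fixes_per_animal)
    for (i in seq_len(fixes_per_animal)) {
      xs[i] <- pos[1]; ys[i] <- pos[2]; ts[i] <- t
      cand <- pos + stats::rnorm(2, 0, step_sd_m)
      cand[1] <- min(max(cand[1], xmin + 1), xmax - 1)
      cand[2] <- min(max(cand[2], ymin + 1), ymax - 1)
      pcand <- extract_values(preference, cand[1], cand[2])
      phere <- extract_values(preference, pos[1], pos[2])
      ratio <- if (is.na(pcand) || is.na(phere)) 0 else
        if (phere <= 0) 1 else pcand / phere
      if (stats::runif(1) < ratio) pos <- cand
      dt <- fix_interval_hours * 3600
      if (stats::runif(1) < gap_rate) dt <- dt + 48 * 3600
      t <- t + dt
    }
    out[[a]] <- tibble::tibble(animal_id = sprintf("animal_%02d", a),
                               timestamp = ts, x = xs, y = ys)
  }
  dplyr::bind_rows(out)
}

#' Generate decadal future climate covariates for two scenarios
#'
#' Temperature shifts additively by the per-decade trend; precipitation
#' scales multiplicatively. Smooth noise fields of the given standard
#' deviations are superimposed per decade. The default high-change scenario
#' (+0.9 deg C per decade) deliberately pushes part of the landscape
#' outside the training climate range by the final decades so extrapolation
#' flagging is exercised.
#'
#' @param stack Baseline landscape (`spring_temp`, `winter_precip` layers).
#' @param truth A `gs_truth` carrying `climate_trend`.
#' @param decades Number of decades to emit (decade 0 is the baseline).
#' @param seed Integer seed.
#' @param temp_noise_sd Additive noise sd, deg C (0 for exact trends).
#' @param precip_noise_sd Log-scale multiplicative noise sd (0 for exact).
#' @param scenarios Which scenarios to emit.
#' @return Tibble with columns `scenario`, `decade`, and list-columns
#'   `spring_temp`, `winter_precip` of `gs_raster` layers.
#' @export
make_future_climate <- function(stack, truth, decades, seed = 1,
                                temp_noise_sd = 0.1, precip_noise_sd = 0.02,
                                scenarios = names(truth$climate_trend)) {
  set.seed(seed)
  g <- stack$grid
  t0 <- stack$layers[["spring_temp"]]$values
  p0 <- stack$layers[["winter_precip"]]$values
  rows <- list()
  for (sc in scenarios) {
    tr <- truth$climate_trend[[sc]]
    for (d in seq_len(decades) - 1L) {
      tnoise <- if (temp_noise_sd > 0 && d > 0) {
        temp_noise_sd * gaussian_field(g$n_rows, g$n_cols, 8)
      } else 0
      pnoise <- if (precip_noise_sd > 0 && d > 0) {
        exp(precip_noise_sd * gaussian_field(g$n_rows, g$n_cols, 8))
      } else 1
      rows[[length(rows) + 1L]] <- tibble::tibble(
        scenario = sc, decade = d,
        spring_temp = list(raster_layer(g, t0 + d * tr$temp + tnoise,
                                        "spring_temp")),
        winter_precip = list(raster_layer(g, p0 * tr$precip^d * pnoise,
                                          "winter_precip")))
    }
  }
  dplyr::bind_rows(rows)
}

#' Generate protection-category polygons and an impervious-surface raster
#'
#' Always contains a Designated polygon nested inside a Proclamation
#' polygon (exercising the precedence rule), disjoint Designated, Other,
#' BLM and Solar polygons (Solar overlapping BLM), a Tribal polygon (to be
#' removed by precedence resolution) and a state-owned Fee polygon (to be
#' merged into Proclamation), plus an impervious raster with a development
#' blob exceeding the 20% masking threshold.
#'
#' @param grid A `gs_grid`.
#' @param seed Integer seed (affects the impervious background only; the
#'   polygon layout is deterministic in grid coordinates).
#' @return List with `polygons` (a `gs_polygons` tibble with `category`,
#'   `owner` columns) and `impervious` (a `gs_raster` in \[0, 1\]).
#' @export
make_protection_and_impervious <- function(grid, seed = 1) {
  set.seed(seed)
  W <- grid$n_cols * grid$cell_size
  H <- grid$n_rows * grid$cell_size
  x0 <- grid$origin_x; y0 <- grid$origin_y - H  # SW corner
  rect <- function(fx0, fy0, fx1, fy1) {
    cbind(x = x0 + c(fx0, fx1, fx1, fx0) * W,
          y = y0 + c(fy0, fy0, fy1, fy1) * H)
  }
  polys <- tibble::tibble(
    category = c("Proclamation", "Designated", "Designated", "Other",
                 "BLM", "Solar", "Tribal", "Fee"),
    owner = c(NA, NA, NA, NA, NA, NA, NA, "state"),
    geometry = list(
      rect(0.05, 0.55, 0.45, 0.95),   # Proclamation block (NW)
      rect(0.15, 0.65, 0.35, 0.85),   # Designated nested inside it
      rect(0.55, 0.70, 0.75, 0.90),   # disjoint Designated
      rect(0.80, 0.80, 0.92, 0.92),   # Other (state/local)
      rect(0.05, 0.05, 0.70, 0.45),   # BLM multiple-use block (S half)
      rect(0.45, 0.10, 0.65, 0.30),   # Solar zone inside BLM
      rect(0.80, 0.05, 0.95, 0.20),   # Tribal (removed in resolution)
      rect(0.47, 0.55, 0.57, 0.65)))  # state Fee parcel -> Proclamation
  polys <- dplyr::mutate(polys, poly_id = dplyr::row_number(), .before = 1)
  class(polys) <- c("gs_polygons", class(polys))
  cc <- cell_centers(grid)
  bx <- x0 + 0.85 * W; by <- y0 + 0.55 * H
  blob <- 0.6 * exp(-((cc$x - bx)^2 + (cc$y - by)^2) / (2 * (0.06 * W)^2))
  imp <- matrix(stats::runif(grid$n_rows * grid$n_cols, 0, 0.05),
                grid$n_rows, grid$n_cols) +
    matrix(blob, grid$n_rows, grid$n_cols)
  list(polygons = polys,
       impervious = raster_layer(grid, pmin(imp, 1), "impervious"))
}

#' Simulate movement-regression samples with the true sign structure
#'
#' Draws per-animal covariate samples and builds a log-probability response
#' from the movement-preference coefficients, a per-animal random
#' intercept, and Gaussian noise. Used to test coefficient and sign
#' recovery of the movement-selection model without running the full
#' telemetry-to-bridge pipeline.
#'
#' @param truth A `gs_truth`.
#' @param n_animals,points_per_animal Sample dimensions.
#' @param noise_sd Residual sd of the log response.
#' @param intercept_sd Between-animal random-intercept sd.
#' @param seed Integer seed.
#' @return Tibble with movement covariates, `animal_id`, and `log_prob`.
#' @export
simulate_movement_samples <- function(truth, n_animals = 30,
                                      points_per_animal = 100,
                                      noise_sd = 0.5, intercept_sd = 0.3,
                                      seed = 1) {
  set.seed(seed)
  n <- n_animals * points_per_animal
  df <- tibble::tibble(
    animal_id = rep(sprintf("animal_%02d", seq_len(n_animals)),
                    each = points_per_animal),
    slope = stats::rnorm(n), ruggedness = stats::rnorm(n),
    tpi = stats::rnorm(n), shrub = stats::rnorm(n),
    suitability = stats::rnorm(n),
    dist_road = exp(stats::rnorm(n, 5, 1)),
    dist_path = exp(stats::rnorm(n, 5, 1)))
  b <- truth$movement_linear; q <- truth$movement_quadratic
  ldr <- scale(log(df$dist_road))[, 1]
  ldp <- scale(log(df$dist_path))[, 1]
  eta <- b[["slope"]] * df$slope + q[["slope"]] * df$slope^2 +
    b[["ruggedness"]] * df$ruggedness + q[["ruggedness"]] * df$ruggedness^2 +
    b[["tpi"]] * df$tpi +
    b[["shrub"]] * df$shrub + q[["shrub"]] * df$shrub^2 +
    b[["suitability"]] * df$suitability +
    b[["log_dist_road"]] * ldr + b[["log_dist_path"]] * ldp
  re <- stats::rnorm(n_animals, 0, intercept_sd)
  df$log_prob <- eta + rep(re, each = points_per_animal) +
    stats::rnorm(n, 0, noise_sd)
  df
}
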