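const_layer <- function(g, v, nm = "layer") raster_layer(g, matrix(v, g$n_rows, g$n_cols), nm)

test_that("decadal averaging computes Nov-Mar totals and Mar-May means", {
  g <- small_grid(2, 2, 250)
  # two years of hand-built monthlies, repeated over a decade
  mk_series <- function(temp_by_month, prcp_by_month, years) {
    rows <- list()
    for (y in years) for (m in 1:12) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        year = y, month = m, variable = "temperature",
        layer = list(const_layer(g, temp_by_month[m] + (y %% 2))))
      rows[[length(rows) + 1L]] <- tibble::tibble(
        year = y, month = m, variable = "precipitation",
        layer = list(const_layer(g, prcp_by_month[m] + (y %% 2))))
    }
    dplyr::bind_rows(rows)
  }
  temp <- 1:12; prcp <- seq(2, 24, by = 2)
  series <- mk_series(temp, prcp, 2040:2050)
  out <- decadal_average(series, 2040)
  # spring temp: mean of Mar-May plus the alternating year offset (mean 0.5)
  expect_equal(unique(as.vector(out$spring_temp$values)),
               mean(temp[3:5]) + 0.5)
  # winter precip: Nov + Dec of y plus Jan-Mar of y+1, with the year offsets
  # (y%%2 twice in Nov/Dec, (y+1)%%2 three times in Jan-Mar); averaging the
  # decade's alternating offsets gives (2*0.5 + 3*0.5) = 2.5
  expect_equal(unique(as.vector(out$winter_precip$values)),
               sum(prcp[c(11, 12)]) + sum(prcp[1:3]) + 2.5)
  # constant series gives constant covariates
  series_c <- mk_series(rep(3, 12), rep(5, 12), 2040:2050) |>
    dplyr::mutate(layer = purrr::map2(variable, layer, function(v, l) l))
  out_c <- decadal_average(dplyr::mutate(series_c,
    layer = purrr::map(layer, function(l) const_layer(g, 3))), 2040)
  expect_equal(unique(as.vector(out_c$spring_temp$values)), 3)
  # a missing month is an error (the window is exactly ten years)
  expect_error(decadal_average(series, 2041), "missing")
})

test_that("delta downscaling is exact for uniform deltas and ratios", {
  coarse <- small_grid(3, 3, 1000, origin_y = 3000)
  fine <- raster_grid(0, 3000, 250, 12, 12, crs = coarse$crs)
  set.seed(43)
  ref <- raster_layer(fine, matrix(rnorm(144, 20, 3), 12, 12), "ref")
  base <- raster_layer(coarse, matrix(rnorm(9, 15, 2), 3, 3))
  # future = baseline: output equals the reference
  same <- delta_downscale(base, base, ref, "additive")
  expect_equal(same$values, ref$values)
  # uniform +2 deg C anomaly
  fut <- raster_layer(coarse, base$values + 2)
  warm <- delta_downscale(fut, base, ref, "additive")
  expect_equal(warm$values, ref$values + 2)
  # uniform precipitation ratio 0.5
  half <- delta_downscale(raster_layer(coarse, base$values * 0.5), base,
                          ref, "ratio")
  expect_equal(half$values, ref$values * 0.5)
  # zero-baseline cells are floored and counted
  base0 <- raster_layer(coarse, matrix(c(0, rep(2, 8)), 3, 3))
  fut0 <- raster_layer(coarse, matrix(2, 3, 3))
  out0 <- delta_downscale(fut0, base0, ref, "ratio")
  expect_equal(attr(out0, "n_floored"), 1L)
})

test_that("extrapolation flagging matches a brute-force range check", {
  P <- test_prep()
  ranges <- P$stack$ranges[P$stack$ranges$covariate %in%
                             c("spring_temp", "winter_precip"), ]
  # identical stack: nothing flagged
  fl <- flag_extrapolation(P$stack, ranges)
  expect_equal(sum(fl$mask$values), 0)
  # push one cell above the training maximum
  t2 <- P$stack[["spring_temp"]]$values
  t2[4, 7] <- max(t2) + 5
  st2 <- replace_layers(P$stack, list(
    spring_temp = raster_layer(P$grid, t2, "spring_temp")))
  fl2 <- flag_extrapolation(st2, ranges)
  expect_equal(which(fl2$mask$values > 0), which(t2 > max(P$stack[["spring_temp"]]$values)))
  expect_equal(sum(fl2$mask$values), 1)
  # brute-force fraction agreement on a shifted stack
  st3 <- replace_layers(P$stack, list(
    spring_temp = raster_layer(P$grid, t2 + 2, "spring_temp")))
  fl3 <- flag_extrapolation(st3, ranges)
  brute <- mean((t2 + 2) < ranges$min[ranges$covariate == "spring_temp"] |
                  (t2 + 2) > ranges$max[ranges$covariate == "spring_temp"])
  expect_equal(fl3$report$flagged_fraction[
    fl3$report$covariate == "spring_temp"], brute)
})

test_that("the 3 km reachability rule is exact in cell distances", {
  g <- small_grid(30, 30, 250)
  cfg <- pipeline_config()  # 3000 m radius = 12 cells
  O <- matrix(0, 30, 30); O[15, 2] <- 1
  S <- matrix(1, 30, 30)
  mv <- const_layer(g, 1, "movement")
  imp <- const_layer(g, 0, "impervious")
  upd <- occupiable_update(raster_layer(g, O), raster_layer(g, S), mv, 0.5,
                           imp, cfg)
  # 12 cells away (3000 m center-to-center): included
  expect_equal(upd$reachable$values[15, 14], 1)
  # 13 cells away (3250 m): excluded
  expect_equal(upd$reachable$values[15, 15], 0)
  # diagonal: sqrt(8^2+9^2) = 12.04 cells -> excluded; sqrt(8^2+8^2) = 11.3 -> included
  expect_equal(upd$reachable$values[15 + 9, 2 + 8], 0)
  expect_equal(upd$reachable$values[15 + 8, 2 + 8], 1)
})

test_that("no newly suitable habitat means pure persistence", {
  g <- small_grid(10, 10, 250)
  set.seed(47)
  O <- random_logical(10, 10, 0.5)
  S <- O & random_logical(10, 10, 0.7)  # S subset of O: N empty
  upd <- occupiable_update(raster_layer(g, O + 0), raster_layer(g, S + 0),
                           const_layer(g, 1), 0.5, const_layer(g, 0))
  expect_equal(upd$occupiable$values > 0, O & S)
  expect_equal(sum(upd$newly_suitable$values), 0)
})

test_that("occupiable update equals the brute-force oracle on random instances", {
  cfg <- pipeline_config(dispersal_radius_m = 1000)  # 4 cells at 250 m
  g <- small_grid(50, 50, 250)
  set.seed(53)
  for (r in 1:100) {
    O <- random_logical(50, 50, runif(1, 0.02, 0.2))
    S <- random_logical(50, 50, runif(1, 0.2, 0.6))
    mv <- matrix(runif(2500), 50, 50)
    imp <- matrix(runif(2500, 0, 0.4), 50, 50)
    cutoff <- runif(1, 0.1, 0.5)
    upd <- occupiable_update(raster_layer(g, O + 0), raster_layer(g, S + 0),
                             raster_layer(g, mv, "movement"), cutoff,
                             raster_layer(g, imp, "impervious"), cfg)
    oracle <- occupiable_oracle(O, S, mv, cutoff, imp,
                                cfg$impervious_cutoff, 1000, 250)
    expect_identical(upd$reachable$values > 0, oracle$R)
    expect_identical(upd$occupiable$values > 0, oracle$O)
    # set-algebra invariants
    R <- upd$reachable$values > 0
    N <- upd$newly_suitable$values > 0
    Sm <- upd$suitable$values > 0
    expect_true(all(!R | N))       # R subset of N
    expect_true(all(!N | Sm))      # N subset of S
  }
})

test_that("areas use the cell area (6.25 ha at 250 m)", {
  g <- small_grid(10, 10, 250)
  O <- matrix(0, 10, 10); O[5, 5] <- 1
  S <- matrix(0, 10, 10); S[5, 5] <- 1; S[5, 6] <- 1
  upd <- occupiable_update(raster_layer(g, O), raster_layer(g, S),
                           const_layer(g, 1), 0.5, const_layer(g, 0))
  expect_equal(upd$areas$suitable_ha, 2 * 6.25)
  expect_equal(upd$areas$occupiable_ha, 2 * 6.25)
})

test_that("movement cutoff at localities uses the interpolated percentile", {
  g <- small_grid(10, 10, 250)
  vals <- matrix(as.numeric(1:100), 10, 10)
  mv <- raster_layer(g, vals, "movement")
  cc <- cell_centers(g)
  cutoff <- movement_cutoff_at_localities(mv, cc, percentile = 0.01)
  expect_equal(cutoff, as.numeric(quantile(1:100, 0.01)))
  expect_equal(cutoff, 1.99)
  # all values equal: cutoff is that value
  flat <- raster_layer(g, matrix(3, 10, 10), "movement")
  expect_equal(movement_cutoff_at_localities(flat, cc), 3)
  # percentile 0 returns the minimum
  expect_equal(movement_cutoff_at_localities(mv, cc, percentile = 1e-9), 1,
               tolerance = 1e-6)
})

test_that("projecting onto the current stack reproduces current suitability", {
  F <- projection_fixture()
  now <- ensemble_predict(F$ensemble, F$stack)
  again <- project_suitability(F$ensemble, F$stack)
  expect_equal(again$mean$values, now$mean$values)
  expect_equal(again$binary$values + 0,
               (now$mean$values >= F$ensemble$threshold) + 0)
  expect_equal(sum(again$extrapolation$mask$values), 0)
})

test_that("a static climate gives an occupiable ratio of exactly 1", {
  F <- projection_fixture()
  static <- tibble::tibble(
    scenario = "static", decade = 0:3,
    spring_temp = rep(list(F$stack[["spring_temp"]]), 4),
    winter_precip = rep(list(F$stack[["winter_precip"]]), 4))
  proj <- run_decadal_projection(F$ensemble, F$stack, static, F$preference,
                                 F$impervious, F$presences)
  expect_identical(proj$ratios$ratio, 1)
  # identical masks in every decade
  areas <- proj$series$occupiable_ha
  expect_true(all(areas == areas[1]))
})

test_that("a contraction-only scenario is monotonically non-increasing", {
  F <- projection_fixture()
  # progressively colder climate shrinks the warm-adapted suitable area;
  # suppress any new gains by also zeroing precipitation growth
  cold <- tibble::tibble(
    scenario = "cold", decade = 0:3,
    spring_temp = lapply(0:3, function(d) {
      raster_layer(F$grid, F$stack[["spring_temp"]]$values - 3 * d,
                   "spring_temp")
    }),
    winter_precip = rep(list(F$stack[["winter_precip"]]), 4))
  proj <- run_decadal_projection(F$ensemble, F$stack, cold, F$preference,
                                 F$impervious, F$presences)
  occ <- proj$series$occupiable_ha
  expect_true(all(diff(occ) <= 0))
  expect_lte(proj$ratios$ratio, 1)
})

test_that("a >3 km suitability jump is newly suitable but unreachable", {
  g <- small_grid(40, 40, 250)
  cfg <- pipeline_config()
  O <- matrix(0, 40, 40); O[20, 1:3] <- 1
  S <- matrix(0, 40, 40); S[20, 1:3] <- 1
  S[20, 30:35] <- 1  # a block 27+ cells (> 6.7 km) away
  upd <- occupiable_update(raster_layer(g, O), raster_layer(g, S),
                           const_layer(g, 1, "movement"), 0.5,
                           const_layer(g, 0, "impervious"), cfg)
  expect_gt(sum(upd$newly_suitable$values), 0)
  expect_equal(sum(upd$reachable$values), 0)
  expect_equal(upd$occupiable$values, O + 0)
})

test_that("an unlimited dispersal radius makes occupiable equal suitable", {
  g <- small_grid(20, 20, 250)
  cfg <- pipeline_config(dispersal_radius_m = 1e9)
  set.seed(59)
  O <- random_logical(20, 20, 0.1)
  S <- random_logical(20, 20, 0.5)
  upd <- occupiable_update(raster_layer(g, O + 0), raster_layer(g, S + 0),
                           const_layer(g, 1, "movement"), 0,
                           const_layer(g, 0, "impervious"), cfg)
  expect_gt(sum(O), 0)
  expect_equal(upd$occupiable$values > 0, S)
})

test_that("the occupiable series plots and prints", {
  F <- projection_fixture()
  static <- tibble::tibble(
    scenario = "static", decade = 0:1,
    spring_temp = rep(list(F$stack[["spring_temp"]]), 2),
    winter_precip = rep(list(F$stack[["winter_precip"]]), 2))
  proj <- run_decadal_projection(F$ensemble, F$stack, static, F$preference,
                                 F$impervious, F$presences)
  p <- autoplot(proj)
  expect_s3_class(p, "ggplot")
  expect_output(print(proj), "occupiable")
})
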