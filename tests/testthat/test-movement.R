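# Simulate a pure Brownian motion track (the generating model of the
# bridge variance estimator) with optional location error.
simulate_bm_track <- function(n_fixes, sigma2, dt = 3600, delta = 0,
                              seed = 1, animal_id = "sim") {
  set.seed(seed)
  steps_x <- rnorm(n_fixes - 1, 0, sqrt(sigma2 * dt))
  steps_y <- rnorm(n_fixes - 1, 0, sqrt(sigma2 * dt))
  tibble::tibble(animal_id = animal_id,
                 timestamp = (seq_len(n_fixes) - 1) * dt,
                 x = cumsum(c(0, steps_x)) + rnorm(n_fixes, 0, delta),
                 y = cumsum(c(0, steps_y)) + rnorm(n_fixes, 0, delta),
                 burst = 1L)
}

test_that("telemetry filtering applies the duplicate, gap, step and inclusion rules", {
  cfg <- pipeline_config()
  base_t <- seq(0, by = 12 * 3600, length.out = 50)
  # animal with 49+ fixes over > 1 year: base interval 12 h is too short, so
  # stretch to 8-day spacing
  t_long <- seq(0, by = 8 * 86400, length.out = 50)
  x <- seq(0, by = 100, length.out = 50)
  trk <- tibble::tibble(animal_id = "a1", timestamp = t_long, x = x, y = 0)
  # insert a duplicate fix (zero displacement)
  dup <- trk[10, ]; dup$timestamp <- trk$timestamp[10] + 3600
  trk2 <- dplyr::bind_rows(trk, dup) |> dplyr::arrange(timestamp)
  out <- filter_telemetry(trk2, cfg)
  expect_equal(nrow(out), 50)  # duplicate removed
  # every 8-day gap exceeds 36 h: each fix is its own burst
  expect_equal(max(out$burst), 50)
  # a 30-fix animal is excluded
  short <- tibble::tibble(animal_id = "a2",
                          timestamp = seq(0, by = 16 * 86400, length.out = 30),
                          x = seq(0, by = 100, length.out = 30), y = 0)
  both <- dplyr::bind_rows(trk, short)
  out2 <- filter_telemetry(both, cfg)
  expect_equal(attr(out2, "excluded"), "a2")
  expect_false("a2" %in% out2$animal_id)
})

test_that("sub-50 m steps are removed sequentially and bridges never span 36 h gaps", {
  cfg <- pipeline_config()
  n <- 60
  ts <- seq(0, by = 12 * 3600, length.out = n)
  ts[31:n] <- ts[31:n] + 40 * 3600          # one 40 h gap
  x <- seq(0, by = 200, length.out = n)
  x[5] <- x[4] + 30                          # a 30 m step
  trk <- tibble::tibble(animal_id = "a1", timestamp = ts, x = x, y = 0)
  # needs > 1 year: widen via min_days override instead
  out <- filter_telemetry(trk, cfg, min_days = 10)
  # the 30 m step was dropped
  expect_false(any(abs(out$x - x[5]) < 1e-9))
  # fixes across the 40 h gap are in different bursts
  b_before <- out$burst[which.max(out$timestamp[out$timestamp < ts[31]])]
  b_after <- out$burst[out$timestamp == ts[31]]
  expect_gt(b_after, b_before)
  # no bridge segment within a burst exceeds the gap
  for (b in split(out, out$burst)) {
    if (nrow(b) > 1) expect_true(all(diff(b$timestamp) <= 36 * 3600))
  }
})

test_that("bridge variance estimation recovers the generating variance", {
  errs <- vapply(1:20, function(r) {
    trk <- simulate_bm_track(200, sigma2 = 0.01, dt = 3600, delta = 0,
                             seed = 100 + r)
    est <- estimate_bm_variance(trk, location_error_sd = 0)
    as.numeric(est) / 0.01
  }, numeric(1))
  expect_lt(abs(mean(errs) - 1), 0.25)
  expect_true(all(errs > 0.5 & errs < 2))
})

test_that("the likelihood is maximized at the returned variance", {
  trk <- simulate_bm_track(100, sigma2 = 0.05, seed = 7)
  est <- estimate_bm_variance(trk, location_error_sd = 0)
  ll_at <- function(s2) {
    d2 <- 0
    ll <- 0
    for (i in seq(2, 99, by = 2)) {
      T_tot <- trk$timestamp[i + 1] - trk$timestamp[i - 1]
      a <- (trk$timestamp[i] - trk$timestamp[i - 1]) / T_tot
      mux <- trk$x[i - 1] + a * (trk$x[i + 1] - trk$x[i - 1])
      muy <- trk$y[i - 1] + a * (trk$y[i + 1] - trk$y[i - 1])
      v <- T_tot * a * (1 - a) * s2
      ll <- ll + dnorm(trk$x[i], mux, sqrt(v), log = TRUE) +
        dnorm(trk$y[i], muy, sqrt(v), log = TRUE)
    }
    ll
  }
  s2 <- as.numeric(est)
  expect_gte(ll_at(s2), ll_at(s2 / 2))
  expect_gte(ll_at(s2), ll_at(s2 * 2))
  expect_equal(ll_at(s2), attr(est, "log_lik"), tolerance = 1e-6)
})

test_that("a stationary (jittered) track drives the variance to the lower bound", {
  set.seed(9)
  trk <- tibble::tibble(animal_id = "s", burst = 1L,
                        timestamp = (0:49) * 3600,
                        x = rnorm(50, 0, 0.01), y = rnorm(50, 0, 0.01))
  est <- estimate_bm_variance(trk, location_error_sd = 0,
                              interval = c(1e-8, 100))
  expect_lt(as.numeric(est), 1e-7)
  expect_error(estimate_bm_variance(trk[1:2, ]), "interior")
})

test_that("the bridge surface sums to one and has the analytic midpoint variance", {
  g <- raster_grid(-500, 500, 5, 200, 320)  # 5 m cells
  trk <- tibble::tibble(animal_id = "b", burst = 1L,
                        timestamp = c(0, 3600), x = c(0, 1000), y = c(0, 0))
  bb <- bbmm_surface(trk, sigma2_m = 0.01, grid = g, n_alpha_steps = 101,
                     location_error_sd = 0)
  expect_equal(sum(bb$surface$values), 1, tolerance = 1e-6)
  # the alpha = 0.5 slice is Normal(midpoint, T a (1-a) sigma2 = 9 m^2):
  # estimate the positional variance of the mass near x = 500 (the
  # midpoint step dominates a thin slab around it)
  tab <- as_tibble(bb$surface)
  # weight-average squared deviation from the line across y at x = 500
  slab <- tab[abs(tab$x - 500) <= 2.5, ]
  v_y <- sum(slab$value * slab$y^2) / sum(slab$value)
  expect_equal(v_y, 3600 * 0.25 * 0.01, tolerance = 0.15)
})

test_that("the bridge surface agrees with a Monte-Carlo bridge simulation", {
  # 5 m cells, small relative to the bridge sd (~9.5 m at the midpoint), so
  # center-density x area approximates the cell mass well
  g <- raster_grid(-100, 100, 5, 40, 200)
  trk <- tibble::tibble(animal_id = "mc", burst = 1L,
                        timestamp = c(0, 7200), x = c(0, 800), y = c(0, 0))
  sigma2 <- 0.05
  bb <- bbmm_surface(trk, sigma2, g, n_alpha_steps = 400,
                     location_error_sd = 0)
  # simulate Brownian bridge paths and bin time-uniform positions
  set.seed(77)
  n_paths <- 20000; n_t <- 80
  T_tot <- 7200
  tgrid <- (seq_len(n_t) - 0.5) / n_t
  sim_axis <- function(target) {
    dw <- matrix(rnorm(n_t * n_paths, 0, sqrt(sigma2 * T_tot / n_t)),
                 n_t, n_paths)
    w <- apply(dw, 2, cumsum)
    # condition on the endpoints: bridge = w - (t/T) w(T) + linear drift
    w - outer(tgrid, w[n_t, ]) + tgrid * target
  }
  bx <- sim_axis(800); by <- sim_axis(0)
  rc <- cells_from_xy(g, as.vector(bx), as.vector(by))
  okc <- !is.na(rc$cell)
  counts <- tabulate(rc$cell[okc], nbins = g$n_rows * g$n_cols)
  mc <- matrix(counts / sum(counts), g$n_rows, g$n_cols)
  # compare on the cells holding 90% of analytic mass
  ord <- order(bb$surface$values, decreasing = TRUE)
  top <- ord[cumsum(bb$surface$values[ord]) <= 0.9]
  rel_err <- abs(mc[top] - bb$surface$values[top]) / bb$surface$values[top]
  expect_lt(stats::median(rel_err), 0.10)
})

test_that("the surface is translation-invariant and entropy grows with sigma2", {
  g1 <- raster_grid(-400, 400, 25, 32, 48)
  trk <- tibble::tibble(animal_id = "t", burst = 1L,
                        timestamp = c(0, 3600, 7200),
                        x = c(0, 300, 500), y = c(0, 100, 0))
  bb1 <- bbmm_surface(trk, 0.01, g1)
  shift <- 1000
  g2 <- raster_grid(-400 + shift, 400, 25, 32, 48)
  trk2 <- dplyr::mutate(trk, x = x + shift)
  bb2 <- bbmm_surface(trk2, 0.01, g2)
  expect_lt(max(abs(bb1$surface$values - bb2$surface$values)), 1e-6)
  entropy <- function(bb) {
    p <- bb$surface$values[bb$surface$values > 0]
    -sum(p * log(p))
  }
  bb_wide <- bbmm_surface(trk, 0.02, g1)
  expect_gt(entropy(bb_wide), entropy(bb1))
})

test_that("halving the alpha steps changes cell masses by under 1%", {
  g <- raster_grid(-400, 400, 25, 32, 48)
  trk <- tibble::tibble(animal_id = "h", burst = 1L,
                        timestamp = c(0, 3600, 7200),
                        x = c(0, 300, 500), y = c(0, 100, 0))
  b50 <- bbmm_surface(trk, 0.01, g, n_alpha_steps = 50)
  b25 <- bbmm_surface(trk, 0.01, g, n_alpha_steps = 25)
  expect_lt(max(abs(b50$surface$values - b25$surface$values)), 0.01)
})

test_that("bridge point sampling respects the cutoff and is uniform over support", {
  g <- small_grid(8, 8, 100)
  m <- matrix(0, 8, 8)
  m[2, 2] <- 1
  bb <- structure(list(surface = raster_layer(g, m / sum(m), "bbmm"),
                       sigma2_m = 0.01, location_error_sd = 0,
                       animal_id = "u"), class = "gs_bbmm")
  pts <- sample_bbmm_points(bb, n = 100, seed = 5)
  expect_equal(nrow(pts), 100)
  rc <- cells_from_xy(g, pts$x, pts$y)
  expect_true(all(rc$row == 2 & rc$col == 2))
  # uniform over a known support, chi-square at 10,000 draws
  m2 <- matrix(runif(64), 8, 8)
  m2[m2 < 0.3] <- 0                        # some cells out of support
  bb2 <- structure(list(surface = raster_layer(g, m2 / sum(m2), "bbmm"),
                        sigma2_m = 0.01, location_error_sd = 0,
                        animal_id = "u2"), class = "gs_bbmm")
  pts2 <- sample_bbmm_points(bb2, n = 10000, cutoff = 1e-8, seed = 6)
  expect_true(all(pts2$prob > 1e-8))
  rc2 <- cells_from_xy(g, pts2$x, pts2$y)
  support <- which(as.vector(bb2$surface$values) > 1e-8)
  counts <- tabulate(rc2$cell, nbins = 64)[support]
  gof <- suppressWarnings(chisq.test(counts))
  expect_gt(gof$p.value, 0.01)
})

test_that("a noiseless single-covariate movement fit recovers the slope exactly", {
  set.seed(15)
  df <- tibble::tibble(animal_id = rep(c("a", "b"), each = 50),
                       slope = rnorm(100),
                       log_prob = NA_real_)
  df$log_prob <- 2.5 * df$slope - 1
  fit <- suppressWarnings(
    fit_movement_model(df, linear = "slope", quadratic = character(0),
                       log_distance = character(0)))
  est <- fit$coefficients$estimate[fit$coefficients$term == "slope"]
  expect_equal(est, 2.5, tolerance = 1e-6)
})

test_that("a singular random-effect fit falls back to the fixed-effects model", {
  truth <- truth_params()
  # no between-animal variance and little noise: the random intercept
  # collapses to the boundary
  df <- simulate_movement_samples(truth, n_animals = 4,
                                  points_per_animal = 80, noise_sd = 0.3,
                                  intercept_sd = 0, seed = 66)
  expect_warning(fit <- fit_movement_model(df), "singular")
  expect_true(fit$singular)
  expect_s3_class(fit$fit, "lm")
  expect_true(all(is.finite(fit$coefficients$std_error)))
})

test_that("the movement model recovers the generating sign structure", {
  truth <- truth_params()
  hits <- 0L
  for (r in 1:20) {
    df <- simulate_movement_samples(truth, n_animals = 30,
                                    points_per_animal = 100,
                                    noise_sd = 0.5, seed = 400 + r)
    fit <- fit_movement_model(df)
    co <- fit$coefficients
    est <- function(term) co$estimate[co$term == term]
    ok <- est("slope") > 0 && est("I(slope^2)") < 0 &&
      est("tpi") < 0 &&
      est("shrub") > 0 && est("I(shrub^2)") < 0 &&
      est("suitability") > 0 &&
      est("log_dist_road") < 0 && est("log_dist_path") < 0
    hits <- hits + ok
  }
  expect_gte(hits, 18)
})

test_that("coefficient recovery bias is under 10% at 30 animals x 100 points", {
  truth <- truth_params()
  ests <- replicate(10, {
    df <- simulate_movement_samples(truth, 30, 100, noise_sd = 0.5,
                                    seed = sample.int(1e6, 1))
    co <- fit_movement_model(df)$coefficients
    c(slope = co$estimate[co$term == "slope"],
      tpi = co$estimate[co$term == "tpi"])
  })
  expect_lt(abs(mean(ests["slope", ]) - truth$movement_linear[["slope"]]),
            0.1 * abs(truth$movement_linear[["slope"]]))
  expect_lt(abs(mean(ests["tpi", ]) - truth$movement_linear[["tpi"]]),
            0.1 * abs(truth$movement_linear[["tpi"]]))
})

test_that("permuted covariates show no significant effects", {
  truth <- truth_params()
  clean <- 0L
  for (r in 1:10) {
    df <- simulate_movement_samples(truth, 15, 60, noise_sd = 0.5,
                                    seed = 900 + r)
    set.seed(1000 + r)
    for (nm in c("slope", "ruggedness", "tpi", "shrub", "suitability",
                 "dist_road", "dist_path")) {
      df[[nm]] <- sample(df[[nm]])
    }
    fit <- fit_movement_model(df)
    co <- fit$coefficients
    z <- co$statistic[co$term != "(Intercept)"]
    clean <- clean + all(abs(z) < 3)
  }
  expect_gte(clean, 9)
})

test_that("movement prediction is constant for constant covariates and masks barriers", {
  g <- small_grid(6, 6, 100)
  const <- function(v, nm) raster_layer(g, matrix(v, 6, 6), nm)
  st <- covariate_stack(list(slope = const(1, "slope"),
                             ruggedness = const(0.5, "ruggedness"),
                             tpi = const(0, "tpi"), shrub = const(2, "shrub"),
                             suitability = const(0.5, "suitability"),
                             dist_road = const(100, "dist_road"),
                             dist_path = const(200, "dist_path")))
  df <- simulate_movement_samples(truth_params(), 5, 40, seed = 3)
  fit <- fit_movement_model(df)
  imp <- matrix(0, 6, 6); imp[1, 1] <- 0.5
  pred <- predict_movement(fit, st, impervious = raster_layer(g, imp, "imp"))
  expect_true(is.na(pred$values[1, 1]))
  vals <- pred$values[!is.na(pred$values)]
  expect_equal(length(unique(vals)), 1)
})

test_that("movement prediction increases with shrub below the fitted optimum", {
  truth <- truth_params()
  df <- simulate_movement_samples(truth, 20, 80, noise_sd = 0.2, seed = 21)
  fit <- fit_movement_model(df)
  co <- fit$coefficients
  b1 <- co$estimate[co$term == "shrub"]
  b2 <- co$estimate[co$term == "I(shrub^2)"]
  opt <- -b1 / (2 * b2)
  grid_vals <- seq(min(df$shrub), opt - 0.1, length.out = 20)
  resp <- b1 * grid_vals + b2 * grid_vals^2
  expect_true(all(diff(resp) > 0))
})

test_that("percentile validation ranks a high-preference holdout above 0.8", {
  g <- small_grid(10, 10, 100)
  set.seed(33)
  vals <- matrix(runif(100), 10, 10)
  pred <- raster_layer(g, vals, "movement")
  # holdout at the global maximum cell
  top <- which(vals == max(vals), arr.ind = TRUE)
  pt <- xy_from_cells(g, top[1, 1], top[1, 2])
  expect_equal(as.numeric(validate_percentile(pred, pt)), 1.0)
  # constant raster: convention 1.0 with degeneracy flag
  flat <- raster_layer(g, matrix(0.4, 10, 10), "movement")
  out <- validate_percentile(flat, pt)
  expect_equal(as.numeric(out), 1.0)
  expect_true(attr(out, "degenerate"))
  # synthetic holdout drawn from the upper preference tail
  hi_cells <- which(as.vector(vals) >= quantile(vals, 0.9))
  row <- ((hi_cells - 1) %% 10) + 1; col <- ((hi_cells - 1) %/% 10) + 1
  pts <- xy_from_cells(g, row, col)
  expect_gt(as.numeric(validate_percentile(pred, pts)), 0.8)
})
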