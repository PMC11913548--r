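# Telemetry filtering, Brownian bridge movement models, point sampling
# over the bridge surfaces, the mixed-effects movement-selection model,
# landscape-wide movement prediction, and percentile validation against a
# holdout site.

#' Filter telemetry to actual movements
#'
#' Animals with too few fixes or under a year of data are excluded; within
#' an animal, consecutive relocations with zero displacement are dropped,
#' then steps shorter than the minimum are removed sequentially, and fixes
#' separated by more than the maximum gap are split into bursts so no
#' Brownian bridge spans a long gap.
#'
#' @param tracks Telemetry tibble (`animal_id`, `timestamp` seconds, `x`,
#'   `y`).
#' @param config A `gs_config` (`telemetry_min_fixes`,
#'   `telemetry_min_step_m`, `telemetry_max_gap_hours`).
#' @param min_days Minimum data span in days for inclusion (default 365).
#' @return Filtered tibble with an added `burst` column; excluded animals
#'   are listed in `attr(, "excluded")`.
#' @export
filter_telemetry <- function(tracks, config = pipeline_config(),
                             min_days = 365) {
  tracks <- validate_points(tracks, "telemetry")
  max_gap_s <- config$telemetry_max_gap_hours * 3600
  excluded <- character(0)
  out <- tracks |>
    dplyr::group_by(.data$animal_id) |>
    dplyr::group_map(function(d, key) {
      span_days <- (max(d$timestamp) - min(d$timestamp)) / 86400
      if (nrow(d) <= config$telemetry_min_fixes || span_days <= min_days) {
        excluded <<- c(excluded, key$animal_id)
        return(NULL)
      }
      # sequential step filter: drop a fix whose displacement from the last
      # retained fix is below the minimum (zero-displacement duplicates
      # included)
      keep <- 1L
      last <- 1L
      for (i in 2:nrow(d)) {
        step <- sqrt((d$x[i] - d$x[last])^2 + (d$y[i] - d$y[last])^2)
        if (step >= config$telemetry_min_step_m) {
          keep <- c(keep, i)
          last <- i
        }
      }
      d <- d[keep, , drop = FALSE]
      if (nrow(d) < 2) {
        excluded <<- c(excluded, key$animal_id)
        return(NULL)
      }
      gaps <- c(0, diff(d$timestamp))
      d$burst <- cumsum(gaps > max_gap_s) + 1L
      d$animal_id <- key$animal_id
      d
    }) |>
    dplyr::bind_rows()
  attr(out, "excluded") <- excluded
  out
}

# Leave-one-out bridge triples (previous fix, dropped fix, next fix) for
# the odd-indexed interior fixes of each burst.
loo_triples <- function(track) {
  triples <- list()
  for (b in split(track, track$burst)) {
    n <- nrow(b)
    if (n < 3) next
    for (i in seq(2, n - 1, by = 2)) {
      triples[[length(triples) + 1L]] <- list(
        a = c(b$x[i - 1], b$y[i - 1]), z = c(b$x[i], b$y[i]),
        b = c(b$x[i + 1], b$y[i + 1]),
        t_a = b$timestamp[i - 1], t_z = b$timestamp[i],
        t_b = b$timestamp[i + 1])
    }
  }
  triples
}

#' Estimate the Brownian motion variance of a track
#'
#' Leave-one-out maximum likelihood: every odd-indexed interior fix is
#' dropped in turn and its likelihood computed under the Brownian bridge
#' connecting its neighbors — Normal around the connecting line at time
#' fraction `alpha` with variance
#' `T alpha (1 - alpha) sigma2 + (1 - alpha)^2 delta^2 + alpha^2 delta^2`
#' (`delta` the telemetry location error). The product over triples is
#' maximized by bounded one-dimensional search on `log(sigma2)`.
#'
#' @param track Filtered single-animal tibble (with `burst`).
#' @param location_error_sd Location error `delta`, m (default 15, typical
#'   VHF accuracy).
#' @param interval Search bounds for `sigma2` (m^2/s).
#' @return `sigma2_m` (m^2/s) with attributes `log_lik` and `n_triples`.
#' @export
estimate_bm_variance <- function(track, location_error_sd = 15,
                                 interval = c(1e-8, 100)) {
  if (is.null(track$burst)) track$burst <- 1L
  triples <- loo_triples(track)
  if (length(triples) < 1) {
    stop("need at least one odd-indexed interior fix (>= 3 fixes in a burst)",
         call. = FALSE)
  }
  d2 <- location_error_sd^2
  negll <- function(log_s2) {
    s2 <- exp(log_s2)
    ll <- 0
    for (tr in triples) {
      T_tot <- tr$t_b - tr$t_a
      a <- (tr$t_z - tr$t_a) / T_tot
      mu <- tr$a + a * (tr$b - tr$a)
      v <- T_tot * a * (1 - a) * s2 + (1 - a)^2 * d2 + a^2 * d2
      ll <- ll + sum(stats::dnorm(tr$z, mu, sqrt(v), log = TRUE))
    }
    if (!is.finite(ll)) stop("non-finite bridge likelihood", call. = FALSE)
    -ll
  }
  opt <- stats::optimize(negll, log(interval))
  out <- exp(opt$minimum)
  attr(out, "log_lik") <- -opt$objective
  attr(out, "n_triples") <- length(triples)
  out
}

#' Brownian bridge occurrence-probability surface for one animal
#'
#' Each between-fix segment contributes a time-weighted mixture of
#' bivariate Normal densities along the connecting line (midpoint rule over
#' `n_alpha_steps` time fractions), with positional variance
#' `T alpha (1 - alpha) sigma2 + (1 - alpha)^2 delta^2 + alpha^2 delta^2`.
#' Cell probabilities are density times cell area, renormalized to sum to
#' one: the surface is the animal's occurrence distribution over the
#' tracking period. Bridges never span burst boundaries.
#'
#' @param track Filtered single-animal tibble (with `burst`).
#' @param sigma2_m Brownian motion variance (m^2/s).
#' @param grid Output `gs_grid`.
#' @param n_alpha_steps Midpoint integration steps per segment.
#' @param location_error_sd Location error `delta`, m.
#' @param animal_id Stored identifier (defaults to the track's).
#' @return A `gs_bbmm`: `surface` (`gs_raster`), `sigma2_m`,
#'   `location_error_sd`, `animal_id`.
#' @export
bbmm_surface <- function(track, sigma2_m, grid, n_alpha_steps = 50,
                         location_error_sd = 15, animal_id = NULL) {
  stopifnot(sigma2_m > 0)
  if (is.null(track$burst)) track$burst <- 1L
  d2 <- location_error_sd^2
  acc <- matrix(0, grid$n_rows, grid$n_cols)
  xs <- grid$origin_x + (seq_len(grid$n_cols) - 0.5) * grid$cell_size
  ys <- grid$origin_y - (seq_len(grid$n_rows) - 0.5) * grid$cell_size
  segs <- list()
  for (b in split(track, track$burst)) {
    n <- nrow(b)
    if (n < 2) next
    for (i in seq_len(n - 1)) {
      segs[[length(segs) + 1L]] <- list(
        a = c(b$x[i], b$y[i]), b = c(b$x[i + 1], b$y[i + 1]),
        T = b$timestamp[i + 1] - b$timestamp[i])
    }
  }
  if (!length(segs)) stop("track has no usable segment", call. = FALSE)
  T_sum <- sum(vapply(segs, function(s) s$T, numeric(1)))
  alphas <- (seq_len(n_alpha_steps) - 0.5) / n_alpha_steps
  for (s in segs) {
    w_seg <- s$T / T_sum / n_alpha_steps
    for (a in alphas) {
      mu <- s$a + a * (s$b - s$a)
      v <- s$T * a * (1 - a) * sigma2_m + (1 - a)^2 * d2 + a^2 * d2
      sd_v <- sqrt(v)
      r5 <- 5 * sd_v
      ci <- which(xs >= mu[1] - r5 & xs <= mu[1] + r5)
      ri <- which(ys >= mu[2] - r5 & ys <= mu[2] + r5)
      if (!length(ci) || !length(ri)) next
      acc[ri, ci] <- acc[ri, ci] +
        w_seg * outer(stats::dnorm(ys[ri], mu[2], sd_v),
                      stats::dnorm(xs[ci], mu[1], sd_v))
    }
  }
  mass <- acc * grid$cell_size^2
  total <- sum(mass)
  if (total <= 0) stop("bridge mass fell entirely outside the grid", call. = FALSE)
  structure(list(surface = raster_layer(grid, mass / total, "bbmm"),
                 sigma2_m = sigma2_m, location_error_sd = location_error_sd,
                 animal_id = animal_id %||% track$animal_id[1]),
            class = "gs_bbmm")
}

#' @export
print.gs_bbmm <- function(x, ...) {
  cat(sprintf("<gs_bbmm> animal %s, sigma2 = %.4g m^2/s, delta = %g m\n",
              x$animal_id, x$sigma2_m, x$location_error_sd))
  invisible(x)
}

#' Sample random points over a Brownian bridge surface
#'
#' Uniform draws (with replacement) over the cells whose probability
#' exceeds the cutoff — the area the animal could have moved through.
#' Sampling is uniform rather than probability-weighted so the surface
#' value can serve as the regression response without confounding.
#'
#' @param bbmm A `gs_bbmm`.
#' @param n Number of points (default 100).
#' @param cutoff Probability-mass cutoff defining the support (default
#'   1e-8).
#' @param seed Integer seed.
#' @return Tibble with `animal_id`, `x`, `y` (cell centers), `prob` (the
#'   surface value).
#' @export
sample_bbmm_points <- function(bbmm, n = 100, cutoff = 1e-8, seed = 1) {
  v <- as.vector(bbmm$surface$values)
  support <- which(!is.na(v) & v > cutoff)
  if (!length(support)) stop("no cell exceeds the cutoff", call. = FALSE)
  set.seed(seed)
  g <- bbmm$surface$grid
  cells <- support[sample.int(length(support), n, replace = TRUE)]
  row <- ((cells - 1L) %% g$n_rows) + 1L
  col <- ((cells - 1L) %/% g$n_rows) + 1L
  ctr <- xy_from_cells(g, row, col)
  tibble::tibble(animal_id = bbmm$animal_id, x = ctr$x, y = ctr$y,
                 prob = v[cells])
}

#' Fit the movement-selection mixed model
#'
#' Regresses the log of the bridge occurrence probability at the sampled
#' points on the movement covariates — linear + quadratic terms for the
#' natural covariates, a linear term for habitat suitability, and
#' log-distance terms for roads and paths — with a random intercept per
#' animal, by REML. Inference is by Wald statistics. A singular
#' random-effect fit triggers a refit without the random intercept and a
#' warning.
#'
#' @param samples Tibble with `animal_id`, the covariate columns, and
#'   either `log_prob` or `prob` (logged internally).
#' @param linear Covariates entering linearly.
#' @param quadratic Covariates also entering squared.
#' @param log_distance Distance covariates entering as `log(x + offset)`.
#' @param log_offset Offset (m) inside the distance logs.
#' @return A `gs_movement_model` with elements `fit`, `coefficients`
#'   (tibble: `term`, `estimate`, `std_error`, `statistic`, `p_value`),
#'   `singular`, and the term structure.
#' @export
fit_movement_model <- function(samples,
                               linear = c("slope", "ruggedness", "tpi",
                                          "shrub", "suitability"),
                               quadratic = c("slope", "ruggedness", "shrub"),
                               log_distance = c("dist_road", "dist_path"),
                               log_offset = 1) {
  samples <- tibble::as_tibble(samples)
  if (!"log_prob" %in% names(samples)) {
    if (!"prob" %in% names(samples)) {
      stop("samples need a 'log_prob' or 'prob' column", call. = FALSE)
    }
    samples$log_prob <- log(samples$prob)
  }
  if (length(unique(samples$animal_id)) < 2) {
    stop("at least two animals are required for the random intercept",
         call. = FALSE)
  }
  terms <- character(0)
  for (nm in linear) terms <- c(terms, nm)
  for (nm in quadratic) terms <- c(terms, sprintf("I(%s^2)", nm))
  for (nm in log_distance) {
    lnm <- paste0("log_", nm)
    samples[[lnm]] <- log(samples[[nm]] + log_offset)
    terms <- c(terms, lnm)
  }
  fixed_formula <- paste("log_prob ~", paste(terms, collapse = " + "))
  fml <- stats::as.formula(paste(fixed_formula, "+ (1 | animal_id)"))
  fit <- suppressMessages(lme4::lmer(fml, data = samples, REML = TRUE))
  singular <- lme4::isSingular(fit)
  if (singular) {
    warning("random-intercept fit is singular; refitting without it",
            call. = FALSE)
    fit <- stats::lm(stats::as.formula(fixed_formula), data = samples)
    est <- stats::coef(fit)
    se <- sqrt(diag(stats::vcov(fit)))
  } else {
    est <- lme4::fixef(fit)
    se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  }
  z <- est / se
  coefs <- tibble::tibble(term = names(est), estimate = as.numeric(est),
                          std_error = as.numeric(se),
                          statistic = as.numeric(z),
                          p_value = 2 * stats::pnorm(-abs(as.numeric(z))))
  structure(list(fit = fit, coefficients = coefs, singular = singular,
                 linear = linear, quadratic = quadratic,
                 log_distance = log_distance, log_offset = log_offset),
            class = "gs_movement_model")
}

#' @export
print.gs_movement_model <- function(x, ...) {
  cat("<gs_movement_model>", if (x$singular) "(no random intercept; singular)",
      "\n")
  print(x$coefficients)
  invisible(x)
}

#' @rdname fit_movement_model
#' @param x A `gs_movement_model`.
#' @param ... Unused.
#' @export
tidy.gs_movement_model <- function(x, ...) x$coefficients

#' @rdname fit_movement_model
#' @export
glance.gs_movement_model <- function(x, ...) {
  tibble::tibble(singular = x$singular,
                 n_terms = nrow(x$coefficients),
                 sigma = stats::sigma(x$fit))
}

#' Predict the movement surface over a landscape
#'
#' Fixed-effects linear predictor, exponentiated and min-max rescaled to
#' \[0, 1\]. Cells with impervious surface above the cutoff (or flagged in
#' a water mask) are set to missing — barriers to movement.
#'
#' @param model A `gs_movement_model`.
#' @param stack A `gs_stack` at the movement resolution containing the
#'   covariate layers (`slope`, `ruggedness`, `tpi`, `shrub`,
#'   `suitability`, `dist_road`, `dist_path` under the default structure).
#' @param impervious Optional `gs_raster` of impervious fraction.
#' @param impervious_cutoff Masking threshold (default 0.20).
#' @return A `gs_raster` in \[0, 1\] with masked cells missing.
#' @export
predict_movement <- function(model, stack, impervious = NULL,
                             impervious_cutoff = 0.20) {
  tab <- stack_table(stack)
  for (nm in model$log_distance) {
    tab[[paste0("log_", nm)]] <- log(tab[[nm]] + model$log_offset)
  }
  fe <- model$coefficients
  eta <- rep(fe$estimate[fe$term == "(Intercept)"], nrow(tab))
  for (i in seq_len(nrow(fe))) {
    term <- fe$term[i]
    if (term == "(Intercept)") next
    if (grepl("^I\\(.*\\^2\\)$", term)) {
      nm <- sub("^I\\((.*)\\^2\\)$", "\\1", term)
      eta <- eta + fe$estimate[i] * tab[[nm]]^2
    } else {
      eta <- eta + fe$estimate[i] * tab[[term]]
    }
  }
  p <- exp(eta - max(eta, na.rm = TRUE))  # overflow-safe; rescaled anyway
  rng <- range(p, na.rm = TRUE)
  p <- if (rng[2] > rng[1]) (p - rng[1]) / (rng[2] - rng[1]) else p * 0 + 1
  m <- matrix(p, stack$grid$n_rows, stack$grid$n_cols)
  if (!is.null(impervious)) {
    stop_if_grid_mismatch(stack$grid, impervious$grid, "impervious layer")
    m[impervious$values > impervious_cutoff] <- NA_real_
  }
  raster_layer(stack$grid, m, "movement")
}

#' Percentile of holdout telemetry under a movement prediction
#'
#' The empirical percentile of the mean predicted value at holdout points
#' among all predicted cells — the validation used for an independent
#' telemetry site. A constant prediction returns 1 with
#' `attr(, "degenerate") = TRUE`.
#'
#' @param prediction A `gs_raster`.
#' @param holdout_points Tibble (`x`, `y`).
#' @return Percentile in \[0, 1\].
#' @export
validate_percentile <- function(prediction, holdout_points) {
  hv <- extract_values(prediction, holdout_points$x, holdout_points$y)
  m <- mean(hv, na.rm = TRUE)
  vals <- prediction$values[!is.na(prediction$values)]
  out <- mean(vals <= m)
  if (min(vals) == max(vals)) attr(out, "degenerate") <- TRUE
  out
}
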