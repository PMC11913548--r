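# Ensemble species distribution modeling: covariate screening, the four
# learner backends behind one fit/predict contract, cross-validation with
# fresh pseudo-absence draws, candidate selection at the per-algorithm
# median AUC, and TSS-weighted ensemble prediction with a standard-error
# layer.

#' Specify a learner
#'
#' @param algorithm One of `"rf"` (random forest), `"gbm"` (gradient
#'   boosted trees), `"gam"` (generalized additive model), `"maxent"`
#'   (L1-regularized logistic model on linear + quadratic features against
#'   a uniform background — the standard MaxEnt equivalence).
#' @param hyperparameters Named list of backend options.
#' @return A `gs_learner_spec`.
#' @export
learner_spec <- function(algorithm = c("rf", "gbm", "gam", "maxent"),
                         hyperparameters = list()) {
  algorithm <- match.arg(algorithm)
  supports_weights <- algorithm %in% c("gbm", "gam", "maxent")
  structure(list(algorithm = algorithm, hyperparameters = hyperparameters,
                 supports_weights = supports_weights),
            class = "gs_learner_spec")
}

#' The default four-algorithm ensemble
#'
#' @return Named list of `gs_learner_spec` objects.
#' @export
default_learner_specs <- function() {
  list(rf = learner_spec("rf"), gbm = learner_spec("gbm"),
       gam = learner_spec("gam"), maxent = learner_spec("maxent"))
}

#' Screen covariates for collinearity
#'
#' Greedy rule: while any retained pair has |r| at or above the cutoff,
#' drop the member of the worst (highest |r|) pair with the higher variance
#' inflation factor (ties drop the later-named member). Reports all
#' pairwise correlations and VIFs.
#'
#' @param stack A `gs_stack`.
#' @param points Presence + background tibble (`x`, `y`) supplying the
#'   values at which correlation is assessed.
#' @param cutoff Absolute-correlation cutoff (default 0.7).
#' @param covariates Candidate covariate names (default: the stack's SDM
#'   subset, else all layers).
#' @return List with `retained`, `dropped`, `correlations` (tibble of all
#'   pairs among the inputs), `vif` (final-model VIFs).
#' @export
screen_covariates <- function(stack, points, cutoff = 0.7, covariates = NULL) {
  covariates <- covariates %||% attr(stack, "sdm_covariates") %||%
    names(stack$layers)
  stopifnot(length(covariates) >= 2)
  vals <- stack_extract(stack, points, covariates)[, covariates, drop = FALSE]
  vals <- vals[stats::complete.cases(vals), , drop = FALSE]
  keep <- covariates[vapply(vals, function(v) stats::sd(v) > 0, logical(1))]
  cm <- suppressWarnings(stats::cor(vals[keep]))
  pairs <- which(upper.tri(cm), arr.ind = TRUE)
  cor_report <- tibble::tibble(a = keep[pairs[, 1]], b = keep[pairs[, 2]],
                               r = cm[pairs])
  vif_of <- function(nm, others) {
    if (!length(others)) return(1)
    fit <- stats::lm(stats::reformulate(others, response = nm), data = vals)
    # a perfectly collinear pair legitimately yields an R^2 of 1 here
    r2 <- suppressWarnings(summary(fit)$r.squared)
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }
  dropped <- character(0)
  repeat {
    cm <- suppressWarnings(stats::cor(vals[keep]))
    diag(cm) <- 0
    if (max(abs(cm)) < cutoff) break
    worst <- which(abs(cm) == max(abs(cm)), arr.ind = TRUE)[1, ]
    a <- keep[worst[1]]; b <- keep[worst[2]]
    vif_a <- vif_of(a, setdiff(keep, a))
    vif_b <- vif_of(b, setdiff(keep, b))
    drop_nm <- if (vif_a > vif_b) a else b
    dropped <- c(dropped, drop_nm)
    keep <- setdiff(keep, drop_nm)
    if (length(keep) < 2) break
  }
  vif_final <- tibble::tibble(
    covariate = keep,
    vif = vapply(keep, function(nm) vif_of(nm, setdiff(keep, nm)), numeric(1)))
  list(retained = keep, dropped = dropped, correlations = cor_report,
       vif = vif_final)
}

#' Fit a learner to presence/background features
#'
#' @param spec A `gs_learner_spec`.
#' @param features Data frame of covariate values (one column per
#'   covariate, numeric).
#' @param labels 0/1 vector (1 = presence).
#' @param weights Optional case weights; silently ignored by backends that
#'   do not accept them (currently the random forest).
#' @param seed Integer seed; refitting with the same seed reproduces
#'   predictions exactly.
#' @return A `gs_learner` model handle.
#' @export
fit_learner <- function(spec, features, labels, weights = NULL, seed = 1) {
  stopifnot(inherits(spec, "gs_learner_spec"))
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2) {
    stop("single-class input: both presence and background labels required",
         call. = FALSE)
  }
  features <- as.data.frame(features)
  hp <- spec$hyperparameters
  set.seed(seed)
  fit <- switch(
    spec$algorithm,
    rf = suppressWarnings(randomForest::randomForest(
      # regression-mode forest on the 0/1 response: the standard
      # presence-background choice, giving smoother probability surfaces
      # than classification votes; large terminal nodes aid calibration
      x = features, y = as.numeric(labels),
      ntree = hp$ntree %||% 1000, nodesize = hp$nodesize %||% 40)),
    gbm = xgboost::xgb.train(
      params = list(objective = "binary:logistic",
                    max_depth = hp$max_depth %||% 2,
                    eta = hp$eta %||% 0.05,
                    subsample = hp$subsample %||% 0.5,
                    min_child_weight = hp$min_child_weight %||% 10,
                    nthread = 1),
      data = xgboost::xgb.DMatrix(as.matrix(features), label = labels,
                                  weight = weights, nthread = 1),
      nrounds = hp$nrounds %||% 300, verbose = 0),
    gam = {
      k <- hp$k %||% 5
      terms <- vapply(names(features), function(nm) {
        if (length(unique(features[[nm]])) <= k + 1) nm
        else sprintf("s(%s, k = %d)", nm, k)
      }, character(1))
      dat <- cbind(.label = labels, features)
      if (!is.null(weights)) dat$.w <- weights else dat$.w <- 1
      mgcv::gam(stats::as.formula(paste(".label ~", paste(terms, collapse = " + "))),
                family = stats::binomial(), data = dat, weights = .w,
                method = "REML")
    },
    maxent = {
      ctr <- vapply(features, mean, numeric(1))
      scl <- vapply(features, stats::sd, numeric(1))
      scl[scl == 0] <- 1
      z <- scale(as.matrix(features), center = ctr, scale = scl)
      x <- cbind(z, z^2)
      colnames(x) <- c(names(features), paste0(names(features), "_sq"))
      path <- glmnet::glmnet(x, labels, family = "binomial", alpha = 1,
                             nlambda = hp$nlambda %||% 50,
                             weights = weights)
      # AIC-style choice along the path: deviance + 2 * df
      dev <- (1 - path$dev.ratio) * path$nulldev
      lam <- path$lambda[which.min(dev + 2 * path$df)]
      list(path = path, lambda = lam, center = ctr, scale = scl)
    })
  structure(list(spec = spec, fit = fit, feature_names = names(features),
                 seed = seed),
            class = "gs_learner")
}

#' Predict habitat-suitability scores from a fitted learner
#'
#' @param model A `gs_learner`.
#' @param features Data frame with the training covariate columns.
#' @return Numeric scores in \[0, 1\].
#' @export
predict_learner <- function(model, features) {
  features <- as.data.frame(features)[, model$feature_names, drop = FALSE]
  switch(
    model$spec$algorithm,
    rf = pmin(pmax(as.numeric(stats::predict(model$fit,
                                             newdata = features)), 0), 1),
    gbm = as.numeric(stats::predict(
      model$fit, xgboost::xgb.DMatrix(as.matrix(features), nthread = 1))),
    gam = as.numeric(stats::predict(model$fit, newdata = features,
                                    type = "response")),
    maxent = {
      z <- scale(as.matrix(features), center = model$fit$center,
                 scale = model$fit$scale)
      x <- cbind(z, z^2)
      as.numeric(stats::predict(model$fit$path, newx = x,
                                s = model$fit$lambda, type = "response"))
    })
}

# Uniform background cells for the MaxEnt-family learner (up to
# `n_background`, fewer on small landscapes), drawn over valid cells.
maxent_background <- function(stack, covariates, n_background = 10000,
                              seed = 1) {
  tab <- stack_table(stack, covariates)
  tab <- tab[stats::complete.cases(tab[covariates]), , drop = FALSE]
  set.seed(seed)
  n <- min(n_background, nrow(tab))
  tab[sample.int(nrow(tab), n), covariates, drop = FALSE]
}

#' Cross-validate the learner ensemble
#'
#' Per iteration: withhold a random `cv_test_fraction` of the presences
#' (without replacement), draw fresh pseudo-absences (equal to the training
#' presence count, plus a test draw equal to the withheld count), fit every
#' algorithm on the training split, and evaluate AUC, TSS (at each model's
#' own max sens + spec threshold) and the continuous Boyce index on the
#' withheld data. The MaxEnt-family learner is fit against its own uniform
#' background rather than the envelope pseudo-absences. A separate
#' `importance_iterations`-fold 80/20 pass is tagged `pass = "importance"`.
#'
#' @param specs Named list of `gs_learner_spec` (default the four-algorithm
#'   set).
#' @param presences Thinned presence tibble (`x`, `y`).
#' @param stack A `gs_stack`.
#' @param bias Effort bias `gs_raster`.
#' @param config A `gs_config`.
#' @param covariates Retained covariate names (default: screened
#'   automatically).
#' @param include_importance_pass Whether to run the extra 80/20 pass.
#' @return A `gs_cv` tibble: `pass`, `algorithm`, `iteration`, `auc`,
#'   `tss`, `boyce`, `threshold`, `model` (list), `test_idx` (list).
#' @export
cross_validate <- function(specs = default_learner_specs(), presences, stack,
                           bias, config = pipeline_config(),
                           covariates = NULL,
                           include_importance_pass = FALSE) {
  covariates <- covariates %||% attr(stack, "sdm_covariates") %||%
    names(stack$layers)
  n_pres <- nrow(presences)
  stopifnot(n_pres >= 5)
  cell_tab <- stack_table(stack, covariates)
  cell_ok <- stats::complete.cases(cell_tab[covariates])
  cell_feats <- cell_tab[cell_ok, covariates, drop = FALSE]
  pres_feats <- stack_extract(stack, presences, covariates)
  passes <- tibble::tibble(pass = "cv", n_iter = config$cv_iterations)
  if (include_importance_pass) {
    passes <- dplyr::bind_rows(passes,
      tibble::tibble(pass = "importance", n_iter = config$importance_iterations))
  }
  records <- list()
  for (p in seq_len(nrow(passes))) {
    for (iter in seq_len(passes$n_iter[p])) {
      seed_i <- config$random_seed + 1000L * p + iter
      set.seed(seed_i)
      n_test <- max(1L, round(config$cv_test_fraction * n_pres))
      test_idx <- sort(sample.int(n_pres, n_test))
      train_idx <- setdiff(seq_len(n_pres), test_idx)
      env <- fit_bioclim(presences[train_idx, ], stack)
      pa_train <- sample_pseudoabsences(
        env, stack, bias, n = length(train_idx),
        threshold = config$pseudoabsence_envelope_threshold, seed = seed_i)
      pa_test <- sample_pseudoabsences(
        env, stack, bias, n = n_test,
        threshold = config$pseudoabsence_envelope_threshold,
        seed = seed_i + 500000L)
      pa_train_feats <- stack_extract(stack, pa_train, covariates)
      pa_test_feats <- stack_extract(stack, pa_test, covariates)
      bg_max <- maxent_background(stack, covariates, seed = seed_i)
      for (alg in names(specs)) {
        if (specs[[alg]]$algorithm == "maxent") {
          feats <- rbind(pres_feats[train_idx, covariates, drop = FALSE], bg_max)
          labels <- c(rep(1L, length(train_idx)), rep(0L, nrow(bg_max)))
          wts <- NULL
        } else {
          feats <- rbind(pres_feats[train_idx, covariates, drop = FALSE],
                         pa_train_feats[, covariates, drop = FALSE])
          labels <- c(rep(1L, length(train_idx)), rep(0L, nrow(pa_train)))
          wts <- if (specs[[alg]]$supports_weights) {
            c(rep(1, length(train_idx)), pa_train$weight)
          } else NULL
        }
        ok <- stats::complete.cases(feats)
        model <- fit_learner(specs[[alg]], feats[ok, , drop = FALSE],
                             labels[ok], weights = wts[ok], seed = seed_i)
        sc_test <- predict_learner(model,
                                   pres_feats[test_idx, covariates, drop = FALSE])
        sc_bg <- predict_learner(model, pa_test_feats[, covariates, drop = FALSE])
        sc_cells <- predict_learner(model, cell_feats)
        thr <- find_threshold_maxss(sc_test, sc_bg)
        bi <- continuous_boyce(sc_test, sc_cells)$boyce
        records[[length(records) + 1L]] <- tibble::tibble(
          pass = passes$pass[p], algorithm = alg, iteration = iter,
          auc = auc(sc_test, sc_bg),
          tss = tss(sc_test, sc_bg, as.numeric(thr)),
          boyce = bi, threshold = as.numeric(thr),
          model = list(model), test_idx = list(test_idx))
      }
    }
  }
  out <- dplyr::bind_rows(records)
  class(out) <- c("gs_cv", class(out))
  out
}

#' Select candidate models above the per-algorithm median AUC
#'
#' Within each algorithm, fitted models whose AUC strictly exceeds that
#' algorithm's median AUC are kept; ties at the median are excluded. A
#' single record is kept as-is; when every AUC ties (so nothing survives)
#' the algorithm falls back to keeping all its records, with a warning.
#'
#' @param cv_records A `gs_cv` tibble (the `pass == "cv"` rows are used).
#' @return The selected subset of `cv_records`.
#' @export
select_candidates <- function(cv_records) {
  recs <- dplyr::filter(cv_records, .data$pass == "cv")
  out <- recs |>
    dplyr::group_by(.data$algorithm) |>
    dplyr::group_modify(function(d, key) {
      if (nrow(d) == 1) return(d)
      keep <- d$auc > stats::median(d$auc)
      if (!any(keep)) {
        warning("all AUC scores tie at the median for algorithm '",
                key$algorithm, "'; keeping all its models", call. = FALSE)
        return(d)
      }
      d[keep, , drop = FALSE]
    }) |>
    dplyr::ungroup()
  class(out) <- c("gs_cv", class(out))
  out
}

#' Combine member predictions into a TSS-weighted mean and SE
#'
#' The mean is the TSS-weighted average (negative TSS clipped to zero
#' before normalizing); the standard error is the unweighted standard
#' deviation across members divided by the square root of the member
#' count.
#'
#' @param pred_matrix Numeric matrix, one column per member model.
#' @param tss_weights Per-member TSS scores.
#' @return List with `mean` and `se` vectors.
#' @export
weighted_ensemble <- function(pred_matrix, tss_weights) {
  w <- pmax(tss_weights, 0)
  if (sum(w) == 0) w <- rep(1, length(w))
  w <- w / sum(w)
  k <- ncol(pred_matrix)
  mean_v <- as.numeric(pred_matrix %*% w)
  se_v <- if (k > 1) apply(pred_matrix, 1, stats::sd) / sqrt(k) else
    rep(0, nrow(pred_matrix))
  list(mean = mean_v, se = se_v)
}

#' Fit the full ensemble habitat model
#'
#' Screens covariates, cross-validates the four algorithms with fresh
#' pseudo-absence draws, selects candidates above each algorithm's median
#' AUC, forms per-algorithm TSS-weighted ensembles, combines the algorithm
#' ensembles with weights proportional to their mean TSS, and sets the
#' binary threshold at the maximum of summed sensitivity and specificity of
#' the ensemble prediction.
#'
#' @inheritParams cross_validate
#' @return A `gs_ensemble`: `candidates` (selected `gs_cv` rows),
#'   `algorithm_weights`, `threshold`, `covariates`, `screening`,
#'   `training_ranges`, `cv` (all records), `config`.
#' @export
fit_ensemble_sdm <- function(presences, stack, bias,
                             config = pipeline_config(),
                             specs = default_learner_specs(),
                             covariates = NULL) {
  if (is.null(covariates)) {
    env0 <- fit_bioclim(presences, stack)
    pa0 <- sample_pseudoabsences(env0, stack, bias, n = nrow(presences),
                                 threshold = config$pseudoabsence_envelope_threshold,
                                 seed = config$random_seed)
    screening <- screen_covariates(stack, dplyr::bind_rows(
      presences[c("x", "y")], pa0[c("x", "y")]),
      cutoff = config$correlation_cutoff)
    covariates <- screening$retained
  } else {
    screening <- NULL
  }
  cv <- cross_validate(specs, presences, stack, bias, config, covariates)
  cand <- select_candidates(cv)
  alg_w <- cand |>
    dplyr::group_by(.data$algorithm) |>
    dplyr::summarise(weight = mean(pmax(.data$tss, 0)), .groups = "drop") |>
    dplyr::mutate(weight = if (sum(.data$weight) > 0) {
      .data$weight / sum(.data$weight)
    } else rep(1 / dplyr::n(), dplyr::n()))
  ens <- structure(
    list(candidates = cand, algorithm_weights = alg_w, threshold = NA_real_,
         covariates = covariates, screening = screening,
         training_ranges = stack$ranges[stack$ranges$covariate %in% covariates, ],
         cv = cv, config = config),
    class = "gs_ensemble")
  # threshold from the ensemble prediction at presences vs a final
  # pseudo-absence draw
  pred <- ensemble_predict(ens, stack)
  pres_scores <- extract_values(pred$mean, presences$x, presences$y)
  env_f <- fit_bioclim(presences, stack)
  pa_f <- sample_pseudoabsences(env_f, stack, bias, n = nrow(presences),
                                threshold = config$pseudoabsence_envelope_threshold,
                                seed = config$random_seed + 999983L)
  bg_scores <- extract_values(pred$mean, pa_f$x, pa_f$y)
  ok_p <- !is.na(pres_scores); ok_b <- !is.na(bg_scores)
  ens$threshold <- as.numeric(find_threshold_maxss(pres_scores[ok_p],
                                                   bg_scores[ok_b]))
  ens
}

#' @export
print.gs_ensemble <- function(x, ...) {
  cat(sprintf("<gs_ensemble> %d candidate models over %d algorithms; tau = %.3f\n",
              nrow(x$candidates), nrow(x$algorithm_weights), x$threshold))
  invisible(x)
}

#' Predict ensemble suitability over a covariate stack
#'
#' Per cell: each algorithm's candidates are combined by TSS weights, the
#' algorithm means are combined by the algorithm weights, and the standard
#' error is the unweighted standard deviation across all candidate models
#' divided by the square root of their count. When the ensemble's threshold
#' is set, a binary layer (`mean >= tau`) is included.
#'
#' @param ensemble A `gs_ensemble`.
#' @param stack A `gs_stack` holding the ensemble covariates (current or
#'   future climate).
#' @return List of `gs_raster`s: `mean`, `se`, and `binary` (if the
#'   threshold is set).
#' @export
ensemble_predict <- function(ensemble, stack) {
  covs <- ensemble$covariates
  tab <- stack_table(stack, covs)
  ok <- stats::complete.cases(tab[covs])
  feats <- tab[ok, covs, drop = FALSE]
  cand <- ensemble$candidates
  preds <- vapply(cand$model, function(m) predict_learner(m, feats),
                  numeric(nrow(feats)))
  if (is.null(dim(preds))) preds <- matrix(preds, ncol = nrow(cand))
  # within-algorithm TSS weighting, then across-algorithm weights
  mean_ok <- numeric(nrow(feats))
  for (i in seq_len(nrow(ensemble$algorithm_weights))) {
    alg <- ensemble$algorithm_weights$algorithm[i]
    w_alg <- ensemble$algorithm_weights$weight[i]
    cols <- which(cand$algorithm == alg)
    comb <- weighted_ensemble(preds[, cols, drop = FALSE], cand$tss[cols])
    mean_ok <- mean_ok + w_alg * comb$mean
  }
  k <- ncol(preds)
  se_ok <- if (k > 1) apply(preds, 1, stats::sd) / sqrt(k) else
    rep(0, nrow(feats))
  g <- stack$grid
  to_raster <- function(v, nm) {
    full <- rep(NA_real_, g$n_rows * g$n_cols)
    full[ok] <- v
    raster_layer(g, matrix(full, g$n_rows, g$n_cols), nm)
  }
  out <- list(mean = to_raster(mean_ok, "suitability"),
              se = to_raster(se_ok, "suitability_se"))
  if (!is.na(ensemble$threshold)) {
    out$binary <- to_raster(as.numeric(mean_ok >= ensemble$threshold),
                            "suitable")
  }
  out
}

#' Evaluate scored predictions against presences and background
#'
#' @param prediction A `gs_raster` of suitability scores.
#' @param presences,background Point tibbles (`x`, `y`).
#' @param threshold Classification threshold (default: max sens + spec of
#'   the supplied data).
#' @return One-row tibble: `auc`, `tss`, `boyce`, `sorensen`, `threshold`.
#' @export
evaluate_prediction <- function(prediction, presences, background,
                                threshold = NULL) {
  ps <- extract_values(prediction, presences$x, presences$y)
  bs <- extract_values(prediction, background$x, background$y)
  ps <- ps[!is.na(ps)]; bs <- bs[!is.na(bs)]
  thr <- threshold %||% as.numeric(find_threshold_maxss(ps, bs))
  tibble::tibble(
    auc = auc(ps, bs),
    tss = tss(ps, bs, thr),
    boyce = continuous_boyce(ps, as.vector(prediction$values))$boyce,
    sorensen = sorensen_index(ps, bs, thr),
    threshold = thr)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the candidate models of an ensemble
#'
#' @param x A `gs_ensemble`.
#' @param ... Unused.
#' @return Tibble with one row per candidate model: `algorithm`,
#'   `iteration`, `auc`, `tss`, `boyce`, `algorithm_weight`.
#' @export
tidy.gs_ensemble <- function(x, ...) {
  dplyr::left_join(
    dplyr::select(tibble::as_tibble(x$candidates), "algorithm", "iteration",
                  "auc", "tss", "boyce"),
    dplyr::rename(x$algorithm_weights, algorithm_weight = "weight"),
    by = "algorithm")
}

#' One-row ensemble summary
#'
#' @param x A `gs_ensemble`.
#' @param ... Unused.
#' @return Tibble: candidate count, threshold, mean CV metrics.
#' @export
glance.gs_ensemble <- function(x, ...) {
  tibble::tibble(
    n_candidates = nrow(x$candidates),
    n_algorithms = nrow(x$algorithm_weights),
    threshold = x$threshold,
    mean_auc = mean(x$candidates$auc),
    mean_tss = mean(x$candidates$tss),
    mean_boyce = mean(x$candidates$boyce, na.rm = TRUE))
}

#' Per-algorithm CV metric report
#'
#' Averages the evaluation metrics over cross-validation iterations, one
#' row per algorithm — the layout of a model-diagnostics table.
#'
#' @param cv_records A `gs_cv` tibble.
#' @return Tibble: `algorithm`, `auc`, `boyce`, `tss` (means over
#'   iterations).
#' @export
cv_metric_report <- function(cv_records) {
  cv_records |>
    dplyr::filter(.data$pass == "cv") |>
    dplyr::group_by(.data$algorithm) |>
    dplyr::summarise(auc = mean(.data$auc), boyce = mean(.data$boyce, na.rm = TRUE),
                     tss = mean(.data$tss), .groups = "drop")
}
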