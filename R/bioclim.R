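#' Fit a Bioclim climate envelope to presence covariate values
#'
#' Stores the empirical CDF of presence values for each covariate. The
#' envelope scores how central a location's climate is among the presences:
#' by default only the two climate covariates define it (it is a climate
#' envelope), configurable to any subset.
#'
#' @param presences Presence tibble (`x`, `y`).
#' @param stack A `gs_stack`.
#' @param covariates Covariate names for the envelope (default
#'   `c("spring_temp", "winter_precip")`).
#' @return A `gs_bioclim` with per-covariate sorted presence values.
#' @export
fit_bioclim <- function(presences, stack,
                        covariates = c("spring_temp", "winter_precip")) {
  stopifnot(all(covariates %in% names(stack$layers)))
  if (nrow(presences) < 20) {
    warning("fewer than 20 presences; envelope will be coarse", call. = FALSE)
  }
  vals <- stack_extract(stack, presences, covariates)
  samples <- lapply(covariates, function(nm) sort(vals[[nm]][!is.na(vals[[nm]])]))
  names(samples) <- covariates
  if (any(lengths(samples) == 0)) {
    stop("no presence falls on valid cells for some covariate", call. = FALSE)
  }
  structure(list(covariates = covariates, samples = samples),
            class = "gs_bioclim")
}

# Empirical CDF with the <= convention: F(x) = mean(sample <= x).
ecdf_leq <- function(sample, x) {
  findInterval(x, sample) / length(sample)
}

#' Score locations under a Bioclim envelope
#'
#' Per covariate, the tail score is `2 * min(F(x), 1 - F(x))` with `F` the
#' presence ECDF (<= convention); the overall score is the minimum across
#' covariates. A location at the presence median of every covariate scores
#' 1; one beyond all presence values in any covariate scores 0.
#'
#' @param envelope A `gs_bioclim`.
#' @param point_covariates Data frame with one column per envelope
#'   covariate.
#' @return Numeric score vector in \[0, 1\].
#' @export
bioclim_score <- function(envelope, point_covariates) {
  miss <- setdiff(envelope$covariates, names(point_covariates))
  if (length(miss)) {
    stop("missing covariate column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  scores <- rep(1, nrow(point_covariates))
  for (nm in envelope$covariates) {
    f <- ecdf_leq(envelope$samples[[nm]], point_covariates[[nm]])
    s <- 2 * pmin(f, 1 - f)
    # exactly at a degenerate (all-equal) sample value: central, score 1
    degenerate <- length(unique(envelope$samples[[nm]])) == 1
    if (degenerate) {
      s <- ifelse(point_covariates[[nm]] == envelope$samples[[nm]][1], 1, 0)
    }
    s[is.na(point_covariates[[nm]])] <- NA_real_
    scores <- pmin(scores, s)
  }
  scores
}

#' Score an entire stack under a Bioclim envelope
#'
#' @param envelope A `gs_bioclim`.
#' @param stack A `gs_stack` containing the envelope covariates.
#' @return A `gs_raster` of envelope scores.
#' @export
bioclim_score_raster <- function(envelope, stack) {
  tab <- stack_table(stack, envelope$covariates)
  s <- bioclim_score(envelope, tab)
  raster_layer(stack$grid, matrix(s, stack$grid$n_rows, stack$grid$n_cols),
               "bioclim_score")
}

#' Draw effort-weighted pseudo-absences outside the climate envelope
#'
#' Candidate cells are those scoring below the envelope threshold (default
#' 0.05) — locations outside the species' general climate envelope. `n`
#' cells (by default the presence count, giving equal class sizes) are
#' drawn without replacement with selection probability proportional to the
#' sampling-effort bias raster, so pseudo-absences concentrate where
#' effort indicates the species would have been reported had it been
#' present. The bias value is returned as a `weight` column and is also
#' forwarded as a case weight to learners that accept one.
#'
#' @param envelope A `gs_bioclim`.
#' @param stack A `gs_stack`.
#' @param bias A `gs_raster` of effort weights in (0, 1].
#' @param n Number of pseudo-absences.
#' @param threshold Envelope score below which a cell is a candidate.
#' @param seed Integer seed.
#' @return Tibble with `x`, `y`, `score`, `weight`.
#' @export
sample_pseudoabsences <- function(envelope, stack, bias, n, threshold = 0.05,
                                  seed = 1) {
  stop_if_grid_mismatch(stack$grid, bias$grid, "bias raster")
  sc <- bioclim_score_raster(envelope, stack)
  w <- as.vector(bias$values)
  s <- as.vector(sc$values)
  cand <- which(!is.na(s) & s < threshold & !is.na(w))
  if (length(cand) < n) {
    stop("only ", length(cand), " cells score below the envelope threshold; ",
         n, " pseudo-absences requested", call. = FALSE)
  }
  set.seed(seed)
  drawn <- sample(cand, n, prob = w[cand])
  g <- stack$grid
  row <- ((drawn - 1L) %% g$n_rows) + 1L
  col <- ((drawn - 1L) %/% g$n_rows) + 1L
  ctr <- xy_from_cells(g, row, col)
  tibble::tibble(x = ctr$x, y = ctr$y, score = s[drawn], weight = w[drawn])
}
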