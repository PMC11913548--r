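# Shared fixtures, built in code and cached per test session.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, builder(), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

small_grid <- function(n_rows = 10, n_cols = 10, cell_size = 250,
                       origin_x = 0, origin_y = n_rows * cell_size) {
  raster_grid(origin_x, origin_y, cell_size, n_rows, n_cols)
}

# A 60x60 landscape shared by several test files.
test_landscape <- function() {
  fixture("landscape60", function() {
    g <- raster_grid(0, 15000, 250, 60, 60)
    st <- make_landscape(g, seed = 101)
    truth <- truth_params()
    suit <- true_suitability(st, truth)
    list(grid = g, stack = st, truth = truth, suitability = suit)
  })
}

# Occurrences + effort + prep products on the shared landscape.
test_prep <- function() {
  fixture("prep60", function() {
    L <- test_landscape()
    occ <- sample_occurrences(L$suitability, L$stack[["effort"]], 600, seed = 11)
    eff <- sample_occurrences(L$suitability, L$stack[["effort"]], 300, seed = 12)
    prep <- prep_occurrences(occ, eff, L$grid,
                             pipeline_config(random_seed = 13))
    c(L, list(occurrences = occ, effort_points = eff), prep)
  })
}

# A small fitted ensemble plus movement/impervious layers shared by the
# projection-series tests.
projection_fixture <- function() {
  fixture("proj_ens", function() {
    P <- test_prep()
    cfg <- pipeline_config(cv_iterations = 3, random_seed = 5)
    ens <- fit_ensemble_sdm(P$presences, P$stack, P$bias, cfg)
    pref <- true_movement_preference(P$stack, P$truth, P$suitability)
    prot <- make_protection_and_impervious(P$grid, seed = 8)
    c(P, list(ensemble = ens, preference = pref,
              impervious = prot$impervious, protection = prot))
  })
}

# Brute-force Gaussian-kernel-density oracle at probe locations.
kde_oracle <- function(points, bw, probe_x, probe_y) {
  vapply(seq_along(probe_x), function(i) {
    mean(stats::dnorm(probe_x[i], points$x, bw[1]) *
           stats::dnorm(probe_y[i], points$y, bw[2]))
  }, numeric(1))
}

# Exhaustive pair-counting AUC oracle.
auc_oracle <- function(pos, neg) {
  wins <- 0
  for (p in pos) for (n in neg) {
    wins <- wins + (p > n) + 0.5 * (p == n)
  }
  wins / (length(pos) * length(neg))
}

# Brute-force occupiable update on logical matrices: all-pairs
# center-to-center distances.
occupiable_oracle <- function(O_prev, S, mv, cutoff, imp, imp_cutoff,
                              radius_m, cell_size) {
  nr <- nrow(S); nc <- ncol(S)
  N <- S & !O_prev
  R <- matrix(FALSE, nr, nc)
  prev_idx <- which(O_prev, arr.ind = TRUE)
  if (nrow(prev_idx) > 0) {
    for (k in which(N)) {
      r <- ((k - 1) %% nr) + 1; c <- ((k - 1) %/% nr) + 1
      d2 <- (prev_idx[, 1] - r)^2 + (prev_idx[, 2] - c)^2
      if (min(d2) * cell_size^2 <= radius_m^2 &&
          mv[r, c] >= cutoff && imp[r, c] <= imp_cutoff) {
        R[r, c] <- TRUE
      }
    }
  }
  list(N = N, R = R, O = (O_prev & S) | R)
}

random_logical <- function(nr, nc, p) {
  matrix(stats::runif(nr * nc) < p, nr, nc)
}
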