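# Evaluation statistics for presence/background prediction: ROC area,
# True Skill Statistic, Sorensen similarity, the continuous Boyce index
# with its predicted/expected curve, and the max(sens + spec) threshold.
# Classification convention throughout: score >= threshold is "presence".

#' Area under the ROC curve (Mann-Whitney form)
#'
#' Probability that a random presence scores above a random background
#' point, ties counted one half.
#'
#' @param presence_scores,background_scores Numeric score vectors.
#' @return AUC in \[0, 1\].
#' @export
auc <- function(presence_scores, background_scores) {
  n1 <- length(presence_scores); n2 <- length(background_scores)
  if (n1 == 0 || n2 == 0) stop("both score vectors must be non-empty", call. = FALSE)
  r <- rank(c(presence_scores, background_scores))
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

#' True Skill Statistic at a threshold
#'
#' Sensitivity + specificity - 1, with scores at or above the threshold
#' classified as presence.
#'
#' @inheritParams auc
#' @param threshold Classification threshold.
#' @return TSS in \[-1, 1\].
#' @export
tss <- function(presence_scores, background_scores, threshold) {
  sens <- mean(presence_scores >= threshold)
  spec <- mean(background_scores < threshold)
  sens + spec - 1
}

#' Sorensen similarity index at a threshold
#'
#' `2 TP / (2 TP + FN + FP)`: presence-oriented F-measure robust to unknown
#' prevalence when only pseudo-absences are available.
#'
#' @inheritParams tss
#' @return Index in \[0, 1\].
#' @export
sorensen_index <- function(presence_scores, background_scores, threshold) {
  tp <- sum(presence_scores >= threshold)
  fn <- sum(presence_scores < threshold)
  fp <- sum(background_scores >= threshold)
  denom <- 2 * tp + fn + fp
  if (denom == 0) return(0)
  2 * tp / denom
}

#' Threshold maximizing the sum of sensitivity and specificity
#'
#' Scans all unique observed scores; among tied maxima the lowest
#' candidate wins. When a strictly lower score exists, the midpoint of the
#' half-open interval it bounds is returned, so a perfectly separable
#' instance yields the gap midpoint. A fully degenerate instance (all
#' scores equal) returns that value with `attr(, "degenerate") = TRUE`.
#'
#' @inheritParams auc
#' @return The threshold, with attribute `ss` (achieved sens + spec).
#' @export
find_threshold_maxss <- function(presence_scores, background_scores) {
  all_scores <- sort(unique(c(presence_scores, background_scores)))
  if (length(all_scores) == 1) {
    out <- all_scores
    attr(out, "ss") <- tss(presence_scores, background_scores, out) + 1
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  ss <- vapply(all_scores, function(t) {
    mean(presence_scores >= t) + mean(background_scores < t)
  }, numeric(1))
  best <- all_scores[which.max(ss)]  # which.max takes the first (lowest) tie
  below <- all_scores[all_scores < best]
  tau <- if (length(below)) (max(below) + best) / 2 else best
  attr(tau, "ss") <- max(ss)
  tau
}

#' Continuous Boyce index and predicted/expected curve
#'
#' Slides a window of width `window_width` times the observed score range
#' across `n_windows` midpoints. In each window, P is the fraction of
#' presence scores inside and E the fraction of raster cells inside; the
#' P/E ratio (dropped where E = 0) against the window midpoint summarizes
#' calibration, and the Boyce index is their Spearman rank correlation. A
#' well-calibrated presence-only model has P/E increasing with suitability
#' (Boyce near 1); a random one has Boyce near 0. Invariant to monotone
#' transforms of the scores up to window discretization.
#'
#' @param presence_scores Scores at presence locations.
#' @param raster_scores Scores over all (valid) raster cells.
#' @param window_width Window width as a fraction of the score range.
#' @param n_windows Number of window midpoints.
#' @return List with `pe_curve` (tibble `midpoint`, `p`, `e`, `pe`) and
#'   `boyce` (Spearman correlation, `NA` if degenerate).
#' @export
continuous_boyce <- function(presence_scores, raster_scores,
                             window_width = 0.1, n_windows = 101) {
  raster_scores <- raster_scores[!is.na(raster_scores)]
  lo <- min(raster_scores); hi <- max(raster_scores)
  if (hi <= lo) {
    return(list(pe_curve = tibble::tibble(midpoint = numeric(0),
                                          p = numeric(0), e = numeric(0),
                                          pe = numeric(0)),
                boyce = NA_real_))
  }
  w <- window_width * (hi - lo)
  mids <- seq(lo + w / 2, hi - w / 2, length.out = n_windows)
  p <- vapply(mids, function(m) {
    mean(presence_scores >= m - w / 2 & presence_scores <= m + w / 2)
  }, numeric(1))
  e <- vapply(mids, function(m) {
    mean(raster_scores >= m - w / 2 & raster_scores <= m + w / 2)
  }, numeric(1))
  keep <- e > 0 & is.finite(p)
  curve <- tibble::tibble(midpoint = mids[keep], p = p[keep], e = e[keep],
                          pe = p[keep] / e[keep])
  boyce <- if (nrow(curve) >= 3 && isTRUE(stats::sd(curve$pe) > 0)) {
    suppressWarnings(stats::cor(curve$pe, curve$midpoint, method = "spearman"))
  } else NA_real_
  list(pe_curve = curve, boyce = boyce)
}

#' Plot a predicted/expected calibration curve
#'
#' @param pe_curve The `pe_curve` tibble from [continuous_boyce()].
#' @return A ggplot object.
#' @export
plot_pe_curve <- function(pe_curve) {
  ggplot2::ggplot(pe_curve, ggplot2::aes(.data$midpoint, .data$pe)) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Suitability (window midpoint)",
                  y = "Predicted / expected ratio") +
    ggplot2::theme_minimal()
}
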