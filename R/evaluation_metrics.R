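#' Rank-based AUC
#'
#' Area under the ROC curve computed from the Mann-Whitney U statistic,
#' `AUC = U / (n_pos * n_neg)`, with tied scores counted one half.
#'
#' @param pos_scores,neg_scores non-empty numeric score vectors for the
#'   positive (presence) and negative (contrast) class.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(pos_scores, neg_scores) {
  if (length(pos_scores) == 0 || length(neg_scores) == 0)
    stop("both score vectors must be non-empty")
  np <- length(pos_scores); nn <- length(neg_scores)
  r <- rank(c(pos_scores, neg_scores))
  u <- sum(r[seq_len(np)]) - np * (np + 1) / 2
  u / (np * nn)
}

#' 10 percent omission rate
#'
#' The suitability threshold is the 10th percentile of the training
#' presence scores (linear interpolation); the omission rate is the
#' fraction of test presence scores strictly below that threshold.
#'
#' @param train_presence_scores at least 10 training presence scores.
#' @param test_presence_scores at least 1 test presence score.
#' @return omission rate in `[0, 1]`.
#' @export
omission_rate_10 <- function(train_presence_scores, test_presence_scores) {
  if (length(train_presence_scores) < 10)
    stop("need at least 10 training presence scores")
  if (length(test_presence_scores) < 1)
    stop("need at least 1 test presence score")
  thr <- stats::quantile(train_presence_scores, 0.10, names = FALSE)
  mean(test_presence_scores < thr)
}

# suitability values of a map at occurrence records (NA off-mask)
map_values_at <- function(map, occ) {
  r <- occ$y - map$origin[1] + 1L
  c_ <- occ$x - map$origin[2] + 1L
  d <- dim(map$values)
  ok <- r >= 1 & r <= d[1] & c_ >= 1 & c_ <= d[2]
  out <- rep(NA_real_, nrow(occ))
  out[ok] <- map$values[cbind(r[ok], c_[ok])]
  out
}

#' Partial ROC significance test
#'
#' Bootstrapped AUC-ratio test restricted to the low-omission region of
#' the ROC plot (omission of test points at most `E`). The x axis is the
#' fraction of valid cells predicted suitable at each threshold; per
#' iteration a fraction of the test points is resampled with
#' replacement, the ROC is evaluated exactly at the resampled test-score
#' thresholds, the partial area under the model's curve over the region
#' with sensitivity `>= 1 - E` is computed by trapezoids, and divided by
#' the analytic partial area of the uniform-score null (the diagonal)
#' over the same region, `(1 - x0^2) / 2` for boundary `x0` — so an
#' uninformative model scores 1 and a perfect one approaches 2. The
#' reported p-value is the fraction of iterations with ratio at most 1.
#'
#' @param map a [suit_map()].
#' @param test_points [occurrences()] with at least 10 records on valid
#'   cells.
#' @param E allowed omission (default 0.05).
#' @param iterations bootstrap iterations (default 500).
#' @param resample_frac fraction of test points resampled per iteration
#'   (default 0.5).
#' @param seed integer seed.
#' @return list with `ratio_mean` and `p`.
#' @export
partial_roc <- function(map, test_points, E = 0.05, iterations = 500,
                        resample_frac = 0.5, seed = 1) {
  stopifnot(E > 0, E < 1)
  s_test <- map_values_at(map, test_points)
  s_test <- s_test[!is.na(s_test)]
  if (length(s_test) < 10)
    stop("need at least 10 test points on valid cells")
  bg <- sort(map$values[map$mask])
  nbg <- length(bg)
  ymin <- 1 - E
  n <- length(s_test)
  m <- max(1L, round(resample_frac * n))
  ratios <- with_seed(derive_seed(seed, "partial_roc"), {
    vapply(seq_len(iterations), function(i) {
      ss <- sort(s_test[sample.int(n, m, replace = TRUE)])
      thr <- unique(ss)
      y <- (m - findInterval(thr, ss, left.open = TRUE)) / m
      x <- (nbg - findInterval(thr, bg, left.open = TRUE)) / nbg
      pa <- partial_auc_above(rev(x), rev(y), ymin)
      # diagonal (uniform-score null) over the same x-interval
      null_area <- (1 - pa$x0^2) / 2
      pa$area / null_area
    }, numeric(1))
  })
  list(ratio_mean = mean(ratios), p = mean(ratios <= 1))
}

# Trapezoidal integral of y dx over the part of the curve with y >= ymin,
# interpolating the boundary crossing. (x, y) must be sorted by x with
# y non-decreasing in x (both approach (1, 1)). Returns the area and the
# x at which the curve enters the region.
partial_auc_above <- function(x, y, ymin) {
  x <- c(0, x, 1); y <- c(0, y, 1)
  keep <- y >= ymin
  if (!any(keep)) return(list(area = 0, x0 = 1))
  first <- which(keep)[1]
  if (first > 1 && y[first] > ymin) {
    # interpolate the crossing point on the segment entering the region
    x0 <- x[first - 1]; x1 <- x[first]
    y0 <- y[first - 1]; y1 <- y[first]
    t <- (ymin - y0) / (y1 - y0)
    xs <- c(x0 + t * (x1 - x0), x[keep])
    ys <- c(ymin, y[keep])
  } else {
    xs <- x[keep]; ys <- y[keep]
  }
  list(area = sum(diff(xs) * (utils::head(ys, -1) + utils::tail(ys, -1)) / 2),
       x0 = xs[1])
}

#' Continuous Boyce Index
#'
#' Moving-window predicted-to-expected ratio curve: windows of width
#' `window_width_frac` times the map's observed suitability range slide
#' across that range (`n_windows` overlapping positions); in each
#' window, P is the fraction of evaluation points and E the fraction of
#' valid cells whose suitability falls inside. The index is the Spearman
#' correlation between P/E and the window midpoint, in `[-1, 1]`
#' (windows with zero expected fraction are skipped; at least 3 usable
#' windows are required). A positive index means higher-suitability
#' cells hold disproportionately many evaluation points.
#'
#' @param map a [suit_map()].
#' @param eval_points [occurrences()] with at least 10 records on valid
#'   cells.
#' @param n_windows number of window positions (default 101).
#' @param window_width_frac window width as a fraction of the observed
#'   suitability range (default 0.1).
#' @return the index, a single number in `[-1, 1]`.
#' @export
continuous_boyce <- function(map, eval_points, n_windows = 101,
                             window_width_frac = 0.1) {
  s_eval <- map_values_at(map, eval_points)
  s_eval <- s_eval[!is.na(s_eval)]
  if (length(s_eval) < 10)
    stop("need at least 10 evaluation points on valid cells")
  v <- map$values[map$mask]
  rng <- range(v)
  w <- window_width_frac * diff(rng)
  if (w <= 0) stop("constant suitability map")
  mids <- seq(rng[1] + w / 2, rng[2] - w / 2, length.out = n_windows)
  P <- vapply(mids, function(m0)
    mean(s_eval >= m0 - w / 2 & s_eval <= m0 + w / 2), numeric(1))
  Ex <- vapply(mids, function(m0)
    mean(v >= m0 - w / 2 & v <= m0 + w / 2), numeric(1))
  use <- Ex > 0
  if (sum(use) < 3) stop("fewer than 3 usable suitability windows")
  pe <- P[use] / Ex[use]
  if (stats::sd(pe) == 0) return(0)
  stats::cor(pe, mids[use], method = "spearman")
}

#' Mobility-oriented parity (MOP) extrapolation analysis
#'
#' Flags the environmental novelty of a projection region relative to
#' the calibration region. Strict extrapolation: projection cells where
#' any variable falls outside the calibration min-max range. The
#' distance surface is the mean Euclidean distance (on variables
#' standardized by the calibration mean/sd) from each projection cell
#' to its nearest `ref_pct` fraction of calibration cells, scaled to
#' `[0, 1]` by its maximum; cells whose environment coincides exactly
#' with a calibration cell's score 0. Distances are computed in row
#' chunks of `chunk_rows` projection cells (a memory bound only; results
#' are chunk-invariant).
#'
#' @param calib,proj [env_stack()]s with identical layer names; `calib`
#'   needs at least 10 valid cells.
#' @param ref_pct fraction of nearest calibration cells averaged over
#'   (default 0.10).
#' @param chunk_rows projection cells per distance-matrix chunk
#'   (default 2000).
#' @return an object of class `mop_result`: `distance_surface` (matrix
#'   on `proj`'s grid), `strict_mask` (logical matrix), `strict_pct`.
#' @export
mop <- function(calib, proj, ref_pct = 0.10, chunk_rows = 2000) {
  if (!identical(layer_names(calib), layer_names(proj)))
    stop("calibration and projection stacks have different layers/axes")
  Ec <- env_values(calib)
  if (nrow(Ec) < 10) stop("calibration stack needs at least 10 valid cells")
  Ep <- env_values(proj)
  lo <- apply(Ec, 2, min); hi <- apply(Ec, 2, max)
  strict <- rowSums(sweep(Ep, 2, lo, "<") | sweep(Ep, 2, hi, ">")) > 0

  ctr <- colMeans(Ec)
  scl <- apply(Ec, 2, stats::sd)
  scl[scl == 0] <- 1
  Zc <- sweep(sweep(Ec, 2, ctr), 2, scl, "/")
  Zp <- sweep(sweep(Ep, 2, ctr), 2, scl, "/")
  k <- max(1L, ceiling(ref_pct * nrow(Zc)))
  cn2 <- rowSums(Zc^2)
  dist_raw <- numeric(nrow(Zp))
  for (start in seq(1, nrow(Zp), by = chunk_rows)) {
    idx <- start:min(start + chunk_rows - 1, nrow(Zp))
    d2 <- outer(rowSums(Zp[idx, , drop = FALSE]^2), cn2, "+") -
      2 * Zp[idx, , drop = FALSE] %*% t(Zc)
    d2[d2 < 0] <- 0
    dist_raw[idx] <- apply(d2, 1, function(row) {
      if (min(row) <= 1e-12) return(0) # exact calibration analogue
      mean(sqrt(sort(row, partial = k)[seq_len(k)]))
    })
  }
  dmax <- max(dist_raw)
  if (dmax > 0) dist_raw <- dist_raw / dmax

  dist_surface <- matrix(NA_real_, nrow(proj$mask), ncol(proj$mask))
  strict_mask <- matrix(FALSE, nrow(proj$mask), ncol(proj$mask))
  cells <- attr(Ep, "cells")
  dist_surface[cells] <- dist_raw
  strict_mask[cells] <- strict
  structure(list(distance_surface = dist_surface,
                 strict_mask = strict_mask,
                 strict_pct = 100 * sum(strict) / nrow(Ep)),
            class = "mop_result")
}

#' @export
print.mop_result <- function(x, ...) {
  cat(sprintf("<mop_result> strict extrapolation in %.2f%% of cells\n",
              x$strict_pct))
  invisible(x)
}

#' Full evaluation report for one projected/modern model pair
#'
#' @param run_hist the historical `replicate_run_set` (or ensemble run).
#' @param projected_map Distribution 1: the historical model projected
#'   to modern climate.
#' @param modern_map Distribution 2: the modern-trained averaged map.
#' @param train_env historical presence environment matrix.
#' @param test_points independent modern test [occurrences()].
#' @param proc_iterations,proc_E partial-ROC settings.
#' @param seed integer seed.
#' @return one-row `data.frame` with the AUC family, OR10, partial ROC,
#'   and the two Boyce indices.
#' @export
evaluation_report <- function(run_hist, projected_map, modern_map,
                              train_env, test_points,
                              proc_iterations = 500, proc_E = 0.05,
                              seed = 1) {
  aucs <- mean_auc(run_hist)
  or10 <- tryCatch({
    tr <- projected_map_scores_at_train(run_hist, train_env)
    te <- map_values_at(projected_map, test_points)
    omission_rate_10(tr, te[!is.na(te)])
  }, error = function(e) NA_real_)
  proc <- tryCatch(partial_roc(projected_map, test_points, E = proc_E,
                               iterations = proc_iterations, seed = seed),
                   error = function(e) list(ratio_mean = NA_real_,
                                            p = NA_real_))
  cbi_m <- tryCatch(continuous_boyce(modern_map, test_points),
                    error = function(e) NA_real_)
  cbi_p <- tryCatch(continuous_boyce(projected_map, test_points),
                    error = function(e) NA_real_)
  data.frame(AUC_TRAIN = aucs$auc_train, AUC_TEST = aucs$auc_test,
             AUC_DIFF = aucs$auc_diff, OR10 = or10,
             pROC_ratio_mean = proc$ratio_mean, pROC_p = proc$p,
             CBI_modern = cbi_m, CBI_projected = cbi_p)
}

# averaged replicate scores at the training presence environments
projected_map_scores_at_train <- function(run, train_env) {
  if (inherits(run, "ensemble_run_set")) {
    w <- run$auc_test / sum(run$auc_test)
    acc <- 0
    for (i in seq_along(run$members))
      acc <- acc + w[i] * projected_map_scores_at_train(run$members[[i]], train_env)
    return(acc)
  }
  acc <- 0
  for (rep in run$replicates) acc <- acc + predict(rep$adapter, train_env)
  acc / length(run$replicates)
}
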