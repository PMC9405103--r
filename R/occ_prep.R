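#' Occurrence cleaning cascade
#'
#' The cleaning cascade applied to each species before modelling:
#' (1) thin to at most one record per grid cell and period
#' ([thin_to_cells()]); (2) remove environmental outliers by Mahalanobis
#' distance from the per-period ellipsoid niche
#' ([remove_env_outliers()]); (3) reduce the larger period dataset to
#' the smaller one's size by greedily deleting the records whose removal
#' maximizes the ellipsoid niche overlap between periods
#' ([balance_by_overlap()]). Modern records discarded by the balancing
#' step become the independent modern test set.
#'
#' @name occ_prep
NULL

#' Thin occurrences to one record per cell
#'
#' Keeps at most one record per (species, period, cell), first by input
#' order, and drops records falling on masked-out or off-grid cells.
#'
#' @param occ an [occurrences()] table.
#' @param env the [env_stack()] defining the grid and mask.
#' @return the thinned [occurrences()] table.
#' @export
thin_to_cells <- function(occ, env) {
  if (nrow(occ) == 0) return(occ)
  cell <- occ_cell_id(env, occ$x, occ$y)
  keep <- !is.na(cell) & !duplicated(data.frame(occ$species, occ$period, cell))
  occ[keep, , drop = FALSE]
}

# mu, inverse covariance and chi-square radius of the level-`level`
# Mahalanobis ellipsoid of a point matrix.
ellipsoid_fit <- function(X, level = 0.975) {
  mu <- colMeans(X)
  S <- stats::cov(X)
  Sinv <- tryCatch(solve(S), error = function(e)
    stop("singular covariance: use fewer variables or more records"))
  list(mu = mu, S = S, Sinv = Sinv,
       q = stats::qchisq(level, df = ncol(X)))
}

#' Remove environmental outliers per period
#'
#' For each period separately, fits the ellipsoid niche (centroid and
#' covariance of the records' environment vectors) and drops records
#' whose squared Mahalanobis distance exceeds the chi-square quantile at
#' `level` with as many degrees of freedom as environmental layers.
#' A single pass: the ellipsoid is not refitted after removal.
#'
#' @param occ a thinned [occurrences()] table for one species.
#' @param env the [env_stack()] supplying environment vectors.
#' @param level chi-square coverage level of the retained ellipsoid
#'   (default 0.975).
#' @return the filtered [occurrences()] table.
#' @export
remove_env_outliers <- function(occ, env, level = 0.975) {
  L <- dim(env$layers)[3]
  keep <- rep(TRUE, nrow(occ))
  for (p in unique(occ$period)) {
    idx <- which(occ$period == p)
    if (length(idx) < L + 2)
      stop(sprintf("period '%s' has %d records; need at least %d to fit the ellipsoid",
                   p, length(idx), L + 2))
    E <- env_extract(env, occ$x[idx], occ$y[idx])
    if (anyNA(E)) stop("records on masked cells; thin_to_cells first")
    ell <- ellipsoid_fit(E, level)
    md2 <- stats::mahalanobis(E, ell$mu, ell$Sinv, inverted = TRUE)
    keep[idx] <- md2 <= ell$q
  }
  occ[keep, , drop = FALSE]
}

# Quadratic-form coefficients of md2(p) - q for fast batch membership:
# a point-feature row [p_j p_k (j<=k), p_j, 1] dotted with these
# coefficients is <= 0 exactly inside the ellipsoid.
ellipsoid_qf_coefs <- function(mu, Sinv, q) {
  L <- length(mu)
  quad <- numeric(L * (L + 1) / 2)
  i <- 1
  for (j in seq_len(L)) for (k in j:L) {
    quad[i] <- if (j == k) Sinv[j, j] else 2 * Sinv[j, k]
    i <- i + 1
  }
  lin <- -2 * as.numeric(Sinv %*% mu)
  cst <- as.numeric(t(mu) %*% Sinv %*% mu) - q
  c(quad, lin, cst)
}

quad_features <- function(P) {
  L <- ncol(P)
  cols <- vector("list", L * (L + 1) / 2)
  i <- 1
  for (j in seq_len(L)) for (k in j:L) {
    cols[[i]] <- P[, j] * P[, k]
    i <- i + 1
  }
  cbind(do.call(cbind, cols), P, 1)
}

ellipsoid_aabb <- function(ell) {
  half <- sqrt(ell$q * diag(ell$S))
  rbind(lo = ell$mu - half, hi = ell$mu + half)
}

#' Monte Carlo overlap of two ellipsoid niches
#'
#' Fits the level-`level` Mahalanobis ellipsoid to each record-by-variable
#' matrix and estimates the Jaccard overlap of the two ellipsoids by
#' uniform Monte Carlo sampling over the union's bounding box, testing
#' membership analytically.
#'
#' @param envA,envB numeric matrices (records x variables) in the same
#'   variable space.
#' @param level ellipsoid coverage level (default 0.975).
#' @param n_mc Monte Carlo sample size (default 20000).
#' @param seed integer seed.
#' @return overlap in `[0, 1]`.
#' @export
ellipsoid_overlap <- function(envA, envB, level = 0.975, n_mc = 20000,
                              seed = 1) {
  ea <- ellipsoid_fit(as.matrix(envA), level)
  eb <- ellipsoid_fit(as.matrix(envB), level)
  ba <- ellipsoid_aabb(ea); bb <- ellipsoid_aabb(eb)
  lo <- pmin(ba["lo", ], bb["lo", ]); hi <- pmax(ba["hi", ], bb["hi", ])
  with_seed(derive_seed(seed, "ellipsoid_overlap"), {
    P <- sapply(seq_along(lo), function(j) stats::runif(n_mc, lo[j], hi[j]))
    ina <- stats::mahalanobis(P, ea$mu, ea$Sinv, inverted = TRUE) <= ea$q
    inb <- stats::mahalanobis(P, eb$mu, eb$Sinv, inverted = TRUE) <= eb$q
    either <- sum(ina | inb)
    if (either == 0) return(0)
    sum(ina & inb) / either
  })
}

#' Balance historical and modern datasets by maximizing niche overlap
#'
#' Reduces the larger of the two period datasets to the smaller one's
#' size by greedy one-at-a-time deletion: at each step the record whose
#' removal maximizes the Monte Carlo ellipsoid overlap between the two
#' period niches is deleted (ties broken by input order). Modern records
#' discarded here are returned as the independent modern test set.
#'
#' The candidate search is vectorized: per deletion step a fresh seeded
#' uniform sample is drawn once over the union bounding box (slightly
#' inflated so shrinking candidate ellipsoids stay covered) and every
#' candidate's ellipsoid membership is evaluated through a single
#' quadratic-feature matrix product.
#'
#' @param hist,mod per-period [occurrences()] tables (already thinned
#'   and outlier-screened).
#' @param envH,envM the period [env_stack()]s.
#' @param seed integer seed.
#' @param level ellipsoid coverage level.
#' @param n_mc Monte Carlo points per deletion step (default 5000; the
#'   ranking of candidate deletions needs fewer points than a final
#'   overlap estimate).
#' @return list with `historical`, `modern`, `test_modern`
#'   ([occurrences()] tables) and `report` (a `cleaning_report`).
#' @export
balance_by_overlap <- function(hist, mod, envH, envM, seed = 1,
                               level = 0.975, n_mc = 5000) {
  EH <- env_extract(envH, hist$x, hist$y)
  EM <- env_extract(envM, mod$x, mod$y)
  if (anyNA(EH) || anyNA(EM)) stop("records on masked cells; thin_to_cells first")
  L <- ncol(EH)
  if (nrow(EH) < L + 2 || nrow(EM) < L + 2)
    stop(sprintf("each period needs at least %d records to balance", L + 2))

  n_target <- min(nrow(hist), nrow(mod))
  larger_is_mod <- nrow(mod) > nrow(hist)
  big <- if (larger_is_mod) EM else EH
  small <- if (larger_is_mod) EH else EM
  keep <- seq_len(nrow(big))

  if (nrow(big) > n_target) {
    ell_small <- ellipsoid_fit(small, level)
    step <- 0L
    while (length(keep) > n_target) {
      step <- step + 1L
      cur <- big[keep, , drop = FALSE]
      ell_big <- ellipsoid_fit(cur, level)
      bs <- ellipsoid_aabb(ell_small); bb <- ellipsoid_aabb(ell_big)
      lo <- pmin(bs["lo", ], bb["lo", ]); hi <- pmax(bs["hi", ], bb["hi", ])
      pad <- 0.15 * (hi - lo)
      lo <- lo - pad; hi <- hi + pad
      P <- with_seed(derive_seed(seed, "balance", step), {
        sapply(seq_along(lo), function(j) stats::runif(n_mc, lo[j], hi[j]))
      })
      Fm <- quad_features(P)
      in_small <- as.numeric(
        Fm %*% ellipsoid_qf_coefs(ell_small$mu, ell_small$Sinv, ell_small$q) <= 0)
      coefs <- vapply(seq_along(keep), function(i) {
        sub <- cur[-i, , drop = FALSE]
        e <- ellipsoid_fit(sub, level)
        ellipsoid_qf_coefs(e$mu, e$Sinv, e$q)
      }, numeric(ncol(Fm)))
      in_cand <- (Fm %*% coefs) <= 0
      both <- as.numeric(crossprod(in_cand, in_small))
      either <- colSums(in_cand) + sum(in_small) - both
      J <- ifelse(either == 0, 0, both / either)
      keep <- keep[-which.max(J)]
    }
  }

  if (larger_is_mod) {
    mod_out <- mod[keep, , drop = FALSE]
    test_mod <- mod[setdiff(seq_len(nrow(mod)), keep), , drop = FALSE]
    hist_out <- hist
  } else {
    hist_out <- hist[keep, , drop = FALSE]
    mod_out <- mod
    test_mod <- mod[0, , drop = FALSE]
  }
  report <- cleaning_report(
    n_after_outliers = c(historical = nrow(hist), modern = nrow(mod)),
    n_after_balancing = c(historical = nrow(hist_out), modern = nrow(mod_out)),
    discarded_modern_test = test_mod)
  list(historical = hist_out, modern = mod_out, test_modern = test_mod,
       report = report)
}

#' Cleaning report
#'
#' Per-period record counts along the cleaning cascade, plus the modern
#' records discarded by balancing (the independent test set). Counts are
#' non-increasing along the cascade and the balanced counts are equal
#' across periods.
#'
#' @param n_input,n_after_thinning,n_after_outliers,n_after_balancing
#'   named per-period counts (`historical`, `modern`).
#' @param discarded_modern_test the held-out modern [occurrences()].
#' @return an object of class `cleaning_report`.
#' @export
cleaning_report <- function(n_input = NULL, n_after_thinning = NULL,
                            n_after_outliers = NULL,
                            n_after_balancing = NULL,
                            discarded_modern_test = NULL) {
  structure(list(n_input = n_input, n_after_thinning = n_after_thinning,
                 n_after_outliers = n_after_outliers,
                 n_after_balancing = n_after_balancing,
                 discarded_modern_test = discarded_modern_test),
            class = "cleaning_report")
}

#' @export
print.cleaning_report <- function(x, ...) {
  cat("<cleaning_report>\n")
  for (f in c("n_input", "n_after_thinning", "n_after_outliers",
              "n_after_balancing")) {
    if (!is.null(x[[f]]))
      cat(sprintf("  %-18s historical %d, modern %d\n", f,
                  x[[f]][["historical"]], x[[f]][["modern"]]))
  }
  if (!is.null(x$discarded_modern_test))
    cat(sprintf("  modern test records: %d\n", nrow(x$discarded_modern_test)))
  invisible(x)
}

#' @rdname cleaning_report
#' @param report a `cleaning_report`.
#' @param path output JSON path.
#' @export
write_cleaning_report <- function(report, path) {
  out <- lapply(report[c("n_input", "n_after_thinning", "n_after_outliers",
                         "n_after_balancing")],
                function(v) if (is.null(v)) NULL else as.list(v))
  out$n_modern_test <- if (is.null(report$discarded_modern_test)) 0L else
    nrow(report$discarded_modern_test)
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Run the full cleaning cascade for one species
#'
#' Convenience wrapper chaining [thin_to_cells()],
#' [remove_env_outliers()] and [balance_by_overlap()], assembling the
#' complete [cleaning_report()].
#'
#' @param occ all records of one species (both periods).
#' @param envH,envM historical and modern [env_stack()]s.
#' @param level ellipsoid coverage level.
#' @param seed integer seed.
#' @param n_mc Monte Carlo points per balancing step.
#' @return list with `historical`, `modern`, `test_modern`, `report`.
#' @export
clean_occurrences <- function(occ, envH, envM, level = 0.975, seed = 1,
                              n_mc = 5000) {
  counts <- function(o) c(historical = sum(o$period == "historical"),
                          modern = sum(o$period == "modern"))
  n_input <- counts(occ)
  hist0 <- thin_to_cells(occ[occ$period == "historical", , drop = FALSE], envH)
  mod0 <- thin_to_cells(occ[occ$period == "modern", , drop = FALSE], envM)
  n_thin <- c(historical = nrow(hist0), modern = nrow(mod0))
  hist1 <- remove_env_outliers(hist0, envH, level)
  mod1 <- remove_env_outliers(mod0, envM, level)
  n_out <- c(historical = nrow(hist1), modern = nrow(mod1))
  bal <- balance_by_overlap(hist1, mod1, envH, envM, seed = seed,
                            level = level, n_mc = n_mc)
  bal$report$n_input <- n_input
  bal$report$n_after_thinning <- n_thin
  bal$report$n_after_outliers <- n_out
  bal
}
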