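#' Replicated subsampling fits and averaged suitability maps
#'
#' Implements the core modelling workflow: the presences are split into
#' a training and a testing subset, a fresh contrast (background or
#' pseudoabsence) sample is drawn, the procedure's adapter is fitted and
#' predicted over the study area, and the whole step is repeated
#' (10 times by default) to yield a cellwise-averaged habitat
#' suitability map. Per-replicate training and testing AUCs (presences
#' versus the replicate's contrast sample) are recorded.
#'
#' @param presence_env matrix (presences x variables) aligned with
#'   `env_fit`'s layers.
#' @param spec a procedure spec from [procedure_registry()] (or a
#'   procedure name).
#' @param env_fit the [env_stack()] to fit and predict on.
#' @param reps number of replicates (default 10).
#' @param train_frac fraction of presences used for training each
#'   replicate (default 0.7; 1 disables the test split and test AUCs
#'   are `NA`).
#' @param seed integer seed; replicate sub-seeds are derived from it.
#' @param presence_cells cell indices of the presences (used by
#'   presence-derived contrast rules and pseudoabsence exclusion).
#' @param species species label stamped on the output map.
#' @return an object of class `replicate_run_set`: fields `avg` (the
#'   averaged [suit_map()]), `replicates` (list with `adapter`,
#'   `train_idx`, `test_idx`, `auc_train`, `auc_test` per replicate),
#'   `env_fit`, `spec`.
#' @export
run_replicates <- function(presence_env, spec, env_fit, reps = 10,
                           train_frac = 0.7, seed = 1,
                           presence_cells = NULL, species = "sp") {
  if (is.character(spec)) spec <- procedure_spec(spec)
  if (identical(spec$fitter, "ensemble"))
    return(run_ensemble(presence_env, spec, env_fit, reps = reps,
                        train_frac = train_frac, seed = seed,
                        presence_cells = presence_cells, species = species))
  P <- as.matrix(presence_env)
  n <- nrow(P)
  stopifnot(reps >= 1, train_frac > 0, train_frac <= 1)
  n_train <- max(1L, round(train_frac * n))
  min_needed <- switch(spec$fitter, bioclim = 5L, domain = 2L,
                       kde = ncol(P) + 2L, classifier = 2L, 2L)
  if (n_train < min_needed)
    stop(sprintf("procedure '%s' needs at least %d training presences, got %d",
                 spec$name, min_needed, n_train))
  vals <- env_values(env_fit)
  acc <- numeric(nrow(vals))
  replicates <- vector("list", reps)
  for (r in seq_len(reps)) {
    rseed <- derive_seed(seed, species, spec$name, "rep", r)
    train_idx <- if (n_train == n) seq_len(n) else
      with_seed(rseed, sort(sample.int(n, n_train)))
    test_idx <- setdiff(seq_len(n), train_idx)
    contrast <- sample_contrast(env_fit, spec$contrast,
                                presence_cells = presence_cells,
                                seed = derive_seed(rseed, "contrast"))
    adapter <- with_seed(derive_seed(rseed, "fit"),
                         fit_procedure(spec, P[train_idx, , drop = FALSE],
                                       contrast))
    map_scores <- predict(adapter, vals)
    acc <- acc + map_scores
    contrast_scores <- predict(adapter, contrast)
    auc_train <- auc(predict(adapter, P[train_idx, , drop = FALSE]),
                     contrast_scores)
    auc_test <- if (length(test_idx) > 0)
      auc(predict(adapter, P[test_idx, , drop = FALSE]), contrast_scores)
    else NA_real_
    replicates[[r]] <- list(index = r, adapter = adapter,
                            train_idx = train_idx, test_idx = test_idx,
                            contrast_cells = attr(contrast, "cells"),
                            auc_train = auc_train, auc_test = auc_test)
  }
  avg_vals <- matrix(NA_real_, nrow(env_fit$mask), ncol(env_fit$mask))
  avg_vals[attr(vals, "cells")] <- acc / reps
  avg <- suit_map(avg_vals, env_fit$mask,
                  source = list(species = species, procedure = spec$name,
                                period_trained = env_fit$period,
                                period_projected = env_fit$period),
                  origin = env_fit$origin)
  structure(list(avg = avg, replicates = replicates, env_fit = env_fit,
                 spec = spec, species = species),
            class = "replicate_run_set")
}

run_ensemble <- function(presence_env, spec, env_fit, reps = 10,
                         train_frac = 0.7, seed = 1, presence_cells = NULL,
                         species = "sp") {
  runs <- lapply(spec$members, function(m)
    run_replicates(presence_env, procedure_spec(m), env_fit, reps = reps,
                   train_frac = train_frac,
                   seed = derive_seed(seed, "ensemble_member", m),
                   presence_cells = presence_cells, species = species))
  auc_test <- vapply(runs, function(r) mean_auc(r)$auc_test, numeric(1))
  auc_test[is.na(auc_test)] <- 0.5
  avg <- ensemble_predict(lapply(runs, `[[`, "avg"),
                          weights = "auc_weighted", auc_test = auc_test)
  avg$source$species <- species
  structure(list(avg = avg, members = runs, auc_test = auc_test,
                 env_fit = env_fit, spec = spec, species = species),
            class = "ensemble_run_set")
}

#' Mean replicate AUCs of a run
#'
#' @param run a `replicate_run_set` or `ensemble_run_set`.
#' @return list with `auc_train`, `auc_test`, `auc_diff`.
#' @export
mean_auc <- function(run) {
  if (inherits(run, "ensemble_run_set")) {
    per <- lapply(run$members, mean_auc)
    tr <- mean(vapply(per, `[[`, numeric(1), "auc_train"))
    te <- mean(vapply(per, `[[`, numeric(1), "auc_test"))
  } else {
    tr <- mean(vapply(run$replicates, `[[`, numeric(1), "auc_train"))
    te <- mean(vapply(run$replicates, `[[`, numeric(1), "auc_test"))
  }
  list(auc_train = tr, auc_test = te, auc_diff = tr - te)
}

#' Project a fitted run onto another period's environment
#'
#' Re-predicts every replicate's fitted adapter on the target stack and
#' averages, exactly mirroring the construction of the original averaged
#' map (this is a re-evaluation of the fitted models, not a resampling
#' of the fitted map). For PCA variable sets the target stack must carry
#' axis-alignment metadata (see [pca_reduce()]), unless it is the
#' fitting stack itself.
#'
#' @param run a `replicate_run_set` or `ensemble_run_set`.
#' @param env_other the target [env_stack()]; must have the same layer
#'   names as the fitting stack.
#' @return the projected, averaged [suit_map()] on `env_other`'s grid.
#' @export
project <- function(run, env_other) {
  stopifnot(inherits(run, c("replicate_run_set", "ensemble_run_set")))
  if (!identical(layer_names(env_other), layer_names(run$env_fit)))
    stop("layer mismatch: fit stack has [",
         paste(layer_names(run$env_fit), collapse = ", "), "], target has [",
         paste(layer_names(env_other), collapse = ", "), "]")
  same_stack <- identical(env_other$layers, run$env_fit$layers)
  if (identical(run$env_fit$provenance, "pca3") && !same_stack &&
      !isTRUE(env_other$pca_aligned))
    stop("pca3 projection stack lacks axis-alignment metadata; ",
         "rebuild it with pca_reduce(align_to = <fitting-period stack>)")
  if (inherits(run, "ensemble_run_set")) {
    maps <- lapply(run$members, project, env_other = env_other)
    out <- ensemble_predict(maps, weights = "auc_weighted",
                            auc_test = run$auc_test)
    out$source <- run$avg$source
    out$source$period_projected <- env_other$period
    return(out)
  }
  vals <- env_values(env_other)
  acc <- numeric(nrow(vals))
  for (rep in run$replicates) acc <- acc + predict(rep$adapter, vals)
  out_vals <- matrix(NA_real_, nrow(env_other$mask), ncol(env_other$mask))
  out_vals[attr(vals, "cells")] <- acc / length(run$replicates)
  src <- run$avg$source
  src$period_projected <- env_other$period
  suit_map(out_vals, env_other$mask, source = src, origin = env_other$origin)
}

#' Convert a suitability map to a binary map via a prevalence-calibrated
#' logistic curve
#'
#' Suitability `s` is mapped to an occurrence probability
#' `P = 1 / (1 + exp(-(s - beta) / alpha))`, with the curve midpoint
#' `beta` solved numerically so that the mean of `P` over the valid
#' cells equals the species' prevalence (tolerance 1e-6). In
#' `"bernoulli"` mode (the default, honouring the probabilistic
#' conversion) each cell is drawn independently with probability `P`;
#' `"expected_threshold"` mode deterministically sets cells with
#' `P >= 0.5` (equivalently `s >= beta`) to presence.
#'
#' @param map a non-constant [suit_map()].
#' @param prevalence target mean occurrence probability, in `(0, 1)`.
#' @param alpha logistic steepness on the suitability scale
#'   (default 0.05).
#' @param mode `"bernoulli"` or `"expected_threshold"`.
#' @param seed integer seed (bernoulli mode).
#' @return a [binary_map()]; `threshold_meta` records
#'   `(prevalence, alpha, beta, mode, seed)`.
#' @export
prevalence_logistic_binarize <- function(map, prevalence, alpha = 0.05,
                                         mode = c("bernoulli",
                                                  "expected_threshold"),
                                         seed = 1) {
  mode <- match.arg(mode)
  stopifnot(inherits(map, "suit_map"), prevalence > 0, prevalence < 1,
            alpha > 0)
  s <- map$values[map$mask]
  if (diff(range(s)) < 1e-12)
    stop("constant suitability map: prevalence calibration is unreachable")
  f <- function(beta) mean(stats::plogis((s - beta) / alpha)) - prevalence
  lo <- min(s) - 50 * alpha
  hi <- max(s) + 50 * alpha
  if (f(lo) < 0 || f(hi) > 0)
    stop("prevalence unreachable for any curve midpoint")
  beta <- stats::uniroot(f, c(lo, hi), tol = 1e-12)$root
  P <- stats::plogis((s - beta) / alpha)
  if (abs(mean(P) - prevalence) > 1e-6)
    stop("prevalence calibration did not converge to tolerance 1e-6")
  b <- if (mode == "bernoulli") {
    with_seed(derive_seed(seed, "binarize"),
              as.numeric(stats::runif(length(P)) < P))
  } else {
    as.numeric(P >= 0.5)
  }
  vals <- matrix(NA_real_, nrow(map$values), ncol(map$values))
  vals[map$mask] <- b
  binary_map(vals, map$mask, source = map$source, origin = map$origin,
             threshold_meta = list(prevalence = prevalence, alpha = alpha,
                                   beta = beta, mode = mode, seed = seed))
}

#' Species prevalence over a study area
#'
#' Prevalence used for binarization: distinct presence cells divided by
#' valid study-area cells, computed from the cleaned period-specific
#' occurrences.
#'
#' @param occ cleaned [occurrences()] of one species and period.
#' @param env the study-area [env_stack()].
#' @return prevalence in `(0, 1]`.
#' @export
species_prevalence <- function(occ, env) {
  cells <- occ_cell_id(env, occ$x, occ$y)
  length(unique(cells[!is.na(cells)])) / n_valid_cells(env)
}
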