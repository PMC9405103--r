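#' Configure a synthetic transferability experiment
#'
#' Bundles every knob of the end-to-end experiment: the synthetic world
#' (grid shape, climate drift, species count and prevalence, sample
#' sizes), the modelling workflow (procedures, variable sets,
#' replicates, train fraction), the cleaning cascade, binarization, and
#' which evaluation layers to run. Defaults encode the study conditions
#' the pipeline is designed around: two 30-year-style climate periods
#' separated by a moderate warming drift, narrow-ranged species at 1-5
#' percent prevalence, modern datasets twice the size of historical
#' ones, and 10-replicate subsampling fits.
#'
#' @param n_species number of virtual species (default 10).
#' @param prevalence target species prevalence (default 0.03).
#' @param procedures procedure names from [procedure_registry()].
#' @param variable_sets subset of `c("apriori3", "pca3")`.
#' @param shape world grid shape (default 60 x 60).
#' @param roughness climate smoothing width, cells.
#' @param drift a [drift_spec()]; default +1 degree C warming, slightly
#'   drier, with small cellwise noise.
#' @param n_modern modern occurrence draws per species (default 150).
#' @param hist_frac historical sample size as a fraction of `n_modern`
#'   (default 0.5, mimicking sparser historical archives).
#' @param reps,train_frac replicate count and training fraction.
#' @param buffer_cells study-area buffer around the occurrence bounding
#'   box.
#' @param binarize_mode,binarize_alpha binarization settings (see
#'   [prevalence_logistic_binarize()]).
#' @param outlier_level ellipsoid coverage for outlier screening.
#' @param balance_n_mc Monte Carlo points per balancing step.
#' @param evaluate compute the evaluation-metric report per pair?
#' @param proc_iterations partial-ROC bootstrap iterations.
#' @param run_mop run the MOP extrapolation screen per species and
#'   variable set?
#' @return a list of class `experiment_config`.
#' @export
experiment_config <- function(n_species = 10, prevalence = 0.03,
                              procedures = default_procedures(),
                              variable_sets = c("apriori3", "pca3"),
                              shape = c(60, 60), roughness = 3,
                              drift = drift_spec(temp_offset = 1,
                                                 prec_offset = -3,
                                                 noise_sd_temp = 0.3,
                                                 noise_sd_prec = 2),
                              n_modern = 150, hist_frac = 0.5,
                              reps = 10, train_frac = 0.7,
                              buffer_cells = 10,
                              binarize_mode = "bernoulli",
                              binarize_alpha = 0.05,
                              outlier_level = 0.975,
                              balance_n_mc = 5000,
                              evaluate = TRUE, proc_iterations = 500,
                              run_mop = TRUE) {
  variable_sets <- match.arg(variable_sets, c("apriori3", "pca3"),
                             several.ok = TRUE)
  reg <- procedure_registry()
  unknown <- setdiff(procedures, names(reg))
  if (length(unknown))
    stop("unknown procedure(s): ", paste(unknown, collapse = ", "))
  structure(as.list(environment()), class = "experiment_config")
}

#' Enumerate the cells and rasters of an experiment grid
#'
#' Pure bookkeeping used for design accounting: one comparison row per
#' species x procedure x variable set, and one tailored raster stack
#' per species x variable set x period.
#'
#' @param n_species number of species (or a vector of species ids).
#' @param procedures procedure names.
#' @param variable_sets variable-set names.
#' @return list with data frames `comparisons` and `stacks`.
#' @export
plan_experiment <- function(n_species, procedures = default_procedures(),
                            variable_sets = c("apriori3", "pca3")) {
  species <- if (length(n_species) == 1 && is.numeric(n_species))
    sprintf("species%02d", seq_len(n_species)) else as.character(n_species)
  comparisons <- expand.grid(species = species, procedure = procedures,
                             variable_set = variable_sets,
                             stringsAsFactors = FALSE)
  stacks <- expand.grid(species = species, variable_set = variable_sets,
                        period = c("historical", "modern"),
                        stringsAsFactors = FALSE)
  stacks$stack_id <- with(stacks, paste(species, variable_set, period,
                                        sep = "/"))
  list(comparisons = comparisons, stacks = stacks)
}

#' Simulate the synthetic world of an experiment
#'
#' Generates the drifting climate pair, derives the raw variable stacks
#' for both periods, builds the requested variable sets (the modern PCA
#' stack is axis-aligned to the historical one), creates the virtual
#' species (Gaussian niches over the three a-priori variables of the
#' historical period), and samples the per-period occurrence records.
#'
#' @param config an [experiment_config()].
#' @param seed master integer seed.
#' @return list with `stacks` (per variable set, per period), `species`
#'   (list of [virtual_species_spec()]), `occ` (all records), `truth`
#'   (per species, per period true suitability on the a-priori
#'   variables).
#' @export
simulate_world <- function(config, seed = 1) {
  stopifnot(inherits(config, "experiment_config"))
  clim <- make_climate_pair(config$shape, drift = config$drift,
                            roughness = config$roughness,
                            seed = derive_seed(seed, "world"))
  rawH <- derive_bioclim(clim$historical)
  rawM <- derive_bioclim(clim$modern)
  stacks <- list()
  aprH <- select_apriori(rawH); aprM <- select_apriori(rawM)
  if ("apriori3" %in% config$variable_sets)
    stacks$apriori3 <- list(historical = aprH, modern = aprM)
  if ("pca3" %in% config$variable_sets) {
    pcaH <- pca_reduce(rawH)
    pcaM <- pca_reduce(rawM, align_to = pcaH)
    stacks$pca3 <- list(historical = pcaH, modern = pcaM)
  }
  ids <- sprintf("species%02d", seq_len(config$n_species))
  species <- lapply(ids, function(id)
    make_virtual_species(aprH, id, prevalence = config$prevalence,
                         seed = derive_seed(seed, "niche", id)))
  names(species) <- ids
  n_hist <- max(1L, round(config$hist_frac * config$n_modern))
  occ_list <- list(); truth <- list()
  for (id in ids) {
    tH <- true_suitability(species[[id]], aprH)
    tM <- true_suitability(species[[id]], aprM)
    truth[[id]] <- list(historical = tH, modern = tM)
    occ_list[[id]] <- rbind(
      sample_occurrences(tH, n_hist, "historical",
                         seed = derive_seed(seed, "sample", id, "hist")),
      sample_occurrences(tM, config$n_modern, "modern",
                         seed = derive_seed(seed, "sample", id, "mod")))
  }
  occ <- do.call(rbind, occ_list)
  class(occ) <- c("occurrences", "data.frame")
  list(stacks = stacks, species = species, occ = occ, truth = truth,
       raw = list(historical = rawH, modern = rawM))
}

# One species x procedure x variable-set cell: fit both periods,
# project, binarize, compare, optionally evaluate.
run_pair <- function(spec, cleaned, envH, envM, config, seed, species_id,
                     variable_set) {
  PH <- env_extract(envH, cleaned$historical$x, cleaned$historical$y)
  PM <- env_extract(envM, cleaned$modern$x, cleaned$modern$y)
  cellsH <- occ_cell_id(envH, cleaned$historical$x, cleaned$historical$y)
  cellsM <- occ_cell_id(envM, cleaned$modern$x, cleaned$modern$y)
  runH <- run_replicates(PH, spec, envH, reps = config$reps,
                         train_frac = config$train_frac,
                         seed = derive_seed(seed, "hist"),
                         presence_cells = cellsH, species = species_id)
  dist1 <- project(runH, envM)
  runM <- run_replicates(PM, spec, envM, reps = config$reps,
                         train_frac = config$train_frac,
                         seed = derive_seed(seed, "mod"),
                         presence_cells = cellsM, species = species_id)
  dist2 <- runM$avg
  prevH <- species_prevalence(cleaned$historical, envH)
  prevM <- species_prevalence(cleaned$modern, envM)
  bin1 <- prevalence_logistic_binarize(dist1, prevH,
                                       alpha = config$binarize_alpha,
                                       mode = config$binarize_mode,
                                       seed = derive_seed(seed, "bin1"))
  bin2 <- prevalence_logistic_binarize(dist2, prevM,
                                       alpha = config$binarize_alpha,
                                       mode = config$binarize_mode,
                                       seed = derive_seed(seed, "bin2"))
  row <- pair_comparison(dist1, dist2, bin1, bin2, species = species_id,
                         procedure = spec$name,
                         variable_set = variable_set)
  if (config$evaluate) {
    ev <- evaluation_report(runH, dist1, dist2, PH,
                            test_points = cleaned$test_modern,
                            proc_iterations = config$proc_iterations,
                            seed = derive_seed(seed, "eval"))
    row <- cbind(row, ev)
  }
  row
}

#' Run the full species x procedure x variable-set experiment
#'
#' For every cell of the grid: clean the species' occurrences in the
#' cell's environmental space, fit the procedure on historical data and
#' project it to modern climate (Distribution 1), fit it on modern data
#' (Distribution 2), binarize both at the species' prevalence, and
#' record the pair-comparison statistics (and, optionally, the
#' evaluation metrics and the per-species MOP screen). Each cell is
#' seeded independently from the master seed, so any subset of the grid
#' reruns bit-identically. Stage errors are caught per cell and reported
#' in the `error` column rather than aborting the run.
#'
#' @param config an [experiment_config()].
#' @param seed master integer seed.
#' @param world optionally, a pre-built [simulate_world()] result (must
#'   match `config` and `seed`).
#' @param resume optionally, a previous `experiment_result` from the
#'   same config and seed; its successfully completed cells are reused
#'   instead of recomputed (failed cells are retried). Because every
#'   cell is independently seeded, resumed and fresh runs are
#'   bit-identical.
#' @return list of class `experiment_result`: `results` (one row per
#'   grid cell), `mop` (per species x variable set strict-extrapolation
#'   percentages), `cleaning` (per species x variable set
#'   [cleaning_report()]s), `config`, `seed`.
#' @export
run_experiment <- function(config, seed = 1, world = NULL, resume = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  done <- NULL
  if (!is.null(resume)) {
    stopifnot(inherits(resume, "experiment_result"))
    if (resume$seed != seed) stop("resume result was produced under a different seed")
    done <- resume$results[is.na(resume$results$error), , drop = FALSE]
  }
  if (is.null(world)) world <- simulate_world(config, seed)
  rows <- list(); mop_rows <- list(); cleaning <- list()
  for (vs in config$variable_sets) {
    globH <- world$stacks[[vs]]$historical
    globM <- world$stacks[[vs]]$modern
    for (id in names(world$species)) {
      occ_sp <- world$occ[world$occ$species == id, , drop = FALSE]
      envH <- tailor_study_area(globH, occ_sp, config$buffer_cells)
      envM <- tailor_study_area(globM, occ_sp, config$buffer_cells)
      cleaned <- tryCatch(
        clean_occurrences(occ_sp, envH, envM, level = config$outlier_level,
                          seed = derive_seed(seed, "clean", id, vs),
                          n_mc = config$balance_n_mc),
        error = function(e) e)
      if (inherits(cleaned, "error")) {
        for (pr in config$procedures) {
          rows[[length(rows) + 1]] <- data.frame(
            species = id, procedure = pr, variable_set = vs,
            D = NA_real_, S = NA_real_, RSV = NA_real_, d = NA_real_,
            error = conditionMessage(cleaned), stringsAsFactors = FALSE)
        }
        next
      }
      cleaning[[paste(id, vs, sep = "/")]] <- cleaned$report
      if (config$run_mop) {
        mres <- mop(envH, envM)
        mop_rows[[length(mop_rows) + 1]] <- data.frame(
          species = id, variable_set = vs, strict_pct = mres$strict_pct,
          stringsAsFactors = FALSE)
      }
      for (pr in config$procedures) {
        if (!is.null(done) &&
            any(done$species == id & done$variable_set == vs &
                  done$procedure == pr)) {
          rows[[length(rows) + 1]] <-
            done[done$species == id & done$variable_set == vs &
                   done$procedure == pr, , drop = FALSE]
          next
        }
        spec <- procedure_spec(pr)
        cell_seed <- derive_seed(seed, "cell", id, vs, pr)
        row <- tryCatch(
          run_pair(spec, cleaned, envH, envM, config, cell_seed, id, vs),
          error = function(e) data.frame(
            species = id, procedure = pr, variable_set = vs,
            D = NA_real_, S = NA_real_, RSV = NA_real_, d = NA_real_,
            error = conditionMessage(e), stringsAsFactors = FALSE))
        if (is.null(row$error)) row$error <- NA_character_
        rows[[length(rows) + 1]] <- row
      }
    }
  }
  results <- do.call(rbind, lapply(rows, function(r) {
    all_cols <- c("species", "procedure", "variable_set", "D", "S", "RSV",
                  "d", "AUC_TRAIN", "AUC_TEST", "AUC_DIFF", "OR10",
                  "pROC_ratio_mean", "pROC_p", "CBI_modern",
                  "CBI_projected", "error")
    for (cn in setdiff(all_cols, names(r))) r[[cn]] <- NA
    r[all_cols]
  }))
  rownames(results) <- NULL
  structure(list(results = results,
                 mop = if (length(mop_rows)) do.call(rbind, mop_rows) else NULL,
                 cleaning = cleaning, config = config, seed = seed),
            class = "experiment_result")
}

#' @export
print.experiment_result <- function(x, ...) {
  n_fail <- sum(!is.na(x$results$error))
  cat(sprintf("<experiment_result> %d comparison rows (%d failed), seed %d\n",
              nrow(x$results), n_fail, x$seed))
  invisible(x)
}

#' Kruskal-Wallis test across procedure groups
#'
#' Tie-corrected H statistic with the chi-square approximation
#' (df = groups - 1). The fully degenerate case (every value identical
#' across all groups) returns H = 0, p = 1 rather than an error.
#'
#' @param groups named list of numeric vectors (one per procedure), at
#'   least 2 groups, each non-empty.
#' @return list with `H`, `df`, `p`.
#' @export
kruskal_wallis <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2)
  if (any(vapply(groups, length, integer(1)) == 0))
    stop("all groups must be non-empty")
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), vapply(groups, length, integer(1))))
  if (length(unique(values)) == 1)
    return(list(H = 0, df = length(groups) - 1, p = 1))
  kt <- stats::kruskal.test(values, g)
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p = kt$p.value)
}

#' Pairwise Mann-Whitney tests with Bonferroni correction
#'
#' Two-sided, tie-corrected normal-approximation tests on every pair of
#' groups. With Bonferroni correction a pair is significant iff its raw
#' p-value is below `alpha / m`, `m = g (g - 1) / 2`. Fully tied pairs
#' (zero rank variance) get p = 1.
#'
#' @param groups named list of numeric vectors, each of size >= 2.
#' @param alpha familywise significance level (default 0.01).
#' @param correction `"bonferroni"` or `"none"`.
#' @return an object of class `significance_matrix` with `p` (raw
#'   p-values), `significant` (logical), `alpha`, `correction`, `m`.
#' @export
pairwise_mann_whitney <- function(groups, alpha = 0.01,
                                  correction = c("bonferroni", "none")) {
  correction <- match.arg(correction)
  stopifnot(is.list(groups), length(groups) >= 2)
  if (any(vapply(groups, length, integer(1)) < 2))
    stop("every group needs at least 2 values")
  g <- length(groups)
  nm <- names(groups) %||% paste0("group", seq_len(g))
  p <- matrix(NA_real_, g, g, dimnames = list(nm, nm))
  for (i in seq_len(g - 1)) for (j in (i + 1):g) {
    pv <- suppressWarnings(
      stats::wilcox.test(groups[[i]], groups[[j]], exact = FALSE,
                         correct = FALSE)$p.value)
    if (is.na(pv)) pv <- 1 # zero rank variance: fully tied
    p[i, j] <- p[j, i] <- pv
  }
  m <- g * (g - 1) / 2
  thr <- if (correction == "bonferroni") alpha / m else alpha
  sig <- p < thr
  structure(list(p = p, significant = sig, alpha = alpha,
                 correction = correction, m = m),
            class = "significance_matrix")
}

#' @export
print.significance_matrix <- function(x, ...) {
  cat(sprintf("<significance_matrix> %d groups, %d comparisons, %d significant (alpha %.3g, %s)\n",
              nrow(x$p), x$m, sum(x$significant[upper.tri(x$significant)]),
              x$alpha, x$correction))
  invisible(x)
}

#' Summarize an experiment's results per procedure
#'
#' Per procedure and variable set: mean D, stability, range-size
#' variation, distance and Boyce indices; the distance class at the
#' standard cutpoints (`low` d < 60, `intermediate` 60 <= d <= 70,
#' `high` d > 70); and counts of cases in the range-size-variation
#' magnitude bins (|RSV| < 2, 2 <= |RSV| <= 5, > 5). The per-case rows
#' (one point per species x procedure) double as scatter-plot data.
#'
#' @param result an `experiment_result` or its `results` data frame.
#' @return list with `summary` (per procedure x variable set) and
#'   `scatter` (per-case rows).
#' @export
summarize_experiment <- function(result) {
  res <- if (inherits(result, "experiment_result")) result$results else result
  ok <- res[is.na(res$error) & !is.na(res$d), , drop = FALSE]
  if (nrow(ok) == 0) stop("no successful comparison rows to summarize")
  key <- interaction(ok$procedure, ok$variable_set, drop = TRUE)
  agg <- function(v) as.numeric(tapply(v, key, mean, na.rm = TRUE))
  summary <- data.frame(
    procedure = as.character(tapply(ok$procedure, key, `[`, 1)),
    variable_set = as.character(tapply(ok$variable_set, key, `[`, 1)),
    n = as.integer(table(key)),
    D = agg(ok$D), S = agg(ok$S), RSV = agg(ok$RSV), d = agg(ok$d),
    stringsAsFactors = FALSE)
  if ("CBI_modern" %in% names(ok)) {
    summary$CBI_modern <- agg(suppressWarnings(as.numeric(ok$CBI_modern)))
    summary$CBI_projected <- agg(suppressWarnings(as.numeric(ok$CBI_projected)))
  }
  summary$distance_class <- distance_class(summary$d)
  summary$n_rsv_lt2 <- as.integer(tapply(abs(ok$RSV) < 2, key, sum))
  summary$n_rsv_2_5 <- as.integer(tapply(abs(ok$RSV) >= 2 & abs(ok$RSV) <= 5,
                                         key, sum))
  summary$n_rsv_gt5 <- as.integer(tapply(abs(ok$RSV) > 5, key, sum))
  rownames(summary) <- NULL
  list(summary = summary,
       scatter = ok[, c("species", "procedure", "variable_set", "D", "S",
                        "RSV", "d")])
}

#' @rdname summarize_experiment
#' @param d numeric vector of distances.
#' @export
distance_class <- function(d) {
  ifelse(d < 60, "low", ifelse(d <= 70, "intermediate", "high"))
}

#' The default synthetic benchmark
#'
#' A fixed configuration used to demonstrate behavioural recovery: 10
#' niche-conserved virtual species under moderate climate drift, modern
#' samples of 150 records (historical half that), the three a-priori
#' variables, and seven genuine procedures plus the permuted-label
#' control. Genuine procedures should land at low-to-intermediate
#' distances while the control, whose suitability surface carries no
#' signal, falls in the high-distance class.
#'
#' @param evaluate compute evaluation metrics too (slower)?
#' @param ... overrides passed to [experiment_config()].
#' @return an [experiment_config()].
#' @export
benchmark_config <- function(evaluate = FALSE, ...) {
  experiment_config(
    n_species = 10,
    procedures = c("bioclim", "domain", "glm", "kde", "maxent_surrogate",
                   "rf", "fda", "control_permuted"),
    variable_sets = "apriori3",
    evaluate = evaluate,
    ...)
}

#' Run the default benchmark and report distance classes
#'
#' @param seed master integer seed.
#' @param config optionally, an alternative [experiment_config()].
#' @return list with the `experiment_result`, the per-procedure
#'   `summary`, and `classes` (named distance-class vector).
#' @export
run_benchmark <- function(seed = 1, config = benchmark_config()) {
  res <- run_experiment(config, seed = seed)
  summ <- summarize_experiment(res)$summary
  classes <- stats::setNames(summ$distance_class, summ$procedure)
  list(result = res, summary = summ, classes = classes)
}

#' Compare modern and projected Boyce indices per procedure
#'
#' For each procedure and variable set, tests whether the Boyce index of
#' the modern map differs from that of the projected map across species,
#' with the same two-sided tie-corrected Mann-Whitney machinery used for
#' the other metrics (values are paired across species but tested
#' unpaired, matching the protocol's stated tests).
#'
#' @param result an `experiment_result` run with `evaluate = TRUE`.
#' @param alpha significance level (default 0.01).
#' @return data frame with one row per procedure x variable set: mean
#'   CBI of each map type, the Mann-Whitney p-value, and a significance
#'   flag.
#' @export
compare_cbi <- function(result, alpha = 0.01) {
  res <- result$results
  ok <- res[is.na(res$error) & !is.na(res$CBI_modern) &
              !is.na(res$CBI_projected), , drop = FALSE]
  if (nrow(ok) == 0) stop("no rows with both Boyce indices; run with evaluate = TRUE")
  out <- list()
  for (vs in unique(ok$variable_set)) {
    sub <- ok[ok$variable_set == vs, ]
    for (pr in unique(sub$procedure)) {
      g <- sub[sub$procedure == pr, ]
      if (nrow(g) < 2) next
      pv <- suppressWarnings(
        stats::wilcox.test(g$CBI_modern, g$CBI_projected, exact = FALSE,
                           correct = FALSE)$p.value)
      if (is.na(pv)) pv <- 1
      out[[length(out) + 1]] <- data.frame(
        procedure = pr, variable_set = vs, n = nrow(g),
        mean_CBI_modern = mean(g$CBI_modern),
        mean_CBI_projected = mean(g$CBI_projected),
        p = pv, significant = pv < alpha, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Read an experiment scenario from a YAML file
#'
#' The YAML keys mirror the arguments of [experiment_config()]; a
#' `drift` mapping is passed to [drift_spec()]. A `seed` key, if
#' present, is returned alongside.
#'
#' @param path YAML file path.
#' @return list with `config` (an [experiment_config()]) and `seed`.
#' @export
read_scenario <- function(path) {
  sc <- yaml::read_yaml(path)
  seed <- sc$seed %||% 1
  sc$seed <- NULL
  if (!is.null(sc$drift)) sc$drift <- do.call(drift_spec, sc$drift)
  if (!is.null(sc$shape)) sc$shape <- unlist(sc$shape)
  if (!is.null(sc$variable_sets)) sc$variable_sets <- unlist(sc$variable_sets)
  if (!is.null(sc$procedures)) sc$procedures <- unlist(sc$procedures)
  list(config = do.call(experiment_config, sc), seed = seed)
}

#' Write experiment outputs to disk
#'
#' Results as CSV, the significance matrices for a metric as CSV, and
#' the per-procedure summary as JSON.
#'
#' @param result an `experiment_result`.
#' @param dir output directory.
#' @param metric metric for the significance matrices (default `"d"`).
#' @param alpha significance level.
#' @return the directory, invisibly.
#' @export
write_experiment <- function(result, dir, metric = "d", alpha = 0.01) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(result$results, file.path(dir, "results.csv"),
                   row.names = FALSE)
  summ <- summarize_experiment(result)
  utils::write.csv(summ$scatter, file.path(dir, "scatter.csv"),
                   row.names = FALSE)
  jsonlite::write_json(summ$summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  for (vs in unique(result$results$variable_set)) {
    ok <- result$results[result$results$variable_set == vs &
                           is.na(result$results$error), ]
    groups <- split(ok[[metric]], ok$procedure)
    groups <- groups[vapply(groups, length, integer(1)) >= 2]
    if (length(groups) >= 2) {
      sm <- pairwise_mann_whitney(groups, alpha = alpha)
      utils::write.csv(sm$p,
                       file.path(dir, sprintf("mw_p_%s_%s.csv", metric, vs)))
      utils::write.csv(sm$significant,
                       file.path(dir, sprintf("mw_sig_%s_%s.csv", metric, vs)))
    }
  }
  if (!is.null(result$mop))
    utils::write.csv(result$mop, file.path(dir, "mop_strict_pct.csv"),
                     row.names = FALSE)
  invisible(dir)
}
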