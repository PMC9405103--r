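#' Algorithm adapters
#'
#' Every modelling procedure is wrapped in an adapter: a fitted state
#' plus a `predict` method mapping a matrix of environment vectors to
#' suitability scores in `[0, 1]`. Presence-only scorers (BIOCLIM,
#' DOMAIN, KDE) are implemented natively; classifier slots (logistic
#' GLM, GAM, tree, random forest, SVM, neural network, discriminant
#' analysis, L1-regularized logistic "Maxent surrogate") train on
#' presences versus a background or pseudoabsence contrast sample.
#'
#' @param object a fitted `enm_adapter`.
#' @param newdata numeric matrix (points x variables) in the adapter's
#'   training variable space.
#' @param ... unused.
#' @return `predict` returns a numeric vector of scores in `[0, 1]`.
#' @name enm_adapter
#' @export
predict.enm_adapter <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$variables))
    stop("newdata has ", ncol(newdata), " variables; adapter was trained on ",
         length(object$variables))
  s <- object$score(newdata)
  pmin(1, pmax(0, as.numeric(s)))
}

#' @export
print.enm_adapter <- function(x, ...) {
  cat(sprintf("<enm_adapter> %s (%s), %d variables\n",
              x$name, x$input_kind, length(x$variables)))
  invisible(x)
}

new_adapter <- function(name, input_kind, variables, score, extra = list()) {
  structure(c(list(name = name, input_kind = input_kind,
                   variables = variables, score = score), extra),
            class = "enm_adapter")
}

#' BIOCLIM percentile envelope
#'
#' Per variable, the empirical CDF of the training presences is computed
#' with the midpoint tie convention `F(x) = (#<x + 0.5 #=x) / n`; the
#' score of a candidate environment is `2 * min_j min(F_j, 1 - F_j)`
#' clamped to `[0, 1]`, and 0 whenever any variable falls strictly
#' outside the training range.
#'
#' @param presence_env matrix (presences x variables), at least 5 rows.
#' @return an `enm_adapter`.
#' @export
fit_bioclim <- function(presence_env) {
  X <- as.matrix(presence_env)
  if (nrow(X) < 5) stop("BIOCLIM needs at least 5 presences")
  sorted <- lapply(seq_len(ncol(X)), function(j) sort(X[, j]))
  n <- nrow(X)
  score <- function(newdata) {
    tail_min <- rep(Inf, nrow(newdata))
    outside <- rep(FALSE, nrow(newdata))
    for (j in seq_along(sorted)) {
      v <- sorted[[j]]; x <- newdata[, j]
      nle <- findInterval(x, v)
      nlt <- findInterval(x, v, left.open = TRUE)
      F <- (nlt + 0.5 * (nle - nlt)) / n
      tail_min <- pmin(tail_min, pmin(F, 1 - F))
      outside <- outside | x < v[1] | x > v[n]
    }
    out <- 2 * tail_min
    out[outside] <- 0
    out
  }
  new_adapter("bioclim", "presence_only", colnames(X) %||% seq_len(ncol(X)),
              score)
}

#' DOMAIN Gower-similarity scorer
#'
#' Score of a candidate is one minus the Gower distance (mean absolute
#' per-variable difference scaled by the training range) to the closest
#' training presence, clamped to `[0, 1]`. Variables with zero training
#' range are dropped with a warning.
#'
#' @param presence_env matrix (presences x variables), at least 2 rows.
#' @return an `enm_adapter`.
#' @export
fit_domain <- function(presence_env) {
  X <- as.matrix(presence_env)
  if (nrow(X) < 2) stop("DOMAIN needs at least 2 presences")
  rng <- apply(X, 2, function(v) diff(range(v)))
  if (all(rng == 0)) stop("all variables have zero training range")
  if (any(rng == 0)) {
    warning("dropping zero-range variable(s): ",
            paste(colnames(X)[rng == 0], collapse = ", "))
  }
  keep <- which(rng > 0)
  Xk <- X[, keep, drop = FALSE]
  rk <- rng[keep]
  vars <- colnames(X) %||% seq_len(ncol(X))
  score <- function(newdata) {
    Q <- newdata[, keep, drop = FALSE]
    acc <- matrix(0, nrow(Q), nrow(Xk))
    for (j in seq_along(rk)) {
      acc <- acc + abs(outer(Q[, j], Xk[, j], "-")) / rk[j]
    }
    1 - apply(acc, 1, min) / length(rk)
  }
  new_adapter("domain", "presence_only", vars, score)
}

#' Gaussian product-kernel density scorer
#'
#' Presence environments are standardized per dimension; a Gaussian
#' product kernel with per-dimension Silverman bandwidth
#' `h = (4 / ((L + 2) n))^(1 / (L + 4))` (on the standardized scale)
#' estimates the presence density, and scores are the density divided
#' by its maximum over the training presences, clamped to `[0, 1]`.
#'
#' @param presence_env matrix (presences x variables), at least
#'   `L + 2` rows.
#' @param bandwidth_rule `"silverman"` (default) or a numeric vector of
#'   per-dimension bandwidths on the standardized scale.
#' @param standardize standardize dimensions first (default `TRUE`; set
#'   `FALSE` to interpret `bandwidth_rule` on the raw scale).
#' @return an `enm_adapter`; its `density_fun` element exposes the raw
#'   (unnormalized) density for diagnostics.
#' @export
fit_kde <- function(presence_env, bandwidth_rule = "silverman",
                    standardize = TRUE) {
  X <- as.matrix(presence_env)
  L <- ncol(X); n <- nrow(X)
  if (n < L + 2) stop("KDE needs at least L + 2 presences")
  ctr <- if (standardize) colMeans(X) else rep(0, L)
  scl <- if (standardize) apply(X, 2, stats::sd) else rep(1, L)
  if (any(scl == 0)) stop("zero-variance dimension(s): ",
                          paste(colnames(X)[scl == 0], collapse = ", "))
  Z <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  h <- if (identical(bandwidth_rule, "silverman")) {
    rep((4 / ((L + 2) * n))^(1 / (L + 4)), L)
  } else rep(as.numeric(bandwidth_rule), length.out = L)
  density_fun <- function(newdata) {
    Q <- sweep(sweep(as.matrix(newdata), 2, ctr), 2, scl, "/")
    logk <- matrix(0, nrow(Q), n)
    for (j in seq_len(L)) {
      logk <- logk + stats::dnorm(outer(Q[, j], Z[, j], "-"), sd = h[j],
                                  log = TRUE)
    }
    rowMeans(exp(logk))
  }
  dmax <- max(density_fun(X))
  score <- function(newdata) density_fun(newdata) / dmax
  new_adapter("kde", "presence_only", colnames(X) %||% seq_len(ncol(X)),
              score, extra = list(density_fun = density_fun))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# standardized linear + quadratic design used by the logistic learners
quad_design <- function(X, ctr, scl) {
  Z <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  cbind(Z, Z^2)
}

# Native iteratively reweighted least squares with a small ridge penalty
# on the non-intercept coefficients (stabilizes separable fits).
irls_ridge_logistic <- function(X, y, lambda = 1e-6, maxit = 50, tol = 1e-8) {
  Xd <- cbind(1, X)
  beta <- rep(0, ncol(Xd))
  for (it in seq_len(maxit)) {
    eta <- drop(Xd %*% beta)
    p <- stats::plogis(eta)
    w <- pmax(p * (1 - p), 1e-10)
    z <- eta + (y - p) / w
    A <- crossprod(Xd, Xd * w)
    diag(A)[-1] <- diag(A)[-1] + lambda
    beta_new <- drop(solve(A, crossprod(Xd, w * z)))
    if (max(abs(beta_new - beta)) < tol) {
      beta <- beta_new
      break
    }
    beta <- beta_new
  }
  beta
}

#' Fit a presence-versus-contrast classifier adapter
#'
#' Trains a binary scorer on presence (= 1) versus contrast (= 0)
#' environment vectors. `glm_logistic` is a native implementation:
#' logistic regression on standardized linear plus quadratic terms,
#' fitted by iteratively reweighted least squares with a ridge penalty
#' of 1e-6. `maxent_surrogate` is an L1-regularized logistic regression
#' on the same features against a large background sample (a surrogate
#' sharing Maxent's exponential-family form, not Maxent itself;
#' regularization weight chosen by BIC along the glmnet path). The
#' remaining learners delegate to standard engines: `tree` (rpart),
#' `forest` (randomForest), `svm` (e1071, probability outputs),
#' `neuralnet` (nnet), `discriminant` (MASS::lda), `gam`
#' (mgcv smooths).
#'
#' @param presence_env,contrast_env non-empty matrices over the same
#'   variables.
#' @param learner one of `"glm_logistic"`, `"maxent_surrogate"`,
#'   `"tree"`, `"forest"`, `"svm"`, `"neuralnet"`, `"discriminant"`,
#'   `"gam"`.
#' @param permute_labels if `TRUE`, the 0/1 labels are randomly permuted
#'   before fitting (the degenerate control procedure; uses the current
#'   RNG stream).
#' @return an `enm_adapter`.
#' @export
fit_classifier <- function(presence_env, contrast_env,
                           learner = c("glm_logistic", "maxent_surrogate",
                                       "tree", "forest", "svm", "neuralnet",
                                       "discriminant", "gam"),
                           permute_labels = FALSE) {
  learner <- match.arg(learner)
  P <- as.matrix(presence_env); C <- as.matrix(contrast_env)
  if (nrow(P) == 0 || nrow(C) == 0)
    stop("both presence and contrast samples must be non-empty")
  X <- rbind(P, C)
  y <- c(rep(1, nrow(P)), rep(0, nrow(C)))
  if (permute_labels) y <- sample(y)
  if (length(unique(y)) < 2) stop("degenerate single-class input")
  vars <- colnames(X) %||% paste0("v", seq_len(ncol(X)))
  colnames(X) <- vars

  score <- switch(
    learner,
    glm_logistic = {
      ctr <- colMeans(X); scl <- pmax(apply(X, 2, stats::sd), 1e-12)
      beta <- irls_ridge_logistic(quad_design(X, ctr, scl), y)
      function(newdata)
        stats::plogis(drop(cbind(1, quad_design(newdata, ctr, scl)) %*% beta))
    },
    maxent_surrogate = {
      ctr <- colMeans(X); scl <- pmax(apply(X, 2, stats::sd), 1e-12)
      D <- quad_design(X, ctr, scl)
      fit <- glmnet::glmnet(D, y, family = "binomial", alpha = 1,
                            standardize = FALSE)
      dev <- (1 - fit$dev.ratio) * fit$nulldev
      bic <- dev + log(nrow(D)) * fit$df
      lam <- fit$lambda[which.min(bic)]
      function(newdata)
        as.numeric(stats::predict(fit, quad_design(newdata, ctr, scl),
                                  s = lam, type = "response"))
    },
    tree = {
      df <- data.frame(X, .y = factor(y, levels = c(0, 1)))
      fit <- rpart::rpart(.y ~ ., data = df, method = "class")
      function(newdata)
        stats::predict(fit, data.frame(matrix(newdata, ncol = length(vars),
                                              dimnames = list(NULL, vars))),
                       type = "prob")[, "1"]
    },
    forest = {
      fit <- randomForest::randomForest(X, factor(y, levels = c(0, 1)),
                                        ntree = 500)
      function(newdata) {
        colnames(newdata) <- vars
        stats::predict(fit, newdata, type = "prob")[, "1"]
      }
    },
    svm = {
      fit <- e1071::svm(X, factor(y, levels = c(0, 1)), probability = TRUE)
      function(newdata) {
        colnames(newdata) <- vars
        pr <- stats::predict(fit, newdata, probability = TRUE)
        attr(pr, "probabilities")[, "1"]
      }
    },
    neuralnet = {
      ctr <- colMeans(X); scl <- pmax(apply(X, 2, stats::sd), 1e-12)
      Z <- sweep(sweep(X, 2, ctr), 2, scl, "/")
      fit <- nnet::nnet(Z, y, size = 5, decay = 0.01, maxit = 200,
                        trace = FALSE)
      function(newdata)
        as.numeric(stats::predict(fit, sweep(sweep(newdata, 2, ctr), 2, scl, "/")))
    },
    discriminant = {
      fit <- MASS::lda(X, grouping = factor(y, levels = c(0, 1)))
      function(newdata) {
        colnames(newdata) <- vars
        stats::predict(fit, newdata)$posterior[, "1"]
      }
    },
    gam = {
      df <- data.frame(X, .y = y)
      kk <- max(3, min(10, floor(nrow(X) / 10)))
      form <- stats::as.formula(paste(".y ~",
        paste(sprintf("s(%s, k = %d)", vars, kk), collapse = " + ")))
      fit <- mgcv::gam(form, data = df, family = stats::binomial())
      function(newdata)
        as.numeric(stats::predict(fit,
          data.frame(matrix(newdata, ncol = length(vars),
                            dimnames = list(NULL, vars))),
          type = "response"))
    })

  kind <- if (learner == "maxent_surrogate") "presence_background"
          else "presence_pseudoabsence"
  new_adapter(learner, kind, vars, score)
}

#' Sample background cells from a study area
#'
#' Draws a uniform sample of valid cells without replacement. Background
#' samples describe the whole study area, so presence cells are not
#' excluded; pseudoabsence samples (the `exclude_presences = TRUE`
#' variant used by the presence-pseudoabsence procedures) never coincide
#' with presence cells.
#'
#' @param env an [env_stack()].
#' @param n cells to draw; with `rule = "equal_presences"` or
#'   `"presences_x10"`, `n` is derived from `presence_cells` instead.
#' @param seed integer seed.
#' @param rule `"fixed_n"` (use `n`), `"equal_presences"`, or
#'   `"presences_x10"`.
#' @param presence_cells cell indices of the presences (required by the
#'   presence-derived rules and by `exclude_presences`).
#' @param exclude_presences drop presence cells from the candidate pool
#'   (pseudoabsence semantics).
#' @return matrix (n x layers) of environment vectors, with attribute
#'   `cells` giving the sampled cell indices.
#' @export
sample_background <- function(env, n = NULL, seed = 1,
                              rule = c("fixed_n", "equal_presences",
                                       "presences_x10"),
                              presence_cells = NULL,
                              exclude_presences = FALSE) {
  rule <- match.arg(rule)
  vals <- env_values(env)
  cells <- attr(vals, "cells")
  if (rule != "fixed_n") {
    if (is.null(presence_cells)) stop("presence-derived rules need presence_cells")
    n <- length(presence_cells) * if (rule == "presences_x10") 10L else 1L
  }
  if (is.null(n)) stop("n is required for rule 'fixed_n'")
  pool <- seq_along(cells)
  if (exclude_presences && !is.null(presence_cells))
    pool <- pool[!(cells %in% presence_cells)]
  if (n > length(pool))
    stop(sprintf("requested %d contrast cells but only %d are available",
                 n, length(pool)))
  with_seed(derive_seed(seed, "background", rule, n), {
    take <- pool[sample.int(length(pool), n)]
    out <- vals[take, , drop = FALSE]
    attr(out, "cells") <- cells[take]
    out
  })
}

#' Combine member suitability maps into an ensemble
#'
#' Cellwise weighted mean of member maps after weight normalization.
#' In `auc_weighted` mode, members are weighted by their test AUC and
#' members below the AUC floor are dropped (falling back to all members
#' if none pass).
#'
#' @param members list of [suit_map()]s on one grid.
#' @param weights numeric weights (non-negative, not all zero), or
#'   `"auc_weighted"`.
#' @param auc_test per-member test AUCs (required for `auc_weighted`).
#' @param auc_floor members below this AUC are dropped (default 0.7).
#' @return the combined [suit_map()].
#' @export
ensemble_predict <- function(members, weights = "auc_weighted",
                             auc_test = NULL, auc_floor = 0.7) {
  stopifnot(length(members) >= 1)
  ref <- members[[1]]
  for (m in members) {
    if (!identical(dim(m$values), dim(ref$values)) ||
        !identical(m$mask, ref$mask))
      stop("ensemble members must share grid and mask")
  }
  if (identical(weights, "auc_weighted")) {
    if (is.null(auc_test) || length(auc_test) != length(members))
      stop("auc_weighted mode needs one auc_test per member")
    keep <- which(auc_test >= auc_floor)
    if (length(keep) == 0) keep <- seq_along(members)
    members <- members[keep]
    weights <- auc_test[keep]
  }
  weights <- as.numeric(weights)
  if (length(weights) != length(members)) stop("one weight per member required")
  if (any(weights < 0) || sum(weights) == 0)
    stop("weights must be non-negative and not all zero")
  w <- weights / sum(weights)
  acc <- ref$values * 0
  for (i in seq_along(members)) acc <- acc + w[i] * members[[i]]$values
  suit_map(acc, ref$mask,
           source = c(ref$source[setdiff(names(ref$source), "procedure")],
                      list(procedure = "ensemble")),
           origin = ref$origin)
}

#' The procedure registry
#'
#' Named adapter specifications for the modelling procedures, keyed by
#' procedure name. Each spec records the fitter (presence-only scorer or
#' classifier learner), the contrast design (background versus
#' pseudoabsence, and the sample-size rule), and for the ensemble its
#' member procedures. The default set has 12 procedures: three native
#' presence-only scorers with 1000 background cells (`bioclim`,
#' `domain`, `kde`), classifiers with 1000 pseudoabsences (`glm`,
#' `gam`), classifiers with as many pseudoabsences as presences (`fda`,
#' `cta`, `ann`, `rf`, `svm`), the `maxent_surrogate` against up to
#' 10,000 background cells, and a 7-member weighted `ensemble` with 10
#' pseudoabsences per presence. `control_permuted` (not in the default
#' set) is a deliberately degenerate control: a logistic GLM trained on
#' randomly permuted labels.
#'
#' Background samples may include presence cells (the background is the
#' whole study area); pseudoabsence samples exclude them. Fixed-size
#' contrast rules are capped at the number of available cells in the
#' study area.
#'
#' @param name procedure name.
#' @return `procedure_registry()` returns the named list of specs;
#'   `procedure_spec(name)` one spec; `default_procedures()` the default
#'   12 procedure names.
#' @export
procedure_registry <- function() {
  bg1000 <- list(kind = "background", rule = "fixed_n", n = 1000)
  pa1000 <- list(kind = "pseudoabsence", rule = "fixed_n", n = 1000)
  pa_eq <- list(kind = "pseudoabsence", rule = "equal_presences")
  list(
    bioclim = list(name = "bioclim", fitter = "bioclim", contrast = bg1000),
    domain = list(name = "domain", fitter = "domain", contrast = bg1000),
    kde = list(name = "kde", fitter = "kde", contrast = bg1000),
    glm = list(name = "glm", fitter = "classifier", learner = "glm_logistic",
               contrast = pa1000),
    gam = list(name = "gam", fitter = "classifier", learner = "gam",
               contrast = pa1000),
    fda = list(name = "fda", fitter = "classifier", learner = "discriminant",
               contrast = pa_eq),
    cta = list(name = "cta", fitter = "classifier", learner = "tree",
               contrast = pa_eq),
    ann = list(name = "ann", fitter = "classifier", learner = "neuralnet",
               contrast = pa_eq),
    rf = list(name = "rf", fitter = "classifier", learner = "forest",
              contrast = pa_eq),
    svm = list(name = "svm", fitter = "classifier", learner = "svm",
               contrast = pa_eq),
    maxent_surrogate = list(name = "maxent_surrogate", fitter = "classifier",
                            learner = "maxent_surrogate",
                            contrast = list(kind = "background",
                                            rule = "fixed_n", n = 10000)),
    ensemble = list(name = "ensemble", fitter = "ensemble",
                    members = c("glm", "gam", "maxent_surrogate", "rf",
                                "cta", "ann", "fda"),
                    contrast = list(kind = "pseudoabsence",
                                    rule = "presences_x10")),
    control_permuted = list(name = "control_permuted", fitter = "classifier",
                            learner = "glm_logistic", permute_labels = TRUE,
                            contrast = pa1000)
  )
}

#' @rdname procedure_registry
#' @export
procedure_spec <- function(name) {
  reg <- procedure_registry()
  if (!name %in% names(reg))
    stop("unknown procedure '", name, "'; available: ",
         paste(names(reg), collapse = ", "))
  reg[[name]]
}

#' @rdname procedure_registry
#' @export
default_procedures <- function() {
  c("bioclim", "domain", "glm", "gam", "fda", "cta", "ann", "rf", "svm",
    "maxent_surrogate", "kde", "ensemble")
}

# Draw the contrast sample prescribed by a procedure spec.
# Fixed-n rules are capped at the available pool size.
sample_contrast <- function(env, contrast, presence_cells, seed) {
  exclude <- contrast$kind == "pseudoabsence"
  n <- contrast$n
  if (contrast$rule == "fixed_n") {
    avail <- n_valid_cells(env) -
      if (exclude) length(unique(presence_cells)) else 0L
    n <- min(n, avail)
  }
  sample_background(env, n = n, seed = seed, rule = contrast$rule,
                    presence_cells = presence_cells,
                    exclude_presences = exclude)
}

# Fit one adapter per a registry spec (single-procedure specs only).
fit_procedure <- function(spec, presence_env, contrast_env) {
  switch(spec$fitter,
         bioclim = fit_bioclim(presence_env),
         domain = fit_domain(presence_env),
         kde = fit_kde(presence_env),
         classifier = fit_classifier(presence_env, contrast_env,
                                     learner = spec$learner,
                                     permute_labels = isTRUE(spec$permute_labels)),
         stop("spec '", spec$name, "' is not a single-procedure fitter"))
}
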