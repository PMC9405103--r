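test_that("BIOCLIM scores follow the percentile-envelope formula", {
  X <- cbind(v1 = 1:10, v2 = 1:10)
  ad <- fit_bioclim(X)
  # medians of both variables -> both tails 0.5 -> score 1
  expect_equal(predict(ad, cbind(5.5, 5.5)), 1)
  # v1 at its 25th percentile (3rd of 10 values), v2 at the median -> 0.5
  expect_equal(predict(ad, cbind(3, 5.5)), 0.5)
  # any variable strictly outside the training range -> 0
  expect_equal(predict(ad, cbind(0.99, 5.5)), 0)
  expect_equal(predict(ad, cbind(5.5, 10.01)), 0)
  expect_error(fit_bioclim(X[1:4, ]), "at least 5")
})

test_that("DOMAIN scores follow the Gower-similarity formula", {
  X <- rbind(c(0, 0), c(10, 2))
  ad <- fit_domain(X)
  expect_equal(predict(ad, rbind(c(10, 2))), 1)   # exact presence
  expect_equal(predict(ad, rbind(c(5, 1))), 0.5)  # mean(5/10, 1/2) = 0.5
  expect_equal(predict(ad, rbind(c(100, 50))), 0) # clamped
  expect_error(fit_domain(rbind(c(1, 1), c(1, 1))), "zero")
})

test_that("KDE normalizes at the densest presence and matches the two-kernel oracle", {
  X1 <- matrix(c(-2, -1, 0, 1, 2), ncol = 1)
  ad <- fit_kde(X1)
  expect_equal(max(predict(ad, X1)), 1)
  # mirror symmetry
  expect_equal(predict(ad, matrix(1.5)), predict(ad, matrix(-1.5)),
               tolerance = 1e-10)
  # hand oracle: presences {0, 1}, bandwidth 1, raw scale:
  # density(0) = (phi(0) + phi(1)) / 2 = 0.3204565...
  ad2 <- fit_kde(matrix(c(0, 1, 0.4, 0.6), ncol = 1),
                 bandwidth_rule = 1, standardize = FALSE)
  dens <- ad2$density_fun(matrix(c(0, 1)))
  two_kernel <- function(q) (dnorm(q) + dnorm(q - 1)) / 2
  ad3 <- fit_kde(matrix(c(0, 1, 0.5), ncol = 1), bandwidth_rule = 1,
                 standardize = FALSE)
  expect_equal(ad3$density_fun(matrix(0)),
               (dnorm(0) + dnorm(1) + dnorm(0.5)) / 3, tolerance = 1e-12)
  expect_error(fit_kde(matrix(rep(1, 5), ncol = 1)), "zero-variance")
})

test_that("classifier adapters separate separable data and stay in [0, 1]", {
  withr::with_seed(10, {
    pres <- matrix(rnorm(60, 10), ncol = 1)
    bg <- matrix(rnorm(200, 0), ncol = 1)
  })
  for (lrn in c("glm_logistic", "maxent_surrogate", "tree", "forest",
                "svm", "neuralnet", "discriminant", "gam")) {
    ad <- withr::with_seed(1, fit_classifier(pres, bg, learner = lrn))
    sc_p <- predict(ad, pres); sc_b <- predict(ad, bg)
    expect_true(all(sc_p >= 0 & sc_p <= 1), info = lrn)
    expect_true(all(sc_b >= 0 & sc_b <= 1), info = lrn)
    expect_gte(auc(sc_p, sc_b), 0.99)
  }
  expect_error(fit_classifier(pres[0, , drop = FALSE], bg), "non-empty")
})

test_that("permuted labels give chance-level training AUC", {
  aucs <- numeric(100)
  for (i in 1:100) {
    withr::with_seed(i, {
      pres <- matrix(rnorm(30), ncol = 1)
      bg <- matrix(rnorm(30), ncol = 1)
      ad <- fit_classifier(pres, bg, learner = "glm_logistic",
                           permute_labels = TRUE)
    })
    aucs[i] <- auc(predict(ad, pres), predict(ad, bg))
  }
  expect_lt(abs(mean(aucs) - 0.5), 0.05)
})

test_that("background sampling honours the registry size rules and seeding", {
  env <- make_stack(list(a = matrix(rnorm(10000), 100, 100)))
  bg <- sample_background(env, n = 1000, seed = 1)
  expect_equal(nrow(bg), 1000)
  expect_identical(bg, sample_background(env, n = 1000, seed = 1))
  expect_false(identical(bg, sample_background(env, n = 1000, seed = 2)))
  pres <- attr(env_values(env), "cells")[1:37]
  x10 <- sample_background(env, seed = 1, rule = "presences_x10",
                           presence_cells = pres)
  expect_equal(nrow(x10), 370)
  eq <- sample_background(env, seed = 1, rule = "equal_presences",
                          presence_cells = pres, exclude_presences = TRUE)
  expect_equal(nrow(eq), 37)
  expect_true(all(!attr(eq, "cells") %in% pres))
  expect_error(sample_background(env, n = 10001, seed = 1), "available")
})

test_that("ensemble combination is a convex cellwise mean with AUC weighting", {
  mask <- matrix(TRUE, 2, 2)
  m1 <- suit_map(matrix(c(0.2, 0.4, 0.6, 0.8), 2, 2), mask)
  m2 <- suit_map(matrix(c(0.6, 0.4, 0.2, 0.0), 2, 2), mask)
  expect_equal(ensemble_predict(list(m1, m1), c(1, 1))$values, m1$values)
  expect_equal(ensemble_predict(list(m1, m2), c(1, 0))$values, m1$values)
  expect_equal(ensemble_predict(list(m1, m2), c(1, 1))$values[1, 1], 0.4)
  # auc weighting drops sub-floor members
  out <- ensemble_predict(list(m1, m2), "auc_weighted",
                          auc_test = c(0.9, 0.5))
  expect_equal(out$values, m1$values)
  # all below floor: fall back to all members
  out2 <- ensemble_predict(list(m1, m2), "auc_weighted",
                           auc_test = c(0.6, 0.6))
  expect_equal(out2$values[1, 1], 0.4)
  bad <- suit_map(matrix(0.5, 3, 3), matrix(TRUE, 3, 3))
  expect_error(ensemble_predict(list(m1, bad), c(1, 1)), "share grid")
})

test_that("BIOCLIM and DOMAIN are invariant to shifting a variable", {
  withr::with_seed(4, {
    X <- cbind(rnorm(30), rnorm(30, sd = 3))
    Q <- cbind(rnorm(15), rnorm(15, sd = 3))
  })
  shift <- function(M) sweep(M, 2, c(100, 0), "+")
  expect_equal(predict(fit_bioclim(X), Q),
               predict(fit_bioclim(shift(X)), shift(Q)), tolerance = 1e-12)
  expect_equal(predict(fit_domain(X), Q),
               predict(fit_domain(shift(X)), shift(Q)), tolerance = 1e-12)
})

test_that("adapters recover a Gaussian niche from abundant presences", {
  tw <- tiny_world()
  envH <- tw$envH
  truth <- true_suitability(tw$world$species$species01, envH)
  occ <- sample_occurrences(truth, 500, "historical", seed = 31,
                            mode = "weighted")
  P <- env_extract(envH, occ$x, occ$y)
  vals <- env_values(envH)
  tvals <- truth$values[truth$mask]
  bg <- sample_background(envH, n = min(1000, n_valid_cells(envH)), seed = 5)
  for (fit in list(fit_bioclim(P), fit_domain(P), fit_kde(P),
                   withr::with_seed(1, fit_classifier(P, bg, "glm_logistic")),
                   withr::with_seed(1, fit_classifier(P, bg, "maxent_surrogate")),
                   withr::with_seed(1, fit_classifier(P, bg, "forest")))) {
    rho <- suppressWarnings(cor(predict(fit, vals), tvals,
                                method = "spearman"))
    expect_gt(rho, 0.5)
  }
})
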