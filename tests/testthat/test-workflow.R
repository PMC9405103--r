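test_that("replicate runs split presences 70/30 and produce 10 replicates", {
  tw <- tiny_world()
  envH <- tw$envH
  truth <- true_suitability(tw$world$species$species01, envH)
  occ <- sample_occurrences(truth, 100, "historical", seed = 17)
  P <- env_extract(envH, occ$x, occ$y)
  run <- run_replicates(P, "bioclim", envH, reps = 10, train_frac = 0.7,
                        seed = 5)
  expect_length(run$replicates, 10)
  for (rep in run$replicates) {
    expect_length(rep$train_idx, 70)
    expect_length(rep$test_idx, 30)
    expect_length(intersect(rep$train_idx, rep$test_idx), 0)
    expect_setequal(c(rep$train_idx, rep$test_idx), 1:100)
  }
  v <- run$avg$values[run$avg$mask]
  expect_true(all(v >= 0 & v <= 1))
})

test_that("a deterministic adapter with no subsampling averages to a single fit", {
  tw <- tiny_world()
  envH <- tw$envH
  P <- env_extract(envH, tw$cleaned$historical$x, tw$cleaned$historical$y)
  run <- run_replicates(P, "bioclim", envH, reps = 10, train_frac = 1,
                        seed = 5)
  single <- fit_bioclim(P)
  vals <- env_values(envH)
  expect_equal(run$avg$values[run$avg$mask], predict(single, vals))
  expect_true(all(is.na(vapply(run$replicates, `[[`, numeric(1),
                               "auc_test"))))
})

test_that("insufficient training presences name the adapter minimum", {
  env <- make_stack(list(a = matrix(rnorm(400), 20, 20)))
  P <- matrix(rnorm(4), ncol = 1)
  expect_error(run_replicates(P, "bioclim", env, train_frac = 1, seed = 1),
               "at least 5")
})

test_that("projection onto the fitting stack is the identity", {
  tw <- tiny_world()
  P <- env_extract(tw$envH, tw$cleaned$historical$x, tw$cleaned$historical$y)
  run <- run_replicates(P, "glm", tw$envH, seed = 3,
                        presence_cells = occ_cell_id(tw$envH,
                                                     tw$cleaned$historical$x,
                                                     tw$cleaned$historical$y))
  proj <- project(run, tw$envH)
  expect_identical(proj$values, run$avg$values)
})

test_that("projection re-evaluates the fitted envelope at shifted inputs", {
  tw <- tiny_world()
  envH <- tw$envH
  P <- env_extract(envH, tw$cleaned$historical$x, tw$cleaned$historical$y)
  run <- run_replicates(P, "bioclim", envH, reps = 3, seed = 4)
  delta <- 0.75
  shifted <- envH
  shifted$layers[, , "bio1"] <- shifted$layers[, , "bio1"] + delta
  proj <- project(run, shifted)
  # oracle: direct re-evaluation of each replicate at the shifted inputs
  vals <- env_values(shifted)
  acc <- 0
  for (rep in run$replicates) acc <- acc + predict(rep$adapter, vals)
  expect_equal(proj$values[proj$mask], acc / 3, tolerance = 1e-12)
})

test_that("cross-period pca3 projection demands alignment metadata", {
  pair <- make_climate_pair(c(16, 16),
                            drift_spec(temp_offset = 0.5,
                                       noise_sd_temp = 0.2),
                            seed = 19)
  rawH <- derive_bioclim(pair$historical)
  rawM <- derive_bioclim(pair$modern)
  pcH <- pca_reduce(rawH)
  pcM_plain <- pca_reduce(rawM)
  pcM_aligned <- pca_reduce(rawM, align_to = pcH)
  withr::with_seed(2, P <- env_values(pcH)[sample(200, 40), ])
  run <- run_replicates(P, "bioclim", pcH, reps = 2, seed = 1)
  expect_error(project(run, pcM_plain), "alignment")
  expect_s3_class(project(run, pcM_aligned), "suit_map")
  expect_identical(project(run, pcH)$values, run$avg$values)
  # layer mismatch
  expect_error(project(run, select_apriori(rawM)), "mismatch")
})

test_that("binarization calibrates the mean occurrence probability to prevalence", {
  map <- random_suit_map(25, 25, seed = 6)
  for (prev in c(0.02, 0.1, 0.4)) {
    bin <- prevalence_logistic_binarize(map, prev, mode = "expected_threshold")
    beta <- bin$threshold_meta$beta
    P <- plogis((map$values[map$mask] - beta) / bin$threshold_meta$alpha)
    expect_lt(abs(mean(P) - prev), 1e-6)
  }
  flat <- suit_map(matrix(0.3, 12, 12), matrix(TRUE, 12, 12))
  expect_error(prevalence_logistic_binarize(flat, 0.1), "constant")
})

test_that("the steep-curve limit reduces to direct thresholding", {
  map <- random_suit_map(25, 25, seed = 8)
  prev <- 0.15
  bin <- prevalence_logistic_binarize(map, prev, alpha = 1e-6,
                                      mode = "expected_threshold")
  beta <- bin$threshold_meta$beta
  direct <- as.numeric(map$values[map$mask] >= beta)
  expect_equal(bin$values[bin$mask], direct)
  expect_equal(sum(direct), sum(map$values[map$mask] > beta), tolerance = 1)
})

test_that("bernoulli binarization is seeded and hits the expected presence count", {
  map <- random_suit_map(40, 40, seed = 9)
  prev <- 0.2
  b1 <- prevalence_logistic_binarize(map, prev, mode = "bernoulli", seed = 3)
  b2 <- prevalence_logistic_binarize(map, prev, mode = "bernoulli", seed = 3)
  expect_identical(b1$values, b2$values)
  n <- sum(map$mask)
  count <- sum(b1$values[b1$mask])
  half <- 2.576 * sqrt(prev * (1 - prev) * n)
  expect_gt(count, prev * n - half)
  expect_lt(count, prev * n + half)
})

test_that("species prevalence is presence cells over valid cells", {
  mask <- matrix(TRUE, 10, 10)
  mask[1, ] <- FALSE
  env <- make_stack(list(a = matrix(rnorm(100), 10, 10)), mask = mask)
  occ <- occ_at(y = c(2, 2, 3), x = c(2, 2, 5)) # one duplicate cell
  expect_equal(species_prevalence(occ, env), 2 / 90)
})
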