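test_that("zero drift and zero noise reproduce the historical climate exactly", {
  pair <- make_climate_pair(c(12, 12), drift_spec(), seed = 3)
  expect_identical(pair$modern$tmin, pair$historical$tmin)
  expect_identical(pair$modern$tmax, pair$historical$tmax)
  expect_identical(pair$modern$prec, pair$historical$prec)
})

test_that("a constant temperature drift shifts every temperature layer additively", {
  pair <- make_climate_pair(c(12, 15), drift_spec(temp_offset = 2), seed = 3)
  expect_equal(pair$modern$tmax - pair$historical$tmax,
               array(2, dim(pair$modern$tmax)))
  expect_equal(pair$modern$tmin - pair$historical$tmin,
               array(2, dim(pair$modern$tmin)))
  expect_identical(pair$modern$prec, pair$historical$prec)
})

test_that("climate generation is a pure function of seed", {
  dr <- drift_spec(temp_offset = 1, noise_sd_temp = 0.5, noise_sd_prec = 3)
  a <- make_climate_pair(c(14, 14), dr, seed = 11)
  b <- make_climate_pair(c(14, 14), dr, seed = 11)
  c <- make_climate_pair(c(14, 14), dr, seed = 12)
  expect_identical(a, b)
  expect_false(identical(a$historical$tmin, c$historical$tmin))
  expect_false(identical(a$modern$tmax, c$modern$tmax))
})

test_that("climate invariants hold under noisy drift and bad configs error", {
  dr <- drift_spec(temp_offset = 3, prec_offset = -40, noise_sd_temp = 2,
                   noise_sd_prec = 30)
  pair <- make_climate_pair(c(16, 16), dr, seed = 5)
  expect_true(all(pair$modern$tmax >= pair$modern$tmin))
  expect_true(all(pair$modern$prec >= 0))
  expect_error(make_climate_pair(c(8, 20), drift_spec(), seed = 1),
               "at least 10")
  expect_error(drift_spec(noise_sd_temp = -1), "non-negative")
})

test_that("true suitability follows the Gaussian niche formula", {
  env <- stack1(matrix(c(0, 1, 2, 5), 2, 2))
  sp <- virtual_species_spec("s", niche_mean = 0, niche_cov = matrix(1),
                             max_suitability = 1)
  s <- true_suitability(sp, env)
  expect_equal(s$values[1, 1], 1)                     # at the optimum
  expect_equal(s$values[2, 1], exp(-0.5), tolerance = 1e-12)
  sp2 <- virtual_species_spec("s", 0, matrix(1), max_suitability = 0.8)
  expect_equal(true_suitability(sp2, env)$values[1, 1], 0.8)
})

test_that("suitability is invariant under joint invertible reparameterization", {
  withr::with_seed(42, {
    nr <- 6; nc <- 6
    layers <- list(a = matrix(rnorm(36), nr), b = matrix(rnorm(36), nr),
                   c = matrix(rnorm(36), nr))
    env <- make_stack(layers)
    mu <- c(0.2, -0.1, 0.5)
    S <- crossprod(matrix(rnorm(9), 3)) + diag(3)
    A <- matrix(rnorm(9), 3) + 2 * diag(3)
    b <- c(1, -2, 3)
    vals <- env_values(env)
    tv <- vals %*% t(A) + matrix(b, nrow(vals), 3, byrow = TRUE)
    tlayers <- lapply(1:3, function(j) matrix(tv[, j], nr, nc))
    names(tlayers) <- c("a", "b", "c")
    env2 <- make_stack(tlayers)
    s1 <- true_suitability(virtual_species_spec("s", mu, S), env)
    s2 <- true_suitability(
      virtual_species_spec("s", as.numeric(A %*% mu + b), A %*% S %*% t(A)),
      env2)
    expect_equal(s1$values, s2$values, tolerance = 1e-8)
  })
})

test_that("degenerate niche covariances are rejected", {
  expect_error(virtual_species_spec("s", c(0, 0), matrix(c(1, 1, 1, 1), 2)),
               "positive-definite")
  expect_error(virtual_species_spec("s", c(0, 0),
                                    matrix(c(1, 0.5, 0.2, 1), 2)),
               "symmetric")
})

test_that("weighted sampling returns exactly the positive-support cells when forced", {
  v <- matrix(0, 5, 5)
  v[c(2, 9, 17)] <- c(0.5, 0.9, 0.1)
  truth <- suit_map(v, matrix(TRUE, 5, 5), source = list(species = "sp"))
  occ <- sample_occurrences(truth, 3, "modern", seed = 1)
  got <- sort((occ$x - 1) * 5 + occ$y)
  expect_equal(got, c(2, 9, 17))
  expect_error(sample_occurrences(truth, 4, "modern", seed = 1),
               "short by 1")
})

test_that("occurrence sampling is seeded and respects the suitability weighting", {
  truth <- random_suit_map(20, 20, seed = 2, peaked = TRUE)
  a <- sample_occurrences(truth, 50, "modern", seed = 9)
  b <- sample_occurrences(truth, 50, "modern", seed = 9)
  expect_identical(a, b)
  c <- sample_occurrences(truth, 50, "modern", seed = 10)
  expect_false(identical(a, c))
  # mean true suitability of sampled cells exceeds the map mean (n = 200)
  big <- sample_occurrences(truth, 200, "modern", seed = 4)
  s_at <- truth$values[cbind(big$y, big$x)]
  expect_gt(mean(s_at), mean(truth$values))
})

test_that("weighted draws from a uniform truth are uniform (chi-square check)", {
  K <- 25
  truth <- suit_map(matrix(1, 5, 5), matrix(TRUE, 5, 5),
                    source = list(species = "sp"))
  counts <- integer(K)
  for (i in 1:2000) {
    occ <- sample_occurrences(truth, 5, "modern", seed = i)
    cells <- (occ$x - 1) * 5 + occ$y
    counts[cells] <- counts[cells] + 1
  }
  p <- suppressWarnings(chisq.test(counts)$p.value)
  expect_gt(p, 1e-3)
})

test_that("bernoulli-then-subsample mode realizes presences from the map", {
  truth <- random_suit_map(15, 15, seed = 3)
  occ <- sample_occurrences(truth, 20, "historical", seed = 2,
                            mode = "bernoulli_then_subsample")
  expect_lte(nrow(occ), 20)
  expect_true(all(occ$period == "historical"))
  expect_identical(occ, sample_occurrences(truth, 20, "historical", seed = 2,
                                           mode = "bernoulli_then_subsample"))
})

test_that("virtual species hit their target prevalence band", {
  cfg_stack <- local({
    pair <- make_climate_pair(c(30, 30), drift_spec(), seed = 21)
    select_apriori(derive_bioclim(pair$historical))
  })
  for (prev in c(0.02, 0.05)) {
    sp <- make_virtual_species(cfg_stack, "sp", prevalence = prev, seed = 5)
    s <- true_suitability(sp, cfg_stack)
    frac <- mean(s$values[s$mask] >= 0.5)
    expect_gt(frac, prev * 0.5)
    expect_lt(frac, prev * 2)
  }
})
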