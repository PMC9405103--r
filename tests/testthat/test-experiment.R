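test_that("experiment planning accounts for every grid cell and raster stack", {
  plan <- plan_experiment(3, procedures = c("bioclim", "glm"),
                          variable_sets = c("apriori3", "pca3"))
  expect_equal(nrow(plan$comparisons), 12)
  expect_equal(nrow(plan$stacks), 12) # 3 species x 2 sets x 2 periods
  expect_equal(length(unique(plan$stacks$stack_id)), 12)
})

test_that("Kruskal-Wallis matches the hand-ranked oracle and its degenerate case", {
  kw <- kruskal_wallis(list(a = c(1, 2, 3), b = c(4, 5, 6)))
  # ranks 1..6: H = 12/42 * (3*1.5^2 + 3*1.5^2) = 27/7
  expect_equal(kw$H, 3.857142857143, tolerance = 1e-10)
  expect_equal(kw$p, 0.049534613436, tolerance = 1e-10)
  expect_equal(kw$df, 1)
  flat <- kruskal_wallis(list(a = c(2, 2), b = c(2, 2), c = c(2, 2)))
  expect_equal(flat$H, 0)
  expect_equal(flat$p, 1)
  expect_error(kruskal_wallis(list(a = 1:3)), "2")
})

test_that("Kruskal-Wallis is stable under relabeling of pooled data", {
  withr::with_seed(55, {
    pooled <- rnorm(60)
    h0 <- kruskal_wallis(split(pooled, rep(1:3, 20)))$H
    hs <- vapply(1:500, function(i) {
      kruskal_wallis(split(sample(pooled), rep(1:3, 20)))$H
    }, numeric(1))
  })
  # the observed H is a typical draw from the permutation distribution
  p_perm <- mean(hs >= h0)
  expect_gt(p_perm, 0.01)
})

test_that("pairwise Mann-Whitney applies the Bonferroni rule over all pairs", {
  withr::with_seed(2, groups <- replicate(12, rnorm(25), simplify = FALSE))
  names(groups) <- paste0("g", 1:12)
  sm <- pairwise_mann_whitney(groups, alpha = 0.01)
  expect_equal(sm$m, 66)
  expect_true(isSymmetric(sm$p))
  # identical groups: nothing significant
  same <- replicate(5, c(1, 2, 3, 4, 5), simplify = FALSE)
  names(same) <- paste0("s", 1:5)
  sm0 <- pairwise_mann_whitney(same)
  expect_equal(sum(sm0$significant, na.rm = TRUE), 0)
  # one group shifted far out: all its pairs significant
  withr::with_seed(3, groups2 <- replicate(4, rnorm(25), simplify = FALSE))
  groups2[[5]] <- rnorm(25) + 10
  names(groups2) <- paste0("g", 1:5)
  sm1 <- pairwise_mann_whitney(groups2, alpha = 0.01)
  expect_true(all(sm1$significant[5, -5]))
  expect_error(pairwise_mann_whitney(list(a = 1, b = 1:3)), "at least 2")
})

test_that("distance classes follow the printed cutpoints", {
  expect_equal(distance_class(c(55, 60, 65, 70, 70.01, 85)),
               c("low", "intermediate", "intermediate", "intermediate",
                 "high", "high"))
})

test_that("a small experiment runs, accounts for its grid, and is deterministic", {
  cfg <- experiment_config(n_species = 1, procedures = c("bioclim", "glm"),
                           variable_sets = "apriori3", shape = c(48, 48),
                           n_modern = 80, evaluate = FALSE, run_mop = TRUE)
  r1 <- run_experiment(cfg, seed = 99)
  expect_equal(nrow(r1$results), 2)
  expect_true(all(is.na(r1$results$error)))
  expect_true(all(r1$results$D >= 0 & r1$results$D <= 1))
  expect_true(all(r1$results$S >= 0 & r1$results$S <= 100))
  expect_equal(r1$results$d,
               distance_to_ideal(r1$results$D, r1$results$S, r1$results$RSV))
  expect_equal(nrow(r1$mop), 1)
  r2 <- run_experiment(cfg, seed = 99)
  expect_identical(r1$results, r2$results)
  summ <- summarize_experiment(r1)
  expect_equal(nrow(summ$summary), 2)
  expect_equal(summ$summary$n, c(1, 1))
  expect_equal(nrow(summ$scatter), 2)
  # RSV magnitude bins partition the cases
  expect_equal(summ$summary$n_rsv_lt2 + summ$summary$n_rsv_2_5 +
                 summ$summary$n_rsv_gt5, summ$summary$n)
})

test_that("a resumed experiment reuses completed cells bit-identically", {
  cfg <- experiment_config(n_species = 1, procedures = c("bioclim", "glm"),
                           variable_sets = "apriori3", shape = c(48, 48),
                           n_modern = 80, evaluate = FALSE, run_mop = FALSE)
  full <- run_experiment(cfg, seed = 31)
  partial <- full
  partial$results <- partial$results[partial$results$procedure == "bioclim", ]
  resumed <- run_experiment(cfg, seed = 31, resume = partial)
  expect_identical(resumed$results, full$results)
  expect_error(run_experiment(cfg, seed = 32, resume = partial),
               "different seed")
})

test_that("modern and projected Boyce indices are compared per procedure", {
  cfg <- experiment_config(n_species = 2, procedures = c("bioclim", "glm"),
                           variable_sets = "apriori3", shape = c(48, 48),
                           n_modern = 80, evaluate = TRUE,
                           proc_iterations = 50, run_mop = FALSE)
  res <- run_experiment(cfg, seed = 13)
  cc <- compare_cbi(res)
  expect_equal(sort(unique(cc$procedure)), c("bioclim", "glm"))
  expect_true(all(cc$p >= 0 & cc$p <= 1))
  expect_true(all(cc$n == 2))
})

test_that("experiment outputs are written as text artifacts", {
  cfg <- experiment_config(n_species = 1, procedures = c("bioclim", "glm"),
                           variable_sets = "apriori3", shape = c(48, 48),
                           n_modern = 80, evaluate = FALSE, run_mop = TRUE)
  res <- run_experiment(cfg, seed = 99)
  dir <- tempfile()
  write_experiment(res, dir)
  expect_true(file.exists(file.path(dir, "results.csv")))
  expect_true(file.exists(file.path(dir, "summary.json")))
  expect_true(file.exists(file.path(dir, "mop_strict_pct.csv")))
  back <- read.csv(file.path(dir, "results.csv"))
  expect_equal(nrow(back), 2)
})

test_that("scenario YAML round-trips into an experiment config", {
  path <- tempfile(fileext = ".yml")
  writeLines(c("n_species: 2", "prevalence: 0.04", "seed: 7",
               "shape: [40, 40]", "variable_sets: [apriori3]",
               "procedures: [bioclim, glm]",
               "drift:", "  temp_offset: 1.5", "  noise_sd_temp: 0.2"),
             path)
  sc <- read_scenario(path)
  expect_equal(sc$seed, 7)
  expect_equal(sc$config$n_species, 2)
  expect_equal(sc$config$drift$temp_offset, 1.5)
  expect_equal(sc$config$variable_sets, "apriori3")
})
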