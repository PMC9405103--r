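test_that("cell thinning keeps one record per cell and drops masked cells", {
  mask <- matrix(TRUE, 10, 10)
  mask[3, 3] <- FALSE
  env <- make_stack(list(a = matrix(rnorm(100), 10, 10)), mask = mask)
  # 5 records: rows 1-2 duplicate one cell, row 5 sits on the masked cell
  occ <- occ_at(y = c(2, 2, 4, 6, 3), x = c(2, 2, 4, 6, 3))
  thin <- thin_to_cells(occ, env)
  expect_equal(nrow(thin), 3)
  expect_equal(thin$y, c(2, 4, 6))
  # same cell in different periods is kept in both
  occ2 <- rbind(occ_at(2, 2, "historical"), occ_at(2, 2, "modern"))
  expect_equal(nrow(thin_to_cells(occ2, env)), 2)
})

test_that("outlier screening keeps the centroid and drops a planted outlier", {
  withr::with_seed(33, {
    n <- 500
    X <- cbind(rnorm(n), rnorm(n))
  })
  grid <- matrix(0, 30, 30)
  # build a stack whose first 501 cells carry the records' environments
  pts <- rbind(X, c(10, 10), colMeans(rbind(X, c(10, 10))))
  la <- grid; lb <- grid
  la[seq_len(nrow(pts))] <- pts[, 1]
  lb[seq_len(nrow(pts))] <- pts[, 2]
  env <- make_stack(list(a = la, b = lb))
  idx <- seq_len(nrow(pts))
  occ <- occ_at(y = (idx - 1) %% 30 + 1, x = (idx - 1) %/% 30 + 1)
  kept <- remove_env_outliers(occ, env, level = 0.975)
  kept_idx <- (kept$x - 1) * 30 + kept$y
  expect_false((n + 1) %in% kept_idx)   # the planted (10, 10) point
  expect_true((n + 2) %in% kept_idx)    # the centroid is never dropped
})

test_that("outlier drop fraction matches the chi-square coverage level", {
  withr::with_seed(12, {
    n <- 2000
    X <- cbind(rnorm(n), rnorm(n))
  })
  nr <- 45; nc <- 45
  la <- matrix(0, nr, nc); lb <- la
  la[seq_len(n)] <- X[, 1]; lb[seq_len(n)] <- X[, 2]
  env <- make_stack(list(a = la, b = lb))
  idx <- seq_len(n)
  occ <- occ_at(y = (idx - 1) %% nr + 1, x = (idx - 1) %/% nr + 1)
  dropped <- 1 - nrow(remove_env_outliers(occ, env)) / n
  half <- 2.576 * sqrt(0.025 * 0.975 / n)
  expect_gt(dropped, 0.025 - half)
  expect_lt(dropped, 0.025 + half)
})

test_that("ellipsoid overlap hits the trivial anchors", {
  withr::with_seed(5, X <- matrix(rnorm(200), 100, 2))
  expect_gt(ellipsoid_overlap(X, X, seed = 1), 0.97)
  far <- sweep(X, 2, c(100, 100), "+")
  expect_lt(ellipsoid_overlap(X, far, seed = 1), 0.01)
})

test_that("ellipsoid overlap matches the circle-lens closed form", {
  # exactly whitened clouds -> unit-covariance ellipsoids = circles of
  # radius sqrt(qchisq(.975, 2)); centers 1 apart -> Jaccard 0.6219967702
  withr::with_seed(8, Z <- whiten_exact(matrix(rnorm(120), 60, 2)))
  Z2 <- sweep(Z, 2, c(1, 0), "+")
  ov <- ellipsoid_overlap(Z, Z2, n_mc = 50000, seed = 3)
  expect_equal(ov, 0.6219967702, tolerance = 0.02)
})

test_that("balancing is a no-op for equal sizes and strips planted records first", {
  withr::with_seed(21, core <- matrix(rnorm(80), 40, 2))
  planted <- matrix(8 + rnorm(10, sd = 0.1), 5, 2)
  nr <- 40; nc <- 40
  mk_env <- function(pts) {
    la <- matrix(0, nr, nc); lb <- la
    la[seq_len(nrow(pts))] <- pts[, 1]; lb[seq_len(nrow(pts))] <- pts[, 2]
    make_stack(list(a = la, b = lb))
  }
  idx_occ <- function(n, period) {
    idx <- seq_len(n)
    occ_at(y = (idx - 1) %% nr + 1, x = (idx - 1) %/% nr + 1, period = period)
  }
  envH <- mk_env(core)
  hist <- idx_occ(40, "historical")
  modpts <- rbind(core, planted)
  envM <- mk_env(modpts)
  mod <- idx_occ(45, "modern")

  bal <- balance_by_overlap(hist, mod, envH, envM, seed = 2)
  expect_equal(nrow(bal$historical), 40)
  expect_equal(nrow(bal$modern), 40)
  removed_idx <- (bal$test_modern$x - 1) * nr + bal$test_modern$y
  expect_setequal(removed_idx, 41:45)  # exactly the planted records
  # equal sizes: unchanged, empty test set
  bal0 <- balance_by_overlap(hist, idx_occ(40, "modern"), envH, envH, seed = 2)
  expect_equal(nrow(bal0$test_modern), 0)
  expect_identical(bal0$historical, hist)
})

test_that("greedy balancing beats random deletion on the planted fixture", {
  withr::with_seed(77, core <- matrix(rnorm(60), 30, 2))
  planted <- matrix(6 + rnorm(10, sd = 0.2), 5, 2)
  nr <- 40
  mk_env <- function(pts) {
    la <- matrix(0, nr, nr); lb <- la
    la[seq_len(nrow(pts))] <- pts[, 1]; lb[seq_len(nrow(pts))] <- pts[, 2]
    make_stack(list(a = la, b = lb))
  }
  idx_occ <- function(n, period) {
    idx <- seq_len(n)
    occ_at(y = (idx - 1) %% nr + 1, x = (idx - 1) %/% nr + 1, period = period)
  }
  envH <- mk_env(core); hist <- idx_occ(30, "historical")
  modpts <- rbind(core, planted); envM <- mk_env(modpts)
  mod <- idx_occ(35, "modern")
  EH <- env_extract(envH, hist$x, hist$y)
  bal <- balance_by_overlap(hist, mod, envH, envM, seed = 3)
  EMb <- env_extract(envM, bal$modern$x, bal$modern$y)
  greedy_ov <- ellipsoid_overlap(EH, EMb, seed = 1)
  EM <- env_extract(envM, mod$x, mod$y)
  wins <- 0L
  for (trial in 1:20) {
    drop <- withr::with_seed(trial, sample.int(35, 5))
    rand_ov <- ellipsoid_overlap(EH, EM[-drop, , drop = FALSE], seed = 1)
    if (greedy_ov >= rand_ov) wins <- wins + 1L
  }
  expect_gte(wins, 19)
})

test_that("the cleaning cascade is monotone and balances the periods", {
  tw <- tiny_world()
  rep <- tw$cleaned$report
  for (p in c("historical", "modern")) {
    counts <- c(rep$n_input[p], rep$n_after_thinning[p],
                rep$n_after_outliers[p], rep$n_after_balancing[p])
    expect_true(all(diff(counts) <= 0))
  }
  expect_equal(rep$n_after_balancing[["historical"]],
               rep$n_after_balancing[["modern"]])
  expect_equal(nrow(tw$cleaned$test_modern),
               rep$n_after_outliers[["modern"]] -
                 rep$n_after_balancing[["modern"]])
  tmp <- tempfile(fileext = ".json")
  write_cleaning_report(rep, tmp)
  parsed <- jsonlite::read_json(tmp)
  expect_equal(parsed$n_after_balancing$historical,
               rep$n_after_balancing[["historical"]])
})
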