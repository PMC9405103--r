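# Shared fixtures: all built in code at test time.

# A small env_stack from named matrices (full mask unless given).
make_stack <- function(layers, mask = NULL, period = "historical",
                       provenance = "raw", origin = c(1L, 1L)) {
  env_stack(layers, mask = mask, period = period, provenance = provenance,
            origin = origin)
}

# Single-layer stack holding given values.
stack1 <- function(values, mask = NULL, name = "v1") {
  l <- list(values); names(l) <- name
  make_stack(l, mask = mask)
}

# A smooth random suitability map in [0, 1] on an nr x nc grid.
random_suit_map <- function(nr = 20, nc = 20, seed = 1, peaked = FALSE) {
  withr::with_seed(seed, {
    m <- matrix(runif(nr * nc), nr, nc)
    k <- matrix(1 / 9, 3, 3)
    sm <- m
    for (i in 1:3) {
      pad <- rbind(sm[1, ], sm, sm[nr, ])
      pad <- cbind(pad[, 1], pad, pad[, nc])
      out <- matrix(0, nr, nc)
      for (dr in -1:1) for (dc in -1:1)
        out <- out + pad[2:(nr + 1) + dr, 2:(nc + 1) + dc] / 9
      sm <- out
    }
    sm <- (sm - min(sm)) / diff(range(sm))
    if (peaked) sm <- sm^4
    suit_map(sm, matrix(TRUE, nr, nc))
  })
}

# A constant-free monthly climate with fixed temperature everywhere.
constant_climate <- function(nr = 12, nc = 12, temp = 10, diurnal = 0,
                             prec = 50) {
  tm <- array(temp, c(nr, nc, 12))
  monthly_climate(tm - diurnal / 2, tm + diurnal / 2,
                  array(prec, c(nr, nc, 12)))
}

# Occurrence table from row/col vectors for one species.
occ_at <- function(y, x, period = "modern", species = "sp") {
  occurrences(species, x = x, y = y, period = period)
}

# Whiten a point matrix to exact sample mean 0 and identity covariance.
whiten_exact <- function(X) {
  X <- scale(X, scale = FALSE)
  E <- eigen(cov(X), symmetric = TRUE)
  Z <- X %*% E$vectors %*% diag(1 / sqrt(E$values)) %*% t(E$vectors)
  scale(Z, scale = FALSE)
}

# A tiny prepared world: one species, cleaned records, tailored stacks.
# Cached per session because several files reuse it.
tiny_world <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    cfg <- experiment_config(n_species = 1, variable_sets = "apriori3",
                             shape = c(48, 48), n_modern = 80,
                             evaluate = FALSE)
    world <- simulate_world(cfg, seed = 7)
    occ_sp <- world$occ[world$occ$species == "species01", ]
    envH <- tailor_study_area(world$stacks$apriori3$historical, occ_sp, 10)
    envM <- tailor_study_area(world$stacks$apriori3$modern, occ_sp, 10)
    cleaned <- clean_occurrences(occ_sp, envH, envM, seed = 7)
    cache <<- list(cfg = cfg, world = world, occ = occ_sp,
                   envH = envH, envM = envM, cleaned = cleaned)
    cache
  }
})
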