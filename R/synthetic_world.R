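#' Monthly climate stacks
#'
#' Raw product of the climate simulator and raw input of the variable
#' derivation step: twelve monthly grids each of minimum temperature,
#' maximum temperature (degrees C) and precipitation sum (mm), plus a
#' shared validity mask and a period label. Cellwise `tmax >= tmin` and
#' `prec >= 0` are enforced on the mask.
#'
#' @param tmin,tmax,prec numeric arrays (`nrow x ncol x 12`).
#' @param mask logical validity matrix.
#' @param period `"historical"` or `"modern"`.
#' @return an object of class `monthly_climate`.
#' @export
monthly_climate <- function(tmin, tmax, prec, mask = NULL, period = "historical") {
  stopifnot(length(dim(tmin)) == 3, dim(tmin)[3] == 12,
            all(dim(tmax) == dim(tmin)), all(dim(prec) == dim(tmin)))
  if (is.null(mask)) mask <- matrix(TRUE, dim(tmin)[1], dim(tmin)[2])
  stopifnot(all(dim(mask) == dim(tmin)[1:2]))
  period <- match.arg(period, c("historical", "modern"))
  mrep <- array(mask, dim = dim(tmin))
  if (any(tmax[mrep] < tmin[mrep]))
    stop("tmax must be >= tmin on every valid cell")
  if (any(prec[mrep] < 0))
    stop("precipitation must be non-negative on every valid cell")
  structure(list(tmin = tmin, tmax = tmax, prec = prec, mask = mask,
                 period = period),
            class = "monthly_climate")
}

#' @export
print.monthly_climate <- function(x, ...) {
  cat(sprintf("<monthly_climate> %d x %d cells (%s), 36 monthly grids\n",
              dim(x$tmin)[1], dim(x$tmin)[2], x$period))
  invisible(x)
}

# Separable Gaussian blur with edge renormalization; gives the smoothed
# white-noise fields their spatial autocorrelation.
gaussian_smooth <- function(mat, sigma) {
  if (sigma <= 0) return(mat)
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  blur1d <- function(m) { # along rows of m
    n <- nrow(m)
    acc <- matrix(0, n, ncol(m)); wt <- acc
    for (i in seq_along(k)) {
      off <- i - r - 1L
      src <- seq_len(n) + off
      ok <- src >= 1 & src <= n
      acc[ok, ] <- acc[ok, ] + k[i] * m[src[ok], , drop = FALSE]
      wt[ok, ] <- wt[ok, ] + k[i]
    }
    acc / wt
  }
  t(blur1d(t(blur1d(mat))))
}

#' Specify the climate drift between the historical and modern periods
#'
#' Additive offsets applied to every monthly layer of the modern period,
#' optionally varying linearly from the top (row 1) to the bottom row of
#' the grid, plus the standard deviation of seeded cellwise noise.
#' Temperature noise perturbs the monthly mean and is applied identically
#' to `tmin` and `tmax`, so the diurnal range (and the `tmax >= tmin`
#' invariant) is preserved by construction.
#'
#' @param temp_offset constant temperature offset, degrees C.
#' @param prec_offset constant precipitation offset, mm/month.
#' @param temp_gradient,prec_gradient additional offset reached at the
#'   bottom row (linear in the row index, 0 at row 1).
#' @param noise_sd_temp,noise_sd_prec standard deviation of the seeded
#'   noise fields (must be `>= 0`).
#' @return an object of class `drift_spec`.
#' @export
drift_spec <- function(temp_offset = 0, prec_offset = 0,
                       temp_gradient = 0, prec_gradient = 0,
                       noise_sd_temp = 0, noise_sd_prec = 0) {
  if (noise_sd_temp < 0 || noise_sd_prec < 0)
    stop("noise scale must be non-negative")
  structure(list(temp_offset = temp_offset, prec_offset = prec_offset,
                 temp_gradient = temp_gradient, prec_gradient = prec_gradient,
                 noise_sd_temp = noise_sd_temp, noise_sd_prec = noise_sd_prec),
            class = "drift_spec")
}

#' Generate a seeded historical/modern climate pair
#'
#' The historical climate is built from deterministic latitudinal
#' gradients plus smoothed seeded white noise (Gaussian blur of width
#' `roughness`), with monthly temperatures following a sinusoidal
#' seasonal cycle around a cellwise annual mean, and `tmin`/`tmax`
#' generated as mean -/+ half a cellwise diurnal range. The modern
#' climate is the historical one plus the additive drift and seeded
#' noise described by a [drift_spec()].
#'
#' @param shape `c(nrow, ncol)`, at least 10 x 10.
#' @param drift a [drift_spec()].
#' @param roughness Gaussian blur sigma (cells) of the smoothed noise
#'   fields; larger values give smoother climate surfaces.
#' @param seed integer seed; identical seeds give bitwise-identical pairs.
#' @return list with elements `historical` and `modern`, both
#'   [monthly_climate()] objects.
#' @export
make_climate_pair <- function(shape, drift = drift_spec(), roughness = 3,
                              seed = 1) {
  stopifnot(length(shape) == 2)
  if (any(shape < 10)) stop("grid shape must be at least 10 x 10")
  if (!inherits(drift, "drift_spec")) stop("drift must be a drift_spec")
  if (roughness <= 0) stop("roughness must be positive")
  nr <- as.integer(shape[1]); nc <- as.integer(shape[2])
  lat <- matrix((seq_len(nr) - 1) / (nr - 1), nr, nc) # 0 at top row

  with_seed(derive_seed(seed, "climate"), {
    noise <- function(sd) gaussian_smooth(matrix(stats::rnorm(nr * nc, 0, sd), nr, nc),
                                          roughness)
    tmean_annual <- 6 + 14 * lat + noise(2)        # degC, cold north
    amp <- pmax(3, 7 + noise(1.5))                 # seasonal amplitude
    diurnal <- pmax(3, 8 + noise(1))               # tmax - tmin
    prec_annual <- pmax(150, 1200 - 700 * lat + noise(150))

    tmin <- tmax <- prec <- array(0, c(nr, nc, 12))
    for (m in 1:12) {
      tmean_m <- tmean_annual + amp * cos(2 * pi * (m - 7) / 12) # July peak
      tmin[, , m] <- tmean_m - diurnal / 2
      tmax[, , m] <- tmean_m + diurnal / 2
      season <- 1 + 0.4 * cos(2 * pi * (m - 1) / 12)             # wet winters
      prec[, , m] <- pmax(0, prec_annual / 12 * season + noise(4))
    }
    historical <- monthly_climate(tmin, tmax, prec, period = "historical")

    dtemp <- drift$temp_offset + drift$temp_gradient * lat
    dprec <- drift$prec_offset + drift$prec_gradient * lat
    tmin2 <- tmin; tmax2 <- tmax; prec2 <- prec
    for (m in 1:12) {
      ntemp <- if (drift$noise_sd_temp > 0)
        matrix(stats::rnorm(nr * nc, 0, drift$noise_sd_temp), nr, nc) else 0
      nprec <- if (drift$noise_sd_prec > 0)
        matrix(stats::rnorm(nr * nc, 0, drift$noise_sd_prec), nr, nc) else 0
      tmin2[, , m] <- tmin[, , m] + dtemp + ntemp
      tmax2[, , m] <- tmax[, , m] + dtemp + ntemp
      prec2[, , m] <- pmax(0, prec[, , m] + dprec + nprec)
    }
    modern <- monthly_climate(tmin2, tmax2, prec2, period = "modern")
    list(historical = historical, modern = modern)
  })
}

#' Virtual species with a known Gaussian niche
#'
#' A virtual species is defined by a multivariate Gaussian response in
#' environmental space: suitability at a cell with environment `e` is
#' `max_suitability * exp(-0.5 * (e - mu)' Sigma^-1 (e - mu))`.
#'
#' @param id species label.
#' @param niche_mean niche optimum, one value per environmental layer.
#' @param niche_cov symmetric positive-definite niche covariance matrix.
#' @param max_suitability suitability at the optimum, in `(0, 1]`.
#' @return an object of class `virtual_species_spec`.
#' @export
virtual_species_spec <- function(id, niche_mean, niche_cov,
                                 max_suitability = 1) {
  niche_mean <- as.numeric(niche_mean)
  niche_cov <- as.matrix(niche_cov)
  stopifnot(nrow(niche_cov) == length(niche_mean),
            ncol(niche_cov) == length(niche_mean))
  if (max(abs(niche_cov - t(niche_cov))) > 1e-8)
    stop("niche_cov must be symmetric")
  ev <- eigen(niche_cov, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("niche_cov must be positive-definite")
  if (max_suitability <= 0 || max_suitability > 1)
    stop("max_suitability must lie in (0, 1]")
  structure(list(id = as.character(id), niche_mean = niche_mean,
                 niche_cov = niche_cov, max_suitability = max_suitability),
            class = "virtual_species_spec")
}

#' True suitability of a virtual species over an environmental stack
#'
#' @param spec a [virtual_species_spec()] defined over `env`'s layers.
#' @param env an [env_stack()].
#' @return a [suit_map()] with the Gaussian-niche suitability on the
#'   valid cells.
#' @export
true_suitability <- function(spec, env) {
  stopifnot(inherits(spec, "virtual_species_spec"), inherits(env, "env_stack"))
  if (length(spec$niche_mean) != dim(env$layers)[3])
    stop("species niche is not defined over this stack's layers")
  vals <- env_values(env)
  md2 <- stats::mahalanobis(vals, spec$niche_mean, spec$niche_cov)
  s <- spec$max_suitability * exp(-0.5 * md2)
  out <- matrix(NA_real_, nrow(env$mask), ncol(env$mask))
  out[attr(vals, "cells")] <- s
  suit_map(out, env$mask,
           source = list(species = spec$id, kind = "true_suitability",
                         period = env$period),
           origin = env$origin)
}

#' Create a virtual species calibrated to a target prevalence
#'
#' The niche optimum is the environment of a randomly chosen valid cell;
#' the niche covariance is diagonal with per-variable standard deviation
#' proportional to the layer's spatial standard deviation, with the
#' proportionality constant solved in closed form so that the fraction
#' of valid cells with suitability `>= 0.5` equals `prevalence`. This
#' mimics stenochorous (narrow-ranged) endemics when `prevalence` is a
#' few percent.
#'
#' @param env an [env_stack()] on which the niche is defined.
#' @param id species label.
#' @param prevalence target fraction of valid cells with suitability
#'   `>= 0.5`; default 0.03 (range 1-5 percent is realistic for
#'   narrow endemics).
#' @param seed integer seed (picks the niche centre).
#' @return a [virtual_species_spec()].
#' @export
make_virtual_species <- function(env, id, prevalence = 0.03, seed = 1) {
  stopifnot(prevalence > 0, prevalence < 1)
  vals <- env_values(env)
  sds <- apply(vals, 2, stats::sd)
  if (any(sds == 0)) stop("cannot place a niche over a constant layer")
  with_seed(derive_seed(seed, "species", id), {
    centre <- vals[sample.int(nrow(vals), 1), ]
    # base squared Mahalanobis distance under unit breadth
    md2 <- stats::mahalanobis(vals, centre, diag(sds^2, length(sds)))
    # suitability >= 0.5  <=>  md2 <= 2 log(2) b^2 ; pick b so that the
    # prevalence-quantile of md2 sits exactly at the threshold
    t0 <- stats::quantile(md2, prevalence, names = FALSE)
    b <- sqrt(max(t0, 1e-8) / (2 * log(2)))
    virtual_species_spec(id, centre, diag((b * sds)^2, length(sds)))
  })
}

#' Sample occurrence records from a true suitability map
#'
#' @param truth a [suit_map()] of true suitability.
#' @param n number of records to draw.
#' @param period period label attached to the records.
#' @param seed integer seed.
#' @param mode `"weighted"` draws `n` distinct cells with probability
#'   proportional to suitability; `"bernoulli_then_subsample"` draws a
#'   Bernoulli realization of the map and uniformly subsamples `n` cells
#'   from it (all of them if fewer than `n` are realized).
#' @param species species id stamped on the records (default: the map's
#'   source species).
#' @return an [occurrences()] table with at most one record per cell.
#' @export
sample_occurrences <- function(truth, n, period, seed = 1,
                               mode = c("weighted", "bernoulli_then_subsample"),
                               species = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(truth, "suit_map"), n >= 1)
  if (is.null(species)) species <- truth$source$species
  if (is.null(species)) species <- "sp"
  cells <- which(truth$mask & !is.na(truth$values) & truth$values > 0)
  s <- truth$values[cells]
  nr <- nrow(truth$values)
  with_seed(derive_seed(seed, "occ", species, period, mode), {
    if (mode == "weighted") {
      if (length(cells) < n)
        stop(sprintf("requested %d records but only %d cells have positive suitability (short by %d)",
                     n, length(cells), n - length(cells)))
      picked <- if (length(cells) == n) cells else
        cells[sample.int(length(cells), n, prob = s)]
    } else {
      hit <- stats::runif(length(cells)) < s
      realized <- cells[hit]
      picked <- if (length(realized) > n)
        realized[sample.int(length(realized), n)] else realized
      if (length(picked) == 0)
        stop("bernoulli draw realized no presences")
    }
    row <- (picked - 1L) %% nr + 1L
    col <- (picked - 1L) %/% nr + 1L
    occurrences(species,
                x = col + truth$origin[2] - 1L,
                y = row + truth$origin[1] - 1L,
                period = period, source = "synthetic")
  })
}
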