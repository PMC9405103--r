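#' Derive bioclimatic variables and Thornthwaite PET from monthly climate
#'
#' Computes the 19 standard bioclimatic variables (`bio1`..`bio19`) from
#' monthly minimum/maximum temperature and precipitation, plus monthly
#' and annual potential evapotranspiration (PET) after Thornthwaite.
#' Monthly mean temperature is `(tmin + tmax) / 2`. "Quarters" are all 12
#' runs of 3 consecutive months, wrapping across the year boundary
#' (Dec-Jan-Feb counts); ties for the wettest/driest/warmest/coldest
#' quarter are broken by the first-encountered run scanning Jan to Dec.
#'
#' Units: temperatures in degrees C (`bio4` is the standard deviation of
#' monthly means times 100; `bio3` is `100 * bio2 / bio7`), precipitation
#' in mm (`bio15` is `100 * sd / (1 + bio12/12)`), PET in mm.
#'
#' @param mc a [monthly_climate()].
#' @param day_length_correction if `TRUE`, apply the Thornthwaite
#'   day-length/month-length correction using `lat_deg`; by default the
#'   correction is disabled (12-hour days, 30-day months), which keeps
#'   the synthetic grids latitude-free.
#' @param lat_deg latitude (degrees) per grid row, used only when
#'   `day_length_correction` is `TRUE`.
#' @return an [env_stack()] with provenance `"raw"` and layers
#'   `bio1..bio19`, `pet_01..pet_12`, `pet_annual`.
#' @export
derive_bioclim <- function(mc, day_length_correction = FALSE, lat_deg = NULL) {
  stopifnot(inherits(mc, "monthly_climate"))
  d <- dim(mc$tmin)
  ncell <- d[1] * d[2]
  flat <- function(a) matrix(a, ncell, 12)
  TN <- flat(mc$tmin); TX <- flat(mc$tmax); PR <- flat(mc$prec)
  for (nm in c("TN", "TX", "PR")) {
    m <- get(nm)
    if (any(apply(is.na(m), 2, all)))
      stop("an input monthly layer is entirely NA")
  }
  TM <- (TN + TX) / 2

  first_max <- function(m) max.col(m, ties.method = "first")
  first_min <- function(m) max.col(-m, ties.method = "first")
  pick <- function(m, idx) m[cbind(seq_len(nrow(m)), idx)]

  # quarter aggregates: columns q = months (q, q+1, q+2), wrap-around
  qsum <- function(m) {
    out <- matrix(0, nrow(m), 12)
    for (q in 1:12) {
      mo <- ((q - 1):(q + 1)) %% 12 + 1
      out[, q] <- m[, mo[1]] + m[, mo[2]] + m[, mo[3]]
    }
    out
  }
  QT <- qsum(TM) / 3 # quarter mean temperature
  QP <- qsum(PR)     # quarter precipitation sum

  bio <- matrix(NA_real_, ncell, 19)
  bio[, 1] <- rowMeans(TM)
  bio[, 2] <- rowMeans(TX - TN)
  bio[, 4] <- apply(TM, 1, stats::sd) * 100
  bio[, 5] <- pick(TX, first_max(TX))
  bio[, 6] <- pick(TN, first_min(TN))
  bio[, 7] <- bio[, 5] - bio[, 6]
  bio[, 3] <- ifelse(bio[, 7] == 0, 0, 100 * bio[, 2] / bio[, 7])
  wetq <- first_max(QP); dryq <- first_min(QP)
  warmq <- first_max(QT); coldq <- first_min(QT)
  bio[, 8] <- pick(QT, wetq)
  bio[, 9] <- pick(QT, dryq)
  bio[, 10] <- pick(QT, warmq)
  bio[, 11] <- pick(QT, coldq)
  bio[, 12] <- rowSums(PR)
  bio[, 13] <- pick(PR, first_max(PR))
  bio[, 14] <- pick(PR, first_min(PR))
  bio[, 15] <- 100 * apply(PR, 1, stats::sd) / (1 + bio[, 12] / 12)
  bio[, 16] <- pick(QP, wetq)
  bio[, 17] <- pick(QP, dryq)
  bio[, 18] <- pick(QP, warmq)
  bio[, 19] <- pick(QP, coldq)

  pet <- thornthwaite_pet(TM, day_length_correction = day_length_correction,
                          lat_deg = lat_deg, nrow_grid = d[1])

  vals <- cbind(bio, pet, rowSums(pet))
  nm <- c(paste0("bio", 1:19), sprintf("pet_%02d", 1:12), "pet_annual")
  layers <- array(vals, dim = c(d[1], d[2], ncol(vals)),
                  dimnames = list(NULL, NULL, nm))
  off <- !mc$mask
  if (any(off)) for (j in seq_len(dim(layers)[3])) {
    lay <- layers[, , j]; lay[off] <- NA_real_; layers[, , j] <- lay
  }
  env_stack(layers, mask = mc$mask, period = mc$period, provenance = "raw")
}

#' Thornthwaite monthly potential evapotranspiration
#'
#' Classical Thornthwaite formulation: heat index
#' `I = sum_m (T_m / 5)^1.514` over months with `T_m > 0`, exponent
#' `a = 6.75e-7 I^3 - 7.71e-5 I^2 + 1.792e-2 I + 0.49239`, and monthly
#' PET `16 (10 T / I)^a` mm for `0 < T < 26.5` C, with the standard
#' hot-month polynomial `-415.85 + 32.24 T - 0.43 T^2` above 26.5 C and
#' 0 for freezing months. The day-length correction multiplies by
#' `(N/12)(days/30)`; disabled by default.
#'
#' @param TM matrix of monthly mean temperatures (cells x 12), degrees C.
#' @param day_length_correction apply the latitude correction?
#' @param lat_deg per-row latitudes (degrees) when correcting.
#' @param nrow_grid grid row count (to map cells to rows).
#' @return matrix (cells x 12) of monthly PET, mm.
#' @export
thornthwaite_pet <- function(TM, day_length_correction = FALSE,
                             lat_deg = NULL, nrow_grid = NULL) {
  Tpos <- pmax(TM, 0)
  I <- rowSums((Tpos / 5)^1.514)
  a <- 6.75e-7 * I^3 - 7.71e-5 * I^2 + 1.792e-2 * I + 0.49239
  pet <- matrix(0, nrow(TM), 12)
  warm <- TM > 0 & TM < 26.5 & I > 0
  hot <- TM >= 26.5
  if (any(warm)) {
    Im <- matrix(I, nrow(TM), 12); am <- matrix(a, nrow(TM), 12)
    pet[warm] <- 16 * (10 * TM[warm] / Im[warm])^am[warm]
  }
  if (any(hot)) pet[hot] <- -415.85 + 32.24 * TM[hot] - 0.43 * TM[hot]^2
  if (day_length_correction) {
    if (is.null(lat_deg) || is.null(nrow_grid))
      stop("day-length correction requires lat_deg and nrow_grid")
    phi <- rep(lat_deg * pi / 180, length.out = nrow(TM) %/% 1)
    phi <- phi[(seq_len(nrow(TM)) - 1) %% nrow_grid + 1]
    days <- c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31)
    mid <- c(15, 45, 74, 105, 135, 166, 196, 227, 258, 288, 319, 349)
    for (m in 1:12) {
      decl <- 0.409 * sin(2 * pi * mid[m] / 365 - 1.39)
      cosws <- pmin(1, pmax(-1, -tan(phi) * tan(decl)))
      N <- 24 / pi * acos(cosws)
      pet[, m] <- pet[, m] * (N / 12) * (days[m] / 30)
    }
  }
  pet
}

#' Crop a stack to a species' study area
#'
#' The study area is the bounding box of the species' records (both
#' periods pooled) expanded by `buffer_cells` cells on each side and
#' clipped at the grid edge; layers and mask are cropped to that box.
#' Tailoring is idempotent for fixed inputs.
#'
#' @param env an [env_stack()].
#' @param occ an [occurrences()] table (global coordinates).
#' @param buffer_cells buffer width in cells (default 10).
#' @return the cropped [env_stack()]; its `origin` records the global
#'   position of the new upper-left cell.
#' @export
tailor_study_area <- function(env, occ, buffer_cells = 10) {
  stopifnot(inherits(env, "env_stack"))
  if (nrow(occ) == 0) stop("cannot tailor a study area from an empty occurrence set")
  d <- dim(env$layers)
  r0 <- max(env$origin[1], min(occ$y) - buffer_cells)
  r1 <- min(env$origin[1] + d[1] - 1L, max(occ$y) + buffer_cells)
  c0 <- max(env$origin[2], min(occ$x) - buffer_cells)
  c1 <- min(env$origin[2] + d[2] - 1L, max(occ$x) + buffer_cells)
  if (r0 > r1 || c0 > c1) stop("occurrence records fall outside the stack")
  rr <- (r0:r1) - env$origin[1] + 1L
  cc <- (c0:c1) - env$origin[2] + 1L
  env_stack(env$layers[rr, cc, , drop = FALSE],
            mask = env$mask[rr, cc, drop = FALSE],
            period = env$period, provenance = env$provenance,
            origin = c(r0, c0),
            pca_loadings = env$pca_loadings, pca_center = env$pca_center,
            pca_scale = env$pca_scale, pca_aligned = env$pca_aligned,
            crs_meta = env$crs_meta)
}

#' Select the three a-priori environmental variables
#'
#' Returns the fixed, biologically motivated 3-layer set: annual mean
#' temperature (`bio1`), annual precipitation (`bio12`), and annual
#' Thornthwaite PET (`pet_annual`), in that order.
#'
#' @param env a raw [env_stack()] containing those layers.
#' @return an [env_stack()] with provenance `"apriori3"`.
#' @export
select_apriori <- function(env) {
  want <- c("bio1", "bio12", "pet_annual")
  missing <- setdiff(want, layer_names(env))
  if (length(missing))
    stop("raw stack is missing layer(s): ", paste(missing, collapse = ", "))
  env_stack(env$layers[, , want, drop = FALSE], mask = env$mask,
            period = env$period, provenance = "apriori3",
            origin = env$origin, crs_meta = env$crs_meta)
}

#' Reduce a raw stack to its first principal components
#'
#' Each layer is standardized to mean 0 / sd 1 over the valid cells (so
#' all layers weigh equally), a PCA is computed over all valid cells,
#' and the first `k` axis scores are returned as layers `PC1..PCk`.
#' Loadings, centering/scaling, and explained-variance shares are stored
#' on the result.
#'
#' Historical and modern stacks are transformed independently; because
#' independently derived axes can flip sign, pass the historical result
#' as `align_to` when transforming the modern stack (the default
#' workflow behaviour) to flip each modern axis so its loadings
#' correlate positively with the historical ones. Cross-period
#' projection onto an unaligned pca3 stack is refused by [project()].
#'
#' @param env a raw [env_stack()] with at least `k` non-constant layers.
#' @param k number of axes to keep (default 3).
#' @param align_to optional reference pca3 [env_stack()] whose axis
#'   orientations should be matched.
#' @return an [env_stack()] with provenance `"pca3"`.
#' @export
pca_reduce <- function(env, k = 3, align_to = NULL) {
  vals <- env_values(env)
  if (ncol(vals) < k) stop("need at least k layers for a k-axis PCA")
  if (nrow(vals) < k + 1) stop("need at least k + 1 valid cells")
  sds <- apply(vals, 2, stats::sd)
  if (any(sds == 0))
    stop("constant layer(s) cannot be standardized: ",
         paste(colnames(vals)[sds == 0], collapse = ", "))
  ctr <- colMeans(vals)
  std <- scale(vals, center = ctr, scale = sds)
  pc <- stats::prcomp(std, center = FALSE, scale. = FALSE)
  rot <- pc$rotation[, seq_len(k), drop = FALSE]
  if (!is.null(align_to)) {
    if (is.null(align_to$pca_loadings))
      stop("align_to must be a pca3 stack carrying loadings")
    if (!identical(rownames(align_to$pca_loadings), colnames(vals)))
      stop("align_to was built over different variables")
    for (j in seq_len(k)) {
      if (sum(rot[, j] * align_to$pca_loadings[, j]) < 0)
        rot[, j] <- -rot[, j]
    }
  }
  scores <- std %*% rot
  colnames(rot) <- colnames(scores) <- paste0("PC", seq_len(k))
  ncell <- prod(dim(env$mask))
  layers <- array(NA_real_, c(nrow(env$mask), ncol(env$mask), k),
                  dimnames = list(NULL, NULL, colnames(scores)))
  cells <- attr(vals, "cells")
  for (j in seq_len(k)) {
    lay <- matrix(NA_real_, nrow(env$mask), ncol(env$mask))
    lay[cells] <- scores[, j]
    layers[, , j] <- lay
  }
  out <- env_stack(layers, mask = env$mask, period = env$period,
                   provenance = "pca3", origin = env$origin,
                   pca_loadings = rot, pca_center = ctr, pca_scale = sds,
                   pca_aligned = if (!is.null(align_to)) TRUE else NA,
                   crs_meta = env$crs_meta)
  ev <- pc$sdev^2
  out$pca_explained <- (ev / sum(ev))[seq_len(k)]
  out
}

#' Write PCA loadings to CSV
#'
#' @param env a pca3 [env_stack()].
#' @param path output CSV (variables x axes).
#' @export
write_pca_loadings <- function(env, path) {
  if (is.null(env$pca_loadings)) stop("stack carries no PCA loadings")
  utils::write.csv(as.data.frame(env$pca_loadings), path, row.names = TRUE)
  invisible(path)
}
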