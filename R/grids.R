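#' Environmental grid stacks
#'
#' An `env_stack` is the container every model lives in: a set of named,
#' co-registered layers (stored as a `nrow x ncol x nlayer` array), a
#' logical validity mask, a period label (`"historical"` or `"modern"`),
#' and a provenance tag saying how the stack was built (`"raw"` for the
#' full derived-variable set, `"apriori3"` for the three a-priori
#' variables, `"pca3"` for the first three PCA axes).
#'
#' Grids are treated as planar: cells are addressed by row (`y`) and
#' column (`x`) indices. Stacks cropped to a species' study area keep an
#' `origin` (global row/col of their upper-left cell) so occurrence
#' coordinates remain global throughout the pipeline. Any coordinate
#' reference metadata supplied by the user is carried through untouched
#' in `crs_meta`.
#'
#' @param layers 3-d numeric array (`nrow x ncol x nlayer`) with layer
#'   names on the third dimension, or a named list of matrices.
#' @param mask logical matrix of valid cells; defaults to cells that are
#'   non-`NA` in every layer.
#' @param period `"historical"` or `"modern"`.
#' @param provenance one of `"raw"`, `"apriori3"`, `"pca3"`.
#' @param origin global (row, col) of the stack's upper-left cell.
#' @param pca_loadings,pca_center,pca_scale,pca_aligned PCA metadata,
#'   populated by [pca_reduce()].
#' @param crs_meta opaque pass-through metadata.
#' @return an object of class `env_stack`.
#' @export
env_stack <- function(layers, mask = NULL, period = "historical",
                      provenance = "raw", origin = c(1L, 1L),
                      pca_loadings = NULL, pca_center = NULL,
                      pca_scale = NULL, pca_aligned = NA,
                      crs_meta = NULL) {
  if (is.list(layers) && !is.array(layers)) {
    nm <- names(layers)
    if (is.null(nm) || any(nm == "")) stop("all layers must be named")
    layers <- array(unlist(layers, use.names = FALSE),
                    dim = c(nrow(layers[[1]]), ncol(layers[[1]]), length(layers)),
                    dimnames = list(NULL, NULL, nm))
  }
  stopifnot(is.array(layers), length(dim(layers)) == 3)
  if (is.null(dimnames(layers)[[3]])) stop("layers must carry names")
  if (is.null(mask)) {
    mask <- apply(!is.na(layers), c(1, 2), all)
    dimnames(mask) <- NULL
  }
  stopifnot(is.logical(mask),
            all(dim(mask) == dim(layers)[1:2]))
  period <- match.arg(period, c("historical", "modern"))
  provenance <- match.arg(provenance, c("raw", "apriori3", "pca3"))
  if (provenance == "apriori3" && dim(layers)[3] != 3)
    stop("apriori3 stacks must have exactly 3 layers")
  if (provenance == "pca3" && is.null(pca_loadings))
    stop("pca3 stacks must carry loadings")
  structure(list(layers = layers, mask = mask, period = period,
                 provenance = provenance, origin = as.integer(origin),
                 pca_loadings = pca_loadings, pca_center = pca_center,
                 pca_scale = pca_scale, pca_aligned = pca_aligned,
                 crs_meta = crs_meta),
            class = "env_stack")
}

#' @export
print.env_stack <- function(x, ...) {
  d <- dim(x$layers)
  cat(sprintf("<env_stack> %d x %d cells, %d layers (%s, %s), %d valid\n",
              d[1], d[2], d[3], x$provenance, x$period, sum(x$mask)))
  cat("  layers:", paste(layer_names(x), collapse = ", "), "\n")
  invisible(x)
}

#' @rdname env_stack
#' @param env an `env_stack`.
#' @export
layer_names <- function(env) dimnames(env$layers)[[3]]

#' @rdname env_stack
#' @export
n_valid_cells <- function(env) sum(env$mask)

# Matrix of environmental vectors at all valid cells (cells x layers),
# with attribute "cells" giving the column-major cell index into the grid.
#' Extract the valid-cell environment matrix from a stack
#'
#' @param env an `env_stack`.
#' @return numeric matrix (valid cells x layers) with attribute `cells`
#'   (column-major cell indices into the grid).
#' @export
env_values <- function(env) {
  cells <- which(env$mask)
  L <- dim(env$layers)[3]
  ncell <- prod(dim(env$mask))
  out <- vapply(seq_len(L), function(j) env$layers[cells + (j - 1) * ncell],
                numeric(length(cells)))
  out <- matrix(out, nrow = length(cells), ncol = L,
                dimnames = list(NULL, layer_names(env)))
  attr(out, "cells") <- cells
  out
}

# Environmental vectors at given global (x = col, y = row) coordinates.
# Rows falling outside the stack or on masked cells are NA.
#' Extract environment vectors at occurrence coordinates
#'
#' @param env an `env_stack`.
#' @param x,y global column and row indices (vectors of equal length).
#' @return numeric matrix (records x layers); off-grid or masked records
#'   give `NA` rows.
#' @export
env_extract <- function(env, x, y) {
  stopifnot(length(x) == length(y))
  d <- dim(env$layers)
  r <- as.integer(y) - env$origin[1] + 1L
  c_ <- as.integer(x) - env$origin[2] + 1L
  ok <- r >= 1 & r <= d[1] & c_ >= 1 & c_ <= d[2]
  ok[ok] <- env$mask[cbind(r[ok], c_[ok])]
  out <- matrix(NA_real_, length(x), d[3],
                dimnames = list(NULL, layer_names(env)))
  if (any(ok)) {
    idx <- cbind(r[ok], c_[ok])
    for (j in seq_len(d[3])) out[ok, j] <- env$layers[, , j][idx]
  }
  out
}

# Global column-major cell id for records on env's parent grid frame;
# NA where off-stack/off-mask. Used for thinning and presence bookkeeping.
occ_cell_id <- function(env, x, y) {
  d <- dim(env$layers)
  r <- as.integer(y) - env$origin[1] + 1L
  c_ <- as.integer(x) - env$origin[2] + 1L
  ok <- r >= 1 & r <= d[1] & c_ >= 1 & c_ <= d[2]
  ok[ok] <- env$mask[cbind(r[ok], c_[ok])]
  out <- rep(NA_integer_, length(x))
  out[ok] <- (c_[ok] - 1L) * d[1] + r[ok]
  out
}

#' Construct an occurrence table
#'
#' Occurrence records are plain data frames with columns `species`,
#' `x` (column index), `y` (row index), `period`
#' (`"historical"`/`"modern"`), and `source` (free-text provenance).
#'
#' @param species,x,y,period,source column vectors (recycled to a common
#'   length).
#' @param crs_meta opaque pass-through metadata attached as an attribute.
#' @return a `data.frame` of class `occurrences`.
#' @export
occurrences <- function(species, x, y, period, source = "synthetic",
                        crs_meta = NULL) {
  df <- data.frame(species = as.character(species), x = as.integer(x),
                   y = as.integer(y), period = as.character(period),
                   source = as.character(source),
                   stringsAsFactors = FALSE)
  stopifnot(all(df$period %in% c("historical", "modern")))
  attr(df, "crs_meta") <- crs_meta
  class(df) <- c("occurrences", "data.frame")
  df
}

#' Suitability and binary prediction maps
#'
#' A `suit_map` holds a continuous habitat-suitability surface in
#' `[0, 1]` on the valid cells of an [env_stack()] (NA elsewhere); a
#' `binary_map` holds its 0/1 counterpart after prevalence-calibrated
#' binarization.
#'
#' @param values numeric matrix, same shape as `mask`.
#' @param mask logical validity matrix.
#' @param source named list describing how the map was produced
#'   (species, procedure, period trained, period projected).
#' @param origin global (row, col) of the upper-left cell.
#' @return an object of class `suit_map`.
#' @export
suit_map <- function(values, mask, source = list(), origin = c(1L, 1L)) {
  stopifnot(is.matrix(values), all(dim(values) == dim(mask)))
  v <- values[mask]
  if (any(!is.finite(v))) stop("suitability must be finite on the mask")
  if (any(v < -1e-9 | v > 1 + 1e-9)) stop("suitability must lie in [0, 1]")
  values[!mask] <- NA_real_
  structure(list(values = values, mask = mask, source = source,
                 origin = as.integer(origin)),
            class = "suit_map")
}

#' @rdname suit_map
#' @param threshold_meta list recording how the binarization threshold was
#'   obtained (prevalence, alpha, beta, mode, seed).
#' @export
binary_map <- function(values, mask, source = list(), origin = c(1L, 1L),
                       threshold_meta = list()) {
  stopifnot(is.matrix(values), all(dim(values) == dim(mask)))
  v <- values[mask]
  if (!all(v %in% c(0, 1))) stop("binary map values must be 0/1 on the mask")
  values[!mask] <- NA_real_
  structure(list(values = values, mask = mask, source = source,
                 origin = as.integer(origin), threshold_meta = threshold_meta),
            class = "binary_map")
}

#' @export
print.suit_map <- function(x, ...) {
  v <- x$values[x$mask]
  cat(sprintf("<suit_map> %d x %d, %d valid cells, range [%.3f, %.3f]\n",
              nrow(x$values), ncol(x$values), sum(x$mask),
              min(v), max(v)))
  invisible(x)
}

#' @export
print.binary_map <- function(x, ...) {
  cat(sprintf("<binary_map> %d x %d, %d valid cells, %d presences\n",
              nrow(x$values), ncol(x$values), sum(x$mask),
              sum(x$values[x$mask] == 1)))
  invisible(x)
}
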