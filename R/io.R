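#' Read and write grids and occurrence tables as plain text
#'
#' Grid layers are stored in the ESRI ASCII grid format (one `.asc` file
#' per layer; `NODATA_value` encodes masked cells) together with a YAML
#' sidecar holding the stack metadata (layer order, period, provenance,
#' origin, PCA loadings). Occurrence tables are plain CSV with the header
#' `species,x,y,period,source`. Both formats are readable by standard GIS
#' and spreadsheet tools and diff cleanly under version control.
#'
#' @param mat numeric matrix to write.
#' @param path file path.
#' @param nodata value used for `NA` cells.
#' @return `read_ascii_grid` returns a numeric matrix; writers return the
#'   path invisibly.
#' @name grid_io
NULL

#' @rdname grid_io
#' @export
write_ascii_grid <- function(mat, path, nodata = -9999) {
  stopifnot(is.matrix(mat))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("ncols %d", ncol(mat)),
               sprintf("nrows %d", nrow(mat)),
               "xllcorner 0", "yllcorner 0", "cellsize 1",
               sprintf("NODATA_value %g", nodata)), con)
  m <- mat
  m[is.na(m)] <- nodata
  utils::write.table(format(m, digits = 10, trim = TRUE, scientific = FALSE),
                     con, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname grid_io
#' @export
read_ascii_grid <- function(path) {
  hdr <- readLines(path, n = 6)
  kv <- strsplit(hdr, "\\s+")
  vals <- stats::setNames(as.numeric(vapply(kv, `[`, "", 2)),
                          tolower(vapply(kv, `[`, "", 1)))
  m <- as.matrix(utils::read.table(path, skip = 6))
  dimnames(m) <- NULL
  stopifnot(nrow(m) == vals[["nrows"]], ncol(m) == vals[["ncols"]])
  m[m == vals[["nodata_value"]]] <- NA_real_
  m
}

#' @rdname grid_io
#' @param env an [env_stack()] to write.
#' @param dir output directory (created if missing).
#' @param name base name for the stack's files.
#' @export
write_env_stack <- function(env, dir, name) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  nm <- layer_names(env)
  files <- file.path(dir, sprintf("%s_%s.asc", name, nm))
  for (j in seq_along(nm)) {
    m <- env$layers[, , j]
    m[!env$mask] <- NA_real_
    write_ascii_grid(m, files[j])
  }
  meta <- list(layers = as.list(nm), period = env$period,
               provenance = env$provenance, origin = as.integer(env$origin),
               pca_aligned = env$pca_aligned, crs_meta = env$crs_meta)
  if (!is.null(env$pca_loadings)) {
    meta$pca_loadings <- apply(env$pca_loadings, 2, as.list)
    meta$pca_center <- as.list(env$pca_center)
    meta$pca_scale <- as.list(env$pca_scale)
    meta$pca_variables <- as.list(rownames(env$pca_loadings))
  }
  yaml::write_yaml(meta, file.path(dir, sprintf("%s_stack.yml", name)),
                   precision = 15)
  invisible(file.path(dir, sprintf("%s_stack.yml", name)))
}

#' @rdname grid_io
#' @export
read_env_stack <- function(dir, name) {
  meta <- yaml::read_yaml(file.path(dir, sprintf("%s_stack.yml", name)))
  nm <- unlist(meta$layers)
  mats <- lapply(nm, function(l)
    read_ascii_grid(file.path(dir, sprintf("%s_%s.asc", name, l))))
  names(mats) <- nm
  loadings <- NULL; center <- NULL; scl <- NULL
  if (!is.null(meta$pca_loadings)) {
    loadings <- do.call(cbind, lapply(meta$pca_loadings, unlist))
    rownames(loadings) <- unlist(meta$pca_variables)
    colnames(loadings) <- nm
    center <- unlist(meta$pca_center)
    scl <- unlist(meta$pca_scale)
  }
  env_stack(mats, period = meta$period, provenance = meta$provenance,
            origin = unlist(meta$origin),
            pca_loadings = loadings, pca_center = center, pca_scale = scl,
            pca_aligned = if (is.null(meta$pca_aligned)) NA else meta$pca_aligned,
            crs_meta = meta$crs_meta)
}

#' @rdname grid_io
#' @param occ an [occurrences()] table.
#' @export
write_occurrences <- function(occ, path) {
  utils::write.csv(as.data.frame(occ)[, c("species", "x", "y", "period", "source")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname grid_io
#' @export
read_occurrences <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("species", "x", "y", "period", "source")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("occurrence file lacks columns: ", paste(missing, collapse = ", "))
  occurrences(df$species, df$x, df$y, df$period, df$source)
}
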