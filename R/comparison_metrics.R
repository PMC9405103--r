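#' Schoener's D overlap between two suitability maps
#'
#' Both maps are normalized to sum to one over the shared valid cells
#' (giving densities `p` and `q`); `D = 1 - 0.5 * sum |p - q|`, a
#' symmetric similarity in `[0, 1]` (1 for identical surfaces, 0 for
#' disjoint positive supports).
#'
#' @param map1,map2 [suit_map()]s on the same grid and mask, each with
#'   at least one positive cell.
#' @return Schoener's D in `[0, 1]`.
#' @export
schoener_d <- function(map1, map2) {
  stopifnot(inherits(map1, "suit_map"), inherits(map2, "suit_map"))
  if (!identical(map1$mask, map2$mask) ||
      !identical(dim(map1$values), dim(map2$values)))
    stop("maps must share grid and mask")
  v1 <- map1$values[map1$mask]
  v2 <- map2$values[map2$mask]
  if (sum(v1) == 0 || sum(v2) == 0)
    stop("all-zero map: Schoener's D is undefined")
  p <- v1 / sum(v1)
  q <- v2 / sum(v2)
  1 - 0.5 * sum(abs(p - q))
}

#' Percentage of stable cells between two binary maps
#'
#' The share of presence cells found in both potential distributions,
#' expressed as a percentage. With the default `"union"` denominator
#' this is the Jaccard index of the two presence-cell sets times 100;
#' `"total_cells"` divides by all valid cells instead.
#'
#' @param bin1,bin2 [binary_map()]s on the same grid and mask, with at
#'   least one presence cell between them.
#' @param denominator `"union"` (default) or `"total_cells"`.
#' @return stability in `[0, 100]`.
#' @export
stability <- function(bin1, bin2, denominator = c("union", "total_cells")) {
  denominator <- match.arg(denominator)
  stopifnot(inherits(bin1, "binary_map"), inherits(bin2, "binary_map"))
  if (!identical(bin1$mask, bin2$mask) ||
      !identical(dim(bin1$values), dim(bin2$values)))
    stop("maps must share grid and mask")
  a <- bin1$values[bin1$mask] == 1
  b <- bin2$values[bin2$mask] == 1
  both <- sum(a & b)
  either <- sum(a | b)
  if (either == 0) stop("no presence cells in either map")
  den <- if (denominator == "union") either else length(a)
  100 * both / den
}

#' Range-size variation between projected and modern distributions
#'
#' Signed percent change in predicted range size:
#' `100 * (|projected| - |modern|) / |modern|` presence cells. Positive
#' values mean the projection overestimates the modern range.
#'
#' @param projected the historical-trained, modern-projected
#'   [binary_map()].
#' @param modern the modern-trained [binary_map()]; must have at least
#'   one presence cell.
#' @return signed percentage.
#' @export
range_size_variation <- function(projected, modern) {
  stopifnot(inherits(projected, "binary_map"), inherits(modern, "binary_map"))
  np <- sum(projected$values[projected$mask] == 1)
  nm <- sum(modern$values[modern$mask] == 1)
  if (nm == 0) stop("modern map has no presence cells")
  100 * (np - nm) / nm
}

#' Distance to the theoretical-best performance point
#'
#' Euclidean distance of a `(D, S, RSV)` triple from the point of best
#' theoretical performance `(D = 1, S = 100, RSV = 0)`:
#' `d = sqrt((1 - D)^2 + (100 - S)^2 + RSV^2)`. Axes are mixed on their
#' raw scales (D unit-scaled, stability and range-size variation in
#' percent), so the stability axis dominates in practice and the
#' empirical ceiling for small `|RSV|` is about 100.
#'
#' @param D Schoener's D, in `[0, 1]`.
#' @param S stability percentage, in `[0, 100]`.
#' @param RSV signed range-size variation percentage.
#' @return non-negative distance; 0 exactly at the best point.
#' @export
distance_to_ideal <- function(D, S, RSV) {
  if (any(D < 0 | D > 1)) stop("D must lie in [0, 1]")
  if (any(S < 0 | S > 100)) stop("S must lie in [0, 100]")
  sqrt((1 - D)^2 + (100 - S)^2 + RSV^2)
}

#' Assemble a pair-comparison record
#'
#' Computes all four comparison statistics for one Distribution 1 /
#' Distribution 2 pair (continuous maps for D, binary maps for S and
#' RSV) and returns them as a single-row data frame.
#'
#' @param proj_cont,mod_cont continuous [suit_map()]s (projected and
#'   modern).
#' @param proj_bin,mod_bin their binarized counterparts.
#' @param species,procedure,variable_set identifiers for the record.
#' @return one-row `data.frame` with columns `species`, `procedure`,
#'   `variable_set`, `D`, `S`, `RSV`, `d`.
#' @export
pair_comparison <- function(proj_cont, mod_cont, proj_bin, mod_bin,
                            species = "sp", procedure = "proc",
                            variable_set = "apriori3") {
  D <- schoener_d(proj_cont, mod_cont)
  S <- stability(proj_bin, mod_bin)
  RSV <- range_size_variation(proj_bin, mod_bin)
  data.frame(species = species, procedure = procedure,
             variable_set = variable_set, D = D, S = S, RSV = RSV,
             d = distance_to_ideal(D, S, RSV),
             stringsAsFactors = FALSE)
}
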