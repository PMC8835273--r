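#' Spatial-structure indicators of a study unit
#'
#' Ratio metrics describing a unit's perceptual and vegetation
#' structure, computed from already-measured field primitives (the
#' photo/CAD segmentation that produces the extents is out of scope).
#'
#' `space_enclosure` is L1/L: the fraction of the unit boundary
#' perimeter enclosed by qualifying vegetation at the bottom layer.
#' `tree_cover` is S1/S: summed vertical tree-projection area over unit
#' site area. `panorama_fraction` converts a 125-degree three-photo
#' panorama extent pair into a percentage; it serves both the
#' visible-space proportion (visual obstacles) and the greenery-element
#' proportion (green view index).
#'
#' @param L boundary perimeter of the unit (m), positive.
#' @param L1 enclosed perimeter length (m), in \[0, L\].
#' @return `space_enclosure`: ratio in \[0, 1\].
#' @export
space_enclosure <- function(L1, L) {
  if (any(L <= 0)) stop("unit boundary perimeter L must be positive", call. = FALSE)
  if (any(L1 < 0 | L1 > L)) stop("L1 must lie in [0, L]", call. = FALSE)
  L1 / L
}

#' @rdname space_enclosure
#' @param S unit site area (m^2), positive.
#' @param S1 summed vertical tree-projection area (m^2), in \[0, S\].
#' @return `tree_cover`: ratio in \[0, 1\].
#' @export
tree_cover <- function(S1, S) {
  if (any(S <= 0)) stop("unit site area S must be positive", call. = FALSE)
  if (any(S1 < 0 | S1 > S)) stop("S1 must lie in [0, S]", call. = FALSE)
  S1 / S
}

#' @rdname space_enclosure
#' @param part_extent measured extent of the part (visible space or
#'   greenery elements), nonnegative.
#' @param total_extent total panorama extent, positive; `part_extent`
#'   must not exceed it.
#' @return `panorama_fraction`: percent in \[0, 100\].
#' @export
panorama_fraction <- function(part_extent, total_extent) {
  if (any(total_extent <= 0)) stop("total extent must be positive", call. = FALSE)
  if (any(part_extent < 0 | part_extent > total_extent))
    stop("part extent must lie in [0, total]", call. = FALSE)
  100 * part_extent / total_extent
}

#' Shannon-Wiener vegetation diversity
#'
#' \eqn{H = -\sum_i P_i \ln P_i} with \eqn{P_i = N_i / N} over vegetation
#' species counts; natural log, so H is in nats. H is 0 for a single
#' species and at most `ln(number of species)`.
#'
#' @param species_counts positive integer vector of per-species counts
#'   (names optional).
#' @return nonnegative real H.
#' @export
shannon_diversity <- function(species_counts) {
  if (!length(species_counts)) stop("empty vegetation census", call. = FALSE)
  if (any(species_counts < 1)) stop("species counts must be >= 1", call. = FALSE)
  p <- species_counts / sum(species_counts)
  -sum(p * log(p))
}
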