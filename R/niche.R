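normalizeGrid <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop("grids must have identical shape")
  naA <- is.na(a); naB <- is.na(b)
  if (!identical(naA, naB))
    stop("no-data masks differ between grids; harmonize them explicitly")
  va <- a[!naA]; vb <- b[!naB]
  if (any(va < 0) || any(vb < 0)) stop("suitability values must be nonnegative")
  if (sum(va) <= 0 || sum(vb) <= 0)
    stop("overlap undefined: a grid has zero total suitability")
  list(pa = va / sum(va), pb = vb / sum(vb))
}

#' Schoener's D niche overlap
#'
#' Both suitability surfaces are normalized to sum 1 over valid cells and
#' compared as distributions: `D = 1 - 0.5 * sum |p_a - p_b|`. 1 means
#' identical distributions, 0 disjoint supports.
#'
#' @param a,b numeric suitability matrices of identical shape and no-data
#'   (`NA`) mask.
#' @return Overlap in `[0, 1]`.
#' @export
schoenersD <- function(a, b) {
  p <- normalizeGrid(a, b)
  1 - 0.5 * sum(abs(p$pa - p$pb))
}

#' Hellinger-based I niche overlap
#'
#' `I = 1 - 0.5 * sum (sqrt(p_a) - sqrt(p_b))^2`, one minus half the squared
#' Hellinger distance between the normalized surfaces. Like Schoener's D it
#' ranges from 0 (disjoint) to 1 (identical), and `I >= D` on any shared
#' support.
#'
#' @inheritParams schoenersD
#' @return Overlap in `[0, 1]`.
#' @export
hellingersI <- function(a, b) {
  p <- normalizeGrid(a, b)
  1 - 0.5 * sum((sqrt(p$pa) - sqrt(p$pb))^2)
}
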