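# Conversion of recombination frequencies into additive map distances.

MAPPING_FUNCTIONS <- c("haldane", "kosambi", "carter_falconer")

#' Convert a recombination frequency to a genetic distance
#'
#' Inverse mapping functions, all returning centiMorgans and agreeing with
#' `100 * theta` as `theta -> 0`:
#' \itemize{
#'   \item Haldane (no crossover interference):
#'     `d = -50 * ln(1 - 2 theta)`
#'   \item Kosambi (moderate interference):
#'     `d = 25 * ln((1 + 2 theta) / (1 - 2 theta))`
#'   \item Carter-Falconer (strong interference, mouse-derived):
#'     `d = 12.5 * ln((1 + 2 theta) / (1 - 2 theta)) + 25 * atan(2 theta)`
#' }
#' All are strictly increasing with `d(0) = 0` and diverge (Haldane) or stay
#' finite-slope-free as `theta -> 0.5`; an exact input of 0.5 is undefined,
#' so by default it is clamped to `0.5 - 1e-6` with a warning (grouping
#' should prevent unlinked adjacencies from reaching the spacing step).
#'
#' @param theta recombination frequency (vectorized), in `[0, 0.5]`.
#' @param fn one of `"haldane"` (default), `"kosambi"`, `"carter_falconer"`.
#' @param clamp clamp `theta >= 0.5` down to `0.5 - 1e-6` (with a warning)
#'   instead of raising an error.
#' @return distance(s) in centiMorgans.
#' @examples
#' map_distance(0.25, "haldane")  # 34.657
#' map_distance(0.25, "kosambi")  # 27.465
#' @export
map_distance <- function(theta, fn = MAPPING_FUNCTIONS, clamp = TRUE) {
  fn <- match.arg(fn)
  if (any(theta < 0 | theta > 0.5))
    stop("recombination frequency must lie in [0, 0.5]", call. = FALSE)
  hit <- theta >= 0.5
  if (any(hit)) {
    if (!clamp)
      stop("theta = 0.5 has no finite map distance (unlinked markers)",
           call. = FALSE)
    warning("theta = 0.5 clamped to 0.5 - 1e-6 for spacing", call. = FALSE)
    theta[hit] <- 0.5 - 1e-6
  }
  switch(fn,
    haldane = -50 * log(1 - 2 * theta),
    kosambi = 25 * log((1 + 2 * theta) / (1 - 2 * theta)),
    carter_falconer = 12.5 * log((1 + 2 * theta) / (1 - 2 * theta)) +
      25 * atan(2 * theta))
}

#' Map distance back to a recombination frequency (Haldane)
#'
#' @param d distance in centiMorgans.
#' @return recombination frequency `(1 - exp(-2 d / 100)) / 2`.
#' @export
haldane_theta <- function(d) (1 - exp(-2 * d / 100)) / 2

#' Cumulative cM positions for an ordered group
#'
#' The first marker sits at 0; each subsequent position adds the mapped
#' distance of the adjacent recombination frequency, giving nondecreasing
#' cumulative positions.
#'
#' @param s resolved, oriented marker order (character vector).
#' @param theta recombination-frequency matrix covering the markers of `s`.
#' @param fn mapping function name, see [map_distance()].
#' @return numeric vector of positions (cM), named by marker.
#' @export
space_group <- function(s, theta, fn = MAPPING_FUNCTIONS) {
  fn <- match.arg(fn)
  n <- length(s)
  if (n == 0) stop("empty order", call. = FALSE)
  if (n == 1) return(stats::setNames(0, s))
  idx <- match(s, rownames(theta))
  if (anyNA(idx)) stop("order contains markers absent from the matrix", call. = FALSE)
  adj <- unclass(theta)[cbind(idx[-n], idx[-1])]
  d <- tryCatch(map_distance(adj, fn),
                error = function(e) stop(sprintf(
                  "spacing failed between '%s' and '%s': %s",
                  s[which.max(adj)], s[which.max(adj) + 1], conditionMessage(e)),
                  call. = FALSE))
  stats::setNames(cumsum(c(0, d)), s)
}

#' Build a full linkage map from a grouping
#'
#' Runs ordering ([order_markers()]) and spacing ([space_group()]) for every
#' linkage group of a grouping and assembles the result, carrying
#' filtered-out markers along as unassigned.
#'
#' @param theta recombination-frequency matrix over all markers.
#' @param grouping a `grouping` from [cut_groups()] /
#'   [filter_small_groups()].
#' @param fn mapping function name.
#' @return a [linkage_map].
#' @export
build_linkage_map <- function(theta, grouping, fn = MAPPING_FUNCTIONS) {
  fn <- match.arg(fn)
  stopifnot(inherits(grouping, "grouping"))
  gids <- unique(unname(grouping$assignment))
  groups <- lapply(gids, function(gid) {
    ms <- names(grouping$assignment)[grouping$assignment == gid]
    sub <- unclass(theta)[ms, ms, drop = FALSE]
    s <- order_markers(sub)
    pos <- space_group(s, sub, fn)
    data.frame(marker = s, position = unname(pos), stringsAsFactors = FALSE)
  })
  names(groups) <- gids
  linkage_map(groups, unassigned = grouping$filtered_out)
}
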