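# Linkage-group assignment: single-linkage hierarchical clustering on the
# estimated recombination frequencies, a manual threshold (or group-count)
# cut, and a minimum-size filter.
#
# Single linkage is used deliberately: markers with the lowest recombination
# frequency always end up in the same group, unaffected by markers at the
# other end of the chromosome (which complete or average linkage would drag
# in).

#' Single-linkage dendrogram over markers
#'
#' Clusters all markers hierarchically with single linkage, using the
#' estimated recombination frequencies directly as distances. Merge heights
#' are therefore on the theta-hat scale and are nondecreasing along the
#' merge sequence.
#'
#' @param theta symmetric recombination-frequency matrix
#'   (see [recombination_matrix()]), or any symmetric distance-like matrix
#'   with zero diagonal.
#' @return an object of class `hclust`.
#' @export
rf_dendrogram <- function(theta) {
  theta <- unclass(theta)
  if (!is.matrix(theta) || nrow(theta) != ncol(theta) ||
      any(abs(theta - t(theta)) > 1e-12) || any(diag(theta) != 0))
    stop("input must be a symmetric matrix with zero diagonal", call. = FALSE)
  if (any(theta < 0)) stop("distances must be nonnegative", call. = FALSE)
  stats::hclust(stats::as.dist(theta), method = "single")
}

#' Cut a dendrogram into linkage groups
#'
#' Cuts the single-linkage tree either at a recombination-frequency height
#' (subtrees merged strictly below `threshold` become groups) or into a
#' requested number of groups `k`. Exactly one of the two must be given;
#' recommended practice is to inspect the dendrogram and choose the cut
#' deliberately. Group ids are assigned in order of each group's first
#' marker in the input marker order, so the labelling is deterministic.
#'
#' @param dend `hclust` object from [rf_dendrogram()].
#' @param threshold cut height on the theta-hat scale.
#' @param k number of groups.
#' @return a `grouping`: list with `assignment` (named character vector
#'   marker -> group id), `filtered_out` (empty here; see
#'   [filter_small_groups()]), and the `threshold`/`k` used.
#' @export
cut_groups <- function(dend, threshold = NULL, k = NULL) {
  stopifnot(inherits(dend, "hclust"))
  if (is.null(threshold) == is.null(k))
    stop("give exactly one of threshold or k", call. = FALSE)
  n <- length(dend$labels)
  if (!is.null(k) && (k < 1 || k > n))
    stop(sprintf("k must be in [1, %d]", n), call. = FALSE)
  cl <- if (!is.null(threshold)) {
    # cutree(h=) cuts at height <= h; group markers merged strictly below
    # the threshold, so nudge just under it
    stats::cutree(dend, h = threshold - 1e-12)
  } else {
    stats::cutree(dend, k = k)
  }
  # relabel group ids by first occurrence in input marker order
  first <- match(unique(cl), cl)
  relabel <- rank(first)[match(cl, unique(cl))]
  assignment <- paste0("LG", relabel)
  names(assignment) <- dend$labels
  structure(list(assignment = assignment, filtered_out = character(0),
                 threshold = threshold, k = k, min_frac = NULL),
            class = "grouping")
}

#' @export
print.grouping <- function(x, ...) {
  sizes <- sort(table(x$assignment), decreasing = TRUE)
  cat(sprintf("grouping: %d group(s), %d filtered marker(s)\n",
              length(sizes), length(x$filtered_out)))
  print(sizes)
  invisible(x)
}

#' Dissolve undersized linkage groups
#'
#' Groups holding fewer than `min_frac * n_total` markers are usually
#' clustering artefacts (noisy markers, small-sample overestimation of the
#' group count); their markers are moved to `filtered_out` and excluded from
#' ordering and spacing. The default fraction is 0.05, i.e. each group must
#' contain at least 5 percent of the markers; decrease it for species with
#' more than 10 chromosomes or uneven marker coverage.
#'
#' @param grouping a `grouping` from [cut_groups()].
#' @param min_frac minimum group size as a fraction of `n_total`, in `[0, 1)`.
#' @param n_total total marker count the fraction refers to; defaults to the
#'   number of assigned plus already-filtered markers.
#' @return the filtered `grouping`, with surviving groups renumbered
#'   `LG1, LG2, ...` in order of first marker.
#' @export
filter_small_groups <- function(grouping, min_frac = 0.05, n_total = NULL) {
  stopifnot(inherits(grouping, "grouping"))
  if (min_frac < 0 || min_frac >= 1)
    stop("min_frac must be in [0, 1)", call. = FALSE)
  if (is.null(n_total))
    n_total <- length(grouping$assignment) + length(grouping$filtered_out)
  sizes <- table(grouping$assignment)
  drop <- names(sizes)[sizes < min_frac * n_total]
  dropped <- names(grouping$assignment)[grouping$assignment %in% drop]
  keep <- grouping$assignment[!grouping$assignment %in% drop]
  if (length(keep) > 0) {
    old <- unique(keep)
    keep[] <- paste0("LG", match(keep, old))
  }
  structure(list(assignment = keep,
                 filtered_out = c(grouping$filtered_out, dropped),
                 threshold = grouping$threshold, k = grouping$k,
                 min_frac = min_frac),
            class = "grouping")
}

#' Write a grouping as TSV
#'
#' @param grouping a `grouping`.
#' @param path output path; columns `marker`, `group` (`"filtered"` for
#'   removed markers).
#' @export
write_grouping <- function(grouping, path) {
  df <- rbind(
    data.frame(marker = names(grouping$assignment),
               group = unname(grouping$assignment),
               stringsAsFactors = FALSE),
    if (length(grouping$filtered_out) > 0)
      data.frame(marker = grouping$filtered_out, group = "filtered",
                 stringsAsFactors = FALSE)
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
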