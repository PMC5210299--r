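# Linkage maps as dendrograms, and statistics to compare two maps.
#
# A linkage map is transformed into a dendrogram whose leaf order and branch
# heights encode the marker order and spacing exactly: within each group the
# markers form a left-to-right chain whose merge heights are the cumulative
# cM positions, and all groups hang from a root line placed 0.2 times higher
# than the highest within-group connection (the root line aids readability,
# it does not express similarity). Two such dendrograms are compared by the
# Goodman-Kruskal gamma index (rank concordance of all pairwise cophenetic
# distances) and by cophenetic correlation (Pearson correlation of the same
# distances), with permutation (Mantel-type) tests for significance.

#' Transform a linkage map into a dendrogram
#'
#' @param map a [linkage_map] with at least two assigned markers.
#' @return an `hclust` object whose leaf order equals the concatenated group
#'   orders and whose cophenetic distance between two markers of the same
#'   group is the cM position of the later of the two (the root-line height
#'   separates markers of different groups).
#' @export
map_to_dendrogram <- function(map) {
  stopifnot(inherits(map, "linkage_map"))
  groups <- map$groups
  labels <- unlist(lapply(groups, `[[`, "marker"), use.names = FALSE)
  n <- length(labels)
  if (n < 2) stop("map must contain at least two assigned markers", call. = FALSE)
  leaf_idx <- stats::setNames(seq_len(n), labels)
  max_h <- max(vapply(groups, function(g) max(g$position), numeric(1)))
  root_h <- if (max_h > 0) 1.2 * max_h else 1
  # within-group chain events, then root-line events joining the groups
  ev_group <- integer(0); ev_leaf <- integer(0); ev_h <- numeric(0)
  for (gi in seq_along(groups)) {
    g <- groups[[gi]]
    if (nrow(g) < 2) next
    ev_group <- c(ev_group, rep(gi, nrow(g) - 1))
    ev_leaf <- c(ev_leaf, leaf_idx[g$marker[-1]])
    ev_h <- c(ev_h, g$position[-1])
  }
  ord <- order(ev_h)                      # stable: preserves chain order
  ev_group <- ev_group[ord]; ev_leaf <- ev_leaf[ord]; ev_h <- ev_h[ord]
  merge <- matrix(0L, 0, 2); height <- numeric(0)
  top <- vapply(groups, function(g) -leaf_idx[g$marker[1]], numeric(1))
  for (e in seq_along(ev_h)) {
    gi <- ev_group[e]
    merge <- rbind(merge, c(top[gi], -ev_leaf[e]))
    height <- c(height, ev_h[e])
    top[gi] <- nrow(merge)
  }
  if (length(groups) > 1) {
    cur <- top[1]
    for (gi in 2:length(groups)) {
      merge <- rbind(merge, c(cur, top[gi]))
      height <- c(height, root_h)
      cur <- nrow(merge)
    }
  }
  structure(list(merge = merge, height = height, order = seq_len(n),
                 labels = labels, method = "map",
                 call = match.call(), dist.method = "cM"),
            class = "hclust")
}

#' Cophenetic distance matrix of a dendrogram
#'
#' Entry (i, j) is the height of the lowest merge joining leaves i and j;
#' the matrix is symmetric, zero-diagonal and ultrametric.
#'
#' @param dend `hclust` object.
#' @return numeric matrix with leaf labels as dimnames.
#' @export
cophenetic_matrix <- function(dend) {
  stopifnot(inherits(dend, "hclust"))
  as.matrix(stats::cophenetic(dend))
}

upper_entries <- function(x) x[upper.tri(x)]

align_common <- function(x, y) {
  common <- intersect(rownames(x), rownames(y))
  if (length(common) < 3)
    stop("need at least 3 common markers to compare", call. = FALSE)
  list(x = x[common, common], y = y[common, common],
       n_common = length(common),
       dropped_x = setdiff(rownames(x), common),
       dropped_y = setdiff(rownames(y), common))
}

#' Goodman-Kruskal gamma between two distance matrices
#'
#' Rank-concordance of the two upper triangles: over all pairs of
#' marker-pairs, gamma = (C - D) / (C + D) with C and D the concordant and
#' discordant counts; pairs tied in either matrix are excluded. The
#' comparison is restricted to markers present in both matrices.
#'
#' @param x,y symmetric distance matrices with marker ids as dimnames.
#' @return gamma in `[-1, 1]`.
#' @export
gk_gamma <- function(x, y) {
  al <- align_common(x, y)
  gamma_vec(upper_entries(al$x), upper_entries(al$y))
}

# sort-based concordance count, O(E log E)
gamma_vec <- function(xv, yv) {
  E <- length(xv)
  total <- E * (E - 1) / 2
  o <- order(xv, yv)
  xv <- xv[o]; yv <- yv[o]
  D <- count_inversions(yv)
  tie_pairs <- function(v) sum(vapply(table(v), function(c) c * (c - 1) / 2,
                                      numeric(1)))
  Tx <- tie_pairs(xv); Ty <- tie_pairs(yv)
  Txy <- tie_pairs(paste(xv, yv, sep = "\r"))
  C <- total - Tx - Ty + Txy - D
  if (C + D == 0)
    stop("Goodman-Kruskal gamma undefined: all pairs tied", call. = FALSE)
  (C - D) / (C + D)
}

count_inversions <- function(v) {
  n <- length(v)
  if (n < 2) return(0)
  mid <- n %/% 2
  left <- v[seq_len(mid)]; right <- v[(mid + 1):n]
  il <- count_inversions(left); ir <- count_inversions(right)
  ls <- sort(left)
  cross <- sum(length(ls) - findInterval(right, ls))
  il + ir + cross
}

# quadratic reference implementation, kept as an independent oracle
gamma_naive <- function(xv, yv) {
  E <- length(xv); C <- 0; D <- 0
  for (i in seq_len(E - 1)) for (j in (i + 1):E) {
    s <- sign(xv[i] - xv[j]) * sign(yv[i] - yv[j])
    if (s > 0) C <- C + 1 else if (s < 0) D <- D + 1
  }
  if (C + D == 0) stop("gamma undefined", call. = FALSE)
  (C - D) / (C + D)
}

#' Cophenetic correlation between two distance matrices
#'
#' Pearson correlation of the two upper-triangle vectors over the common
#' markers. More sensitive than [gk_gamma()] to spacing differences because
#' it uses the distances themselves, not just their ranks.
#'
#' @param x,y symmetric distance matrices with marker ids as dimnames.
#' @return correlation in `[-1, 1]`.
#' @export
cophenetic_correlation <- function(x, y) {
  al <- align_common(x, y)
  xv <- upper_entries(al$x); yv <- upper_entries(al$y)
  if (stats::sd(xv) == 0 || stats::sd(yv) == 0)
    stop("cophenetic correlation undefined: zero variance", call. = FALSE)
  stats::cor(xv, yv)
}

#' Permutation test for dendrogram similarity
#'
#' Tests the null hypothesis that the two dendrograms are stochastically
#' independent: marker labels of the second matrix are permuted uniformly at
#' random, the statistic recomputed, and the Monte-Carlo p-value estimated
#' with the add-one estimator `p = (1 + #(perm >= observed)) / (n_perm + 1)`
#' (a Mantel-type matrix permutation test when the statistic is the
#' cophenetic correlation).
#'
#' @param x,y symmetric distance matrices with marker ids as dimnames.
#' @param statistic `"gk_gamma"` or `"cophenetic"`.
#' @param n_perm number of permutations (>= 1).
#' @param seed mandatory integer seed for reproducibility.
#' @return list of class `comparison_result`: `statistic`, `observed`,
#'   `p_value`, `n_perm`, `seed`, `n_common`, `n_dropped_x`, `n_dropped_y`.
#' @export
permutation_test <- function(x, y, statistic = c("gk_gamma", "cophenetic"),
                             n_perm = 99, seed) {
  statistic <- match.arg(statistic)
  if (missing(seed) || is.null(seed))
    stop("a seed is required for the permutation test", call. = FALSE)
  if (n_perm < 1) stop("n_perm must be >= 1", call. = FALSE)
  al <- align_common(x, y)
  stat_fun <- if (statistic == "gk_gamma") {
    function(a, b) gamma_vec(upper_entries(a), upper_entries(b))
  } else {
    function(a, b) stats::cor(upper_entries(a), upper_entries(b))
  }
  observed <- stat_fun(al$x, al$y)
  set.seed(seed)
  m <- al$n_common
  hits <- 0L
  for (i in seq_len(n_perm)) {
    p <- sample.int(m)
    perm <- al$y[p, p]
    val <- tryCatch(stat_fun(al$x, perm), error = function(e) NA_real_)
    if (!is.na(val) && val >= observed) hits <- hits + 1L
  }
  structure(list(statistic = statistic, observed = observed,
                 p_value = (1 + hits) / (n_perm + 1), n_perm = n_perm,
                 seed = seed, n_common = al$n_common,
                 n_dropped_x = length(al$dropped_x),
                 n_dropped_y = length(al$dropped_y)),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("%s = %.4f (n = %d common markers", x$statistic, x$observed,
              x$n_common))
  if (x$n_dropped_x + x$n_dropped_y > 0)
    cat(sprintf("; dropped %d/%d", x$n_dropped_x, x$n_dropped_y))
  cat(")\n")
  if (!is.null(x$p_value))
    cat(sprintf("Monte-Carlo p = %.4g (%d permutations, seed %d)\n",
                x$p_value, x$n_perm, x$seed))
  invisible(x)
}

#' Export a dendrogram as a Newick string
#'
#' Branch lengths are derived from merge heights (ultrametric tree), so a
#' parse-roundtrip preserves topology and cophenetic structure.
#'
#' @param dend `hclust` object.
#' @param path optional file path; if given the tree is written there.
#' @return the Newick string, invisibly when `path` is given.
#' @export
to_newick <- function(dend, path = NULL) {
  stopifnot(inherits(dend, "hclust"))
  phy <- ape::as.phylo(dend)
  txt <- ape::write.tree(phy)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' Read a dendrogram's cophenetic structure from a Newick file
#'
#' @param path Newick file.
#' @return list with `cophenetic` (matrix of merge heights; the export
#'   convention makes the leaf-to-leaf path length equal the merge height)
#'   and `leaf_order`.
#' @export
read_dendrogram_newick <- function(path) {
  phy <- ape::read.tree(path)
  coph <- ape::cophenetic.phylo(phy)
  tips <- phy$tip.label[phy$edge[phy$edge[, 2] <= ape::Ntip(phy), 2]]
  list(cophenetic = coph, leaf_order = tips)
}

#' Tanglegram leaf pairing of two dendrograms
#'
#' Pairs each leaf shared by both dendrograms with its position index in
#' either leaf order; leaves present on only one side are excluded from the
#' pairing but counted, since their number should accompany any tanglegram.
#'
#' @param d1,d2 `hclust` objects.
#' @return data.frame `(marker, pos1, pos2)` with attributes `n_dropped_1`
#'   and `n_dropped_2`.
#' @export
tanglegram_pairs <- function(d1, d2) {
  l1 <- d1$labels[d1$order]
  l2 <- d2$labels[d2$order]
  common <- intersect(l1, l2)
  if (length(common) == 0) stop("no common leaves", call. = FALSE)
  keep1 <- l1[l1 %in% common]
  out <- data.frame(marker = keep1,
                    pos1 = match(keep1, l1[l1 %in% common]),
                    pos2 = match(keep1, l2[l2 %in% common]),
                    stringsAsFactors = FALSE)
  attr(out, "n_dropped_1") <- length(l1) - length(common)
  attr(out, "n_dropped_2") <- length(l2) - length(common)
  out
}

#' Compare two linkage maps
#'
#' Transforms both maps into dendrograms and computes the requested
#' similarity statistics with permutation tests.
#'
#' @param map_a,map_b [linkage_map] objects.
#' @param stat `"gk"`, `"cophenetic"` or `"both"`.
#' @param n_perm permutations for the tests (0 to skip testing).
#' @param seed integer seed (required when `n_perm > 0`).
#' @return named list of `comparison_result`s.
#' @export
compare_maps <- function(map_a, map_b, stat = c("both", "gk", "cophenetic"),
                         n_perm = 99, seed = NULL) {
  stat <- match.arg(stat)
  xa <- cophenetic_matrix(map_to_dendrogram(map_a))
  xb <- cophenetic_matrix(map_to_dendrogram(map_b))
  wanted <- switch(stat, both = c("gk_gamma", "cophenetic"),
                   gk = "gk_gamma", cophenetic = "cophenetic")
  out <- lapply(wanted, function(w) {
    if (n_perm > 0) {
      permutation_test(xa, xb, statistic = w, n_perm = n_perm, seed = seed)
    } else {
      al <- align_common(xa, xb)
      obs <- if (w == "gk_gamma") gk_gamma(al$x, al$y)
             else cophenetic_correlation(al$x, al$y)
      structure(list(statistic = w, observed = obs, p_value = NULL,
                     n_perm = 0, seed = NULL, n_common = al$n_common,
                     n_dropped_x = length(al$dropped_x),
                     n_dropped_y = length(al$dropped_y)),
                class = "comparison_result")
    }
  })
  stats::setNames(out, wanted)
}
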