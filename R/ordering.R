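# Deterministic marker ordering within a linkage group.
#
# The order minimizes the sum of adjacent recombination frequencies (SARF)
# over all leaf orders of the group's single-linkage dendrogram that are
# consistent with the tree (optimal leaf ordering: only internal-node
# orientations may flip, the clustering itself is unchanged; 2^(n-1)
# possible orders, solved by dynamic programming). When several orders share
# the minimal SARF — typical for dense marker sets — the criterion is
# extended to neighborhoods of increasing size l (SARF_l sums all pairwise
# distances at lags 1..l along the order) until a single order, up to
# reversal, survives. A final lexicographic rule makes pathological
# fully-tied instances deterministic as well.

#' Sum of adjacent recombination frequencies (SARF) of an order
#'
#' `SARF_l(s) = sum over k = 1..l, i = 1..n-k of D(a_i, a_(i+k))`: at the
#' base level `l = 1` the sum of distances between adjacent markers; larger
#' neighborhoods add every pair up to `l` positions apart. Lags beyond the
#' order length contribute nothing.
#'
#' @param s character vector of marker ids, the candidate order.
#' @param D symmetric distance (or recombination-frequency) matrix with the
#'   markers of `s` in its dimnames.
#' @param l neighborhood size, a positive integer.
#' @return the SARF_l score (0 for a single-marker order).
#' @export
sarf <- function(s, D, l = 1) {
  if (l < 1) stop("l must be >= 1", call. = FALSE)
  n <- length(s)
  if (n < 2) return(0)
  idx <- match(s, rownames(D))
  if (anyNA(idx)) stop("order contains markers absent from the matrix", call. = FALSE)
  total <- 0
  for (k in seq_len(min(l, n - 1))) {
    i <- seq_len(n - k)
    total <- total + sum(D[cbind(idx[i], idx[i + k])])
  }
  total
}

# Bottom-up DP over the dendrogram: for every internal node and every
# (leftmost leaf a, rightmost leaf b) spanning its two subtrees, the minimal
# within-block SARF_1. Matrices are indexed by leaf position in dend$labels;
# Inf marks infeasible end pairs.
olo_dp <- function(dend, D) {
  n <- length(dend$labels)
  idx <- match(dend$labels, rownames(D))
  Dm <- unclass(D)[idx, idx, drop = FALSE]
  merge <- dend$merge
  leaf_sets <- vector("list", n - 1)
  M <- vector("list", n - 1)
  leaf_M <- function(a) {
    m <- matrix(Inf, n, n); m[a, a] <- 0; m
  }
  child_info <- function(code) {
    if (code < 0) list(leaves = -code, M = leaf_M(-code))
    else list(leaves = leaf_sets[[code]], M = M[[code]])
  }
  for (v in seq_len(n - 1)) {
    cl <- child_info(merge[v, 1])
    cr <- child_info(merge[v, 2])
    L <- cl$leaves; R <- cr$leaves
    leaf_sets[[v]] <- c(L, R)
    Mv <- matrix(Inf, n, n)
    ML <- cl$M[L, L, drop = FALSE]
    MR <- cr$M[R, R, drop = FALSE]
    DLR <- Dm[L, R, drop = FALSE]
    for (ai in seq_along(L)) {
      # T[y] = min_x ML[a,x] + D[x,y]; then Mv[a,b] = min_y T[y] + MR[y,b]
      Tm <- ML[ai, ] + DLR                       # |L| x |R|
      Ty <- suppressWarnings(apply(Tm, 2, min))
      row <- suppressWarnings(apply(Ty + MR, 2, min))
      Mv[L[ai], R] <- row
      Mv[R, L[ai]] <- row                        # reversal symmetry
    }
    M[[v]] <- Mv
  }
  list(M = M, leaf_sets = leaf_sets, merge = merge, labels = dend$labels,
       Dm = Dm, n = n)
}

# Enumerate, in a deterministic depth-first order, all tree-consistent
# orders achieving the DP optimum; stops adding once `cap` orders collected.
olo_enumerate <- function(dp, cap = 10000, eps = 1e-9) {
  n <- dp$n
  if (n == 1) return(list(orders = list(dp$labels), sarf1 = 0, capped = FALSE))
  root <- n - 1
  Mroot <- dp$M[[root]]
  best <- min(Mroot)
  state <- new.env()
  state$capped <- FALSE
  child_of <- function(code) {
    if (code < 0) list(leaves = -code, M = NULL, code = code)
    else list(leaves = dp$leaf_sets[[code]], M = dp$M[[code]], code = code)
  }
  enum <- function(code, a, b, budget) {
    if (code < 0) return(list(list(-code)))
    cl <- child_of(dp$merge[code, 1])
    cr <- child_of(dp$merge[code, 2])
    if (a %in% cr$leaves) { tmp <- cl; cl <- cr; cr <- tmp }
    getM <- function(ch, i, j) {
      if (ch$code < 0) { if (i == ch$leaves && j == ch$leaves) 0 else Inf }
      else ch$M[i, j]
    }
    target <- dp$M[[code]][a, b]
    out <- list()
    for (x in cl$leaves) {
      mlx <- getM(cl, a, x)
      if (!is.finite(mlx)) next
      for (y in cr$leaves) {
        mry <- getM(cr, y, b)
        if (!is.finite(mry)) next
        if (abs(mlx + dp$Dm[x, y] + mry - target) <= eps) {
          lefts <- enum(cl$code, a, x, budget)
          for (lo in lefts) {
            rights <- enum(cr$code, y, b, budget)
            for (ro in rights) {
              if (length(out) >= budget) { state$capped <- TRUE; return(out) }
              out[[length(out) + 1]] <- c(lo, ro)
            }
          }
        }
      }
    }
    out
  }
  orders <- list()
  ends <- which(Mroot - best <= eps & is.finite(Mroot), arr.ind = TRUE)
  ends <- ends[order(ends[, 1], ends[, 2]), , drop = FALSE]
  for (e in seq_len(nrow(ends))) {
    if (length(orders) >= cap) { state$capped <- TRUE; break }
    part <- enum(root, ends[e, 1], ends[e, 2], cap - length(orders))
    orders <- c(orders, part)
  }
  orders <- lapply(orders, function(o) dp$labels[unlist(o)])
  list(orders = orders, sarf1 = best, capped = state$capped)
}

#' Optimal leaf ordering of a linkage-group dendrogram
#'
#' Finds, among the `2^(n-1)` leaf orders consistent with the group's
#' single-linkage dendrogram, every order achieving the minimal SARF_1
#' (sum of adjacent recombination frequencies). Orders that are reversals of
#' one another are collapsed to one canonical representative.
#'
#' @param dend `hclust` object over the group's markers
#'   (see [rf_dendrogram()]).
#' @param theta symmetric distance matrix with those markers in its dimnames.
#' @param cap safety cap on the number of enumerated optimal orders in
#'   heavily tied instances; enumeration order is deterministic, so the
#'   retained set is too.
#' @return list with `orders` (list of marker-id vectors, all reaching the
#'   minimum), `sarf1` (the minimal score) and `capped` (logical).
#' @export
olo_order <- function(dend, theta, cap = 10000) {
  stopifnot(inherits(dend, "hclust"))
  dp <- olo_dp(dend, theta)
  res <- olo_enumerate(dp, cap = cap)
  canon <- lapply(res$orders, canonical_reversal)
  keys <- vapply(canon, paste, character(1), collapse = "\r")
  res$orders <- canon[!duplicated(keys)]
  res
}

canonical_reversal <- function(s) {
  r <- rev(s)
  if (lex_less(r, s)) r else s
}

# strict elementwise lexicographic comparison of two equal-length id vectors
lex_less <- function(a, b) {
  d <- which(a != b)
  if (length(d) == 0) return(FALSE)
  a[d[1]] < b[d[1]]
}

#' Resolve SARF ties by extending the neighborhood
#'
#' Given the set of orders sharing the minimal SARF_1, the neighborhood size
#' is increased step by step (`l = 2, 3, ...`), discarding orders that are
#' no longer minimal at each level, until a single order (up to reversal)
#' remains or `l = n - 1` is reached. A still-tied set — constructible in
#' degenerate instances, e.g. all pairwise distances equal — is resolved to
#' the lexicographically smallest order so that the result is always
#' deterministic.
#'
#' @param candidates list of marker-id vectors with equal SARF_1
#'   (as produced by [olo_order()]).
#' @param theta symmetric distance matrix.
#' @param eps numeric tolerance for score equality.
#' @return a single marker-id vector.
#' @export
tie_break_order <- function(candidates, theta, eps = 1e-9) {
  if (length(candidates) == 0) stop("empty candidate set", call. = FALSE)
  cands <- lapply(candidates, canonical_reversal)
  keys <- vapply(cands, paste, character(1), collapse = "\r")
  cands <- cands[!duplicated(keys)]
  n <- length(cands[[1]])
  l <- 1
  while (length(cands) > 1 && l < n - 1) {
    l <- l + 1
    scores <- vapply(cands, sarf, numeric(1), D = theta, l = l)
    cands <- cands[scores - min(scores) <= eps]
  }
  if (length(cands) == 1) return(cands[[1]])
  best <- cands[[1]]
  for (s in cands[-1]) if (lex_less(s, best)) best <- s
  best
}

#' Canonical orientation of a resolved order
#'
#' SARF is invariant under reversal, so a group order has a free
#' orientation; for reproducible output the endpoint marker with the smaller
#' id is placed first.
#'
#' @param s marker-id vector.
#' @return `s` or its reversal.
#' @export
orient_group <- function(s) {
  n <- length(s)
  if (n > 1 && s[n] < s[1]) rev(s) else s
}

#' Order the markers of one linkage group
#'
#' Convenience pipeline: single-linkage dendrogram on the group's
#' recombination frequencies, optimal leaf ordering, SARF_l tie-breaking and
#' orientation canonicalization. Identical inputs (in any marker
#' permutation) give the identical final order.
#'
#' @param theta symmetric distance matrix restricted to the group's markers.
#' @return ordered character vector of marker ids.
#' @export
order_markers <- function(theta) {
  ids <- rownames(theta)
  if (length(ids) <= 2) return(orient_group(sort(ids)))
  sub <- unclass(theta)[order(ids), order(ids), drop = FALSE]
  dend <- rf_dendrogram(sub)
  cand <- olo_order(dend, sub)
  orient_group(tie_break_order(cand$orders, sub))
}

#' Exhaustive SARF minimization (test oracle)
#'
#' Searches all `n!/2` reversal-distinct permutations for the global SARF_l
#' minimum, without the dendrogram constraint. Only feasible for small
#' groups; refuses `n > 9`.
#'
#' @param D symmetric distance matrix.
#' @param l neighborhood size.
#' @return list with `order` (marker ids) and `score`.
#' @export
brute_force_min_sarf <- function(D, l = 1) {
  ids <- rownames(D)
  n <- length(ids)
  if (n > 9) stop("brute force limited to n <= 9 markers", call. = FALSE)
  if (n < 2) return(list(order = ids, score = 0))
  perms <- all_permutations(n)
  # reversal dedup: keep permutations with first element < last
  perms <- perms[perms[, 1] < perms[, n], , drop = FALSE]
  best <- Inf; best_p <- NULL
  for (r in seq_len(nrow(perms))) {
    s <- ids[perms[r, ]]
    sc <- sarf(s, D, l)
    if (sc < best - 1e-12) { best <- sc; best_p <- s }
  }
  list(order = best_p, score = best)
}

all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

#' Enumerate all tree-consistent leaf orders (test oracle)
#'
#' Generates every leaf order reachable by flipping internal-node
#' orientations of a dendrogram — the `2^(n-1)` orders optimal leaf
#' ordering searches over.
#'
#' @param dend `hclust` object.
#' @return list of character vectors of leaf ids.
#' @export
enumerate_tree_orders <- function(dend) {
  stopifnot(inherits(dend, "hclust"))
  n <- length(dend$labels)
  expand <- function(code) {
    if (code < 0) return(list(-code))
    l <- expand(dend$merge[code, 1])
    r <- expand(dend$merge[code, 2])
    out <- list()
    for (a in l) for (b in r) {
      out[[length(out) + 1]] <- c(a, b)
      out[[length(out) + 1]] <- c(b, a)
    }
    out
  }
  lapply(expand(n - 1), function(o) dend$labels[o])
}
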