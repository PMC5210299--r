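# Heuristic pairwise recombination-frequency estimation from dosages.
#
# For two markers m, n with dosages m_i, n_i at ploidy p, the minimum number
# of recombination events per individual is |m_i - n_i| under one allelic
# configuration and |m_i - (p - n_i)| under the flipped one. Summing each
# over individuals gives A and B; theta-hat = min(A, B) / (A + B) never
# exceeds 0.5. The heuristic always assumes the lowest possible number of
# recombinations (no double crossovers, no double reduction), which
# overestimates linkage for distant markers but is accurate for close ones.

#' Recombination-event sums for a marker pair
#'
#' Computes `A = sum(|m_i - n_i|)` and `B = sum(|m_i - p + n_i|)` over the
#' individuals where both dosages are observed — the minimum recombination
#' counts under the two possible allelic configurations (the parental origin
#' of the alleles is unknown).
#'
#' @param m,n integer dosage vectors of equal length, values in `0..ploidy`
#'   or `NA`.
#' @param ploidy even positive integer.
#' @return list with `A`, `B` (nonnegative event sums) and `n_used`, the
#'   number of pairwise-complete individuals.
#' @examples
#' pair_counts(4, 3, 4)  # A = 1, B = 3
#' @export
pair_counts <- function(m, n, ploidy) {
  check_ploidy(ploidy)
  if (length(m) != length(n))
    stop("dosage vectors differ in length", call. = FALSE)
  ok <- !is.na(m) & !is.na(n)
  if (!any(ok))
    stop("no individuals with both genotypes observed for this marker pair",
         call. = FALSE)
  m <- m[ok]; n <- n[ok]
  if (any(m < 0 | m > ploidy | n < 0 | n > ploidy))
    stop(sprintf("dosage outside [0, %d]", ploidy), call. = FALSE)
  list(A = as.integer(sum(abs(m - n))), B = as.integer(sum(abs(m - ploidy + n))),
       n_used = as.integer(sum(ok)))
}

#' Estimate the recombination frequency between two markers
#'
#' `theta-hat = min(A, B) / (A + B)` with `A`, `B` from [pair_counts()].
#' The result is always in `[0, 0.5]`. When `A + B = 0` (both markers
#' constant, identical or complementary, across the observed individuals)
#' there is no recombination evidence and 0 is returned.
#'
#' @inheritParams pair_counts
#' @return estimated recombination frequency in `[0, 0.5]`.
#' @examples
#' estimate_theta(4, 3, 4)  # 0.25
#' @export
estimate_theta <- function(m, n, ploidy) {
  cnt <- pair_counts(m, n, ploidy)
  if (cnt$A + cnt$B == 0) return(0)
  min(cnt$A, cnt$B) / (cnt$A + cnt$B)
}

#' Pairwise recombination-frequency matrix
#'
#' Applies the minimum-recombination estimator to every marker pair of a
#' genotype matrix. Sums run over pairwise-complete individuals, so missing
#' genotypes are tolerated without imputation.
#'
#' @param g a [genotype_matrix] with at least two markers.
#' @return an `rf_matrix`: symmetric numeric matrix of estimated
#'   recombination frequencies with zero diagonal, marker ids as dimnames
#'   and the ploidy as attribute `ploidy`.
#' @export
recombination_matrix <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  d <- g$dosages
  p <- g$ploidy
  n_mark <- nrow(d)
  if (n_mark < 2) stop("n >= 2 markers required", call. = FALSE)
  obs <- !is.na(d)
  d0 <- d; d0[!obs] <- 0L
  # A[i,j] = sum_k |d[i,k] - d[j,k]| over pairwise-complete k, and likewise
  # B with d[j,] flipped to p - d[j,]. Computed row-against-matrix to keep
  # memory at O(n^2) without an n^2 x individuals intermediate.
  theta <- matrix(0, n_mark, n_mark, dimnames = list(rownames(d), rownames(d)))
  no_overlap <- NULL
  for (i in seq_len(n_mark - 1)) {
    js <- (i + 1):n_mark
    mi <- d0[i, ]; oi <- obs[i, ]
    both <- obs[js, , drop = FALSE] & matrix(oi, length(js), ncol(d), byrow = TRUE)
    dj <- d0[js, , drop = FALSE]
    Ai <- rowSums(abs(sweep(dj, 2, mi, function(a, b) b - a)) * both)
    Bi <- rowSums(abs(sweep(dj, 2, mi, function(a, b) b - p + a)) * both)
    n_used <- rowSums(both)
    if (any(n_used == 0))
      no_overlap <- rbind(no_overlap,
                          cbind(rownames(d)[i], rownames(d)[js][n_used == 0]))
    tot <- Ai + Bi
    th <- ifelse(tot == 0, 0, pmin(Ai, Bi) / tot)
    theta[i, js] <- th
    theta[js, i] <- th
  }
  if (!is.null(no_overlap))
    stop("marker pair(s) with no overlapping individuals: ",
         paste(apply(no_overlap, 1, paste, collapse = "/"), collapse = ", "),
         call. = FALSE)
  structure(theta, class = c("rf_matrix", "matrix"), ploidy = p)
}

#' Exhaustive bound check for the recombination estimator
#'
#' Enumerates, for each ploidy, every achievable pair of event sums
#' `(A, B)` over 1 to `n_max` individuals — each individual contributes one
#' of the `(p+1)^2` pairs `(|m - n|, |m - p + n|)` with dosages `m, n` in
#' `0..p`, and the n-individual sums are the n-fold sumset of those
#' contributions — and returns the maximum of `min(A, B) / (A + B)` over
#' all of them. This covers every dosage-vector pair of those lengths
#' exactly, without materializing the `(p+1)^(2n)` vectors.
#'
#' @param ploidies even integers to check.
#' @param n_max maximum number of individuals.
#' @return the maximum estimated recombination frequency encountered
#'   (0.5 when attained, as the theory demands it never be exceeded).
#' @export
theta_bound_enumeration <- function(ploidies = c(2, 4, 6), n_max = 5) {
  worst <- 0
  for (p in ploidies) {
    check_ploidy(p)
    grid <- expand.grid(m = 0:p, n = 0:p)
    contrib <- unique(data.frame(a = abs(grid$m - grid$n),
                                 b = abs(grid$m - p + grid$n)))
    sums <- contrib
    for (k in seq_len(n_max)) {
      if (k > 1) {
        ex <- expand.grid(i = seq_len(nrow(sums)), j = seq_len(nrow(contrib)))
        sums <- unique(data.frame(a = sums$a[ex$i] + contrib$a[ex$j],
                                  b = sums$b[ex$i] + contrib$b[ex$j]))
      }
      tot <- sums$a + sums$b
      th <- ifelse(tot == 0, 0, pmin(sums$a, sums$b) / tot)
      worst <- max(worst, th)
    }
  }
  worst
}

#' Validate a recombination-frequency matrix
#'
#' @param theta numeric square matrix.
#' @return the matrix, invisibly, after checking symmetry, zero diagonal and
#'   range `[0, 0.5]`.
#' @keywords internal
validate_rf_matrix <- function(theta) {
  if (!is.matrix(theta) || nrow(theta) != ncol(theta))
    stop("recombination matrix must be square", call. = FALSE)
  if (any(abs(theta - t(theta)) > 1e-12))
    stop("recombination matrix must be symmetric", call. = FALSE)
  if (any(diag(theta) != 0))
    stop("recombination matrix diagonal must be zero", call. = FALSE)
  if (any(theta < 0 | theta > 0.5))
    stop("recombination frequencies must lie in [0, 0.5]", call. = FALSE)
  invisible(theta)
}

#' Write a recombination-frequency matrix as square TSV
#'
#' @param theta matrix from [recombination_matrix()].
#' @param path output file path.
#' @export
write_rf_matrix <- function(theta, path) {
  utils::write.table(cbind(marker = rownames(theta), as.data.frame(theta)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
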