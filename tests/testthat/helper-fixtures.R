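# Shared fixtures, built in code.

# 6-marker pairwise distance matrix with two documented ordering
# ambiguities: C/D are swappable at SARF_1, and B fits at either end.
ambiguous_six <- function() {
  ids <- LETTERS[1:6]
  D <- matrix(0, 6, 6, dimnames = list(ids, ids))
  low <- list(
    B = c(A = 2),
    C = c(A = 4, B = 4),
    D = c(A = 6, B = 4, C = 2),
    E = c(A = 8, B = 7, C = 4, D = 4),
    F = c(A = 12, B = 10, C = 7, D = 5, E = 3))
  for (r in names(low)) for (cn in names(low[[r]])) {
    D[r, cn] <- low[[r]][cn]
    D[cn, r] <- low[[r]][cn]
  }
  D
}

# small two-block recombination matrix: markers 1,2 and 3,4 tightly linked
# within blocks, near-unlinked across
two_block_theta <- function() {
  ids <- paste0("m", 1:4)
  th <- matrix(0.45, 4, 4, dimnames = list(ids, ids))
  diag(th) <- 0
  th["m1", "m2"] <- th["m2", "m1"] <- 0.05
  th["m3", "m4"] <- th["m4", "m3"] <- 0.08
  th
}

random_theta <- function(n, seed) {
  set.seed(seed)
  ids <- sprintf("r%02d", seq_len(n))
  v <- matrix(stats::runif(n * n, 0, 0.5), n, n)
  th <- (v + t(v)) / 2
  diag(th) <- 0
  dimnames(th) <- list(ids, ids)
  th
}

toy_map <- function() {
  linkage_map(list(
    LG1 = data.frame(marker = c("a", "b", "c", "d"), position = c(0, 3, 7, 15)),
    LG2 = data.frame(marker = c("e", "f", "g"), position = c(0, 5, 9))))
}

hexaploid_sim <- function(seed, n_offspring = 100, markers_per_chrom = 15) {
  truth <- random_true_map(c(75, 110, 85, 100, 110, 95, 80),
                           markers_per_chrom, seed = seed)
  pop <- simulate_population(truth, n_offspring, 6, seed = seed + 1)
  list(truth = truth, pop = pop)
}

true_assignment <- function(truth) {
  unlist(lapply(truth$chromosomes, function(ch)
    stats::setNames(rep(ch$id, nrow(ch$markers)), ch$markers$marker)))
}

# TRUE iff the grouping is exactly the chromosome partition
is_exact_partition <- function(grouping, truth) {
  ta <- true_assignment(truth)
  if (length(grouping$filtered_out) > 0) return(FALSE)
  tab <- table(grouping$assignment, ta[names(grouping$assignment)])
  all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1)
}

# Minimum per-group absolute Kendall rank correlation between estimated and
# true marker orders (1 = exact up to reversal). With ~100 offspring, markers
# separated by well under a centiMorgan yield so few informative recombinants
# that their local order is undetermined; a single adjacent transposition in a
# 15-marker group still gives |tau| = 1 - 2/105 ~ 0.98, so near-exact recovery
# shows up as a minimum tau close to 1 while any real ordering failure
# (misplaced distant marker, wrong group) drops it far below.
# A group whose markers span more than one true chromosome (chimeric) gives
# NA, which propagates to the returned minimum.
order_tau <- function(map, truth) {
  taus <- vapply(map$groups, function(gr) {
    est <- gr$marker
    ch <- Find(function(ch) all(est %in% ch$markers$marker), truth$chromosomes)
    if (is.null(ch)) return(NA_real_)
    pos <- ch$markers$position[match(est, ch$markers$marker)]
    abs(stats::cor(pos, seq_along(est), method = "kendall"))
  }, numeric(1))
  if (anyNA(taus)) return(NA_real_)
  min(taus)
}
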