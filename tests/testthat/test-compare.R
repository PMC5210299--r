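test_that("map dendrograms encode order, spacing and the root line", {
  map <- toy_map()
  dend <- map_to_dendrogram(map)
  expect_identical(dend$labels[dend$order],
                   c("a", "b", "c", "d", "e", "f", "g"))
  coph <- cophenetic_matrix(dend)
  # within-group cophenetic distance = position of the later marker
  expect_equal(coph["a", "b"], 3)
  expect_equal(coph["a", "d"], 15)
  expect_equal(coph["b", "c"], 7)
  expect_equal(coph["e", "g"], 9)
  # root line sits 0.2 above the highest within-group connection
  expect_equal(coph["a", "e"], 1.2 * 15)
  expect_equal(max(dend$height), 18)
  # two markers at distance d: one merge at d, root rule degenerate (1 group)
  m2 <- linkage_map(list(LG1 = data.frame(marker = c("p", "q"),
                                          position = c(0, 8))))
  expect_equal(map_to_dendrogram(m2)$height, 8)
  expect_error(map_to_dendrogram(linkage_map(list(LG1 = data.frame(
    marker = "p", position = 0)))), "at least two")
})

test_that("cophenetic matrices are symmetric, zero-diagonal and ultrametric", {
  coph <- cophenetic_matrix(map_to_dendrogram(toy_map()))
  expect_equal(unname(diag(coph)), rep(0, 7))
  expect_equal(coph, t(coph))
  n <- nrow(coph)
  for (i in 1:n) for (j in 1:n) for (k in 1:n)
    expect_lte(coph[i, k], max(coph[i, j], coph[j, k]) + 1e-12)
})

test_that("gamma is 1 on identical and -1 on rank-reversed matrices", {
  x <- cophenetic_matrix(map_to_dendrogram(toy_map()))
  expect_equal(gk_gamma(x, x), 1)
  y <- max(x) + 1 - x
  diag(y) <- 0
  expect_equal(gk_gamma(x, y), -1)
  # all-tied input is undefined
  z <- matrix(1, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  diag(z) <- 0
  expect_error(gk_gamma(z, z), "undefined")
})

test_that("fast concordance counting agrees with the quadratic oracle", {
  set.seed(31)
  for (i in 1:15) {
    n <- sample(8:14, 1)
    x <- random_theta(n, seed = 500 + i)
    y <- random_theta(n, seed = 600 + i)
    # inject ties
    x[x < 0.1] <- 0.1
    y[y > 0.4] <- 0.4
    xv <- x[upper.tri(x)]; yv <- y[upper.tri(y)]
    expect_equal(dosagemap:::gamma_vec(xv, yv),
                 dosagemap:::gamma_naive(xv, yv))
  }
})

test_that("label-permuted gamma averages to zero under the null", {
  x <- cophenetic_matrix(map_to_dendrogram(toy_map()))
  set.seed(41)
  vals <- replicate(100, {
    p <- sample(nrow(x))
    y <- x[p, p]
    dimnames(y) <- dimnames(x)
    gk_gamma(x, y)
  })
  expect_lt(abs(mean(vals)), 0.15)
})

test_that("cophenetic correlation is affine-invariant and bounded", {
  x <- cophenetic_matrix(map_to_dendrogram(toy_map()))
  expect_equal(cophenetic_correlation(x, x), 1)
  expect_equal(cophenetic_correlation(x, 3 * x + 2), 1)
  set.seed(51)
  p <- sample(nrow(x)); y <- x[p, p]; dimnames(y) <- dimnames(x)
  r <- cophenetic_correlation(x, y)
  expect_true(r >= -1 && r <= 1)
  z <- matrix(2, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(z) <- 0
  expect_error(cophenetic_correlation(z, z), "zero variance")
})

test_that("self-comparison with 99 permutations gives the add-one floor 0.01", {
  x <- cophenetic_matrix(map_to_dendrogram(toy_map()))
  for (stat in c("gk_gamma", "cophenetic")) {
    pt <- permutation_test(x, x, statistic = stat, n_perm = 99, seed = 7)
    expect_equal(pt$p_value, 0.01)
    expect_equal(pt$observed, 1)
  }
  expect_error(permutation_test(x, x, "cophenetic", n_perm = 99), "seed")
})

test_that("permutation p-values respect the Monte-Carlo floor and reproduce", {
  x <- cophenetic_matrix(map_to_dendrogram(toy_map()))
  set.seed(61)
  p <- sample(nrow(x)); y <- x[p, p]; dimnames(y) <- dimnames(x)
  a <- permutation_test(x, y, "gk_gamma", n_perm = 49, seed = 99)
  b <- permutation_test(x, y, "gk_gamma", n_perm = 49, seed = 99)
  expect_identical(a$p_value, b$p_value)
  expect_gte(a$p_value, 1 / 50)
  expect_lte(a$p_value, 1)
})

test_that("the permutation test agrees with an independent Mantel oracle", {
  skip_if_not_installed("vegan")
  sim <- hexaploid_sim(701, n_offspring = 60, markers_per_chrom = 5)
  tm <- true_map_to_linkage_map(sim$truth)
  map <- run_map(sim$pop$genotypes, threshold = 0.35, quiet = TRUE)
  x <- cophenetic_matrix(map_to_dendrogram(tm))
  y <- cophenetic_matrix(map_to_dendrogram(map))
  y <- y[rownames(x), rownames(x)]
  ours <- permutation_test(x, y, "cophenetic", n_perm = 199, seed = 3)
  mv <- vegan::mantel(stats::as.dist(x), stats::as.dist(y),
                      permutations = 199)
  expect_equal(ours$observed, unname(mv$statistic), tolerance = 1e-10)
  expect_lt(abs(ours$p_value - mv$signif), 0.05)
})

test_that("newick export round-trips the cophenetic structure", {
  dend <- map_to_dendrogram(toy_map())
  path <- withr::local_tempfile(fileext = ".nwk")
  to_newick(dend, path)
  back <- read_dendrogram_newick(path)
  expect_setequal(rownames(back$cophenetic), dend$labels)
  coph <- cophenetic_matrix(dend)
  ids <- rownames(coph)
  expect_equal(back$cophenetic[ids, ids], coph[ids, ids], tolerance = 1e-8)
  # 2-leaf tree: both branches get half the merge height, so the
  # leaf-to-leaf path equals the height
  m2 <- linkage_map(list(LG1 = data.frame(marker = c("A", "B"),
                                          position = c(0, 4))))
  txt <- to_newick(map_to_dendrogram(m2))
  expect_match(txt, "^\\(.*A:2.*B:2.*\\);$|^\\(.*B:2.*A:2.*\\);$")
})

test_that("tanglegram pairing reports positions and dropped leaves", {
  d1 <- map_to_dendrogram(toy_map())
  id <- tanglegram_pairs(d1, d1)
  expect_identical(id$pos1, id$pos2)
  # reverse one group in the second map
  m2 <- linkage_map(list(
    LG1 = data.frame(marker = c("d", "c", "b", "a"), position = c(0, 8, 12, 15)),
    LG2 = data.frame(marker = c("e", "f", "g"), position = c(0, 5, 9))))
  d2 <- map_to_dendrogram(m2)
  tp <- tanglegram_pairs(d1, d2)
  expect_identical(tp$pos2[match(c("a", "b", "c", "d"), tp$marker)],
                   c(4L, 3L, 2L, 1L))
  # dropped leaves counted
  m3 <- linkage_map(list(LG1 = data.frame(marker = c("a", "b", "z"),
                                          position = c(0, 3, 6))))
  tp2 <- tanglegram_pairs(d1, map_to_dendrogram(m3))
  expect_identical(attr(tp2, "n_dropped_1"), 5L)
  expect_identical(attr(tp2, "n_dropped_2"), 1L)
})
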