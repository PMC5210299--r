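test_that("true maps are reproducible, bounded and sorted", {
  lens <- c(75, 110, 85, 100, 110, 95, 80)
  tm1 <- random_true_map(lens, 10, seed = 1)
  tm2 <- random_true_map(lens, 10, seed = 1)
  expect_identical(tm1, tm2)
  expect_length(tm1$chromosomes, 7L)
  for (i in seq_along(lens)) {
    ch <- tm1$chromosomes[[i]]
    expect_equal(ch$length, lens[i])
    expect_true(all(ch$markers$position >= 0 & ch$markers$position <= lens[i]))
    expect_false(is.unsorted(ch$markers$position))
  }
  expect_error(random_true_map(lens, 10), "seed")
})

test_that("simulated dosages are valid and seed-deterministic", {
  truth <- random_true_map(c(60, 80), 6, seed = 2)
  p1 <- simulate_population(truth, 40, 6, seed = 3)
  p2 <- simulate_population(truth, 40, 6, seed = 3)
  expect_identical(p1$genotypes$dosages, p2$genotypes$dosages)
  expect_true(all(p1$genotypes$dosages >= 0 & p1$genotypes$dosages <= 6))
  expect_identical(dim(p1$genotypes), c(12L, 40L))
  expect_error(simulate_population(truth, 40, 3, seed = 1), "even")
})

test_that("co-located markers show zero recombination", {
  truth <- structure(list(chromosomes = list(list(
    id = "c1", length = 50,
    markers = data.frame(marker = c("m1", "m2"), position = c(20, 20))))),
    class = "true_map")
  pop <- simulate_population(truth, 200, 4, seed = 5)
  expect_equal(estimate_theta(pop$genotypes$dosages[1, ],
                              pop$genotypes$dosages[2, ], 4), 0)
})

test_that("diploid meiosis matches the Haldane recombination fraction", {
  # gamete-level check: markers 10 cM apart recombine with frequency
  # (1 - exp(-0.2)) / 2 under the no-interference crossover model
  set.seed(8)
  f1 <- rbind(c(1L, 1L), c(0L, 0L))
  n <- 10000
  rec <- sum(replicate(n, {
    gm <- dosagemap:::gamete_chromosome(f1, c(0, 10), 10)
    gm[1, 1] != gm[1, 2]
  }))
  expected <- (1 - exp(-0.2)) / 2
  se <- sqrt(expected * (1 - expected) / n)
  expect_lt(abs(rec / n - expected), 3 * se)
})

test_that("theta estimates grow with distance and stay below 0.5", {
  truth <- structure(list(chromosomes = list(list(
    id = "c1", length = 100,
    markers = data.frame(marker = paste0("m", 1:5),
                         position = c(0, 5, 20, 50, 100))))),
    class = "true_map")
  pop <- simulate_population(truth, 400, 2, seed = 9)
  th <- recombination_matrix(pop$genotypes)
  row1 <- unclass(th)[1, -1]
  expect_false(is.unsorted(row1))
  expect_true(all(th <= 0.5))
})

test_that("perturbation changes the requested cell counts by one unit", {
  truth <- random_true_map(c(90, 90), 25, seed = 11)
  pop <- simulate_population(truth, 20, 6, seed = 12)
  g0 <- pop$genotypes
  expect_identical(perturb_genotypes(g0, 0, 0, seed = 13)$dosages, g0$dosages)
  gp <- perturb_genotypes(g0, 0.3, 0.1, seed = 14)
  n_cells <- length(g0$dosages)          # 1000 cells, none missing
  changed <- which(!is.na(gp$dosages) & gp$dosages != g0$dosages)
  expect_length(changed, round(0.3 * n_cells))
  expect_true(all(abs(gp$dosages[changed] - g0$dosages[changed]) == 1))
  expect_identical(sum(is.na(gp$dosages)), as.integer(round(0.1 * n_cells)))
  expect_error(perturb_genotypes(g0, 0.6, 0, seed = 1), "\\[0, 0.5\\]")
})

test_that("marker shuffling preserves rows and the downstream grouping", {
  sim <- hexaploid_sim(801, n_offspring = 60, markers_per_chrom = 6)
  g <- sim$pop$genotypes
  gs <- shuffle_markers(g, seed = 802)
  expect_identical(shuffle_markers(g, seed = 802)$dosages, gs$dosages)
  expect_setequal(rownames(gs$dosages), rownames(g$dosages))
  expect_identical(gs$dosages[rownames(g$dosages), ], g$dosages)
  grp_a <- cut_groups(rf_dendrogram(recombination_matrix(g)), threshold = 0.35)
  grp_b <- cut_groups(rf_dendrogram(recombination_matrix(gs)), threshold = 0.35)
  common <- names(grp_a$assignment)
  tab <- table(grp_a$assignment[common], grp_b$assignment[common])
  expect_true(all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1))
})

test_that("error-free hexaploid groups are chromosome-pure and well ordered", {
  sim <- hexaploid_sim(901, n_offspring = 100, markers_per_chrom = 15)
  g <- shuffle_markers(sim$pop$genotypes, seed = 902)
  map <- run_map(g, threshold = 0.35, quiet = TRUE)
  # every linkage group draws from a single chromosome; a chromosome may
  # split in two when an internal gap exceeds the threshold's resolution,
  # so the group count can exceed, but never undershoot, the truth
  expect_gte(length(map$groups), 7L)
  # within every group the order matches the true positions up to local
  # swaps of markers too close to resolve with 100 offspring; a chimeric
  # group would make order_tau NA and fail here
  expect_gte(order_tau(map, sim$truth), 0.9)
})

test_that("diploid recovery does not degrade as the population grows", {
  coph_by_n <- vapply(c(50, 200), function(n_off) {
    vals <- vapply(1:3, function(rep) {
      truth <- random_true_map(c(80, 100), 10, seed = 950 + rep)
      pop <- simulate_population(truth, n_off, 2, seed = 960 + rep + n_off)
      map <- run_map(pop$genotypes, threshold = 0.35, quiet = TRUE)
      cophenetic_correlation(
        cophenetic_matrix(map_to_dendrogram(true_map_to_linkage_map(truth))),
        cophenetic_matrix(map_to_dendrogram(map)))
    }, numeric(1))
    mean(vals)
  }, numeric(1))
  expect_gte(coph_by_n[2], coph_by_n[1] - 0.02)
})
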