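# Polyploid F2 mapping-population simulator.
#
# The cross is founded from two fully homozygous, opposite parents (dosage p
# and dosage 0 at every marker), so the F1 is maximally informative: p/2
# homologues carry the reference allele and p/2 the alternate at every
# locus. Each F2 offspring is a selfing of the F1. One meiosis pairs the p
# homologues of a chromosome into p/2 random bivalents; the chromatid a
# bivalent transmits is a crossover mosaic of its two homologues, with
# switch points drawn as a Poisson process of rate 1 per Morgan (crossover
# count ~ Poisson(length in Morgans), positions uniform, no interference —
# the Haldane model, so simulated distances are directly comparable to
# Haldane-spaced estimates). Quadrivalent pairing, double reduction and
# preferential pairing are deliberately not modelled: the recombination
# heuristic ignores them by construction.

#' Random multi-chromosome true map
#'
#' Marker positions are drawn i.i.d. uniform on each chromosome and sorted;
#' deterministic given the seed.
#'
#' @param lengths numeric vector of chromosome lengths in cM.
#' @param markers_per_chrom integer vector (recycled) of marker counts.
#' @param seed mandatory integer seed.
#' @param prefix marker-id prefix, default `"M"`.
#' @return a `true_map`: list of chromosomes, each with `id`, `length`, and
#'   a data.frame `markers` (`marker`, `position` in cM, sorted).
#' @export
random_true_map <- function(lengths, markers_per_chrom, seed, prefix = "M") {
  if (missing(seed) || is.null(seed)) stop("a seed is required", call. = FALSE)
  if (any(lengths <= 0) || any(markers_per_chrom < 1))
    stop("lengths and marker counts must be positive", call. = FALSE)
  set.seed(seed)
  counts <- rep_len(markers_per_chrom, length(lengths))
  next_id <- 0L
  chroms <- lapply(seq_along(lengths), function(ci) {
    pos <- sort(stats::runif(counts[ci], 0, lengths[ci]))
    ids <- sprintf("%s%03d", prefix, next_id + seq_along(pos))
    next_id <<- next_id + counts[ci]
    list(id = paste0("chr", ci), length = lengths[ci],
         markers = data.frame(marker = ids, position = pos,
                              stringsAsFactors = FALSE))
  })
  structure(list(chromosomes = chroms), class = "true_map")
}

#' @export
print.true_map <- function(x, ...) {
  for (ch in x$chromosomes)
    cat(sprintf("%s: %d markers, %.0f cM\n", ch$id, nrow(ch$markers),
                ch$length))
  invisible(x)
}

#' True map as a linkage map
#'
#' Re-expresses the simulated truth in the [linkage_map] container (per
#' chromosome, positions shifted to start at 0) so it can be transformed
#' into a dendrogram and compared against an estimated map.
#'
#' @param truth a `true_map`.
#' @return a [linkage_map].
#' @export
true_map_to_linkage_map <- function(truth) {
  stopifnot(inherits(truth, "true_map"))
  groups <- lapply(truth$chromosomes, function(ch) {
    data.frame(marker = ch$markers$marker,
               position = ch$markers$position - ch$markers$position[1],
               stringsAsFactors = FALSE)
  })
  names(groups) <- vapply(truth$chromosomes, `[[`, character(1), "id")
  linkage_map(groups)
}

# gamete from an F1 cell for one chromosome: p/2 transmitted chromatids,
# each a crossover mosaic of one random bivalent's two homologues.
# homolog_alleles: p x n_markers 0/1 matrix (rows = homologues).
gamete_chromosome <- function(homolog_alleles, pos_cM, len_cM) {
  p <- nrow(homolog_alleles)
  pairing <- matrix(sample.int(p), ncol = 2, byrow = TRUE)
  out <- matrix(0L, p / 2, ncol(homolog_alleles))
  for (b in seq_len(p / 2)) {
    h1 <- homolog_alleles[pairing[b, 1], ]
    h2 <- homolog_alleles[pairing[b, 2], ]
    n_x <- stats::rpois(1, len_cM / 100)
    cur <- sample(2L, 1)
    if (n_x == 0) {
      out[b, ] <- if (cur == 1) h1 else h2
    } else {
      xp <- sort(stats::runif(n_x, 0, len_cM))
      flips <- findInterval(pos_cM, xp) %% 2
      take1 <- (flips == 0) == (cur == 1)
      out[b, ] <- ifelse(take1, h1, h2)
    }
  }
  out
}

#' Simulate an F2 mapping population
#'
#' @param truth a `true_map` from [random_true_map()].
#' @param n_offspring number of F2 individuals (>= 1).
#' @param ploidy even positive integer (2 = diploid, 6 = hexaploid, ...).
#' @param seed mandatory integer seed.
#' @return a `simulated_population`: list with `genotypes`
#'   (a [genotype_matrix], markers in randomized storage order equal to the
#'   truth order here; see [shuffle_markers()]), `truth`, `ploidy`, `seed`.
#' @export
simulate_population <- function(truth, n_offspring, ploidy, seed) {
  stopifnot(inherits(truth, "true_map"))
  check_ploidy(ploidy)
  if (missing(seed) || is.null(seed)) stop("a seed is required", call. = FALSE)
  if (n_offspring < 1) stop("n_offspring must be >= 1", call. = FALSE)
  set.seed(seed)
  p <- as.integer(ploidy)
  ind_ids <- sprintf("F2_%03d", seq_len(n_offspring))
  per_chrom <- lapply(truth$chromosomes, function(ch) {
    n_m <- nrow(ch$markers)
    # F1 homologues: p/2 from each parent; parent 1 carries the reference
    # allele everywhere, parent 2 nowhere
    f1 <- rbind(matrix(1L, p / 2, n_m), matrix(0L, p / 2, n_m))
    dos <- matrix(0L, n_m, n_offspring)
    for (i in seq_len(n_offspring)) {
      g1 <- gamete_chromosome(f1, ch$markers$position, ch$length)
      g2 <- gamete_chromosome(f1, ch$markers$position, ch$length)
      dos[, i] <- colSums(g1) + colSums(g2)
    }
    rownames(dos) <- ch$markers$marker
    dos
  })
  dosages <- do.call(rbind, per_chrom)
  colnames(dosages) <- ind_ids
  structure(list(genotypes = genotype_matrix(dosages, p), truth = truth,
                 ploidy = p, seed = seed,
                 error_rate = 0, missing_rate = 0),
            class = "simulated_population")
}

#' @export
print.simulated_population <- function(x, ...) {
  cat(sprintf("simulated_population: ploidy %d, seed %d\n", x$ploidy, x$seed))
  print(x$genotypes)
  invisible(x)
}

#' Inject genotyping errors and missing values
#'
#' A fraction `error_rate` of the non-missing cells is shifted by one dosage
#' unit (direction random, clamped to `[0, ploidy]`, so e.g. a hexaploid
#' AAATTT can become AAAATT), and a disjoint fraction `missing_rate` is set
#' missing. Cell counts are rounded to the nearest integer.
#'
#' @param g a [genotype_matrix].
#' @param error_rate,missing_rate fractions in `[0, 0.5]`, summing to at
#'   most 1.
#' @param seed mandatory integer seed.
#' @return a perturbed [genotype_matrix].
#' @export
perturb_genotypes <- function(g, error_rate, missing_rate, seed) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (missing(seed) || is.null(seed)) stop("a seed is required", call. = FALSE)
  if (error_rate < 0 || error_rate > 0.5 || missing_rate < 0 || missing_rate > 0.5)
    stop("rates must lie in [0, 0.5]", call. = FALSE)
  if (error_rate + missing_rate > 1) stop("rates sum above 1", call. = FALSE)
  set.seed(seed)
  d <- g$dosages
  cells <- which(!is.na(d))
  n_err <- round(error_rate * length(cells))
  n_mis <- round(missing_rate * length(cells))
  pick <- sample(cells, n_err + n_mis)
  err_cells <- pick[seq_len(n_err)]
  mis_cells <- pick[n_err + seq_len(n_mis)]
  if (n_err > 0) {
    shift <- sample(c(-1L, 1L), n_err, replace = TRUE)
    v <- d[err_cells] + shift
    # clamping at the dosage bounds must still change the genotype
    at_bound <- v < 0L | v > g$ploidy
    v[at_bound] <- d[err_cells][at_bound] - shift[at_bound]
    d[err_cells] <- v
  }
  if (n_mis > 0) d[mis_cells] <- NA_integer_
  genotype_matrix(d, g$ploidy)
}

#' Randomize marker order
#'
#' Permutes the rows of a genotype matrix uniformly at random, removing any
#' prior positional knowledge that would not be available for a real
#' dataset. Downstream grouping and ordering results are invariant to this
#' permutation up to group relabeling.
#'
#' @param g a [genotype_matrix].
#' @param seed mandatory integer seed.
#' @return a [genotype_matrix] with permuted rows.
#' @export
shuffle_markers <- function(g, seed) {
  stopifnot(inherits(g, "genotype_matrix"))
  if (missing(seed) || is.null(seed)) stop("a seed is required", call. = FALSE)
  set.seed(seed)
  perm <- sample.int(nrow(g$dosages))
  genotype_matrix(g$dosages[perm, , drop = FALSE], g$ploidy)
}

#' Write a true map as TSV
#'
#' @param truth a `true_map`.
#' @param path output path; columns `marker`, `chromosome`, `position_cM`.
#' @export
write_true_map <- function(truth, path) {
  df <- do.call(rbind, lapply(truth$chromosomes, function(ch)
    data.frame(marker = ch$markers$marker, chromosome = ch$id,
               position_cM = ch$markers$position, stringsAsFactors = FALSE)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
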