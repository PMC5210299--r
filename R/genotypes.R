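# Data model and I/O for dosage genotypes and linkage maps.

#' Construct a validated genotype matrix
#'
#' A `genotype_matrix` holds integer allele dosages for a set of markers
#' (rows) scored on a set of individuals (columns) at a common, even ploidy
#' level. A dosage is the count of the reference allele in one individual at
#' one marker, so valid values are `0..ploidy`; missing genotypes are `NA`.
#'
#' @param dosages integer matrix, markers in rows, individuals in columns.
#'   Row names are marker ids and column names individual ids; both must be
#'   unique. `NA` marks missing genotypes.
#' @param ploidy even positive integer, the number of chromosome sets.
#' @return an object of class `genotype_matrix`: a list with elements
#'   `dosages` (integer matrix) and `ploidy`.
#' @examples
#' g <- genotype_matrix(matrix(c(4L, 0L, 2L, 1L), 2, 2,
#'   dimnames = list(c("m1", "m2"), c("i1", "i2"))), ploidy = 4)
#' @export
genotype_matrix <- function(dosages, ploidy) {
  if (!is.matrix(dosages)) dosages <- as.matrix(dosages)
  check_ploidy(ploidy)
  if (is.null(rownames(dosages)) || is.null(colnames(dosages)))
    stop("dosage matrix needs marker row names and individual column names",
         call. = FALSE)
  if (anyDuplicated(rownames(dosages)))
    stop("duplicate marker ids: ",
         paste(unique(rownames(dosages)[duplicated(rownames(dosages))]),
               collapse = ", "), call. = FALSE)
  if (anyDuplicated(colnames(dosages)))
    stop("duplicate individual ids", call. = FALSE)
  storage.mode(dosages) <- "integer"
  bad <- which(!is.na(dosages) & (dosages < 0L | dosages > ploidy),
               arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("dosage outside [0, %d] at marker '%s', individual '%s'",
                 ploidy, rownames(dosages)[bad[1, 1]],
                 colnames(dosages)[bad[1, 2]]), call. = FALSE)
  }
  structure(list(dosages = dosages, ploidy = as.integer(ploidy)),
            class = "genotype_matrix")
}

check_ploidy <- function(ploidy) {
  if (length(ploidy) != 1 || is.na(ploidy) || ploidy < 2 || ploidy %% 2 != 0)
    stop("ploidy must be a single even positive integer, got: ", ploidy,
         call. = FALSE)
  invisible(TRUE)
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d markers x %d individuals, ploidy %d, %d missing\n",
              nrow(x$dosages), ncol(x$dosages), x$ploidy,
              sum(is.na(x$dosages))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

#' Convert an allele string to a reference-allele dosage
#'
#' For a biallelic polyploid genotype written as an allele string (for
#' example `"AABB"` at tetraploid level), the dosage is the number of times
#' the reference allele appears: `AAAA`, `AABB` and `ABBB` give 4, 2 and 1.
#'
#' @param genotype character string of length-`ploidy` allele symbols,
#'   or a vector of such strings.
#' @param ref_allele single character, the reference allele symbol.
#' @param ploidy even positive integer.
#' @param alleles optional character vector of allowed symbols; any symbol
#'   outside it is a parse error. The default allows the nucleotides
#'   `A,C,G,T`, the generic major/minor symbols `A,B` and `ref_allele`.
#' @return integer dosage(s) in `0..ploidy`.
#' @examples
#' dosage_from_string("ABBB", "A", 4)  # 1
#' @export
dosage_from_string <- function(genotype, ref_allele, ploidy,
                               alleles = union(c("A", "B", "C", "G", "T"), ref_allele)) {
  check_ploidy(ploidy)
  if (nchar(ref_allele) != 1)
    stop("ref_allele must be a single character", call. = FALSE)
  vapply(genotype, function(g) {
    if (is.na(g)) return(NA_integer_)
    chars <- strsplit(g, "", fixed = TRUE)[[1]]
    if (length(chars) != ploidy)
      stop(sprintf("genotype string '%s' has %d alleles but ploidy is %d",
                   g, length(chars), ploidy), call. = FALSE)
    unknown <- setdiff(chars, alleles)
    if (length(unknown) > 0)
      stop(sprintf("unknown allele symbol(s) %s in genotype '%s'",
                   paste(unknown, collapse = ","), g), call. = FALSE)
    sum(chars == ref_allele)
  }, integer(1), USE.NAMES = FALSE)
}

#' Read a dosage genotype table
#'
#' Reads a CSV/TSV table whose first column holds marker ids and whose header
#' row holds individual ids; cells are integer dosages in `0..ploidy` or `NA`
#' (case-insensitive, or empty) for missing.
#'
#' @param path file path.
#' @param ploidy even positive integer.
#' @param sep field separator; `NULL` (default) picks tab for `.tsv`/`.txt`
#'   and comma otherwise.
#' @return a [genotype_matrix].
#' @export
read_genotypes <- function(path, ploidy, sep = NULL) {
  if (is.null(sep))
    sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           na.strings = c("NA", "na", "Na", "nA", ""),
                           colClasses = "character")
  if (ncol(tab) < 2) stop("genotype table needs a marker column and at least one individual", call. = FALSE)
  ids <- tab[[1]]
  cells <- as.matrix(tab[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(cells), nrow = nrow(cells)))
  bad_cell <- !is.na(cells) & is.na(num)
  if (any(bad_cell)) {
    w <- which(bad_cell, arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric dosage '%s' at marker '%s', individual '%s'",
                 cells[w[1], w[2]], ids[w[1]], colnames(cells)[w[2]]),
         call. = FALSE)
  }
  if (any(!is.na(num) & num != round(num))) stop("dosages must be integers", call. = FALSE)
  dimnames(num) <- list(ids, colnames(cells))
  genotype_matrix(num, ploidy)
}

#' Write a dosage genotype table
#'
#' Inverse of [read_genotypes()]: writes a TSV (or CSV) with marker ids in
#' the first column and one column per individual; missing dosages become
#' `NA`.
#'
#' @param g a [genotype_matrix].
#' @param path output file path.
#' @param sep field separator, default tab.
#' @export
write_genotypes <- function(g, path, sep = "\t") {
  stopifnot(inherits(g, "genotype_matrix"))
  tab <- data.frame(marker = rownames(g$dosages), g$dosages,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = sep, quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Construct a linkage map
#'
#' A `linkage_map` holds, per linkage group, an ordered vector of marker ids
#' and their cumulative positions in centiMorgans (starting at 0 and
#' nondecreasing), plus the ids of markers that were filtered out and not
#' assigned to any group.
#'
#' @param groups named list; each element is a data.frame with columns
#'   `marker` (character) and `position` (numeric cM).
#' @param unassigned character vector of filtered-out marker ids.
#' @return an object of class `linkage_map`.
#' @export
linkage_map <- function(groups, unassigned = character(0)) {
  if (is.null(names(groups)) || any(names(groups) == ""))
    stop("groups must be a named list", call. = FALSE)
  groups <- lapply(groups, function(gr) {
    gr <- as.data.frame(gr, stringsAsFactors = FALSE)
    stopifnot(all(c("marker", "position") %in% names(gr)))
    if (nrow(gr) == 0) stop("empty linkage group", call. = FALSE)
    if (gr$position[1] != 0) stop("group positions must start at 0", call. = FALSE)
    if (is.unsorted(gr$position)) stop("group positions must be nondecreasing", call. = FALSE)
    gr <- gr[, c("marker", "position")]
    rownames(gr) <- NULL
    gr
  })
  all_m <- unlist(lapply(groups, `[[`, "marker"), use.names = FALSE)
  if (anyDuplicated(c(all_m, unassigned)))
    stop("a marker appears in more than one group", call. = FALSE)
  structure(list(groups = groups, unassigned = as.character(unassigned)),
            class = "linkage_map")
}

#' @export
print.linkage_map <- function(x, ...) {
  sizes <- vapply(x$groups, nrow, integer(1))
  lens <- vapply(x$groups, function(g) max(g$position), numeric(1))
  cat(sprintf("linkage_map: %d group(s), %d marker(s), %d unassigned\n",
              length(x$groups), sum(sizes), length(x$unassigned)))
  for (i in seq_along(x$groups))
    cat(sprintf("  %s: %d markers, %.1f cM\n", names(x$groups)[i],
                sizes[i], lens[i]))
  invisible(x)
}

#' Flatten a linkage map to a data frame
#'
#' @param x a [linkage_map].
#' @param ... unused.
#' @return data.frame with columns `marker`, `group`, `position`; unassigned
#'   markers appear with group `"filtered"` and position `NA`.
#' @export
as.data.frame.linkage_map <- function(x, ...) {
  rows <- lapply(names(x$groups), function(gid) {
    data.frame(marker = x$groups[[gid]]$marker, group = gid,
               position = x$groups[[gid]]$position,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(
    if (length(x$unassigned) > 0)
      data.frame(marker = x$unassigned, group = "filtered",
                 position = NA_real_, stringsAsFactors = FALSE)
  )))
  if (is.null(out))
    out <- data.frame(marker = character(0), group = character(0),
                      position = numeric(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Write a linkage map as TSV
#'
#' Columns are `marker`, `group`, `position_cM`; filtered (unassigned)
#' markers are listed with group `"filtered"` and position `NA`. The file
#' read back with [read_linkage_map()] reproduces the map exactly.
#'
#' @param map a [linkage_map].
#' @param path output file path.
#' @export
write_linkage_map <- function(map, path) {
  stopifnot(inherits(map, "linkage_map"))
  df <- as.data.frame(map)
  names(df) <- c("marker", "group", "position_cM")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Read a linkage map written by [write_linkage_map()]
#'
#' @param path TSV file with columns `marker`, `group`, `position_cM`.
#' @return a [linkage_map].
#' @export
read_linkage_map <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = c("character", "character", "numeric"))
  names(df) <- c("marker", "group", "position")
  unas <- df$marker[df$group == "filtered"]
  df <- df[df$group != "filtered", , drop = FALSE]
  gids <- unique(df$group)
  groups <- lapply(gids, function(gid) df[df$group == gid, c("marker", "position")])
  names(groups) <- gids
  if (length(groups) == 0)
    return(structure(list(groups = structure(list(), names = character(0)),
                          unassigned = unas), class = "linkage_map"))
  linkage_map(groups, unas)
}
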