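#' Codominant SSR genotype matrix
#'
#' `ssr_matrix()` builds the package's central container: a rectangular table
#' of diploid SSR genotypes for a set of accessions (rows) scored at a set of
#' microsatellite markers (columns). Alleles at a locus are labelled by
#' consecutive capital letters starting at "A", the convention being that "A"
#' is the band of largest molecular weight on the gel. A genotype is an
#' unordered pair of allele labels written as a two-letter string ("AB",
#' "AA"); a cell where no band was scored is missing as a whole (`NA` or
#' `"--"`): single-allele missingness is not representable, matching
#' band-based scoring.
#'
#' @param genotypes character matrix with one row per accession and one
#'   column per marker; entries are two-letter genotype strings, `"--"` or
#'   `NA` for missing. Row names are accession ids, column names marker ids.
#' @param missing token used for missing cells in `genotypes` (default
#'   `"--"`); `NA` is always accepted.
#'
#' @return an object of class `"ssr_matrix"`: a list with elements
#'   `ids` (accession ids), `markers` (marker ids), `alleles` (named list of
#'   per-locus allele label vectors, contiguous from "A"), and integer
#'   matrices `a1`, `a2` holding the canonically ordered allele indices
#'   (`a1 <= a2`, both `NA` when the cell is missing).
#'
#' @details The per-locus allele set is declared by the data: it runs from
#'   "A" up to the largest letter observed at that locus anywhere in the
#'   matrix. At most nine alleles per locus are supported, the bound imposed
#'   by the single-character identity-card coding (see
#'   [encode_genotype()]).
#'
#' @examples
#' g <- rbind(TJx = c("AB", "--"), TJy = c("AA", "CC"))
#' colnames(g) <- c("s1", "s2")
#' m <- ssr_matrix(g)
#' m
#' @seealso [read_genotypes()], [recode_bands()], [locus_stats_table()]
#' @export
ssr_matrix <- function(genotypes, missing = "--") {
  if (!is.matrix(genotypes) || !is.character(genotypes))
    stop("'genotypes' must be a character matrix")
  ids <- rownames(genotypes)
  markers <- colnames(genotypes)
  if (is.null(ids)) ids <- paste0("acc", seq_len(nrow(genotypes)))
  if (is.null(markers)) markers <- paste0("m", seq_len(ncol(genotypes)))
  if (anyDuplicated(ids))
    stop("duplicate accession ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (anyDuplicated(markers))
    stop("duplicate marker ids: ",
         paste(unique(markers[duplicated(markers)]), collapse = ", "))

  g <- genotypes
  g[!is.na(g) & g == missing] <- NA_character_
  bad <- !is.na(g) & !grepl("^[A-Z][A-Z]$", g)
  if (any(bad)) {
    k <- which(bad, arr.ind = TRUE)[1, ]
    stop(sprintf("malformed genotype '%s' (accession %s, marker %s)",
                 g[bad][1], ids[k[1]], markers[k[2]]))
  }
  a1 <- matrix(match(substr(g, 1, 1), LETTERS), nrow(g), ncol(g))
  a2 <- matrix(match(substr(g, 2, 2), LETTERS), nrow(g), ncol(g))
  # canonical (lexicographic) pair order: Genotype(x, y) == Genotype(y, x)
  swap <- !is.na(a1) & a1 > a2
  if (any(swap)) {
    tmp <- a1[swap]; a1[swap] <- a2[swap]; a2[swap] <- tmp
  }
  kmax <- apply(a2, 2, function(x) if (all(is.na(x))) 1L else max(x, na.rm = TRUE))
  if (any(kmax > 9L))
    stop("more than 9 alleles at marker(s): ",
         paste(markers[kmax > 9L], collapse = ", "),
         " (single-character coding supports at most 9)")
  alleles <- lapply(kmax, function(k) LETTERS[seq_len(k)])
  names(alleles) <- markers
  dimnames(a1) <- dimnames(a2) <- list(ids, markers)
  structure(list(ids = ids, markers = markers, alleles = alleles,
                 a1 = a1, a2 = a2),
            class = "ssr_matrix")
}

# internal fast path: a1/a2 already canonical integer matrices
new_ssr_matrix <- function(ids, markers, a1, a2) {
  dimnames(a1) <- dimnames(a2) <- list(ids, markers)
  kmax <- apply(a2, 2, function(x) if (all(is.na(x))) 1L else max(x, na.rm = TRUE))
  alleles <- lapply(kmax, function(k) LETTERS[seq_len(k)])
  names(alleles) <- markers
  structure(list(ids = ids, markers = markers, alleles = alleles,
                 a1 = a1, a2 = a2),
            class = "ssr_matrix")
}

#' @export
dim.ssr_matrix <- function(x) c(length(x$ids), length(x$markers))

#' @export
print.ssr_matrix <- function(x, ...) {
  cat(sprintf("ssr_matrix: %d accessions x %d markers\n",
              length(x$ids), length(x$markers)))
  na <- vapply(x$alleles, length, 1L)
  cat(sprintf("  alleles per locus: %d-%d; missing cells: %.1f%%\n",
              min(na), max(na), 100 * mean(is.na(x$a1))))
  invisible(x)
}

#' Extract a sub-matrix of accessions and/or markers
#'
#' Declared per-locus allele sets are preserved, so allele frequencies on a
#' subset are reported over the full collection's allele labels (alleles
#' absent from the subset get frequency zero and are not counted in Na).
#'
#' @param x an `ssr_matrix`
#' @param i accession selector (indices, names or logical)
#' @param j marker selector
#' @param ... ignored
#' @export
`[.ssr_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_along(x$ids)
  if (missing(j)) j <- seq_along(x$markers)
  a1 <- x$a1[i, j, drop = FALSE]
  a2 <- x$a2[i, j, drop = FALSE]
  structure(list(ids = rownames(a1), markers = colnames(a1),
                 alleles = x$alleles[colnames(a1)], a1 = a1, a2 = a2),
            class = "ssr_matrix")
}

#' Genotypes as two-letter strings
#'
#' @param x an `ssr_matrix`
#' @param missing token for missing cells (default `NA`)
#' @return character matrix of "AB"-style strings
#' @export
genotype_strings <- function(x, missing = NA_character_) {
  g <- matrix(missing, nrow(x$a1), ncol(x$a1), dimnames = dimnames(x$a1))
  ok <- !is.na(x$a1)
  g[ok] <- paste0(LETTERS[x$a1[ok]], LETTERS[x$a2[ok]])
  g
}

#' Recode raw band molecular weights into letter genotypes
#'
#' Implements gel-scoring conventions for codominant SSRs: at each locus the
#' distinct band weights observed across the panel are ranked by decreasing
#' molecular weight and assigned letters A, B, C, ...; an accession showing a
#' single band is recorded as homozygous for it, and an accession with no
#' band is missing.
#'
#' @param bands a named list (one element per marker) of named lists (one
#'   element per accession) of numeric band weight vectors of length 0, 1
#'   or 2.
#' @return an [ssr_matrix()]
#' @examples
#' b <- list(s1 = list(x = c(210, 185), y = 198, z = numeric(0)))
#' genotype_strings(recode_bands(b))  # "AC", "BB", NA
#' @export
recode_bands <- function(bands) {
  if (!length(bands) || is.null(names(bands)))
    stop("'bands' must be a named list of markers")
  markers <- names(bands)
  acc <- unique(unlist(lapply(bands, names)))
  if (is.null(acc)) stop("no accessions found in 'bands'")
  g <- matrix(NA_character_, length(acc), length(markers),
              dimnames = list(acc, markers))
  for (mk in markers) {
    per <- bands[[mk]]
    w <- unlist(per, use.names = FALSE)
    if (length(w) && any(w <= 0)) stop("band weights must be positive")
    lab <- sort(unique(w), decreasing = TRUE)  # heaviest band -> "A"
    if (length(lab) > 9L)
      stop("more than 9 distinct bands at marker ", mk)
    for (id in names(per)) {
      x <- per[[id]]
      if (length(x) > 2L)
        stop(sprintf("accession %s has %d bands at marker %s (diploid: at most 2)",
                     id, length(x), mk))
      if (length(x) == 0L) next
      a <- LETTERS[match(x, lab)]
      if (length(a) == 1L) a <- c(a, a)  # single band scored homozygous
      g[id, mk] <- paste(sort(a), collapse = "")
    }
  }
  ssr_matrix(g)
}
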