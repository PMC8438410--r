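#' Single-character genotype coding for identity cards
#'
#' Each diploid genotype state is written as one character so that an
#' accession's genotypes over an ordered marker panel concatenate into a
#' compact identity string. The map is fixed and global: homozygotes A/A,
#' B/B, C/C, D/D are coded "1", "2", "3", "4" (the k-th homozygote gets
#' digit k, up to 9 alleles); the heterozygotes among the first four
#' alleles, in lexicographic order A/B, A/C, A/D, B/C, B/D, C/D, are coded
#' "A".."F"; heterozygote pairs involving alleles beyond "D" are appended
#' after "F" in lexicographic pair order (continuing "G".."Z" then
#' "a".."j"). A missing genotype (no band) is coded "0".
#'
#' @param g character vector of two-letter genotype strings ("AB", "AA"),
#'   with `NA` or `"--"` for missing
#' @return character vector of single-character codes
#' @examples
#' encode_genotype(c("BC", "AA", NA))  # "D" "1" "0"
#' decode_char(c("D", "0", "F"))       # "BC" NA "CD"
#' @export
encode_genotype <- function(g) {
  map <- ident_code_map()
  out <- rep("0", length(g))
  miss <- is.na(g) | g == "--"
  gg <- g[!miss]
  bad <- !gg %in% names(map)
  if (any(bad)) stop("genotype not representable in the coding alphabet: ",
                     paste(unique(gg[bad]), collapse = ", "))
  out[!miss] <- unname(map[gg])
  out
}

#' @rdname encode_genotype
#' @param code character vector of single-character identity codes
#' @return `decode_char()`: character vector of two-letter genotype strings,
#'   `NA` for "0"
#' @export
decode_char <- function(code) {
  map <- ident_code_map()
  inv <- stats::setNames(names(map), map)
  out <- rep(NA_character_, length(code))
  nz <- !is.na(code) & code != "0"
  cc <- code[nz]
  bad <- !cc %in% names(inv)
  if (any(bad)) stop("unknown identity code: ",
                     paste(unique(cc[bad]), collapse = ", "))
  out[nz] <- unname(inv[cc])
  out
}

# genotype string -> single character, for all pairs over 9 alleles
ident_code_map <- local({
  map <- NULL
  function() {
    if (!is.null(map)) return(map)
    hom <- stats::setNames(as.character(1:9),
                           paste0(LETTERS[1:9], LETTERS[1:9]))
    pr <- which(upper.tri(matrix(0, 9, 9)), arr.ind = TRUE)
    pr <- pr[order(pr[, "row"], pr[, "col"]), , drop = FALSE]
    first <- pr[, "row"] <= 4L & pr[, "col"] <= 4L
    pr <- rbind(pr[first, ], pr[!first, ])  # A/B..C/D first, rest appended
    het_sym <- c(LETTERS, letters)[seq_len(nrow(pr))]
    het <- stats::setNames(het_sym,
                           paste0(LETTERS[pr[, "row"]], LETTERS[pr[, "col"]]))
    map <<- c(hom, het)
    map
  }
})

#' Greedy PIC-ordered selection of a discriminating marker set
#'
#' Markers are ranked by PIC (ties broken by input order) and added one at a
#' time, most informative first, until the identity-string prefixes of all
#' accessions are pairwise distinct. Missing genotypes are coded "0" and the
#' "0" counts as a distinguishing character. If even the full panel leaves
#' identical accessions, all markers are returned together with the groups
#' that cannot be separated.
#'
#' @param x an [ssr_matrix()] with at least 2 accessions
#' @return a list with `markers` (the selected ordered prefix), `order`
#'   (all markers in PIC-descending order), `pic` (named PIC vector),
#'   `complete` (`TRUE` if all accessions are distinguished) and
#'   `collisions` (list of indistinguishable accession id groups, empty if
#'   complete)
#' @seealso [build_identities()], [verify_uniqueness()]
#' @export
select_discriminating_markers <- function(x) {
  if (length(x$ids) < 2L) stop("need at least 2 accessions")
  pv <- vapply(x$markers, function(mk) {
    p <- allele_freqs(x, mk)$p
    pic(p[p > 0])
  }, numeric(1))
  ord <- x$markers[order(-pv)]  # stable: PIC ties keep input order
  codes <- apply(genotype_strings(x), 2L, encode_genotype)
  key <- rep("", length(x$ids))
  for (k in seq_along(ord)) {
    key <- paste0(key, codes[, ord[k]])
    if (!anyDuplicated(key))
      return(list(markers = ord[seq_len(k)], order = ord,
                  pic = pv, complete = TRUE, collisions = list()))
  }
  dup <- split(x$ids, key)
  dup <- unname(dup[lengths(dup) > 1L])
  list(markers = ord, order = ord, pic = pv, complete = FALSE,
       collisions = dup)
}

#' Build identity strings over an ordered marker panel
#'
#' @param x an [ssr_matrix()]
#' @param markers ordered character vector of marker ids (e.g. the
#'   `markers` element of [select_discriminating_markers()]); must be a
#'   subset of `x`'s markers
#' @return named character vector: one identity string per accession,
#'   characters in `markers` order
#' @examples
#' g <- rbind(a = c("AB", "AA"), b = c("AB", "BB"))
#' colnames(g) <- c("s1", "s2")
#' build_identities(ssr_matrix(g), c("s2", "s1"))
#' @export
build_identities <- function(x, markers) {
  bad <- setdiff(markers, x$markers)
  if (length(bad)) stop("markers not in matrix: ", paste(bad, collapse = ", "))
  codes <- apply(genotype_strings(x)[, markers, drop = FALSE], 2L,
                 encode_genotype)
  if (length(x$ids) == 1L) codes <- matrix(codes, nrow = 1L)
  stats::setNames(apply(codes, 1L, paste, collapse = ""), x$ids)
}

#' Check identity strings for uniqueness
#'
#' @param identities named character vector as from [build_identities()]
#' @return list with `unique` (`TRUE` iff all strings are distinct) and
#'   `duplicates` (list of accession id groups sharing a string)
#' @export
verify_uniqueness <- function(identities) {
  if (!length(identities)) return(list(unique = TRUE, duplicates = list()))
  ids <- names(identities)
  if (is.null(ids)) ids <- as.character(seq_along(identities))
  grp <- split(ids, identities)
  grp <- unname(grp[lengths(grp) > 1L])
  list(unique = length(grp) == 0L, duplicates = grp)
}

#' Decode identity strings into a genotype matrix
#'
#' Inverse of [build_identities()]: given per-accession identity strings and
#' the ordered marker panel they were written over, reconstructs the
#' [ssr_matrix()] (missing where the code is "0").
#'
#' @param identities named character vector of equal-length identity strings
#' @param markers ordered marker ids, one per string position
#' @return an [ssr_matrix()]
#' @export
decode_identities <- function(identities, markers) {
  len <- unique(nchar(identities))
  if (length(len) != 1L || len != length(markers))
    stop("identity strings must all have length ", length(markers))
  chars <- do.call(rbind, strsplit(identities, "", fixed = TRUE))
  g <- apply(chars, 2L, decode_char)
  if (length(identities) == 1L) g <- matrix(g, nrow = 1L)
  dimnames(g) <- list(names(identities), markers)
  ssr_matrix(g)
}
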