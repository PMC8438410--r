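#' Read a genotype matrix from disk
#'
#' Two dialects are supported. The native dialect is a delimited text table
#' (comma or tab, auto-detected from the header line) with a mandatory
#' header, one row per accession, the first column holding the accession id
#' and one column per marker holding two-letter genotypes ("AB") with "--"
#' for missing. The GenePop dialect is the classic population-genetics
#' interchange format with 4-digit diploid codes per locus ("0102"; "0000"
#' missing), alleles mapped A = 01, B = 02, ...
#'
#' @param path path to an existing file
#' @param dialect `"native"` or `"genepop"`
#' @return an [ssr_matrix()]
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("id,s1,s2", "TJx,AB,--", "TJy,AA,CC"), f)
#' read_genotypes(f)
#' @export
read_genotypes <- function(path, dialect = c("native", "genepop")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "native") read_native(path) else read_genepop(path)
}

read_native <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L) stop("no data rows in ", path)
  sep <- if (grepl("\t", lines[1L])) "\t" else ","
  split1 <- strsplit(lines, sep, fixed = TRUE)
  header <- trimws(split1[[1L]])
  markers <- header[-1L]
  if (!length(markers)) stop("header has no marker columns (line 1)")
  n_col <- length(header)
  rows <- split1[-1L]
  bad <- which(lengths(rows) != n_col)
  if (length(bad))
    stop(sprintf("ragged row: line %d has %d fields, expected %d",
                 bad[1L] + 1L, lengths(rows)[bad[1L]], n_col))
  tab <- do.call(rbind, lapply(rows, trimws))
  ids <- tab[, 1L]
  if (anyDuplicated(ids))
    stop("duplicate accession id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  g <- tab[, -1L, drop = FALSE]
  ok <- is.na(g) | g == "--" | grepl("^[A-Z][A-Z]$", g)
  if (!all(ok)) {
    k <- which(!ok, arr.ind = TRUE)[1L, ]
    stop(sprintf("line %d: malformed genotype '%s' at marker %s",
                 k[1L] + 1L, g[k[1L], k[2L]], markers[k[2L]]))
  }
  dimnames(g) <- list(ids, markers)
  ssr_matrix(g)
}

#' Write a genotype matrix to disk
#'
#' Round-trip identity holds for both dialects:
#' `read_genotypes(write_genotypes(m, f, d), d)` equals `m`.
#'
#' @param x an [ssr_matrix()]
#' @param path output file path
#' @param dialect `"native"` (delimiter chosen from the file extension:
#'   `.csv` comma, otherwise tab) or `"genepop"`
#' @return `path`, invisibly
#' @export
write_genotypes <- function(x, path, dialect = c("native", "genepop")) {
  dialect <- match.arg(dialect)
  if (dialect == "native") {
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
    g <- genotype_strings(x, missing = "--")
    out <- c(paste(c("id", x$markers), collapse = sep),
             paste(x$ids, apply(g, 1L, paste, collapse = sep), sep = sep))
    writeLines(out, path)
  } else {
    g4 <- matrix("0000", nrow(x$a1), ncol(x$a1))
    ok <- !is.na(x$a1)
    g4[ok] <- sprintf("%02d%02d", x$a1[ok], x$a2[ok])
    out <- c("ssrcore genotype export",
             x$markers,
             "POP",
             paste0(x$ids, " ,  ", apply(g4, 1L, paste, collapse = " ")))
    writeLines(out, path)
  }
  invisible(path)
}

read_genepop <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  pop_at <- which(toupper(trimws(lines)) == "POP")[1L]
  if (is.na(pop_at) || pop_at < 3L) stop("not a GenePop file (no POP line): ", path)
  markers <- trimws(unlist(strsplit(lines[2:(pop_at - 1L)], ",", fixed = TRUE)))
  markers <- markers[nzchar(markers)]
  rows <- lines[-seq_len(pop_at)]
  rows <- rows[toupper(trimws(rows)) != "POP"]  # single logical population
  parts <- strsplit(rows, ",", fixed = TRUE)
  if (any(lengths(parts) != 2L))
    stop("malformed GenePop individual line in ", path)
  ids <- trimws(vapply(parts, `[`, "", 1L))
  codes <- lapply(parts, function(p) strsplit(trimws(p[2L]), "[ \t]+")[[1L]])
  if (any(lengths(codes) != length(markers)))
    stop("GenePop row with wrong locus count in ", path)
  tab <- do.call(rbind, codes)
  if (!all(grepl("^[0-9]{4}$", tab)))
    stop("GenePop alleles must be 4-digit codes in ", path)
  i1 <- matrix(as.integer(substr(tab, 1, 2)), nrow(tab))
  i2 <- matrix(as.integer(substr(tab, 3, 4)), nrow(tab))
  if (any((i1 == 0L) != (i2 == 0L)))
    stop("half-missing GenePop genotype (one allele 00) in ", path)
  g <- matrix(NA_character_, nrow(tab), ncol(tab), dimnames = list(ids, markers))
  ok <- i1 > 0L
  if (any(i1 > 9L | i2 > 9L))
    stop("allele code beyond 09 in ", path, " (at most 9 alleles per locus)")
  lo <- pmin(i1, i2); hi <- pmax(i1, i2)
  g[ok] <- paste0(LETTERS[lo[ok]], LETTERS[hi[ok]])
  ssr_matrix(g)
}
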