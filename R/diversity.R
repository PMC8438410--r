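#' Allele frequencies at one locus
#'
#' Frequencies are counted over gene copies (a heterozygote contributes one
#' copy of each allele, a homozygote two of the same), with missing cells
#' excluded listwise at the locus. The frequency vector spans the locus's
#' declared allele set, so alleles unobserved in the (sub)matrix appear with
#' frequency zero.
#'
#' @param x an [ssr_matrix()]
#' @param locus marker id
#' @return a list with `locus`, `p` (named frequency vector summing to 1
#'   when `n > 0`) and `n` (number of non-missing genotyped individuals)
#' @export
allele_freqs <- function(x, locus) {
  j <- match(locus, x$markers)
  if (is.na(j)) stop("no such marker: ", locus)
  a1 <- x$a1[, j]; a2 <- x$a2[, j]
  keep <- !is.na(a1)
  k <- length(x$alleles[[j]])
  cnt <- tabulate(c(a1[keep], a2[keep]), nbins = k)
  n <- sum(keep)
  p <- if (n > 0L) cnt / (2 * n) else rep(NA_real_, k)
  names(p) <- x$alleles[[j]]
  list(locus = locus, p = p, n = n)
}

#' Nei's gene diversity
#'
#' \eqn{D = 1 - \sum_i p_i^2}, the expected heterozygosity of a randomly
#' mating population with allele frequencies `p`, without small-sample
#' correction.
#'
#' @param p vector of allele frequencies (non-negative, summing to 1)
#' @return D in [0, 1)
#' @export
nei_gene_diversity <- function(p) {
  check_freqs(p)
  1 - sum(p^2)
}

#' Effective number of alleles
#'
#' \eqn{N_e = 1 / \sum_i p_i^2}: the number of equally frequent alleles that
#' would give the same homozygosity. Satisfies `Ne == 1 / (1 - D)` exactly.
#'
#' @inheritParams nei_gene_diversity
#' @return Ne in [1, number of alleles]
#' @export
effective_alleles <- function(p) {
  check_freqs(p)
  1 / sum(p^2)
}

#' Observed heterozygosity at one locus
#'
#' Fraction of non-missing genotypes whose two alleles differ.
#'
#' @inheritParams allele_freqs
#' @return Ho in [0, 1]; `NaN` if the locus has no non-missing genotypes
#' @export
observed_heterozygosity <- function(x, locus) {
  j <- match(locus, x$markers)
  if (is.na(j)) stop("no such marker: ", locus)
  a1 <- x$a1[, j]; a2 <- x$a2[, j]
  keep <- !is.na(a1)
  mean(a1[keep] != a2[keep])
}

#' Unbiased expected heterozygosity
#'
#' Small-sample corrected expected heterozygosity,
#' \eqn{H_E = \frac{2n}{2n-1} D}, with `n` the number of individuals
#' genotyped at the locus.
#'
#' @param D Nei's gene diversity at the locus
#' @param n number of non-missing genotyped individuals
#' @return He
#' @export
expected_het_unbiased <- function(D, n) {
  if (any(n < 1)) stop("n must be >= 1")
  2 * n / (2 * n - 1) * D
}

#' Shannon information index
#'
#' \eqn{I = -\sum_i p_i \ln p_i} (natural log); zero-frequency alleles
#' contribute nothing.
#'
#' @inheritParams nei_gene_diversity
#' @return I >= 0 (nats); 0 iff the locus is monomorphic
#' @export
shannon_index <- function(p) {
  check_freqs(p)
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Polymorphic information content
#'
#' Botstein's PIC for a codominant marker:
#' \deqn{PIC = 1 - \sum_i p_i^2 - \sum_{i<j} 2 p_i^2 p_j^2.}
#' Always satisfies `0 <= PIC <= D`.
#'
#' @inheritParams nei_gene_diversity
#' @return PIC in [0, 1]
#' @export
pic <- function(p) {
  check_freqs(p)
  p2 <- p^2
  # sum_{i<j} 2 p_i^2 p_j^2 = (sum p^2)^2 - sum p^4
  1 - sum(p2) - (sum(p2)^2 - sum(p2^2))
}

check_freqs <- function(p) {
  if (!is.numeric(p) || !length(p)) stop("'p' must be a numeric vector")
  if (any(p < 0)) stop("negative allele frequency")
  if (abs(sum(p) - 1) > 1e-9) stop("allele frequencies must sum to 1")
  invisible(p)
}

#' Per-locus diversity statistics panel
#'
#' Computes, for every marker: number of individuals genotyped (n), observed
#' allele count (Na), effective allele number (Ne), observed (Ho) and
#' unbiased expected (He) heterozygosity, Nei's gene diversity (Nei),
#' Shannon index (I, nats) and PIC, plus an arithmetic mean row.
#'
#' @param x an [ssr_matrix()]
#' @param mean_row append a row of column means labelled "Mean"
#'   (default `TRUE`)
#' @return a data frame with one row per marker (and optionally a mean row)
#'   and columns `marker`, `n`, `Na`, `Ne`, `Ho`, `He`, `Nei`, `I`, `PIC`
#' @examples
#' g <- rbind(a = c("AB", "AA"), b = c("AB", "AC"), c = c("AA", "BC"))
#' colnames(g) <- c("s1", "s2")
#' locus_stats_table(ssr_matrix(g))
#' @export
locus_stats_table <- function(x, mean_row = TRUE) {
  rows <- lapply(x$markers, function(mk) {
    af <- allele_freqs(x, mk)
    if (af$n == 0L) stop("all genotypes missing at marker ", mk)
    p <- af$p[af$p > 0]
    D <- nei_gene_diversity(p)
    data.frame(marker = mk, n = af$n, Na = length(p),
               Ne = effective_alleles(p),
               Ho = observed_heterozygosity(x, mk),
               He = expected_het_unbiased(D, af$n),
               Nei = D, I = shannon_index(p), PIC = pic(p),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (mean_row) {
    m <- colMeans(out[, -1L])
    out <- rbind(out, data.frame(marker = "Mean", as.list(m)))
  }
  rownames(out) <- NULL
  out
}

#' Collection-level mean diversity statistics
#'
#' Convenience wrapper returning the mean row of [locus_stats_table()] as a
#' named vector, the unit of comparison between a core collection and its
#' source collection.
#'
#' @inheritParams locus_stats_table
#' @return named numeric vector (n, Na, Ne, Ho, He, Nei, I, PIC)
#' @export
mean_locus_stats <- function(x) {
  tab <- locus_stats_table(x, mean_row = FALSE)
  colMeans(tab[, -1L])
}
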