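#' Allele-sharing distance between accessions
#'
#' For a pair of diploid individuals the proportion of alleles shared at a
#' locus is \eqn{s/2}, where `s` is the number of alleles of one genotype
#' matched by the other (counting multiplicity: AA vs AB share one allele,
#' AA vs AA two). The distance is one minus the proportion shared averaged
#' over the loci typed in both individuals (pairwise deletion of missing
#' cells):
#' \deqn{d(i, j) = 1 - \frac{1}{L'} \sum_{l} s_l(i, j) / 2.}
#' This is the standard individual-level distance for codominant markers and
#' the one used for clustering accessions here; frequency-based distances
#' such as [nei_1972_distance()] are defined on populations, not single
#' diploids.
#'
#' @param x an [ssr_matrix()] with at least two accessions
#' @return a [stats::dist] object with values in [0, 1]
#' @export
allele_sharing_dist <- function(x) {
  n <- length(x$ids)
  if (n < 2L) stop("need at least 2 accessions")
  num <- matrix(0, n, n)    # summed shared-allele counts
  den <- matrix(0L, n, n)   # number of commonly typed loci
  for (j in seq_along(x$markers)) {
    a1 <- x$a1[, j]; a2 <- x$a2[, j]
    ok <- !is.na(a1)
    if (!any(ok)) next
    # genotype state per accession; shared counts via a small state x state table
    st <- (a1 - 1L) * 9L + a2
    us <- sort(unique(st[ok]))
    idx <- match(st, us)
    u1 <- ((us - 1L) %/% 9L) + 1L
    u2 <- ((us - 1L) %% 9L) + 1L
    k <- length(us)
    share <- matrix(0L, k, k)
    for (a in seq_len(k)) for (b in seq_len(k)) {
      ca <- tabulate(c(u1[a], u2[a]), 9L)
      cb <- tabulate(c(u1[b], u2[b]), 9L)
      share[a, b] <- sum(pmin(ca, cb))
    }
    S <- share[idx, idx, drop = FALSE]
    S[!ok, ] <- 0L; S[, !ok] <- 0L
    num <- num + S
    den <- den + outer(ok, ok)
  }
  diag(den) <- pmax(diag(den), 1L)
  if (any(den == 0L)) {
    w <- which(den == 0L, arr.ind = TRUE)[1L, ]
    stop(sprintf("accessions %s and %s share no commonly typed locus",
                 x$ids[w[1L]], x$ids[w[2L]]))
  }
  d <- 1 - num / (2 * den)
  diag(d) <- 0
  dimnames(d) <- list(x$ids, x$ids)
  stats::as.dist(d)
}

#' Nei's (1972) standard genetic distance between two populations
#'
#' Computed from per-locus allele frequency vectors of two populations
#' sharing a locus panel:
#' \deqn{D = -\ln \frac{\sum_l \sum_i p_{xi} p_{yi}}
#'   {\sqrt{(\sum_l \sum_i p_{xi}^2)(\sum_l \sum_i p_{yi}^2)}}.}
#' If the populations share no alleles the normalized identity is zero and
#' the distance is returned as `Inf`.
#'
#' @param fx,fy named lists of allele frequency vectors, one element per
#'   locus, over the same locus set (as produced by [allele_freqs()]`$p`).
#'   Within a locus the two vectors are aligned by allele name; alleles
#'   absent from one population may simply be absent from its vector.
#' @return non-negative scalar distance (possibly `Inf`)
#' @export
nei_1972_distance <- function(fx, fy) {
  if (is.null(names(fx)) || is.null(names(fy)) ||
      !setequal(names(fx), names(fy)))
    stop("'fx' and 'fy' must be named lists over the same loci")
  jxy <- jx <- jy <- 0
  for (l in names(fx)) {
    px <- fx[[l]]; py <- fy[[l]]
    check_freqs(px); check_freqs(py)
    lab <- union(names(px), names(py))
    if (is.null(names(px)) || is.null(names(py))) {
      if (length(px) != length(py))
        stop("unnamed frequency vectors of unequal length at locus ", l)
      lab <- seq_along(px)
      names(px) <- names(py) <- lab
    }
    qx <- qy <- stats::setNames(numeric(length(lab)), lab)
    qx[names(px)] <- px; qy[names(py)] <- py
    jxy <- jxy + sum(qx * qy)
    jx <- jx + sum(qx^2)
    jy <- jy + sum(qy^2)
  }
  if (jxy == 0) return(Inf)
  max(0, -log(jxy / sqrt(jx * jy)))
}
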