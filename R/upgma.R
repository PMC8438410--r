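#' UPGMA clustering of a distance matrix
#'
#' Unweighted pair-group method with arithmetic mean: the closest pair of
#' clusters is merged repeatedly, the distance from a merged cluster to any
#' other being the size-weighted arithmetic mean of its members' distances.
#' The resulting tree is ultrametric; a node joining two clusters at
#' distance \eqn{d_{min}} is placed at height \eqn{d_{min}/2}, so the path
#' height between two leaves equals half their cophenetic distance.
#'
#' Ties in the minimum distance are broken deterministically by the lowest
#' (row, column) index pair, so the tree is a pure function of the input
#' order.
#'
#' @param d a [stats::dist] object or symmetric numeric matrix with zero
#'   diagonal and finite non-negative entries; labels become leaf labels.
#' @return an object of class `"upgma"`: list with `merge` (n-1 x 2 matrix,
#'   [stats::hclust] convention: negative entries are leaves, positive
#'   entries earlier merge rows), `height` (node heights, i.e. half the
#'   merge distances) and `labels`.
#' @examples
#' d <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3,
#'             dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
#' to_newick(upgma(d))  # ((A:1,B:1):1,C:2);
#' @seealso [to_newick()], [cherries()], [stats::as.hclust()]
#' @export
upgma <- function(d) {
  D <- as.matrix(d)
  n <- nrow(D)
  if (n < 2L) stop("need at least 2 items")
  if (any(!is.finite(D))) stop("distance matrix has non-finite entries")
  if (max(abs(D - t(D))) > 1e-12) stop("distance matrix is not symmetric")
  labels <- rownames(D)
  if (is.null(labels)) labels <- as.character(seq_len(n))
  diag(D) <- Inf
  node <- -seq_len(n)          # slot -> node code (hclust convention)
  size <- rep(1L, n)
  active <- rep(TRUE, n)
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  for (m in seq_len(n - 1L)) {
    # merged rows/cols and the diagonal are Inf. The column-major first
    # minimum of the symmetric matrix is the tied pair with the lowest
    # (row, column) indices: pair {a, b}, a < b, is first met at column a.
    idx <- which.min(D)
    r <- (idx - 1L) %% n + 1L
    c <- (idx - 1L) %/% n + 1L
    i <- min(r, c); j <- max(r, c)
    mn <- D[i, j]
    merge[m, ] <- c(node[i], node[j])   # i < j: earlier slot first
    height[m] <- mn / 2
    w <- size[i] + size[j]
    upd <- active; upd[c(i, j)] <- FALSE
    D[i, upd] <- D[upd, i] <- (size[i] * D[i, upd] + size[j] * D[j, upd]) / w
    D[j, ] <- D[, j] <- Inf
    active[j] <- FALSE
    size[i] <- w
    node[i] <- m
  }
  structure(list(merge = merge, height = height, labels = labels),
            class = "upgma")
}

#' @export
print.upgma <- function(x, ...) {
  cat(sprintf("UPGMA tree: %d leaves, root height %.4g\n",
              length(x$labels), max(x$height)))
  invisible(x)
}

#' Cherries of a UPGMA tree
#'
#' A cherry is an internal node whose two children are both leaves: the
#' tightest groups in the dendrogram and the removal unit of stepwise core
#' selection (see [stepwise_core()]).
#'
#' @param t an [upgma()] tree
#' @return data frame with columns `leaf1`, `leaf2` (labels) and `height`,
#'   ordered by increasing height (most redundant pair first)
#' @export
cherries <- function(t) {
  is_cherry <- t$merge[, 1L] < 0L & t$merge[, 2L] < 0L
  out <- data.frame(leaf1 = t$labels[-t$merge[is_cherry, 1L]],
                    leaf2 = t$labels[-t$merge[is_cherry, 2L]],
                    height = t$height[is_cherry],
                    stringsAsFactors = FALSE)
  out[order(out$height), , drop = FALSE]
}

#' Serialize a UPGMA tree to Newick
#'
#' Branch lengths are parent height minus child height (leaves have height
#' zero), so leaf-to-root path lengths equal the root height and the string
#' parses back (e.g. with \pkg{ape}) to an ultrametric tree with the same
#' cophenetic structure.
#'
#' @param t an [upgma()] tree
#' @param digits significant digits for branch lengths
#' @return a single Newick string terminated by ";"
#' @export
to_newick <- function(t, digits = 10L) {
  n <- length(t$labels)
  fmt <- function(x) sprintf(paste0("%.", digits, "g"), x)
  str <- character(n - 1L)
  part <- function(code, parent_h) {
    if (code < 0L)
      paste0(t$labels[-code], ":", fmt(parent_h))
    else
      paste0(str[code], ":", fmt(parent_h - t$height[code]))
  }
  for (m in seq_len(n - 1L))
    str[m] <- paste0("(", part(t$merge[m, 1L], t$height[m]), ",",
                     part(t$merge[m, 2L], t$height[m]), ")")
  paste0(str[n - 1L], ";")
}

#' Convert to hclust
#'
#' Heights follow the [stats::hclust] convention (the merge distance, i.e.
#' twice the node height used here).
#'
#' @param x an [upgma()] tree
#' @param ... ignored
#' @export
as.hclust.upgma <- function(x, ...) {
  n <- length(x$labels)
  leafset <- vector("list", n - 1L)
  for (m in seq_len(n - 1L)) {
    get <- function(code) if (code < 0L) -code else leafset[[code]]
    leafset[[m]] <- c(get(x$merge[m, 1L]), get(x$merge[m, 2L]))
  }
  structure(list(merge = x$merge, height = 2 * x$height,
                 order = leafset[[n - 1L]], labels = x$labels,
                 method = "upgma", call = match.call(),
                 dist.method = "allele-sharing"),
            class = "hclust")
}
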