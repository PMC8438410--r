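#' Stepwise-clustering extraction of a core collection
#'
#' One round of stepwise clustering computes allele-sharing distances on the
#' current accession set, builds the UPGMA dendrogram, finds every cherry
#' (pair of accessions joined at the lowest level, i.e. the most similar
#' groups) and removes one member of each cherry uniformly at random;
#' accessions not in a cherry are retained. The reduced set is re-clustered
#' and the procedure repeats. When a full round would undershoot the target
#' size, only enough cherries are processed to land exactly on it, taking
#' cherries in order of increasing height (the most redundant pairs first).
#' Exact duplicates (distance zero) are always cherries at height zero, so
#' duplicated material is thinned before anything else.
#'
#' @param x an [ssr_matrix()] of the full collection
#' @param target_fraction fraction of accessions to retain; the core size is
#'   `ceiling(target_fraction * N)`. Exactly one of `target_fraction` and
#'   `size` must be given.
#' @param size absolute core size (overrides the ceiling arithmetic)
#' @param seed integer seed making the random cherry choices reproducible
#' @param min_na_retention optional guard in (0, 100]: stop removing (with a
#'   warning) if the next round would push mean-Na retention below this
#'   percentage of the full collection
#' @return an object of class `"core_collection"`: list with `selected`
#'   (accession ids), `target`, `fraction`, `seed`, `rounds` (list of ids
#'   removed per round), `stats` (per-locus panel of the core, see
#'   [locus_stats_table()]) and `retention` (named percentages of the full
#'   collection's mean Na, Ho, Nei and PIC)
#' @examples
#' cfg <- sim_config(n = 40, allele_counts = rep(4, 8), seed = 7)
#' m <- simulate_ssr(cfg)$matrix
#' core <- stepwise_core(m, target_fraction = 0.25, seed = 1)
#' core$retention
#' @seealso [random_cores()], [compare_collections()]
#' @export
stepwise_core <- function(x, target_fraction = NULL, size = NULL, seed = NULL,
                          min_na_retention = NULL) {
  n <- length(x$ids)
  if (is.null(size) == is.null(target_fraction))
    stop("give exactly one of 'target_fraction' or 'size'")
  if (!is.null(target_fraction)) {
    if (target_fraction <= 0 || target_fraction > 1)
      stop("'target_fraction' must be in (0, 1]")
    size <- as.integer(ceiling(target_fraction * n))
  } else {
    target_fraction <- size / n
  }
  if (size < 1L || size > n)
    stop("target size ", size, " outside 1..", n)
  if (!is.null(seed)) set.seed(seed)

  full_means <- mean_locus_stats(x)
  keep <- x$ids
  rounds <- list()
  while (length(keep) > size) {
    cur <- x[keep, ]
    tr <- upgma(allele_sharing_dist(cur))
    ch <- cherries(tr)  # ordered by height, most redundant first
    excess <- length(keep) - size
    if (nrow(ch) > excess) ch <- ch[seq_len(excess), , drop = FALSE]
    pick <- ifelse(stats::runif(nrow(ch)) < 0.5, ch$leaf1, ch$leaf2)
    if (!is.null(min_na_retention)) {
      cand <- setdiff(keep, pick)
      ret_na <- 100 * mean_locus_stats(x[cand, ])[["Na"]] / full_means[["Na"]]
      if (ret_na < min_na_retention) {
        warning(sprintf(
          "stopped at %d accessions: next round would drop Na retention to %.1f%%",
          length(keep), ret_na))
        break
      }
    }
    rounds[[length(rounds) + 1L]] <- pick
    keep <- setdiff(keep, pick)
  }
  core <- x[keep, ]
  core_means <- mean_locus_stats(core)
  structure(list(selected = keep, target = size,
                 fraction = target_fraction, seed = seed, rounds = rounds,
                 stats = locus_stats_table(core),
                 retention = retention(core_means, full_means)),
            class = "core_collection")
}

#' @export
print.core_collection <- function(x, ...) {
  cat(sprintf("core collection: %d accessions (%.1f%%), %d removal rounds\n",
              length(x$selected), 100 * x$fraction, length(x$rounds)))
  cat("retention vs full collection (%):\n")
  print(round(x$retention, 1))
  invisible(x)
}

#' Random pseudo-core collections
#'
#' Uniform samples of accessions without replacement, the null benchmark
#' against which a stepwise core's diversity retention is judged.
#'
#' @param x an [ssr_matrix()]
#' @param size accessions per pseudo-core
#' @param reps number of pseudo-cores
#' @param seed integer seed; the same seed reproduces the same subsets
#' @return list of `reps` character vectors of accession ids
#' @export
random_cores <- function(x, size, reps = 3L, seed = NULL) {
  n <- length(x$ids)
  if (size > n) stop("size ", size, " exceeds collection size ", n)
  if (reps < 1L) stop("'reps' must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(reps), function(i) sample(x$ids, size))
}

#' Diversity retention of a core relative to the full collection
#'
#' @param core_means,full_means named numeric vectors of collection-level
#'   mean statistics over the same locus panel (see [mean_locus_stats()]);
#'   only names present in both are compared
#' @return named vector of percentages, 100 * core / full, rounded to 1
#'   decimal place
#' @examples
#' retention(c(Na = 3.5, Ho = 0.2351), c(Na = 3.7143, Ho = 0.2382))
#' @export
retention <- function(core_means, full_means) {
  keep <- intersect(names(core_means), names(full_means))
  keep <- setdiff(keep, "n")
  if (!length(keep)) stop("no shared statistic names")
  if (any(full_means[keep] == 0))
    stop("full-collection mean is zero for: ",
         paste(keep[full_means[keep] == 0], collapse = ", "))
  round(100 * core_means[keep] / full_means[keep], 1)
}

#' Compare diversity of a core against pseudo-cores
#'
#' For each statistic (Na, Ho, Nei's gene diversity, PIC) the per-locus
#' values of every collection form the observations, with loci as the
#' replicate unit. Two tests are reported per statistic: a one-way ANOVA of
#' value against collection, and a distribution-free permutation test that
#' reshuffles collection labels within each locus (loci as blocks) and
#' recomputes the ANOVA F statistic.
#'
#' @param x an [ssr_matrix()] covering all accessions involved
#' @param collections named list of accession id vectors (e.g. the stepwise
#'   core first, then the pseudo-cores); at least 2
#' @param n_perm number of label permutations (default 9999)
#' @param seed integer seed for the permutations
#' @return a list with `means` (collection x statistic matrix of
#'   collection-level means) and `tests` (data frame with columns
#'   `statistic`, `F`, `p_anova`, `p_perm`)
#' @export
compare_collections <- function(x, collections, n_perm = 9999L, seed = NULL) {
  if (length(collections) < 2L) stop("need at least 2 collections")
  if (length(x$markers) < 2L) stop("need at least 2 loci")
  if (is.null(names(collections)))
    names(collections) <- paste0("collection", seq_along(collections))
  if (!is.null(seed)) set.seed(seed)
  stat_cols <- c("Na", "Ho", "Nei", "PIC")
  tabs <- lapply(collections, function(ids)
    locus_stats_table(x[ids, ], mean_row = FALSE))
  means <- t(vapply(tabs, function(tb) colMeans(tb[, stat_cols]),
                    numeric(length(stat_cols))))
  grp <- factor(rep(names(collections), each = length(x$markers)),
                levels = names(collections))
  tests <- lapply(stat_cols, function(sc) {
    y <- unlist(lapply(tabs, function(tb) tb[[sc]]), use.names = FALSE)
    f_obs <- anova_f(y, grp)
    if (is.na(f_obs)) {   # no variance at all: collections identical
      return(data.frame(statistic = sc, F = 0, p_anova = 1, p_perm = 1))
    }
    p_anova <- stats::pf(f_obs, nlevels(grp) - 1L,
                         length(y) - nlevels(grp), lower.tail = FALSE)
    ymat <- matrix(y, nrow = length(x$markers))  # loci x collections
    hits <- 0L
    for (b in seq_len(n_perm)) {
      yp <- t(apply(ymat, 1L, sample))           # shuffle within locus
      fp <- anova_f(as.vector(yp), grp)          # column-major = per collection
      if (!is.na(fp) && fp >= f_obs - 1e-12) hits <- hits + 1L
    }
    data.frame(statistic = sc, F = f_obs, p_anova = p_anova,
               p_perm = (hits + 1L) / (n_perm + 1L))
  })
  list(means = means, tests = do.call(rbind, tests))
}

# one-way ANOVA F; NA when there is no residual variance
anova_f <- function(y, grp) {
  gm <- tapply(y, grp, mean)
  ssb <- sum(tabulate(grp) * (gm - mean(y))^2)
  ssw <- sum((y - gm[grp])^2)
  dfb <- nlevels(grp) - 1L
  dfw <- length(y) - nlevels(grp)
  if (ssw <= 1e-24 && ssb <= 1e-24) return(NA_real_)
  if (ssw <= 1e-24) return(Inf)
  (ssb / dfb) / (ssw / dfw)
}
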