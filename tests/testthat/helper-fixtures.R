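# build an ssr_matrix from named character rows, e.g.
#   mk(a = c("AB", "AA"), b = c("AB", "BC"), markers = c("s1", "s2"))
mk <- function(..., markers = NULL) {
  rows <- list(...)
  g <- do.call(rbind, rows)
  if (is.null(markers)) markers <- paste0("s", seq_len(ncol(g)))
  dimnames(g) <- list(names(rows), markers)
  ssr_matrix(g)
}

# independent UPGMA oracle: cluster-to-cluster distance recomputed each step
# as the plain mean of the ORIGINAL pairwise distances across the two
# clusters (equivalent formulation of the size-weighted update), clusters
# stored as index sets. Returns the cophenetic matrix (leaf-pair merge
# distances).
naive_upgma_cophenetic <- function(D) {
  D <- as.matrix(D)
  n <- nrow(D)
  clusters <- as.list(seq_len(n))
  coph <- matrix(0, n, n, dimnames = dimnames(D))
  while (length(clusters) > 1L) {
    best <- NULL
    bd <- Inf
    for (a in seq_along(clusters)) for (b in seq_along(clusters)) {
      if (a >= b) next
      d_ab <- mean(D[clusters[[a]], clusters[[b]]])
      if (d_ab < bd - 1e-15) { bd <- d_ab; best <- c(a, b) }
    }
    for (i in clusters[[best[1L]]]) for (j in clusters[[best[2L]]])
      coph[i, j] <- coph[j, i] <- bd
    clusters[[best[1L]]] <- c(clusters[[best[1L]]], clusters[[best[2L]]])
    clusters[[best[2L]]] <- NULL
  }
  coph
}

# cophenetic matrix of a package UPGMA tree, in label order of `labels`
upgma_cophenetic <- function(t) {
  n <- length(t$labels)
  leafset <- vector("list", n - 1L)
  coph <- matrix(0, n, n, dimnames = list(t$labels, t$labels))
  for (m in seq_len(n - 1L)) {
    get <- function(code) if (code < 0L) -code else leafset[[code]]
    l1 <- get(t$merge[m, 1L]); l2 <- get(t$merge[m, 2L])
    coph[l1, l2] <- coph[l2, l1] <- 2 * t$height[m]
    leafset[[m]] <- c(l1, l2)
  }
  coph
}

# brute-force per-locus statistics by explicit genotype loops
brute_locus_stats <- function(x, locus) {
  g <- genotype_strings(x)[, locus]
  g <- g[!is.na(g)]
  n <- length(g)
  copies <- unlist(strsplit(g, ""))
  cnt <- table(copies)
  p <- as.numeric(cnt) / (2 * n)
  het <- sum(substr(g, 1, 1) != substr(g, 2, 2)) / n
  D <- 1 - sum(p^2)
  pic_bf <- 1 - sum(p^2)
  for (i in seq_along(p)) for (j in seq_along(p)) {
    if (i < j) pic_bf <- pic_bf - 2 * p[i]^2 * p[j]^2
  }
  list(n = n, p = p, Na = length(p), Ho = het, D = D,
       He = 2 * n / (2 * n - 1) * D, I = -sum(p * log(p)), PIC = pic_bf)
}

# a small random valid matrix for property tests
random_matrix <- function(n = 8, loci = 5, seed = 1, missing_rate = 0.1) {
  set.seed(seed)
  cfg <- sim_config(n = n, allele_counts = sample(2:5, loci, replace = TRUE),
                    k = 1, fis = 0.3, missing_rate = missing_rate,
                    seed = seed)
  simulate_ssr(cfg)$matrix
}
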