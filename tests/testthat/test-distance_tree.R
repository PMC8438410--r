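test_that("allele-sharing distance counts shared alleles with multiplicity", {
  m <- mk(a = c("AB", "CC"), b = c("AB", "CC"))
  expect_equal(as.vector(allele_sharing_dist(m)), 0)

  m2 <- mk(a = c("AA", "BB"), b = c("BB", "AA"))
  expect_equal(as.vector(allele_sharing_dist(m2)), 1)

  m3 <- mk(a = "AB", b = "AC", markers = "s1")
  expect_equal(as.vector(allele_sharing_dist(m3)), 0.5)

  # AA vs AB share one allele of two
  m4 <- mk(a = "AA", b = "AB", markers = "s1")
  expect_equal(as.vector(allele_sharing_dist(m4)), 0.5)
})

test_that("missing loci are dropped pairwise, empty intersections error", {
  m <- mk(a = c("AA", "BB", NA), b = c("AA", NA, "CC"))
  expect_equal(as.vector(allele_sharing_dist(m)), 0)  # only s1 shared

  m2 <- mk(a = c("AA", NA), b = c(NA, "BB"))
  expect_error(allele_sharing_dist(m2), "no commonly typed locus")
})

test_that("Nei 1972 distance has its closed-form values and Inf flag", {
  fx <- list(s1 = c(A = 1, B = 0))
  expect_equal(nei_1972_distance(fx, fx), 0)
  fy <- list(s1 = c(A = 0, B = 1))
  expect_equal(nei_1972_distance(fx, fy), Inf)
  fz <- list(s1 = c(A = 0.5, B = 0.5))
  expect_equal(nei_1972_distance(fx, fz), -log(0.5 / sqrt(0.5)))
  expect_equal(round(nei_1972_distance(fx, fz), 4), 0.3466)
  expect_error(nei_1972_distance(fx, list(s9 = c(A = 1))), "same loci")
})

test_that("UPGMA reproduces the worked 3-leaf example", {
  d <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  t <- upgma(d)
  expect_equal(sort(t$height), c(1, 2))
  expect_equal(to_newick(t), "((A:1,B:1):1,C:2);")

  d2 <- matrix(c(0, 3, 3, 0), 2, dimnames = list(c("x", "y"), c("x", "y")))
  t2 <- upgma(d2)
  expect_equal(t2$height, 1.5)
  expect_equal(to_newick(t2), "(x:1.5,y:1.5);")
})

test_that("ties are broken by the lowest index pair", {
  d <- matrix(1, 4, 4); diag(d) <- 0
  dimnames(d) <- list(letters[1:4], letters[1:4])
  t <- upgma(d)
  expect_equal(t$height, rep(0.5, 3))
  expect_equal(t$merge[1, ], c(-1L, -2L))   # first merge is (a, b)
})

test_that("UPGMA agrees with an independent naive oracle for n <= 7", {
  for (seed in 1:8) {
    set.seed(200 + seed)
    n <- sample(3:7, 1)
    x <- matrix(rnorm(n * 3), n)
    rownames(x) <- paste0("L", seq_len(n))
    D <- as.matrix(dist(x))
    t <- upgma(D)
    expect_equal(upgma_cophenetic(t)[rownames(D), colnames(D)],
                 naive_upgma_cophenetic(D), tolerance = 1e-12)
  }
})

test_that("UPGMA matches average-linkage hclust heights on random input", {
  set.seed(5)
  d <- dist(matrix(rnorm(60), 12))
  t <- upgma(d)
  h <- hclust(d, method = "average")
  expect_equal(sort(2 * t$height), sort(h$height))
  expect_equal(as.matrix(cophenetic(as.hclust(t))), as.matrix(cophenetic(h)))
})

test_that("already-ultrametric distances are reproduced exactly", {
  d <- matrix(c(0, 2, 8, 8,
                2, 0, 8, 8,
                8, 8, 0, 4,
                8, 8, 4, 0), 4, dimnames = list(letters[1:4], letters[1:4]))
  t <- upgma(d)
  expect_equal(upgma_cophenetic(t)[letters[1:4], letters[1:4]], d)
})

test_that("tree is invariant to input order up to label permutation", {
  m <- random_matrix(n = 10, loci = 6, seed = 31)
  d <- allele_sharing_dist(m)
  perm <- c(4, 1, 9, 2, 10, 3, 7, 5, 8, 6)
  d2 <- allele_sharing_dist(m[perm, ])
  c1 <- upgma_cophenetic(upgma(d))
  c2 <- upgma_cophenetic(upgma(d2))
  expect_equal(c2[rownames(c1), colnames(c1)], c1, tolerance = 1e-12)
})

test_that("Newick output parses back to the same ultrametric tree", {
  skip_if_not_installed("ape")
  for (seed in 1:4) {
    m <- random_matrix(n = 7, loci = 5, seed = 40 + seed)
    t <- upgma(allele_sharing_dist(m))
    ph <- ape::read.tree(text = to_newick(t))
    expect_s3_class(ph, "phylo")
    coph <- ape::cophenetic.phylo(ph)
    mine <- upgma_cophenetic(t)
    expect_equal(coph[rownames(mine), colnames(mine)], mine,
                 tolerance = 1e-8)
    expect_true(ape::is.ultrametric(ph, tol = 1e-8))
  }
})

test_that("non-finite or asymmetric input is rejected", {
  d <- matrix(c(0, Inf, Inf, 0), 2)
  expect_error(upgma(d), "non-finite")
  d2 <- matrix(c(0, 1, 2, 0), 2)
  expect_error(upgma(d2), "symmetric")
})
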