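test_that("a target fraction of 1 returns the whole collection untouched", {
  m <- random_matrix(n = 10, loci = 5, seed = 50)
  core <- stepwise_core(m, target_fraction = 1, seed = 1)
  expect_equal(core$selected, m$ids)
  expect_equal(length(core$rounds), 0L)
  expect_equal(unname(core$retention), rep(100, length(core$retention)))
})

test_that("exact duplicates are thinned first (one survivor per pair)", {
  g <- rbind(a1 = c("AB", "CC", "AD"), a2 = c("AB", "CC", "AD"),
             b1 = c("AA", "BB", "CC"), b2 = c("AA", "BB", "CC"))
  colnames(g) <- paste0("s", 1:3)
  m <- ssr_matrix(g)
  for (seed in 1:5) {
    core <- stepwise_core(m, target_fraction = 0.5, seed = seed)
    expect_equal(length(core$selected), 2L)
    expect_equal(sum(core$selected %in% c("a1", "a2")), 1L)
    expect_equal(sum(core$selected %in% c("b1", "b2")), 1L)
  }
})

test_that("core size equals ceiling(fraction x N) for random fractions", {
  m <- random_matrix(n = 23, loci = 6, seed = 60)
  set.seed(61)
  for (f in runif(5, 0.1, 0.9)) {
    core <- stepwise_core(m, target_fraction = f, seed = 62)
    expect_equal(length(core$selected), ceiling(f * 23))
  }
  expect_error(stepwise_core(m, size = 50, seed = 1), "outside")
  expect_error(stepwise_core(m, seed = 1), "exactly one")
})

test_that("the same seed replays the identical selection", {
  m <- random_matrix(n = 30, loci = 8, seed = 70)
  c1 <- stepwise_core(m, size = 9, seed = 123)
  c2 <- stepwise_core(m, size = 9, seed = 123)
  expect_identical(c1$selected, c2$selected)
  expect_identical(c1$rounds, c2$rounds)
  c3 <- stepwise_core(m, size = 9, seed = 124)
  expect_equal(length(c3$selected), 9L)
})

test_that("every removal round strictly shrinks the set down to the target", {
  m <- random_matrix(n = 40, loci = 8, seed = 80)
  core <- stepwise_core(m, size = 11, seed = 3)
  sizes <- 40 - cumsum(lengths(core$rounds))
  expect_true(all(diff(c(40, sizes)) < 0))
  expect_equal(sizes[length(sizes)], 11)
})

test_that("random pseudo-cores are uniform, sized and seed-reproducible", {
  m <- random_matrix(n = 20, loci = 5, seed = 90)
  r1 <- random_cores(m, size = 7, reps = 3, seed = 5)
  r2 <- random_cores(m, size = 7, reps = 3, seed = 5)
  expect_identical(r1, r2)
  expect_true(all(lengths(r1) == 7))
  expect_true(all(vapply(r1, function(s) !anyDuplicated(s), TRUE)))
  expect_equal(sort(random_cores(m, size = 20, reps = 1, seed = 1)[[1]]),
               sort(m$ids))
  expect_error(random_cores(m, size = 21), "exceeds")
})

test_that("retention percentages reproduce the reference-panel arithmetic", {
  means <- akebia_collection_means()
  full <- unlist(means[means$collection == "full", -1])
  core <- unlist(means[means$collection == "core", -1])
  ret <- retention(core, full)
  expect_equal(unname(ret[c("Na", "Ho", "Nei")]), c(94.2, 98.7, 116.4))
  expect_equal(unname(retention(full, full)), rep(100, 4))
  expect_error(retention(c(Na = 1), c(Na = 0)), "zero")
})

test_that("identical collections give F = 0 and permutation p = 1", {
  m <- random_matrix(n = 16, loci = 6, seed = 95)
  ids <- m$ids[1:8]
  cmp <- compare_collections(m, list(a = ids, b = ids, c = ids),
                             n_perm = 99, seed = 1)
  expect_equal(cmp$tests$F, rep(0, 4))
  expect_equal(cmp$tests$p_perm, rep(1, 4))
  expect_equal(cmp$tests$p_anova, rep(1, 4))
})

test_that("a dominant diversity difference yields small p-values", {
  # two internally variable accession groups vs a monomorphic-ish group:
  # per-locus Nei/PIC strictly higher in the diverse collections
  g_div <- c("AB", "CD", "AC", "BD", "AD", "BC")
  g_mono <- rep("AA", 6)
  rows <- c(lapply(1:6, function(i) g_div[c(i:6, seq_len(i - 1))]),
            lapply(1:6, function(i) g_mono))
  names(rows) <- c(paste0("d", 1:6), paste0("m", 1:6))
  g <- do.call(rbind, rows)
  colnames(g) <- paste0("s", 1:6)
  m <- ssr_matrix(g)
  cmp <- compare_collections(m, list(div = paste0("d", 1:6),
                                     mono = paste0("m", 1:6)),
                             n_perm = 499, seed = 2)
  nei_row <- cmp$tests[cmp$tests$statistic == "Nei", ]
  expect_lt(nei_row$p_anova, 0.001)
  # within-locus shuffling of 2 labels over 6 loci has 2^6 distinct
  # permutations, so the attainable floor is about 1/64
  expect_lt(nei_row$p_perm, 0.05)
  expect_gt(cmp$means["div", "Nei"], cmp$means["mono", "Nei"])
})

test_that("the retention floor guard stops removal with a warning", {
  m <- random_matrix(n = 30, loci = 6, seed = 99)
  expect_warning(
    core <- stepwise_core(m, size = 2, seed = 4, min_na_retention = 95),
    "retention")
  expect_gt(length(core$selected), 2L)
})
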