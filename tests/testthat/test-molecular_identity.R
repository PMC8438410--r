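test_that("the printed code map is honoured", {
  expect_equal(encode_genotype(c("AA", "BB", "CC", "DD")), c("1", "2", "3", "4"))
  expect_equal(encode_genotype(c("AB", "AC", "AD", "BC", "BD", "CD")),
               c("A", "B", "C", "D", "E", "F"))
  expect_equal(encode_genotype(c(NA, "--")), c("0", "0"))
  expect_equal(decode_char(c("D", "0", "F", "1")), c("BC", NA, "CD", "AA"))
})

test_that("codes beyond the four-allele block extend without disturbing it", {
  expect_equal(encode_genotype("EE"), "5")
  expect_equal(encode_genotype("II"), "9")
  # first appended heterozygote is A/E, in lexicographic order after C/D
  expect_equal(encode_genotype("AE"), "G")
  expect_equal(encode_genotype("AF"), "H")
  expect_error(encode_genotype("AJ"), "not representable")  # 10th allele
  expect_error(decode_char("!"), "unknown")
})

test_that("encode/decode is a bijection over the full 9-allele alphabet", {
  states <- c(paste0(LETTERS[1:9], LETTERS[1:9]),
              apply(which(upper.tri(diag(9)), arr.ind = TRUE), 1,
                    function(ij) paste0(LETTERS[min(ij)], LETTERS[max(ij)])))
  codes <- encode_genotype(states)
  expect_equal(anyDuplicated(codes), 0L)
  expect_false("0" %in% codes)
  expect_equal(decode_char(codes), states)
})

test_that("greedy selection returns the minimal PIC-ordered prefix", {
  # s1 (highest PIC) separates {a,b} from {c,d}; s2 splits both pairs;
  # s3 is nearly uninformative. No single marker suffices.
  m <- mk(a = c("AB", "AA", "AA"),
          b = c("AB", "BB", "AA"),
          c = c("CC", "AA", "AA"),
          d = c("CC", "BB", "AB"))
  sch <- select_discriminating_markers(m)
  expect_true(sch$complete)
  expect_equal(sch$markers, c("s1", "s2"))
  expect_equal(sch$markers, sch$order[seq_along(sch$markers)])
  # brute force: every single marker leaves collisions
  for (mk_id in m$markers)
    expect_false(verify_uniqueness(build_identities(m, mk_id))$unique)
})

test_that("a single fully discriminating marker is chosen alone", {
  m <- mk(a = c("AB", "AA"), b = c("AC", "AA"), c = c("BC", "AA"))
  sch <- select_discriminating_markers(m)
  expect_equal(sch$markers, "s1")
  expect_true(sch$complete)
})

test_that("identical accessions are reported as collisions, not an error", {
  m <- mk(a = c("AB", "CC"), b = c("AB", "CC"), c = c("AA", "CC"))
  sch <- select_discriminating_markers(m)
  expect_false(sch$complete)
  expect_equal(sch$markers, sch$order)
  expect_equal(sch$collisions, list(c("a", "b")))
})

test_that("identity strings follow the scheme order; missing codes to 0", {
  # accession with the published genotype profile of TJ2
  g <- rbind(TJ2 = c("BC", "AA", NA, NA, "BB", "CC", "BB", "BB", "AA", NA, NA))
  colnames(g) <- c("s28", "s25", "s74", "s89", "s68", "s30", "s13", "s100",
                   "s72", "s77", "s3")
  onerow <- rbind(g, other = c("AA", "AA", "AA", "AA", "AA", "AA", "AA",
                               "AA", "AA", "AA", "AA"))
  m <- ssr_matrix(onerow)
  ident <- build_identities(m, colnames(g))
  expect_equal(unname(ident["TJ2"]), "D1002322100")

  m2 <- mk(a = "AB", markers = "s1")
  expect_equal(unname(build_identities(m2, "s1")), "A")

  m3 <- mk(a = c(NA, NA), b = c("AA", "AA"))
  expect_equal(unname(build_identities(m3, m3$markers)["a"]), "00")
})

test_that("uniqueness verification groups duplicates", {
  ids <- c(x = "D1002322100", y = "D1002322100", z = "A0000000000")
  v <- verify_uniqueness(ids)
  expect_false(v$unique)
  expect_equal(v$duplicates, list(c("x", "y")))
  expect_true(verify_uniqueness(character(0))$unique)
})

test_that("the packaged 164-accession panel round-trips bit-exactly", {
  m <- akebia_core_matrix()
  expect_equal(dim(m), c(164L, 11L))
  ident <- build_identities(m, akebia_identity_markers())
  expect_identical(ident, attr(m, "identity"))
  expect_true(verify_uniqueness(ident)$unique)
  expect_equal(genotype_strings(m)["TJ2", "s28"], "BC")
})

test_that("decode_identities rejects ragged or mismatched input", {
  expect_error(decode_identities(c(a = "12", b = "123"), c("s1", "s2")),
               "length")
})
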