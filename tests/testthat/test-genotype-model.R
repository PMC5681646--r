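test_that("genotype tables parse into profiles with set semantics", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("strain_id\tlocus\tlength",
               "a\tC3\t210", "a\tC4\t150",
               "b\tC3\t204", "b\tC4\t156"), tf)
  set <- readGenotypeTable(tf)
  expect_identical(strainIds(set), c("a", "b"))
  expect_equal(nrow(profileCalls(set, "a")), 2)
  expect_equal(nrow(profileCalls(set, "b")), 2)

  # a duplicated row collapses to the same profile
  tf2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("strain_id\tlocus\tlength",
               "a\tC3\t210", "a\tC3\t210", "a\tC4\t150"), tf2)
  expect_equal(nrow(profileCalls(readGenotypeTable(tf2), "a")), 2)
})

test_that("malformed genotype tables raise informative errors", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("strain_id\tlocus\tlength", "a\tC3\t210", "a\tC4\t-3"), tf)
  expect_error(readGenotypeTable(tf), "line 3")

  tf2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("strain_id\tlocus", "a\tC3"), tf2)
  expect_error(readGenotypeTable(tf2), "length")

  tf3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("strain_id\tlocus\tlength", "a\tWEIRD\t210"), tf3)
  expect_error(readGenotypeTable(tf3, panel = ssrPanel()), "WEIRD")
})

test_that("genotype tables round-trip through write/read", {
  set <- makeSet(s1 = list(C3 = c(210, 216), C4 = 150),
                 s2 = list(C3 = 204))
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeGenotypeTable(set, tf)
  back <- readGenotypeTable(tf)
  expect_identical(profileCalls(back), profileCalls(set))
})

test_that("meta-profile queries read per sample", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tlocus\tlength",
               "m1\tC3\t210", "m1\tC3\t204", "m2\tC4\t150"), tf)
  qs <- readMetaProfiles(tf)
  expect_named(qs, c("m1", "m2"))
  expect_equal(nrow(profileCalls(qs$m1)), 2)
})

test_that("more than two alleles per strain/locus warns but validates", {
  df <- data.frame(strain_id = "a", locus = "C3",
                   length = c(100, 103, 106))
  expect_warning(StrainProfileSet(df), "more than 2")
})

test_that("allele universe is the sorted union over reference and query", {
  set <- makeSet(s1 = list(L1 = 10), s2 = list(L1 = 12))
  expect_equal(length(buildUniverse(set)), 2)

  # idempotent union: identical strains add nothing
  twins <- makeSet(s1 = list(L1 = c(10, 12), L2 = 30),
                   s2 = list(L1 = c(10, 12), L2 = 30))
  expect_equal(length(buildUniverse(twins)), 3)

  # query-only alleles are included
  q <- metaProfile(alleleCalls("L2", 30), "q")
  u <- buildUniverse(set, q)
  expect_equal(length(u), 3)
  expect_true(any(profileCalls(u)$locus == "L2"))

  # deterministic ordering
  e <- profileCalls(u)
  expect_identical(order(e$locus, e$length), seq_len(nrow(e)))

  expect_error(buildUniverse(list()), "empty")
})

test_that("encoding is positional and invertible", {
  u <- buildUniverse(list(alleleCalls(rep("L1", 5),
                                      c(10, 12, 14, 16, 18))))
  prof <- alleleCalls(c("L1", "L1"), c(10, 16))   # entries 1 and 4
  expect_identical(encodeProfile(prof, u), c(1L, 0L, 0L, 1L, 0L))
  expect_identical(encodeProfile(profileCalls(u), u), rep(1L, 5))
  expect_identical(encodeProfile(alleleCalls(), u), rep(0L, 5))
  expect_error(encodeProfile(alleleCalls("L9", 1), u), "outside")

  # round-trip over seeded random profiles
  set.seed(7)
  for (i in 1:20) {
    keep <- sample(c(TRUE, FALSE), 5, replace = TRUE)
    p <- profileCalls(u)[keep, , drop = FALSE]
    expect_identical(decodeProfile(encodeProfile(p, u), u),
                     alleleCalls(p$locus, p$length))
  }
})

test_that("binary matrix columns are strain profiles", {
  set <- makeSet(s1 = list(L1 = c(10, 12), L2 = 30),
                 s2 = list(L1 = 12, L2 = c(30, 33)))
  u <- buildUniverse(set)
  X <- encodeReference(set, u)
  counts <- table(profileCalls(set)$strain_id)
  expect_equal(unname(colSums(X)), as.vector(counts[colnames(X)]))

  # invariant under strain reordering, up to column permutation
  X2 <- encodeReference(set[c("s2", "s1")], u)
  expect_identical(X2[, c("s1", "s2")], X[, c("s1", "s2")])
})

test_that("profile union is a commutative idempotent set union", {
  set <- makeSet(s1 = list(L1 = 10), s2 = list(L1 = 12))
  u12 <- unionProfiles(set)
  expect_equal(nrow(profileCalls(u12)), 2)
  expect_identical(profileCalls(unionProfiles(set, c("s1", "s1"))),
                   profileCalls(unionProfiles(set, "s1")))
  expect_identical(profileCalls(unionProfiles(set, c("s2", "s1"))),
                   profileCalls(u12))
  expect_error(unionProfiles(list()), "empty")

  # inclusion-exclusion on a hand-built overlapping fixture
  a <- alleleCalls(c("L1", "L1", "L2"), c(10, 12, 30))
  b <- alleleCalls(c("L1", "L2", "L2"), c(12, 30, 33))
  c_ <- alleleCalls(c("L1", "L2", "L3"), c(10, 30, 50))
  pair_int <- function(x, y) {
    d <- profileDifference(x, y)
    (d$n_a + d$n_b - d$n_diff) / 2
  }
  triple <- 1  # (L2,30) is in all three, by construction
  expected <- 3 + 3 + 3 - pair_int(a, b) - pair_int(a, c_) -
    pair_int(b, c_) + triple
  expect_equal(nrow(profileCalls(unionProfiles(list(a, b, c_)))),
               expected)
})

test_that("profile difference is a symmetric set distance", {
  x <- alleleCalls(rep("L", 4), c(1, 2, 3, 4))
  y <- alleleCalls(rep("L", 4), c(1, 2, 3, 5))
  expect_equal(profileDifference(x, x)$n_diff, 0)
  expect_equal(profileDifference(x, y)$n_diff, 2)
  expect_equal(profileDifference(alleleCalls(),
                                 alleleCalls(rep("L", 7), 1:7))$n_diff, 7)
  expect_equal(profileDifference(x, y)$n_diff,
               profileDifference(y, x)$n_diff)

  # triangle inequality on seeded random triples
  set.seed(11)
  pool <- alleleCalls(rep(c("L1", "L2"), each = 6), rep(1:6, 2))
  for (i in 1:30) {
    tri <- lapply(1:3, function(j)
      pool[sample(12, sample(0:12, 1)), , drop = FALSE])
    d <- function(p, q) profileDifference(p, q)$n_diff
    expect_lte(d(tri[[1]], tri[[3]]),
               d(tri[[1]], tri[[2]]) + d(tri[[2]], tri[[3]]))
  }
})

test_that("locus panel files read and restrict", {
  tf <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("C3", "C4", ""), tf)
  expect_identical(readLocusPanel(tf), c("C3", "C4"))

  set <- makeSet(s1 = list(C3 = 100, C4 = 200, C6 = 300))
  r <- restrictLoci(set, c("C3", "C4"))
  expect_identical(sort(unique(profileCalls(r)$locus)), c("C3", "C4"))
  expect_error(restrictLoci(set, "NOPE"), "unknown locus")
})
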