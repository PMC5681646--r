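chordMax <- 2 * sqrt(2) / pi

test_that("per-strain locus frequencies are uniform over scored alleles", {
  p <- alleleCalls(c("C3", "C4", "C4"), c(100, 200, 206))
  expect_equal(locusFrequencies(p, "C3"), c(`100` = 1.0))
  expect_equal(locusFrequencies(p, "C4"), c(`200` = 0.5, `206` = 0.5))
  expect_length(locusFrequencies(p, "C5"), 0)
  tri <- alleleCalls(rep("C3", 3), c(100, 103, 106))
  expect_equal(unname(locusFrequencies(tri, "C3")), rep(1 / 3, 3))
})

test_that("chord distance matches its closed form", {
  p <- alleleCalls(c("C3", "C4"), c(100, 200))
  expect_equal(chordDistance(p, p), 0)

  # zero shared alleles at every locus -> upper bound
  q <- alleleCalls(c("C3", "C4"), c(103, 203))
  expect_equal(chordDistance(p, q), chordMax, tolerance = 1e-9)

  # one locus, {a} vs {a,b}: sum sqrt(f g) = sqrt(0.5)
  a <- alleleCalls("C3", 100)
  ab <- alleleCalls(c("C3", "C3"), c(100, 103))
  expect_equal(chordDistance(a, ab),
               (2 / pi) * sqrt(2 * (1 - sqrt(0.5))), tolerance = 1e-9)
  expect_equal(round(chordDistance(a, ab), 4), 0.4872)

  # untyped loci are dropped pairwise
  pq <- alleleCalls(c("C3", "C5"), c(100, 300))
  expect_equal(chordDistance(p, pq), 0)  # only C3 shared, identical there
  expect_error(chordDistance(alleleCalls("C3", 1), alleleCalls("C4", 1)),
               "no locus")
})

test_that("chord distance is a bounded semimetric on random profiles", {
  set.seed(19)
  ref <- simulateReference(simulationConfig(n_strains = 30,
                                            n_clusters = 0, seed = 19))
  ids <- strainIds(ref)
  for (i in 1:200) {
    pr <- sample(ids, 2)
    a <- profileCalls(ref, pr[1]); b <- profileCalls(ref, pr[2])
    d <- chordDistance(a, b)
    expect_gte(d, 0); expect_lte(d, chordMax + 1e-12)
    expect_equal(d, chordDistance(b, a))
  }
  expect_equal(chordDistance(profileCalls(ref, ids[1]),
                             profileCalls(ref, ids[1])), 0)
})

test_that("distance matrices are symmetric with zero diagonal", {
  ref <- simulateReference(simulationConfig(n_strains = 6,
                                            n_clusters = 0, seed = 23))
  m <- as.matrix(chordDistanceMatrix(ref))
  expect_identical(rownames(m), strainIds(ref))
  expect_equal(m, t(m))
  expect_true(all(diag(m) == 0))
  expect_true(all(m <= chordMax + 1e-12))
})

test_that("neighbor joining solves the 3-taxon closed form", {
  d <- matrix(c(0, 5, 9, 5, 0, 10, 9, 10, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- njTree(d)
  expect_setequal(tr$tip.label, c("A", "B", "C"))
  # pendant lengths: a = (dAB + dAC - dBC)/2 etc.
  co <- ape::cophenetic.phylo(tr)
  expect_equal(co[c("A", "B", "C"), c("A", "B", "C")],
               d, tolerance = 1e-10)
  expect_error(njTree(d[1:2, 1:2]), "at least 3")
})

test_that("additive matrices are recovered exactly", {
  set.seed(29)
  for (i in 1:10) {
    n <- sample(4:8, 1)
    tr0 <- ape::rtree(n, br = function(k) runif(k, 0.1, 1))
    tr0 <- ape::unroot(tr0)
    d <- ape::cophenetic.phylo(tr0)
    tr <- njTree(d)
    expect_equal(phangorn::RF.dist(tr, tr0), 0)
    co <- ape::cophenetic.phylo(tr)[rownames(d), colnames(d)]
    expect_equal(co, d, tolerance = 1e-8)
  }
})

test_that("identical rows join first with zero-length pendants", {
  d <- matrix(c(0, 0, 8, 8,
                0, 0, 8, 8,
                8, 8, 0, 2,
                8, 8, 2, 0), 4, 4,
              dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  tr <- njTree(d)
  co <- ape::cophenetic.phylo(tr)
  expect_equal(co["A", "B"], 0, tolerance = 1e-10)
  # A and B are siblings
  mrca <- ape::getMRCA(tr, c("A", "B"))
  expect_setequal(
    tr$tip.label[phangorn::Descendants(tr, mrca, "tips")[[1]]],
    c("A", "B"))
})

test_that("midpoint rooting halves the longest leaf-to-leaf path", {
  set.seed(31)
  for (i in 1:5) {
    tr <- ape::unroot(ape::rtree(6, br = function(k) runif(k, 0.1, 2)))
    rooted <- midpointRoot(tr)
    expect_true(ape::is.rooted(rooted))
    d0 <- ape::cophenetic.phylo(tr)
    d1 <- ape::cophenetic.phylo(rooted)[rownames(d0), colnames(d0)]
    expect_equal(d1, d0, tolerance = 1e-10)  # path lengths preserved
    depths <- ape::node.depth.edgelength(rooted)
    tipd <- depths[seq_along(rooted$tip.label)]
    expect_equal(max(tipd), max(d0) / 2, tolerance = 1e-10)
  }

  # zero-length tree: arbitrary rooting with a warning
  tz <- ape::unroot(ape::rtree(4))
  tz$edge.length <- rep(0, nrow(tz$edge))
  expect_warning(rz <- midpointRoot(tz), "zero")
  expect_true(ape::is.rooted(rz))
})

test_that("newick output round-trips, quoting awkward labels", {
  tr <- njTree(matrix(c(0, 2, 3, 2, 0, 3, 3, 3, 0), 3, 3,
                      dimnames = list(c("A", "B", "C"),
                                      c("A", "B", "C"))))
  tf <- withr::local_tempfile(fileext = ".nwk")
  writeNewick(tr, tf)
  txt <- readLines(tf)
  expect_match(txt, "^\\(.*\\);$")
  for (lab in c("A:", "B:", "C:")) expect_match(txt, lab, fixed = TRUE)
  back <- readNewick(tf)
  expect_setequal(back$tip.label, tr$tip.label)
  expect_equal(ape::cophenetic.phylo(back)[c("A", "B", "C"),
                                           c("A", "B", "C")],
               ape::cophenetic.phylo(tr)[c("A", "B", "C"),
                                         c("A", "B", "C")],
               tolerance = 1e-6)

  # labels with spaces are single-quoted and recovered
  tr$tip.label <- c("strain one", "B", "C")
  tf2 <- withr::local_tempfile(fileext = ".nwk")
  writeNewick(tr, tf2)
  expect_match(readLines(tf2), "'strain one'")
  back2 <- readNewick(tf2)
  expect_true("strain one" %in% back2$tip.label)
})

test_that("clone pairs sit closer than unrelated strains", {
  # near-identical pairs (clonal clusters) vs unrelated strains
  ok <- 0L
  for (s in 1:20) {
    ref <- simulateReference(simulationConfig(
      n_strains = 12, n_clusters = 6, within_cluster_mut_prob = 0.05,
      seed = s))
    ids <- strainIds(ref)
    within <- mean(sapply(1:6, function(cl) {
      pair <- ids[c(cl, cl + 6)]  # round-robin cluster assignment
      chordDistance(profileCalls(ref, pair[1]),
                    profileCalls(ref, pair[2]))
    }))
    betw <- mean(replicate(10, {
      pr <- sample(6, 2)  # founders of different clusters
      chordDistance(profileCalls(ref, ids[pr[1]]),
                    profileCalls(ref, ids[pr[2]]))
    }))
    if (within < betw) ok <- ok + 1L
  }
  expect_gte(ok, 20L * 0.99)
})
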