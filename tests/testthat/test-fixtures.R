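# Synthetic fixture generator and the deduplicating molecule split.

test_that("generation is deterministic under (spec, seed)", {
  a <- quietFixtures(15, seed = 42)
  b <- quietFixtures(15, seed = 42)
  f1 <- tempfile(fileext = ".sdf"); f2 <- tempfile(fileext = ".sdf")
  writeLabeledSdf(a, f1); writeLabeledSdf(b, f2)
  expect_identical(readLines(f1), readLines(f2))
  c <- quietFixtures(15, seed = 43)
  expect_false(identical(vapply(a, atomCount, integer(1)),
                         vapply(c, atomCount, integer(1))) &&
               identical(lapply(a, somLabels), lapply(c, somLabels)))
})

test_that("the alpha-carbon rule labels exactly the ether alpha carbons", {
  ether <- pmol("CCOCC", "diethylether")
  expect_equal(somkit:::.ruleLabels(ether), c(2L, 4L))
  # alcohol oxygen (degree 1) does not trigger the ether rule
  ethanol <- pmol("CCO", "ethanol")
  expect_equal(somkit:::.ruleLabels(ethanol), integer(0))
  amine <- pmol("CCNC", "ethylmethylamine")
  expect_equal(somkit:::.ruleLabels(amine), c(2L, 4L))
})

test_that("the aromatic rule labels CH positions ortho to a substituent", {
  tol <- pmol("Cc1ccccc1", "toluene")
  # ring atoms 2..7; ortho positions to the methyl-bearing carbon are 3 and 7
  expect_equal(somkit:::.ruleLabels(tol), c(3L, 7L))
})

test_that("invalid noise levels are rejected by the generator settings", {
  expect_error(fixtureSpec(labelNoise = 0.5), "0.5")
  expect_error(fixtureSpec(labelNoise = -0.1), "0.5")
  expect_s3_class(fixtureSpec(labelNoise = 0.49), "somkit_fixture_spec")
})

test_that("label noise flips labels at the requested rate", {
  clean <- quietFixtures(80, seed = 12, noise = 0)
  noisy <- quietFixtures(80, seed = 12, noise = 0.3)
  flips <- 0L; total <- 0L
  for (i in seq_along(clean)) {
    n <- atomCount(clean[[i]])
    a <- seq_len(n) %in% somLabels(clean[[i]])
    b <- seq_len(n) %in% somLabels(noisy[[i]])
    flips <- flips + sum(a != b)
    total <- total + n
  }
  expect_gt(flips / total, 0.2)
  expect_lt(flips / total, 0.4)
})

test_that("positive-atom prevalence is stable across seeds", {
  prev <- vapply(c(101, 202, 303), function(s) {
    mols <- quietFixtures(200, seed = s)
    mean(unlist(lapply(mols, function(m)
      seq_len(atomCount(m)) %in% somLabels(m))))
  }, numeric(1))
  expect_lt(max(prev) - min(prev), 0.04)
})

test_that("duplicate skeletons are always co-partitioned by the split", {
  mols <- quietFixtures(30, seed = 9)
  withDup <- c(mols, mols[1:3])  # exact duplicate records
  sp <- splitMolecules(withDup, c(0.7, 0.3), seed = 5)
  trainIds <- vapply(sp$train, molId, character(1))
  testIds <- vapply(sp$test, molId, character(1))
  for (i in 1:3) {
    dup <- which(vapply(withDup, function(m)
      identical(atomTable(m), atomTable(mols[[i]])) &&
      identical(bondTable(m), bondTable(mols[[i]])), logical(1)))
    inTrain <- vapply(withDup[dup], molId, character(1)) %in% trainIds
    expect_true(all(inTrain) || all(!inTrain))
  }
})

test_that("fractions control partition sizes on unique skeletons", {
  mols <- quietFixtures(300, seed = 21)
  ids <- somkit:::.canonicalIdentifiers(mols)
  uniq <- mols[!duplicated(ids)][1:100]
  sp <- splitMolecules(uniq, c(0.8, 0.2), seed = 3)
  expect_equal(length(sp$train), 80L)
  expect_equal(length(sp$test), 20L)
  sp2 <- splitMolecules(uniq, c(0.8, 0.2), seed = 3)
  expect_identical(vapply(sp$train, molId, character(1)),
                   vapply(sp2$train, molId, character(1)))
  expect_error(splitMolecules(uniq, c(0.6, 0.2), seed = 1), "sum to 1")
})
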