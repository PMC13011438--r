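# Rooted circular fingerprints: block encoding, count variant, invariants.

test_that("hand-derived fingerprints match the encoding rule", {
  met <- pmol("C", "methane")
  fp <- fameBinaryFingerprint(met, 1, radius = 2)
  expect_equal(sum(fp), 1)
  expect_equal(names(fp)[fp == 1], "fp_d0_C.3_b1")
  cf <- countFingerprint(met, 1, radius = 2)
  expect_equal(sum(cf), 1)
  expect_equal(cf[["fp_d0_C.3"]], 1L)

  eth <- pmol("CCO", "ethanol")
  f <- fameBinaryFingerprint(eth, 2, radius = 1)
  expect_equal(sum(f), 3)
  expect_setequal(names(f)[f == 1],
                  c("fp_d0_C.3_b1", "fp_d1_C.3_b1", "fp_d1_O.3_b1"))

  neo <- pmol("CC(C)(C)C", "neopentane")
  fn <- fameBinaryFingerprint(neo, 2, radius = 1)
  expect_equal(names(fn)[fn == 1],
               c("fp_d0_C.3_b1", paste0("fp_d1_C.3_b", 1:4)))
  expect_equal(countFingerprint(neo, 2, radius = 1)[["fp_d1_C.3"]], 4L)

  benz <- pmol("c1ccccc1", "benzene")
  cb <- countFingerprint(benz, 1, radius = 3)
  expect_equal(cb[["fp_d1_C.ar"]], 2L)
  expect_equal(cb[["fp_d2_C.ar"]], 2L)
  expect_equal(cb[["fp_d3_C.ar"]], 1L)
})

test_that("binary blocks are prefix-coded popcounts of the exact counts", {
  mols <- quietFixtures(40, seed = 17)
  nT <- nrow(sybylTypeTable())
  for (m in mols) {
    for (atom in seq_len(atomCount(m))) {
      cf <- countFingerprint(m, atom, radius = 3)
      bf <- fameBinaryFingerprint(m, atom, radius = 3)
      blocks <- matrix(bf, nrow = 32)
      pops <- colSums(blocks)
      expect_equal(unname(pops), pmin(32, unname(cf)))
      # set bits form a prefix within each block
      for (blk in which(pops > 0))
        expect_equal(which(blocks[, blk] == 1), seq_len(pops[blk]))
    }
  }
})

test_that("radius-restricted fingerprints nest (radius monotonicity)", {
  mols <- quietFixtures(8, seed = 23)
  for (m in mols) {
    atom <- 1L
    f5 <- countFingerprint(m, atom, radius = 5)
    f4 <- countFingerprint(m, atom, radius = 4)
    expect_equal(unname(f5[seq_along(f4)]), unname(f4))
    b5 <- fameBinaryFingerprint(m, atom, radius = 5)
    b4 <- fameBinaryFingerprint(m, atom, radius = 4)
    expect_equal(unname(b5[seq_along(b4)]), unname(b4))
  }
})

test_that("exactly one distance-0 block is set, with a single bit", {
  mols <- quietFixtures(10, seed = 29)
  nT <- nrow(sybylTypeTable())
  for (m in mols) {
    for (atom in seq_len(atomCount(m))) {
      cf <- countFingerprint(m, atom, radius = 2)
      d0 <- cf[seq_len(nT)]
      expect_equal(sum(d0 > 0), 1L)
      expect_equal(sum(d0), 1L)
      expect_equal(unname(which(d0 > 0)), atomTable(m)$typeOrdinal[atom])
    }
  }
})

test_that("the fingerprint is a function of the rooted environment only", {
  mol <- quietFixtures(5, seed = 41)[[3]]
  n <- atomCount(mol)
  set.seed(1)
  perm <- sample(n); inv <- order(perm)
  b <- bondTable(mol)
  pb <- cbind(from = inv[b[, "from"]], to = inv[b[, "to"]],
              order = b[, "order"])
  storage.mode(pb) <- "integer"
  permMol <- somkit:::.perceiveGraph(atomTable(mol)$element[perm],
                                     atomTable(mol)$formalCharge[perm],
                                     pb, "perm")
  for (atom in seq_len(n)) {
    expect_equal(fameBinaryFingerprint(mol, atom, 4),
                 fameBinaryFingerprint(permMol, inv[atom], 4))
  }
})
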