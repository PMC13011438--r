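# Perception, SYBYL typing and topological distances.

test_that("perception assigns elements, implicit hydrogens and aromaticity", {
  benz <- pmol("c1ccccc1", "benzene")
  expect_equal(atomCount(benz), 6L)
  expect_true(all(atomTable(benz)$aromatic))
  expect_equal(atomTable(benz)$implicitH, rep(1L, 6))
  expect_equal(atomTable(benz)$sybylType, rep("C.ar", 6))

  met <- pmol("C", "methane")
  expect_equal(atomCount(met), 1L)
  expect_equal(atomTable(met)$implicitH, 4L)
  expect_false(atomTable(met)$aromatic)

  eth <- pmol("CCO", "ethanol")
  expect_equal(atomCount(eth), 3L)
  expect_equal(atomTable(eth)$element[3], "O")
  expect_equal(atomTable(eth)$implicitH[3], 1L)
})

test_that("SYBYL typing follows hybridization and functional context", {
  expect_equal(atomTable(pmol("CC"))$sybylType, c("C.3", "C.3"))
  expect_equal(assignSybylType(pmol("c1ccccc1"), 1)$code, "C.ar")
  ace <- pmol("CC(=O)[O-]", "acetate")
  expect_equal(atomTable(ace)$sybylType[3:4], c("O.co2", "O.co2"))
  # acid form: both oxygens still carboxylate-typed
  acid <- pmol("CC(=O)O", "acetic")
  expect_equal(atomTable(acid)$sybylType[3:4], c("O.co2", "O.co2"))
  amide <- pmol("CC(=O)NC", "n-methylacetamide")
  expect_equal(atomTable(amide)$sybylType[4], "N.am")
  pyr <- pmol("c1ccncc1", "pyridine")
  expect_equal(atomTable(pyr)$sybylType[4], "N.ar")
  nitrile <- pmol("CC#N", "acetonitrile")
  expect_equal(atomTable(nitrile)$sybylType, c("C.3", "C.1", "N.1"))
  sulfone <- pmol("CS(=O)(=O)C", "dimethylsulfone")
  expect_equal(atomTable(sulfone)$sybylType[2], "S.O2")
})

test_that("elements outside the type table are rejected unless mapped to Any", {
  expect_error(pmol("C[Se]C", "selenide"), class = "somkit_perception_error")
  txt <- ChemmineOB::convertFormat("SMI", "SDF", "C[Se]C\n")
  mol <- perceiveMolecule(strsplit(txt, "\n")[[1]], "selenide",
                          onUnknownElement = "any")
  expect_equal(atomTable(mol)$sybylType[2], "Any")
})

test_that("aromatic-order input bonds are rejected with a clear reason", {
  rec <- c("arom", "", "",
           "  2  1  0  0  0  0  0  0  0  0999 V2000",
           "    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
           "    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
           "  1  2  4  0  0  0  0",
           "M  END", "$$$$")
  expect_error(perceiveMolecule(rec, "arom"), regexp = "order 4",
               class = "somkit_perception_error")
})

test_that("multi-fragment inputs keep the largest fragment with a log", {
  expect_message(mol <- pmol("CCO.[Na+]", "salt"), "dropped")
  expect_equal(atomCount(mol), 3L)
  expect_equal(atomTable(mol)$element, c("C", "C", "O"))
})

test_that("topological distances match the shortest bond paths", {
  but <- pmol("CCCC", "butane")
  d <- topologicalDistances(but)
  expect_equal(d[1, 4], 3)
  expect_true(all(diag(d) == 0))
  expect_equal(d, t(d))
  expect_equal(max(topologicalDistances(pmol("c1ccccc1"))), 3)
})

test_that("distance matrix equals a Floyd-Warshall oracle on random fixtures", {
  mols <- quietFixtures(100, seed = 31)
  small <- Filter(function(m) atomCount(m) <= 12L, mols)
  expect_gt(length(small), 10)
  for (m in small) {
    expect_equal(topologicalDistances(m), fwDistances(m))
  }
})

test_that("perception is invariant to input atom order", {
  mols <- quietFixtures(10, seed = 5)
  for (mol in mols[1:5]) {
    n <- atomCount(mol)
    set.seed(n)
    perm <- sample(n)
    inv <- order(perm)
    b <- bondTable(mol)
    pb <- cbind(from = inv[b[, "from"]], to = inv[b[, "to"]],
                order = b[, "order"])
    storage.mode(pb) <- "integer"
    pmolc <- somkit:::.perceiveGraph(atomTable(mol)$element[perm],
                                     atomTable(mol)$formalCharge[perm],
                                     pb, "perm")
    sig <- function(m) {
      d <- topologicalDistances(m)
      sort(vapply(seq_len(atomCount(m)), function(i)
        paste(atomTable(m)$sybylType[i],
              paste(sort(d[i, ]), collapse = ",")), character(1)))
    }
    expect_equal(sig(pmolc), sig(mol))
  }
})

test_that("every fixture atom receives a type from the table", {
  mols <- quietFixtures(40, seed = 13)
  tab <- sybylTypeTable()$code
  for (m in mols) expect_true(all(atomTable(m)$sybylType %in% tab))
})
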