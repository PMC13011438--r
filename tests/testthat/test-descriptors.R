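# The ten physicochemical and four topological descriptors.

test_that("topological descriptors match hand-derived values", {
  but <- pmol("CCCC", "butane")
  expect_equal(unname(topoDescriptors(topologicalDistances(but), 2)),
               c(3, 2, 1, 2 / 3))
  met <- pmol("C", "methane")
  expect_equal(unname(topoDescriptors(topologicalDistances(met), 1)),
               c(0, 0, 0, 1.0))
  benz <- pmol("c1ccccc1", "benzene")
  for (i in 1:6)
    expect_equal(unname(topoDescriptors(topologicalDistances(benz), i)),
                 c(3, 3, 0, 1.0))
})

test_that("degree and formal valence count heavy neighbours and bond orders", {
  iso <- pmol("CC(C)C", "isobutane")
  expect_equal(atomDegree(iso, 2), 3)
  expect_equal(atomDegree(pmol("C"), 1), 0)
  expect_equal(atomDegree(pmol("c1ccccc1"), 1), 2)
  expect_equal(formalValence(pmol("CC"), 1), 4)
  expect_equal(formalValence(pmol("CCO"), 3), 2)
  ace <- pmol("CC(=O)C", "acetone")
  expect_equal(formalValence(ace, 2), 4)
})

test_that("PEOE charges conserve total charge and follow electronegativity", {
  for (m in quietFixtures(25, seed = 3)) {
    q <- peoeCharges(m)
    expect_lt(abs(sum(q$sigmaCharge) - sum(atomTable(m)$formalCharge)), 1e-6)
  }
  meoh <- peoeCharges(pmol("CO", "methanol"))
  expect_lt(meoh$sigmaCharge[2], 0)
  expect_gt(meoh$sigmaCharge[1], 0)
  etn <- peoeCharges(pmol("CC", "ethane"))
  expect_equal(etn$sigmaCharge[1], etn$sigmaCharge[2])
  expect_equal(etn$sigmaElectronegativity[1], etn$sigmaElectronegativity[2])
})

test_that("polarizabilities follow the lookup table and neighbour damping", {
  etn <- polarizabilities(pmol("CC"))
  expect_equal(etn$hybrid[1], etn$hybrid[2])
  neo <- polarizabilities(pmol("CC(C)(C)C"))
  met <- polarizabilities(pmol("C"))
  expect_gt(neo$effective[2], met$effective[1])
  hal <- vapply(c("CF", "CCl", "CBr", "CI"),
                function(s) polarizabilities(pmol(s))$hybrid[2], numeric(1))
  expect_true(all(diff(hal) > 0))
})

test_that("VSEPR geometry codes follow the steric-number rules", {
  expect_equal(vseprGeometry(pmol("CC(C)(C)C"), 2), 4L)  # tetrahedral
  expect_equal(vseprGeometry(pmol("CCO"), 3), 3L)        # bent (2 lone pairs)
  expect_equal(vseprGeometry(pmol("CN"), 2), 5L)         # trigonal pyramidal
  expect_equal(vseprGeometry(pmol("CC(=O)C"), 2), 2L)    # trigonal planar
  expect_equal(vseprGeometry(pmol("CC#N"), 2), 1L)       # linear
  expect_equal(vseprGeometry(pmol("CF"), 2), 0L)         # terminal halogen
})

test_that("force-field-style charges give a negative carbonyl oxygen", {
  ace <- pmol("CC(=O)C", "acetone")
  expect_lt(bciCharges(ace)[3], 0)
  expect_gt(bciCharges(ace)[2], 0)
})

test_that("the Open Babel MMFF94 provider agrees on sign patterns", {
  ace <- pmol("CC(=O)C", "acetone")
  q <- mmffChargesOB(list(ace))[[1]]
  expect_length(q, 4)
  expect_lt(q[3], 0)
  pm <- descriptorProviderMap()
  pm[["mmff94_charge"]] <- "openbabel"
  d <- physchemDescriptors(ace, providerMap = pm)
  expect_equal(unname(d[, "mmff94_charge"]), q)
})

test_that("symmetry-equivalent atoms receive identical descriptor vectors", {
  benz <- pmol("c1ccccc1", "benzene")
  d <- physchemDescriptors(benz)
  t <- topoDescriptorMatrix(benz)
  for (i in 2:6) {
    expect_equal(unname(d[i, ]), unname(d[1, ]))
    expect_equal(unname(t[i, ]), unname(t[1, ]))
  }
  neo <- pmol("CC(C)(C)C", "neopentane")
  dn <- physchemDescriptors(neo)
  methyls <- c(1, 3, 4, 5)
  for (i in methyls[-1])
    expect_equal(unname(dn[i, ]), unname(dn[methyls[1], ]))
})

test_that("disabling a slot removes exactly that column", {
  eth <- pmol("CCO")
  full <- physchemDescriptors(eth)
  noPi <- physchemDescriptors(eth,
                              slots = setdiff(physchemSlots(),
                                              "pi_electronegativity"))
  expect_equal(colnames(noPi),
               setdiff(physchemSlots(), "pi_electronegativity"))
  expect_equal(noPi, full[, colnames(noPi)])
})

test_that("provider misconfiguration fails at configuration time", {
  pm <- descriptorProviderMap()
  pm[["mmff94_charge"]] <- "no_such_provider"
  expect_error(featurizationConfig(providerMap = pm), "not registered")
  pm[["mmff94_charge"]] <- "reference"
  expect_error(featurizationConfig(providerMap = pm), "does not fill")
})

test_that("molecules with unparameterized elements are skipped, not crashed", {
  txt <- ChemmineOB::convertFormat("SMI", "SDF", "C[Si](C)C\n")
  sil <- perceiveMolecule(strsplit(txt, "\n")[[1]], "silane")
  expect_error(peoeCharges(sil), class = "somkit_perception_error")
  good <- pmol("CCO")
  fz <- suppressMessages(featurizeAtoms(list(sil, good)))
  expect_equal(unique(fz$info$molId), "CCO")
  expect_match(unname(fz$skipped["silane"]), "PEOE")
})
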