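# Random-forest SOM classifier: determinism, ranking, thresholding,
# serialization, schema guards.

mols <- quietFixtures(60, seed = 19)
sp <- splitMolecules(mols, c(0.8, 0.2), seed = 2)
cfg <- somTrainingConfig(nTrees = 100L, seed = 4L)
model <- trainSomModel(sp$train, cfg)
pred <- predictSom(model, sp$test)

test_that("identical data, config and seed give identical predictions", {
  model2 <- trainSomModel(sp$train, cfg)
  pred2 <- predictSom(model2, sp$test)
  expect_identical(pred$probability, pred2$probability)
  expect_identical(pred, pred2)
})

test_that("probabilities are bounded and ranks are consistent with them", {
  expect_true(all(pred$probability >= 0 & pred$probability <= 1))
  expect_identical(pred$call, pred$probability >= cfg$threshold)
  for (id in unique(pred$molId)) {
    rows <- pred[pred$molId == id, ]
    expect_setequal(rows$rank, seq_len(nrow(rows)))
    ord <- rows[order(rows$rank), ]
    expect_true(all(diff(ord$probability) <= 0))
    ties <- which(diff(ord$probability) == 0)
    if (length(ties))  # equal probabilities: lower atom index ranks first
      expect_true(all(ord$atomIdx[ties] < ord$atomIdx[ties + 1L]))
  }
})

test_that("input molecule order does not change per-molecule outputs", {
  shuffled <- rev(sp$test)
  predR <- predictSom(model, shuffled)
  reord <- predR[order(match(predR$molId, unique(pred$molId)), predR$atomIdx), ]
  rownames(reord) <- NULL
  base <- pred
  rownames(base) <- NULL
  expect_equal(reord, base, ignore_attr = TRUE)
})

test_that("lowering the threshold never hurts recall nor helps precision", {
  labels <- labelsByMolecule(sp$test)
  yTrue <- mapply(function(id, idx) as.integer(idx %in% labels[[id]]),
                  pred$molId, pred$atomIdx)
  ths <- seq(0.05, 0.95, by = 0.05)
  reps <- lapply(ths, function(t) atomMetrics(yTrue, pred$probability, t))
  recalls <- vapply(reps, function(r) r@recall, numeric(1))
  precisions <- vapply(reps, function(r) r@precision, numeric(1))
  expect_true(all(diff(recalls) <= 1e-12))
  nz <- precisions[vapply(reps, function(r) r@precision > 0, logical(1))]
  expect_true(all(diff(nz) >= -1e-12))
})

test_that("model bundles round-trip bit-identically and verify their format", {
  path <- tempfile(fileext = ".bundle")
  saveSomModel(model, path)
  back <- loadSomModel(path)
  expect_identical(predictSom(back, sp$test), pred)

  writeLines("not a bundle", path)
  expect_error(loadSomModel(path), "corrupted|not a somkit")
  saveRDS(list(format = "somkit-model-0", model = NULL), path)
  expect_error(loadSomModel(path), "format mismatch")
})

test_that("schema drift between training and prediction is refused", {
  shortTable <- sybylTypeTable(head(sybylTypeTable()$code, 25))
  tmp <- tempfile(fileext = ".sdf")
  writeLabeledSdf(sp$test, tmp)
  other <- suppressMessages(readLabeledSdf(tmp, typeTable = shortTable))
  expect_error(predictSom(model, other), "schema mismatch")
})

test_that("reliability scoring requires the bundled reference fingerprints", {
  stripped <- model
  stripped@referenceFps <- NULL
  expect_error(predictSom(stripped, sp$test, withReliability = TRUE),
               "reference fingerprints")
  withRel <- predictSom(model, sp$test, withReliability = TRUE)
  expect_true(all(withRel$fameScore >= 0 & withRel$fameScore <= 1))
  expect_equal(withRel$shannonEntropy, shannonEntropy(withRel$probability))
  expect_identical(withRel$probability, pred$probability)
})

test_that("degenerate training inputs are rejected with clear errors", {
  unlabeled <- lapply(sp$train[1:5], function(m) {
    m@labeled <- FALSE; m@somLabels <- integer(0); m
  })
  expect_error(trainSomModel(unlabeled, cfg), "no labeled molecules")
  allPos <- lapply(sp$train[1:5], function(m) {
    m@somLabels <- seq_len(atomCount(m)); m
  })
  expect_error(trainSomModel(allPos, cfg), "positive and .* negative")
})
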