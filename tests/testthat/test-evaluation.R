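# Metric suite: rank-based ROC-AUC, average precision, confusion metrics,
# molecule-level top-2 correctness, reliability comparison.

test_that("confusion metrics match the direct formulas", {
  # TP=6, TN=2, FP=1, FN=1
  y <- c(rep(1, 7), rep(0, 3))
  s <- c(rep(0.8, 6), 0.1, 0.9, 0.05, 0.02)
  rep1 <- atomMetrics(y, s, threshold = 0.3)
  expect_equal(rep1@mcc, 11 / 21)
  expect_equal(rep1@precision, 6 / 7)
  expect_equal(rep1@recall, 6 / 7)
  expect_equal(rep1@f1, 6 / 7)
})

test_that("degenerate score patterns hit the documented conventions", {
  y <- c(1, 1, 0, 0)
  expect_equal(atomMetrics(y, c(0.9, 0.8, 0.2, 0.1))@rocAuc, 1.0)
  expect_equal(atomMetrics(y, c(0.9, 0.8, 0.2, 0.1))@prAuc, 1.0)
  expect_equal(atomMetrics(y, rep(0.4, 4))@rocAuc, 0.5)
  one <- atomMetrics(c(1, 1), c(0.9, 0.2))
  expect_true(is.na(one@rocAuc))
  expect_match(one@flags, "single-class")
  expect_equal(one@recall, 0.5)  # threshold metrics still computed
  # MCC denominator zero -> 0 by convention
  expect_equal(atomMetrics(c(1, 1, 0, 0), c(0.1, 0.2, 0.05, 0.15))@mcc, 0)
})

test_that("rank metrics equal brute-force oracles on random instances", {
  set.seed(4321)
  for (trial in 1:200) {
    n <- sample(5:50, 1)
    y <- integer(n)
    y[sample(n, sample(seq_len(n - 1), 1))] <- 1L
    if (sum(y) == 0 || sum(y) == n) next
    s <- stats::runif(n)
    if (trial %% 4 == 0) s <- round(s, 1)  # force ties (ROC oracle handles them)
    m <- atomMetrics(y, s)
    expect_equal(m@rocAuc, bruteRocAuc(y, s), tolerance = 1e-12)
    if (!anyDuplicated(s))
      expect_equal(m@prAuc, bruteAveragePrecision(y, s), tolerance = 1e-12)
  }
})

test_that("average precision handles tied scores by threshold groups", {
  # worked by hand: thresholds 0.5 -> P=1/2, R=1/2; 0.3 -> P=2/3, R=1
  y <- c(1, 0, 1, 0)
  s <- c(0.5, 0.5, 0.3, 0.2)
  expect_equal(atomMetrics(y, s)@prAuc, 0.5 * 0.5 + 0.5 * 2 / 3)
})

test_that("ROC-AUC agrees with an established implementation", {
  set.seed(11)
  for (trial in 1:10) {
    y <- rbinom(40, 1, 0.4)
    if (length(unique(y)) < 2) next
    s <- stats::runif(40)
    expect_equal(atomMetrics(y, s)@rocAuc,
                 as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                                direction = "<"))),
                 tolerance = 1e-12)
  }
})

test_that("top-2 correctness follows the worked examples", {
  pred1 <- data.frame(molId = "m1", atomIdx = 1:4,
                      probability = c(0.9, 0.2, 0.1, 0.05), rank = 1:4)
  expect_equal(top2Correctness(pred1, list(m1 = 1L))$top2, 1.0)
  expect_equal(top2Correctness(pred1, list(m1 = 3L))$top2, 0.0)
  pred2 <- rbind(pred1,
                 data.frame(molId = "m2", atomIdx = 1:3,
                            probability = c(0.1, 0.9, 0.3), rank = c(3, 1, 2)))
  expect_equal(top2Correctness(pred2, list(m1 = 3L, m2 = 3L))$top2, 0.5)
  # molecules without annotated SOMs are excluded and counted
  t2 <- top2Correctness(pred2, list(m1 = 1L, m2 = integer(0)))
  expect_equal(t2$top2, 1.0)
  expect_equal(t2$nExcluded, 1L)
  # single-atom molecule: its one atom is the top-2 set
  single <- data.frame(molId = "s", atomIdx = 1L, probability = 0.1, rank = 1L)
  expect_equal(top2Correctness(single, list(s = 1L))$top2, 1.0)
})

test_that("top-2 equals exhaustive per-molecule verification on fixtures", {
  set.seed(555)
  for (trial in 1:30) {
    nMol <- sample(3:10, 1)
    pred <- do.call(rbind, lapply(seq_len(nMol), function(i) {
      n <- sample(2:8, 1)
      data.frame(molId = sprintf("m%02d", i), atomIdx = seq_len(n),
                 probability = round(stats::runif(n), 1))
    }))
    pred$rank <- NA_integer_
    for (id in unique(pred$molId)) {
      rows <- which(pred$molId == id)
      ord <- order(-pred$probability[rows], pred$atomIdx[rows])
      pred$rank[rows[ord]] <- seq_along(rows)
    }
    labels <- lapply(stats::setNames(unique(pred$molId), unique(pred$molId)),
                     function(id) {
      n <- sum(pred$molId == id)
      sample(n, sample(0:2, 1))
    })
    got <- top2Correctness(pred, labels)
    keep <- vapply(labels, length, integer(1)) > 0
    if (!any(keep)) next
    expect_equal(got$top2, bruteTop2(pred, labels))
  }
})

test_that("metrics are invariant to atom order within molecules", {
  set.seed(77)
  n <- 60
  y <- rbinom(n, 1, 0.3)
  if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
  s <- stats::runif(n)
  perm <- sample(n)
  m1 <- atomMetrics(y, s)
  m2 <- atomMetrics(y[perm], s[perm])
  expect_equal(metricsAsList(m1), metricsAsList(m2))
})

test_that("reliability correlation report behaves as specified", {
  set.seed(2024)
  f <- stats::runif(500)
  ent <- 1 - f^2  # monotone transform of the complement
  correct <- stats::runif(500) < 0.7
  rel <- reliabilityCorrelation(f, ent, correct)
  expect_equal(rel$rankCorrelation, -1)
  expect_s3_class(rel$binTable, "data.frame")
  expect_equal(sum(rel$binTable$n), 2 * 500)

  ind <- reliabilityCorrelation(stats::runif(1000), stats::runif(1000),
                                rep(TRUE, 1000))
  expect_lt(abs(ind$rankCorrelation), 0.1)

  const <- reliabilityCorrelation(rep(0.5, 10), stats::runif(10),
                                  rep(TRUE, 10))
  expect_true(is.na(const$rankCorrelation))
  expect_match(const$flags, "constant")
})
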