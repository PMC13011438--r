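# Metric suite: atom-level ROC-AUC (rank formulation, half-credit ties),
# PR-AUC (step-wise average precision), F1/MCC/precision/recall at the
# decision threshold, molecule-level top-2 correctness, and the
# reliability-metric comparison report.

.rocAucRank <- function(yTrue, yScore) {
  n1 <- sum(yTrue == 1L); n0 <- sum(yTrue == 0L)
  r <- rank(yScore)  # average ranks give half-credit for ties
  (sum(r[yTrue == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# step-wise average precision over descending score thresholds; tied scores
# enter together at their common threshold
.averagePrecision <- function(yTrue, yScore) {
  nPos <- sum(yTrue == 1L)
  th <- sort(unique(yScore), decreasing = TRUE)
  ap <- 0
  prevRecall <- 0
  for (t in th) {
    sel <- yScore >= t
    tp <- sum(yTrue[sel] == 1L)
    prec <- tp / sum(sel)
    recall <- tp / nPos
    ap <- ap + (recall - prevRecall) * prec
    prevRecall <- recall
  }
  ap
}

.confusionMetrics <- function(tp, tn, fp, fn) {
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (den == 0) 0 else (tp * tn - fp * fn) / den
  list(precision = precision, recall = recall, f1 = f1, mcc = mcc)
}

#' Atom-level performance metrics
#'
#' ROC-AUC by the rank (Mann-Whitney) formulation with half-credit for score
#' ties; PR-AUC as step-wise average precision; F1, MCC, precision and recall
#' from the confusion matrix at \code{score >= threshold} (MCC is 0 when its
#' denominator vanishes). With single-class truth the ranking metrics are
#' reported as \code{NA} and flagged while the threshold metrics are still
#' computed.
#'
#' @param yTrue binary 0/1 labels
#' @param yScore predicted probabilities
#' @param threshold decision threshold (default 0.3)
#' @return a partial \code{\link{MetricsReport}} (no molecule-level fields)
#' @export
atomMetrics <- function(yTrue, yScore, threshold = 0.3) {
  stopifnot(length(yTrue) == length(yScore))
  yTrue <- as.integer(yTrue)
  flags <- character(0)
  oneClass <- length(unique(yTrue)) < 2L
  if (oneClass) flags <- c(flags, "single-class truth: ranking metrics undefined")
  roc <- if (oneClass) NA_real_ else .rocAucRank(yTrue, yScore)
  pr <- if (oneClass) NA_real_ else .averagePrecision(yTrue, yScore)
  pred <- as.integer(yScore >= threshold)
  cm <- .confusionMetrics(sum(pred == 1L & yTrue == 1L),
                          sum(pred == 0L & yTrue == 0L),
                          sum(pred == 1L & yTrue == 0L),
                          sum(pred == 0L & yTrue == 1L))
  new("MetricsReport", rocAuc = roc, prAuc = pr, f1 = cm$f1, mcc = cm$mcc,
      precision = cm$precision, recall = cm$recall,
      nAtoms = length(yTrue), nPositive = sum(yTrue == 1L),
      threshold = threshold, flags = flags)
}

#' Molecule-level top-2 correctness rate
#'
#' Fraction of molecules for which at least one annotated SOM appears among
#' the two top-ranked atoms (the model's deterministic rank, probability
#' descending with atom-index tie-break). Molecules without any annotated
#' SOM are excluded and counted; a single-atom molecule's one atom is its
#' top-2 set.
#'
#' @param predictions prediction \code{data.frame} from
#'   \code{\link{predictSom}} (columns \code{molId}, \code{atomIdx},
#'   \code{rank})
#' @param labels named list mapping \code{molId} to the integer vector of
#'   annotated SOM atom indices
#' @return list with \code{top2} (the rate, \code{NA} if no molecule was
#'   evaluable), \code{nEvaluated} and \code{nExcluded}
#' @export
top2Correctness <- function(predictions, labels) {
  ids <- unique(predictions$molId)
  hits <- 0L; nEval <- 0L; nExcl <- 0L
  for (id in ids) {
    som <- labels[[id]]
    if (is.null(som) || length(som) == 0L) { nExcl <- nExcl + 1L; next }
    rows <- predictions[predictions$molId == id, ]
    top <- rows$atomIdx[rows$rank <= 2L]
    nEval <- nEval + 1L
    if (any(som %in% top)) hits <- hits + 1L
  }
  list(top2 = if (nEval > 0L) hits / nEval else NA_real_,
       nEvaluated = nEval, nExcluded = nExcl)
}

#' Full evaluation of predictions against labeled molecules
#'
#' Combines \code{\link{atomMetrics}} over all atoms (molecules without
#' annotated SOMs participate as all-negative) with the molecule-level
#' \code{\link{top2Correctness}} (those molecules excluded).
#'
#' @param predictions prediction \code{data.frame} from
#'   \code{\link{predictSom}}
#' @param mols the labeled \code{\link{MoleculeRecord}} list the predictions
#'   refer to
#' @param threshold decision threshold
#' @return a \code{\link{MetricsReport}}
#' @export
evaluatePredictions <- function(predictions, mols, threshold = 0.3) {
  labels <- stats::setNames(lapply(mols, somLabels),
                            vapply(mols, molId, character(1)))
  labeledIds <- names(labels)[vapply(mols, isLabeled, logical(1))]
  pred <- predictions[predictions$molId %in% labeledIds, ]
  if (!nrow(pred)) stop("no predictions for labeled molecules")
  yTrue <- mapply(function(id, idx) as.integer(idx %in% labels[[id]]),
                  pred$molId, pred$atomIdx)
  rep1 <- atomMetrics(yTrue, pred$probability, threshold)
  t2 <- top2Correctness(pred, labels)
  new("MetricsReport", rocAuc = rep1@rocAuc, prAuc = rep1@prAuc,
      f1 = rep1@f1, mcc = rep1@mcc, precision = rep1@precision,
      recall = rep1@recall, top2 = t2$top2, nAtoms = rep1@nAtoms,
      nMolecules = t2$nEvaluated, nPositive = rep1@nPositive,
      nExcludedMolecules = t2$nExcluded, threshold = threshold,
      flags = rep1@flags)
}

#' Reliability-metric comparison report
#'
#' Rank (Spearman) correlation between the FAME applicability-domain score
#' and the Shannon entropy, plus per-quantile-bin accuracy and MCC for each
#' metric — a compact view of how well each reliability signal tracks actual
#' predictive performance.
#'
#' @param fameScores per-atom FAME scores
#' @param entropies per-atom Shannon entropies
#' @param correct per-atom logical correctness flags (thresholded call ==
#'   truth)
#' @param bins number of quantile bins (default 5)
#' @param yTrue,call optional binary truth and thresholded call vectors; when
#'   supplied, each bin additionally reports the MCC of its confusion matrix
#' @return list with \code{rankCorrelation} (\code{NA} and a flag when either
#'   vector is constant) and \code{binTable} (\code{data.frame}: metric, bin,
#'   lower, upper, n, accuracy, mcc)
#' @export
reliabilityCorrelation <- function(fameScores, entropies, correct, bins = 5L,
                                   yTrue = NULL, call = NULL) {
  stopifnot(length(fameScores) == length(entropies),
            length(fameScores) == length(correct))
  flags <- character(0)
  rho <- NA_real_
  if (stats::sd(fameScores) == 0 || stats::sd(entropies) == 0) {
    flags <- c(flags, "constant reliability vector: correlation undefined")
  } else {
    rho <- stats::cor(fameScores, entropies, method = "spearman")
  }
  binOne <- function(x, name) {
    qs <- unique(stats::quantile(x, probs = seq(0, 1, length.out = bins + 1L)))
    if (length(qs) < 2L) return(NULL)
    b <- cut(x, qs, include.lowest = TRUE)
    do.call(rbind, lapply(seq_along(levels(b)), function(k) {
      sel <- as.integer(b) == k
      mcc <- NA_real_
      if (!is.null(yTrue) && !is.null(call) && any(sel)) {
        yt <- as.integer(yTrue[sel]); cl <- as.integer(call[sel])
        mcc <- .confusionMetrics(sum(cl == 1L & yt == 1L),
                                 sum(cl == 0L & yt == 0L),
                                 sum(cl == 1L & yt == 0L),
                                 sum(cl == 0L & yt == 1L))$mcc
      }
      data.frame(metric = name, bin = k,
                 lower = qs[k], upper = qs[k + 1L], n = sum(sel),
                 accuracy = mean(correct[sel]),
                 mcc = mcc, stringsAsFactors = FALSE)
    }))
  }
  tab <- rbind(binOne(fameScores, "fame_score"),
               binOne(entropies, "shannon_entropy"))
  list(rankCorrelation = rho, binTable = tab, flags = flags)
}
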