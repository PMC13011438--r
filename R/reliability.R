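# Prediction-reliability metrics: the FAME applicability-domain score (mean
# Tanimoto similarity to the k nearest training-atom fingerprints) and the
# Shannon entropy of the predicted probability.

#' Tanimoto similarity of two binary fingerprints
#'
#' \code{|intersection| / |union|} on bit vectors, equivalently
#' \code{a.b / (|a|^2 + |b|^2 - a.b)}. Two all-zero vectors yield 0 by
#' convention. The two fingerprints must share the same layout schema
#' (identical names).
#'
#' @param a,b 0/1 vectors with identical names
#' @return similarity in \code{[0, 1]}
#' @export
tanimoto <- function(a, b) {
  if (length(a) != length(b))
    stop(sprintf("fingerprint schema mismatch: lengths %d vs %d",
                 length(a), length(b)))
  if (!is.null(names(a)) && !is.null(names(b)) && !identical(names(a), names(b)))
    stop(sprintf("fingerprint schema mismatch: '%s...' vs '%s...'",
                 names(a)[1L], names(b)[1L]))
  ab <- sum(a * b)
  un <- sum(a) + sum(b) - ab
  if (un == 0) return(0)
  ab / un
}

#' FAME applicability-domain score
#'
#' Mean Tanimoto similarity between a query atom's binary fingerprint and its
#' \code{k} most-similar fingerprints in the reference (training) set. Values
#' near 1 mean the atom's environment is well represented in the training
#' data. Ties at the k-th rank do not affect the score (values are averaged);
#' neighbour identity is made deterministic by breaking ties on the reference
#' index.
#'
#' @param query 0/1 fingerprint vector
#' @param referenceSet matrix (dense or sparse) of reference fingerprints,
#'   one row each, same column layout as \code{query}
#' @param k neighbourhood size (default 3)
#' @return score in \code{[0, 1]}
#' @export
fameScore <- function(query, referenceSet, k = 3L) {
  nRef <- nrow(referenceSet)
  if (k < 1L) stop("k must be >= 1")
  if (nRef < k)
    stop(sprintf("reference set (%d) smaller than k = %d", nRef, k))
  if (ncol(referenceSet) != length(query))
    stop(sprintf("fingerprint schema mismatch: query %d vs reference %d bits",
                 length(query), ncol(referenceSet)))
  if (sum(query) == 0) {
    message("all-zero query fingerprint: FAME score 0 (out of domain)")
    return(0)
  }
  sims <- .tanimotoToSet(query, referenceSet)
  ordSel <- order(-sims, seq_along(sims))[seq_len(k)]
  mean(sims[ordSel])
}

.tanimotoToSet <- function(query, referenceSet) {
  inter <- as.vector(referenceSet %*% query)
  sizes <- Matrix::rowSums(referenceSet)
  un <- sizes + sum(query) - inter
  sims <- ifelse(un == 0, 0, inter / un)
  as.numeric(sims)
}

# batch FAME scores for a query fingerprint matrix (rows = atoms)
.fameScoresBatch <- function(queries, referenceSet, k = 3L) {
  nRef <- nrow(referenceSet)
  if (nRef < k)
    stop(sprintf("reference set (%d) smaller than k = %d", nRef, k))
  inter <- as.matrix(queries %*% Matrix::t(referenceSet))
  qs <- Matrix::rowSums(queries)
  rs <- Matrix::rowSums(referenceSet)
  vapply(seq_len(nrow(queries)), function(i) {
    if (qs[i] == 0) return(0)
    un <- qs[i] + rs - inter[i, ]
    sims <- ifelse(un == 0, 0, inter[i, ] / un)
    mean(sort(sims, decreasing = TRUE)[seq_len(k)])
  }, numeric(1))
}

#' Shannon entropy of a predicted probability
#'
#' Binary entropy \code{-(p log2 p + (1-p) log2(1-p))} with the convention
#' \code{0 log2 0 = 0}. Ranges over \code{[0, 1]}; lower values indicate more
#' confident (and typically more reliable) predictions, with the maximum at
#' \code{p = 0.5}.
#'
#' @param p probability (vectorized), each in \code{[0, 1]}
#' @return entropy value(s) in \code{[0, 1]}
#' @export
#' @examples
#' shannonEntropy(c(0, 0.3, 0.5, 1))
shannonEntropy <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("probabilities must lie in [0, 1]")
  term <- function(x) ifelse(x == 0, 0, x * log2(x))
  -(term(p) + term(1 - p))
}
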