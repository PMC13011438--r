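# Shared fixtures and independent brute-force oracles. Molecules come from
# SMILES through Open Babel so every test exercises the real perception path.

pmol <- function(smiles, id = smiles) {
  txt <- ChemmineOB::convertFormat("SMI", "SDF", paste0(smiles, "\n"))
  perceiveMolecule(strsplit(txt, "\n", fixed = TRUE)[[1]], id)
}

quietFixtures <- function(n, seed, noise = 0) {
  suppressMessages(generateFixtures(fixtureSpec(nMolecules = n, seed = seed,
                                                labelNoise = noise)))
}

# Floyd-Warshall all-pairs shortest paths, independent of igraph
fwDistances <- function(mol) {
  n <- atomCount(mol)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  b <- bondTable(mol)
  for (r in seq_len(nrow(b))) {
    d[b[r, "from"], b[r, "to"]] <- 1
    d[b[r, "to"], b[r, "from"]] <- 1
  }
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

# all-pairs concordance ROC-AUC with half-credit for ties
bruteRocAuc <- function(y, s) {
  pos <- s[y == 1]; neg <- s[y == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# per-positive precision-step average precision (valid without score ties)
bruteAveragePrecision <- function(y, s) {
  ord <- order(-s)
  y <- y[ord]
  hits <- 0; ap <- 0
  for (i in seq_along(y)) {
    if (y[i] == 1) {
      hits <- hits + 1
      ap <- ap + hits / i
    }
  }
  ap / sum(y == 1)
}

bruteMcc <- function(tp, tn, fp, fn) {
  den <- sqrt((tp + fp)) * sqrt((tp + fn)) * sqrt((tn + fp)) * sqrt((tn + fn))
  if (den == 0) 0 else (tp * tn - fp * fn) / den
}

bruteTanimoto <- function(a, b) {
  i <- sum(a == 1 & b == 1)
  u <- sum(a == 1 | b == 1)
  if (u == 0) 0 else i / u
}

bruteFameScore <- function(query, refs, k) {
  sims <- apply(refs, 1L, bruteTanimoto, b = query)
  mean(sort(sims, decreasing = TRUE)[seq_len(k)])
}

# exhaustive per-molecule top-2 verification from raw probabilities
bruteTop2 <- function(pred, labels) {
  hits <- 0L; n <- 0L
  for (id in unique(pred$molId)) {
    som <- labels[[id]]
    if (is.null(som) || !length(som)) next
    rows <- pred[pred$molId == id, ]
    ord <- order(-rows$probability, rows$atomIdx)
    top <- rows$atomIdx[ord][seq_len(min(2L, nrow(rows)))]
    n <- n + 1L
    if (any(som %in% top)) hits <- hits + 1L
  }
  hits / n
}

# random sparse 0/1 fingerprint matrix for reliability oracles
randomBitMatrix <- function(nrow, nbits, density = 0.15) {
  matrix(as.integer(stats::runif(nrow * nbits) < density), nrow = nrow)
}

labelsByMolecule <- function(mols) {
  stats::setNames(lapply(mols, somLabels), vapply(mols, molId, character(1)))
}

# globally shuffle which atoms carry a label, preserving the total count
permuteLabels <- function(mols, seed) {
  set.seed(seed)
  sizes <- vapply(mols, atomCount, integer(1))
  total <- sum(sizes)
  nPos <- sum(vapply(mols, function(m) length(somLabels(m)), integer(1)))
  flat <- sample(total, nPos)
  off <- c(0L, cumsum(sizes))
  for (i in seq_along(mols)) {
    sel <- flat[flat > off[i] & flat <= off[i + 1L]] - off[i]
    mols[[i]]@somLabels <- as.integer(sort(sel))
    mols[[i]]@labeled <- TRUE
  }
  mols
}
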