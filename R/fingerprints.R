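# Rooted circular FAME fingerprints. One 32-bit block per (bond distance,
# SYBYL type) combination: if the root has n neighbours of type t at distance
# d, the first min(n, 32) bits of block (d, t) are set. Distance 0 encodes the
# root's own type. The count variant stores the exact neighbour counts in the
# same (distance-major, type-ordinal-minor) layout and is lossless.

.BLOCK_BITS <- 32L

.fpBlockNames <- function(typeTable, radius) {
  as.vector(t(outer(0:radius, typeTable$code,
                    function(d, c) paste0("fp_d", d, "_", c))))
}

.fpBitNames <- function(typeTable, radius) {
  blocks <- .fpBlockNames(typeTable, radius)
  paste0(rep(blocks, each = .BLOCK_BITS), "_b", seq_len(.BLOCK_BITS))
}

# counts for every atom of a molecule at once: nAtoms x (T*(radius+1)) matrix
.countMatrix <- function(mol, radius, dm = NULL) {
  if (is.null(dm)) dm <- topologicalDistances(mol)
  tt <- mol@typeTable
  nT <- nrow(tt)
  n <- atomCount(mol)
  ord <- mol@atoms$typeOrdinal
  out <- matrix(0L, nrow = n, ncol = nT * (radius + 1L))
  for (i in seq_len(n)) {
    d <- dm[i, ]
    ok <- is.finite(d) & d <= radius
    if (any(ok)) {
      col <- as.integer(d[ok]) * nT + ord[ok]
      tb <- table(col)
      out[i, as.integer(names(tb))] <- as.integer(tb)
    }
  }
  colnames(out) <- .fpBlockNames(tt, radius)
  out
}

# expand a count matrix into prefix-coded 32-bit blocks (clamped at 32)
.binaryFromCounts <- function(counts, typeTable, radius) {
  n <- nrow(counts)
  nBlk <- ncol(counts)
  out <- matrix(0L, nrow = n, ncol = nBlk * .BLOCK_BITS)
  for (b in seq_len(.BLOCK_BITS)) {
    hit <- counts >= b
    if (any(hit)) out[, (seq_len(nBlk) - 1L) * .BLOCK_BITS + b][hit] <-
        rep(1L, sum(hit))
  }
  colnames(out) <- .fpBitNames(typeTable, radius)
  out
}

#' Rooted circular count fingerprint of one atom
#'
#' Exact number of heavy atoms of each SYBYL type at each topological
#' distance \code{0..radius} from the root (the root itself is counted at
#' distance 0). Same informational content as the binary FAME variant for
#' counts up to 32, but dense and unclamped.
#'
#' @param mol a \code{\link{MoleculeRecord}}
#' @param root heavy-atom index (1-based)
#' @param radius maximum bond distance encoded (>= 0)
#' @return named integer vector of length \code{T * (radius + 1)} in
#'   distance-major, type-ordinal-minor order
#' @export
countFingerprint <- function(mol, root, radius = 5L) {
  stopifnot(is(mol, "MoleculeRecord"), radius >= 0L)
  n <- atomCount(mol)
  if (root < 1L || root > n) stop(sprintf("root %d outside 1..%d", root, n))
  .countMatrix(mol, as.integer(radius))[root, ]
}

#' Rooted circular FAME binary fingerprint of one atom
#'
#' 32-bit block encoding: for every (distance, SYBYL type) combination the
#' first \code{min(n, 32)} bits are set when the root has \code{n} neighbours
#' of that type at that distance; within each block the set bits therefore
#' always form a prefix. Exactly one block is nonzero at distance 0 (the
#' root's own type, one bit).
#'
#' @inheritParams countFingerprint
#' @return named integer 0/1 vector of length \code{T * (radius + 1) * 32}
#' @export
#' @examples
#' \donttest{
#' mol <- perceiveMolecule(ChemmineR::smiles2sdf("CC(C)(C)C")[[1]], "neopentane")
#' fp <- fameBinaryFingerprint(mol, root = 2, radius = 1)
#' sum(fp)  # root bit + four methyl-carbon bits
#' }
fameBinaryFingerprint <- function(mol, root, radius = 5L) {
  counts <- countFingerprint(mol, root, radius)
  .binaryFromCounts(matrix(counts, nrow = 1L,
                           dimnames = list(NULL, names(counts))),
                    mol@typeTable, as.integer(radius))[1L, ]
}

# binary fingerprints of all atoms of a list of molecules as a sparse 0/1
# matrix (rows follow the concatenated atom order) -- the reliability module's
# reference/query representation
.binaryFpMatrix <- function(mols, radius) {
  mats <- lapply(mols, function(m)
    .binaryFromCounts(.countMatrix(m, radius), m@typeTable, radius))
  dense <- do.call(rbind, mats)
  Matrix::Matrix(dense, sparse = TRUE)
}
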