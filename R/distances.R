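# Heavy-atom topological distances: all-pairs shortest bond-path lengths on
# the unweighted heavy-atom graph.

#' Topological distance matrix of a molecule
#'
#' All-pairs shortest bond-path lengths between heavy atoms, computed on the
#' unweighted heavy-atom graph. Disconnected atom pairs (possible only when
#' perception is bypassed, since perception keeps one fragment) carry the
#' \code{Inf} sentinel.
#'
#' @param mol a \code{\link{MoleculeRecord}}
#' @return numeric \code{n x n} matrix; \code{d[i, i] == 0}, symmetric
#' @export
#' @examples
#' \donttest{
#' mol <- perceiveMolecule(ChemmineR::smiles2sdf("CCCC")[[1]], "butane")
#' topologicalDistances(mol)
#' }
topologicalDistances <- function(mol) {
  stopifnot(is(mol, "MoleculeRecord"))
  n <- atomCount(mol)
  b <- mol@bonds
  g <- igraph::make_graph(t(b[, c("from", "to"), drop = FALSE]),
                          n = n, directed = FALSE)
  d <- igraph::distances(g)
  dimnames(d) <- NULL
  d
}
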