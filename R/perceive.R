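# Molecule perception: explicit hydrogens folded into implicit counts,
# largest fragment kept, implicit hydrogens completed from standard valences,
# aromaticity perceived by a single documented Hueckel-style model on Kekule
# input, hybridization assigned, SYBYL types attached.

.perceptionError <- function(msg) {
  stop(structure(class = c("somkit_perception_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}

# standard valence target for implicit-hydrogen completion; explicitSum is
# the bond-order sum already present (heavy bonds + explicit hydrogens)
.targetValence <- function(element, charge, explicitSum) {
  pick <- function(set) {
    ok <- set[set >= explicitSum]
    if (length(ok)) min(ok) else NA_integer_
  }
  switch(element,
    C = 4L - abs(charge),
    N = 3L + charge,
    O = 2L + charge,
    S = pick(c(max(0L, 2L + charge), 4L, 6L)),
    P = pick(c(3L + charge, 5L)),
    F = max(0L, 1L + charge), Cl = max(0L, 1L + charge),
    Br = max(0L, 1L + charge), I = max(0L, 1L + charge),
    Si = 4L,
    B = 3L,
    explicitSum  # unknown element: no implicit hydrogens added
  )
}

.adjacency <- function(n, bonds) {
  ad <- vector("list", n)
  for (i in seq_len(n)) ad[[i]] <- integer(0)
  if (nrow(bonds)) {
    for (r in seq_len(nrow(bonds))) {
      i <- bonds[r, "from"]; j <- bonds[r, "to"]
      ad[[i]] <- c(ad[[i]], j)
      ad[[j]] <- c(ad[[j]], i)
    }
  }
  ad
}

# smallest rings (size 3..maxSize) through every cyclic edge: for each edge in
# a cycle, the shortest path between its endpoints with the edge removed
.findRings <- function(n, bonds, maxSize = 7L) {
  if (nrow(bonds) < 3L || n < 3L) return(list())
  g <- igraph::make_graph(t(bonds[, c("from", "to"), drop = FALSE]),
                          n = n, directed = FALSE)
  rings <- list()
  seen <- character(0)
  for (e in seq_len(igraph::ecount(g))) {
    ends <- igraph::ends(g, e)
    g2 <- igraph::delete_edges(g, e)
    sp <- suppressWarnings(igraph::shortest_paths(
      g2, from = ends[1L], to = ends[2L], output = "vpath"))
    vp <- as.integer(sp$vpath[[1L]])
    if (length(vp) >= 3L && length(vp) <= maxSize) {
      key <- paste(sort(vp), collapse = ",")
      if (!(key %in% seen)) {
        seen <- c(seen, key)
        rings[[length(rings) + 1L]] <- vp  # in ring-path order
      }
    }
  }
  rings
}

# Hueckel-style aromaticity on Kekule structures: a candidate ring is aromatic
# if every ring atom can carry a p orbital (degree + implicit H <= 3, element
# C/N/O/S) and the pi-electron count over the ring is 4n+2. Contributions:
# a ring atom with a double bond to another atom of the same ring gives 1; an
# exocyclic double bond gives 0; otherwise N/O/S donate a lone pair (2) and
# carbon (neutral) breaks aromaticity.
.perceiveAromaticity <- function(atoms, bonds, ad, totalH) {
  n <- nrow(atoms)
  aromAtom <- rep(FALSE, n)
  aromBond <- rep(FALSE, nrow(bonds))
  rings <- .findRings(n, bonds)
  if (!length(rings)) return(list(atom = aromAtom, bond = aromBond))
  bondIdx <- function(i, j) {
    which((bonds[, "from"] == i & bonds[, "to"] == j) |
          (bonds[, "from"] == j & bonds[, "to"] == i))[1L]
  }
  for (ring in rings) {
    m <- length(ring)
    pi <- 0L
    ok <- TRUE
    for (i in ring) {
      deg <- length(ad[[i]]) + totalH[i]
      if (deg > 3L || !(atoms$element[i] %in% c("C", "N", "O", "S"))) {
        ok <- FALSE; break
      }
      dbl <- ad[[i]][vapply(ad[[i]], function(j)
        bonds[bondIdx(i, j), "order"] == 2L, logical(1))]
      if (length(dbl) && any(dbl %in% ring)) {
        pi <- pi + 1L
      } else if (length(dbl)) {
        pi <- pi + 0L  # exocyclic double bond contributes no pi electrons
      } else if (atoms$element[i] %in% c("N", "O", "S")) {
        pi <- pi + 2L
      } else if (atoms$element[i] == "C" && atoms$formalCharge[i] == -1L) {
        pi <- pi + 2L
      } else {
        ok <- FALSE; break
      }
    }
    if (ok && pi %% 4L == 2L) {
      aromAtom[ring] <- TRUE
      for (k in seq_along(ring)) {
        j <- ring[if (k == length(ring)) 1L else k + 1L]
        aromBond[bondIdx(ring[k], j)] <- TRUE
      }
    }
  }
  list(atom = aromAtom, bond = aromBond)
}

.perceiveHybridization <- function(atoms, bonds, ad, arom) {
  n <- nrow(atoms)
  vapply(seq_len(n), function(i) {
    e <- atoms$element[i]
    if (!(e %in% c("C", "N", "O", "S", "P", "Si", "B",
                   "F", "Cl", "Br", "I")))
      return("other")
    if (arom[i]) return("sp2")
    if (!nrow(bonds)) return("sp3")
    mine <- bonds[bonds[, "from"] == i | bonds[, "to"] == i, , drop = FALSE]
    nTriple <- sum(mine[, "order"] == 3L)
    nDouble <- sum(mine[, "order"] == 2L)
    if (nTriple >= 1L || nDouble >= 2L) return("sp")
    if (nDouble == 1L) return("sp2")
    "sp3"
  }, character(1))
}

# Core perception on a raw heavy/explicit-H graph. elements/charges are
# per-atom over the raw atom list (may include explicit H); bonds is an
# integer matrix (from, to, order) over raw indices. Returns a MoleculeRecord
# plus the raw->kept index map (0 for dropped atoms).
.perceiveGraph <- function(elements, charges, bonds, molId,
                           typeTable = sybylTypeTable(),
                           onUnknownElement = c("reject", "any")) {
  onUnknownElement <- match.arg(onUnknownElement)
  nRaw <- length(elements)
  if (nRaw < 1L) .perceptionError("no atoms in record")
  if (nrow(bonds) && any(bonds[, "order"] == 4L))
    .perceptionError("aromatic (order 4) input bonds are not supported; supply Kekule structures")
  if (nrow(bonds) && !all(bonds[, "order"] %in% c(1L, 2L, 3L)))
    .perceptionError("bond orders must be 1, 2 or 3")

  isH <- elements %in% c("H", "D", "T")
  explicitH <- integer(nRaw)
  if (any(isH) && nrow(bonds)) {
    for (r in seq_len(nrow(bonds))) {
      i <- bonds[r, "from"]; j <- bonds[r, "to"]
      if (isH[i] && isH[j]) next
      if (isH[j]) explicitH[i] <- explicitH[i] + 1L
      if (isH[i]) explicitH[j] <- explicitH[j] + 1L
    }
  }
  keep <- which(!isH)
  if (!length(keep)) .perceptionError("no heavy atoms in record")

  map <- integer(nRaw)
  map[keep] <- seq_along(keep)
  hb <- bonds[!isH[bonds[, "from"]] & !isH[bonds[, "to"]], , drop = FALSE]
  hb <- cbind(from = map[hb[, "from"]], to = map[hb[, "to"]],
              order = hb[, "order"])
  nH0 <- length(keep)

  # keep the largest connected fragment (salts / counter-ions dropped)
  if (nH0 > 1L) {
    g <- igraph::make_graph(t(hb[, c("from", "to"), drop = FALSE]),
                            n = nH0, directed = FALSE)
    comp <- igraph::components(g)
    if (comp$no > 1L) {
      big <- which.max(comp$csize)
      inBig <- comp$membership == big
      message(sprintf("[%s] dropped %d atom(s) in %d smaller fragment(s)",
                      molId, sum(!inBig), comp$no - 1L))
      sub <- which(inBig)
      map2 <- integer(nH0); map2[sub] <- seq_along(sub)
      hb <- hb[inBig[hb[, "from"]] & inBig[hb[, "to"]], , drop = FALSE]
      hb <- cbind(from = map2[hb[, "from"]], to = map2[hb[, "to"]],
                  order = hb[, "order"])
      map[keep] <- map2[map[keep]]
      keep <- keep[inBig]
    }
  }

  el <- elements[keep]
  chg <- as.integer(charges[keep])
  exH <- explicitH[keep]
  n <- length(keep)
  storage.mode(hb) <- "integer"
  ad <- .adjacency(n, hb)

  # implicit hydrogen completion from standard valences
  bondSum <- integer(n)
  if (nrow(hb)) {
    for (r in seq_len(nrow(hb))) {
      bondSum[hb[r, "from"]] <- bondSum[hb[r, "from"]] + hb[r, "order"]
      bondSum[hb[r, "to"]] <- bondSum[hb[r, "to"]] + hb[r, "order"]
    }
  }
  explicitSum <- bondSum + exH
  implicitH <- integer(n)
  for (i in seq_len(n)) {
    tv <- .targetValence(el[i], chg[i], explicitSum[i])
    if (is.na(tv) || explicitSum[i] > tv)
      .perceptionError(sprintf(
        "valence error at atom %d (%s, explicit valence %d)",
        i, el[i], explicitSum[i]))
    implicitH[i] <- exH[i] + (tv - explicitSum[i])
  }

  atoms <- data.frame(element = el, formalCharge = chg,
                      implicitH = implicitH, stringsAsFactors = FALSE)
  ar <- .perceiveAromaticity(atoms, hb, ad, implicitH)
  atoms$aromatic <- ar$atom
  atoms$hybridization <- .perceiveHybridization(atoms, hb, ad, ar$atom)
  types <- .assignSybylTypes(atoms, hb, ad, onUnknownElement)
  ord <- match(types, typeTable$code)
  if (anyNA(ord))
    .perceptionError(sprintf("type(s) %s absent from the configured table",
      paste(unique(types[is.na(ord)]), collapse = ", ")))
  atoms$sybylType <- types
  atoms$typeOrdinal <- typeTable$ordinal[ord]

  bondsOut <- cbind(hb, aromatic = as.integer(ar$bond))
  storage.mode(bondsOut) <- "integer"
  mol <- new("MoleculeRecord", molId = as.character(molId), atoms = atoms,
             bonds = bondsOut, somLabels = integer(0), labeled = FALSE,
             typeTable = typeTable)
  attr(mol, "indexMap") <- map  # raw 1-based -> kept heavy index (0 = dropped)
  mol
}

# Fixed-width V2000 atom/bond block parse of one raw record. Used for file
# input: it handles the degenerate records (single atom, zero bonds) that
# ChemmineR's block extractor cannot represent.
.parseV2000Record <- function(lines) {
  if (length(lines) < 5L) .perceptionError("truncated record")
  counts <- lines[4L]
  nA <- suppressWarnings(as.integer(substr(counts, 1L, 3L)))
  nB <- suppressWarnings(as.integer(substr(counts, 4L, 6L)))
  if (is.na(nA) || nA < 1L || is.na(nB) || nB < 0L)
    .perceptionError("unparsable counts line")
  if (length(lines) < 4L + nA + nB) .perceptionError("truncated record")
  at <- lines[5L:(4L + nA)]
  elements <- trimws(substr(at, 32L, 34L))
  if (any(!grepl("^[A-Z][a-z]?$", elements) & !(elements %in% c("D", "T"))))
    .perceptionError("unparsable atom block")
  code <- suppressWarnings(as.integer(substr(at, 37L, 39L)))
  code[is.na(code)] <- 0L
  known <- c(`1` = 3L, `2` = 2L, `3` = 1L, `5` = -1L, `6` = -2L, `7` = -3L)
  charges <- integer(nA)
  nz <- which(code != 0L)
  charges[nz] <- unname(known[as.character(code[nz])])
  charges[is.na(charges)] <- 0L
  bonds <- if (nB > 0L) {
    bl <- lines[(5L + nA):(4L + nA + nB)]
    cbind(from = as.integer(substr(bl, 1L, 3L)),
          to = as.integer(substr(bl, 4L, 6L)),
          order = as.integer(substr(bl, 7L, 9L)))
  } else {
    cbind(from = integer(0), to = integer(0), order = integer(0))
  }
  if (anyNA(bonds)) .perceptionError("unparsable bond block")
  # M CHG supersedes all atom-line charge codes per the V2000 convention
  chgLines <- grep("^M  CHG", lines, value = TRUE)
  if (length(chgLines)) {
    charges[] <- 0L
    for (ln in chgLines) {
      tok <- strsplit(trimws(ln), "\\s+")[[1]]
      cnt <- as.integer(tok[3L])
      for (k in seq_len(cnt))
        charges[as.integer(tok[2L + 2L * k])] <- as.integer(tok[3L + 2L * k])
    }
  }
  list(elements = elements, charges = charges, bonds = bonds)
}

#' Perceive a molecule from a parsed SDF record
#'
#' Applies the package's perception pipeline to one ChemmineR \code{SDF}
#' record: explicit hydrogens are removed from the graph and folded into
#' implicit counts, the largest connected fragment is kept (counter-ions are
#' logged and dropped), implicit hydrogens are completed from standard
#' valences, aromaticity is perceived with the documented Hueckel-style model
#' on the Kekule input, hybridization is assigned, and every heavy atom
#' receives a SYBYL type from \code{typeTable}.
#'
#' @param sdf a \code{ChemmineR::SDF} object, or a character vector holding
#'   the raw lines of one V2000 record (the raw form also handles
#'   single-atom / zero-bond records)
#' @param molId identifier used in messages and outputs
#' @param typeTable SYBYL type table (default \code{\link{sybylTypeTable}()})
#' @param onUnknownElement \code{"reject"} (default) to refuse molecules with
#'   elements outside the type table, or \code{"any"} to map them to the
#'   catch-all type
#' @param charges optional per-atom formal charges overriding the atom-block
#'   charge codes (used by the reader to honour \code{M  CHG} lines)
#' @return a \code{\link{MoleculeRecord}}; perception failures signal an
#'   error of class \code{somkit_perception_error}
#' @export
#' @examples
#' \donttest{
#' sdf <- ChemmineR::smiles2sdf("CCO")[[1]]
#' mol <- perceiveMolecule(sdf, "ethanol")
#' atomTable(mol)
#' }
perceiveMolecule <- function(sdf, molId, typeTable = sybylTypeTable(),
                             onUnknownElement = c("reject", "any"),
                             charges = NULL) {
  if (is.character(sdf)) {
    rec <- .parseV2000Record(sdf)
    if (is.null(charges)) charges <- rec$charges
    return(.perceiveGraph(rec$elements, charges, rec$bonds, molId,
                          typeTable, onUnknownElement))
  }
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  elements <- gsub("_\\d+$", "", rownames(ab))
  if (any(!grepl("^[A-Z][a-z]?$", elements)))
    .perceptionError("degenerate block parse; pass the raw V2000 record lines instead")
  n <- length(elements)
  if (is.null(charges)) {
    code <- if ("C6" %in% colnames(ab)) as.integer(ab[, "C6"]) else integer(n)
    charges <- integer(n)
    known <- c(`1` = 3L, `2` = 2L, `3` = 1L, `5` = -1L, `6` = -2L, `7` = -3L)
    nz <- code != 0L & !is.na(code)
    charges[nz] <- unname(known[as.character(code[nz])])
    charges[is.na(charges)] <- 0L
  }
  bonds <- if (is.null(nrow(bb)) || nrow(bb) == 0L || ncol(bb) < 3L ||
               all(bb[, 1L] == 0)) {
    cbind(from = integer(0), to = integer(0), order = integer(0))
  } else {
    cbind(from = as.integer(bb[, 1L]), to = as.integer(bb[, 2L]),
          order = as.integer(bb[, 3L]))
  }
  .perceiveGraph(elements, charges, bonds, molId, typeTable, onUnknownElement)
}
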