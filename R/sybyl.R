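# SYBYL atom typing: element + hybridization/functional context -> one of the
# 26 codes in the configured type table. The table is configurable so an
# alternative 26-type list can be substituted without touching the encoder.

.SYBYL_DEFAULT <- c(
  "C.1", "C.2", "C.3", "C.ar", "C.cat",
  "N.1", "N.2", "N.3", "N.4", "N.ar", "N.am", "N.pl3",
  "O.2", "O.3", "O.co2",
  "S.2", "S.3", "S.O", "S.O2",
  "P.3", "F", "Cl", "Br", "I", "Si.3", "Any"
)

#' SYBYL atom type table
#'
#' The default table covers the common organic elements (C, N, O, S, P,
#' halogens, Si) across hybridization states plus a catch-all \code{"Any"}
#' type, 26 entries in total. Ordinals are a stable bijection onto the table
#' and define the fingerprint block layout, so a model is only compatible
#' with data featurized under the same table.
#'
#' @param codes character vector of type codes; the default 26-entry table
#'   when omitted.
#' @return \code{data.frame} with columns \code{code} and \code{ordinal}
#'   (1-based, stable).
#' @export
#' @examples
#' head(sybylTypeTable())
sybylTypeTable <- function(codes = .SYBYL_DEFAULT) {
  codes <- as.character(codes)
  if (anyDuplicated(codes)) stop("duplicate SYBYL type codes in table")
  if (length(codes) < 1L) stop("empty SYBYL type table")
  data.frame(code = codes, ordinal = seq_along(codes),
             stringsAsFactors = FALSE)
}

#' Load a SYBYL type table from a plain-text file
#'
#' One type code per line; blank lines and lines starting with \code{#} are
#' ignored. Ordinals follow file order.
#'
#' @param path file path
#' @return a type table as from \code{\link{sybylTypeTable}}
#' @export
loadSybylTypeTable <- function(path) {
  ln <- trimws(readLines(path, warn = FALSE))
  ln <- ln[nzchar(ln) & !startsWith(ln, "#")]
  sybylTypeTable(ln)
}

# Internal: type every atom of a perceived (but not yet typed) atom table.
# ad: adjacency list; bonds: bond matrix. Returns character vector of codes or
# signals a somkit_perception_error for elements outside the table when
# onUnknownElement = "reject".
.assignSybylTypes <- function(atoms, bonds, ad, onUnknownElement = c("reject", "any")) {
  onUnknownElement <- match.arg(onUnknownElement)
  n <- nrow(atoms)
  el <- atoms$element
  hyb <- atoms$hybridization
  arom <- atoms$aromatic
  chg <- atoms$formalCharge
  deg <- vapply(ad, length, integer(1))

  bondOrder <- function(i, j) {
    hit <- (bonds[, "from"] == i & bonds[, "to"] == j) |
           (bonds[, "from"] == j & bonds[, "to"] == i)
    bonds[hit, "order"][1L]
  }
  hasDoubleTo <- function(i, elSet) {
    any(vapply(ad[[i]], function(j)
      el[j] %in% elSet && bondOrder(i, j) == 2L, logical(1)))
  }

  # carboxylate-like carbon: two terminal oxygens, at least one double-bonded
  isCarboxylC <- vapply(seq_len(n), function(i) {
    if (el[i] != "C") return(FALSE)
    os <- ad[[i]][el[ad[[i]]] == "O" & deg[ad[[i]]] == 1L]
    length(os) == 2L && any(vapply(os, function(j) bondOrder(i, j) == 2L,
                                   logical(1)))
  }, logical(1))

  typeOne <- function(i) {
    e <- el[i]
    nb <- ad[[i]]
    if (e == "C") {
      if (arom[i]) return("C.ar")
      if (hyb[i] == "sp") return("C.1")
      if (hyb[i] == "sp2") {
        if (length(nb) == 3L && all(el[nb] == "N")) return("C.cat")
        return("C.2")
      }
      return("C.3")
    }
    if (e == "N") {
      if (arom[i]) return("N.ar")
      if (deg[i] + atoms$implicitH[i] == 4L ||
          (chg[i] == 1L && hyb[i] == "sp3")) return("N.4")
      amide <- any(vapply(nb, function(j)
        el[j] %in% c("C", "S") && bondOrder(i, j) == 1L &&
          hasDoubleTo(j, c("O", "S")), logical(1)))
      if (amide && hyb[i] == "sp3") return("N.am")
      if (hyb[i] == "sp") return("N.1")
      if (hyb[i] == "sp2") return("N.2")
      conj <- any(arom[nb] | hyb[nb] == "sp2")
      if (conj) return("N.pl3")
      return("N.3")
    }
    if (e == "O") {
      if (deg[i] == 1L && any(isCarboxylC[nb])) return("O.co2")
      if (hyb[i] == "sp2" && !arom[i]) return("O.2")
      return("O.3")
    }
    if (e == "S") {
      nDoubleO <- sum(vapply(nb, function(j)
        el[j] == "O" && bondOrder(i, j) == 2L, logical(1)))
      if (nDoubleO >= 2L) return("S.O2")
      if (nDoubleO == 1L) return("S.O")
      if (hyb[i] == "sp2" && !arom[i]) return("S.2")
      return("S.3")
    }
    if (e == "P") return("P.3")
    if (e %in% c("F", "Cl", "Br", "I")) return(e)
    if (e == "Si") return("Si.3")
    NA_character_
  }

  types <- vapply(seq_len(n), typeOne, character(1))
  if (anyNA(types)) {
    if (onUnknownElement == "reject") {
      bad <- unique(el[is.na(types)])
      .perceptionError(sprintf("element(s) outside the SYBYL type table: %s",
                               paste(bad, collapse = ", ")))
    }
    types[is.na(types)] <- "Any"
  }
  types
}

#' SYBYL type of one atom
#'
#' Returns the type assigned at perception time; typing is a deterministic
#' function of element, hybridization, aromaticity and functional context
#' (e.g. both oxygens of a carboxylate map to \code{O.co2}, amide nitrogens
#' to \code{N.am}).
#'
#' @param mol a \code{\link{MoleculeRecord}}
#' @param atomIndex heavy-atom index (1-based)
#' @return single-row \code{data.frame} with \code{code} and \code{ordinal}
#' @export
assignSybylType <- function(mol, atomIndex) {
  stopifnot(is(mol, "MoleculeRecord"))
  n <- atomCount(mol)
  if (atomIndex < 1L || atomIndex > n)
    stop(sprintf("atom index %d outside 1..%d", atomIndex, n))
  data.frame(code = mol@atoms$sybylType[atomIndex],
             ordinal = mol@atoms$typeOrdinal[atomIndex],
             stringsAsFactors = FALSE)
}
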