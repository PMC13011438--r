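# Synthetic fixture generator: rule-labeled molecules assembled from a small
# fragment grammar (alkyl chains, ethers, amines, benzene rings, halides).
# The default label rules mark environments that are detectable from the
# rooted circular fingerprint, so the learning task is well-posed by
# construction: (A) sp3 carbons alpha to an ether oxygen or amine nitrogen,
# (B) aromatic CH carbons ortho to a substituted ring position. Labels are
# then flipped i.i.d. with probability labelNoise.

#' Fixture generation specification
#'
#' @param nMolecules number of molecules to generate
#' @param seed RNG seed (single stream; identical spec + seed reproduce the
#'   output byte-identically)
#' @param labelNoise per-atom label flip probability in \code{[0, 0.5)}
#' @param grammarWeights sampling weights of the backbone building blocks
#' @param sizeRange allowed heavy-atom counts (molecules outside are
#'   resampled, bounded retries)
#' @return classed list consumed by \code{\link{generateFixtures}}
#' @export
fixtureSpec <- function(nMolecules = 100L, seed = 7L, labelNoise = 0,
                        grammarWeights = c(chain = 0.4, ether = 0.15,
                                           amine = 0.15, ring = 0.3),
                        sizeRange = c(5L, 25L)) {
  if (labelNoise < 0 || labelNoise >= 0.5)
    stop("labelNoise must lie in [0, 0.5)")
  stopifnot(nMolecules >= 1L, length(sizeRange) == 2L,
            all(c("chain", "ether", "amine", "ring") %in% names(grammarWeights)))
  structure(list(nMolecules = as.integer(nMolecules), seed = as.integer(seed),
                 labelNoise = labelNoise, grammarWeights = grammarWeights,
                 sizeRange = as.integer(sizeRange)),
            class = "somkit_fixture_spec")
}

# assemble one random skeleton; returns list(elements, bonds) or NULL when a
# retry is needed
.buildSkeleton <- function(weights, sizeRange) {
  el <- character(0)
  bonds <- matrix(integer(0), ncol = 3,
                  dimnames = list(NULL, c("from", "to", "order")))
  addAtom <- function(e) { el[[length(el) + 1L]] <<- e; length(el) }
  addBond <- function(i, j, o = 1L)
    bonds <<- rbind(bonds, c(from = i, to = j, order = o))

  nUnits <- sample(2:5, 1L)
  last <- 0L
  lastHetero <- FALSE
  for (u in seq_len(nUnits)) {
    kind <- sample(names(weights), 1L, prob = weights)
    if (lastHetero && kind %in% c("ether", "amine")) kind <- "chain"
    if (kind == "chain") {
      len <- sample(1:3, 1L)
      for (s in seq_len(len)) {
        a <- addAtom("C")
        if (last > 0L) addBond(last, a)
        last <- a
      }
      if (len >= 2L && stats::runif(1) < 0.3) {
        b <- addAtom("C")          # methyl branch
        addBond(last - 1L, b)
      }
      lastHetero <- FALSE
    } else if (kind == "ether") {
      a <- addAtom("O")
      if (last > 0L) addBond(last, a)
      last <- a; lastHetero <- TRUE
    } else if (kind == "amine") {
      a <- addAtom("N")
      if (last > 0L) addBond(last, a)
      last <- a; lastHetero <- TRUE
    } else {  # benzene ring, Kekule orders, random exit position
      base <- length(el)
      for (s in 1:6) addAtom("C")
      ringOrders <- c(2L, 1L, 2L, 1L, 2L, 1L)
      for (s in 1:6)
        addBond(base + s, base + if (s == 6L) 1L else s + 1L, ringOrders[s])
      if (last > 0L) addBond(last, base + 1L)
      exit <- sample(c(2L, 3L, 4L), 1L)   # ortho / meta / para continuation
      last <- base + exit
      lastHetero <- FALSE
    }
  }
  # terminal decoration: halide or methyl on the open end
  if (stats::runif(1) < 0.35) {
    deg <- tabulate(c(bonds[, "from"], bonds[, "to"]), nbins = length(el))
    cap <- switch(el[last], C = 4L, N = 3L, O = 2L, 2L)
    if (deg[last] < cap) {
      a <- addAtom(sample(c("F", "Cl", "Br"), 1L))
      addBond(last, a)
    }
  }
  n <- length(el)
  if (n < sizeRange[1L] || n > sizeRange[2L]) return(NULL)
  storage.mode(bonds) <- "integer"
  list(elements = el, bonds = bonds)
}

# default deterministic label rules on a perceived record
.ruleLabels <- function(mol) {
  n <- atomCount(mol)
  ad <- .adjacency(n, mol@bonds)
  at <- mol@atoms
  deg <- vapply(ad, length, integer(1))
  pos <- logical(n)
  for (i in seq_len(n)) {
    if (at$element[i] == "C" && at$hybridization[i] == "sp3") {
      # alpha to an ether oxygen or (non-aromatic) amine nitrogen
      if (any(vapply(ad[[i]], function(j)
        (at$element[j] == "O" && deg[j] == 2L && !at$aromatic[j]) ||
        (at$element[j] == "N" && !at$aromatic[j]), logical(1))))
        pos[i] <- TRUE
    }
    if (at$aromatic[i] && at$implicitH[i] >= 1L) {
      # ortho to a substituted aromatic position
      if (any(vapply(ad[[i]], function(j)
        at$aromatic[j] && any(!at$aromatic[ad[[j]]]), logical(1))))
        pos[i] <- TRUE
    }
  }
  which(pos)
}

#' Generate rule-labeled synthetic molecules
#'
#' Deterministic under (spec, seed): assembles random skeletons from the
#' fragment grammar, perceives them through the standard pipeline, applies
#' the deterministic atom-environment label rules, and flips each atom's
#' label i.i.d. with probability \code{labelNoise}. Invalid skeletons are
#' rejected and resampled (bounded retries).
#'
#' @param spec a \code{\link{fixtureSpec}}
#' @return list of labeled \code{\link{MoleculeRecord}}
#' @export
#' @examples
#' mols <- generateFixtures(fixtureSpec(nMolecules = 5, seed = 1))
#' mols[[1]]
generateFixtures <- function(spec = fixtureSpec()) {
  stopifnot(inherits(spec, "somkit_fixture_spec"))
  set.seed(spec$seed)
  mols <- vector("list", spec$nMolecules)
  anyRuleFired <- FALSE
  for (m in seq_len(spec$nMolecules)) {
    mol <- NULL
    for (try in 1:50) {
      sk <- .buildSkeleton(spec$grammarWeights, spec$sizeRange)
      if (is.null(sk)) next
      mol <- tryCatch(
        .perceiveGraph(sk$elements, integer(length(sk$elements)), sk$bonds,
                       sprintf("FIX%04d", m)),
        somkit_perception_error = function(e) NULL)
      if (!is.null(mol)) break
    }
    if (is.null(mol))
      stop("fixture generation failed: grammar produced no valid molecule in 50 tries")
    lab <- .ruleLabels(mol)
    if (length(lab)) anyRuleFired <- TRUE
    if (spec$labelNoise > 0) {
      flip <- stats::runif(atomCount(mol)) < spec$labelNoise
      lab <- sort(union(setdiff(lab, which(flip)),
                        setdiff(which(flip), lab)))
    }
    mol@somLabels <- as.integer(lab)
    mol@labeled <- TRUE
    mols[[m]] <- mol
  }
  if (!anyRuleFired)
    stop("no label rule fired on any generated molecule; check the grammar")
  mols
}

# joint Weisfeiler-Lehman refinement over a molecule list; returns one
# stereo-agnostic canonical identifier string per molecule (identical
# skeletons map to identical identifiers)
.canonicalIdentifiers <- function(mols, rounds = 3L) {
  per <- lapply(mols, function(m) {
    at <- m@atoms
    list(lab = paste(at$element, at$formalCharge, at$hybridization,
                     at$implicitH, sep = ":"),
         ad = .adjacency(nrow(at), m@bonds))
  })
  for (r in seq_len(rounds)) {
    keys <- lapply(per, function(p)
      vapply(seq_along(p$lab), function(i)
        paste(p$lab[i], paste(sort(p$lab[p$ad[[i]]]), collapse = ","),
              sep = "|"), character(1)))
    dict <- sort(unique(unlist(keys)))
    per <- mapply(function(p, k) { p$lab <- as.character(match(k, dict)); p },
                  per, keys, SIMPLIFY = FALSE)
  }
  vapply(per, function(p) paste(sort(p$lab), collapse = "."), character(1))
}

#' Molecule-level train/test split with duplicate co-partitioning
#'
#' Splits molecules into partitions at the molecule level; records sharing a
#' stereo-agnostic canonical skeleton identifier are forced into the same
#' partition, so (near-)duplicates and stereoisomer records can never leak
#' between train and test.
#'
#' @param mols list of \code{\link{MoleculeRecord}}
#' @param fractions numeric vector summing to 1 (default \code{c(0.8, 0.2)})
#' @param seed RNG seed for the shuffle
#' @return list of molecule lists, one per fraction (named \code{train} /
#'   \code{test} for two fractions)
#' @export
splitMolecules <- function(mols, fractions = c(0.8, 0.2), seed = 1L) {
  if (abs(sum(fractions) - 1) > 1e-9) stop("fractions must sum to 1")
  ids <- .canonicalIdentifiers(mols)
  groups <- split(seq_along(mols), ids)
  set.seed(seed)
  groups <- groups[sample(length(groups))]
  target <- round(length(mols) * fractions)
  nPart <- length(fractions)
  parts <- rep(list(integer(0)), nPart)
  cur <- 1L
  for (g in groups) {
    while (cur < nPart && length(parts[[cur]]) >= target[cur]) cur <- cur + 1L
    parts[[cur]] <- c(parts[[cur]], g)
  }
  if (any(vapply(parts, length, integer(1)) == 0L))
    stop("split produced an empty partition")
  out <- lapply(parts, function(ix) mols[sort(ix)])
  if (nPart == 2L) names(out) <- c("train", "test")
  out
}
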