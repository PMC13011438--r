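# The ten physicochemical atom descriptors and the four topological
# descriptors. Physicochemical slots sit behind a pluggable provider
# contract: the reference providers below are self-contained; the
# "openbabel" provider computes true MMFF94 charges through the Open Babel
# command-line tool when selected.

.PHYSCHEM_SLOTS <- c(
  "atom_degree", "formal_valence", "hybrid_polarizability",
  "vsepr_geometry", "effective_polarizability", "inductive_effect",
  "peoe_sigma_charge", "peoe_sigma_electronegativity",
  "pi_electronegativity", "mmff94_charge"
)

.TOPO_SLOTS <- c("longest_max_top_dist_in_molecule",
                 "highest_max_top_dist_in_row",
                 "dist_difference", "dist_ratio")

#' Names of the ten physicochemical descriptor slots
#' @return character vector in the fixed schema order
#' @export
physchemSlots <- function() .PHYSCHEM_SLOTS

#' Names of the four topological descriptor slots
#' @return character vector in the fixed schema order
#' @export
topoSlots <- function() .TOPO_SLOTS

# ---------------------------------------------------------------------------
# parameter tables (reference providers)

# Gasteiger-Marsili PEOE parameters chi(q) = a + b q + c q^2 per valence
# state; classical published values for H/C/N/O/halogens/S plus the common
# phosphorus extension. Elements without parameters reject the molecule.
.PEOE_PARAMS <- list(
  H     = c(7.17, 6.24, -0.56),
  C.sp3 = c(7.98, 9.18, 1.88),
  C.sp2 = c(8.79, 9.32, 1.51),
  C.sp  = c(10.39, 9.45, 0.73),
  N.sp3 = c(11.54, 10.82, 1.36),
  N.sp2 = c(12.87, 11.15, 0.85),
  N.sp  = c(15.68, 11.70, -0.27),
  O.sp3 = c(14.18, 12.92, 1.39),
  O.sp2 = c(17.07, 13.79, 0.47),
  F     = c(14.66, 13.85, 2.31),
  Cl    = c(11.00, 9.69, 1.35),
  Br    = c(10.08, 8.47, 1.16),
  I     = c(9.90, 7.96, 0.96),
  S.sp3 = c(10.14, 9.13, 1.38),
  S.sp2 = c(10.14, 9.13, 1.38),
  P.sp3 = c(8.90, 8.24, 0.96)
)

.peoeKey <- function(element, hybridization) {
  if (element %in% c("F", "Cl", "Br", "I", "H")) return(element)
  hy <- if (hybridization %in% c("sp", "sp2", "sp3")) hybridization else "sp3"
  paste0(element, ".", hy)
}

# atomic hybrid polarizabilities (A^3), per (element, hybridization);
# Miller-style atomic hybrid components
.POLARIZABILITY <- list(
  H = 0.387,
  C.sp3 = 1.061, C.sp2 = 1.352, C.sp = 1.283,
  N.sp3 = 0.964, N.sp2 = 1.030, N.sp = 0.956,
  O.sp3 = 0.637, O.sp2 = 0.569,
  S.sp3 = 3.000, S.sp2 = 3.729,
  P.sp3 = 1.538,
  F = 0.296, Cl = 2.315, Br = 3.013, I = 5.415,
  Si.sp3 = 1.970
)

# Pauling electronegativities (inductive-effect and bond-charge-increment
# reference forms)
.PAULING_EN <- c(H = 2.20, C = 2.55, N = 3.04, O = 3.44, S = 2.58, P = 2.19,
                 F = 3.98, Cl = 3.16, Br = 2.96, I = 2.66, Si = 1.90, B = 2.04)

# pi-orbital electronegativity lookup (eV scale) for pi-capable valence
# states; zero for saturated atoms
.PI_EN <- c(C.sp2 = 5.60, C.sp = 7.00, N.sp2 = 7.95, N.sp = 9.50,
            O.sp2 = 10.09, S.sp2 = 6.50)

.VALENCE_ELECTRONS <- c(C = 4L, N = 5L, O = 6L, S = 6L, P = 5L, Si = 4L,
                        B = 3L, F = 7L, Cl = 7L, Br = 7L, I = 7L, H = 1L)

# ---------------------------------------------------------------------------
# topological descriptors

#' Topological descriptors of one atom
#'
#' Four quantities derived from the heavy-atom distance matrix: (1) the
#' maximum bond distance between any two atoms of the molecule, (2) the
#' maximum bond distance from the described atom to any other atom, (3) their
#' difference and (4) their ratio. A single-atom molecule yields
#' \code{(0, 0, 0, 1)} by convention (its only atom trivially attains the
#' molecular maximum).
#'
#' @param dm distance matrix from \code{\link{topologicalDistances}}
#' @param atom heavy-atom index
#' @return named numeric vector of length 4
#' @export
topoDescriptors <- function(dm, atom) {
  fin <- dm[is.finite(dm)]
  longest <- if (length(fin)) max(fin) else 0
  row <- dm[atom, ]
  rowMax <- max(0, row[is.finite(row)])
  ratio <- if (longest == 0) 1.0 else rowMax / longest
  c(longest_max_top_dist_in_molecule = longest,
    highest_max_top_dist_in_row = rowMax,
    dist_difference = longest - rowMax,
    dist_ratio = ratio)
}

#' Heavy-atom degree of one atom
#' @param mol a \code{\link{MoleculeRecord}}
#' @param atom heavy-atom index
#' @return number of heavy-atom neighbours
#' @export
atomDegree <- function(mol, atom) {
  b <- mol@bonds
  sum(b[, "from"] == atom | b[, "to"] == atom)
}

#' Formal (explicit) valence of one atom
#'
#' Sum of bond orders to all neighbours, implicit hydrogens included;
#' aromatic systems are counted through the Kekule bond orders fixed at
#' perception.
#'
#' @inheritParams atomDegree
#' @return integer valence
#' @export
formalValence <- function(mol, atom) {
  b <- mol@bonds
  mine <- b[b[, "from"] == atom | b[, "to"] == atom, , drop = FALSE]
  sum(mine[, "order"]) + mol@atoms$implicitH[atom]
}

# ---------------------------------------------------------------------------
# PEOE sigma charges / electronegativities

#' PEOE (Gasteiger-Marsili) sigma charges and electronegativities
#'
#' Iterative partial equalization of orbital electronegativities: per cycle,
#' charge flows across every bond from the less to the more electronegative
#' atom, proportionally to the electronegativity difference and attenuated by
#' \code{damping^cycle}. Implicit hydrogens participate as pseudo-atoms; the
#' reported sigma charge of a heavy atom folds in the charges of its attached
#' hydrogens, so the charges of a neutral molecule sum to ~0. The reported
#' electronegativity is the heavy atom's own orbital electronegativity at the
#' converged charge.
#'
#' @param mol a \code{\link{MoleculeRecord}}
#' @param nIter number of equalization cycles (default 6, the classical
#'   scheme)
#' @param damping attenuation factor per cycle (default 0.5)
#' @return \code{data.frame} with columns \code{sigmaCharge} and
#'   \code{sigmaElectronegativity}, one row per heavy atom
#' @export
peoeCharges <- function(mol, nIter = 6L, damping = 0.5) {
  stopifnot(is(mol, "MoleculeRecord"))
  n <- atomCount(mol)
  el <- mol@atoms$element
  keys <- vapply(seq_len(n), function(i)
    .peoeKey(el[i], mol@atoms$hybridization[i]), character(1))
  missing <- !(keys %in% names(.PEOE_PARAMS))
  if (any(missing))
    .perceptionError(sprintf("[%s] no PEOE parameters for %s", mol@molId,
                             paste(unique(keys[missing]), collapse = ", ")))

  # expand implicit hydrogens as pseudo-atoms
  hOwner <- rep(seq_len(n), mol@atoms$implicitH)
  nTot <- n + length(hOwner)
  allKeys <- c(keys, rep("H", length(hOwner)))
  pr <- do.call(rbind, .PEOE_PARAMS[allKeys])
  a <- pr[, 1L]; bb <- pr[, 2L]; cc <- pr[, 3L]
  chiPlus <- a + bb + cc
  chiPlus[allKeys == "H"] <- 20.02

  bf <- c(mol@bonds[, "from"], hOwner)
  bt <- c(mol@bonds[, "to"], if (length(hOwner)) n + seq_along(hOwner) else integer(0))

  q <- c(as.numeric(mol@atoms$formalCharge), numeric(length(hOwner)))
  for (it in seq_len(nIter)) {
    chi <- a + bb * q + cc * q * q
    att <- damping^it
    dq <- numeric(nTot)
    if (length(bf)) {
      lo <- ifelse(chi[bf] <= chi[bt], bf, bt)   # less electronegative end
      hi <- ifelse(chi[bf] <= chi[bt], bt, bf)
      tr <- (chi[hi] - chi[lo]) / chiPlus[lo] * att
      for (kk in seq_along(tr)) {
        dq[lo[kk]] <- dq[lo[kk]] + tr[kk]
        dq[hi[kk]] <- dq[hi[kk]] - tr[kk]
      }
    }
    q <- q + dq
  }
  chi <- a + bb * q + cc * q * q
  folded <- q[seq_len(n)]
  if (length(hOwner)) {
    hq <- q[n + seq_along(hOwner)]
    for (kk in seq_along(hOwner))
      folded[hOwner[kk]] <- folded[hOwner[kk]] + hq[kk]
  }
  data.frame(sigmaCharge = folded, sigmaElectronegativity = chi[seq_len(n)])
}

# ---------------------------------------------------------------------------
# polarizabilities

.polKey <- function(element, hybridization) {
  if (element %in% c("F", "Cl", "Br", "I", "H")) return(element)
  hy <- if (hybridization %in% c("sp", "sp2", "sp3")) hybridization else "sp3"
  paste0(element, ".", hy)
}

#' Hybrid and effective atom polarizabilities
#'
#' Hybrid polarizability is a per-(element, hybridization) lookup of atomic
#' hybrid polarizability components (in cubic Angstroms). Effective
#' polarizability augments the atom's own value with the contributions of
#' all topological neighbours damped by \code{0.5^distance}; implicit
#' hydrogens contribute at one bond beyond their carrier.
#'
#' @param mol a \code{\link{MoleculeRecord}}
#' @param dm optional precomputed distance matrix
#' @return \code{data.frame} with columns \code{hybrid} and \code{effective}
#' @export
polarizabilities <- function(mol, dm = NULL) {
  stopifnot(is(mol, "MoleculeRecord"))
  n <- atomCount(mol)
  keys <- vapply(seq_len(n), function(i)
    .polKey(mol@atoms$element[i], mol@atoms$hybridization[i]), character(1))
  missing <- !(keys %in% names(.POLARIZABILITY))
  if (any(missing))
    .perceptionError(sprintf("[%s] no polarizability entry for %s", mol@molId,
                             paste(unique(keys[missing]), collapse = ", ")))
  alpha <- unlist(.POLARIZABILITY[keys], use.names = FALSE)
  aH <- .POLARIZABILITY$H
  if (is.null(dm)) dm <- topologicalDistances(mol)
  w <- 0.5^dm
  w[!is.finite(dm)] <- 0
  hC <- mol@atoms$implicitH * aH
  eff <- as.vector(w %*% alpha) + as.vector(w %*% hC) * 0.5
  data.frame(hybrid = alpha, effective = eff)
}

# ---------------------------------------------------------------------------
# VSEPR coordination geometry

# stable small-integer geometry codes:
# 0 terminal/undefined, 1 linear, 2 trigonal planar, 3 bent, 4 tetrahedral,
# 5 trigonal pyramidal, 6 trigonal bipyramidal, 7 octahedral
.VSEPR_CODES <- c(terminal = 0L, linear = 1L, trigonal_planar = 2L,
                  bent = 3L, tetrahedral = 4L, trigonal_pyramidal = 5L,
                  trigonal_bipyramidal = 6L, octahedral = 7L)

#' VSEPR coordination geometry code of one atom
#'
#' Steric-number rule: sigma partners (heavy neighbours + implicit hydrogens)
#' plus lone pairs determine the electron-domain arrangement; the occupied
#' geometry is encoded as a stable small integer (0 terminal, 1 linear,
#' 2 trigonal planar, 3 bent, 4 tetrahedral, 5 trigonal pyramidal,
#' 6 trigonal bipyramidal, 7 octahedral).
#'
#' @inheritParams atomDegree
#' @return integer geometry code
#' @export
vseprGeometry <- function(mol, atom) {
  sigma <- atomDegree(mol, atom) + mol@atoms$implicitH[atom]
  if (sigma <= 1L) return(.VSEPR_CODES[["terminal"]])
  el <- mol@atoms$element[atom]
  ve <- .VALENCE_ELECTRONS[el]
  if (is.na(ve)) return(.VSEPR_CODES[["terminal"]])
  lp <- max(0L, (ve - mol@atoms$formalCharge[atom] -
                   formalValence(mol, atom)) %/% 2L)
  sn <- sigma + lp
  if (sn <= 2L) return(.VSEPR_CODES[["linear"]])
  if (sn == 3L)
    return(if (lp == 0L) .VSEPR_CODES[["trigonal_planar"]]
           else .VSEPR_CODES[["bent"]])
  if (sn == 4L)
    return(switch(min(lp, 2L) + 1L, .VSEPR_CODES[["tetrahedral"]],
                  .VSEPR_CODES[["trigonal_pyramidal"]],
                  .VSEPR_CODES[["bent"]]))
  if (sn == 5L) return(.VSEPR_CODES[["trigonal_bipyramidal"]])
  .VSEPR_CODES[["octahedral"]]
}

# ---------------------------------------------------------------------------
# electronegativity-based reference forms

#' Inductive effect (electronegativity group-contribution reference form)
#'
#' Sum over all other atoms of the Pauling electronegativity difference to
#' the described atom, damped by the squared topological distance; implicit
#' hydrogens contribute at one bond beyond their carrier. Positive values
#' mark atoms surrounded by more electronegative environments.
#'
#' @inheritParams polarizabilities
#' @return numeric vector, one value per heavy atom
#' @export
inductiveEffect <- function(mol, dm = NULL) {
  stopifnot(is(mol, "MoleculeRecord"))
  n <- atomCount(mol)
  en <- .PAULING_EN[mol@atoms$element]
  en[is.na(en)] <- 2.50
  if (is.null(dm)) dm <- topologicalDistances(mol)
  w <- 1 / dm^2
  diag(w) <- 0
  w[!is.finite(w)] <- 0
  enH <- .PAULING_EN[["H"]]
  wH <- 1 / (dm + 1)^2
  wH[!is.finite(dm)] <- 0
  hN <- mol@atoms$implicitH
  vapply(seq_len(n), function(i) {
    sum(w[i, ] * (en - en[i])) + sum(wH[i, ] * hN * (enH - en[i]))
  }, numeric(1))
}

#' Pi electronegativity (tabulated valence-state reference form)
#'
#' Tabulated pi-orbital electronegativity of the atom's valence state for
#' pi-capable atoms (sp2/sp or aromatic C, N, O, S); saturated atoms carry 0.
#'
#' @param mol a \code{\link{MoleculeRecord}}
#' @return numeric vector, one value per heavy atom
#' @export
piElectronegativity <- function(mol) {
  stopifnot(is(mol, "MoleculeRecord"))
  n <- atomCount(mol)
  vapply(seq_len(n), function(i) {
    hy <- mol@atoms$hybridization[i]
    if (mol@atoms$aromatic[i]) hy <- "sp2"
    key <- paste0(mol@atoms$element[i], ".", hy)
    if (key %in% names(.PI_EN)) .PI_EN[[key]] else 0
  }, numeric(1))
}

#' Bond-charge-increment partial charges (force-field-style reference form)
#'
#' Self-contained partial-charge scheme in the spirit of force-field charge
#' assignment: each bond contributes an increment proportional to the Pauling
#' electronegativity difference of its two atoms times the bond order;
#' implicit hydrogens contribute their increments to the carrier, and formal
#' charges are added. For exact MMFF94 charges select the
#' \code{"openbabel"} provider (see \code{\link{descriptorProviderMap}}).
#'
#' @param mol a \code{\link{MoleculeRecord}}
#' @param scale increment per unit electronegativity difference and bond
#'   order (default 0.12)
#' @return numeric vector, one charge per heavy atom
#' @export
bciCharges <- function(mol, scale = 0.12) {
  stopifnot(is(mol, "MoleculeRecord"))
  n <- atomCount(mol)
  en <- .PAULING_EN[mol@atoms$element]
  en[is.na(en)] <- 2.50
  q <- as.numeric(mol@atoms$formalCharge)
  b <- mol@bonds
  if (nrow(b)) {
    for (r in seq_len(nrow(b))) {
      i <- b[r, "from"]; j <- b[r, "to"]
      inc <- scale * (en[j] - en[i]) * b[r, "order"]
      q[i] <- q[i] + inc
      q[j] <- q[j] - inc
    }
  }
  q + mol@atoms$implicitH * scale * (.PAULING_EN[["H"]] - en)
}

# ---------------------------------------------------------------------------
# Open Babel MMFF94 provider

#' MMFF94 partial charges via Open Babel
#'
#' Writes the molecules to a temporary SDF, runs the \code{obabel}
#' command-line tool with \code{--partialcharge mmff94} (hydrogens added for
#' the assignment), and folds hydrogen charges back into their heavy
#' carriers. Requires \code{obabel} on the PATH.
#'
#' @param mols list of \code{\link{MoleculeRecord}}
#' @return list of numeric charge vectors, one per molecule
#' @export
mmffChargesOB <- function(mols) {
  if (Sys.which("obabel") == "")
    stop("the 'openbabel' provider requires the obabel executable on the PATH")
  sdf <- tempfile(fileext = ".sdf")
  mol2 <- tempfile(fileext = ".mol2")
  on.exit(unlink(c(sdf, mol2)), add = TRUE)
  writeLabeledSdf(mols, sdf, writeLabels = FALSE)
  status <- system2("obabel", c("-isdf", sdf, "-omol2", "-O", mol2, "-h",
                                "--partialcharge", "mmff94"),
                    stdout = FALSE, stderr = FALSE)
  if (status != 0L) stop("obabel failed while assigning MMFF94 charges")
  ln <- readLines(mol2, warn = FALSE)
  starts <- grep("^@<TRIPOS>MOLECULE", ln)
  out <- vector("list", length(mols))
  for (m in seq_along(starts)) {
    end <- if (m < length(starts)) starts[m + 1L] - 1L else length(ln)
    blk <- ln[starts[m]:end]
    aStart <- grep("^@<TRIPOS>ATOM", blk)[1L] + 1L
    aEnd <- grep("^@<TRIPOS>BOND", blk)[1L] - 1L
    at <- read.table(text = blk[aStart:aEnd], stringsAsFactors = FALSE)
    chg <- as.numeric(at[[ncol(at)]])
    isH <- grepl("^H", at[[6L]])
    bStart <- grep("^@<TRIPOS>BOND", blk)[1L] + 1L
    bEnd <- length(blk)
    while (bEnd >= bStart && !grepl("^\\s*\\d", blk[bEnd])) bEnd <- bEnd - 1L
    q <- chg[!isH]
    if (bEnd >= bStart) {
      bt <- read.table(text = blk[bStart:bEnd], stringsAsFactors = FALSE)
      hmap <- cumsum(!isH)  # mol2 index -> heavy index
      for (r in seq_len(nrow(bt))) {
        i <- bt[[2L]][r]; j <- bt[[3L]][r]
        if (isH[i] && !isH[j]) q[hmap[j]] <- q[hmap[j]] + chg[i]
        if (isH[j] && !isH[i]) q[hmap[i]] <- q[hmap[i]] + chg[j]
      }
    }
    out[[m]] <- q
  }
  out
}

# ---------------------------------------------------------------------------
# provider registry

.providerRegistry <- new.env(parent = emptyenv())

#' Register a physicochemical descriptor provider
#'
#' A provider fills one or more named descriptor slots for every heavy atom
#' of a molecule (no partial fills). The built-in \code{"reference"} provider
#' covers nine slots; \code{"bci"} (default) and \code{"openbabel"} provide
#' \code{mmff94_charge}.
#'
#' @param name provider name
#' @param provides character vector of slot names the provider fills
#' @param fun \code{function(mol, dm)} returning a numeric matrix with one
#'   row per heavy atom and one named column per provided slot
#' @return invisibly, the provider name
#' @export
registerDescriptorProvider <- function(name, provides, fun) {
  stopifnot(is.character(name), length(name) == 1L,
            all(provides %in% .PHYSCHEM_SLOTS), is.function(fun))
  assign(name, list(name = name, provides = provides, compute = fun),
         envir = .providerRegistry)
  invisible(name)
}

#' Default slot-to-provider mapping
#' @return named character vector mapping every physicochemical slot to the
#'   provider that fills it by default
#' @export
descriptorProviderMap <- function() {
  m <- rep("reference", length(.PHYSCHEM_SLOTS))
  names(m) <- .PHYSCHEM_SLOTS
  m[["mmff94_charge"]] <- "bci"
  m
}

.referenceProviderCompute <- function(mol, dm) {
  n <- atomCount(mol)
  deg <- vapply(seq_len(n), function(i) atomDegree(mol, i), numeric(1))
  val <- vapply(seq_len(n), function(i) formalValence(mol, i), numeric(1))
  pol <- polarizabilities(mol, dm)
  vsepr <- vapply(seq_len(n), function(i) vseprGeometry(mol, i), integer(1))
  peoe <- peoeCharges(mol)
  cbind(atom_degree = deg, formal_valence = val,
        hybrid_polarizability = pol$hybrid,
        vsepr_geometry = as.numeric(vsepr),
        effective_polarizability = pol$effective,
        inductive_effect = inductiveEffect(mol, dm),
        peoe_sigma_charge = peoe$sigmaCharge,
        peoe_sigma_electronegativity = peoe$sigmaElectronegativity,
        pi_electronegativity = piElectronegativity(mol))
}

.initProviders <- function() {
  registerDescriptorProvider("reference",
    setdiff(.PHYSCHEM_SLOTS, "mmff94_charge"),
    .referenceProviderCompute)
  registerDescriptorProvider("bci", "mmff94_charge",
    function(mol, dm) cbind(mmff94_charge = bciCharges(mol)))
  registerDescriptorProvider("openbabel", "mmff94_charge",
    function(mol, dm) cbind(mmff94_charge = mmffChargesOB(list(mol))[[1L]]))
}

# resolve (and validate) the providers needed for a slot selection; errors at
# configuration time, not at compute time
.resolveProviders <- function(slots, providerMap = descriptorProviderMap()) {
  if (!length(ls(.providerRegistry))) .initProviders()
  unknown <- setdiff(slots, .PHYSCHEM_SLOTS)
  if (length(unknown))
    stop("unknown descriptor slot(s): ", paste(unknown, collapse = ", "))
  sel <- providerMap[slots]
  if (anyNA(sel))
    stop("no provider configured for slot(s): ",
         paste(slots[is.na(sel)], collapse = ", "))
  for (p in unique(sel)) {
    if (!exists(p, envir = .providerRegistry))
      stop(sprintf("descriptor provider '%s' is not registered", p))
    prov <- get(p, envir = .providerRegistry)
    missing <- setdiff(slots[sel == p], prov$provides)
    if (length(missing))
      stop(sprintf("provider '%s' does not fill slot(s) %s", p,
                   paste(missing, collapse = ", ")))
  }
  sel
}

#' Physicochemical descriptor matrix of one molecule
#'
#' Computes the enabled physicochemical slots for every heavy atom through
#' the configured providers. Disabling a slot removes exactly that named
#' column; the column order always follows \code{\link{physchemSlots}}.
#'
#' @param mol a \code{\link{MoleculeRecord}}
#' @param slots enabled slot names (default: all ten)
#' @param providerMap named slot-to-provider mapping (default
#'   \code{\link{descriptorProviderMap}})
#' @param dm optional precomputed distance matrix
#' @return numeric matrix, one row per heavy atom, named columns
#' @export
physchemDescriptors <- function(mol, slots = physchemSlots(),
                                providerMap = descriptorProviderMap(),
                                dm = NULL) {
  stopifnot(is(mol, "MoleculeRecord"))
  slots <- .PHYSCHEM_SLOTS[.PHYSCHEM_SLOTS %in% slots]
  sel <- .resolveProviders(slots, providerMap)
  if (is.null(dm)) dm <- topologicalDistances(mol)
  cols <- vector("list", 0L)
  for (p in unique(sel)) {
    prov <- get(p, envir = .providerRegistry)
    res <- prov$compute(mol, dm)
    for (s in slots[sel == p]) cols[[s]] <- res[, s]
  }
  out <- do.call(cbind, cols[slots])
  colnames(out) <- slots
  out
}

#' Topological descriptor matrix of one molecule
#' @inheritParams physchemDescriptors
#' @return numeric matrix with the four columns of \code{\link{topoSlots}}
#' @export
topoDescriptorMatrix <- function(mol, dm = NULL) {
  if (is.null(dm)) dm <- topologicalDistances(mol)
  t(vapply(seq_len(atomCount(mol)), function(i) topoDescriptors(dm, i),
           numeric(4L)))
}
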