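#' @import methods
NULL

#' Perceived small molecule with optional atom-level SOM labels
#'
#' A \code{MoleculeRecord} holds the heavy-atom graph of one small molecule
#' after perception: explicit hydrogens folded into implicit counts,
#' aromaticity and hybridization assigned by the package's single perception
#' model, and every atom mapped to a SYBYL atom type from the configured type
#' table. Site-of-metabolism (SOM) annotations, when present, are a set of
#' heavy-atom indices (1-based, matching SDF convention in files).
#'
#' @slot molId single molecule identifier.
#' @slot atoms \code{data.frame} with one row per heavy atom and columns
#'   \code{element}, \code{formalCharge}, \code{implicitH}, \code{aromatic},
#'   \code{hybridization} (one of \code{"sp"}, \code{"sp2"}, \code{"sp3"},
#'   \code{"other"}), \code{sybylType}, \code{typeOrdinal}.
#' @slot bonds integer matrix with columns \code{from}, \code{to},
#'   \code{order}, \code{aromatic}; each bond stored once.
#' @slot somLabels integer vector of labeled heavy-atom indices (may be empty).
#' @slot labeled \code{TRUE} if the record carries SOM annotations (an empty
#'   label set on a labeled record means "no SOM anywhere"; unlabeled records
#'   are excluded from training).
#' @slot typeTable the SYBYL type table used at perception (see
#'   \code{\link{sybylTypeTable}}).
#'
#' @seealso \code{\link{perceiveMolecule}}, \code{\link{readLabeledSdf}}
#' @export
setClass("MoleculeRecord",
  representation(
    molId = "character",
    atoms = "data.frame",
    bonds = "matrix",
    somLabels = "integer",
    labeled = "logical",
    typeTable = "data.frame"
  )
)

setValidity("MoleculeRecord", function(object) {
  msgs <- character(0)
  n <- nrow(object@atoms)
  need <- c("element", "formalCharge", "implicitH", "aromatic",
            "hybridization", "sybylType", "typeOrdinal")
  if (!all(need %in% names(object@atoms)))
    msgs <- c(msgs, "atoms table is missing required columns")
  if (n < 1L) msgs <- c(msgs, "molecule must have at least one heavy atom")
  if (length(msgs) == 0L && any(object@atoms$implicitH < 0L))
    msgs <- c(msgs, "implicit hydrogen counts must be >= 0")
  b <- object@bonds
  if (nrow(b) > 0L) {
    if (any(b[, "from"] < 1L | b[, "from"] > n | b[, "to"] < 1L | b[, "to"] > n))
      msgs <- c(msgs, "bond references an invalid atom index")
    if (any(b[, "from"] == b[, "to"]))
      msgs <- c(msgs, "self-bond found")
    key <- paste(pmin(b[, "from"], b[, "to"]), pmax(b[, "from"], b[, "to"]))
    if (anyDuplicated(key))
      msgs <- c(msgs, "duplicate bond found (each bond must be stored once)")
  }
  if (length(object@somLabels) > 0L &&
      (any(object@somLabels < 1L) || any(object@somLabels > n)))
    msgs <- c(msgs, "SOM label index outside the heavy-atom range")
  if (length(msgs)) msgs else TRUE
})

#' @describeIn MoleculeRecord compact display
#' @param object a \code{MoleculeRecord}
#' @export
setMethod("show", "MoleculeRecord", function(object) {
  cat(sprintf("MoleculeRecord %s: %d heavy atoms, %d bonds, %s\n",
              object@molId, nrow(object@atoms), nrow(object@bonds),
              if (object@labeled)
                sprintf("%d SOM label(s)", length(object@somLabels))
              else "unlabeled"))
  invisible(NULL)
})

#' @rdname MoleculeRecord
#' @param x a \code{MoleculeRecord}
#' @export
molId <- function(x) x@molId

#' @rdname MoleculeRecord
#' @export
atomTable <- function(x) x@atoms

#' @rdname MoleculeRecord
#' @export
bondTable <- function(x) x@bonds

#' @rdname MoleculeRecord
#' @export
somLabels <- function(x) x@somLabels

#' @rdname MoleculeRecord
#' @export
isLabeled <- function(x) x@labeled

#' @rdname MoleculeRecord
#' @export
atomCount <- function(x) nrow(x@atoms)

#' Trained atom-level SOM classifier
#'
#' Bundles the fitted random forest with everything needed to reproduce its
#' predictions: the ordered feature schema, the training configuration
#' (radius, fingerprint kind, descriptor slots, threshold, seed), the binary
#' FAME fingerprints of all training atoms (the reference set for the
#' applicability-domain score) and a model-format version string.
#'
#' @slot forest fitted \code{ranger} probability forest.
#' @slot featureSchema ordered character vector of feature column names.
#' @slot referenceFps sparse 0/1 matrix (\code{dgCMatrix}) of training-atom
#'   binary fingerprints, or \code{NULL} when the bundle was stripped.
#' @slot config the resolved \code{\link{somTrainingConfig}} list.
#' @slot version model format version string.
#' @export
setClass("SomModel",
  representation(
    forest = "ANY",
    featureSchema = "character",
    referenceFps = "ANY",
    config = "list",
    version = "character"
  )
)

#' @describeIn SomModel compact display
#' @param object a \code{SomModel}
#' @export
setMethod("show", "SomModel", function(object) {
  cat(sprintf(paste0(
    "SomModel (format %s)\n",
    "  trees: %d, features: %d, threshold: %.2f\n",
    "  fingerprint: %s, radius: %d, reference atoms: %d\n"),
    object@version, object@config$nTrees, length(object@featureSchema),
    object@config$threshold, object@config$fingerprintKind,
    object@config$radius,
    if (is.null(object@referenceFps)) 0L else nrow(object@referenceFps)))
  invisible(NULL)
})

#' Atom- and molecule-level performance report
#'
#' Holds the metric suite for one evaluation run: threshold-free ranking
#' metrics (ROC-AUC by the rank/Mann-Whitney formulation with half-credit for
#' ties; PR-AUC as step-wise average precision), confusion-matrix metrics at
#' the decision threshold (F1, MCC, precision, recall), and the
#' molecule-level top-2 correctness rate.
#'
#' @slot rocAuc,prAuc,f1,mcc,precision,recall,top2 numeric metrics
#'   (\code{NA} where undefined, see \code{flags}).
#' @slot nAtoms,nMolecules,nPositive,nExcludedMolecules integer counts.
#' @slot threshold decision threshold used for the confusion metrics.
#' @slot flags character vector of degeneracy notes (e.g. single-class input).
#' @export
setClass("MetricsReport",
  representation(
    rocAuc = "numeric", prAuc = "numeric", f1 = "numeric", mcc = "numeric",
    precision = "numeric", recall = "numeric", top2 = "numeric",
    nAtoms = "integer", nMolecules = "integer", nPositive = "integer",
    nExcludedMolecules = "integer",
    threshold = "numeric", flags = "character"
  ),
  prototype(top2 = NA_real_, nMolecules = 0L, nExcludedMolecules = 0L,
            flags = character(0))
)

#' @describeIn MetricsReport compact display
#' @param object a \code{MetricsReport}
#' @export
setMethod("show", "MetricsReport", function(object) {
  cat("MetricsReport\n")
  cat(sprintf("  atoms: %d (%d positive), molecules: %d, threshold: %.2f\n",
              object@nAtoms, object@nPositive, object@nMolecules,
              object@threshold))
  fmt <- function(x) ifelse(is.na(x), "NA", sprintf("%.4f", x))
  cat(sprintf("  ROC-AUC %s  PR-AUC %s  F1 %s  MCC %s\n",
              fmt(object@rocAuc), fmt(object@prAuc), fmt(object@f1),
              fmt(object@mcc)))
  cat(sprintf("  precision %s  recall %s  TOP-2 %s\n",
              fmt(object@precision), fmt(object@recall), fmt(object@top2)))
  if (length(object@flags))
    cat("  flags:", paste(object@flags, collapse = "; "), "\n")
  invisible(NULL)
})

#' Convert a MetricsReport to a plain list (e.g. for JSON output)
#' @param report a \code{\link{MetricsReport}}
#' @return named list of metrics and counts
#' @export
metricsAsList <- function(report) {
  stopifnot(is(report, "MetricsReport"))
  list(
    roc_auc = report@rocAuc, pr_auc = report@prAuc, f1 = report@f1,
    mcc = report@mcc, precision = report@precision, recall = report@recall,
    top2 = report@top2, n_atoms = report@nAtoms,
    n_molecules = report@nMolecules, n_positive = report@nPositive,
    n_excluded_molecules = report@nExcludedMolecules,
    threshold = report@threshold,
    flags = as.list(report@flags)
  )
}
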