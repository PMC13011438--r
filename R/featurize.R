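# Assembly of the per-atom feature table: fingerprint columns, the enabled
# physicochemical slots, and the four topological descriptors, in a fixed
# global order serialized with the model so train/predict layouts can never
# diverge.

#' Featurization configuration
#'
#' @param radius fingerprint bond radius (default 5)
#' @param fingerprintKind \code{"fame_binary"} (32-bit block encoding) or
#'   \code{"count"}
#' @param slots enabled physicochemical descriptor slots
#' @param providerMap slot-to-provider mapping
#' @param typeTable SYBYL type table
#' @return a classed list used by \code{\link{featurizeAtoms}}
#' @export
featurizationConfig <- function(radius = 5L,
                                fingerprintKind = c("fame_binary", "count"),
                                slots = physchemSlots(),
                                providerMap = descriptorProviderMap(),
                                typeTable = sybylTypeTable()) {
  fingerprintKind <- match.arg(fingerprintKind)
  stopifnot(radius >= 0L)
  .resolveProviders(.PHYSCHEM_SLOTS[.PHYSCHEM_SLOTS %in% slots], providerMap)
  structure(list(radius = as.integer(radius),
                 fingerprintKind = fingerprintKind,
                 slots = .PHYSCHEM_SLOTS[.PHYSCHEM_SLOTS %in% slots],
                 providerMap = providerMap,
                 typeTable = typeTable),
            class = "somkit_featurization")
}

#' Featurize every heavy atom of a molecule list
#'
#' Computes, per heavy atom, the rooted circular fingerprint (binary FAME or
#' count variant), the enabled physicochemical descriptors and the four
#' topological descriptors. Molecules whose descriptors cannot be computed
#' (e.g. missing element parameters) are skipped with a logged reason and the
#' run continues.
#'
#' @param mols list of \code{\link{MoleculeRecord}}
#' @param config a \code{\link{featurizationConfig}}
#' @return list with \code{features} (numeric matrix), \code{info}
#'   (\code{data.frame} with \code{molId}, \code{atomIdx}, \code{element},
#'   \code{sybylType}, \code{label} — \code{NA} for unlabeled molecules),
#'   \code{skipped} (named character vector of reasons), and \code{schema}
#'   (feature column names)
#' @export
featurizeAtoms <- function(mols, config = featurizationConfig()) {
  stopifnot(inherits(config, "somkit_featurization"))
  feats <- vector("list", length(mols))
  infos <- vector("list", length(mols))
  skipped <- character(0)
  for (m in seq_along(mols)) {
    mol <- mols[[m]]
    res <- tryCatch({
      if (!identical(mol@typeTable$code, config$typeTable$code))
        .perceptionError("molecule perceived under a different type table")
      dm <- topologicalDistances(mol)
      counts <- .countMatrix(mol, config$radius, dm)
      fp <- if (config$fingerprintKind == "fame_binary")
        .binaryFromCounts(counts, config$typeTable, config$radius)
      else counts
      pc <- physchemDescriptors(mol, config$slots, config$providerMap, dm)
      topo <- topoDescriptorMatrix(mol, dm)
      storage.mode(fp) <- "double"
      cbind(fp, pc, topo)
    }, somkit_perception_error = function(e) e)
    if (inherits(res, "condition")) {
      skipped[mol@molId] <- conditionMessage(res)
      message(sprintf("skipping %s: %s", mol@molId, conditionMessage(res)))
      next
    }
    n <- atomCount(mol)
    lab <- if (mol@labeled) as.integer(seq_len(n) %in% mol@somLabels)
           else rep(NA_integer_, n)
    feats[[m]] <- res
    infos[[m]] <- data.frame(molId = mol@molId, atomIdx = seq_len(n),
                             element = mol@atoms$element,
                             sybylType = mol@atoms$sybylType,
                             label = lab, stringsAsFactors = FALSE)
  }
  keep <- !vapply(feats, is.null, logical(1))
  if (!any(keep)) stop("no molecule could be featurized")
  features <- do.call(rbind, feats[keep])
  rownames(features) <- NULL
  list(features = features,
       info = do.call(rbind, infos[keep]),
       skipped = skipped,
       schema = colnames(features))
}
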