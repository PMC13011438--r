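# Trainable random-forest SOM classifier: training, probability prediction,
# thresholded calls, within-molecule ranking, and versioned serialization.

.MODEL_FORMAT <- "somkit-model-1"

#' Training configuration
#'
#' Defaults: 250 trees, sqrt-feature sampling, unweighted classes,
#' decision threshold 0.3 (calls use \code{p >= threshold}), binary FAME
#' fingerprints at radius 5, all ten physicochemical slots enabled,
#' applicability-domain neighbourhood k = 3. Every field is overridable; the
#' determinism contract is that identical (data, config, seed) reproduce
#' identical predictions.
#'
#' @param radius fingerprint bond radius
#' @param fingerprintKind \code{"fame_binary"} or \code{"count"}
#' @param nTrees number of trees
#' @param maxFeatures \code{"sqrt"} or an integer mtry
#' @param classWeight \code{"none"} (default; forest probabilities keep the
#'   class prior, matching the sub-0.5 decision threshold) or
#'   \code{"balanced"} (inverse class frequency case weights)
#' @param threshold decision threshold in (0, 1)
#' @param seed integer RNG seed for the forest
#' @param slots enabled physicochemical descriptor slots
#' @param providerMap slot-to-provider mapping
#' @param reliabilityK neighbourhood size of the FAME score
#' @return a named list
#' @export
somTrainingConfig <- function(radius = 5L,
                              fingerprintKind = c("fame_binary", "count"),
                              nTrees = 250L, maxFeatures = "sqrt",
                              classWeight = c("none", "balanced"),
                              threshold = 0.3, seed = 1L,
                              slots = physchemSlots(),
                              providerMap = descriptorProviderMap(),
                              reliabilityK = 3L) {
  fingerprintKind <- match.arg(fingerprintKind)
  classWeight <- match.arg(classWeight)
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  if (nTrees < 1L) stop("nTrees must be >= 1")
  list(radius = as.integer(radius), fingerprintKind = fingerprintKind,
       nTrees = as.integer(nTrees), maxFeatures = maxFeatures,
       classWeight = classWeight, threshold = threshold,
       seed = as.integer(seed), slots = slots, providerMap = providerMap,
       reliabilityK = as.integer(reliabilityK))
}

.featConfigFromTraining <- function(config, typeTable = sybylTypeTable()) {
  featurizationConfig(radius = config$radius,
                      fingerprintKind = config$fingerprintKind,
                      slots = config$slots,
                      providerMap = config$providerMap,
                      typeTable = typeTable)
}

#' Train the atom-level SOM random forest
#'
#' Featurizes every labeled molecule (each annotated heavy atom is a
#' positive, every other heavy atom of a labeled molecule a negative;
#' unlabeled molecules are excluded), fits a probability random forest, and
#' bundles it with the feature schema, the resolved configuration and the
#' binary FAME fingerprints of all training atoms (the reference set of the
#' applicability-domain score, so reliability scoring never needs the raw
#' training structures).
#'
#' @param mols list of \code{\link{MoleculeRecord}}, at least some labeled
#' @param config a \code{\link{somTrainingConfig}}
#' @return a \code{\link{SomModel}}
#' @export
trainSomModel <- function(mols, config = somTrainingConfig()) {
  labeled <- Filter(isLabeled, mols)
  if (!length(labeled)) stop("no labeled molecules in the training input")
  fc <- .featConfigFromTraining(config, labeled[[1L]]@typeTable)
  fz <- featurizeAtoms(labeled, fc)
  y <- fz$info$label
  nPos <- sum(y == 1L); nNeg <- sum(y == 0L)
  if (nPos == 0L || nNeg == 0L)
    stop("training data must contain at least one positive and one negative atom")
  mtry <- if (identical(config$maxFeatures, "sqrt"))
    max(1L, floor(sqrt(ncol(fz$features)))) else as.integer(config$maxFeatures)
  w <- if (config$classWeight == "balanced") {
    n <- length(y)
    ifelse(y == 1L, n / (2 * nPos), n / (2 * nNeg))
  } else rep(1, length(y))
  forest <- ranger::ranger(
    x = fz$features, y = factor(y, levels = c(0L, 1L)),
    num.trees = config$nTrees, mtry = mtry, probability = TRUE,
    case.weights = w, seed = config$seed, num.threads = 1L,
    verbose = FALSE)
  keptMols <- labeled[vapply(labeled, molId, character(1)) %in%
                        unique(fz$info$molId)]
  refFps <- .binaryFpMatrix(keptMols, config$radius)
  new("SomModel", forest = forest, featureSchema = fz$schema,
      referenceFps = refFps, config = config, version = .MODEL_FORMAT)
}

.checkSchema <- function(model, schema) {
  if (!identical(model@featureSchema, schema)) {
    d <- which(model@featureSchema[seq_len(min(length(model@featureSchema),
                                               length(schema)))] !=
               schema[seq_len(min(length(model@featureSchema),
                                  length(schema)))])
    stop(sprintf(paste0(
      "feature schema mismatch: model has %d columns, featurization %d; ",
      "first difference at position %s (model '%s' vs data '%s')"),
      length(model@featureSchema), length(schema),
      if (length(d)) d[1L] else "end",
      if (length(d)) model@featureSchema[d[1L]] else "-",
      if (length(d)) schema[d[1L]] else "-"))
  }
}

#' Predict sites of metabolism
#'
#' Featurizes the query molecules under the model's stored configuration
#' (refusing to run on any schema mismatch), predicts a per-heavy-atom SOM
#' probability, applies the decision threshold (call = \code{p >=
#' threshold}), and ranks atoms within each molecule by descending
#' probability (ties broken by ascending atom index, so ranks are a
#' permutation of 1..n). Optionally attaches the two reliability metrics:
#' the FAME applicability-domain score (always computed on binary FAME
#' fingerprints, whatever the training representation) and the Shannon
#' entropy of the probability. Unfeaturizable molecules are skipped with a
#' logged reason.
#'
#' @param model a \code{\link{SomModel}}
#' @param mols list of \code{\link{MoleculeRecord}}
#' @param withReliability attach \code{fameScore}/\code{shannonEntropy}
#'   columns
#' @return \code{data.frame} with columns \code{molId}, \code{atomIdx},
#'   \code{element}, \code{probability}, \code{call}, \code{rank} and, when
#'   requested, \code{fameScore} and \code{shannonEntropy}
#' @export
predictSom <- function(model, mols, withReliability = FALSE) {
  stopifnot(is(model, "SomModel"))
  if (withReliability && is.null(model@referenceFps))
    stop("model bundle carries no reference fingerprints; reliability scoring unavailable")
  fc <- .featConfigFromTraining(model@config, mols[[1L]]@typeTable)
  fz <- featurizeAtoms(mols, fc)
  .checkSchema(model, fz$schema)
  pr <- predict(model@forest, data = fz$features, num.threads = 1L)
  p <- pr$predictions[, "1"]
  out <- data.frame(molId = fz$info$molId, atomIdx = fz$info$atomIdx,
                    element = fz$info$element, probability = p,
                    call = p >= model@config$threshold,
                    rank = NA_integer_, stringsAsFactors = FALSE)
  for (id in unique(out$molId)) {
    rows <- which(out$molId == id)
    ord <- order(-out$probability[rows], out$atomIdx[rows])
    out$rank[rows[ord]] <- seq_along(rows)
  }
  if (withReliability) {
    keptMols <- mols[vapply(mols, molId, character(1)) %in% unique(fz$info$molId)]
    q <- .binaryFpMatrix(keptMols, model@config$radius)
    if (ncol(q) != ncol(model@referenceFps))
      stop(sprintf("fingerprint schema mismatch: query %d vs reference %d bits",
                   ncol(q), ncol(model@referenceFps)))
    out$fameScore <- .fameScoresBatch(q, model@referenceFps,
                                      model@config$reliabilityK)
    out$shannonEntropy <- shannonEntropy(p)
  }
  attr(out, "skipped") <- fz$skipped
  out
}

#' Save / load a model bundle
#'
#' The bundle is a single-file archive (RDS) holding the forest state, the
#' feature schema, the resolved configuration, the reference fingerprints
#' and the model-format version. Loading verifies the format version and
#' refuses silent reinterpretation; a corrupted file raises an integrity
#' error. Round-tripping preserves predictions bit-identically.
#'
#' @param model a \code{\link{SomModel}}
#' @param path file path
#' @return \code{loadSomModel} returns the restored \code{\link{SomModel}}
#' @export
saveSomModel <- function(model, path) {
  stopifnot(is(model, "SomModel"))
  saveRDS(list(format = .MODEL_FORMAT,
               package = as.character(utils::packageVersion("somkit")),
               model = model), path)
  invisible(path)
}

#' @rdname saveSomModel
#' @export
loadSomModel <- function(path) {
  bundle <- tryCatch(readRDS(path), error = function(e)
    stop(sprintf("corrupted or unreadable model bundle '%s': %s", path,
                 conditionMessage(e))))
  if (!is.list(bundle) || is.null(bundle$format))
    stop(sprintf("'%s' is not a somkit model bundle", path))
  if (!identical(bundle$format, .MODEL_FORMAT))
    stop(sprintf("model format mismatch: bundle '%s', this package reads '%s'",
                 bundle$format, .MODEL_FORMAT))
  bundle$model
}
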