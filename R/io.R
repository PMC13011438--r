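# Readers and writers: labeled SDF V2000 (SOM annotations carried as the
# <SOM_LABELS> SD property, 1-based atom indices by SDF convention), SMILES
# input, deterministic prediction CSV, JSON metric reports.

.CHARGE_TO_CODE <- c(`3` = 1L, `2` = 2L, `1` = 3L, `-1` = 5L, `-2` = 6L,
                     `-3` = 7L)

#' Read a (possibly SOM-labeled) SDF file
#'
#' Reads a multi-record V2000 SDF, perceives every record through
#' \code{\link{perceiveMolecule}}, and attaches SOM annotations from the
#' \code{<SOM_LABELS>} SD property (comma-separated 1-based atom indices;
#' records without the property are unlabeled). \code{M  CHG} lines override
#' atom-line charge codes. Malformed records — unparsable structures, valence
#' errors, label indices outside the heavy-atom range — are skipped with a
#' logged reason; a summary line (read/kept/skipped) is always emitted.
#'
#' @param path SDF file path
#' @param typeTable SYBYL type table
#' @param onUnknownElement \code{"reject"} or \code{"any"}
#' @return list of \code{\link{MoleculeRecord}}; error if no record survives
#' @export
readLabeledSdf <- function(path, typeTable = sybylTypeTable(),
                           onUnknownElement = c("reject", "any")) {
  onUnknownElement <- match.arg(onUnknownElement)
  str <- ChemmineR::read.SDFstr(path)
  nRec <- length(str@a)
  mols <- vector("list", nRec)
  nSkip <- 0L
  for (i in seq_len(nRec)) {
    lines <- str@a[[i]]
    id <- trimws(lines[1L])
    if (!nzchar(id)) id <- sprintf("MOL%04d", i)
    mol <- tryCatch({
      m <- perceiveMolecule(lines, id, typeTable, onUnknownElement)
      propIdx <- grep("^>.*<SOM_LABELS>", lines)
      if (length(propIdx)) {
        raw <- trimws(lines[propIdx[1L] + 1L])
        lab <- if (nzchar(raw) && !startsWith(raw, "$$$$"))
          suppressWarnings(as.integer(strsplit(raw, ",")[[1]]))
        else integer(0)
        map <- attr(m, "indexMap")
        if (anyNA(lab) || any(lab < 1L) || any(lab > length(map)))
          .perceptionError("SOM label index outside the atom range")
        mapped <- map[lab]
        if (any(mapped == 0L))
          .perceptionError("SOM label refers to a removed atom (hydrogen or dropped fragment)")
        m@somLabels <- sort(unique(as.integer(mapped)))
        m@labeled <- TRUE
      }
      m
    }, error = function(e) {
      message(sprintf("skipping record %d (%s): %s", i, id,
                      conditionMessage(e)))
      NULL
    })
    if (is.null(mol)) nSkip <- nSkip + 1L else mols[[i]] <- mol
  }
  mols <- Filter(Negate(is.null), mols)
  message(sprintf("read %d record(s): kept %d, skipped %d",
                  nRec, length(mols), nSkip))
  if (!length(mols)) stop(sprintf("no valid record in '%s'", path))
  mols
}

#' Read molecules from a SMILES file
#'
#' One SMILES per line, optionally followed by a tab-separated molecule
#' identifier. Structures are converted through Open Babel (ChemmineOB) and
#' perceived with the standard pipeline; unparsable lines are skipped with a
#' logged reason.
#'
#' @inheritParams readLabeledSdf
#' @return list of (unlabeled) \code{\link{MoleculeRecord}}
#' @export
readSmilesFile <- function(path, typeTable = sybylTypeTable(),
                           onUnknownElement = c("reject", "any")) {
  onUnknownElement <- match.arg(onUnknownElement)
  ln <- readLines(path, warn = FALSE)
  ln <- ln[nzchar(trimws(ln))]
  mols <- vector("list", length(ln))
  nSkip <- 0L
  for (i in seq_along(ln)) {
    f <- strsplit(ln[i], "\t")[[1]]
    id <- if (length(f) > 1L && nzchar(trimws(f[2L]))) trimws(f[2L])
          else sprintf("SMI%04d", i)
    mols[[i]] <- tryCatch({
      txt <- ChemmineOB::convertFormat("SMI", "SDF",
                                       paste0(trimws(f[1L]), "\n"))
      rec <- strsplit(txt, "\n", fixed = TRUE)[[1L]]
      if (!length(rec) || !any(grepl("V2000", rec)))
        .perceptionError("SMILES did not convert")
      perceiveMolecule(rec, id, typeTable, onUnknownElement)
    }, error = function(e) {
      message(sprintf("skipping SMILES line %d (%s): %s", i, id,
                      conditionMessage(e)))
      nSkip <<- nSkip + 1L
      NULL
    })
  }
  mols <- Filter(Negate(is.null), mols)
  message(sprintf("read %d SMILES: kept %d, skipped %d",
                  length(ln), length(mols), nSkip))
  if (!length(mols)) stop(sprintf("no valid SMILES in '%s'", path))
  mols
}

.moleculeToSDF <- function(mol, comment = "", writeLabels = TRUE,
                           extraProps = NULL) {
  n <- atomCount(mol)
  nb <- nrow(mol@bonds)
  ab <- matrix(0, nrow = n, ncol = 15L,
               dimnames = list(paste(mol@atoms$element, seq_len(n), sep = "_"),
                               c("C1", "C2", "C3", paste0("C", 5:16))))
  code <- .CHARGE_TO_CODE[as.character(mol@atoms$formalCharge)]
  code[is.na(code)] <- 0L
  ab[, "C6"] <- code
  bb <- matrix(0L, nrow = nb, ncol = 7L,
               dimnames = list(seq_len(nb), paste0("C", 1:7)))
  if (nb) bb[, 1:3] <- mol@bonds[, c("from", "to", "order")]
  db <- character(0)
  if (writeLabels && mol@labeled)
    db <- c(db, SOM_LABELS = paste(mol@somLabels, collapse = ","))
  if (!is.null(extraProps)) db <- c(db, extraProps)
  header <- c(Molecule_Name = mol@molId, Source = "  somkit",
              Comment = comment,
              Counts_Line = sprintf(
                "%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nb))
  new(methods::className("SDF", "ChemmineR"), header = header, atomblock = ab, bondblock = bb,
      datablock = db)
}

#' Write molecules to a labeled SDF file
#'
#' Writes V2000 records with the Kekule bond orders fixed at perception and
#' SOM annotations as the \code{<SOM_LABELS>} SD property (1-based heavy-atom
#' indices). Output is deterministic: writing the same records twice yields
#' byte-identical files. The provenance string, when given, is embedded in
#' each record's comment line.
#'
#' @param mols list of \code{\link{MoleculeRecord}}
#' @param path output path
#' @param comment provenance/comment string for the record headers
#' @param writeLabels write the \code{<SOM_LABELS>} property for labeled
#'   records
#' @return invisibly, \code{path}
#' @export
writeLabeledSdf <- function(mols, path, comment = "", writeLabels = TRUE) {
  sdfs <- lapply(mols, .moleculeToSDF, comment = comment,
                 writeLabels = writeLabels)
  set <- new(methods::className("SDFset", "ChemmineR"), SDF = sdfs,
             ID = vapply(mols, molId, character(1)))
  ChemmineR::write.SDF(set, path)
  invisible(path)
}

#' Write predictions as annotated SDF
#'
#' Mirrors the prediction table into SD properties
#' (\code{<SOM_PROBABILITIES>}, \code{<SOM_CALLS>}, \code{<SOM_RANKS>} and,
#' when present, \code{<FAME_SCORES>}, \code{<SHANNON_ENTROPIES>}), one
#' comma-separated value per heavy atom in atom order.
#'
#' @param mols the predicted \code{\link{MoleculeRecord}} list
#' @param predictions prediction table from \code{\link{predictSom}}
#' @param path output path
#' @param comment provenance string
#' @return invisibly, \code{path}
#' @export
writeAnnotatedSdf <- function(mols, predictions, path, comment = "") {
  sdfs <- list()
  ids <- character(0)
  for (mol in mols) {
    rows <- predictions[predictions$molId == mol@molId, ]
    if (!nrow(rows)) next
    rows <- rows[order(rows$atomIdx), ]
    props <- c(SOM_PROBABILITIES = paste(sprintf("%.6f", rows$probability),
                                         collapse = ","),
               SOM_CALLS = paste(ifelse(rows$call, "true", "false"),
                                 collapse = ","),
               SOM_RANKS = paste(rows$rank, collapse = ","))
    if ("fameScore" %in% names(rows))
      props <- c(props,
                 FAME_SCORES = paste(sprintf("%.6f", rows$fameScore),
                                     collapse = ","),
                 SHANNON_ENTROPIES = paste(sprintf("%.6f",
                                                   rows$shannonEntropy),
                                           collapse = ","))
    sdfs[[length(sdfs) + 1L]] <- .moleculeToSDF(mol, comment = comment,
                                                writeLabels = FALSE,
                                                extraProps = props)
    ids <- c(ids, mol@molId)
  }
  if (!length(sdfs)) stop("no molecule with predictions to write")
  ChemmineR::write.SDF(new(methods::className("SDFset", "ChemmineR"), SDF = sdfs, ID = ids), path)
  invisible(path)
}

.provenanceLine <- function(config = NULL) {
  ver <- as.character(utils::packageVersion("somkit"))
  if (is.null(config)) return(sprintf("# somkit %s", ver))
  sprintf("# somkit %s config=%s", ver,
          jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                           force = TRUE))
}

#' Write a prediction table as deterministic CSV
#'
#' Fixed column order (\code{mol_id, atom_idx, element, probability, call,
#' rank[, fame_score, shannon_entropy]}), probabilities printed with six
#' decimals, comma-separated, UTF-8, LF line endings, preceded by one
#' provenance comment line embedding the resolved configuration. Reliability
#' columns are present exactly when the predictions carry them. Identical
#' predictions always produce byte-identical files.
#'
#' @param predictions prediction table from \code{\link{predictSom}}
#' @param path output path
#' @param config resolved configuration list echoed into the header comment
#' @return invisibly, \code{path}
#' @export
writePredictions <- function(predictions, path, config = NULL) {
  rel <- "fameScore" %in% names(predictions)
  header <- c("mol_id", "atom_idx", "element", "probability", "call", "rank",
              if (rel) c("fame_score", "shannon_entropy"))
  body <- sprintf("%s,%d,%s,%.6f,%s,%d", predictions$molId,
                  predictions$atomIdx, predictions$element,
                  predictions$probability,
                  ifelse(predictions$call, "true", "false"),
                  predictions$rank)
  if (rel)
    body <- sprintf("%s,%.6f,%.6f", body, predictions$fameScore,
                    predictions$shannonEntropy)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(.provenanceLine(config), paste(header, collapse = ","), body),
             con, sep = "\n")
  invisible(path)
}

#' Read a prediction CSV written by \code{\link{writePredictions}}
#' @param path CSV path
#' @return \code{data.frame} with the internal column names
#' @export
readPredictions <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  names(df)[names(df) == "mol_id"] <- "molId"
  names(df)[names(df) == "atom_idx"] <- "atomIdx"
  names(df)[names(df) == "fame_score"] <- "fameScore"
  names(df)[names(df) == "shannon_entropy"] <- "shannonEntropy"
  df$call <- df$call == "true" | df$call == "TRUE"
  df
}

#' Write a per-atom descriptor table as CSV
#'
#' One row per heavy atom: \code{mol_id, atom_idx (1-based), element,
#' sybyl_type}, the named feature columns of the featurization, and
#' \code{som_label} (1/0, empty for unlabeled molecules).
#'
#' @param mols list of \code{\link{MoleculeRecord}}
#' @param path output path
#' @param config a \code{\link{featurizationConfig}}
#' @return invisibly, \code{path}
#' @export
writeDescriptorsCsv <- function(mols, path, config = featurizationConfig()) {
  fz <- featurizeAtoms(mols, config)
  header <- c("mol_id", "atom_idx", "element", "sybyl_type", fz$schema,
              "som_label")
  featTxt <- apply(fz$features, 1L, function(r)
    paste(formatC(r, format = "g", digits = 6), collapse = ","))
  lab <- ifelse(is.na(fz$info$label), "", as.character(fz$info$label))
  body <- sprintf("%s,%d,%s,%s,%s,%s", fz$info$molId, fz$info$atomIdx,
                  fz$info$element, fz$info$sybylType, featTxt, lab)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(.provenanceLine(config[c("radius", "fingerprintKind",
                                        "slots")]),
               paste(header, collapse = ","), body), con, sep = "\n")
  invisible(path)
}

#' Write an evaluation report as JSON
#'
#' Emits the \code{\link{MetricsReport}} (plus any extra sections, e.g. the
#' reliability-correlation table) with the resolved configuration embedded,
#' via deterministic JSON serialization.
#'
#' @param report a \code{\link{MetricsReport}}
#' @param path output path
#' @param config resolved configuration list
#' @param extra optional named list merged into the document
#' @return invisibly, \code{path}
#' @export
writeMetricsReport <- function(report, path, config = NULL, extra = NULL) {
  doc <- c(list(somkit = as.character(utils::packageVersion("somkit")),
                config = config,
                metrics = metricsAsList(report)), extra)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null", null = "null")
  invisible(path)
}
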