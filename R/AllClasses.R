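#' Molecule: a parsed small molecule
#'
#' Holds the hydrogen-complete atom/bond graph of one molecule parsed from a
#' SMILES string, optionally with seeded 3D coordinates (Angstrom) and
#' Gasteiger partial charges attached by \code{\link{embed3d}}.
#'
#' @slot smiles input SMILES string.
#' @slot canonical canonical SMILES re-serialisation of the parsed graph.
#' @slot atoms data.frame with one row per atom (explicit hydrogens
#'   included): \code{element}, \code{x}, \code{y}, \code{z},
#'   \code{charge} (Gasteiger partial charge; NA until embedded).
#' @slot bonds data.frame with one row per bond: 1-based atom indices
#'   \code{a1}, \code{a2}, integer \code{order} (aromatic bonds carry 4),
#'   logical \code{aromatic}.
#' @slot has3D TRUE once 3D coordinates have been generated.
#' @slot seed integer seed recorded at embedding time (NA before).
#'
#' @examples
#' mol <- parseSmiles("CCO")
#' nAtoms(mol)
#' @export
setClass("Molecule",
  representation(
    smiles    = "character",
    canonical = "character",
    atoms     = "data.frame",
    bonds     = "data.frame",
    has3D     = "logical",
    seed      = "integer"
  ),
  prototype(has3D = FALSE, seed = NA_integer_)
)

setValidity("Molecule", function(object) {
  msg <- character()
  need <- c("element", "x", "y", "z", "charge")
  if (!all(need %in% names(object@atoms)))
    msg <- c(msg, "atoms must have columns element, x, y, z, charge")
  if (nrow(object@atoms) < 1L)
    msg <- c(msg, "molecule has no atoms")
  if (nrow(object@bonds) > 0L) {
    if (!all(c("a1", "a2", "order", "aromatic") %in% names(object@bonds)))
      msg <- c(msg, "bonds must have columns a1, a2, order, aromatic")
    else if (any(object@bonds$a1 > nrow(object@atoms)) ||
             any(object@bonds$a2 > nrow(object@atoms)))
      msg <- c(msg, "bond indices exceed atom count")
  }
  if (isTRUE(object@has3D) &&
      !all(is.finite(c(object@atoms$x, object@atoms$y, object@atoms$z))))
    msg <- c(msg, "has3D is TRUE but coordinates are not finite")
  if (length(msg)) msg else TRUE
})

#' CoamsDataset: curated labelled binary systems
#'
#' A table of labelled binary systems (one row per API/co-former system)
#' together with a provenance log of every curation action applied.
#'
#' @slot records data.frame in the canonical schema (see
#'   \code{\link{readDataset}}): api_name, api_smiles, coformer_name,
#'   coformer_smiles, coams_class, molar_ratio, prep_technique, label,
#'   stability_reported.
#' @slot provenance data.frame logging curation actions: \code{row_id},
#'   \code{pair}, \code{rule}, \code{action}.
#' @slot curated TRUE once \code{\link{curateDataset}} has been applied.
#' @export
setClass("CoamsDataset",
  representation(
    records    = "data.frame",
    provenance = "data.frame",
    curated    = "logical"
  ),
  prototype(curated = FALSE,
            provenance = data.frame(row_id = integer(), pair = character(),
                                    rule = character(), action = character(),
                                    stringsAsFactors = FALSE))
)

setValidity("CoamsDataset", function(object) {
  msg <- character()
  need <- datasetSchema()
  if (!all(need %in% names(object@records)))
    msg <- c(msg, paste("records must have columns:",
                        paste(setdiff(need, names(object@records)),
                              collapse = ", ")))
  else {
    if (!all(object@records$label %in% c(0L, 1L)))
      msg <- c(msg, "label must be 0 or 1")
    if (!all(object@records$prep_technique %in% c("thermodynamic", "kinetic")))
      msg <- c(msg, "prep_technique must be 'thermodynamic' or 'kinetic'")
    if (!all(object@records$coams_class %in% 1:4))
      msg <- c(msg, "coams_class must be in 1..4")
    if (any(object@records$api_name == object@records$coformer_name))
      msg <- c(msg, "API and co-former must be distinct compounds")
  }
  if (length(msg)) msg else TRUE
})

#' CoamsEnsemble: voting ensemble of binary classifiers
#'
#' The fitted screening model: \code{nModels} member classifiers, each
#' trained on an independent random 85/15 split of the training rows, plus
#' the full training feature matrix retained for the applicability-domain
#' distance.
#'
#' @slot members list of fitted member classifiers (internal representation
#'   depends on the learner).
#' @slot learner one of "gradient_boosted_trees", "random_forest",
#'   "support_vector", "nearest_neighbor".
#' @slot featureOrder frozen 34-name feature column order.
#' @slot trainingMatrix the training feature matrix (rows x 34), kept for
#'   \code{\link{distanceToTraining}}.
#' @slot trainingLabels 0/1 labels aligned with trainingMatrix rows.
#' @slot valAccuracy per-member validation accuracy on its own 15% holdout.
#' @slot config the \code{\link{trainingConfig}} list used.
#' @export
setClass("CoamsEnsemble",
  representation(
    members        = "list",
    learner        = "character",
    featureOrder   = "character",
    trainingMatrix = "matrix",
    trainingLabels = "integer",
    valAccuracy    = "numeric",
    config         = "list"
  )
)

setValidity("CoamsEnsemble", function(object) {
  msg <- character()
  if (length(object@members) < 1L)
    msg <- c(msg, "ensemble needs at least one member")
  if (length(object@valAccuracy) != length(object@members))
    msg <- c(msg, "one validation accuracy per member required")
  if (!identical(colnames(object@trainingMatrix), object@featureOrder))
    msg <- c(msg, "trainingMatrix columns must match featureOrder")
  if (length(object@trainingLabels) != nrow(object@trainingMatrix))
    msg <- c(msg, "labels must align with trainingMatrix rows")
  if (length(msg)) msg else TRUE
})

#' ImportanceReport: aggregated gain-based feature importance
#'
#' Mean and standard deviation of normalised gain importance per feature,
#' aggregated over independent retrainings of the whole ensemble. A feature
#' is flagged important when its mean exceeds 1/nFeatures (the value every
#' feature would take if all contributed equally).
#'
#' @slot table data.frame: feature, mean, sd, important.
#' @slot threshold numeric, 1/number-of-features.
#' @slot repetitions number of full-ensemble retrainings aggregated.
#' @export
setClass("ImportanceReport",
  representation(
    table       = "data.frame",
    threshold   = "numeric",
    repetitions = "integer"
  )
)

setValidity("ImportanceReport", function(object) {
  msg <- character()
  if (!all(c("feature", "mean", "sd", "important") %in% names(object@table)))
    msg <- c(msg, "table must have columns feature, mean, sd, important")
  if (length(msg)) msg else TRUE
})
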