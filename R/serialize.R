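# Ensemble bundle serialization: a directory with the config as YAML,
# the training matrix/labels as CSV and one file per member.

.bundleVersion <- "1"

#' Save / load an ensemble bundle
#'
#' \code{saveEnsemble} writes a directory bundle: \code{config.yaml}
#' (learner, training configuration, frozen feature order, bundle
#' version), \code{training_matrix.csv} (features + label column) and a
#' \code{members/} directory with one file per member
#' (gradient-boosted members in xgboost's native format, others as
#' RDS). \code{loadEnsemble} reconstructs the
#' \linkS4class{CoamsEnsemble} and refuses bundles written under a
#' different bundle version.
#'
#' @param ensemble a \linkS4class{CoamsEnsemble}.
#' @param dir bundle directory (created; must not already contain a
#'   bundle unless \code{overwrite}).
#' @param overwrite replace an existing bundle (default FALSE).
#' @return \code{saveEnsemble}: invisibly, \code{dir};
#'   \code{loadEnsemble}: the ensemble.
#' @export
saveEnsemble <- function(ensemble, dir, overwrite = FALSE) {
  stopifnot(is(ensemble, "CoamsEnsemble"))
  if (dir.exists(file.path(dir, "members")) && !overwrite)
    stop("bundle already exists at ", dir, " (use overwrite = TRUE)",
         call. = FALSE)
  dir.create(file.path(dir, "members"), recursive = TRUE,
             showWarnings = FALSE)
  yaml::write_yaml(
    list(bundle_version = .bundleVersion,
         learner = ensemble@learner,
         feature_order = ensemble@featureOrder,
         config = ensemble@config,
         val_accuracy = ensemble@valAccuracy),
    file.path(dir, "config.yaml"))
  tm <- as.data.frame(ensemble@trainingMatrix)
  tm$label <- ensemble@trainingLabels
  write.csv(tm, file.path(dir, "training_matrix.csv"),
            row.names = FALSE)
  for (i in seq_along(ensemble@members)) {
    m <- ensemble@members[[i]]
    if (m$learner == "gradient_boosted_trees") {
      xgboost::xgb.save(m$fit,
                        file.path(dir, "members",
                                  sprintf("member_%03d.ubj", i)))
    } else {
      saveRDS(m, file.path(dir, "members",
                           sprintf("member_%03d.rds", i)))
    }
  }
  invisible(dir)
}

#' @rdname saveEnsemble
#' @export
loadEnsemble <- function(dir) {
  cfgPath <- file.path(dir, "config.yaml")
  if (!file.exists(cfgPath))
    stop("no ensemble bundle at ", dir, call. = FALSE)
  meta <- yaml::read_yaml(cfgPath)
  if (!identical(as.character(meta$bundle_version), .bundleVersion))
    stop(sprintf("bundle version mismatch: bundle %s, supported %s",
                 meta$bundle_version, .bundleVersion), call. = FALSE)
  tm <- read.csv(file.path(dir, "training_matrix.csv"),
                 check.names = FALSE)
  labels <- as.integer(tm$label)
  tm$label <- NULL
  x <- as.matrix(tm)[, meta$feature_order, drop = FALSE]
  files <- sort(list.files(file.path(dir, "members"),
                           full.names = TRUE))
  members <- lapply(files, function(f) {
    if (grepl("\\.ubj$", f))
      list(learner = "gradient_boosted_trees",
           fit = xgboost::xgb.load(f))
    else readRDS(f)
  })
  new("CoamsEnsemble", members = members, learner = meta$learner,
      featureOrder = meta$feature_order, trainingMatrix = x,
      trainingLabels = labels,
      valAccuracy = as.numeric(meta$val_accuracy),
      config = meta$config)
}
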