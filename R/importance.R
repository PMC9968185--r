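# Gain-based feature importance, aggregated over independent
# retrainings of the whole ensemble.

#' Aggregated gain-based feature importance
#'
#' Retrains the full voting ensemble \code{repetitions} times with fresh
#' master seeds, extracts each member's normalised gain importance
#' (the improvement each feature's split nodes contribute, weighted by
#' the observations they cover, summing to 1 per member), averages over
#' members within a repetition, and reports the mean and standard
#' deviation per feature across repetitions. A feature is flagged
#' important when its mean exceeds 1/nFeatures -- the share every
#' feature would have if all contributed equally (0.029 for the
#' 34-feature panel).
#'
#' Only tree learners expose gain importance; the learner must be
#' \code{"gradient_boosted_trees"}.
#'
#' @param x,y training matrix and 0/1 labels.
#' @param config a \code{\link{trainingConfig}}.
#' @param repetitions number of full-ensemble retrainings (default 10).
#' @return an \linkS4class{ImportanceReport}.
#' @examples
#' \dontrun{
#' rep <- featureImportance(fm$x, fm$y, trainingConfig(nModels = 10))
#' importanceTable(rep)
#' }
#' @export
featureImportance <- function(x, y, config = trainingConfig(),
                              repetitions = 10L) {
  if (config$learner != "gradient_boosted_trees")
    stop("gain importance is reported for gradient_boosted_trees only",
         call. = FALSE)
  x <- .checkColumns(x, pairFeatureNames())
  feats <- colnames(x)
  perRep <- matrix(0, nrow = repetitions, ncol = length(feats),
                   dimnames = list(NULL, feats))
  for (r in seq_len(repetitions)) {
    cfg <- config
    cfg$masterSeed <- as.integer(.memberSeed(config$masterSeed,
                                             1000003 + r))
    ens <- trainEnsemble(x, y, cfg)
    memberImp <- vapply(ens@members, function(m) {
      imp <- xgboost::xgb.importance(feature_names = feats,
                                     model = m$fit)
      v <- setNames(rep(0, length(feats)), feats)
      if (nrow(imp)) v[imp$Feature] <- imp$Gain
      v
    }, numeric(length(feats)))
    perRep[r, ] <- rowMeans(memberImp)
  }
  tab <- data.frame(
    feature = feats,
    mean = colMeans(perRep),
    sd = apply(perRep, 2L, sd),
    stringsAsFactors = FALSE)
  tab$important <- tab$mean > 1 / length(feats)
  tab <- tab[order(-tab$mean), ]
  rownames(tab) <- NULL
  new("ImportanceReport", table = tab,
      threshold = 1 / length(feats),
      repetitions = as.integer(repetitions))
}

#' @describeIn featureImportance the per-feature importance table.
#' @param report an \linkS4class{ImportanceReport}.
#' @export
importanceTable <- function(report) report@table

#' @describeIn featureImportance the 1/nFeatures importance threshold.
#' @export
importanceThreshold <- function(report) report@threshold

setMethod("show", "ImportanceReport", function(object) {
  cat(sprintf(
    "ImportanceReport: %d repetitions, threshold %.3f (1/%d)\n",
    object@repetitions, object@threshold,
    round(1 / object@threshold)))
  imp <- object@table[object@table$important, ]
  cat(sprintf("  %d feature(s) above threshold:\n", nrow(imp)))
  for (i in seq_len(min(10L, nrow(imp))))
    cat(sprintf("    %-22s %.3f +/- %.3f\n", imp$feature[i],
                imp$mean[i], imp$sd[i]))
})
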