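# Voting ensemble of binary classifiers trained on repeated random
# 85/15 splits.
#
# Each of the nModels members sees its own random shuffle of the training
# rows; the last ceil(15%) of the shuffled order is that member's
# validation holdout. Members vote 0/1 on new data and the ensemble score
# p is the fraction of positive votes, so p is always an integer multiple
# of 1/nModels.

#' Training configuration
#'
#' Bundles every tunable of \code{\link{trainEnsemble}} with the
#' defaults used for screening: 50 gradient-boosted tree members,
#' 18 boosting rounds of depth 6, a 15\% per-member validation holdout
#' and an inclusive 0.5 vote threshold.
#'
#' @param nModels number of ensemble members.
#' @param valFraction per-member validation fraction in (0, 1).
#' @param learner one of "gradient_boosted_trees", "random_forest",
#'   "support_vector", "nearest_neighbor".
#' @param nEstimators trees per member (tree learners).
#' @param maxDepth maximum tree depth (gradient boosting).
#' @param kNeighbors k for the nearest-neighbor learner.
#' @param voteThreshold ensemble decision threshold in (0, 1); the
#'   classification is COAMS when p >= voteThreshold (inclusive).
#' @param masterSeed seed from which per-member seeds are derived.
#' @param vote "binary" thresholds each member's probability at 0.5
#'   before averaging (the default voting scheme); "probability"
#'   averages raw member probabilities instead.
#' @return a list of class \code{trainingConfig}.
#' @examples
#' trainingConfig(nModels = 10)
#' @export
trainingConfig <- function(nModels = 50L, valFraction = 0.15,
                           learner = c("gradient_boosted_trees",
                                       "random_forest", "support_vector",
                                       "nearest_neighbor"),
                           nEstimators = 18L, maxDepth = 6L,
                           kNeighbors = 5L, voteThreshold = 0.5,
                           masterSeed = 1L,
                           vote = c("binary", "probability")) {
  learner <- match.arg(learner)
  vote <- match.arg(vote)
  stopifnot(nModels >= 1L, valFraction > 0, valFraction < 1,
            voteThreshold > 0, voteThreshold < 1, nEstimators >= 1L,
            maxDepth >= 1L, kNeighbors >= 1L)
  structure(list(nModels = as.integer(nModels),
                 valFraction = valFraction, learner = learner,
                 nEstimators = as.integer(nEstimators),
                 maxDepth = as.integer(maxDepth),
                 kNeighbors = as.integer(kNeighbors),
                 voteThreshold = voteThreshold,
                 masterSeed = as.integer(masterSeed), vote = vote),
            class = "trainingConfig")
}

# deterministic member-seed fan-out; adding members never perturbs
# earlier ones. Computed in double precision (exact below 2^53).
.memberSeed <- function(masterSeed, i) {
  (as.numeric(masterSeed) * 69069 + as.numeric(i) * 2654435761) %%
    2147483647
}

.checkColumns <- function(x, featureOrder) {
  if (is.null(colnames(x)))
    stop("feature matrix has no column names", call. = FALSE)
  missing <- setdiff(featureOrder, colnames(x))
  extra <- setdiff(colnames(x), featureOrder)
  if (length(missing) || length(extra))
    stop(sprintf("feature columns mismatch; missing: [%s], extra: [%s]",
                 paste(missing, collapse = ", "),
                 paste(extra, collapse = ", ")), call. = FALSE)
  x[, featureOrder, drop = FALSE]
}

.minMaxFit <- function(x) {
  lo <- apply(x, 2L, min); hi <- apply(x, 2L, max)
  rng <- hi - lo
  rng[rng == 0] <- 1  # constant column maps to 0
  list(lo = lo, rng = rng)
}

.minMaxApply <- function(x, sc) {
  sweep(sweep(x, 2L, sc$lo, "-"), 2L, sc$rng, "/")
}

# fit one member on xtr/ytr; representation depends on the learner
.fitMember <- function(xtr, ytr, config) {
  switch(config$learner,
    gradient_boosted_trees = {
      fit <- xgboost::xgb.train(
        params = list(objective = "binary:logistic",
                      max_depth = config$maxDepth, nthread = 1L),
        data = xgboost::xgb.DMatrix(xtr, label = ytr, nthread = 1L),
        nrounds = config$nEstimators, verbose = 0)
      list(learner = config$learner, fit = fit)
    },
    random_forest = {
      fit <- randomForest::randomForest(
        x = xtr, y = factor(ytr, levels = c(0L, 1L)),
        ntree = config$nEstimators)
      list(learner = config$learner, fit = fit)
    },
    support_vector = {
      # constant columns trip e1071's internal scaling warning; they
      # carry no information either way
      fit <- suppressWarnings(
        e1071::svm(x = xtr, y = factor(ytr, levels = c(0L, 1L)),
                   kernel = "radial", probability = TRUE))
      list(learner = config$learner, fit = fit)
    },
    nearest_neighbor = {
      sc <- .minMaxFit(xtr)  # scaling fitted on training rows only
      list(learner = config$learner,
           fit = list(x = .minMaxApply(xtr, sc), y = ytr,
                      k = config$kNeighbors, scaling = sc))
    })
}

# member probability of class 1 on new rows
.memberProb <- function(member, x) {
  switch(member$learner,
    gradient_boosted_trees =
      as.numeric(predict(member$fit,
                         xgboost::xgb.DMatrix(x, nthread = 1L))),
    random_forest =
      as.numeric(predict(member$fit, x, type = "prob")[, "1"]),
    support_vector = {
      pr <- predict(member$fit, x, probability = TRUE)
      as.numeric(attr(pr, "probabilities")[, "1"])
    },
    nearest_neighbor = {
      xs <- .minMaxApply(x, member$fit$scaling)
      pred <- class::knn(train = member$fit$x, test = xs,
                         cl = factor(member$fit$y, levels = c(0L, 1L)),
                         k = member$fit$k, prob = TRUE)
      frac <- attr(pred, "prob")  # proportion of winning class
      ifelse(pred == "1", frac, 1 - frac)
    })
}

#' Train a single ensemble member
#'
#' Shuffles the rows with \code{memberSeed}, holds out the last
#' \code{ceiling(valFraction * n)} shuffled rows for validation, fits
#' one classifier on the remainder and reports its validation accuracy.
#'
#' @param x training feature matrix (columns
#'   \code{\link{pairFeatureNames}}).
#' @param y integer 0/1 labels.
#' @param config a \code{\link{trainingConfig}}.
#' @param memberSeed integer seed for this member's shuffle.
#' @return list with \code{member} (fitted classifier),
#'   \code{valAccuracy}, \code{valIndex} (holdout row indices).
#' @export
trainSingle <- function(x, y, config = trainingConfig(),
                        memberSeed = 1L) {
  stopifnot(nrow(x) == length(y), all(y %in% c(0L, 1L)))
  n <- nrow(x)
  nVal <- ceiling(config$valFraction * n)
  if (n - nVal < 2L)
    stop("too few rows to train after holding out validation data",
         call. = FALSE)
  set.seed(memberSeed)
  perm <- sample.int(n)
  valIdx <- perm[(n - nVal + 1L):n]
  trIdx <- perm[seq_len(n - nVal)]
  if (length(unique(y[trIdx])) < 2L)
    stop(paste("training portion contains a single class;",
               "more (or more balanced) data needed"), call. = FALSE)
  member <- .fitMember(x[trIdx, , drop = FALSE], y[trIdx], config)
  votes <- as.integer(.memberProb(member, x[valIdx, , drop = FALSE])
                      >= 0.5)
  list(member = member,
       valAccuracy = mean(votes == y[valIdx]),
       valIndex = valIdx)
}

#' Train the voting ensemble
#'
#' Trains \code{config$nModels} members, each on its own random 85/15
#' split derived deterministically from \code{config$masterSeed}, and
#' retains the full training matrix for the applicability-domain
#' distance.
#'
#' @inheritParams trainSingle
#' @return a \linkS4class{CoamsEnsemble}.
#' @examples
#' \dontrun{
#' ds <- generateSyntheticDataset(100, seed = 1)
#' fm <- featureMatrix(ds)
#' ens <- trainEnsemble(fm$x, fm$y, trainingConfig(nModels = 10))
#' }
#' @export
trainEnsemble <- function(x, y, config = trainingConfig()) {
  x <- .checkColumns(x, pairFeatureNames())
  y <- as.integer(y)
  fits <- lapply(seq_len(config$nModels), function(i)
    trainSingle(x, y, config, .memberSeed(config$masterSeed, i)))
  new("CoamsEnsemble",
      members = lapply(fits, `[[`, "member"),
      learner = config$learner,
      featureOrder = colnames(x),
      trainingMatrix = x,
      trainingLabels = y,
      valAccuracy = vapply(fits, `[[`, numeric(1L), "valAccuracy"),
      config = unclass(config))
}

#' Predicted score of the voting ensemble
#'
#' Each member votes 0 or 1 (its probability thresholded at 0.5); the
#' score p is the fraction of positive votes, an integer multiple of
#' 1/nModels. With \code{config$vote = "probability"} the raw member
#' probabilities are averaged instead.
#'
#' @param ensemble a \linkS4class{CoamsEnsemble}.
#' @param x feature matrix (or single named feature vector) with exactly
#'   the ensemble's frozen 34 columns.
#' @return numeric vector of scores in [0, 1], one per row.
#' @export
predictScore <- function(ensemble, x) {
  stopifnot(is(ensemble, "CoamsEnsemble"))
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L,
                                   dimnames = list(NULL, names(x)))
  x <- .checkColumns(x, ensemble@featureOrder)
  probs <- vapply(ensemble@members, function(m) .memberProb(m, x),
                  numeric(nrow(x)))
  probs <- matrix(probs, nrow = nrow(x))
  if (identical(ensemble@config$vote, "probability"))
    rowMeans(probs)
  else
    rowMeans(probs >= 0.5)
}

#' Classify a predicted score
#'
#' COAMS when the score reaches the threshold (inclusive: a tied vote of
#' exactly 0.5 is classified COAMS), non-COAMS below.
#'
#' @param p numeric scores in [0, 1].
#' @param threshold decision threshold (default 0.5).
#' @return character vector "COAMS" / "non-COAMS".
#' @examples
#' classifyScore(c(0.5, 0.49, 1))
#' @export
classifyScore <- function(p, threshold = 0.5) {
  stopifnot(all(p >= 0 & p <= 1))
  ifelse(p >= threshold, "COAMS", "non-COAMS")
}

#' Evaluate the ensemble on labelled data
#'
#' @param ensemble a \linkS4class{CoamsEnsemble}.
#' @param x labelled feature matrix.
#' @param y integer 0/1 labels.
#' @param threshold decision threshold (default the config's).
#' @return list with \code{accuracy} and the 2x2 \code{confusion} table
#'   (rows: truth 0/1; columns: predicted 0/1).
#' @export
evaluateEnsemble <- function(ensemble, x, y,
                             threshold = ensemble@config$voteThreshold) {
  if (length(y) == 0L || is.null(nrow(x)) || nrow(x) == 0L)
    stop("empty evaluation input", call. = FALSE)
  stopifnot(nrow(x) == length(y))
  p <- predictScore(ensemble, x)
  pred <- as.integer(p >= threshold)
  y <- as.integer(y)
  confusion <- table(truth = factor(y, levels = c(0L, 1L)),
                     predicted = factor(pred, levels = c(0L, 1L)))
  list(accuracy = mean(pred == y), confusion = confusion)
}

setMethod("show", "CoamsEnsemble", function(object) {
  cat(sprintf("CoamsEnsemble: %d x %s\n", length(object@members),
              object@learner))
  cat(sprintf("  trained on %d systems x %d features\n",
              nrow(object@trainingMatrix), ncol(object@trainingMatrix)))
  cat(sprintf("  mean member validation accuracy: %.3f\n",
              mean(object@valAccuracy)))
})

#' @describeIn trainEnsemble the retained training feature matrix.
#' @param ensemble a \linkS4class{CoamsEnsemble}.
#' @export
trainingMatrix <- function(ensemble) ensemble@trainingMatrix

#' @describeIn trainEnsemble per-member validation accuracies.
#' @export
memberValAccuracy <- function(ensemble) ensemble@valAccuracy
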