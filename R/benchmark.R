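# Hyper-parameter grid search and the four-learner benchmark.

#' Default hyper-parameter grids for the four learners
#'
#' @return named list of grids (lists of parameter value vectors).
#' @export
defaultGrids <- function() {
  list(
    gradient_boosted_trees = list(nEstimators = c(3L, 5L, 8L, 10L, 15L),
                                  maxDepth = c(2L, 3L, 5L, 7L, 10L, 12L,
                                               15L)),
    random_forest = list(nEstimators = c(3L, 5L, 8L, 10L, 15L)),
    support_vector = list(),  # radial-basis defaults
    nearest_neighbor = list(kNeighbors = c(3L, 5L, 8L, 10L, 15L))
  )
}

#' Grid search over ensemble hyper-parameters
#'
#' Trains a full voting ensemble for every combination of the grid's
#' parameter values and scores each cell by its mean member validation
#' accuracy. Ties are broken toward smaller model complexity: fewer
#' estimators first, then shallower trees (then smaller k).
#'
#' @param x,y training matrix and 0/1 labels.
#' @param learner learner name (see \code{\link{trainingConfig}}).
#' @param grid named list of parameter value vectors (names among
#'   nEstimators, maxDepth, kNeighbors); an empty list means a single
#'   cell at the defaults, but an explicitly NULL grid is an error.
#' @param config base \code{\link{trainingConfig}} supplying everything
#'   the grid does not vary.
#' @return list with \code{best} (the winning \code{trainingConfig}) and
#'   \code{table} (one row per cell with its mean validation accuracy).
#' @export
gridSearch <- function(x, y, learner = "gradient_boosted_trees",
                       grid = defaultGrids()[[learner]],
                       config = trainingConfig(learner = learner)) {
  if (is.null(grid))
    stop("empty grid", call. = FALSE)
  config$learner <- learner
  cells <- if (length(grid)) expand.grid(grid) else
    data.frame(row.names = 1L)
  acc <- numeric(nrow(cells))
  for (i in seq_len(nrow(cells))) {
    cfg <- config
    for (p in names(cells)) cfg[[p]] <- cells[i, p]
    ens <- trainEnsemble(x, y, cfg)
    acc[i] <- mean(ens@valAccuracy)
  }
  tab <- cbind(cells, meanValAccuracy = acc)
  ord <- do.call(order, c(list(-acc),
                          lapply(intersect(c("nEstimators", "maxDepth",
                                             "kNeighbors"),
                                           names(cells)),
                                 function(p) cells[[p]])))
  best <- config
  if (length(grid))
    for (p in names(cells)) best[[p]] <- cells[ord[1L], p]
  list(best = best, table = tab)
}

#' Benchmark the four learners
#'
#' Runs \code{\link{gridSearch}} for each learner, retrains the winning
#' configuration, and reports three accuracies per learner: the combined
#' vote's accuracy on all training rows, the mean member accuracy on the
#' same rows, and the mean member validation accuracy. The
#' nearest-neighbor learner min-max-scales its features internally,
#' fitted on its training rows only.
#'
#' @param x,y training matrix and 0/1 labels.
#' @param grids named list of grids per learner (default
#'   \code{\link{defaultGrids}}).
#' @param config base \code{\link{trainingConfig}}.
#' @return data.frame with one row per learner: learner,
#'   trainingVoteAccuracy, trainingMemberAccuracy, validationAccuracy,
#'   plus the winning hyper-parameters as a collapsed string.
#' @export
compareMethods <- function(x, y, grids = defaultGrids(),
                           config = trainingConfig()) {
  rows <- lapply(names(grids), function(learner) {
    gs <- gridSearch(x, y, learner, grids[[learner]], config)
    ens <- trainEnsemble(x, y, gs$best)
    trainVote <- evaluateEnsemble(ens, x, y)$accuracy
    memberTrain <- mean(vapply(ens@members, function(m)
      mean(as.integer(.memberProb(m, x) >= 0.5) == y), numeric(1L)))
    hyper <- gs$best[intersect(c("nEstimators", "maxDepth",
                                 "kNeighbors"),
                               names(gs$table))]
    data.frame(
      learner = learner,
      trainingVoteAccuracy = trainVote,
      trainingMemberAccuracy = memberTrain,
      validationAccuracy = mean(ens@valAccuracy),
      bestParams = if (length(hyper))
        paste(names(hyper), unlist(hyper), sep = "=", collapse = ", ")
      else "defaults",
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
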