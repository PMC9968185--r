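# Applicability domain: distance to the training data and the
# uncertainty factor UF = d / p^4 used to rank positive predictions.

#' Euclidean distance from a candidate to the training data
#'
#' Distance of a candidate feature vector x from the training matrix T
#' on raw (unscaled) features. \code{mode = "nearest"} (the default, the
#' usual applicability-domain convention) takes the minimum Euclidean
#' distance over training rows; \code{"centroid"} measures to the
#' column-mean of T.
#'
#' @param x a named 34-feature vector or a matrix of candidates (rows).
#' @param train training matrix with the frozen feature columns, or a
#'   \linkS4class{CoamsEnsemble} (its retained training matrix is used).
#' @param mode "nearest" or "centroid".
#' @return numeric distance(s), one per candidate row.
#' @examples
#' T <- matrix(0, 1, 2, dimnames = list(NULL, c("a", "b")))
#' distanceToTraining(c(a = 3, b = 4), T)  # 5
#' @export
distanceToTraining <- function(x, train,
                               mode = c("nearest", "centroid")) {
  mode <- match.arg(mode)
  if (is(train, "CoamsEnsemble")) train <- train@trainingMatrix
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L,
                                   dimnames = list(NULL, names(x)))
  stopifnot(nrow(train) >= 1L)
  x <- .checkColumns(x, colnames(train))
  if (mode == "centroid") {
    ctr <- colMeans(train)
    return(sqrt(rowSums(sweep(x, 2L, ctr)^2)))
  }
  # nearest training row; ||x - t||^2 = ||x||^2 - 2 x.t + ||t||^2
  t2 <- rowSums(train^2)
  cross <- x %*% t(train)
  d2 <- outer(rowSums(x^2), t2, "+") - 2 * cross
  sqrt(pmax(apply(d2, 1L, min), 0))
}

#' Uncertainty factor of a positive prediction
#'
#' UF = d / p^4: the Euclidean distance from the training data divided
#' by the fourth power of the predicted score. Defined only for
#' positive predictions (p >= 0.5); scores just above 0.5 inflate UF by
#' up to a factor 16, flagging doubtful positives. Lower UF = more
#' trustworthy.
#'
#' @param d non-negative distance(s) from the training data.
#' @param p predicted score(s) in [0.5, 1].
#' @return numeric UF value(s).
#' @examples
#' uncertaintyFactor(411.0, 1)      # 411
#' uncertaintyFactor(74.2, 0.98)    # ~80.4
#' @export
uncertaintyFactor <- function(d, p) {
  if (any(d < 0)) stop("distance must be non-negative", call. = FALSE)
  if (any(p > 1)) stop("score must not exceed 1", call. = FALSE)
  if (any(p < 0.5))
    stop("UF defined for positive predictions only (p >= 0.5)",
         call. = FALSE)
  d / p^4
}

#' Rank screening candidates by uncertainty factor
#'
#' Drops candidates with p < 0.5 (no UF is defined for them) and sorts
#' the remainder ascending by UF, ties broken by higher score, then by
#' pair name.
#'
#' @param scores data.frame with at least columns \code{p} and
#'   \code{uf}; a \code{pair} column (or api1/api2 names) is used for
#'   the final tie-break.
#' @return the ranked subset with a \code{rank} column prepended.
#' @export
rankCandidates <- function(scores) {
  stopifnot(all(c("p", "uf") %in% names(scores)))
  keep <- scores[scores$p >= 0.5, , drop = FALSE]
  if (nrow(keep) == 0L) {
    keep$rank <- integer(0)
    return(keep)
  }
  pairName <- if ("pair" %in% names(keep)) keep$pair
    else if (all(c("api1_name", "api2_name") %in% names(keep)))
      paste(keep$api1_name, keep$api2_name)
    else rep("", nrow(keep))
  ord <- order(keep$uf, -keep$p, pairName)
  keep <- keep[ord, , drop = FALSE]
  keep$rank <- seq_len(nrow(keep))
  rownames(keep) <- NULL
  keep
}
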