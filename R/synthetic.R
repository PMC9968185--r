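# Synthetic labelled-system generator with a planted decision rule.
#
# Stands in for the literature corpus of binary systems: samples
# API/co-former combinations from a built-in library of real drug-like
# molecules, assigns the COAMS label by a planted threshold rule on the
# true pair features, and flips labels with a configurable noise rate.
# The generator defines the study conditions used by the package's own
# validation (class mix, positive rate, noise), so its defaults are
# fixed and logged.

#' Built-in compound library
#'
#' 46 real drug-like molecules (name, SMILES, role) spanning the four
#' co-former classes: APIs, amino acids, organic acids and other small
#' excipients.
#'
#' @return data.frame with columns name, smiles, role.
#' @export
compoundLibrary <- function() {
  p <- system.file("extdata", "compound_library.csv",
                   package = "coamscreen")
  if (!nzchar(p)) p <- file.path("inst", "extdata", "compound_library.csv")
  read.csv(p, stringsAsFactors = FALSE)
}

#' Planted labelling rule for the synthetic generator
#'
#' The rule labels a system COAMS (1) when every listed feature condition
#' holds: \code{direction = "le"} requires feature <= threshold,
#' \code{"ge"} requires feature >= threshold. Thresholds left NA are
#' calibrated by \code{\link{generateSyntheticDataset}} as empirical
#' quantiles of the sampled pairs (the \code{quantiles} entry), so that
#' the positive rate lands near the target; the calibrated thresholds
#' are stored back into the rule carried by the generated data, making
#' the labels exactly re-evaluable.
#'
#' The default plants a two-feature rule mirroring the directions the
#' screening model is expected to learn: similar relative hydrophobic
#' surface area (small \code{diff_RASA}) and dissimilar rotatable-bond
#' count (large \code{diff_nRot}) favour co-amorphisation.
#'
#' @param features pair-feature names the rule tests.
#' @param directions "le" or "ge" per feature.
#' @param quantiles calibration quantiles per feature (used when the
#'   matching threshold is NA); the finest-grained (most unique values)
#'   uncalibrated feature is instead tuned so the overall positive rate
#'   lands as close as possible to \code{targetPositive}, because
#'   discrete features make plain quantile calibration overshoot.
#' @param thresholds numeric thresholds; NA means calibrate.
#' @param targetPositive target fraction of positive labels before
#'   noise (default 0.68, the positive share of the curated corpus the
#'   generator emulates).
#' @return object of class \code{plantedRule}.
#' @examples
#' plantedRule()
#' @export
plantedRule <- function(features = c("diff_RASA", "diff_nRot"),
                        directions = c("le", "ge"),
                        quantiles = c(0.85, 0.20),
                        thresholds = c(NA_real_, NA_real_),
                        targetPositive = 0.68) {
  stopifnot(length(features) == length(directions),
            length(features) == length(quantiles),
            length(features) == length(thresholds),
            all(directions %in% c("le", "ge")),
            targetPositive > 0, targetPositive < 1)
  structure(list(features = features, directions = directions,
                 quantiles = quantiles, thresholds = thresholds,
                 targetPositive = targetPositive),
            class = "plantedRule")
}

#' @describeIn plantedRule evaluate the rule on a feature matrix;
#'   returns an integer 0/1 label per row. Thresholds must be concrete.
#' @param rule a \code{plantedRule}.
#' @param x numeric matrix with named pair-feature columns.
#' @export
evaluateRule <- function(rule, x) {
  stopifnot(inherits(rule, "plantedRule"))
  if (any(is.na(rule$thresholds)))
    stop("rule has uncalibrated thresholds", call. = FALSE)
  missing <- setdiff(rule$features, colnames(x))
  if (length(missing))
    stop("feature matrix lacks rule feature(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  ok <- rep(TRUE, nrow(x))
  for (i in seq_along(rule$features)) {
    v <- x[, rule$features[i]]
    ok <- ok & if (rule$directions[i] == "le")
      v <= rule$thresholds[i] else v >= rule$thresholds[i]
  }
  as.integer(ok)
}

#' @export
print.plantedRule <- function(x, ...) {
  cat("plantedRule:\n")
  for (i in seq_along(x$features))
    cat(sprintf("  %s %s %s\n", x$features[i],
                if (x$directions[i] == "le") "<=" else ">=",
                if (is.na(x$thresholds[i]))
                  sprintf("quantile(%.2f) [uncalibrated]", x$quantiles[i])
                else format(x$thresholds[i], digits = 4)))
  invisible(x)
}

#' Generate a synthetic labelled dataset
#'
#' Samples \code{n} binary systems from the built-in compound library with
#' a class mix of roughly 31\% API-API, 40\% API-amino-acid, 20\%
#' API-organic-acid and 9\% API-other, assigns each label by evaluating
#' the planted rule on the system's true pair features, then flips each
#' label independently with probability \code{noiseRate}. The calibrated
#' rule, the descriptor cache and the generator parameters are attached
#' as attributes \code{"rule"}, \code{"descriptorCache"} and
#' \code{"params"}. Deterministic for a fixed seed.
#'
#' @param n number of systems (>= 8 so that all classes and both labels
#'   can be represented).
#' @param noiseRate label-flip probability in [0, 1).
#' @param seed integer RNG seed (also used for descriptor embedding).
#' @param rule a \code{\link{plantedRule}}.
#' @param classProbs sampling probabilities of the four classes.
#' @return data.frame of records in the canonical schema (see
#'   \code{\link{datasetSchema}}).
#' @examples
#' \dontrun{
#' ds <- generateSyntheticDataset(100, noiseRate = 0, seed = 1)
#' table(ds$label)
#' }
#' @export
generateSyntheticDataset <- function(n, noiseRate = 0.05, seed = 1L,
                                     rule = plantedRule(),
                                     classProbs = c(0.31, 0.40, 0.20,
                                                    0.09)) {
  if (n < 8L)
    stop("n must be at least 8 to cover four classes and both labels",
         call. = FALSE)
  stopifnot(noiseRate >= 0, noiseRate < 1, length(classProbs) == 4L)
  lib <- compoundLibrary()
  pools <- list(`1` = lib[lib$role == "api", ],
                `2` = lib[lib$role == "amino_acid", ],
                `3` = lib[lib$role == "organic_acid", ],
                `4` = lib[lib$role == "other", ])
  apis <- pools[["1"]]

  set.seed(seed)
  cls <- sample.int(4L, n, replace = TRUE, prob = classProbs)
  apiIdx <- sample.int(nrow(apis), n, replace = TRUE)
  cofName <- vapply(seq_len(n), function(i) {
    pool <- pools[[as.character(cls[i])]]
    if (cls[i] == 1L)  # API-API: a different API
      pool <- pool[pool$name != apis$name[apiIdx[i]], , drop = FALSE]
    pool$name[sample.int(nrow(pool), 1L)]
  }, "")
  cofSmiles <- lib$smiles[match(cofName, lib$name)]

  records <- data.frame(
    api_name = apis$name[apiIdx],
    api_smiles = apis$smiles[apiIdx],
    coformer_name = cofName,
    coformer_smiles = cofSmiles,
    coams_class = cls,
    molar_ratio = sample(c("1:1", "1:2", "2:1"), n, replace = TRUE,
                         prob = c(0.6, 0.2, 0.2)),
    prep_technique = sample(c("thermodynamic", "kinetic"), n,
                            replace = TRUE),
    label = 0L,
    stability_reported = TRUE,
    stringsAsFactors = FALSE
  )

  cache <- descriptorTable(
    data.frame(name = unique(c(records$api_smiles,
                               records$coformer_smiles)),
               smiles = unique(c(records$api_smiles,
                                 records$coformer_smiles))),
    seed = seed)
  fm <- featureMatrix(records, descriptorCache = cache)

  # calibrate NA thresholds on the sampled pairs: the finest-grained
  # (most unique values) feature by matching the target positive rate,
  # the others by their quantiles
  toCal <- which(is.na(rule$thresholds))
  iRate <- if (length(toCal))
    toCal[which.max(vapply(toCal, function(i)
      length(unique(fm$x[, rule$features[i]])), numeric(1L)))]
  else integer(0)
  for (i in setdiff(toCal, iRate)) {
    rule$thresholds[i] <- unname(quantile(x = fm$x[, rule$features[i]],
                                          probs = rule$quantiles[i]))
  }
  if (length(toCal)) {
    i <- iRate
    others <- rule
    others$features <- rule$features[-i]
    others$directions <- rule$directions[-i]
    others$thresholds <- rule$thresholds[-i]
    base <- if (length(others$features))
      evaluateRule(others, fm$x) == 1L else rep(TRUE, n)
    v <- fm$x[, rule$features[i]]
    cand <- sort(unique(v))
    rate <- vapply(cand, function(t)
      mean(base & if (rule$directions[i] == "le") v <= t else v >= t),
      numeric(1L))
    rule$thresholds[i] <- cand[which.min(abs(rate -
                                             rule$targetPositive))]
  }
  labels <- evaluateRule(rule, fm$x)
  flip <- runif(n) < noiseRate
  records$label <- as.integer(ifelse(flip, 1L - labels, labels))

  attr(records, "rule") <- rule
  attr(records, "descriptorCache") <- cache
  attr(records, "params") <- list(n = n, noiseRate = noiseRate,
                                  seed = as.integer(seed),
                                  classProbs = classProbs,
                                  positiveRate = mean(labels))
  records
}
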