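# Virtual screening: enumerate candidate API pairs, score them with a
# trained ensemble, attach distance and uncertainty factor, and write
# ranked reports.

#' Enumerate candidate API pairs
#'
#' All unordered pairs of distinct APIs (n(n-1)/2), optionally plus the
#' n self-pairs. Pair order follows the input order of the API list;
#' within a pair, substance 1 is the API appearing first.
#'
#' @param apis data.frame with columns \code{name} and \code{smiles};
#'   names must be unique.
#' @param includeSelf also emit X-X self-pairs (default FALSE).
#' @return data.frame with columns api1_name, api1_smiles, api2_name,
#'   api2_smiles.
#' @examples
#' apis <- data.frame(name = c("a", "b", "c"),
#'                    smiles = c("C", "CC", "CCC"))
#' nrow(enumeratePairs(apis))  # 3
#' @export
enumeratePairs <- function(apis, includeSelf = FALSE) {
  stopifnot(all(c("name", "smiles") %in% names(apis)))
  if (nrow(apis) < 2L)
    stop("need at least two APIs to enumerate pairs", call. = FALSE)
  if (anyDuplicated(apis$name))
    stop("duplicate API name(s): ",
         paste(unique(apis$name[duplicated(apis$name)]),
               collapse = ", "), call. = FALSE)
  idx <- t(combn(nrow(apis), 2L))
  if (includeSelf)
    idx <- rbind(idx, cbind(seq_len(nrow(apis)), seq_len(nrow(apis))))
  data.frame(api1_name = apis$name[idx[, 1L]],
             api1_smiles = apis$smiles[idx[, 1L]],
             api2_name = apis$name[idx[, 2L]],
             api2_smiles = apis$smiles[idx[, 2L]],
             stringsAsFactors = FALSE)
}

#' Screen API pairs with a trained ensemble
#'
#' For every enumerated pair and preparation technique: builds the
#' 34-feature vector (substance order = enumeration order, molar ratio
#' fixed at 1:1), predicts the score p, computes the applicability
#' distance d against the ensemble's training matrix and, for positive
#' predictions (p >= 0.5), the uncertainty factor UF = d/p^4. APIs whose
#' descriptors cannot be computed are skipped with a logged reason (the
#' run continues); their pairs are reported in the \code{"skipped"}
#' attribute.
#'
#' @param apis data.frame with columns name, smiles.
#' @param ensemble a trained \linkS4class{CoamsEnsemble}.
#' @param techniques preparation techniques to screen (default
#'   \code{"kinetic"}, the pathway commonly reported for screening).
#' @param distanceMode "nearest" or "centroid" (see
#'   \code{\link{distanceToTraining}}).
#' @param includeSelf include self-pairs (default FALSE).
#' @param seed descriptor embedding seed.
#' @return ranked screening table: api1_name, api2_name,
#'   prep_technique, p, d, uf (NA when p < 0.5), rank (NA when
#'   unranked); attribute \code{"skipped"} lists failed APIs.
#' @export
screenPairs <- function(apis, ensemble, techniques = "kinetic",
                        distanceMode = c("nearest", "centroid"),
                        includeSelf = FALSE, seed = 1L) {
  distanceMode <- match.arg(distanceMode)
  stopifnot(is(ensemble, "CoamsEnsemble"),
            all(techniques %in% c("thermodynamic", "kinetic")))
  skipped <- data.frame(name = character(), reason = character(),
                        stringsAsFactors = FALSE)
  descs <- list()
  for (i in seq_len(nrow(apis))) {
    d <- tryCatch(computeDescriptors(apis$smiles[i], seed = seed),
                  error = function(e) conditionMessage(e))
    if (is.character(d) && length(d) == 1L) {
      skipped <- rbind(skipped,
                       data.frame(name = apis$name[i], reason = d,
                                  stringsAsFactors = FALSE))
    } else {
      descs[[apis$name[i]]] <- d
    }
  }
  ok <- apis[apis$name %in% names(descs), , drop = FALSE]
  pairs <- enumeratePairs(ok, includeSelf = includeSelf)
  rows <- do.call(rbind, lapply(techniques, function(tech) {
    feats <- t(vapply(seq_len(nrow(pairs)), function(i)
      buildPairFeatures(descs[[pairs$api1_name[i]]],
                        descs[[pairs$api2_name[i]]], tech),
      numeric(34L)))
    colnames(feats) <- pairFeatureNames()
    p <- predictScore(ensemble, feats)
    d <- distanceToTraining(feats, ensemble, mode = distanceMode)
    data.frame(api1_name = pairs$api1_name,
               api2_name = pairs$api2_name,
               prep_technique = tech, p = p, d = d,
               uf = ifelse(p >= 0.5, d / p^4, NA_real_),
               stringsAsFactors = FALSE)
  }))
  ranked <- rankCandidates(rows)
  rows$rank <- ranked$rank[match(
    paste(rows$api1_name, rows$api2_name, rows$prep_technique),
    paste(ranked$api1_name, ranked$api2_name, ranked$prep_technique))]
  rows <- rows[order(is.na(rows$rank), rows$rank), , drop = FALSE]
  rownames(rows) <- NULL
  attr(rows, "skipped") <- skipped
  attr(rows, "distanceMode") <- distanceMode
  rows
}

#' Write screening reports
#'
#' Writes the full screening table, the top-k ranked subset and a
#' score-versus-distance scatter table (columns p and d, one row per
#' scored pair) as CSV files.
#'
#' @param results a screening table from \code{\link{screenPairs}}.
#' @param topK how many ranked rows the top list keeps (default 100);
#'   if fewer ranked rows exist, all are written with a warning.
#' @param dir output directory (created if needed).
#' @return invisibly, the named list of file paths written.
#' @export
runReport <- function(results, topK = 100L, dir = ".") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ranked <- results[!is.na(results$rank), , drop = FALSE]
  ranked <- ranked[order(ranked$rank), , drop = FALSE]
  if (topK > nrow(ranked)) {
    warning(sprintf("topK = %d exceeds the %d ranked rows; writing all",
                    topK, nrow(ranked)))
    topK <- nrow(ranked)
  }
  paths <- c(full = file.path(dir, "screening_full.csv"),
             top = file.path(dir, "screening_top.csv"),
             scatter = file.path(dir, "score_vs_distance.csv"))
  write.csv(results, paths["full"], row.names = FALSE)
  write.csv(head(ranked, topK), paths["top"], row.names = FALSE)
  write.csv(results[, c("api1_name", "api2_name", "prep_technique",
                        "p", "d")],
            paths["scatter"], row.names = FALSE)
  invisible(as.list(paths))
}
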