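# 34-component model input for one binary system:
# 29 absolute descriptor differences, 4 donor/acceptor-acid/base cross
# features, and the preparation-technique flag.

#' Names of the 34 pair features, in frozen order
#'
#' Column order used by every feature matrix, serialized ensemble and
#' distance computation: \code{diff_<descriptor>} for the 29 panel
#' descriptors (in \code{\link{descriptorNames}} order), then the four
#' cross features \code{nAB}, \code{nBA}, \code{nHBDA}, \code{nHBAD},
#' then \code{prep_flag}.
#'
#' @return character vector of length 34.
#' @examples
#' pairFeatureNames()
#' @export
pairFeatureNames <- function() {
  c(paste0("diff_", descriptorNames()), "nAB", "nBA", "nHBDA", "nHBAD",
    "prep_flag")
}

#' Build the 34-feature vector for one pair of molecules
#'
#' Substance 1 is the API and substance 2 the co-former. The 29
#' \code{diff_*} features are absolute descriptor differences
#' |d1 - d2| and are symmetric under swapping the substances; the four
#' cross features are not: \code{nAB} = |nAcid(s1) - nBase(s2)|,
#' \code{nBA} = |nBase(s1) - nAcid(s2)|, \code{nHBDA} =
#' |nHBDon(s1) - nHBAcc(s2)|, \code{nHBAD} = |nHBAcc(s1) - nHBDon(s2)|.
#' \code{prep_flag} encodes the preparation pathway (thermodynamic = 0,
#' kinetic = 1).
#'
#' @param d1,d2 named 29-descriptor vectors (see
#'   \code{\link{computeDescriptors}}) for substance 1 (API) and
#'   substance 2 (co-former).
#' @param prep \code{"thermodynamic"} or \code{"kinetic"}.
#' @return named numeric vector of length 34 in
#'   \code{\link{pairFeatureNames}} order.
#' @examples
#' d <- setNames(rep(1, 29), descriptorNames())
#' buildPairFeatures(d, d, "kinetic")
#' @export
buildPairFeatures <- function(d1, d2, prep = c("thermodynamic", "kinetic")) {
  prep <- match.arg(prep)
  for (d in list(d1, d2)) {
    missing <- setdiff(descriptorNames(), names(d))
    if (length(missing))
      stop("descriptor vector missing: ", paste(missing, collapse = ", "),
           call. = FALSE)
  }
  d1 <- d1[descriptorNames()]; d2 <- d2[descriptorNames()]
  out <- c(
    abs(d1 - d2),
    nAB = abs(d1[["nAcid"]] - d2[["nBase"]]),
    nBA = abs(d1[["nBase"]] - d2[["nAcid"]]),
    nHBDA = abs(d1[["nHBDon"]] - d2[["nHBAcc"]]),
    nHBAD = abs(d1[["nHBAcc"]] - d2[["nHBDon"]]),
    prep_flag = if (prep == "kinetic") 1 else 0
  )
  names(out) <- pairFeatureNames()
  out
}

#' Feature matrix and label vector for a set of labelled systems
#'
#' Builds the n x 34 model input for a record table (see
#' \code{\link{readDataset}} for the schema), computing descriptors once
#' per unique SMILES. Row order follows the input records.
#'
#' @param records data.frame of systems in the canonical schema, or a
#'   \linkS4class{CoamsDataset}.
#' @param descriptorCache optional precomputed descriptor table as
#'   returned by \code{\link{descriptorTable}} covering every SMILES in
#'   \code{records}; computed on the fly when NULL.
#' @param seed embedding seed passed to \code{\link{descriptorTable}}.
#' @return list with \code{x} (matrix n x 34, columns
#'   \code{\link{pairFeatureNames}}), \code{y} (integer labels) and
#'   \code{cache} (the descriptor table used).
#' @examples
#' \dontrun{
#' ds <- generateSyntheticDataset(20, seed = 1)
#' fm <- featureMatrix(ds)
#' dim(fm$x)
#' }
#' @export
featureMatrix <- function(records, descriptorCache = NULL, seed = 1L) {
  if (is(records, "CoamsDataset")) records <- records@records
  stopifnot(all(datasetSchema() %in% names(records)))
  if (nrow(records) == 0L)
    stop("no records supplied", call. = FALSE)
  smiles <- unique(c(records$api_smiles, records$coformer_smiles))
  if (is.null(descriptorCache)) {
    descriptorCache <- descriptorTable(
      data.frame(name = smiles, smiles = smiles), seed = seed)
  } else {
    missing <- setdiff(smiles, descriptorCache$smiles)
    if (length(missing))
      stop("descriptorCache lacks SMILES: ",
           paste(head(missing, 5L), collapse = ", "), call. = FALSE)
  }
  lookup <- function(s) {
    row <- descriptorCache[match(s, descriptorCache$smiles), ]
    v <- as.numeric(row[descriptorNames()])
    names(v) <- descriptorNames()
    v
  }
  x <- t(vapply(seq_len(nrow(records)), function(i)
    buildPairFeatures(lookup(records$api_smiles[i]),
                      lookup(records$coformer_smiles[i]),
                      records$prep_technique[i]),
    numeric(34L)))
  colnames(x) <- pairFeatureNames()
  rownames(x) <- NULL
  list(x = x, y = as.integer(records$label), cache = descriptorCache)
}
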