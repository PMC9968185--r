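# Labelled-system data model: CSV schema, curation rules and the
# stratified train/test split.

#' Canonical dataset schema
#'
#' Column names (bit-exact, in order) of the labelled-system CSV format:
#' one row per binary system tested for co-amorphisation.
#'
#' @return character vector of the 9 required column names.
#' @export
datasetSchema <- function() {
  c("api_name", "api_smiles", "coformer_name", "coformer_smiles",
    "coams_class", "molar_ratio", "prep_technique", "label",
    "stability_reported")
}

# raw preparation-method -> pathway lookup, editable via the CSV shipped
# in inst/extdata/prep_technique_map.csv
.prepMap <- function() {
  p <- system.file("extdata", "prep_technique_map.csv",
                   package = "coamscreen")
  if (!nzchar(p)) p <- file.path("inst", "extdata",
                                 "prep_technique_map.csv")
  map <- read.csv(p, stringsAsFactors = FALSE)
  setNames(map$pathway, map$method)
}

#' Map a raw preparation method to its pathway
#'
#' Raw technique names (milling, spray-drying, melt-quench, ...) are
#' mapped onto the two-pathway dichotomy used by the model: kinetic
#' (mechanical/fast-drying routes) or thermodynamic (melt or slow
#' solvent routes). \code{"thermodynamic"} and \code{"kinetic"} pass
#' through unchanged.
#'
#' @param method character vector of raw method names.
#' @return character vector of \code{"thermodynamic"} / \code{"kinetic"};
#'   unmapped methods yield NA.
#' @examples
#' prepPathway(c("milling", "melt-quench", "kinetic"))
#' @export
prepPathway <- function(method) {
  m <- tolower(trimws(method))
  out <- ifelse(m %in% c("thermodynamic", "kinetic"), m,
                unname(.prepMap()[m]))
  as.character(out)
}

#' Read a labelled-system CSV
#'
#' Reads and validates a dataset CSV in the canonical schema (see
#' \code{\link{datasetSchema}}). Raw preparation-method names are mapped
#' to the thermodynamic/kinetic dichotomy with \code{\link{prepPathway}};
#' an unmappable value is an error naming the row.
#'
#' @param path CSV file path.
#' @return data.frame of validated records.
#' @export
readDataset <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(datasetSchema(), names(df))
  if (length(missing))
    stop("dataset is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  df <- df[, datasetSchema()]
  prep <- prepPathway(df$prep_technique)
  bad <- which(is.na(prep))
  if (length(bad))
    stop(sprintf("unknown prep_technique %s in row(s) %s",
                 paste(sQuote(unique(df$prep_technique[bad])),
                       collapse = ", "),
                 paste(bad, collapse = ", ")), call. = FALSE)
  df$prep_technique <- prep
  if (!all(df$label %in% c(0, 1)))
    stop("label must be 0 or 1; offending row(s): ",
         paste(which(!df$label %in% c(0, 1)), collapse = ", "),
         call. = FALSE)
  df$label <- as.integer(df$label)
  if (!all(df$coams_class %in% 1:4))
    stop("coams_class must be 1..4; offending row(s): ",
         paste(which(!df$coams_class %in% 1:4), collapse = ", "),
         call. = FALSE)
  df$coams_class <- as.integer(df$coams_class)
  df$stability_reported <- as.logical(df$stability_reported)
  df
}

# order-independent pair key
.pairKey <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "||")
}

#' Curate a labelled-system table
#'
#' Applies, in order, the three curation rules used to clean the
#' literature corpus: (1) positive systems without reported stability
#' data are dropped; (2) any compound pair reported with both labels
#' across entries is deemed inconsistent and removed entirely; (3) any
#' compound pair appearing more than three times is truncated to its
#' first three records in file order. Every removal is logged in the
#' provenance slot. Curation is idempotent and never adds records.
#'
#' @param records data.frame of validated records (see
#'   \code{\link{readDataset}}) or a \linkS4class{CoamsDataset}.
#' @return a \linkS4class{CoamsDataset} with \code{curated = TRUE}.
#' @examples
#' \dontrun{
#' ds <- curateDataset(readDataset("systems.csv"))
#' nrow(records(ds))
#' }
#' @export
curateDataset <- function(records) {
  if (is(records, "CoamsDataset")) records <- records@records
  stopifnot(is.data.frame(records))
  log <- list()
  note <- function(ids, pair, rule, action) {
    if (length(ids))
      log[[length(log) + 1L]] <<- data.frame(
        row_id = ids, pair = pair, rule = rule, action = action,
        stringsAsFactors = FALSE)
  }
  df <- records
  df$.row_id <- seq_len(nrow(df))
  df$.pair <- .pairKey(df$api_name, df$coformer_name)

  # rule 1: COAMS without stability data are unverifiable positives
  drop1 <- df$label == 1L & !df$stability_reported
  note(df$.row_id[drop1], df$.pair[drop1], "no_stability",
       "removed")
  df <- df[!drop1, , drop = FALSE]

  # rule 2: pairs reported with both labels are inconsistencies
  lab <- tapply(df$label, df$.pair, function(v) length(unique(v)))
  incons <- names(lab)[lab > 1L]
  drop2 <- df$.pair %in% incons
  note(df$.row_id[drop2], df$.pair[drop2], "contradictory_labels",
       "removed")
  df <- df[!drop2, , drop = FALSE]

  # rule 3: keep each pair at most three times (first occurrences win)
  keep <- unlist(lapply(split(seq_len(nrow(df)), df$.pair),
                        function(i) i[seq_len(min(3L, length(i)))]),
                 use.names = FALSE)
  drop3 <- setdiff(seq_len(nrow(df)), keep)
  note(df$.row_id[drop3], df$.pair[drop3], "max_three_per_pair",
       "removed")
  df <- df[sort(keep), , drop = FALSE]

  prov <- if (length(log)) do.call(rbind, log) else
    data.frame(row_id = integer(), pair = character(),
               rule = character(), action = character(),
               stringsAsFactors = FALSE)
  df$.row_id <- NULL; df$.pair <- NULL
  rownames(df) <- NULL
  new("CoamsDataset", records = df, provenance = prov, curated = TRUE)
}

#' @describeIn curateDataset records of a \linkS4class{CoamsDataset}.
#' @param x a \linkS4class{CoamsDataset}.
#' @export
records <- function(x) x@records

#' @describeIn curateDataset provenance log of curation actions.
#' @export
provenance <- function(x) x@provenance

setMethod("show", "CoamsDataset", function(object) {
  r <- object@records
  cat(sprintf("CoamsDataset: %d systems (%s)\n", nrow(r),
              if (object@curated) "curated" else "raw"))
  if (nrow(r)) {
    cat(sprintf("  labels: %d COAMS / %d non-COAMS\n",
                sum(r$label == 1L), sum(r$label == 0L)))
    cat("  classes:", paste(sprintf("%d: %d", 1:4,
                                    tabulate(r$coams_class, 4L)),
                            collapse = ", "), "\n")
  }
  if (nrow(object@provenance))
    cat(sprintf("  provenance: %d curation removals\n",
                nrow(object@provenance)))
})

#' Stratified train/test split
#'
#' Splits a curated dataset into training and test parts.
#' \code{testFraction} is the target ratio of test to training rows, so
#' the test part has \code{round(n * testFraction / (1 + testFraction))}
#' rows: at the default 1/12, a 244-system corpus yields 19 test and 225
#' training systems. The test part is drawn by repeated
#' random sampling until both the per-class proportions and the COAMS /
#' non-COAMS proportion in the test part deviate from the full data by
#' at most \code{tolerance} (absolute, per category). Deterministic for
#' a fixed seed.
#'
#' @param dataset a \linkS4class{CoamsDataset} or record data.frame.
#' @param testFraction target test-to-training row ratio (default
#'   1/12).
#' @param seed integer RNG seed.
#' @param tolerance maximum absolute deviation per class/label
#'   proportion (default 0.10).
#' @param maxAttempts resampling budget before giving up (default 10000).
#' @return list with data.frames \code{train} and \code{test}.
#' @examples
#' \dontrun{
#' sp <- splitTrainTest(generateSyntheticDataset(48, seed = 1), seed = 7)
#' nrow(sp$test)
#' }
#' @export
splitTrainTest <- function(dataset, testFraction = 1 / 12, seed = 1L,
                           tolerance = 0.10, maxAttempts = 10000L) {
  df <- if (is(dataset, "CoamsDataset")) dataset@records else dataset
  n <- nrow(df)
  if (length(unique(df$label)) < 2L)
    stop("need both labels present to split", call. = FALSE)
  nTest <- round(n * testFraction / (1 + testFraction))
  if (nTest < 1L || nTest >= n)
    stop("testFraction leaves an empty train or test part", call. = FALSE)
  fullClass <- tabulate(df$coams_class, 4L) / n
  fullLab <- mean(df$label)
  ok <- function(idx) {
    sub <- df[idx, ]
    all(abs(tabulate(sub$coams_class, 4L) / length(idx) - fullClass)
        <= tolerance) &&
      abs(mean(sub$label) - fullLab) <= tolerance
  }
  set.seed(seed)
  for (i in seq_len(maxAttempts)) {
    idx <- sample.int(n, nTest)
    if (ok(idx)) {
      idx <- sort(idx)
      return(list(train = df[-idx, , drop = FALSE],
                  test = df[idx, , drop = FALSE]))
    }
  }
  stop(sprintf(paste("no test split within tolerance %.2f after %d",
                     "attempts; consider a looser tolerance"),
               tolerance, maxAttempts), call. = FALSE)
}
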