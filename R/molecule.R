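# SMILES parsing and 3D embedding.
#
# Structure perception, seeded distance-geometry embedding (ETKDGv3 with a
# short MMFF94 cleanup), Gasteiger partial charges and the standard scalar
# descriptors are delegated to RDKit through a small python helper
# (inst/python/mol_backend.py); jobs and results travel as JSON files.
# Everything RDKit does is deterministic for a fixed (molecule, seed).

.pythonBin <- function() {
  bin <- Sys.getenv("COAMSCREEN_PYTHON", Sys.which("python"))
  if (!nzchar(bin))
    stop("python executable not found on PATH (RDKit backend required)",
         call. = FALSE)
  bin
}

.backendScript <- function() {
  p <- system.file("python", "mol_backend.py", package = "coamscreen")
  if (!nzchar(p)) {
    # not installed yet (e.g. sourced during development)
    p <- file.path("inst", "python", "mol_backend.py")
  }
  if (!file.exists(p))
    stop("mol_backend.py helper not found", call. = FALSE)
  p
}

# One backend invocation for a batch of SMILES. Returns a list, one element
# per input: either list(error=...) or the parsed structure.
.molBackend <- function(smiles, embed = FALSE, seed = 1L) {
  stopifnot(is.character(smiles), length(smiles) >= 1L)
  jobFile <- tempfile(fileext = ".json")
  outFile <- tempfile(fileext = ".json")
  on.exit(unlink(c(jobFile, outFile)), add = TRUE)
  jsonlite::write_json(
    list(smiles = I(smiles), embed = embed, seed = as.integer(seed)),
    jobFile, auto_unbox = TRUE)
  status <- suppressWarnings(system2(
    .pythonBin(), c(.backendScript(), jobFile, outFile),
    stdout = FALSE, stderr = FALSE))
  if (!identical(status, 0L) || !file.exists(outFile))
    stop("RDKit molecule backend failed (is RDKit available to python?)",
         call. = FALSE)
  jsonlite::read_json(outFile, simplifyVector = FALSE)
}

.moleculeFromBackend <- function(smiles, parsed, has3D, seed) {
  atoms <- do.call(rbind, lapply(parsed$atoms, function(a)
    data.frame(element = a$element, x = a$x, y = a$y, z = a$z,
               charge = a$charge, stringsAsFactors = FALSE)))
  bonds <- if (length(parsed$bonds)) {
    do.call(rbind, lapply(parsed$bonds, function(b)
      data.frame(a1 = b$a1, a2 = b$a2, order = b$order,
                 aromatic = b$aromatic)))
  } else {
    data.frame(a1 = integer(), a2 = integer(), order = integer(),
               aromatic = logical())
  }
  mol <- new("Molecule", smiles = smiles, canonical = parsed$canonical,
             atoms = atoms, bonds = bonds, has3D = has3D,
             seed = if (has3D) as.integer(seed) else NA_integer_)
  attr(mol, "props") <- lapply(parsed$props, function(p) as.numeric(p))
  mol
}

# Parse/embed a batch of SMILES into Molecule objects in one backend call.
.parseBatch <- function(smiles, embed = FALSE, seed = 1L) {
  res <- .molBackend(smiles, embed = embed, seed = seed)
  lapply(seq_along(smiles), function(i) {
    r <- res[[i]]
    if (!is.null(r$error))
      stop(sprintf("%s for SMILES '%s'", r$error, smiles[i]), call. = FALSE)
    .moleculeFromBackend(smiles[i], r, has3D = embed, seed = seed)
  })
}

#' Parse a SMILES string into a Molecule
#'
#' Parses a SMILES string, completes explicit hydrogens and returns a
#' \linkS4class{Molecule} carrying the atom/bond graph, Gasteiger partial
#' charges and the canonical SMILES re-serialisation. Coordinates are not
#' generated; use \code{\link{embed3d}} before requesting
#' geometry-dependent descriptors.
#'
#' @param smiles a single non-empty SMILES string.
#' @return a \linkS4class{Molecule}.
#' @examples
#' \dontrun{
#' mol <- parseSmiles("c1ccccc1")
#' nHeavyAtoms(mol)
#' }
#' @export
parseSmiles <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1L || !nzchar(smiles))
    stop("smiles must be a single non-empty string", call. = FALSE)
  .parseBatch(smiles, embed = FALSE)[[1L]]
}

#' Generate seeded 3D coordinates
#'
#' Attaches 3D coordinates (Angstrom) to a molecule using seeded
#' distance-geometry embedding (ETKDGv3) followed by an MMFF94 cleanup.
#' The embedding is deterministic for a fixed (molecule, seed): repeating
#' the call reproduces the coordinates bit for bit. If embedding fails for
#' a pathological structure an error is raised; retrying with a different
#' seed may succeed.
#'
#' @param mol a \linkS4class{Molecule} (or a SMILES string).
#' @param seed integer embedding seed, recorded on the object.
#' @return the molecule with \code{has3D = TRUE}.
#' @examples
#' \dontrun{
#' mol <- embed3d(parseSmiles("C"), seed = 42L)
#' coords3d(mol)
#' }
#' @export
embed3d <- function(mol, seed = 1L) {
  smiles <- if (is.character(mol)) {
    stopifnot(length(mol) == 1L)
    mol
  } else {
    stopifnot(is(mol, "Molecule"))
    mol@smiles
  }
  .parseBatch(smiles, embed = TRUE, seed = seed)[[1L]]
}

#' @describeIn parseSmiles total atom count (explicit hydrogens included).
#' @param mol a \linkS4class{Molecule}.
#' @export
nAtoms <- function(mol) nrow(mol@atoms)

#' @describeIn parseSmiles heavy (non-hydrogen) atom count.
#' @export
nHeavyAtoms <- function(mol) sum(mol@atoms$element != "H")

#' @describeIn parseSmiles n x 3 coordinate matrix (NULL before embedding).
#' @export
coords3d <- function(mol) {
  if (!mol@has3D) return(NULL)
  m <- as.matrix(mol@atoms[, c("x", "y", "z")])
  dimnames(m) <- list(NULL, c("x", "y", "z"))
  m
}

setMethod("show", "Molecule", function(object) {
  cat("Molecule:", object@smiles, "\n")
  cat("  canonical:", object@canonical, "\n")
  cat(sprintf("  %d atoms (%d heavy), %d bonds, 3D: %s\n",
              nAtoms(object), nHeavyAtoms(object), nrow(object@bonds),
              if (object@has3D)
                sprintf("yes (seed %d)", object@seed) else "no"))
})
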