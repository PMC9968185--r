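# The 29-descriptor molecular panel.
#
# Standard scalar descriptors (MW, SLogP, TopoPSA, HB donors/acceptors,
# rotatable bonds, aromatic/ring and acid/base group counts) come from the
# RDKit backend (see molecule.R). Topological indices are computed on the
# hydrogen-suppressed graph with igraph; polarizability sums, the Zhao
# additive van der Waals volume and the charged-partial-surface-area
# family (on the seeded 3D conformer, see sasa.R) are computed here.
# Exact definitions are documented in the methods vignette.

#' Names of the 29-descriptor panel, in canonical order
#'
#' The frozen descriptor order used by every feature matrix and serialized
#' model. \code{TopoShapeIndex} is the Petitjean topological shape index
#' (often printed as "Topo-ShapeIndex"); \code{TopoPSA} is the Ertl
#' topological polar surface area while \code{TPSA} is the 3D polar
#' surface area from the charged-partial-surface-area family.
#'
#' @return character vector of length 29.
#' @examples
#' descriptorNames()
#' @export
descriptorNames <- function() {
  c("ABC", "nAcid", "nBase", "nAromAtom", "nAromBond", "nAtom",
    "nHeavyAtom", "nHetero", "nH", "MW", "Diameter", "TopoShapeIndex",
    "nRot", "SLogP", "TopoPSA", "naRing", "apol", "bpol", "nHBAcc",
    "nHBDon", "RNCS", "RPCS", "TASA", "TPSA", "RASA", "RPSA", "fMF",
    "Vabc", "VAdjMat")
}

# atomic polarizabilities, 10^-24 cm^3 (CRC values)
.atomPol <- c(
  H = 0.666793, C = 1.76, N = 1.10, O = 0.802, F = 0.557, P = 3.63,
  S = 2.90, Cl = 2.18, Br = 3.05, I = 5.35, B = 3.03, Si = 5.38,
  Se = 3.77, Na = 24.11, K = 43.4, Li = 24.33, Ca = 22.8, Mg = 10.6,
  Zn = 7.1
)

# Zhao-style additive van der Waals volume contributions (A^3)
.vdwVolContrib <- c(
  H = 7.24, C = 20.58, N = 15.60, O = 14.71, F = 13.31, Cl = 22.45,
  Br = 26.52, I = 32.52, P = 24.43, S = 24.43, As = 26.52, B = 40.48,
  Si = 38.79, Se = 28.73, Te = 36.62
)

# hydrogen-suppressed graph of a Molecule
.heavyGraph <- function(mol) {
  heavy <- which(mol@atoms$element != "H")
  idx <- match(seq_len(nAtoms(mol)), heavy)  # atom index -> heavy index
  b <- mol@bonds
  keep <- !is.na(idx[b$a1]) & !is.na(idx[b$a2])
  igraph::graph_from_data_frame(
    data.frame(from = idx[b$a1[keep]], to = idx[b$a2[keep]]),
    directed = FALSE,
    vertices = data.frame(name = seq_along(heavy)))
}

# atom-bond connectivity index on the heavy graph
.abcIndex <- function(g) {
  if (igraph::ecount(g) == 0L) return(0)
  deg <- igraph::degree(g)
  el <- igraph::as_edgelist(g, names = FALSE)
  du <- deg[el[, 1L]]; dv <- deg[el[, 2L]]
  sum(sqrt((du + dv - 2) / (du * dv)))
}

# topological diameter and Petitjean shape index on the largest component
.diameterShape <- function(g) {
  if (igraph::vcount(g) <= 1L)
    return(c(Diameter = 0, TopoShapeIndex = 0))
  comp <- igraph::components(g)
  main <- igraph::induced_subgraph(g, which(comp$membership ==
                                            which.max(comp$csize)))
  if (igraph::vcount(main) <= 1L)
    return(c(Diameter = 0, TopoShapeIndex = 0))
  ecc <- igraph::eccentricity(main)
  D <- max(ecc); R <- min(ecc)
  c(Diameter = D,
    TopoShapeIndex = if (R > 0) (D - R) / R else 0)
}

# molecular-framework (ring systems + linkers) heavy-atom fraction:
# iteratively prune terminal heavy atoms; what survives is the framework
.frameworkFraction <- function(g) {
  n <- igraph::vcount(g)
  if (n == 0L) return(0)
  h <- g
  repeat {
    leaves <- which(igraph::degree(h) <= 1L)
    if (!length(leaves) || igraph::vcount(h) == 0L) break
    h <- igraph::delete_vertices(h, leaves)
  }
  igraph::vcount(h) / n
}

.lookupVals <- function(tab, elements, what) {
  v <- tab[elements]
  if (any(is.na(v)))
    stop(sprintf("no %s value for element(s): %s", what,
                 paste(unique(elements[is.na(v)]), collapse = ", ")),
         call. = FALSE)
  unname(v)
}

# backend props cached on the Molecule at parse time; refetched if absent
.molProps <- function(mol) {
  p <- attr(mol, "props")
  if (is.null(p)) {
    r <- .molBackend(mol@smiles, embed = FALSE)[[1L]]
    if (!is.null(r$error))
      stop(sprintf("%s for SMILES '%s'", r$error, mol@smiles),
           call. = FALSE)
    p <- lapply(r$props, as.numeric)
  }
  p
}

#' Compute the 29-descriptor panel for one molecule
#'
#' Computes the full descriptor panel (see \code{\link{descriptorNames}})
#' for a molecule. The charged-partial-surface-area family (RNCS, RPCS,
#' TASA, TPSA, RASA, RPSA) needs 3D coordinates: a SMILES input is parsed
#' and embedded automatically; a \linkS4class{Molecule} must already carry
#' them. Any descriptor that cannot be computed raises an error naming the
#' descriptor and the molecule -- values are never silently imputed.
#'
#' @param mol a SMILES string or an embedded \linkS4class{Molecule}.
#' @param seed embedding seed used when \code{mol} is a SMILES string.
#' @return named numeric vector of length 29 in canonical order.
#' @examples
#' \dontrun{
#' d <- computeDescriptors("CCO")
#' d[c("nHetero", "nHBDon", "nHBAcc")]
#' }
#' @export
computeDescriptors <- function(mol, seed = 1L) {
  if (is.character(mol)) mol <- embed3d(mol, seed = seed)
  stopifnot(is(mol, "Molecule"))
  if (!mol@has3D)
    stop(paste("molecule has no 3D coordinates; the surface descriptors",
               "(RNCS, RPCS, TASA, TPSA, RASA, RPSA) require embed3d()"),
         call. = FALSE)
  smi <- mol@smiles
  fail <- function(which, e)
    stop(sprintf("descriptor %s failed for '%s': %s", which, smi,
                 conditionMessage(e)), call. = FALSE)

  props <- tryCatch(.molProps(mol), error = function(e) fail("backend", e))
  el <- mol@atoms$element
  g <- .heavyGraph(mol)

  topo <- tryCatch({
    ds <- .diameterShape(g)
    m <- igraph::ecount(g)
    c(ABC = .abcIndex(g), ds, fMF = .frameworkFraction(g),
      VAdjMat = if (m > 0) 1 + log2(m) else 0)
  }, error = function(e) fail("graph topology", e))

  pol <- tryCatch({
    a <- .lookupVals(.atomPol, el, "polarizability")
    c(apol = sum(a),
      bpol = sum(abs(a[mol@bonds$a1] - a[mol@bonds$a2])))
  }, error = function(e) fail("apol/bpol", e))

  vabc <- tryCatch({
    contrib <- .lookupVals(.vdwVolContrib, el, "vdW volume")
    nAr <- props$naRing
    nNonAr <- max(0, props$nRing - props$naRing)
    sum(contrib) - 5.92 * nrow(mol@bonds) - 14.7 * nAr - 3.8 * nNonAr
  }, error = function(e) fail("Vabc", e))

  cpsa <- tryCatch(.cpsaDescriptors(mol),
                   error = function(e) fail("surface family", e))

  out <- c(
    ABC = unname(topo[["ABC"]]),
    nAcid = props$nAcid,
    nBase = props$nBase,
    nAromAtom = props$nAromAtom,
    nAromBond = props$nAromBond,
    nAtom = nAtoms(mol),
    nHeavyAtom = nHeavyAtoms(mol),
    nHetero = sum(el != "H" & el != "C"),
    nH = sum(el == "H"),
    MW = props$MW,
    Diameter = unname(topo[["Diameter"]]),
    TopoShapeIndex = unname(topo[["TopoShapeIndex"]]),
    nRot = props$nRot,
    SLogP = props$SLogP,
    TopoPSA = props$TopoPSA,
    naRing = props$naRing,
    apol = unname(pol[["apol"]]),
    bpol = unname(pol[["bpol"]]),
    nHBAcc = props$nHBAcc,
    nHBDon = props$nHBDon,
    RNCS = unname(cpsa[["RNCS"]]),
    RPCS = unname(cpsa[["RPCS"]]),
    TASA = unname(cpsa[["TASA"]]),
    TPSA = unname(cpsa[["TPSA"]]),
    RASA = unname(cpsa[["RASA"]]),
    RPSA = unname(cpsa[["RPSA"]]),
    fMF = unname(topo[["fMF"]]),
    Vabc = vabc,
    VAdjMat = unname(topo[["VAdjMat"]])
  )
  if (any(!is.finite(out)))
    stop(sprintf("non-finite descriptor(s) for '%s': %s", smi,
                 paste(names(out)[!is.finite(out)], collapse = ", ")),
         call. = FALSE)
  out[descriptorNames()]
}

#' Descriptor table for a set of molecules
#'
#' Computes the 29-descriptor panel for each row of a name + SMILES table
#' (or a character vector of SMILES). Molecules are parsed and embedded in
#' a single backend batch; duplicate SMILES are computed once.
#'
#' @param x data.frame with columns \code{name} and \code{smiles}, or a
#'   character vector of SMILES (names optional).
#' @param seed embedding seed.
#' @param fragment \code{"full"} (default) computes on the complete SMILES
#'   including any counter-ions; \code{"largest"} keeps only the largest
#'   covalent fragment (salt stripping).
#' @return data.frame with columns \code{name}, \code{smiles} and the 29
#'   descriptors.
#' @examples
#' \dontrun{
#' descriptorTable(c(ethanol = "CCO"))
#' }
#' @export
descriptorTable <- function(x, seed = 1L, fragment = c("full", "largest")) {
  fragment <- match.arg(fragment)
  if (is.character(x)) {
    nms <- if (!is.null(names(x))) names(x) else x
    x <- data.frame(name = nms, smiles = unname(x), stringsAsFactors = FALSE)
  }
  stopifnot(all(c("name", "smiles") %in% names(x)))
  smiles <- x$smiles
  if (fragment == "largest")
    smiles <- vapply(smiles, largestFragment, "", USE.NAMES = FALSE)
  uniq <- unique(smiles)
  mols <- .parseBatch(uniq, embed = TRUE, seed = seed)
  desc <- do.call(rbind, lapply(mols, computeDescriptors))
  desc <- desc[match(smiles, uniq), , drop = FALSE]
  out <- cbind(x[, c("name", "smiles")], as.data.frame(desc))
  rownames(out) <- NULL
  out
}

#' @describeIn descriptorTable largest covalent fragment of a (possibly
#'   multi-fragment) SMILES, by heavy-atom count.
#' @param smiles a SMILES string.
#' @export
largestFragment <- function(smiles) {
  parts <- strsplit(smiles, ".", fixed = TRUE)[[1L]]
  if (length(parts) == 1L) return(smiles)
  sizes <- vapply(.parseBatch(parts, embed = FALSE), nHeavyAtoms,
                  numeric(1L))
  parts[which.max(sizes)]
}
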