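# Solvent-accessible surface areas and the charged-partial-surface-area
# descriptor family, computed on the embedded 3D conformer with Gasteiger
# partial charges.
#
# Per-atom SASA follows Shrake & Rupley: each atom's sphere (Bondi vdW
# radius + 1.4 A water probe) is sampled on a fixed golden-spiral point
# grid and a point contributes when it lies outside every other atom's
# probe-inflated sphere. The fixed grid makes the values deterministic.

.bondiRadii <- c(
  H = 1.20, C = 1.70, N = 1.55, O = 1.52, F = 1.47, P = 1.80, S = 1.80,
  Cl = 1.75, Br = 1.85, I = 1.98, B = 1.92, Si = 2.10, Se = 1.90,
  Na = 2.27, K = 2.75, Li = 1.82, Ca = 2.31, Mg = 1.73, Zn = 1.39
)
.defaultVdw <- 1.70

.vdwRadius <- function(element) {
  r <- .bondiRadii[element]
  r[is.na(r)] <- .defaultVdw
  unname(r)
}

# Deterministic quasi-uniform unit-sphere points (golden spiral).
.spherePoints <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Per-atom solvent-accessible surface area
#'
#' Shrake-Rupley numerical SASA with Bondi radii, a 1.4 Angstrom probe and
#' a deterministic golden-spiral point grid.
#'
#' @param mol an embedded \linkS4class{Molecule} (\code{has3D} TRUE).
#' @param probe probe radius in Angstrom (default 1.4, water).
#' @param nPoints sphere sample points per atom (default 240).
#' @return numeric vector, one SASA value (Angstrom^2) per atom.
#' @examples
#' mol <- embed3d(parseSmiles("CCO"))
#' sum(atomSasa(mol))
#' @export
atomSasa <- function(mol, probe = 1.4, nPoints = 240L) {
  stopifnot(is(mol, "Molecule"))
  if (!mol@has3D)
    stop("SASA requires 3D coordinates; call embed3d() first", call. = FALSE)
  xyz <- coords3d(mol)
  rad <- .vdwRadius(mol@atoms$element) + probe
  n <- nrow(xyz)
  pts <- .spherePoints(nPoints)
  sasa <- numeric(n)
  for (i in seq_len(n)) {
    p <- sweep(pts * rad[i], 2L, xyz[i, ], "+")
    free <- rep(TRUE, nPoints)
    for (j in seq_len(n)) {
      if (j == i) next
      dc <- sum((xyz[i, ] - xyz[j, ])^2)
      if (dc >= (rad[i] + rad[j])^2) next  # sphere j cannot occlude
      d2 <- (p[, 1L] - xyz[j, 1L])^2 + (p[, 2L] - xyz[j, 2L])^2 +
            (p[, 3L] - xyz[j, 3L])^2
      free <- free & d2 > rad[j]^2
      if (!any(free)) break
    }
    sasa[i] <- 4 * pi * rad[i]^2 * sum(free) / nPoints
  }
  sasa
}

# Charged-partial-surface-area family (Stanton-Jurs style, on Gasteiger
# charges). An atom is "polar" when |q| >= polarCut (0.2), a common
# operational split of surface atoms into polar and hydrophobic.
#   TASA  total hydrophobic SASA          (|q| <  cut)
#   TPSA  total polar SASA                (|q| >= cut)   [3D surface family,
#                                          distinct from topological TopoPSA]
#   RASA  TASA / total SASA, RPSA = TPSA / total SASA
#   RNCS  SASA of the most negative atom scaled by its share of the total
#         negative charge; RPCS the positive analogue.
.cpsaDescriptors <- function(mol, polarCut = 0.2) {
  sasa <- atomSasa(mol)
  q <- mol@atoms$charge
  if (any(!is.finite(q)))
    stop("partial charges missing; embed3d() must be called first",
         call. = FALSE)
  total <- sum(sasa)
  polar <- abs(q) >= polarCut
  tasa <- sum(sasa[!polar])
  tpsa <- sum(sasa[polar])
  negs <- which(q < 0)
  rncs <- if (length(negs)) {
    i <- negs[which.min(q[negs])]
    sasa[i] * q[i] / sum(q[negs])
  } else 0
  poss <- which(q > 0)
  rpcs <- if (length(poss)) {
    i <- poss[which.max(q[poss])]
    sasa[i] * q[i] / sum(q[poss])
  } else 0
  c(RNCS = rncs, RPCS = rpcs, TASA = tasa, TPSA = tpsa,
    RASA = if (total > 0) tasa / total else 0,
    RPSA = if (total > 0) tpsa / total else 0)
}
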