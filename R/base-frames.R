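# Idealized planar base geometries, used both to fit base reference
# frames to observed ring atoms and to build synthetic fixtures.
#
# These are synthetic idealized coordinates constructed in code from
# regular polygons with a uniform 1.38 A ring bond length (a typical
# aromatic C-N/C-C distance): the pyrimidine six-ring is a regular
# hexagon, the purine five-ring a regular pentagon fused on the C4-C5
# edge, and exocyclic O/N substituents sit radially in-plane. Only
# internal consistency matters for the discrepancy metric -- frames are
# compared with each other, never against an external convention -- so
# idealized geometry is sufficient and keeps the package self-contained.

.RING_ATOMS <- list(
  A = c("N9", "C8", "N7", "C5", "C6", "N1", "C2", "N3", "C4"),
  G = c("N9", "C8", "N7", "C5", "C6", "N1", "C2", "N3", "C4"),
  C = c("N1", "C2", "N3", "C4", "C5", "C6"),
  U = c("N1", "C2", "N3", "C4", "C5", "C6")
)

.buildStandardBases <- function(bond = 1.38) {
  deg <- pi / 180
  hexAngles <- c(N1 = 90, C2 = 150, N3 = 210, C4 = 270, C5 = 330, C6 = 30)
  hexagon <- t(vapply(hexAngles, function(a)
    bond * c(cos(a * deg), sin(a * deg), 0), numeric(3)))
  colnames(hexagon) <- c("x", "y", "z")

  # regular pentagon fused on the C4-C5 edge, on the far side of the
  # hexagon center; vertex order around the ring is C4-N9-C8-N7-C5
  pentagonOn <- function(p1, p2) {
    mid <- (p1 + p2) / 2
    edge <- p2 - p1
    out <- c(edge[2], -edge[1], 0)            # in-plane normal to the edge
    if (sum(out * mid) < 0) out <- -out       # point away from the origin
    out <- out / sqrt(sum(out^2))
    apothem <- bond / (2 * tan(36 * deg))
    circum <- bond / (2 * sin(36 * deg))
    ctr <- mid + apothem * out
    a1 <- atan2(p1[2] - ctr[2], p1[1] - ctr[1])
    a2 <- atan2(p2[2] - ctr[2], p2[1] - ctr[1])
    # step from p1 away from p2 in 72 degree increments
    step <- if (sin(a2 - a1) > 0) -72 * deg else 72 * deg
    t(vapply(1:3, function(k)
      ctr + circum * c(cos(a1 + k * step), sin(a1 + k * step), 0),
      numeric(3)))
  }

  exo <- function(ringCtr, at, dist) {
    dir <- at - ringCtr
    dir[3] <- 0
    at + dist * dir / sqrt(sum(dir^2))
  }

  pent <- pentagonOn(hexagon["C4", ], hexagon["C5", ])
  rownames(pent) <- c("N9", "C8", "N7")
  purine <- rbind(hexagon, pent)
  hexCtr <- colMeans(hexagon)
  pentCtr <- colMeans(purine[c("C4", "C5", "N7", "C8", "N9"), ])

  bases <- list(
    A = rbind(purine, N6 = exo(hexCtr, hexagon["C6", ], 1.35)),
    G = rbind(purine, O6 = exo(hexCtr, hexagon["C6", ], 1.25),
              N2 = exo(hexCtr, hexagon["C2", ], 1.35)),
    C = rbind(hexagon, O2 = exo(hexCtr, hexagon["C2", ], 1.25),
              N4 = exo(hexCtr, hexagon["C4", ], 1.35)),
    U = rbind(hexagon, O2 = exo(hexCtr, hexagon["C2", ], 1.25),
              O4 = exo(hexCtr, hexagon["C4", ], 1.25))
  )
  # center each base on the centroid of its frame-defining ring atoms,
  # base plane = xy, so the base normal of the standard pose is +z
  lapply(names(bases), function(b) {
    m <- bases[[b]]
    sweep(m, 2L, colMeans(m[.RING_ATOMS[[b]], , drop = FALSE]))
  }) |> stats::setNames(names(bases))
}

.STANDARD_BASES <- .buildStandardBases()

#' Standard base geometry
#'
#' Returns the embedded idealized planar geometry of a base: ring atoms
#' plus exocyclic O/N substituents, centered on the ring-atom centroid,
#' base plane in xy (normal +z). Row names are atom names.
#'
#' @param baseLetter one of \code{"A"}, \code{"C"}, \code{"G"}, \code{"U"}.
#' @return numeric matrix with one row per heavy atom.
#' @export
standardBaseGeometry <- function(baseLetter) {
  if (!baseLetter %in% names(.STANDARD_BASES))
    stop("unknown base letter '", baseLetter, "'")
  .STANDARD_BASES[[baseLetter]]
}

#' Ring atoms defining the base frame
#' @param baseLetter one of A/C/G/U.
#' @return character vector of atom names (9 for purines, 6 for
#'   pyrimidines).
#' @export
baseRingAtoms <- function(baseLetter) {
  if (!baseLetter %in% names(.RING_ATOMS))
    stop("unknown base letter '", baseLetter, "'")
  .RING_ATOMS[[baseLetter]]
}

# modified nucleotides mapped to a parent letter, so sequences align
# across structures with scattered modifications; unmapped hetero
# residues are excluded from chains with a warning
.MODIFIED_PARENT <- c(
  PSU = "U", H2U = "U", "4SU" = "U", "5MU" = "U", OMU = "U", UR3 = "U",
  "1MA" = "A", A2M = "A", MA6 = "A", "6MA" = "A", "2MA" = "A",
  OMG = "G", "2MG" = "G", M2G = "G", "7MG" = "G", G7M = "G", "1MG" = "G",
  I = "G",
  "5MC" = "C", OMC = "C", "4OC" = "C"
)

#' Map a residue name to its parent base letter
#'
#' Standard residues map to themselves; a built-in table maps common
#' modified nucleotides (pseudouridine, methylated bases, ...) to their
#' parent letter. Unknown residues return \code{NA}.
#'
#' @param resid residue name(s), e.g. \code{"PSU"}.
#' @return character vector of A/C/G/U or \code{NA}.
#' @export
parentBaseLetter <- function(resid) {
  out <- ifelse(resid %in% c("A", "C", "G", "U"), resid,
                unname(.MODIFIED_PARENT[resid]))
  as.character(out)
}

#' Base reference frame from observed atoms
#'
#' Fits the embedded standard planar geometry of the base onto the
#' observed ring atoms (least squares, proper rotation) and returns the
#' base center and orientation. The center is the unweighted mean of the
#' observed ring atoms used in the fit; the rotation carries the standard
#' pose onto the observed base, so identical bases in identical poses
#' yield identical rotations, and rigidly moving the atoms by (Q, t)
#' moves the frame to (Q R, Q c + t).
#'
#' At least 3 of the frame-defining ring atoms must be present
#' (purines: N9 C8 N7 C5 C6 N1 C2 N3 C4; pyrimidines: N1 C2 N3 C4 C5 C6);
#' otherwise the frame is undefined and an error is raised, upon which
#' callers drop the nucleotide and log a warning.
#'
#' @param atoms data.frame with columns \code{elety}, \code{x}, \code{y},
#'   \code{z} (heavy atoms of one nucleotide).
#' @param baseLetter parent base letter, one of A/C/G/U.
#' @return list with \code{center} (length 3) and \code{rotation} (3x3).
#' @export
computeBaseFrame <- function(atoms, baseLetter) {
  ring <- baseRingAtoms(baseLetter)
  std <- standardBaseGeometry(baseLetter)
  present <- intersect(ring, atoms$elety)
  if (length(present) < 3L)
    stop("frame undefined: only ", length(present),
         " of the ring atoms of ", baseLetter, " are present")
  obs <- as.matrix(atoms[match(present, atoms$elety), c("x", "y", "z")])
  fit <- kabschSuperpose(obs, std[present, , drop = FALSE])
  list(center = colMeans(obs), rotation = fit$rotation)
}
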