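#' Fixture specification for synthetic motif scopes
#'
#' Describes a fully-controlled synthetic scope: a set of near-identical
#' RNA chains written as minimal-but-valid mmCIF files (atom_site loop
#' plus entry/exptl/refine/entity records, so metadata filters are
#' exercised too), derived from one ideal helical motif with, per member,
#' optional global rigid motions (which must not change the discrepancy),
#' isotropic Gaussian coordinate noise, in-place per-base rotations
#' (which change the discrepancy by a closed form), indels (which shift
#' author numbering and exercise the aligner), and missing base atoms
#' (which force drops). Member 1 is always the pristine query.
#'
#' @param nNt nucleotides per chain (default 11, echoing the size of the
#'   ribosomal decoding loop used throughout the documentation).
#' @param nMembers number of scope members (chains/files).
#' @param sequence base letters, length \code{nNt}; default: seeded
#'   random draw from A/C/G/U.
#' @param numbers author residue numbers, length \code{nNt}; default
#'   \code{1:nNt}.
#' @param noiseSigma isotropic Gaussian coordinate noise (Angstrom)
#'   applied to members 2..n; 0 disables.
#' @param perBaseRotations data.frame(\code{member}, \code{position},
#'   \code{angle}) of in-place base rotations (radians, about the base
#'   normal, center fixed).
#' @param indels data.frame(\code{member}, \code{position}): the
#'   nucleotide is removed and later author numbers shift down by one.
#' @param missingAtoms data.frame(\code{member}, \code{position}): all
#'   but two ring atoms of that nucleotide are removed, leaving its frame
#'   undefined.
#' @param modifiedResidues data.frame(\code{member}, \code{position},
#'   \code{code}): residue written under a modified-residue code (e.g.
#'   \code{PSU}) with its parent geometry.
#' @param rigidMotions logical; apply a random global rigid motion to
#'   members 2..n.
#' @param resolutions per-member resolution (Angstrom); default
#'   \code{2.0, 2.1, ...}.
#' @param methods per-member experimental method strings.
#' @param neighbors data.frame(\code{member}, \code{chain},
#'   \code{distance}, \code{description}): plant a one-atom ion chain at
#'   an exact minimum distance from the motif chain.
#' @param protein logical; add a short synthetic peptide chain next to
#'   the motif in every member (exercises non-RNA chain handling).
#' @param helical list(\code{rise}, \code{twistDeg}, \code{radius}) of
#'   the ideal helical path.
#' @param seed integer RNG seed; a fixed seed gives byte-identical
#'   output files.
#' @return a validated fixture spec (list, class \code{"fixtureSpec"}).
#' @seealso [makeScope()], [generateIdealMotif()]
#' @export
fixtureSpec <- function(nNt = 11L, nMembers = 6L, sequence = NULL,
                        numbers = NULL, noiseSigma = 0,
                        perBaseRotations = NULL, indels = NULL,
                        missingAtoms = NULL, modifiedResidues = NULL,
                        rigidMotions = TRUE, resolutions = NULL,
                        methods = NULL, neighbors = NULL, protein = FALSE,
                        helical = list(rise = 3.4, twistDeg = 32,
                                       radius = 2.5),
                        seed = 1L) {
  nNt <- as.integer(nNt); nMembers <- as.integer(nMembers)
  stopifnot(nNt >= 2L, nMembers >= 1L)
  if (is.null(numbers)) numbers <- seq_len(nNt)
  stopifnot(length(numbers) == nNt, !is.unsorted(numbers))
  if (!is.null(sequence)) {
    sequence <- toupper(strsplit(paste(sequence, collapse = ""), "")[[1L]])
    stopifnot(length(sequence) == nNt, all(sequence %in% c("A","C","G","U")))
  }
  if (is.null(resolutions))
    resolutions <- round(2.0 + 0.1 * (seq_len(nMembers) - 1L), 2)
  stopifnot(length(resolutions) == nMembers)
  if (is.null(methods)) methods <- rep("X-RAY DIFFRACTION", nMembers)
  stopifnot(length(methods) == nMembers)
  if (!is.null(indels) && !is.null(missingAtoms)) {
    clash <- merge(indels, missingAtoms, by = c("member", "position"))
    if (nrow(clash))
      stop("contradictory spec: position ", clash$position[1L],
           " of member ", clash$member[1L],
           " is flagged both as an indel and as missing atoms")
  }
  spec <- list(nNt = nNt, nMembers = nMembers, sequence = sequence,
               numbers = as.integer(numbers), noiseSigma = noiseSigma,
               perBaseRotations = perBaseRotations, indels = indels,
               missingAtoms = missingAtoms,
               modifiedResidues = modifiedResidues,
               rigidMotions = isTRUE(rigidMotions),
               resolutions = resolutions, methods = methods,
               neighbors = neighbors, protein = isTRUE(protein),
               helical = helical, seed = as.integer(seed))
  class(spec) <- "fixtureSpec"
  spec
}

#' Ideal helical motif coordinates
#'
#' Places the embedded standard base geometries along an ideal helical
#' path (configurable rise, twist and radius): base i is rotated by
#' \code{i * twist} about the helix axis and shifted by \code{i * rise}
#' along it. All base frames are well defined by construction, and with
#' the defaults consecutive bases satisfy the stacking criterion while
#' non-consecutive ones do not.
#'
#' @param nNt number of nucleotides (>= 2).
#' @param sequence base letters (default alternating \code{GCAU...}).
#' @param numbers author residue numbers (default \code{1:nNt}).
#' @param rise,twistDeg,radius helical parameters (Angstrom, degrees,
#'   Angstrom).
#' @param chain chain identifier to stamp on the atoms.
#' @return data.frame of heavy atoms with columns \code{chain},
#'   \code{resid}, \code{resno}, \code{elety}, \code{elesy}, \code{x},
#'   \code{y}, \code{z}.
#' @export
generateIdealMotif <- function(nNt = 11L, sequence = NULL, numbers = NULL,
                               rise = 3.4, twistDeg = 32, radius = 2.5,
                               chain = "A") {
  nNt <- as.integer(nNt)
  stopifnot(nNt >= 2L)
  if (is.null(sequence))
    sequence <- rep(c("G", "C", "A", "U"), length.out = nNt)
  sequence <- toupper(strsplit(paste(sequence, collapse = ""), "")[[1L]])
  stopifnot(length(sequence) == nNt)
  if (is.null(numbers)) numbers <- seq_len(nNt)
  ang <- twistDeg * pi / 180
  out <- lapply(seq_len(nNt), function(i) {
    a <- ang * (i - 1L)
    Rz <- matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1),
                 3L, 3L, byrow = TRUE)
    pos <- as.vector(Rz %*% c(radius, 0, 0)) + c(0, 0, rise * (i - 1L))
    std <- standardBaseGeometry(sequence[i])
    xyz <- applyRigidMotion(std, Rz, pos)
    data.frame(chain = chain, resid = sequence[i], resno = numbers[i],
               elety = rownames(std),
               elesy = substr(rownames(std), 1L, 1L),
               x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

.randomRotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2*(y^2 + z^2), 2*(x*y - w*z),     2*(x*z + w*y),
    2*(x*y + w*z),     1 - 2*(x^2 + z^2), 2*(y*z - w*x),
    2*(x*z - w*y),     2*(y*z + w*x),     1 - 2*(x^2 + y^2)),
    3L, 3L, byrow = TRUE)
}

.axisRotation <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -axis[3], axis[2], axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3L, 3L, byrow = TRUE)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

#' Write a synthetic motif scope to disk
#'
#' Materializes a [fixtureSpec()] as a directory of mmCIF files (one per
#' member, PDB ids \code{SY00}, \code{SY01}, ...), a chain-set scope
#' table (\code{scope.tsv}), a Stockholm alignment of the member
#' sequences with its row map (\code{alignment.sto},
#' \code{rowmap.tsv}) derived from the ground-truth indels, and a JSON
#' manifest (\code{manifest.json}) recording every applied
#' transformation, sufficient to predict retained-instance counts, drop
#' reasons and closed-form discrepancies.
#'
#' @param spec a [fixtureSpec()].
#' @param dir output directory (created if needed).
#' @return list with \code{dir}, \code{scope} (a
#'   [ScopeDefinition-class] in chain_set mode), \code{stockholm} (path),
#'   \code{rowMap} (data.frame) and \code{manifest}.
#' @export
makeScope <- function(spec, dir) {
  stopifnot(inherits(spec, "fixtureSpec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(spec$seed)
  sequence <- spec$sequence
  if (is.null(sequence))
    sequence <- sample(c("A", "C", "G", "U"), spec$nNt, replace = TRUE)
  master <- generateIdealMotif(
    spec$nNt, sequence, spec$numbers,
    rise = spec$helical$rise, twistDeg = spec$helical$twistDeg,
    radius = spec$helical$radius, chain = "A")
  ringIdx <- function(df, pos) {
    which(df$resno == spec$numbers[pos] &
            df$elety %in% baseRingAtoms(sequence[pos]))
  }
  sel <- function(df, member)
    if (is.null(df)) df else df[df$member == member, , drop = FALSE]

  members <- list()
  rows <- character(spec$nMembers)
  for (m in seq_len(spec$nMembers)) {
    pdbId <- sprintf("SY%02d", m - 1L)
    atoms <- master
    row <- sequence                      # alignment row, '-' for indels
    record <- list(pdbId = pdbId, chain = "A", model = 1L,
                   resolution = spec$resolutions[m],
                   method = spec$methods[m])

    mod <- sel(spec$modifiedResidues, m)
    if (!is.null(mod) && nrow(mod)) {
      for (k in seq_len(nrow(mod)))
        atoms$resid[atoms$resno == spec$numbers[mod$position[k]]] <-
          mod$code[k]
      record$modifiedResidues <- mod[c("position", "code")]
    }

    rot <- sel(spec$perBaseRotations, m)
    if (!is.null(rot) && nrow(rot)) {
      for (k in seq_len(nrow(rot))) {
        idx <- which(atoms$resno == spec$numbers[rot$position[k]])
        ri <- ringIdx(master, rot$position[k])
        ctr <- colMeans(as.matrix(master[ri, c("x", "y", "z")]))
        normal <- c(0, 0, 1)  # bases are built normal to z before motion
        a <- rot$position[k] - 1L
        Rz <- .axisRotation(c(0, 0, 1),
                            spec$helical$twistDeg * pi / 180 * a)
        Q <- .axisRotation(as.vector(Rz %*% normal), rot$angle[k])
        xyz <- as.matrix(atoms[idx, c("x", "y", "z")])
        atoms[idx, c("x", "y", "z")] <-
          sweep(sweep(xyz, 2L, ctr) %*% t(Q), 2L, ctr, "+")
      }
      record$perBaseRotations <- rot[c("position", "angle")]
    }

    if (m > 1L && spec$noiseSigma > 0) {
      atoms[c("x", "y", "z")] <- atoms[c("x", "y", "z")] +
        matrix(stats::rnorm(3L * nrow(atoms), sd = spec$noiseSigma),
               ncol = 3L)
      record$noiseSigma <- spec$noiseSigma
    }

    ind <- sel(spec$indels, m)
    if (!is.null(ind) && nrow(ind)) {
      for (pos in sort(ind$position, decreasing = TRUE)) {
        num <- spec$numbers[pos]
        atoms <- atoms[atoms$resno != num, , drop = FALSE]
        later <- atoms$resno > num
        atoms$resno[later] <- atoms$resno[later] - 1L
        row[pos] <- "-"
      }
      record$indels <- sort(ind$position)
    }

    mis <- sel(spec$missingAtoms, m)
    if (!is.null(mis) && nrow(mis)) {
      for (pos in mis$position) {
        ring <- baseRingAtoms(sequence[pos])
        drop <- atoms$resno == spec$numbers[pos] &
          !(atoms$elety %in% ring[1:2])
        atoms <- atoms[!drop, , drop = FALSE]
      }
      record$missingAtoms <- sort(mis$position)
    }

    if (m > 1L && spec$rigidMotions) {
      Q <- .randomRotation()
      tr <- stats::runif(3, -20, 20)
      atoms[c("x", "y", "z")] <-
        applyRigidMotion(as.matrix(atoms[c("x", "y", "z")]), Q, tr)
      record$rigidMotion <- list(rotation = Q, translation = tr)
    }

    atoms$entity <- 1L
    entities <- c("1" = "synthetic RNA motif chain")

    if (spec$protein) {
      pep <- .syntheticPeptide(offset = c(12, 0, 0))
      pep$entity <- 2L
      if (!is.null(record$rigidMotion))
        pep[c("x", "y", "z")] <- applyRigidMotion(
          as.matrix(pep[c("x", "y", "z")]),
          record$rigidMotion$rotation, record$rigidMotion$translation)
      atoms <- rbind(atoms, pep)
      entities <- c(entities, "2" = "synthetic peptide")
    }

    nb <- sel(spec$neighbors, m)
    if (!is.null(nb) && nrow(nb)) {
      motifXyz <- as.matrix(atoms[atoms$chain == "A", c("x", "y", "z")])
      for (k in seq_len(nrow(nb))) {
        eid <- max(atoms$entity) + 1L
        # support point of the cloud in a fixed direction guarantees the
        # planted minimum distance is exact
        u <- c(1, 1, 1) / sqrt(3)
        sp <- motifXyz[which.max(motifXyz %*% u), ]
        p <- sp + nb$distance[k] * u
        desc <- if (!is.null(nb$description)) nb$description[k] else
          paste("synthetic ion", nb$chain[k])
        atoms <- rbind(atoms, data.frame(
          chain = nb$chain[k], resid = "MG", resno = 1L, elety = "MG",
          elesy = "MG", x = p[1], y = p[2], z = p[3], entity = eid,
          stringsAsFactors = FALSE))
        entities <- c(entities, stats::setNames(desc, eid))
        record$neighbors <- rbind(record$neighbors,
          data.frame(chain = nb$chain[k], distance = nb$distance[k],
                     description = desc))
      }
    }

    atoms$model <- 1L
    atoms$alt <- NA_character_
    atoms$insert <- NA_character_
    atoms$occ <- 1
    path <- file.path(dir, paste0(pdbId, ".cif"))
    .writeCif(path, pdbId, atoms, entities = entities,
              method = spec$methods[m], resolution = spec$resolutions[m])
    record$path <- path
    record$sequence <- paste(sequence, collapse = "")
    record$row <- paste(row, collapse = "")
    members[[pdbId]] <- record
    rows[m] <- record$row
  }

  scopeTsv <- file.path(dir, "scope.tsv")
  memberDf <- data.frame(
    path = vapply(members, `[[`, character(1), "path"),
    chain = "A", model = 1L, stringsAsFactors = FALSE)
  rownames(memberDf) <- NULL
  utils::write.table(memberDf, scopeTsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  stoPath <- file.path(dir, "alignment.sto")
  rowNames <- paste0(names(members), "/A")
  writeLines(c("# STOCKHOLM 1.0", "",
               sprintf("%-12s %s", rowNames, rows), "//"), stoPath)
  rowMap <- data.frame(row = rowNames, path = memberDf$path, chain = "A",
                       model = 1L, stringsAsFactors = FALSE)
  utils::write.table(rowMap, file.path(dir, "rowmap.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  manifest <- list(spec = unclass(spec)[setdiff(names(spec),
                     c("perBaseRotations", "indels", "missingAtoms",
                       "modifiedResidues", "neighbors"))],
                   sequence = paste(sequence, collapse = ""),
                   members = members)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  scope <- new("ScopeDefinition", mode = "chain_set", members = memberDf)
  list(dir = dir, scope = scope, stockholm = stoPath, rowMap = rowMap,
       manifest = manifest, scopeTsv = scopeTsv)
}

.syntheticPeptide <- function(offset = c(12, 0, 0)) {
  # two-residue alanine stub; enough to exercise non-RNA chain handling
  base <- rbind(
    c(0.0, 0.0, 0.0), c(1.45, 0.0, 0.0), c(2.0, 1.4, 0.0),
    c(1.4, 2.4, 0.0), c(2.0, -1.1, 0.9))
  one <- function(resno, shift) data.frame(
    chain = "P", resid = "ALA", resno = resno,
    elety = c("N", "CA", "C", "O", "CB"),
    elesy = c("N", "C", "C", "O", "C"),
    x = base[, 1] + offset[1] + shift, y = base[, 2] + offset[2],
    z = base[, 3] + offset[3], stringsAsFactors = FALSE)
  rbind(one(1L, 0), one(2L, 3.8))
}
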