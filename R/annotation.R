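#' Interaction-annotation thresholds
#'
#' Geometric thresholds of the heuristic stacking/pairing annotator.
#' This annotator is an explicit heuristic stand-in for a full
#' basepair-family classification (Leontis-Westhof typing is out of
#' scope): it labels base pairs as plain \code{"stack"} or \code{"pair"}
#' from base-center distance, base-normal angle, vertical offset and
#' polar-atom contacts. Its purpose in the instance table is to make
#' presence/absence shifts of interactions across conformational
#' clusters visible, not to reproduce a reference classification.
#'
#' @param stackMaxDist max base-center distance for a stack (Angstrom).
#' @param stackMaxNormalAngle max angle between base normals, degrees
#'   (folded, so antiparallel normals count as parallel).
#' @param stackOffsetRange allowed |vertical offset| range (projection of
#'   the inter-center vector on the mean base normal), Angstrom.
#' @param pairDistRange allowed base-center distance range for a pair.
#' @param pairMaxNormalAngle max folded normal-normal angle for a
#'   (near-coplanar) pair, degrees.
#' @param pairContactDist max N/O-to-N/O distance counting as a polar
#'   contact (Angstrom).
#' @param pairMinContacts minimum number of polar contacts.
#' @return a named list of thresholds.
#' @export
interactionConfig <- function(stackMaxDist = 5.5, stackMaxNormalAngle = 30,
                              stackOffsetRange = c(2.5, 5.5),
                              pairDistRange = c(4.5, 12.0),
                              pairMaxNormalAngle = 65,
                              pairContactDist = 3.4, pairMinContacts = 2L) {
  list(stackMaxDist = stackMaxDist,
       stackMaxNormalAngle = stackMaxNormalAngle,
       stackOffsetRange = stackOffsetRange, pairDistRange = pairDistRange,
       pairMaxNormalAngle = pairMaxNormalAngle,
       pairContactDist = pairContactDist,
       pairMinContacts = as.integer(pairMinContacts))
}

# folded angle between base normals in degrees, in [0, 90]
.normalAngle <- function(n1, n2) {
  ct <- abs(sum(n1 * n2)) / sqrt(sum(n1^2) * sum(n2^2))
  acos(pmin(1, ct)) * 180 / pi
}

#' Annotate within-motif stacking and pairing
#'
#' Applies the heuristic criteria of [interactionConfig()] to every
#' nucleotide pair of the instance. A pair of bases is a STACK when their
#' centers are closer than \code{stackMaxDist}, their normals within
#' \code{stackMaxNormalAngle} of (anti)parallel, and the vertical offset
#' lies in \code{stackOffsetRange}; it is a PAIR when the center distance
#' falls in \code{pairDistRange}, the normals are within
#' \code{pairMaxNormalAngle} of (anti)parallel, and at least
#' \code{pairMinContacts} N/O atom pairs across the two bases sit within
#' \code{pairContactDist}. Stack takes precedence when both criteria
#' fire. The output is invariant under rigid motion of the instance and
#' symmetric in the pair.
#'
#' @param instance a [MotifInstance-class].
#' @param config thresholds from [interactionConfig()].
#' @return data.frame with columns \code{unit1}, \code{unit2},
#'   \code{label1}, \code{label2}, \code{kind}, \code{centerDist},
#'   \code{normalAngle}, \code{verticalOffset}; zero rows when nothing
#'   qualifies. Pairs are canonically ordered by position.
#' @export
annotateInteractions <- function(instance, config = interactionConfig()) {
  stopifnot(is(instance, "MotifInstance"))
  n <- length(instance@unitIds)
  polar <- instance@atoms[grepl("^[NO]", instance@atoms$elety), ,
                          drop = FALSE]
  labels <- paste0(instance@baseLetters, instance@numbers)
  rows <- list()
  for (i in seq_len(max(0L, n - 1L))) {
    for (j in seq.int(i + 1L, n)) {
      ci <- instance@centers[i, ]; cj <- instance@centers[j, ]
      v <- cj - ci
      d <- sqrt(sum(v^2))
      if (d > max(config$stackMaxDist, config$pairDistRange[2L])) next
      ni <- instance@rotations[[i]][, 3L]
      nj <- instance@rotations[[j]][, 3L]
      ang <- .normalAngle(ni, nj)
      njAligned <- if (sum(ni * nj) < 0) -nj else nj
      nm <- ni + njAligned
      nm <- nm / sqrt(sum(nm^2))
      offset <- abs(sum(v * nm))
      isStack <- d < config$stackMaxDist &&
        ang < config$stackMaxNormalAngle &&
        offset >= config$stackOffsetRange[1L] &&
        offset <= config$stackOffsetRange[2L]
      isPair <- FALSE
      if (!isStack && d >= config$pairDistRange[1L] &&
          d <= config$pairDistRange[2L] &&
          ang <= config$pairMaxNormalAngle) {
        pi_ <- polar[polar$nt == i, c("x", "y", "z"), drop = FALSE]
        pj <- polar[polar$nt == j, c("x", "y", "z"), drop = FALSE]
        if (nrow(pi_) && nrow(pj)) {
          dd <- sqrt(outer(rowSums(pi_^2), rowSums(pj^2), "+") -
                       2 * as.matrix(pi_) %*% t(as.matrix(pj)))
          isPair <- sum(dd <= config$pairContactDist) >=
            config$pairMinContacts
        }
      }
      if (isStack || isPair)
        rows[[length(rows) + 1L]] <- data.frame(
          unit1 = instance@unitIds[i], unit2 = instance@unitIds[j],
          label1 = labels[i], label2 = labels[j],
          kind = if (isStack) "stack" else "pair",
          centerDist = d, normalAngle = ang, verticalOffset = offset,
          stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(unit1 = character(), unit2 = character(),
                      label1 = character(), label2 = character(),
                      kind = character(), centerDist = numeric(),
                      normalAngle = numeric(), verticalOffset = numeric()))
  do.call(rbind, rows)
}

#' Chains within a cutoff of a motif instance
#'
#' A chain of the parent structure is a neighbor when any of its heavy
#' atoms lies within \code{cutoff} of any heavy atom of any instance
#' nucleotide. The instance's own nucleotides are excluded, but its host
#' chain can still be a neighbor through its non-motif residues.
#' Distances use all heavy atoms (hydrogens are discarded at parse time:
#' they are usually absent from experimental structures). The
#' computation is plain all-pairs, blocked per chain.
#'
#' @param instance a [MotifInstance-class].
#' @param structure the [StructureModel-class] the instance came from.
#' @param cutoff neighbor distance in Angstrom (default 10).
#' @return data.frame with columns \code{chain}, \code{identity} (entity
#'   description when the file provides one, else the chain id) and
#'   \code{minDistance}; zero rows when there is no neighbor.
#' @export
detectNeighborChains <- function(instance, structure, cutoff = 10.0) {
  stopifnot(is(instance, "MotifInstance"), is(structure, "StructureModel"))
  inv <- structure@atomInventory
  own <- !is.na(inv$ntUnit) & inv$ntUnit %in% instance@unitIds
  other <- inv[!own, , drop = FALSE]
  mx <- as.matrix(instance@atoms[c("x", "y", "z")])
  out <- list()
  for (ch in unique(other$chain)) {
    cx <- as.matrix(other[other$chain == ch, c("x", "y", "z"),
                          drop = FALSE])
    d2 <- outer(rowSums(mx^2), rowSums(cx^2), "+") - 2 * mx %*% t(cx)
    dmin <- sqrt(max(0, min(d2)))
    if (dmin <= cutoff) {
      ident <- structure@entities[ch]
      if (is.null(ident) || length(ident) == 0L || is.na(ident))
        ident <- ch
      out[[ch]] <- data.frame(chain = ch, identity = unname(ident),
                              minDistance = dmin,
                              stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(chain = character(), identity = character(),
                      minDistance = numeric()))
  res <- do.call(rbind, out)
  res <- res[order(res$chain), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Summarize neighbor chains across instances
#'
#' Counts, per neighboring chain identity, the number of instances it
#' appears near (each instance contributes at most once per identity),
#' making the full range of interaction partners across the scope
#' visible at a glance.
#'
#' @param reports named list of [detectNeighborChains()] results, one
#'   per instance.
#' @return data.frame with columns \code{identity}, \code{count},
#'   \code{minDistance} (smallest distance seen for that identity),
#'   sorted by decreasing count.
#' @export
summarizeNeighbors <- function(reports) {
  stopifnot(length(reports) >= 1L)
  acc <- list()
  for (rep_ in reports) {
    if (!nrow(rep_)) next
    for (ident in unique(rep_$identity)) {
      d <- min(rep_$minDistance[rep_$identity == ident])
      if (is.null(acc[[ident]]))
        acc[[ident]] <- list(count = 0L, minDistance = Inf)
      acc[[ident]]$count <- acc[[ident]]$count + 1L
      acc[[ident]]$minDistance <- min(acc[[ident]]$minDistance, d)
    }
  }
  if (!length(acc))
    return(data.frame(identity = character(), count = integer(),
                      minDistance = numeric()))
  res <- data.frame(
    identity = names(acc),
    count = vapply(acc, function(x) x$count, integer(1)),
    minDistance = vapply(acc, function(x) x$minDistance, numeric(1)),
    stringsAsFactors = FALSE)
  res <- res[order(-res$count, res$identity), , drop = FALSE]
  rownames(res) <- NULL
  res
}
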