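#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation \code{R} and translation \code{t} minimizing
#' \code{sum_i ||a_i - (R b_i + t)||^2}, i.e. the rigid motion carrying the
#' second point cloud onto the first. Reflections are corrected by flipping
#' the sign of the smallest singular direction, so the rotation is always
#' proper (det +1). With fewer than 3 points the rotation part is the
#' identity and only the translation is fitted.
#'
#' @param pointsA,pointsB k x 3 numeric matrices, same k >= 1.
#' @return list with \code{rotation} (3x3), \code{translation} (length 3)
#'   and \code{rmsd} (Angstrom).
#' @examples
#' a <- matrix(rnorm(15), 5, 3)
#' fit <- kabschSuperpose(a, a)
#' fit$rmsd  # 0
#' @export
kabschSuperpose <- function(pointsA, pointsB) {
  pointsA <- as.matrix(pointsA); pointsB <- as.matrix(pointsB)
  if (nrow(pointsA) == 0L) stop("cannot superpose zero points")
  if (!identical(dim(pointsA), dim(pointsB)))
    stop("point sets must have identical dimensions")
  if (ncol(pointsA) != 3L) stop("points must be k x 3")
  k <- nrow(pointsA)
  ca <- colMeans(pointsA); cb <- colMeans(pointsB)
  if (k < 3L) {
    R <- diag(3)
  } else {
    A <- sweep(pointsA, 2L, ca); B <- sweep(pointsB, 2L, cb)
    H <- crossprod(B, A)  # sum_i b_i a_i^T
    sv <- svd(H)
    d <- sign(det(sv$v %*% t(sv$u)))
    R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  }
  tr <- ca - as.vector(R %*% cb)
  moved <- pointsB %*% t(R) + matrix(tr, k, 3L, byrow = TRUE)
  rmsd <- sqrt(sum((pointsA - moved)^2) / k)
  list(rotation = R, translation = tr, rmsd = rmsd)
}

.checkRotation <- function(R, what = "rotation") {
  if (!is.matrix(R) || !identical(dim(R), c(3L, 3L)))
    stop(what, " must be a 3x3 matrix")
  if (max(abs(crossprod(R) - diag(3))) > 1e-6)
    stop(what, " is not orthonormal")
  if (abs(det(R) - 1) > 1e-6)
    stop(what, " is not a proper rotation (det != +1)")
  invisible(TRUE)
}

#' Angle between two rotations
#'
#' The geodesic angle of \code{r1' r2} on SO(3), i.e.
#' \code{arccos((trace(r1' r2) - 1)/2)}. It is evaluated as
#' \code{atan2(sin, cos)} with the sine taken from the skew-symmetric
#' part of \code{r1' r2}: identical mathematically, but well-conditioned
#' near zero angle, where the plain arccos loses half the machine
#' precision.
#'
#' @param r1,r2 proper orthonormal 3x3 matrices.
#' @return angle in radians, in \code{[0, pi]}.
#' @export
rotationAngle <- function(r1, r2) {
  .checkRotation(r1, "r1"); .checkRotation(r2, "r2")
  R <- crossprod(r1, r2)
  ct <- (sum(diag(R)) - 1) / 2
  st <- sqrt((R[3, 2] - R[2, 3])^2 + (R[1, 3] - R[3, 1])^2 +
               (R[2, 1] - R[1, 2])^2) / 2
  atan2(st, ct)
}

#' Apply a rigid motion to a point matrix
#' @param points k x 3 matrix.
#' @param rotation 3x3 proper rotation.
#' @param translation length-3 vector.
#' @return transformed k x 3 matrix.
#' @export
applyRigidMotion <- function(points, rotation, translation = c(0, 0, 0)) {
  points <- as.matrix(points)
  points %*% t(rotation) +
    matrix(translation, nrow(points), 3L, byrow = TRUE)
}

#' Geometric discrepancy between two motif instances
#'
#' The dissimilarity at the heart of the package. The n base centers of
#' instance \code{b} are superposed onto those of \code{a} by the
#' least-squares rigid fit T*; with residual center distances
#' \code{d_i = ||c_i^a - T*(c_i^b)||} and base reorientation angles
#' \code{theta_i} (radians, between \code{R_i^a} and the rotated
#' \code{R_i^b}), the discrepancy is
#'
#' \deqn{D = \frac{1}{n}\sqrt{\sum_i d_i^2 + \sum_i (k \theta_i)^2}}
#'
#' with angle weight \code{k = kAngle} Angstrom per radian (default 1).
#' D is zero iff the two instances are related by a rigid motion, and is
#' invariant to any rigid motion applied to either whole instance. Only
#' base centers enter the superposition, so the value does not depend on
#' sugar/backbone completeness. The per-nucleotide normalization and the
#' 1 Angstrom/radian weight follow the FR3D lineage of discrepancy
#' measures and are exposed so alternative weightings are one argument
#' away.
#'
#' @param instA,instB [MotifInstance-class] objects of equal length n >= 2
#'   with frames defined at every position.
#' @param kAngle angle weight in Angstrom per radian.
#' @return non-negative scalar discrepancy.
#' @export
geometricDiscrepancy <- function(instA, instB, kAngle = 1) {
  stopifnot(is(instA, "MotifInstance"), is(instB, "MotifInstance"))
  n <- length(instA@unitIds)
  if (length(instB@unitIds) != n)
    stop("instances have different lengths (", n, " vs ",
         length(instB@unitIds), ")")
  if (n < 2L) stop("discrepancy needs at least 2 nucleotides")
  if (length(instA@rotations) != n || length(instB@rotations) != n)
    stop("missing base frame")
  fit <- kabschSuperpose(instA@centers, instB@centers)
  moved <- applyRigidMotion(instB@centers, fit$rotation, fit$translation)
  d2 <- rowSums((instA@centers - moved)^2)
  th <- vapply(seq_len(n), function(i) {
    rotationAngle(instA@rotations[[i]],
                  fit$rotation %*% instB@rotations[[i]])
  }, numeric(1))
  sqrt(sum(d2) + sum((kAngle * th)^2)) / n
}

#' All-against-all discrepancy matrix
#'
#' Computes [geometricDiscrepancy()] for every unordered pair of
#' instances. The result is symmetric with zero diagonal by construction,
#' and both properties are asserted before returning.
#'
#' @param instances list of [MotifInstance-class] objects of uniform
#'   length (>= 2 instances).
#' @param kAngle angle weight passed through.
#' @return a [DiscrepancyMatrix-class].
#' @export
discrepancyMatrix <- function(instances, kAngle = 1) {
  if (length(instances) < 2L) stop("need at least 2 instances")
  ids <- vapply(instances, function(x) x@instanceId, character(1))
  n <- length(instances)
  v <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      d <- tryCatch(
        geometricDiscrepancy(instances[[i]], instances[[j]], kAngle),
        error = function(e) stop("discrepancy failed for pair (", ids[i],
                                 ", ", ids[j], "): ", conditionMessage(e)))
      v[i, j] <- v[j, i] <- d
    }
  }
  stopifnot(max(abs(v - t(v))) == 0, all(diag(v) == 0), all(is.finite(v)))
  new("DiscrepancyMatrix", instanceIds = ids, values = v,
      nNt = length(instances[[1L]]@unitIds))
}
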