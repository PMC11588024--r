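# Shared builders and independent oracles for the test suite.

# deterministic-ish random proper rotation (uses the session RNG)
randomRotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2*(y^2+z^2), 2*(x*y-w*z), 2*(x*z+w*y),
           2*(x*y+w*z), 1 - 2*(x^2+z^2), 2*(y*z-w*x),
           2*(x*z-w*y), 2*(y*z+w*x), 1 - 2*(x^2+y^2)),
         3, 3, byrow = TRUE)
}

axisRotation <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -axis[3], axis[2], axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

# MotifInstance built from a raw atom table (frames recomputed per base)
atomsToInstance <- function(atoms, id = "TEST|1|A", resolution = NA_real_,
                            method = NA_character_) {
  keys <- unique(atoms$resno)
  letters_ <- character(); centers <- NULL; rotations <- list()
  instAtoms <- NULL
  for (k in seq_along(keys)) {
    ra <- atoms[atoms$resno == keys[k], , drop = FALSE]
    letter <- parentBaseLetter(ra$resid[1])
    fr <- computeBaseFrame(ra[c("elety", "x", "y", "z")], letter)
    letters_ <- c(letters_, letter)
    centers <- rbind(centers, fr$center)
    rotations[[k]] <- fr$rotation
    instAtoms <- rbind(instAtoms, data.frame(
      nt = k, elety = ra$elety, x = ra$x, y = ra$y, z = ra$z))
  }
  parts <- strsplit(id, "|", fixed = TRUE)[[1]]
  new("MotifInstance", instanceId = id, pdbId = parts[1],
      model = as.integer(parts[2]), chain = parts[3],
      unitIds = sprintf("%s|%s|%s|%s|%d", parts[1], parts[2], parts[3],
                        letters_, keys),
      baseLetters = letters_, numbers = as.integer(keys),
      centers = unname(centers), rotations = rotations,
      atoms = instAtoms, resolution = resolution, method = method,
      source = "")
}

idealInstance <- function(nNt = 11, id = "TEST|1|A", ...) {
  atomsToInstance(generateIdealMotif(nNt, ...), id = id)
}

# instance moved rigidly as a whole (atoms, centers and frames)
rigidMoveInstance <- function(inst, Q, t) {
  inst@centers <- applyRigidMotion(inst@centers, Q, t)
  inst@rotations <- lapply(inst@rotations, function(R) Q %*% R)
  inst@atoms[c("x", "y", "z")] <-
    applyRigidMotion(as.matrix(inst@atoms[c("x", "y", "z")]), Q, t)
  inst
}

addNoiseInstance <- function(inst, sigma) {
  atoms <- inst@atoms
  atoms[c("x", "y", "z")] <- atoms[c("x", "y", "z")] +
    matrix(rnorm(3 * nrow(atoms), sd = sigma), ncol = 3)
  # rebuild frames from the noisy atoms, like parsing a noisy file would
  df <- data.frame(resid = inst@baseLetters[atoms$nt],
                   resno = inst@numbers[atoms$nt],
                   elety = atoms$elety, x = atoms$x, y = atoms$y,
                   z = atoms$z)
  atomsToInstance(df, id = inst@instanceId)
}

# --- independent oracles -------------------------------------------------

# Horn's closed-form quaternion superposition (independent of the SVD
# Kabsch path under test)
hornSuperpose <- function(A, B) {
  k <- nrow(A)
  ca <- colMeans(A); cb <- colMeans(B)
  Ac <- sweep(A, 2, ca); Bc <- sweep(B, 2, cb)
  S <- t(Bc) %*% Ac
  N <- matrix(0, 4, 4)
  N[1, 1] <- S[1,1] + S[2,2] + S[3,3]
  N[1, 2] <- N[2, 1] <- S[2,3] - S[3,2]
  N[1, 3] <- N[3, 1] <- S[3,1] - S[1,3]
  N[1, 4] <- N[4, 1] <- S[1,2] - S[2,1]
  N[2, 2] <- S[1,1] - S[2,2] - S[3,3]
  N[2, 3] <- N[3, 2] <- S[1,2] + S[2,1]
  N[2, 4] <- N[4, 2] <- S[1,3] + S[3,1]
  N[3, 3] <- -S[1,1] + S[2,2] - S[3,3]
  N[3, 4] <- N[4, 3] <- S[2,3] + S[3,2]
  N[4, 4] <- -S[1,1] - S[2,2] + S[3,3]
  e <- eigen(N, symmetric = TRUE)
  q <- e$vectors[, 1]
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(1 - 2*(y^2+z^2), 2*(x*y-w*z), 2*(x*z+w*y),
                2*(x*y+w*z), 1 - 2*(x^2+z^2), 2*(y*z-w*x),
                2*(x*z-w*y), 2*(y*z+w*x), 1 - 2*(x^2+y^2)),
              3, 3, byrow = TRUE)
  tr <- ca - as.vector(R %*% cb)
  moved <- B %*% t(R) + matrix(tr, k, 3, byrow = TRUE)
  list(rotation = R, translation = tr,
       rmsd = sqrt(sum((A - moved)^2) / k))
}

# rotation angle via quaternion extraction (axis-angle decomposition)
quatRotationAngle <- function(R1, R2) {
  R <- t(R1) %*% R2
  w <- sqrt(max(0, 1 + R[1,1] + R[2,2] + R[3,3])) / 2
  2 * acos(min(1, w))
}

# straight-line reimplementation of the discrepancy metric on top of
# the Horn oracle
oracleDiscrepancy <- function(a, b, kAngle = 1) {
  n <- nrow(a$centers)
  fit <- hornSuperpose(a$centers, b$centers)
  moved <- b$centers %*% t(fit$rotation) +
    matrix(fit$translation, n, 3, byrow = TRUE)
  d2 <- rowSums((a$centers - moved)^2)
  th <- vapply(seq_len(n), function(i)
    quatRotationAngle(a$rotations[[i]], fit$rotation %*% b$rotations[[i]]),
    numeric(1))
  sqrt(sum(d2) + sum((kAngle * th)^2)) / n
}

instGeom <- function(inst) list(centers = inst@centers,
                                rotations = inst@rotations)

# exhaustive global aligner: enumerates every alignment of a and b,
# scoring match/mismatch plus gap runs as open + len * extend
bruteForceAlignScore <- function(a, b, match = 2, mismatch = -1,
                                 gapOpen = -5, gapExtend = -1) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  best <- -Inf
  rec <- function(i, j, score, gapState) {
    if (i > length(a) && j > length(b)) {
      best <<- max(best, score); return(invisible())
    }
    if (i <= length(a) && j <= length(b)) {
      s <- if (a[i] == "N" || b[j] == "N") 0 else
        if (a[i] == b[j]) match else mismatch
      rec(i + 1, j + 1, score + s, 0L)
    }
    if (i <= length(a))   # gap in b
      rec(i + 1, j, score + gapExtend +
            if (gapState != 1L) gapOpen else 0, 1L)
    if (j <= length(b))   # gap in a
      rec(i, j + 1, score + gapExtend +
            if (gapState != 2L) gapOpen else 0, 2L)
  }
  rec(1L, 1L, 0, 0L)
  best
}

# Euler-angle rotation grid for the superposition brute force
rotationGrid <- function(stepDeg = 9) {
  s <- stepDeg * pi / 180
  alphas <- seq(0, 2 * pi - s / 2, by = s)
  betas <- seq(0, pi, by = s)
  out <- list()
  for (a in alphas) for (b in betas) for (g in alphas) {
    Ra <- axisRotation(c(0, 0, 1), a)
    Rb <- axisRotation(c(0, 1, 0), b)
    Rg <- axisRotation(c(0, 0, 1), g)
    out[[length(out) + 1]] <- Ra %*% Rb %*% Rg
  }
  out
}

# min rmsd over a rotation grid (translation solved by centroid match);
# uses rmsd^2 = (|A|^2 + |B|^2 - 2 tr(H R^T)) / k with H = A^T B
gridMinRmsd <- function(A, B, grid9) {
  k <- nrow(A)
  Ac <- sweep(A, 2, colMeans(A)); Bc <- sweep(B, 2, colMeans(B))
  H <- t(Ac) %*% Bc
  cross <- as.vector(grid9 %*% as.vector(H))
  sqrt(max(0, (sum(Ac^2) + sum(Bc^2) - 2 * max(cross)) / k))
}

# grid as n x 9 matrix such that row %*% vec(H) = tr(H %*% t(R))
rotationGrid9 <- function(stepDeg = 9) {
  g <- rotationGrid(stepDeg)
  t(vapply(g, as.vector, numeric(9)))
}

# coplanar canonical-geometry base pair: C rotated 60 degrees in plane
# and offset along +y from G's hexagon center gives three ~2.9 A polar
# contacts across the two bases
wcPairAtoms <- function() {
  G <- standardBaseGeometry("G")
  C <- standardBaseGeometry("C")
  hexG <- colMeans(G[c("N1", "C2", "N3", "C4", "C5", "C6"), ])
  Cp <- applyRigidMotion(C, axisRotation(c(0, 0, 1), 60 * pi / 180),
                         hexG + c(0, 5.6, 0))
  rbind(
    data.frame(chain = "A", resid = "G", resno = 1L, elety = rownames(G),
               x = G[, 1], y = G[, 2], z = G[, 3]),
    data.frame(chain = "A", resid = "C", resno = 2L, elety = rownames(C),
               x = Cp[, 1], y = Cp[, 2], z = Cp[, 3]))
}

# all-pairs brute-force neighbor detection (independent of the package
# implementation's per-chain blocking)
bruteForceNeighbors <- function(instance, structure, cutoff) {
  inv <- structure@atomInventory
  own <- !is.na(inv$ntUnit) & inv$ntUnit %in% instance@unitIds
  other <- inv[!own, , drop = FALSE]
  mx <- as.matrix(instance@atoms[c("x", "y", "z")])
  res <- list()
  for (ch in sort(unique(other$chain))) {
    cx <- as.matrix(other[other$chain == ch, c("x", "y", "z"),
                          drop = FALSE])
    dmin <- Inf
    for (i in seq_len(nrow(mx))) for (j in seq_len(nrow(cx)))
      dmin <- min(dmin, sqrt(sum((mx[i, ] - cx[j, ])^2)))
    if (dmin <= cutoff)
      res[[ch]] <- data.frame(chain = ch, minDistance = dmin)
  }
  if (!length(res)) return(data.frame(chain = character(),
                                      minDistance = numeric()))
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

# every leaf order consistent with an hclust dendrogram
dendroConsistentOrders <- function(merge) {
  ordersOf <- function(k) {
    if (k < 0) return(list(-k))
    a <- ordersOf(merge[k, 1]); b <- ordersOf(merge[k, 2])
    out <- list()
    for (x in a) for (y in b) {
      out[[length(out) + 1]] <- c(x, y)
      out[[length(out) + 1]] <- c(y, x)
    }
    out
  }
  ordersOf(nrow(merge))
}

combinat_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in combinat_perms(n - 1)) for (k in 0:(n - 1))
    out[[length(out) + 1]] <- append(p, n, after = k)
  out
}

pathCostOf <- function(v, ord) {
  n <- length(ord)
  sum(v[cbind(ord[-n], ord[-1])])
}
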