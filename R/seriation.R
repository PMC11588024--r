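#' Order instances so similar ones are adjacent
#'
#' Seriation of the discrepancy matrix for the heatmap and the instance
#' table. The default pipeline is average-linkage hierarchical
#' clustering followed by optimal leaf ordering: among all 2^(n-1)
#' leaf orders consistent with the dendrogram, the one minimizing the
#' summed discrepancy between adjacent instances is found by dynamic
#' programming (Bar-Joseph style). Clusters of similar conformations
#' then appear as contiguous dark blocks on the heatmap diagonal.
#'
#' Alternatives: \code{"greedy-path"} (nearest-neighbor path grown from
#' the closest pair, no dendrogram constraint) and \code{"none"}
#' (identity order). All tie-breaks are deterministic (first index
#' wins), so identical inputs always give identical orders.
#'
#' @param dm a [DiscrepancyMatrix-class].
#' @param method \code{"olo"}, \code{"greedy-path"} or \code{"none"}.
#' @return a [SeriationResult-class].
#' @export
seriate <- function(dm, method = c("olo", "greedy-path", "none")) {
  stopifnot(is(dm, "DiscrepancyMatrix"))
  method <- match.arg(method)
  v <- dm@values
  n <- nrow(v)
  ord <- if (n < 2L || method == "none") {
    seq_len(n)
  } else if (method == "greedy-path") {
    .greedyPathOrder(v)
  } else {
    hc <- stats::hclust(stats::as.dist(v), method = "average")
    .optimalLeafOrder(hc$merge, v)
  }
  new("SeriationResult", order = as.integer(ord),
      pathCost = seriationPathCost(dm, ord), methodTag = method)
}

#' Path cost of an instance order
#'
#' Sum of the discrepancies between adjacent instances under the order;
#' the quantity the optimal leaf ordering minimizes.
#'
#' @param dm a [DiscrepancyMatrix-class].
#' @param order a permutation of instance indices.
#' @return numeric scalar.
#' @export
seriationPathCost <- function(dm, order) {
  stopifnot(is(dm, "DiscrepancyMatrix"),
            identical(sort(as.integer(order)), seq_len(nrow(dm@values))))
  n <- length(order)
  if (n < 2L) return(0)
  sum(dm@values[cbind(order[-n], order[-1L])])
}

.greedyPathOrder <- function(v) {
  n <- nrow(v)
  d <- v; diag(d) <- Inf
  start <- arrayInd(which.min(d), dim(d))   # first index wins ties
  path <- as.integer(start[1L, ])
  used <- logical(n); used[path] <- TRUE
  while (length(path) < n) {
    free <- which(!used)
    dHead <- v[path[1L], free]
    dTail <- v[path[length(path)], free]
    if (min(dHead) < min(dTail)) {
      pick <- free[which.min(dHead)]
      path <- c(pick, path)
    } else {
      pick <- free[which.min(dTail)]
      path <- c(path, pick)
    }
    used[pick] <- TRUE
  }
  path
}

# Bar-Joseph optimal leaf ordering: for each dendrogram node and each
# (first leaf u, last leaf w) pair, the cheapest consistent linear order
# of the node's leaves; children may appear in either left/right order.
.optimalLeafOrder <- function(merge, v) {
  n <- nrow(v)
  nodeLeaves <- vector("list", nrow(merge))
  cost <- vector("list", nrow(merge))    # cost[[k]][u, w] over leaf names
  best <- vector("list", nrow(merge))    # backtracking: split leaf pair
  leavesOf <- function(k) if (k < 0L) -k else nodeLeaves[[k]]
  costOf <- function(k) {
    if (k < 0L) {
      m <- matrix(0, 1L, 1L, dimnames = list(-k, -k))
      return(m)
    }
    cost[[k]]
  }
  for (k in seq_len(nrow(merge))) {
    a <- merge[k, 1L]; b <- merge[k, 2L]
    la <- leavesOf(a); lb <- leavesOf(b)
    ca <- costOf(a); cb <- costOf(b)
    leaves <- c(la, lb)
    nodeLeaves[[k]] <- leaves
    m <- matrix(Inf, length(leaves), length(leaves),
                dimnames = list(leaves, leaves))
    bk <- array(NA_integer_, c(length(leaves), length(leaves), 2L),
                dimnames = list(leaves, leaves, NULL))
    fill <- function(lFrom, cFrom, lTo, cTo) {
      for (u in lFrom) for (w in lTo) {
        uu <- as.character(u); ww <- as.character(w)
        for (x in lFrom) for (y in lTo) {
          val <- cFrom[uu, as.character(x)] + v[x, y] +
            cTo[as.character(y), ww]
          if (val < m[uu, ww]) {
            m[uu, ww] <<- val
            bk[uu, ww, ] <<- c(x, y)
          }
        }
      }
    }
    fill(la, ca, lb, cb)   # child a first
    fill(lb, cb, la, ca)   # child b first
    cost[[k]] <- m
    best[[k]] <- bk
  }
  root <- nrow(merge)
  mRoot <- cost[[root]]
  idx <- arrayInd(which.min(mRoot), dim(mRoot))
  u <- as.integer(rownames(mRoot)[idx[1L, 1L]])
  w <- as.integer(colnames(mRoot)[idx[1L, 2L]])
  inLeaves <- function(k, leaf) leaf %in% leavesOf(k)
  reconstruct <- function(k, u, w) {
    if (k < 0L) return(-k)
    a <- merge[k, 1L]; b <- merge[k, 2L]
    if (inLeaves(a, u)) { first <- a; second <- b }
    else { first <- b; second <- a }
    xy <- best[[k]][as.character(u), as.character(w), ]
    c(reconstruct(first, u, xy[1L]), reconstruct(second, xy[2L], w))
  }
  reconstruct(root, u, w)
}
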