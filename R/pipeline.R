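#' Run the full motif-correspondence pipeline
#'
#' End-to-end driver: resolve the query selection, retrieve the
#' corresponding instances across the scope, compute the all-against-all
#' geometric discrepancy, seriate, annotate interactions, detect
#' neighboring chains, and (optionally) write the full set of outputs to
#' a directory:
#' \describe{
#'   \item{instances.tsv}{instance table in seriation order with summary
#'     header.}
#'   \item{discrepancy_ordered.csv}{seriation-ordered discrepancy
#'     matrix.}
#'   \item{discrepancy.json}{full matrix (ids + row-major values).}
#'   \item{heatmap.png}{grayscale heatmap (darker = more similar).}
#'   \item{superposition.cif}{instances superposed onto the query, one
#'     model per instance.}
#'   \item{neighbors.tsv}{per-identity neighbor counts across
#'     instances.}
#'   \item{drops.tsv}{per-member drop log.}
#'   \item{run_log.txt}{human-readable run summary.}
#'   \item{query.json}{machine-readable, re-runnable query
#'     description.}
#' }
#'
#' @param queryFile structure file containing the query chain.
#' @param queryChain author chain id of the query.
#' @param model model number (default 1; the model is part of the
#'   instance identity).
#' @param selection range-selection string (e.g.
#'   \code{"1405:1409,1491:1496"}); exactly one of \code{selection} and
#'   \code{unitIds} must be given.
#' @param unitIds explicit character vector of formatted unit IDs.
#' @param scope a [ScopeDefinition-class] (see [scopeChainSet()],
#'   [scopeStockholm()]); the query chain must be a member.
#' @param ordering seriation method passed to [seriate()].
#' @param kAngle angle weight of the discrepancy metric (Angstrom per
#'   radian).
#' @param neighborCutoff neighbor-chain distance cutoff (Angstrom).
#' @param maxDiscrepancy optional reporting cutoff: instances farther
#'   than this from the query are omitted from the written table and
#'   ordered CSV. Never affects the computation; the full matrix JSON
#'   always contains every retained instance.
#' @param outDir output directory (created); \code{NULL} skips all file
#'   output.
#' @param includeNeighborhood logical; carry residues within
#'   \code{neighborCutoff} of each instance into the superposition
#'   output, moved by the same rigid motion.
#' @param writePng logical; render the heatmap raster.
#' @return (invisibly) list with \code{correspondence},
#'   \code{discrepancy}, \code{seriation}, \code{annotations},
#'   \code{neighbors}, \code{neighborSummary}, \code{table},
#'   \code{files}.
#' @export
runMotifCorrespondence <- function(queryFile, queryChain, model = 1L,
                                   selection = NULL, unitIds = NULL,
                                   scope, ordering = "olo", kAngle = 1,
                                   neighborCutoff = 10.0,
                                   maxDiscrepancy = NULL, outDir = NULL,
                                   includeNeighborhood = FALSE,
                                   writePng = TRUE) {
  if (is.null(selection) == is.null(unitIds))
    stop("give exactly one of 'selection' and 'unitIds'")
  qStructure <- parseStructure(queryFile, model)
  qChainRec <- qStructure@chains[[queryChain]]
  if (is.null(qChainRec))
    stop("chain ", queryChain, " of ", queryFile, " has no nucleotides")
  if (!is.null(selection))
    unitIds <- parseRangeSelection(selection, qChainRec)

  cs <- buildCorrespondence(unitIds, scope)
  instances <- cs@instances
  n <- length(instances)

  dm <- if (n >= 2L) discrepancyMatrix(instances, kAngle = kAngle) else
    new("DiscrepancyMatrix", instanceIds = names(instances),
        values = matrix(0, 1L, 1L), nNt = length(cs@query@unitIds))
  sr <- seriate(dm, ordering)

  # one parsed structure per source file serves annotation + neighbors
  cache <- list()
  getStructure <- function(inst) {
    key <- paste(inst@source, inst@model)
    if (is.null(cache[[key]]))
      cache[[key]] <<- parseStructure(inst@source, inst@model)
    cache[[key]]
  }
  annotations <- lapply(instances, annotateInteractions)
  neighbors <- lapply(instances, function(inst)
    detectNeighborChains(inst, getStructure(inst), neighborCutoff))
  nbSummary <- summarizeNeighbors(neighbors)

  keepIds <- names(instances)
  if (!is.null(maxDiscrepancy)) {
    dq <- dm@values[cs@query@instanceId, ]
    keepIds <- names(instances)[dq <= maxDiscrepancy]
  }
  ordIds <- dm@instanceIds[sr@order]
  tabIds <- ordIds[ordIds %in% keepIds]
  tab <- buildInstanceTable(cs, annotations, neighbors,
                            order = match(tabIds, names(instances)))

  files <- character()
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    fp <- function(x) file.path(outDir, x)
    writeInstanceTable(tab, fp("instances.tsv"))
    keepOrder <- sr@order[dm@instanceIds[sr@order] %in% keepIds]
    exportHeatmap(dm, keepOrder, fp("discrepancy_ordered.csv"),
                  fp("discrepancy.json"),
                  if (writePng) fp("heatmap.png") else NULL,
                  jsonOrder = sr@order)
    nbh <- NULL
    if (includeNeighborhood)
      nbh <- lapply(instances, function(inst)
        .neighborhoodAtoms(inst, getStructure(inst), neighborCutoff))
    sup <- superposeInstances(instances,
                              reference = cs@query@instanceId,
                              selection = tabIds, neighborhoods = nbh)
    writeSuperposition(sup, fp("superposition.cif"))
    utils::write.table(
      data.frame(identity = nbSummary$identity, count = nbSummary$count,
                 minDistance = sprintf("%.3f", nbSummary$minDistance)),
      fp("neighbors.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(cs@dropped, fp("drops.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    .writeQueryJson(fp("query.json"), queryFile, queryChain, model,
                    selection, unitIds, scope, ordering, kAngle,
                    neighborCutoff, maxDiscrepancy)
    .writeRunLog(fp("run_log.txt"), cs, dm, sr, nbSummary)
    files <- file.path(outDir, c(
      "instances.tsv", "discrepancy_ordered.csv", "discrepancy.json",
      if (writePng) "heatmap.png", "superposition.cif", "neighbors.tsv",
      "drops.tsv", "run_log.txt", "query.json"))
  }
  invisible(list(correspondence = cs, discrepancy = dm, seriation = sr,
                 annotations = annotations, neighbors = neighbors,
                 neighborSummary = nbSummary, table = tab,
                 files = files))
}

# residues (any chain, any type) with an atom within cutoff of the
# instance, excluding the instance's own nucleotides
.neighborhoodAtoms <- function(instance, structure, cutoff) {
  inv <- structure@atomInventory
  own <- !is.na(inv$ntUnit) & inv$ntUnit %in% instance@unitIds
  other <- inv[!own, , drop = FALSE]
  if (!nrow(other)) return(NULL)
  mx <- as.matrix(instance@atoms[c("x", "y", "z")])
  ox <- as.matrix(other[c("x", "y", "z")])
  d2 <- outer(rowSums(ox^2), rowSums(mx^2), "+") - 2 * ox %*% t(mx)
  nearAtom <- sqrt(pmax(0, apply(d2, 1L, min))) <= cutoff
  resKey <- paste(other$chain, other$resno, other$resid)
  nearRes <- resKey %in% unique(resKey[nearAtom])
  res <- other[nearRes, c("chain", "resid", "resno", "elety",
                          "x", "y", "z"), drop = FALSE]
  rownames(res) <- NULL
  res
}

.writeQueryJson <- function(path, queryFile, queryChain, model,
                            selection, unitIds, scope, ordering, kAngle,
                            neighborCutoff, maxDiscrepancy) {
  jsonlite::write_json(list(
    query_file = queryFile, query_chain = queryChain, model = model,
    selection = selection, unit_ids = unitIds,
    scope = list(mode = scope@mode,
                 members = scope@members,
                 stockholm = scope@stockholm,
                 resolution_max = scope@resolutionMax,
                 methods_allowed = scope@methodsAllowed),
    ordering = ordering, k_angle = kAngle,
    neighbor_cutoff = neighborCutoff,
    max_discrepancy = maxDiscrepancy),
    path, auto_unbox = TRUE, digits = NA, null = "null")
}

.writeRunLog <- function(path, cs, dm, sr, nbSummary) {
  off <- dm@values[upper.tri(dm@values)]
  writeLines(c(
    sprintf("query: %s (%d nt)", cs@query@instanceId,
            length(cs@query@unitIds)),
    sprintf("instances retained: %d", length(cs@instances)),
    sprintf("members dropped: %d", nrow(cs@dropped)),
    if (nrow(cs@dropped))
      sprintf("  drop %s: %s", cs@dropped$member, cs@dropped$reason),
    sprintf("discrepancy off-diagonal range: [%.4f, %.4f]",
            if (length(off)) min(off) else 0,
            if (length(off)) max(off) else 0),
    sprintf("seriation (%s) path cost: %.4f", sr@methodTag, sr@pathCost),
    sprintf("neighbor identities seen: %d", nrow(nbSummary))),
    path)
}
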