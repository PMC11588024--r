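#' Build a chain-set scope
#'
#' A chain-set scope lists (file, chain, model) members whose sequences
#' are near-identical (structures of the same molecule from the same
#' organism); correspondences are computed by pairwise global alignment
#' against the query chain.
#'
#' @param members data.frame with columns \code{path}, \code{chain} and
#'   optionally \code{model} (default 1), or the path of such a
#'   tab-separated file.
#' @param resolutionMax optional inclusive resolution ceiling (Angstrom).
#' @param methodsAllowed optional character vector of allowed
#'   experimental methods.
#' @param metadata optional sidecar data.frame (or TSV path) with columns
#'   \code{pdb_id}, \code{resolution}, \code{method}; overrides file
#'   headers.
#' @return a [ScopeDefinition-class].
#' @export
scopeChainSet <- function(members, resolutionMax = NA_real_,
                          methodsAllowed = character(), metadata = NULL) {
  members <- .readMembers(members)
  new("ScopeDefinition", mode = "chain_set", members = members,
      resolutionMax = as.numeric(resolutionMax),
      methodsAllowed = as.character(methodsAllowed),
      metadata = .readSidecar(metadata))
}

#' Build a Stockholm (cross-family) scope
#'
#' Correspondences come from a precomputed Stockholm multiple sequence
#' alignment (e.g. a covariance-model alignment of all chains mapped to
#' one RNA family); \code{rowMap} names the structure behind each
#' alignment row.
#'
#' @param stockholm path of the Stockholm alignment.
#' @param rowMap data.frame (or TSV path) with columns \code{row},
#'   \code{path}, \code{chain} and optionally \code{model}.
#' @inheritParams scopeChainSet
#' @return a [ScopeDefinition-class].
#' @export
scopeStockholm <- function(stockholm, rowMap, resolutionMax = NA_real_,
                           methodsAllowed = character(), metadata = NULL) {
  rowMap <- .readMembers(rowMap, needRow = TRUE)
  new("ScopeDefinition", mode = "stockholm", members = rowMap,
      stockholm = stockholm, resolutionMax = as.numeric(resolutionMax),
      methodsAllowed = as.character(methodsAllowed),
      metadata = .readSidecar(metadata))
}

.readMembers <- function(members, needRow = FALSE) {
  if (is.character(members) && length(members) == 1L)
    members <- utils::read.table(members, header = TRUE, sep = "\t",
                                 stringsAsFactors = FALSE)
  stopifnot(is.data.frame(members),
            all(c("path", "chain") %in% names(members)))
  if (needRow && is.null(members$row))
    stop("a stockholm scope needs a 'row' column naming alignment rows")
  if (is.null(members$model)) members$model <- 1L
  members$model <- as.integer(members$model)
  members$chain <- as.character(members$chain)
  members
}

.readSidecar <- function(metadata) {
  if (is.null(metadata))
    return(data.frame(pdb_id = character(), resolution = numeric(),
                      method = character()))
  if (is.character(metadata) && length(metadata) == 1L)
    metadata <- utils::read.table(metadata, header = TRUE, sep = "\t",
                                  stringsAsFactors = FALSE)
  stopifnot(all(c("pdb_id", "resolution", "method") %in% names(metadata)))
  metadata
}

.memberLabel <- function(structure, chain, model)
  paste(structure@pdbId, model, chain, sep = "|")

# parse every member structure once; cache by (path, model)
.parseMembers <- function(scope) {
  key <- paste(scope@members$path, scope@members$model)
  structures <- list()
  for (k in unique(key)) {
    i <- match(k, key)
    structures[[k]] <- parseStructure(scope@members$path[i],
                                      scope@members$model[i])
  }
  structures[key]
}

#' Apply resolution and method filters to a scope
#'
#' Removes members whose resolution exceeds the ceiling (the threshold is
#' inclusive: a member \emph{at} the ceiling is kept) or whose
#' experimental method is not in the allowed set. When a resolution
#' ceiling is set, members with unknown resolution are dropped with
#' reason \code{"resolution unknown"}; without a ceiling they are kept.
#' Sidecar metadata overrides file headers.
#'
#' @param scope a [ScopeDefinition-class].
#' @param structures optional pre-parsed [StructureModel-class] list
#'   aligned with the members (parsed on demand otherwise).
#' @return list with \code{scope} (filtered) and \code{dropped}
#'   (data.frame \code{member}, \code{reason}).
#' @export
filterMembers <- function(scope, structures = NULL) {
  stopifnot(is(scope, "ScopeDefinition"))
  if (is.null(structures)) structures <- .parseMembers(scope)
  m <- scope@members
  keep <- rep(TRUE, nrow(m))
  drops <- data.frame(member = character(), reason = character())
  for (i in seq_len(nrow(m))) {
    st <- structures[[i]]
    res <- st@resolution; meth <- st@method
    side <- scope@metadata[match(st@pdbId, scope@metadata$pdb_id), ]
    if (nrow(side) == 1L && !is.na(side$pdb_id)) {
      if (!is.na(side$resolution)) res <- side$resolution
      if (!is.na(side$method)) meth <- side$method
    }
    label <- .memberLabel(st, m$chain[i], m$model[i])
    reason <- NULL
    if (!is.na(scope@resolutionMax)) {
      if (is.na(res)) reason <- "resolution unknown"
      else if (res > scope@resolutionMax)
        reason <- sprintf("resolution %.2f A exceeds ceiling %.2f A",
                          res, scope@resolutionMax)
    }
    if (is.null(reason) && length(scope@methodsAllowed)) {
      if (is.na(meth)) reason <- "experimental method unknown"
      else if (!toupper(meth) %in% toupper(scope@methodsAllowed))
        reason <- paste0("method '", meth, "' not in the allowed set")
    }
    if (!is.null(reason)) {
      keep[i] <- FALSE
      drops <- rbind(drops, data.frame(member = label, reason = reason))
    }
  }
  scope@members <- m[keep, , drop = FALSE]
  rownames(scope@members) <- NULL
  list(scope = scope, dropped = drops,
       structures = structures[keep])
}

#' Retrieve all instances corresponding to a query selection
#'
#' The central retrieval step: for every scope member the query
#' nucleotides are mapped to the member chain -- by pairwise global
#' alignment of the two observed sequences in \code{chain_set} mode, or
#' through shared alignment columns in \code{stockholm} mode -- and a
#' member yields an instance only if \emph{all} query positions map to
#' observed nucleotides with defined frames. Incomplete members are
#' dropped and logged with the first failing position; the discrepancy
#' metric is only defined between complete, equal-length instances.
#' Resolution/method filters run before any alignment work.
#'
#' @param querySelection ordered character vector of formatted unit IDs
#'   (see [parseUnitId()]); must all resolve in one chain of one scope
#'   member (the query member).
#' @param scope a [ScopeDefinition-class]; the query chain must be a
#'   member.
#' @return a [CorrespondenceSet-class].
#' @export
buildCorrespondence <- function(querySelection, scope) {
  stopifnot(is.character(querySelection), length(querySelection) >= 1L,
            is(scope, "ScopeDefinition"))
  validObject(scope)
  if (length(querySelection) > 30L)
    warning("query has ", length(querySelection), " nucleotides; the ",
            "discrepancy metric is intended for motifs up to around 30 nt")
  q1 <- parseUnitId(querySelection[1L])

  structures <- .parseMembers(scope)
  flt <- filterMembers(scope, structures)
  scope <- flt$scope; structures <- flt$structures
  dropped <- flt$dropped

  m <- scope@members
  qi <- which(vapply(seq_len(nrow(m)), function(i)
    structures[[i]]@pdbId == q1@pdbId && m$chain[i] == q1@chain &&
      m$model[i] == q1@model, logical(1)))
  if (!length(qi))
    stop("the query chain ", q1@pdbId, "|", q1@model, "|", q1@chain,
         " is not a member of the scope (after filtering)")
  qi <- qi[1L]
  qChain <- structures[[qi]]@chains[[m$chain[qi]]]
  if (is.null(qChain)) stop("query chain has no nucleotides")
  qIdx <- match(querySelection, qChain@unitIds)
  if (anyNA(qIdx))
    stop("query selection does not resolve: ",
         querySelection[which(is.na(qIdx))[1L]])
  query <- extractInstance(structures[[qi]], querySelection)

  colMaps <- NULL
  if (scope@mode == "stockholm") {
    chains <- lapply(seq_len(nrow(m)), function(i) {
      ch <- structures[[i]]@chains[[m$chain[i]]]
      if (is.null(ch))
        stop("member ", .memberLabel(structures[[i]], m$chain[i],
                                     m$model[i]),
             " has no nucleotides in chain ", m$chain[i])
      ch
    })
    names(chains) <- m$row
    colMaps <- ingestStockholm(scope@stockholm, m, chains)
    qMap <- colMaps[[m$row[qi]]]
    if (qMap$status != "ok")
      stop("the query row failed sequence validation: ", qMap$reason)
    queryCols <- match(qIdx, qMap$columns)
    if (anyNA(queryCols))
      stop("query position ", querySelection[which(is.na(queryCols))[1L]],
           " has no alignment column")
  }

  instances <- list()
  logRows <- list()
  for (i in seq_len(nrow(m))) {
    st <- structures[[i]]
    label <- .memberLabel(st, m$chain[i], m$model[i])
    ch <- st@chains[[m$chain[i]]]
    if (is.null(ch)) {
      dropped <- rbind(dropped, data.frame(
        member = label, reason = "no nucleotides in the named chain"))
      next
    }
    if (scope@mode == "chain_set") {
      pairs <- alignNearIdentical(qChain@sequence, ch@sequence)
      tgt <- pairs$b[match(qIdx, pairs$a)]
      status <- ifelse(is.na(tgt), "gap_in_target", "mapped")
    } else {
      cm <- colMaps[[m$row[i]]]
      if (cm$status != "ok") {
        dropped <- rbind(dropped,
                         data.frame(member = label, reason = cm$reason))
        next
      }
      tgt <- cm$columns[queryCols]
      status <- ifelse(!cm$hasResidue[queryCols], "gap_in_target",
                       ifelse(is.na(tgt), "unresolved_in_target",
                              "mapped"))
    }
    logRows[[label]] <- data.frame(
      member = label, queryUnit = querySelection,
      targetUnit = ifelse(is.na(tgt), NA_character_, ch@unitIds[tgt]),
      status = status, stringsAsFactors = FALSE)
    if (any(status != "mapped")) {
      bad <- which(status != "mapped")[1L]
      dropped <- rbind(dropped, data.frame(
        member = label,
        reason = paste0("query position ", querySelection[bad], " is ",
                        gsub("_", " ", status[bad]))))
      next
    }
    inst <- extractInstance(st, ch@unitIds[tgt])
    # disambiguate identical ids arising from copied files
    id <- inst@instanceId
    k <- 1L
    while (id %in% names(instances)) {
      k <- k + 1L
      id <- paste0(inst@instanceId, "#", k)
    }
    inst@instanceId <- id
    instances[[id]] <- inst
  }
  if (!length(instances))
    stop("no scope member yields a complete instance; drop log:\n",
         paste(sprintf("  %s: %s", dropped$member, dropped$reason),
               collapse = "\n"))
  mappingLog <- do.call(rbind, c(logRows, list(make.row.names = FALSE)))
  queryId <- names(instances)[vapply(instances, function(x)
    identical(x@unitIds, query@unitIds) && x@source == query@source,
    logical(1))][1L]
  new("CorrespondenceSet", query = instances[[queryId]],
      instances = instances, mappingLog = mappingLog, dropped = dropped)
}
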