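#' Accessors
#'
#' Small accessor generics so downstream code never reaches into slots.
#'
#' @param x an object of the relevant class.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("instanceIds", function(x) standardGeneric("instanceIds"))

#' @rdname accessors
#' @export
setGeneric("discrepancyValues",
           function(x) standardGeneric("discrepancyValues"))

#' @rdname accessors
#' @export
setGeneric("seriationOrder", function(x) standardGeneric("seriationOrder"))

#' @rdname accessors
#' @export
setGeneric("motifInstances", function(x) standardGeneric("motifInstances"))

#' @rdname accessors
#' @export
setGeneric("droppedMembers", function(x) standardGeneric("droppedMembers"))

#' @rdname accessors
#' @export
setGeneric("baseCenters", function(x) standardGeneric("baseCenters"))

#' @rdname accessors
#' @export
setGeneric("baseRotations", function(x) standardGeneric("baseRotations"))

#' @rdname accessors
#' @export
setMethod("instanceIds", "DiscrepancyMatrix", function(x) x@instanceIds)

#' @rdname accessors
#' @export
setMethod("instanceIds", "CorrespondenceSet",
          function(x) names(x@instances))

#' @rdname accessors
#' @export
setMethod("discrepancyValues", "DiscrepancyMatrix", function(x) x@values)

#' @rdname accessors
#' @export
setMethod("seriationOrder", "SeriationResult", function(x) x@order)

#' @rdname accessors
#' @export
setMethod("motifInstances", "CorrespondenceSet", function(x) x@instances)

#' @rdname accessors
#' @export
setMethod("droppedMembers", "CorrespondenceSet", function(x) x@dropped)

#' @rdname accessors
#' @export
setMethod("baseCenters", "MotifInstance", function(x) x@centers)

#' @rdname accessors
#' @export
setMethod("baseRotations", "MotifInstance", function(x) x@rotations)

#' @rdname accessors
#' @export
setMethod("baseCenters", "ChainRecord", function(x) x@centers)

#' @rdname accessors
#' @export
setMethod("baseRotations", "ChainRecord", function(x) x@rotations)

#' Number of nucleotides in a motif instance
#' @param x a [MotifInstance] or [ChainRecord].
#' @export
setMethod("length", "MotifInstance", function(x) length(x@unitIds))

#' @rdname length-MotifInstance-method
#' @export
setMethod("length", "ChainRecord", function(x) length(x@unitIds))

setMethod("show", "UnitId", function(object) {
  cat("UnitId:", formatUnitId(object), "\n")
})

setMethod("show", "ChainRecord", function(object) {
  cat(sprintf("ChainRecord %s|%d|%s: %d nt", object@pdbId, object@model,
              object@chain, length(object@unitIds)))
  if (!is.na(object@resolution))
    cat(sprintf(", %.2f A", object@resolution))
  cat("\n  ", object@sequence, "\n", sep = "")
})

setMethod("show", "StructureModel", function(object) {
  cat(sprintf("StructureModel %s (model %d): %d RNA chain(s), %d atoms\n",
              object@pdbId, object@model, length(object@chains),
              nrow(object@atomInventory)))
})

setMethod("show", "MotifInstance", function(object) {
  cat(sprintf("MotifInstance %s: %d nt [%s]\n", object@instanceId,
              length(object@unitIds),
              paste0(object@baseLetters, object@numbers, collapse = " ")))
})

setMethod("show", "CorrespondenceSet", function(object) {
  cat(sprintf(
    "CorrespondenceSet: %d nt query %s, %d instance(s), %d dropped\n",
    length(object@query@unitIds), object@query@instanceId,
    length(object@instances), nrow(object@dropped)))
})

setMethod("show", "DiscrepancyMatrix", function(object) {
  v <- object@values[upper.tri(object@values)]
  cat(sprintf("DiscrepancyMatrix: %d instances, %d nt each\n",
              length(object@instanceIds), object@nNt))
  if (length(v))
    cat(sprintf("  off-diagonal range [%.4f, %.4f]\n", min(v), max(v)))
})

setMethod("show", "SeriationResult", function(object) {
  cat(sprintf("SeriationResult (%s): path cost %.4f\n", object@methodTag,
              object@pathCost))
})
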