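#' @import methods
NULL

#' Nucleotide address (unit ID)
#'
#' A globally unique address for one nucleotide in one 3D structure, in the
#' pipe-delimited convention used throughout the RNA structure ecosystem:
#' \code{pdb|model|chain|component|number[|atom|alt|insertion|symmetry]}.
#' The atom and symmetry fields are accepted on parsing but play no role in
#' motif-level work.
#'
#' @slot pdbId 4-character structure identifier.
#' @slot model positive integer model number.
#' @slot chain author chain identifier (non-empty string).
#' @slot component residue name (A/C/G/U or a modified-residue code).
#' @slot number author residue number (integer).
#' @slot insertion one-character insertion code, or \code{NA}.
#' @slot alternate one-character altloc code, or \code{NA}.
#'
#' @seealso [parseUnitId()], [formatUnitId()]
#' @export
setClass("UnitId",
  representation(
    pdbId = "character", model = "integer", chain = "character",
    component = "character", number = "integer",
    insertion = "character", alternate = "character"
  ),
  prototype(insertion = NA_character_, alternate = NA_character_)
)

setValidity("UnitId", function(object) {
  msg <- character()
  if (length(object@model) != 1L || is.na(object@model) || object@model < 1L)
    msg <- c(msg, "model must be a positive integer")
  if (length(object@chain) != 1L || is.na(object@chain) || !nzchar(object@chain))
    msg <- c(msg, "chain must be non-empty")
  if (length(object@component) != 1L || is.na(object@component) ||
      !nzchar(object@component))
    msg <- c(msg, "component must be non-empty")
  if (length(object@number) != 1L || is.na(object@number))
    msg <- c(msg, "number must be an integer")
  if (length(msg)) msg else TRUE
})

#' One RNA chain of a parsed structure
#'
#' Holds the observed nucleotides of a chain in author-numbering order
#' (insertion codes respected), with one base reference frame per
#' nucleotide: the base center (mean of the base ring heavy atoms, in
#' Angstrom) and a proper orthonormal 3x3 orientation matrix obtained by
#' fitting the embedded standard planar base geometry onto the observed
#' ring atoms.
#'
#' @slot pdbId,model,chain identity of the chain.
#' @slot sequence character string over A/C/G/U/N in observed-residue
#'   order, after modified-residue mapping.
#' @slot unitIds formatted unit-ID string per nucleotide.
#' @slot numbers integer author residue numbers.
#' @slot insertions insertion codes (\code{NA} when absent).
#' @slot baseLetters parent base letter per nucleotide.
#' @slot centers n x 3 matrix of base centers (Angstrom).
#' @slot rotations list of n proper orthonormal 3x3 matrices.
#' @slot atoms data.frame of the heavy atoms of each nucleotide
#'   (columns \code{nt}, \code{elety}, \code{x}, \code{y}, \code{z}).
#' @slot resolution reported resolution in Angstrom, or \code{NA}.
#' @slot method experimental method string, or \code{NA}.
#'
#' @export
setClass("ChainRecord",
  representation(
    pdbId = "character", model = "integer", chain = "character",
    sequence = "character", unitIds = "character",
    numbers = "integer", insertions = "character",
    baseLetters = "character",
    centers = "matrix", rotations = "list",
    atoms = "data.frame",
    resolution = "numeric", method = "character"
  )
)

setValidity("ChainRecord", function(object) {
  n <- length(object@unitIds)
  msg <- character()
  if (nchar(object@sequence) != n)
    msg <- c(msg, "sequence length must equal nucleotide count")
  if (nrow(object@centers) != n || length(object@rotations) != n ||
      length(object@numbers) != n || length(object@baseLetters) != n)
    msg <- c(msg, "per-nucleotide slots must have equal length")
  for (R in object@rotations) {
    if (max(abs(crossprod(R) - diag(3))) > 1e-8 || abs(det(R) - 1) > 1e-8) {
      msg <- c(msg, "all rotations must be proper orthonormal")
      break
    }
  }
  if (length(msg)) msg else TRUE
})

#' A parsed RNA-containing structure
#'
#' One model of one structure file: the RNA chains as [ChainRecord]
#' objects plus a full heavy-atom inventory of every chain and residue
#' type (protein, ligand, ion, ...) kept for neighbor-chain detection.
#'
#' @slot pdbId structure identifier (from the file's data block or header).
#' @slot model model number that was read.
#' @slot chains named list of [ChainRecord] (RNA chains only).
#' @slot atomInventory data.frame of all heavy atoms with columns
#'   \code{chain}, \code{resid}, \code{resno}, \code{insert}, \code{elety},
#'   \code{x}, \code{y}, \code{z}, \code{isNt}, \code{ntUnit}.
#' @slot entities named character vector mapping chain id to an entity
#'   description when the file provides one.
#' @slot resolution,method structure-level metadata (\code{NA} when absent).
#' @slot source path the structure was read from.
#'
#' @export
setClass("StructureModel",
  representation(
    pdbId = "character", model = "integer", chains = "list",
    atomInventory = "data.frame", entities = "character",
    resolution = "numeric", method = "character", source = "character"
  )
)

#' One motif instance
#'
#' An ordered list of nucleotides from one chain of one structure, each
#' carrying its base reference frame, plus structure metadata. Instances
#' retrieved for the same query all have the same length and position
#' order, which is what makes the geometric discrepancy well defined.
#'
#' @slot instanceId \code{pdb|model|chain} identity string.
#' @slot pdbId,model,chain provenance of the instance.
#' @slot unitIds formatted unit-ID per position, in query order.
#' @slot baseLetters parent base letter per position.
#' @slot numbers author residue number per position.
#' @slot centers n x 3 matrix of base centers.
#' @slot rotations list of n 3x3 base orientation matrices.
#' @slot atoms heavy atoms (\code{nt}, \code{elety}, \code{x}, \code{y},
#'   \code{z}); \code{nt} indexes positions.
#' @slot resolution,method structure metadata.
#' @slot source path of the structure file.
#'
#' @export
setClass("MotifInstance",
  representation(
    instanceId = "character", pdbId = "character", model = "integer",
    chain = "character", unitIds = "character", baseLetters = "character",
    numbers = "integer", centers = "matrix", rotations = "list",
    atoms = "data.frame", resolution = "numeric", method = "character",
    source = "character"
  )
)

setValidity("MotifInstance", function(object) {
  n <- length(object@unitIds)
  if (nrow(object@centers) != n || length(object@rotations) != n)
    return("centers and rotations must match the number of nucleotides")
  TRUE
})

#' Scope definition for a correspondence run
#'
#' The set of chains a query is mapped across: either a
#' \code{"chain_set"} of near-identical sequences that the package aligns
#' pairwise against the query (the within-organism case), or a
#' \code{"stockholm"} mode where a precomputed multiple sequence alignment
#' supplies the cross-species correspondences and its rows are mapped to
#' (file, chain, model) members.
#'
#' @slot mode \code{"chain_set"} or \code{"stockholm"}.
#' @slot members data.frame with columns \code{path}, \code{chain},
#'   \code{model} and, in stockholm mode, \code{row} (alignment row name).
#' @slot stockholm path of the Stockholm alignment (\code{NA} in
#'   chain_set mode).
#' @slot resolutionMax optional resolution ceiling in Angstrom
#'   (inclusive), \code{NA} for none.
#' @slot methodsAllowed optional character vector of allowed experimental
#'   methods; length zero means no restriction.
#' @slot metadata optional sidecar metadata data.frame with columns
#'   \code{pdb_id}, \code{resolution}, \code{method}; overrides file
#'   headers.
#'
#' @export
setClass("ScopeDefinition",
  representation(
    mode = "character", members = "data.frame", stockholm = "character",
    resolutionMax = "numeric", methodsAllowed = "character",
    metadata = "data.frame"
  ),
  prototype(
    stockholm = NA_character_, resolutionMax = NA_real_,
    methodsAllowed = character(),
    metadata = data.frame(
      pdb_id = character(), resolution = numeric(), method = character()
    )
  )
)

setValidity("ScopeDefinition", function(object) {
  msg <- character()
  if (!object@mode %in% c("chain_set", "stockholm"))
    msg <- c(msg, "mode must be 'chain_set' or 'stockholm'")
  if (nrow(object@members) < 1L)
    msg <- c(msg, "scope must have at least one member")
  key <- paste(object@members$path, object@members$chain,
               object@members$model)
  if (anyDuplicated(key))
    msg <- c(msg, "duplicate (path, chain, model) members are not allowed")
  if (object@mode == "stockholm" &&
      (is.null(object@members$row) || is.na(object@stockholm)))
    msg <- c(msg, "stockholm mode needs a 'row' column and an alignment path")
  if (length(msg)) msg else TRUE
})

#' Query instance plus all corresponding instances across the scope
#'
#' @slot query the query [MotifInstance].
#' @slot instances named list of retained [MotifInstance] objects (the
#'   query among them: self-correspondence is the identity).
#' @slot mappingLog data.frame with one row per (member, query position):
#'   \code{member}, \code{queryUnit}, \code{targetUnit}, \code{status}
#'   (\code{mapped}, \code{gap_in_target} or \code{unresolved_in_target}).
#' @slot dropped data.frame (\code{member}, \code{reason}) of scope
#'   members that yielded no complete instance.
#'
#' @export
setClass("CorrespondenceSet",
  representation(
    query = "MotifInstance", instances = "list",
    mappingLog = "data.frame", dropped = "data.frame"
  )
)

setValidity("CorrespondenceSet", function(object) {
  n <- length(object@query@unitIds)
  for (inst in object@instances)
    if (length(inst@unitIds) != n)
      return("every retained instance must have the query's length")
  if (!object@query@instanceId %in% names(object@instances))
    return("the query itself must appear among the instances")
  TRUE
})

#' All-against-all geometric discrepancy matrix
#'
#' @slot instanceIds ordered instance identifiers.
#' @slot values symmetric non-negative matrix of pairwise discrepancies
#'   (Angstrom-equivalent units), zero diagonal.
#' @slot nNt nucleotides per instance.
#'
#' @export
setClass("DiscrepancyMatrix",
  representation(instanceIds = "character", values = "matrix",
                 nNt = "integer")
)

setValidity("DiscrepancyMatrix", function(object) {
  v <- object@values
  msg <- character()
  if (nrow(v) != length(object@instanceIds) || ncol(v) != nrow(v))
    msg <- c(msg, "values must be square and match instanceIds")
  else {
    if (any(!is.finite(v)) || any(v < 0))
      msg <- c(msg, "all entries must be finite and non-negative")
    if (max(abs(v - t(v))) > 1e-12)
      msg <- c(msg, "matrix must be symmetric")
    if (any(diag(v) != 0))
      msg <- c(msg, "diagonal must be zero")
  }
  if (length(msg)) msg else TRUE
})

#' Seriation (heatmap ordering) result
#'
#' @slot order permutation of instance indices placing similar instances
#'   next to each other.
#' @slot pathCost sum of adjacent-pair discrepancies under the order.
#' @slot methodTag which ordering algorithm produced it.
#'
#' @export
setClass("SeriationResult",
  representation(order = "integer", pathCost = "numeric",
                 methodTag = "character")
)

setValidity("SeriationResult", function(object) {
  if (!identical(sort(object@order), seq_along(object@order)))
    return("order must be a permutation of 1..n")
  TRUE
})
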