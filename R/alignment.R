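#' Global alignment of two near-identical RNA sequences
#'
#' Needleman-Wunsch global alignment (end gaps penalized) via
#' \pkg{Biostrings}, with the scoring scheme used for within-organism
#' chain sets: match +2, mismatch -1, and affine gaps where a gap run of
#' length L costs \code{gapOpen + L * gapExtend} (defaults -5 and -1).
#' \code{N} scores 0 against anything. Chains of the same molecule from
#' the same organism are nearly identical, so a simple pairwise global
#' alignment is all the correspondence step needs.
#'
#' @param seqA,seqB character strings over A/C/G/U/N, length >= 1.
#' @param match,mismatch,gapOpen,gapExtend scoring parameters.
#' @return data.frame with columns \code{a}, \code{b}: 1-based index
#'   pairs of aligned (non-gap) positions, and attribute \code{score}.
#' @export
alignNearIdentical <- function(seqA, seqB, match = 2, mismatch = -1,
                               gapOpen = -5, gapExtend = -1) {
  stopifnot(is.character(seqA), is.character(seqB))
  if (!nzchar(seqA) || !nzchar(seqB)) stop("cannot align an empty sequence")
  alpha <- c("A", "C", "G", "U", "N")
  bad <- setdiff(strsplit(paste0(seqA, seqB), "")[[1L]], alpha)
  if (length(bad))
    stop("sequences must be over A/C/G/U/N; found '", bad[1L], "'")
  sub <- matrix(mismatch, 5L, 5L, dimnames = list(alpha, alpha))
  diag(sub) <- match
  sub["N", ] <- 0; sub[, "N"] <- 0
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::RNAString(seqA), Biostrings::RNAString(seqB),
    substitutionMatrix = sub, gapOpening = -gapOpen,
    gapExtension = -gapExtend, type = "global")
  ga <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1L]]
  gb <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1L]]
  ia <- cumsum(ga != "-"); ib <- cumsum(gb != "-")
  keep <- ga != "-" & gb != "-"
  out <- data.frame(a = ia[keep], b = ib[keep])
  attr(out, "score") <- Biostrings::score(pa)
  out
}

#' Map Stockholm alignment columns to chain residues
#'
#' Reads a Stockholm multiple sequence alignment (Rfam/Infernal dialect:
#' \code{.} and \code{-} are gaps, lowercase letters are insert states
#' that still consume a residue) and, for each mapped member, returns the
#' map from alignment column to that chain's observed residue. The
#' alignment is consumed, never computed: cross-species correspondences
#' come from a covariance-model alignment produced elsewhere.
#'
#' A member's row must spell the member chain's observed sequence, up to
#' modified-residue mapping, case, and residues present in the row but
#' unresolved in the coordinates (those columns map to \code{NA} with
#' status \code{"unresolved"}). Any true sequence mismatch, or a chain
#' residue absent from the row, drops the member with a
#' sequence-mismatch reason.
#'
#' @param path Stockholm file.
#' @param rowMap data.frame with columns \code{row}, \code{path},
#'   \code{chain}, \code{model} naming the member behind each alignment
#'   row.
#' @param chains named list of [ChainRecord-class], one per rowMap entry,
#'   keyed by row name.
#' @return named list per member: either list(\code{columns} = integer
#'   vector over alignment columns with the chain nucleotide index or NA,
#'   \code{status} = "ok") or list(\code{status} = "dropped",
#'   \code{reason}).
#' @export
ingestStockholm <- function(path, rowMap, chains) {
  rows <- .readStockholm(path)
  missing <- setdiff(rowMap$row, names(rows))
  if (length(missing))
    stop("alignment row '", missing[1L], "' named in the row map is ",
         "missing from ", path)
  out <- list()
  for (k in seq_len(nrow(rowMap))) {
    rn <- rowMap$row[k]
    aln <- strsplit(rows[[rn]], "")[[1L]]
    isRes <- grepl("[A-Za-z]", aln)
    rowSeq <- toupper(aln[isRes])
    rowSeq[rowSeq == "T"] <- "U"
    chain <- chains[[rn]]
    res <- .matchRowToChain(rowSeq, chain@baseLetters)
    if (is.null(res)) {
      out[[rn]] <- list(status = "dropped", reason = paste0(
        "sequence mismatch between alignment row '", rn,
        "' and chain ", chain@chain, " of ", chain@pdbId))
      next
    }
    columns <- rep(NA_integer_, length(aln))
    columns[which(isRes)] <- res   # chain index or NA (unresolved)
    out[[rn]] <- list(status = "ok", columns = columns,
                      hasResidue = isRes)
  }
  out
}

# align the row's residue sequence to the chain's observed letters:
# every chain residue must match a row residue identically (the chain
# may lack residues that the row has -- unresolved in the coordinates);
# returns per-row-residue chain index (NA = unresolved) or NULL on a
# genuine mismatch
.matchRowToChain <- function(rowSeq, chainLetters) {
  if (!length(chainLetters)) return(NULL)
  pairs <- alignNearIdentical(paste(rowSeq, collapse = ""),
                              paste(chainLetters, collapse = ""))
  if (nrow(pairs) < length(chainLetters)) return(NULL)
  if (any(rowSeq[pairs$a] != chainLetters[pairs$b] &
            rowSeq[pairs$a] != "N" & chainLetters[pairs$b] != "N"))
    return(NULL)
  res <- rep(NA_integer_, length(rowSeq))
  res[pairs$a] <- pairs$b
  res
}

# Stockholm reading is delegated to Biostrings, which normalizes the
# Rfam/Infernal dialect for us ('.' and '-' to '-', lowercase insert
# states to uppercase); both residue-consumption semantics survive that
# normalization, which is all the column mapping needs.
.readStockholm <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !grepl("^# STOCKHOLM", lines[1L]))
    stop(path, " is not a Stockholm file (missing '# STOCKHOLM' header)")
  msa <- tryCatch(
    Biostrings::readRNAMultipleAlignment(path, format = "stockholm"),
    error = function(e)
      stop("cannot parse ", path, " as Stockholm: ",
           conditionMessage(e)))
  rows <- as.list(as.character(msa))
  if (!length(rows)) stop("Stockholm file ", path, " has no sequences")
  rows
}
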