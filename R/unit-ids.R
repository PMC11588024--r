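#' Parse a pipe-delimited unit ID
#'
#' Unit IDs address one nucleotide in one structure:
#' \code{pdb|model|chain|component|number[|atom|alt|insertion|symmetry]}.
#' Five fields are mandatory; the four optional trailing fields may be
#' empty. The atom and symmetry fields are accepted but ignored for
#' motif-level work, which operates on whole nucleotides.
#'
#' @param text a single unit-ID string, e.g. \code{"5J7L|1|AA|A|1492"}.
#' @return a [UnitId-class] object.
#' @examples
#' parseUnitId("5J7L|1|AA|A|1492")
#' @seealso [formatUnitId()]
#' @export
parseUnitId <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  fields <- strsplit(text, "|", fixed = TRUE)[[1L]]
  # a trailing empty field is dropped by strsplit; restore it
  if (grepl("\\|$", text)) fields <- c(fields, "")
  if (length(fields) < 5L || length(fields) > 9L)
    stop("unit ID must have 5-9 pipe-separated fields, got ",
         length(fields), " in '", text, "'")
  asInt <- function(x, what, pos) {
    if (!grepl("^-?[0-9]+$", x))
      stop("unit ID field ", pos, " (", what, ") must be an integer, got '",
           x, "' in '", text, "'")
    as.integer(x)
  }
  opt <- function(i) {
    if (length(fields) >= i && nzchar(fields[i])) fields[i] else NA_character_
  }
  new("UnitId",
      pdbId = fields[1L],
      model = asInt(fields[2L], "model", 2L),
      chain = fields[3L],
      component = fields[4L],
      number = asInt(fields[5L], "number", 5L),
      alternate = opt(7L),
      insertion = opt(8L))
}

#' Format a unit ID back to its string form
#'
#' Produces the shortest string that round-trips through [parseUnitId()]:
#' optional fields are emitted only up to the last one present.
#'
#' @param u a [UnitId-class] object.
#' @return a single string.
#' @export
formatUnitId <- function(u) {
  stopifnot(is(u, "UnitId"))
  fields <- c(u@pdbId, u@model, u@chain, u@component, u@number)
  opt <- c("", if (is.na(u@alternate)) "" else u@alternate,
           if (is.na(u@insertion)) "" else u@insertion)
  last <- max(c(0L, which(nzchar(opt))))
  paste(c(fields, opt[seq_len(last)]), collapse = "|")
}

#' Expand a range selection against a chain
#'
#' Selections are comma-separated items, each a single author number
#' \code{"N"} or an inclusive range \code{"N:M"} (N <= M). Every number in
#' a range must be observed in the chain; a number with no observed
#' nucleotide is an error, never a silent skip. Listed order is preserved
#' and duplicate positions are rejected. Numbers carrying insertion codes
#' expand to all observed insertions at that number, in insertion order.
#'
#' Selections longer than 30 nucleotides run, with a warning: the
#' discrepancy metric is designed for motifs up to around 30 nucleotides,
#' beyond which whole-domain motions dominate the comparison.
#'
#' @param text selection string, e.g. \code{"1405:1409,1491:1496"}.
#' @param chain a [ChainRecord-class].
#' @return ordered character vector of formatted unit IDs.
#' @export
parseRangeSelection <- function(text, chain) {
  stopifnot(is.character(text), length(text) == 1L, is(chain, "ChainRecord"))
  items <- trimws(strsplit(text, ",", fixed = TRUE)[[1L]])
  items <- items[nzchar(items)]
  if (!length(items)) stop("empty selection")
  picked <- integer()
  for (item in items) {
    if (grepl("^-?[0-9]+$", item)) {
      lo <- hi <- as.integer(item)
    } else if (grepl("^-?[0-9]+:-?[0-9]+$", item)) {
      ends <- as.integer(strsplit(item, ":", fixed = TRUE)[[1L]])
      lo <- ends[1L]; hi <- ends[2L]
      if (lo > hi)
        stop("malformed range '", item, "': start exceeds end")
    } else {
      stop("malformed selection item '", item, "'")
    }
    for (num in lo:hi) {
      idx <- which(chain@numbers == num)
      if (!length(idx))
        stop("selection cannot be resolved: no observed nucleotide ",
             "numbered ", num, " in chain ", chain@chain)
      idx <- idx[order(chain@insertions[idx], na.last = FALSE)]
      picked <- c(picked, idx)
    }
  }
  if (anyDuplicated(picked))
    stop("selection lists position ",
         chain@numbers[picked[duplicated(picked)][1L]], " more than once")
  if (length(picked) > 30L)
    warning("selection has ", length(picked),
            " nucleotides; the discrepancy metric is intended for motifs ",
            "up to around 30 nt")
  chain@unitIds[picked]
}
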