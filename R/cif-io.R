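# Minimal name-aware mmCIF reader/writer.
#
# The reader maps loop columns by tag name rather than position, which is
# what the format requires; it covers the subset of mmCIF this package
# consumes: the atom_site loop, entry/exptl/refine/em metadata and entity
# descriptions. Values '.' and '?' become NA per CIF convention.

.cifTokens <- function(line) {
  out <- character()
  i <- 1L; n <- nchar(line)
  while (i <= n) {
    ch <- substr(line, i, i)
    if (ch %in% c(" ", "\t")) { i <- i + 1L; next }
    if (ch == "#") break
    if (ch %in% c("'", "\"")) {
      j <- i + 1L
      while (j <= n && !(substr(line, j, j) == ch &&
                         (j == n || substr(line, j + 1L, j + 1L) %in%
                            c(" ", "\t")))) j <- j + 1L
      if (j > n) stop("unterminated quoted string in: ", line)
      out <- c(out, substr(line, i + 1L, j - 1L))
      i <- j + 1L
    } else {
      j <- i
      while (j <= n && !substr(line, j, j) %in% c(" ", "\t")) j <- j + 1L
      out <- c(out, substr(line, i, j - 1L))
      i <- j
    }
  }
  out
}

# returns list(blockName, items = named list of scalars,
#              loops = named-by-category list of data.frames)
.readCif <- function(path) {
  lines <- readLines(path, warn = FALSE)
  blockName <- NA_character_
  items <- list(); loops <- list()
  i <- 1L; n <- length(lines)
  nextTokenLine <- function(i) {
    while (i <= n && (!nzchar(trimws(lines[i])) ||
                      startsWith(trimws(lines[i]), "#"))) i <- i + 1L
    i
  }
  while ({i <- nextTokenLine(i); i <= n}) {
    line <- trimws(lines[i])
    if (startsWith(line, "data_")) {
      blockName <- sub("^data_", "", line); i <- i + 1L
    } else if (line == "loop_") {
      i <- i + 1L
      tags <- character()
      while ({i <- nextTokenLine(i); i <= n} &&
             startsWith(trimws(lines[i]), "_")) {
        tags <- c(tags, .cifTokens(trimws(lines[i]))[1L]); i <- i + 1L
      }
      if (!length(tags)) stop("mmCIF parse error at line ", i,
                              ": loop_ with no tags")
      vals <- character()
      while ({i <- nextTokenLine(i); i <= n}) {
        l <- trimws(lines[i])
        if (startsWith(l, "_") || startsWith(l, "loop_") ||
            startsWith(l, "data_")) break
        if (startsWith(l, ";")) stop("mmCIF parse error at line ", i,
                                     ": multi-line values in loops are not supported")
        vals <- c(vals, .cifTokens(l)); i <- i + 1L
      }
      if (length(vals) %% length(tags) != 0L)
        stop("mmCIF parse error: loop over ", tags[1L], " has ",
             length(vals), " values for ", length(tags), " columns")
      m <- matrix(vals, ncol = length(tags), byrow = TRUE)
      df <- as.data.frame(m, stringsAsFactors = FALSE)
      names(df) <- sub("^_[^.]+\\.", "", tags)
      df[df == "." | df == "?"] <- NA
      cat_ <- sub("^_([^.]+)\\..*$", "\\1", tags[1L])
      loops[[cat_]] <- df
    } else if (startsWith(line, "_")) {
      toks <- .cifTokens(line)
      if (length(toks) == 1L) {  # value on next line (possibly ;-block)
        i <- i + 1L
        if (i <= n && startsWith(lines[i], ";")) {
          val <- sub("^;", "", lines[i]); i <- i + 1L
          while (i <= n && !startsWith(lines[i], ";")) {
            val <- paste(val, lines[i]); i <- i + 1L
          }
          i <- i + 1L
          toks <- c(toks, trimws(val))
        } else {
          toks <- c(toks, .cifTokens(trimws(lines[i]))[1L]); i <- i + 1L
        }
      } else i <- i + 1L
      v <- toks[2L]
      items[[toks[1L]]] <- if (!is.na(v) && v %in% c(".", "?"))
        NA_character_ else v
    } else {
      stop("mmCIF parse error at line ", i, ": unexpected token '",
           substr(line, 1L, 30L), "'")
    }
  }
  list(blockName = blockName, items = items, loops = loops)
}

.cifQuote <- function(x) {
  ifelse(is.na(x), ".",
         ifelse(grepl("[ '\"]", x) | !nzchar(x), paste0("'", x, "'"), x))
}

# atoms: data.frame with model, chain, entity, resid, resno, insert,
# elety, elesy, alt, occ, x, y, z
.writeCifAtomSite <- function(con, atoms) {
  writeLines(c(
    "loop_",
    paste0("_atom_site.", c(
      "group_PDB", "id", "type_symbol", "label_atom_id", "label_alt_id",
      "label_comp_id", "label_asym_id", "label_entity_id", "label_seq_id",
      "pdbx_PDB_ins_code", "Cartn_x", "Cartn_y", "Cartn_z", "occupancy",
      "B_iso_or_equiv", "auth_seq_id", "auth_comp_id", "auth_asym_id",
      "pdbx_PDB_model_num"))), con)
  rows <- sprintf(
    "ATOM %d %s %s %s %s %s %s %d %s %.3f %.3f %.3f %.2f 0.00 %d %s %s %d",
    seq_len(nrow(atoms)), .cifQuote(atoms$elesy), .cifQuote(atoms$elety),
    ifelse(is.na(atoms$alt), ".", atoms$alt), .cifQuote(atoms$resid),
    .cifQuote(atoms$chain), atoms$entity, atoms$resno,
    ifelse(is.na(atoms$insert), "?", atoms$insert),
    atoms$x, atoms$y, atoms$z,
    if (is.null(atoms$occ)) rep(1, nrow(atoms)) else atoms$occ,
    atoms$resno, .cifQuote(atoms$resid), .cifQuote(atoms$chain),
    atoms$model)
  writeLines(rows, con)
}

# writes a minimal-but-valid mmCIF: entry id, experimental method,
# resolution, entity descriptions and the atom_site loop
.writeCif <- function(path, pdbId, atoms, entities = NULL,
                      method = "X-RAY DIFFRACTION", resolution = NA) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(paste0("data_", pdbId),
               paste("_entry.id", pdbId),
               paste("_exptl.method", .cifQuote(method))), con)
  if (!is.na(resolution))
    writeLines(sprintf("_refine.ls_d_res_high %.2f", resolution), con)
  if (!is.null(entities) && length(entities)) {
    writeLines(c("loop_", "_entity.id", "_entity.pdbx_description"), con)
    writeLines(paste(seq_along(entities), .cifQuote(unname(entities))), con)
  }
  .writeCifAtomSite(con, atoms)
  writeLines("#", con)
  invisible(path)
}
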