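#' Superpose instances onto a reference
#'
#' Rigidly moves each selected instance onto the reference instance
#' using the least-squares fit over base centers (the same fit that
#' underlies the discrepancy metric), so displayed differences are the
#' internal conformational ones the metric measures. Base frames are
#' rotated along with the coordinates. Optional neighborhood atoms
#' supplied per instance are carried through the same motion.
#'
#' @param instances named list of [MotifInstance-class] (uniform length).
#' @param reference instance id to superpose onto (default: first).
#' @param selection character vector of instance ids to include
#'   (default: all); must contain the reference.
#' @param neighborhoods optional named list (by instance id) of atom
#'   data.frames (\code{chain}, \code{resid}, \code{resno}, \code{elety},
#'   \code{x}, \code{y}, \code{z}) transformed by the same motion.
#' @return named list with, per selected id: \code{instance} (moved) and
#'   \code{neighborhood} (moved atoms or NULL).
#' @export
superposeInstances <- function(instances, reference = names(instances)[1L],
                               selection = names(instances),
                               neighborhoods = NULL) {
  stopifnot(length(instances) >= 1L, !is.null(names(instances)))
  if (!reference %in% selection)
    stop("reference '", reference, "' is not in the selection")
  if (!all(selection %in% names(instances)))
    stop("selection names instances that are not present: ",
         paste(setdiff(selection, names(instances)), collapse = ", "))
  ref <- instances[[reference]]
  out <- list()
  for (id in selection) {
    inst <- instances[[id]]
    fit <- kabschSuperpose(ref@centers, inst@centers)
    inst@centers <- applyRigidMotion(inst@centers, fit$rotation,
                                     fit$translation)
    inst@rotations <- lapply(inst@rotations,
                             function(R) fit$rotation %*% R)
    xyz <- applyRigidMotion(as.matrix(inst@atoms[c("x", "y", "z")]),
                            fit$rotation, fit$translation)
    inst@atoms[c("x", "y", "z")] <- xyz
    nb <- NULL
    if (!is.null(neighborhoods[[id]]) && nrow(neighborhoods[[id]])) {
      nb <- neighborhoods[[id]]
      nb[c("x", "y", "z")] <- applyRigidMotion(
        as.matrix(nb[c("x", "y", "z")]), fit$rotation, fit$translation)
    }
    out[[id]] <- list(instance = inst, neighborhood = nb)
  }
  out
}

#' Write superposed instances as a multi-model mmCIF
#'
#' One model per instance (viewers superpose models natively), original
#' chain ids, residue names and author numbers preserved, and a comment
#' header mapping model numbers to instance ids.
#'
#' @param superposed result of [superposeInstances()].
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeSuperposition <- function(superposed, path) {
  rows <- list()
  for (k in seq_along(superposed)) {
    inst <- superposed[[k]]$instance
    comp <- vapply(inst@unitIds, function(u) parseUnitId(u)@component,
                   character(1))
    a <- inst@atoms
    rows[[length(rows) + 1L]] <- data.frame(
      model = k, chain = inst@chain, entity = 1L,
      resid = comp[a$nt], resno = inst@numbers[a$nt],
      insert = NA_character_, elety = a$elety,
      elesy = substr(a$elety, 1L, 1L), alt = NA_character_, occ = 1,
      x = a$x, y = a$y, z = a$z, stringsAsFactors = FALSE)
    nb <- superposed[[k]]$neighborhood
    if (!is.null(nb))
      rows[[length(rows) + 1L]] <- data.frame(
        model = k, chain = nb$chain, entity = 2L, resid = nb$resid,
        resno = nb$resno, insert = NA_character_, elety = nb$elety,
        elesy = substr(nb$elety, 1L, 1L), alt = NA_character_, occ = 1,
        x = nb$x, y = nb$y, z = nb$z, stringsAsFactors = FALSE)
  }
  atoms <- do.call(rbind, rows)
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("data_superposition", con)
  writeLines(sprintf("# model %d = instance %s", seq_along(superposed),
                     names(superposed)), con)
  .writeCifAtomSite(con, atoms)
  writeLines("#", con)
  invisible(path)
}

#' Build the instance table
#'
#' One row per retained instance in seriation order: instance id,
#' resolution, method, the nucleotide letters+numbers at each query
#' position, the annotated interactions and the neighboring chains.
#' Summary counts (retained/dropped) ride along as attributes and are
#' written as comment headers by [writeInstanceTable()].
#'
#' @param cs a [CorrespondenceSet-class].
#' @param annotations named list (by instance id) of
#'   [annotateInteractions()] results.
#' @param neighbors named list (by instance id) of
#'   [detectNeighborChains()] results.
#' @param order integer permutation from [seriate()] (default identity).
#' @return data.frame, one row per instance.
#' @export
buildInstanceTable <- function(cs, annotations = NULL, neighbors = NULL,
                               order = seq_along(cs@instances)) {
  stopifnot(is(cs, "CorrespondenceSet"))
  ids <- names(cs@instances)[order]
  rows <- lapply(ids, function(id) {
    inst <- cs@instances[[id]]
    ann <- annotations[[id]]
    annStr <- if (is.null(ann) || !nrow(ann)) "" else
      paste(sprintf("%s-%s:%s", ann$label1, ann$label2, ann$kind),
            collapse = ";")
    nb <- neighbors[[id]]
    nbStr <- if (is.null(nb) || !nrow(nb)) "" else
      paste(nb$identity, collapse = ";")
    data.frame(
      instance = id, resolution = inst@resolution, method = inst@method,
      nucleotides = paste0(inst@baseLetters, inst@numbers,
                           collapse = ","),
      interactions = annStr, neighborChains = nbStr,
      stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  attr(tab, "query") <- cs@query@instanceId
  attr(tab, "nRetained") <- length(cs@instances)
  attr(tab, "nDropped") <- nrow(cs@dropped)
  tab
}

#' Write the instance table as TSV with a summary header
#'
#' @param tab result of [buildInstanceTable()].
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeInstanceTable <- function(tab, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(
    sprintf("# query: %s", attr(tab, "query")),
    sprintf("# instances retained: %d", attr(tab, "nRetained")),
    sprintf("# members dropped: %d", attr(tab, "nDropped"))), con)
  utils::write.table(format(tab, digits = 6), con, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export the ordered discrepancy matrix
#'
#' Writes the seriation-ordered matrix as CSV (instance ids as header
#' row and column) and the full matrix as JSON (ids plus row-major
#' values), and optionally renders a heatmap raster with a perceptually
#' monotone grayscale where darker means more similar, so clusters of
#' similar instances appear as dark diagonal blocks. The CSV/JSON are
#' the contract and are byte-identical across runs on identical input;
#' a failure to render the image only warns.
#'
#' @param dm a [DiscrepancyMatrix-class].
#' @param order integer index vector from [seriate()]; may be a subset
#'   when a reporting cutoff trims the display.
#' @param csvPath,jsonPath,pngPath output files; \code{pngPath = NULL}
#'   skips the image.
#' @param jsonOrder order used for the JSON export (defaults to
#'   \code{order}); a reporting cutoff trims the CSV/image but the JSON
#'   keeps every computed instance.
#' @return invisibly, the reordered matrix.
#' @export
exportHeatmap <- function(dm, order, csvPath, jsonPath, pngPath = NULL,
                          jsonOrder = order) {
  stopifnot(is(dm, "DiscrepancyMatrix"))
  v <- dm@values[order, order, drop = FALSE]
  ids <- dm@instanceIds[order]
  dimnames(v) <- list(ids, ids)
  con <- file(csvPath, open = "wt")
  writeLines(paste(c("instance", ids), collapse = ","), con)
  for (i in seq_len(nrow(v)))
    writeLines(paste(c(ids[i], sprintf("%.6f", v[i, ])), collapse = ","),
               con)
  close(con)
  vj <- dm@values[jsonOrder, jsonOrder, drop = FALSE]
  jsonlite::write_json(
    list(instance_ids = dm@instanceIds[jsonOrder],
         n_nt = dm@nNt,
         values = as.vector(t(vj))),
    jsonPath, auto_unbox = TRUE, digits = NA)
  if (!is.null(pngPath)) {
    ok <- tryCatch({
      grDevices::png(pngPath, width = 800, height = 800)
      on.exit(grDevices::dev.off(), add = TRUE)
      n <- nrow(v)
      graphics::par(mar = c(6, 6, 2, 1))
      # darker = more similar: map low discrepancy to black
      graphics::image(seq_len(n), seq_len(n), t(v[rev(seq_len(n)), ]),
                      col = grDevices::gray(seq(0, 1, length.out = 256)),
                      axes = FALSE, xlab = "", ylab = "",
                      main = "geometric discrepancy")
      graphics::axis(1, at = seq_len(n), labels = ids, las = 2,
                     cex.axis = 0.7)
      graphics::axis(2, at = seq_len(n), labels = rev(ids), las = 2,
                     cex.axis = 0.7)
      TRUE
    }, error = function(e) {
      warning("heatmap image could not be rendered: ",
              conditionMessage(e), call. = FALSE)
      FALSE
    })
  }
  invisible(v)
}
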