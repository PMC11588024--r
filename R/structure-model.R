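#' Parse an RNA-containing structure file
#'
#' Reads one model of an mmCIF (preferred) or legacy PDB file and builds
#' a [StructureModel-class]: one [ChainRecord-class] per chain containing
#' at least one standard or modified ribonucleotide, plus a full
#' heavy-atom inventory of every chain (protein, ligands, ions included)
#' kept for neighbor-chain detection. Nucleotides are ordered by author
#' numbering with insertion codes; modified residues are mapped to their
#' parent letter ([parentBaseLetter()]); hydrogens are discarded; when a
#' residue has alternate conformers the highest-occupancy altloc wins,
#' ties broken by altloc letter ascending. A nucleotide with fewer than 3
#' base ring atoms has no defined frame: it is excluded from the chain's
#' nucleotides with a warning (its atoms stay in the inventory).
#'
#' Resolution is taken from refinement (\code{_refine.ls_d_res_high}) or
#' EM reconstruction metadata, the method from the experimental-method
#' record; both may be absent.
#'
#' @param path structure file; format chosen by extension (\code{.cif}
#'   vs anything else = PDB).
#' @param model model number to read (default 1).
#' @return a [StructureModel-class].
#' @export
parseStructure <- function(path, model = 1L) {
  if (!file.exists(path)) stop("no such file: ", path)
  model <- as.integer(model)
  raw <- if (grepl("\\.cif$", path, ignore.case = TRUE))
    .readStructureCif(path) else .readStructurePdb(path)
  av <- sort(unique(raw$atoms$model))
  if (!model %in% av)
    stop("model ", model, " not present in ", path,
         "; available models: ", paste(av, collapse = ", "))
  atoms <- raw$atoms[raw$atoms$model == model, , drop = FALSE]
  atoms <- .dropHydrogens(atoms)
  atoms <- .resolveAltlocs(atoms)

  # classify residues and build the inventory
  atoms$resKey <- paste(atoms$chain, atoms$resno,
                        ifelse(is.na(atoms$insert), "", atoms$insert),
                        atoms$resid, sep = "\r")
  resTab <- atoms[!duplicated(atoms$resKey),
                  c("resKey", "chain", "resid", "resno", "insert")]
  resTab$parent <- parentBaseLetter(resTab$resid)

  chains <- list()
  inv <- atoms[c("chain", "resid", "resno", "insert", "elety",
                 "x", "y", "z")]
  inv$isNt <- FALSE
  inv$ntUnit <- NA_character_

  for (ch in unique(resTab$chain)) {
    rt <- resTab[resTab$chain == ch & !is.na(resTab$parent), , drop = FALSE]
    if (!nrow(rt)) next
    ord <- order(rt$resno, ifelse(is.na(rt$insert), "", rt$insert))
    rt <- rt[ord, , drop = FALSE]
    keep <- logical(nrow(rt))
    frames <- vector("list", nrow(rt))
    for (k in seq_len(nrow(rt))) {
      rat <- atoms[atoms$resKey == rt$resKey[k], , drop = FALSE]
      fr <- tryCatch(
        computeBaseFrame(rat[c("elety", "x", "y", "z")], rt$parent[k]),
        error = function(e) e)
      if (inherits(fr, "error")) {
        warning("dropping nucleotide ", rt$resid[k], rt$resno[k],
                " of chain ", ch, " in ", basename(path), ": ",
                conditionMessage(fr), call. = FALSE)
      } else {
        keep[k] <- TRUE
        frames[[k]] <- fr
      }
    }
    rt <- rt[keep, , drop = FALSE]
    frames <- frames[keep]
    if (!nrow(rt)) next
    uids <- vapply(seq_len(nrow(rt)), function(k) {
      formatUnitId(new("UnitId", pdbId = raw$pdbId, model = model,
                       chain = ch, component = rt$resid[k],
                       number = rt$resno[k], insertion = rt$insert[k]))
    }, character(1))
    ntAtoms <- do.call(rbind, lapply(seq_len(nrow(rt)), function(k) {
      rat <- atoms[atoms$resKey == rt$resKey[k], , drop = FALSE]
      data.frame(nt = k, elety = rat$elety, x = rat$x, y = rat$y,
                 z = rat$z)
    }))
    inv$isNt[atoms$resKey %in% rt$resKey] <- TRUE
    inv$ntUnit[atoms$resKey %in% rt$resKey] <-
      uids[match(atoms$resKey[atoms$resKey %in% rt$resKey], rt$resKey)]
    chains[[ch]] <- new("ChainRecord",
      pdbId = raw$pdbId, model = model, chain = ch,
      sequence = paste(rt$parent, collapse = ""),
      unitIds = uids, numbers = rt$resno, insertions = rt$insert,
      baseLetters = rt$parent,
      centers = do.call(rbind, lapply(frames, `[[`, "center")),
      rotations = lapply(frames, `[[`, "rotation"),
      atoms = ntAtoms,
      resolution = raw$resolution, method = raw$method)
  }
  new("StructureModel", pdbId = raw$pdbId, model = model,
      chains = chains, atomInventory = inv, entities = raw$entities,
      resolution = raw$resolution, method = raw$method, source = path)
}

.dropHydrogens <- function(atoms) {
  isH <- !is.na(atoms$elesy) & atoms$elesy %in% c("H", "D") |
    (is.na(atoms$elesy) & grepl("^[0-9]*H", atoms$elety))
  atoms[!isH, , drop = FALSE]
}

# highest-occupancy conformer wins; ties by altloc letter ascending
.resolveAltlocs <- function(atoms) {
  if (all(is.na(atoms$alt))) return(atoms)
  key <- paste(atoms$chain, atoms$resno,
               ifelse(is.na(atoms$insert), "", atoms$insert), atoms$elety,
               sep = "\r")
  ord <- order(key, -atoms$occ, ifelse(is.na(atoms$alt), "", atoms$alt))
  atoms <- atoms[ord, , drop = FALSE]
  atoms[!duplicated(key[ord]), , drop = FALSE]
}

.readStructureCif <- function(path) {
  cif <- tryCatch(.readCif(path), error = function(e)
    stop("cannot read ", path, " as mmCIF: ", conditionMessage(e)))
  as_ <- cif$loops[["atom_site"]]
  if (is.null(as_)) stop("no atom_site loop in ", path)
  col <- function(primary, fallback = NULL, default = NA_character_) {
    if (!is.null(as_[[primary]])) return(as_[[primary]])
    if (!is.null(fallback) && !is.null(as_[[fallback]]))
      return(as_[[fallback]])
    rep(default, nrow(as_))
  }
  atoms <- data.frame(
    model = as.integer(col("pdbx_PDB_model_num", default = "1")),
    chain = col("auth_asym_id", "label_asym_id"),
    entity = col("label_entity_id"),
    resid = col("auth_comp_id", "label_comp_id"),
    resno = as.integer(col("auth_seq_id", "label_seq_id")),
    insert = col("pdbx_PDB_ins_code"),
    elety = col("label_atom_id", "auth_atom_id"),
    elesy = col("type_symbol"),
    alt = col("label_alt_id"),
    occ = suppressWarnings(as.numeric(col("occupancy", default = "1"))),
    x = as.numeric(col("Cartn_x")), y = as.numeric(col("Cartn_y")),
    z = as.numeric(col("Cartn_z")),
    stringsAsFactors = FALSE)
  if (anyNA(atoms$x) || anyNA(atoms$resno) || anyNA(atoms$elety))
    stop("mmCIF atom_site loop in ", path,
         " is missing coordinates, residue numbers or atom names")
  atoms$occ[is.na(atoms$occ)] <- 1

  it <- cif$items
  pdbId <- it[["_entry.id"]]
  if (is.null(pdbId) || is.na(pdbId)) pdbId <- cif$blockName
  res <- NA_real_
  for (tag in c("_refine.ls_d_res_high", "_em_3d_reconstruction.resolution"))
    if (!is.null(it[[tag]]) && !is.na(it[[tag]])) {
      res <- suppressWarnings(as.numeric(it[[tag]])); break
    }
  method <- NA_character_
  if (!is.null(it[["_exptl.method"]])) method <- it[["_exptl.method"]]
  if (is.na(method) && !is.null(cif$loops[["exptl"]]) &&
      !is.null(cif$loops[["exptl"]]$method))
    method <- cif$loops[["exptl"]]$method[1L]

  entities <- character()
  ent <- cif$loops[["entity"]]
  if (!is.null(ent) && !is.null(ent$pdbx_description)) {
    entities <- stats::setNames(ent$pdbx_description, ent$id)
  } else if (!is.null(it[["_entity.id"]])) {
    entities <- stats::setNames(it[["_entity.pdbx_description"]],
                                it[["_entity.id"]])
  }
  # remap entity id -> chain for neighbor naming
  entByChain <- character()
  if (length(entities)) {
    m <- unique(atoms[c("chain", "entity")])
    m <- m[!is.na(m$entity) & m$entity %in% names(entities), , drop = FALSE]
    entByChain <- stats::setNames(unname(entities[m$entity]), m$chain)
  }
  list(pdbId = pdbId, atoms = atoms, resolution = res, method = method,
       entities = entByChain)
}

.readStructurePdb <- function(path) {
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE,
                                     verbose = FALSE)),
    error = function(e)
      stop("cannot read ", path, " as PDB: ", conditionMessage(e)))
  nModels <- if (is.matrix(pdb$xyz)) nrow(pdb$xyz) else 1L
  a <- pdb$atom
  perModel <- lapply(seq_len(nModels), function(m) {
    xyz <- if (is.matrix(pdb$xyz)) pdb$xyz[m, ] else as.vector(pdb$xyz)
    xyz <- matrix(xyz, ncol = 3L, byrow = TRUE)
    data.frame(
      model = m, chain = a$chain, entity = NA_character_,
      resid = a$resid, resno = as.integer(a$resno), insert = a$insert,
      elety = a$elety, elesy = a$elesy, alt = a$alt,
      occ = ifelse(is.na(a$o), 1, a$o),
      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
      stringsAsFactors = FALSE)
  })
  atoms <- do.call(rbind, perModel)
  lines <- readLines(path, warn = FALSE)
  res <- NA_real_
  rl <- grep("^REMARK   2 RESOLUTION", lines, value = TRUE)
  if (length(rl)) {
    m <- regmatches(rl[1], regexpr("[0-9]+\\.[0-9]+", rl[1]))
    if (length(m)) res <- as.numeric(m)
  }
  method <- NA_character_
  el <- grep("^EXPDTA", lines, value = TRUE)
  if (length(el)) method <- trimws(sub("^EXPDTA", "", el[1]))
  hl <- grep("^HEADER", lines, value = TRUE)
  pdbId <- if (length(hl) && nchar(hl[1]) >= 66)
    trimws(substr(hl[1], 63, 66)) else
      toupper(sub("\\.[^.]*$", "", basename(path)))
  if (!nzchar(pdbId))
    pdbId <- toupper(sub("\\.[^.]*$", "", basename(path)))
  list(pdbId = pdbId, atoms = atoms, resolution = res, method = method,
       entities = character())
}

#' Extract a motif instance from a parsed structure
#'
#' Builds a [MotifInstance-class] from an ordered set of unit IDs that
#' must all resolve to nucleotides (with defined frames) of one chain of
#' the structure.
#'
#' @param structure a [StructureModel-class].
#' @param unitIds ordered character vector of formatted unit IDs.
#' @return a [MotifInstance-class].
#' @export
extractInstance <- function(structure, unitIds) {
  stopifnot(is(structure, "StructureModel"), length(unitIds) >= 1L)
  chains <- vapply(unitIds, function(u) parseUnitId(u)@chain, character(1))
  if (length(unique(chains)) != 1L)
    stop("all unit IDs of an instance must come from one chain")
  ch <- structure@chains[[chains[1L]]]
  if (is.null(ch))
    stop("chain ", chains[1L], " has no nucleotides in ", structure@pdbId)
  idx <- match(unitIds, ch@unitIds)
  if (anyNA(idx))
    stop("unit ID ", unitIds[which(is.na(idx))[1L]],
         " does not resolve to a nucleotide with a defined frame")
  atoms <- ch@atoms[ch@atoms$nt %in% idx, , drop = FALSE]
  atoms$nt <- match(atoms$nt, idx)
  atoms <- atoms[order(atoms$nt), , drop = FALSE]
  rownames(atoms) <- NULL
  new("MotifInstance",
      instanceId = paste(ch@pdbId, ch@model, ch@chain, sep = "|"),
      pdbId = ch@pdbId, model = ch@model, chain = ch@chain,
      unitIds = unname(ch@unitIds[idx]),
      baseLetters = ch@baseLetters[idx], numbers = ch@numbers[idx],
      centers = ch@centers[idx, , drop = FALSE],
      rotations = ch@rotations[idx], atoms = atoms,
      resolution = ch@resolution, method = ch@method,
      source = structure@source)
}
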