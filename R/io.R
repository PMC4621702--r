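# Manifest and structure input. One manifest row = one ligand-bound protein
# chain. PDB files are expected pre-superposed onto a template chain with
# consistent residue numbering; no alignment is performed here.

.WATER_RESIDUES <- c("HOH", "WAT", "DOD")

#' Parse a per-target CSV manifest
#'
#' The manifest has one header row and one row per ligand-bound protein
#' chain. Required columns: `pdb_path` and `smiles`. Recognised optional
#' columns: `compound_id`, `model_id`, `chain`, `lig_resno`; all other
#' columns are carried through untouched in the `extra` columns. A missing
#' `model_id` defaults to `<row index>_<PDB file stem>`.
#'
#' @param path path to the CSV manifest (UTF-8, header row).
#' @param checkSmiles validate that every SMILES parses (default `TRUE`).
#' @return A data.frame with columns `pdb_path`, `smiles`, `compound_id`,
#'   `model_id`, `chain`, `lig_resno` plus any passthrough columns, row
#'   order preserved.
#' @export
parseInputCsv <- function(path, checkSmiles = TRUE) {
  if (!file.exists(path))
    stop("I/O error: manifest not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", check.names = FALSE)
  for (col in c("pdb_path", "smiles"))
    if (!col %in% names(df))
      stop("configuration error: manifest is missing required column '",
           col, "'")
  if (nrow(df) == 0L) {
    for (col in c("compound_id", "model_id", "chain", "lig_resno"))
      if (!col %in% names(df)) df[[col]] <- character(0)
    return(df)
  }
  if (any(!nzchar(df$pdb_path)))
    stop("configuration error: empty pdb_path in row(s) ",
         paste(which(!nzchar(df$pdb_path)), collapse = ", "))
  stems <- sub("\\.[^.]*$", "", basename(df$pdb_path))
  if (!"model_id" %in% names(df)) df$model_id <- NA_character_
  blank <- is.na(df$model_id) | !nzchar(df$model_id)
  df$model_id[blank] <- paste0(which(blank), "_", stems[blank])
  if (!"compound_id" %in% names(df)) df$compound_id <- NA_character_
  if (!"chain" %in% names(df)) df$chain <- NA_character_
  if (!"lig_resno" %in% names(df)) df$lig_resno <- NA_character_
  if (anyDuplicated(df$model_id))
    stop("configuration error: duplicated model_id: ",
         paste(unique(df$model_id[duplicated(df$model_id)]), collapse = ", "))
  if (checkSmiles) {
    for (r in seq_len(nrow(df))) {
      ok <- tryCatch({molFromSmiles(df$smiles[r]); TRUE},
                     error = function(e) FALSE)
      if (!ok)
        stop("SMILES parse error in manifest row ", r, ": '",
             df$smiles[r], "'")
    }
  }
  df
}

#' Resolve alternate locations by occupancy
#'
#' For each (chain, residue, atom name) group with several altloc records,
#' keeps the highest-occupancy record; ties are broken by the
#' lexicographically smallest altloc character. Records without altlocs pass
#' through unchanged.
#'
#' @param atoms a bio3d-style atom data.frame (columns `chain`, `resno`,
#'   `insert`, `resid`, `elety`, `alt`, `o`).
#' @return The filtered atom data.frame, original order preserved.
#' @export
selectAltloc <- function(atoms) {
  if (nrow(atoms) == 0L) return(atoms)
  alt <- atoms$alt
  alt[is.na(alt)] <- ""
  occ <- atoms$o
  occ[is.na(occ)] <- 1
  key <- paste(atoms$chain, atoms$resno,
               ifelse(is.na(atoms$insert), "", atoms$insert),
               atoms$resid, atoms$elety, sep = "|")
  keep <- rep(TRUE, nrow(atoms))
  for (g in split(seq_len(nrow(atoms)), key)) {
    if (length(g) > 1L) {
      best <- g[order(-occ[g], alt[g])][1L]
      keep[setdiff(g, best)] <- FALSE
    }
  }
  atoms[keep, , drop = FALSE]
}

#' Transfer template chemistry onto crystallographic ligand atoms
#'
#' Infers connectivity of the crystallographic heavy atoms from interatomic
#' distances (covalent radii + 0.45 Angstrom tolerance), matches that graph
#' to the template molecular graph by element-coloured graph isomorphism,
#' and returns a [LigandPose-class] whose atoms carry the template bond
#' orders, charges and aromaticity while preserving the crystallographic
#' coordinates bit-exactly.
#'
#' @param ligandAtoms data.frame of heavy atoms: `name`, `element`, `x`,
#'   `y`, `z`.
#' @param smiles template SMILES with assigned tautomer/charge state.
#' @param modelId,compoundId identifiers stored on the pose.
#' @return A [LigandPose-class] with atoms in template atom order.
#' @export
assignBondOrders <- function(ligandAtoms, smiles, modelId = "model",
                             compoundId = NA_character_) {
  mol <- molFromSmiles(smiles, name = modelId)
  te <- sort(mol$atoms$element)
  ce <- sort(ligandAtoms$element)
  if (length(te) != length(ce) || !all(te == ce))
    stop("composition error: ligand atoms {",
         paste(ce, collapse = ","), "} do not match template {",
         paste(te, collapse = ","), "} for model ", modelId)
  coords <- as.matrix(ligandAtoms[, c("x", "y", "z")])
  cb <- .inferBonds(coords, ligandAtoms$element)
  n <- nrow(mol$atoms)
  gT <- igraph::make_graph(edges = rbind(mol$bonds$i, mol$bonds$j), n = n,
                           directed = FALSE)
  gC <- igraph::make_graph(edges = rbind(cb$i, cb$j), n = n,
                           directed = FALSE)
  elems <- sort(unique(c(mol$atoms$element, ligandAtoms$element)))
  colT <- match(mol$atoms$element, elems)
  colC <- match(ligandAtoms$element, elems)
  maps <- igraph::subgraph_isomorphisms(
    pattern = gT, target = gC, method = "vf2",
    vertex.color1 = colT, vertex.color2 = colC)
  if (length(maps) == 0L)
    stop("matching error: no isomorphism between the distance-inferred ",
         "ligand connectivity and the template graph for model ", modelId)
  map <- as.integer(maps[[1L]])       # template atom k -> crystal atom map[k]
  atoms <- data.frame(
    name = ligandAtoms$name[map],
    element = ligandAtoms$element[map],
    x = ligandAtoms$x[map], y = ligandAtoms$y[map], z = ligandAtoms$z[map],
    stringsAsFactors = FALSE
  )
  methods::new("LigandPose",
               atoms = atoms, mol = mol, smiles = mol$canonical,
               centroid = colMeans(as.matrix(atoms[, c("x", "y", "z")])),
               modelId = as.character(modelId),
               compoundId = as.character(compoundId))
}

#' Load one manifest record into a StructureModel
#'
#' Parses the PDB file, resolves altlocs by occupancy, drops hydrogens and
#' deuteriums, partitions records into protein residues, waters (residue
#' names HOH/WAT/DOD; oxygen positions only) and hetero groups, identifies
#' the ligand as the hetero group whose heavy-atom element multiset matches
#' the template SMILES, and assigns template bond orders onto it.
#'
#' @param record one manifest row (list or single-row data.frame with
#'   `pdb_path`, `smiles`, `model_id`, and optionally `chain`,
#'   `compound_id`, `lig_resno`).
#' @param baseDir directory that relative `pdb_path`s are resolved against.
#' @return A [StructureModel-class].
#' @export
loadStructure <- function(record, baseDir = ".") {
  record <- as.list(record)
  path <- record$pdb_path
  if (!file.exists(path)) path <- file.path(baseDir, record$pdb_path)
  if (!file.exists(path))
    stop("I/O error: PDB file not found: ", record$pdb_path)
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  at <- at[!(at$elesy %in% c("H", "D")), , drop = FALSE]
  at <- selectAltloc(at)

  mol <- molFromSmiles(record$smiles, name = record$model_id)
  tmplElems <- sort(mol$atoms$element)

  isWater <- at$resid %in% .WATER_RESIDUES
  isHet <- at$type == "HETATM" & !isWater

  chain <- record$chain
  if (is.null(chain) || is.na(chain) || !nzchar(chain)) {
    # first chain containing a hetero group matching the SMILES composition
    chain <- NA_character_
    for (ch in unique(at$chain)) {
      hg <- at[isHet & at$chain %in% ch, , drop = FALSE]
      for (grp in split(seq_len(nrow(hg)),
                        paste(hg$resid, hg$resno, sep = "|"))) {
        if (identical(sort(hg$elesy[grp]), tmplElems)) { chain <- ch; break }
      }
      if (!is.na(chain)) break
    }
    if (is.na(chain))
      stop("structure error: no chain of ", basename(path),
           " contains a hetero group matching the ligand SMILES")
  } else if (!chain %in% at$chain) {
    stop("structure error: chain '", chain, "' absent from ", basename(path))
  }

  inChain <- at$chain %in% chain

  # protein residues of the chain
  prot <- at[at$type == "ATOM" & inChain, , drop = FALSE]
  residues <- list()
  if (nrow(prot)) {
    ins <- ifelse(is.na(prot$insert), "", prot$insert)
    rkey <- paste(prot$chain, prot$resno, ins, prot$resid, sep = "|")
    for (g in split(seq_len(nrow(prot)), factor(rkey, levels = unique(rkey)))) {
      r1 <- prot[g[1L], ]
      residues[[rkey[g[1L]]]] <- list(
        identity = c(chain = r1$chain, resno = as.character(r1$resno),
                     insert = ifelse(is.na(r1$insert), "", r1$insert),
                     resname = r1$resid),
        atomNames = prot$elety[g],
        coords = as.matrix(prot[g, c("x", "y", "z")])
      )
    }
  }

  # waters of the chain (all waters when none carry the chain id)
  wat <- at[isWater & inChain, , drop = FALSE]
  if (nrow(wat) == 0L && any(isWater) && !any(at$chain[isWater] %in% chain))
    wat <- at[isWater, , drop = FALSE]
  wat <- wat[wat$elesy == "O", , drop = FALSE]
  watM <- unname(as.matrix(wat[, c("x", "y", "z")]))
  if (nrow(watM) == 0L) watM <- matrix(numeric(0), 0L, 3L)

  # candidate hetero groups in the chain
  hg <- at[isHet & inChain, , drop = FALSE]
  if (nrow(hg) == 0L)
    stop("ligand-matching error: no hetero group in chain ", chain,
         " of ", basename(path))
  gkey <- paste(hg$resid, hg$resno, sep = "|")
  groups <- split(seq_len(nrow(hg)), gkey)
  matches <- names(groups)[vapply(groups, function(g)
    identical(sort(hg$elesy[g]), tmplElems), logical(1))]
  if (length(matches) == 0L)
    stop("ligand-matching error: no hetero group in chain ", chain,
         " matches the SMILES composition; candidates: ",
         paste(unique(gkey), collapse = ", "))
  if (length(matches) > 1L) {
    lr <- record$lig_resno
    if (!is.null(lr) && !is.na(lr) && nzchar(lr)) {
      matches <- matches[sub(".*\\|", "", matches) == as.character(lr)]
      if (length(matches) != 1L)
        stop("ligand-matching error: lig_resno '", lr,
             "' does not single out a ligand copy in ", basename(path))
    } else {
      stop("ligand-matching error: ", length(matches), " copies of the ",
           "ligand in chain ", chain, " of ", basename(path),
           "; disambiguate with a lig_resno column")
    }
  }
  g <- groups[[matches]]
  ligandAtoms <- data.frame(
    name = hg$elety[g], element = hg$elesy[g],
    x = hg$x[g], y = hg$y[g], z = hg$z[g], stringsAsFactors = FALSE)
  pose <- assignBondOrders(ligandAtoms, record$smiles,
                           modelId = record$model_id,
                           compoundId = if (is.null(record$compound_id))
                             NA_character_ else record$compound_id)
  methods::new("StructureModel", modelId = as.character(record$model_id),
               chainId = as.character(chain), residues = residues,
               waters = watM, ligand = pose)
}

#' Read a full ensemble from a manifest
#'
#' Loads every manifest row with [loadStructure()]. With
#' `skipFailures = TRUE` (the pipeline default) a row that fails to load is
#' skipped with a warning rather than aborting the whole ensemble.
#'
#' @param manifestPath path to the CSV manifest.
#' @param skipFailures skip unreadable rows with a warning.
#' @return A [StructureEnsemble-class].
#' @export
readEnsemble <- function(manifestPath, skipFailures = FALSE) {
  records <- parseInputCsv(manifestPath)
  baseDir <- dirname(manifestPath)
  models <- list()
  for (r in seq_len(nrow(records))) {
    m <- tryCatch(loadStructure(records[r, , drop = FALSE], baseDir = baseDir),
                  error = function(e) e)
    if (inherits(m, "error")) {
      if (!skipFailures) stop(m)
      warning("skipping manifest row ", r, " (",
              records$model_id[r], "): ", conditionMessage(m))
    } else {
      models[[length(models) + 1L]] <- m
    }
  }
  if (nrow(records) > 0L && length(models) == 0L)
    stop("structure error: no model of the manifest could be loaded")
  methods::new("StructureEnsemble", models = models, records = records,
               manifestPath = as.character(manifestPath))
}

#' Write a StructureModel back to a PDB file
#'
#' Writes protein residues as ATOM records and waters plus the ligand as
#' HETATM records, preserving coordinates to the PDB precision of three
#' decimals. Used for round-trip validation and debug dumps.
#'
#' @param model a [StructureModel-class].
#' @param file output path.
#' @param ligResid residue name given to the ligand hetero group.
#' @return `file`, invisibly.
#' @export
writeModelPdb <- function(model, file, ligResid = "LIG") {
  xyz <- c(); type <- c(); resno <- c(); resid <- c(); elety <- c()
  chain <- c(); elesy <- c(); insert <- c()
  for (res in model@residues) {
    k <- nrow(res$coords)
    xyz <- c(xyz, as.vector(t(res$coords)))
    type <- c(type, rep("ATOM", k))
    resno <- c(resno, rep(as.integer(res$identity[["resno"]]), k))
    resid <- c(resid, rep(res$identity[["resname"]], k))
    insert <- c(insert, rep(res$identity[["insert"]], k))
    elety <- c(elety, res$atomNames)
    chain <- c(chain, rep(res$identity[["chain"]], k))
    elesy <- c(elesy, substr(res$atomNames, 1L, 1L))
  }
  nw <- nrow(model@waters)
  if (nw) {
    xyz <- c(xyz, as.vector(t(model@waters)))
    type <- c(type, rep("HETATM", nw))
    base <- max(c(0L, resno)) + 100L
    resno <- c(resno, base + seq_len(nw))
    resid <- c(resid, rep("HOH", nw))
    insert <- c(insert, rep("", nw))
    elety <- c(elety, rep("O", nw))
    chain <- c(chain, rep(model@chainId, nw))
    elesy <- c(elesy, rep("O", nw))
  }
  lig <- model@ligand@atoms
  nl <- nrow(lig)
  xyz <- c(xyz, as.vector(t(as.matrix(lig[, c("x", "y", "z")]))))
  type <- c(type, rep("HETATM", nl))
  resno <- c(resno, rep(max(c(0L, resno)) + 1L, nl))
  resid <- c(resid, rep(ligResid, nl))
  insert <- c(insert, rep("", nl))
  elety <- c(elety, lig$name)
  chain <- c(chain, rep(model@chainId, nl))
  elesy <- c(elesy, lig$element)
  ins <- insert
  ins[!nzchar(ins)] <- ""
  bio3d::write.pdb(file = file, xyz = xyz, type = type, resno = resno,
                   resid = resid, eleno = seq_along(type), elety = elety,
                   chain = chain, insert = ins, o = rep(1, length(type)),
                   b = rep(0, length(type)), elesy = elesy)
  invisible(file)
}
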