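# Seeded synthetic-ensemble generator. Produces a manifest, pre-aligned PDB
# files and a machine-readable planted truth, so every pipeline stage can be
# validated without external data. The protein scaffold is geometric, not
# biological: a rigid helix plus hand-placed pocket residues; all downstream
# analyses are purely geometric so format validity and spatial structure are
# what matters.

.withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Gaussian jitter truncated (by resampling) at a norm of 2 sigma. The
# truncation radius r makes planted sites separable by construction under
# the sequential spawn rule for every seed: any two jittered points of one
# site are at most 2r apart (< lambda), and a point can never come within
# lambda of another site's members when site separations exceed
# lambda + 2r. With sigma = 0.3 and lambda = 1.5 both margins hold.
.truncJitter <- function(n, sigma) {
  if (sigma <= 0 || n == 0L) return(matrix(0, n, 3))
  m <- matrix(stats::rnorm(3L * n, sd = sigma), n, 3L)
  r <- sqrt(rowSums(m^2))
  while (any(r > 2 * sigma)) {
    bad <- r > 2 * sigma
    m[bad, ] <- matrix(stats::rnorm(3L * sum(bad), sd = sigma), sum(bad), 3L)
    r <- sqrt(rowSums(m^2))
  }
  m
}

# idealised planar template coordinates for the demo chemotypes (benzene
# ring of radius 1.39 A in the xy plane, substituent on the +x atom); atom
# order matches the SMILES atom order of the template
.DEMO_TEMPLATES <- local({
  ring <- t(vapply(0:5, function(k) {
    a <- k * pi / 3
    c(1.39 * cos(a), 1.39 * sin(a), 0)
  }, numeric(3)))
  list(
    "Oc1ccccc1" = rbind(c(2.75, 0, 0), ring),       # O, then ring from C1
    "Clc1ccccc1" = rbind(c(3.13, 0, 0), ring)       # Cl, then ring from C1
  )
})

#' Idealised 3-D template coordinates for a SMILES
#'
#' Demo chemotypes use exact planar geometry; anything else is embedded with
#' Open Babel's deterministic 3-D builder.
#'
#' @param smiles template SMILES.
#' @return Numeric matrix (heavy atoms x 3) in template atom order.
#' @export
templateCoords <- function(smiles) {
  if (smiles %in% names(.DEMO_TEMPLATES)) return(.DEMO_TEMPLATES[[smiles]])
  sdf <- .obConvert("SMI", "SDF", paste(smiles, "t"),
                    data.frame(names = "gen3d", args = ""))
  lines <- strsplit(sdf, "\n", fixed = TRUE)[[1L]]
  nat <- as.integer(substr(lines[4L], 1L, 3L))
  atl <- lines[4L + seq_len(nat)]
  el <- trimws(substr(atl, 32L, 34L))
  xyz <- cbind(as.numeric(substr(atl, 1L, 10L)),
               as.numeric(substr(atl, 11L, 20L)),
               as.numeric(substr(atl, 21L, 30L)))
  xyz[!(el %in% c("H", "D")), , drop = FALSE]
}

#' Build an idealised LigandPose directly from a SMILES template
#'
#' Convenience constructor used in examples and tests: the pose carries the
#' template's own 3-D coordinates (optionally rigid-transformed).
#'
#' @param smiles template SMILES.
#' @param modelId model identifier for the pose.
#' @param rotZ rotation about the z axis, degrees.
#' @param shift translation 3-vector, Angstrom.
#' @return A [LigandPose-class].
#' @export
demoLigandPose <- function(smiles, modelId = "demo", rotZ = 0,
                           shift = c(0, 0, 0)) {
  mol <- molFromSmiles(smiles, name = modelId)
  xyz <- templateCoords(smiles)
  if (nrow(xyz) != nrow(mol$atoms))
    stop("internal error: template coordinate/atom count mismatch")
  th <- rotZ * pi / 180
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  xyz <- sweep(xyz %*% t(R), 2L, -shift)
  counts <- stats::ave(seq_len(nrow(xyz)), mol$atoms$element,
                       FUN = seq_along)
  atoms <- data.frame(
    name = paste0(mol$atoms$element, counts),
    element = mol$atoms$element,
    x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L], stringsAsFactors = FALSE)
  methods::new("LigandPose", atoms = atoms, mol = mol,
               smiles = mol$canonical, centroid = colMeans(xyz),
               modelId = modelId, compoundId = NA_character_)
}

# rigid scaffold shared by every model: an 8-residue helix away from the
# pocket, one rigid pocket residue, one distant rigid residue, and the
# bi-rotameric pocket residue whose side chain is supplied per state
.demoScaffold <- function() {
  helix <- list()
  for (t in 1:8) {
    a <- t * 100 * pi / 180
    ca <- c(-12 + 2.3 * cos(a), 2.3 * sin(a), 1.5 * t - 6)
    helix[[t]] <- list(
      identity = c(chain = "A", resno = as.character(9 + t), insert = "",
                   resname = "ALA"),
      atomNames = c("N", "CA", "C", "O", "CB"),
      coords = rbind(ca + c(-1.2, 0.3, -0.5), ca, ca + c(1.2, 0.4, 0.4),
                     ca + c(1.8, 1.4, 0.2), ca + c(-0.4, -1.4, 0.8)))
  }
  pocket <- list(
    list(identity = c(chain = "A", resno = "40", insert = "",
                      resname = "ASN"),
         atomNames = c("CA", "CB", "CG", "OD1"),
         coords = rbind(c(4.0, 3.5, 0), c(3.2, 2.6, 0.5),
                        c(2.8, 2.0, 1.2), c(3.3, 2.0, 2.2))),
    list(identity = c(chain = "A", resno = "80", insert = "",
                      resname = "SER"),
         atomNames = c("CA", "CB", "OG"),
         coords = rbind(c(0, -12, 0), c(0.8, -12.6, 0.6),
                        c(1.5, -13.4, 0)))
  )
  c(helix, pocket)
}

.demoRotamer <- function() {
  base <- rbind(c(0, 5.8, 0), c(0, 4.8, 0))          # CA, CB shared
  up <- rbind(c(0, 4.8, 2), c(0, 4.8, 4), c(0, 4.8, 6))
  list(identity = c(chain = "A", resno = "45", insert = "", resname = "TYR"),
       atomNames = c("CA", "CB", "CG", "CD1", "CE1"),
       confs = list(A = rbind(base, up),
                    B = rbind(base, up * rep(c(1, 1, -1), each = 3))))
}

#' The default demonstration ensemble specification
#'
#' Twenty models of a single binding site holding two ligand chemotypes
#' (phenol-like and chlorobenzene-like, ten models each). Five water sites
#' are planted: four ligand-proximal pocket sites at conservations 1.00,
#' 0.95, 0.90 and 0.60 and one distal site at 0.30, jittered with a
#' 0.3 Angstrom (3-sigma truncated) Gaussian; pairwise separations exceed
#' twice the water clustering penalty so recovery is unambiguous. The
#' 0.95-conserved water is missing from exactly one designated model -- the
#' unique water displacement the summary should single out. One pocket
#' residue is bi-rotameric, split 6/14 across the ensemble with an
#' inter-rotamer heavy-atom RMSD above 4 Angstrom. Each model also carries
#' two decoy waters placed uniformly far from the pocket.
#'
#' @param seed integer seed controlling jitter, subset draws and decoys.
#' @return An ensemble specification list for [generateEnsemble()].
#' @export
defaultDemoSpec <- function(seed = 17L) {
  nModels <- 20L
  ids <- sprintf("m%02d", seq_len(nModels))
  displacer <- "m07"
  waterSites <- data.frame(
    label = c("W1", "W2", "W3", "W4", "W5"),
    x = c(4.15, -1.39, -0.695, 0, 8),
    y = c(0, 0, 1.204, -2.3, 0),
    z = c(0, 1.4, -1.4, 0, 0),
    conservation = c(1.00, 0.95, 0.90, 0.60, 0.30),
    sigma = 0.3,
    stringsAsFactors = FALSE)
  list(
    nModels = nModels,
    modelIds = ids,
    chain = "A",
    ligands = data.frame(
      modelId = ids,
      smiles = rep(c("Oc1ccccc1", "Clc1ccccc1"), length.out = nModels),
      compoundId = paste0("CMP", rep(c(1, 2), length.out = nModels)),
      stringsAsFactors = FALSE),
    ligandMaxRotZ = 4, ligandMaxShift = 0.25,
    waterSites = waterSites,
    forcedMissing = list(W2 = displacer, W4 = displacer),
    rotamer = .demoRotamer(),
    rotamerMinoritySize = 6L,
    decoysPerModel = 2L,
    decoyBox = rbind(c(-20, 20), c(15, 32), c(-8, 8)),
    lamWater = 1.5,
    seed = as.integer(seed)
  )
}

.validateSpec <- function(spec) {
  ws <- spec$waterSites
  if (any(ws$conservation <= 0 | ws$conservation > 1))
    stop("spec error: water-site conservations must lie in (0, 1]")
  if (any(ws$sigma >= spec$lamWater / 3))
    stop("spec error: water jitter sigma must stay below lambda/3")
  # exact-recovery feasibility under the sequential spawn rule, with the
  # jitter norm truncated at r = 2*sigma: within-site pairs <= 2r < lambda,
  # and inter-site separations > lambda + 2r
  if (any(4 * ws$sigma >= spec$lamWater))
    stop("spec error: 4*sigma must stay below the water clustering penalty")
  if (nrow(ws) > 1L) {
    D <- as.matrix(stats::dist(ws[, c("x", "y", "z")]))
    diag(D) <- Inf
    minSep <- spec$lamWater + 4 * max(ws$sigma)
    if (min(D) <= max(minSep, 2 * spec$lamWater))
      stop("spec error: planted water sites separated by only ",
           round(min(D), 2), " A; recovery is not guaranteed")
  }
  invisible(TRUE)
}

#' Generate a synthetic pre-aligned ensemble with planted truth
#'
#' Writes one PDB file per model (rigid shared protein scaffold, planted
#' jittered waters, per-model rotamer state, one placed ligand), a CSV
#' manifest and a `truth.json` documenting the planted ground truth:
#' water-cluster memberships and conservations, displacement cells, the
#' rotamer partition, per-ligand pharmacophore content and site membership.
#' Deterministic: the same spec (including seed) produces byte-identical
#' files.
#'
#' @param spec an ensemble specification, see [defaultDemoSpec()].
#' @param dir output directory (created if needed).
#' @return A list: `manifest` (path), `pdbs` (paths), `truth` (list, also
#'   written to `truth.json`).
#' @export
generateEnsemble <- function(spec = defaultDemoSpec(), dir) {
  .validateSpec(spec)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- spec$nModels
  ids <- spec$modelIds
  ws <- spec$waterSites

  out <- .withSeed(spec$seed, {
    # which models contribute to each water site
    contributors <- list()
    for (k in seq_len(nrow(ws))) {
      lab <- ws$label[k]
      nContrib <- round(ws$conservation[k] * n)
      forced <- spec$forcedMissing[[lab]]
      pool <- setdiff(ids, forced)
      if (nContrib > length(pool))
        stop("spec error: forced-missing set of ", lab,
             " conflicts with its conservation")
      contributors[[lab]] <- sort(sample(pool, nContrib))
    }
    # rotamer minority subset
    minority <- sort(sample(ids, spec$rotamerMinoritySize))
    states <- stats::setNames(ifelse(ids %in% minority, "B", "A"), ids)
    # ligand placement
    rotZ <- stats::runif(n, -spec$ligandMaxRotZ, spec$ligandMaxRotZ)
    shift <- matrix(stats::runif(3L * n, -spec$ligandMaxShift,
                                 spec$ligandMaxShift), n, 3L)
    # water jitter, drawn per (site, contributing model)
    jit <- list()
    for (lab in ws$label)
      jit[[lab]] <- .truncJitter(length(contributors[[lab]]),
                                 ws$sigma[match(lab, ws$label)])
    # decoy waters: uniform in the decoy box, kept >= 2*lambda from planted
    # sites and from each other so each is its own singleton cluster
    bx <- spec$decoyBox
    nDecoy <- spec$decoysPerModel * n
    decoys <- matrix(NA_real_, 0L, 3L)
    tries <- 0L
    while (nrow(decoys) < nDecoy) {
      tries <- tries + 1L
      if (tries > 100000L)
        stop("spec error: decoy box too small for the requested decoy count")
      p <- c(stats::runif(1, bx[1, 1], bx[1, 2]),
             stats::runif(1, bx[2, 1], bx[2, 2]),
             stats::runif(1, bx[3, 1], bx[3, 2]))
      dPlanted <- sqrt(colSums((t(as.matrix(ws[, c("x", "y", "z")])) - p)^2))
      dDecoy <- if (nrow(decoys)) sqrt(colSums((t(decoys) - p)^2)) else Inf
      if (min(dPlanted) > 2 * spec$lamWater && min(dDecoy) > 2 * spec$lamWater)
        decoys <- rbind(decoys, p)
    }
    list(contributors = contributors, states = states, rotZ = rotZ,
         shift = shift, jit = jit, decoys = decoys)
  })

  scaffold <- .demoScaffold()
  rot <- spec$rotamer
  rotKey <- paste(rot$identity[["chain"]], rot$identity[["resno"]],
                  rot$identity[["insert"]], rot$identity[["resname"]],
                  sep = "|")

  pdbs <- character(n)
  truthWaters <- list()
  for (k in seq_len(nrow(ws))) {
    lab <- ws$label[k]
    truthWaters[[lab]] <- list(
      label = lab, x = ws$x[k], y = ws$y[k], z = ws$z[k],
      conservation = length(out$contributors[[lab]]) / n,
      models = out$contributors[[lab]])
  }

  perModelPharma <- list()
  for (i in seq_len(n)) {
    id <- ids[i]
    smiles <- spec$ligands$smiles[i]
    pose <- demoLigandPose(smiles, modelId = id, rotZ = out$rotZ[i],
                           shift = out$shift[i, ])
    pose@compoundId <- spec$ligands$compoundId[i]
    wpts <- list()
    for (k in seq_len(nrow(ws))) {
      lab <- ws$label[k]
      at <- match(id, out$contributors[[lab]])
      if (!is.na(at))
        wpts[[length(wpts) + 1L]] <-
          c(ws$x[k], ws$y[k], ws$z[k]) + out$jit[[lab]][at, ]
    }
    dIdx <- (i - 1L) * spec$decoysPerModel + seq_len(spec$decoysPerModel)
    wat <- rbind(do.call(rbind, wpts), out$decoys[dIdx, , drop = FALSE])
    if (is.null(wat)) wat <- matrix(numeric(0), 0L, 3L)

    residues <- scaffold
    names(residues) <- vapply(scaffold, function(r)
      paste(r$identity[["chain"]], r$identity[["resno"]],
            r$identity[["insert"]], r$identity[["resname"]], sep = "|"),
      character(1))
    residues[[rotKey]] <- list(identity = rot$identity,
                               atomNames = rot$atomNames,
                               coords = rot$confs[[out$states[[id]]]])
    model <- methods::new("StructureModel", modelId = id, chainId = spec$chain,
                          residues = residues, waters = wat, ligand = pose)
    pdbs[i] <- file.path(dir, paste0(id, ".pdb"))
    writeModelPdb(model, pdbs[i])
    ph <- detectPharmacophores(pose)
    perModelPharma[[id]] <- as.list(table(factor(ph$kind,
                                                 levels = .PHARMA_KINDS)))
  }

  manifest <- file.path(dir, "manifest.csv")
  utils::write.csv(data.frame(
    pdb_path = basename(pdbs),
    smiles = spec$ligands$smiles,
    compound_id = spec$ligands$compoundId,
    model_id = ids,
    chain = spec$chain, stringsAsFactors = FALSE),
    manifest, row.names = FALSE, quote = FALSE)

  proximal <- c("W1", "W2", "W3", "W4")
  displacement <- list()
  for (lab in proximal) {
    miss <- setdiff(ids, out$contributors[[lab]])
    for (m in miss)
      displacement[[length(displacement) + 1L]] <-
        list(cluster = lab, model = m)
  }
  uniqueRows <- proximal[vapply(proximal, function(lab)
    length(setdiff(ids, out$contributors[[lab]])) == 1L, logical(1))]

  truth <- list(
    nModels = n,
    modelIds = ids,
    sites = list(list(siteId = 1L, models = ids)),
    waterClusters = unname(truthWaters),
    nDecoyClusters = nrow(out$decoys),
    ligandProximal = proximal,
    displacement = displacement,
    uniqueDisplacement = if (length(uniqueRows) == 1L)
      list(cluster = uniqueRows,
           model = setdiff(ids, out$contributors[[uniqueRows]]))
      else NULL,
    rotamer = list(residue = rotKey,
                   states = as.list(out$states),
                   sizes = sort(as.integer(table(out$states)),
                                decreasing = TRUE),
                   interRmsd = heavyAtomRmsd(
                     list(identity = rot$identity, atomNames = rot$atomNames,
                          coords = rot$confs$A),
                     list(identity = rot$identity, atomNames = rot$atomNames,
                          coords = rot$confs$B))),
    pharmacophores = perModelPharma,
    chemotypes = stats::setNames(as.list(spec$ligands$smiles), ids)
  )
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  list(manifest = manifest, pdbs = pdbs, truth = truth)
}
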