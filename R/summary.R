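# Ensemble summarisation: binding-site assignment, conserved-water ranking
# and displacement, pharmacophore presence grids and ranked residue
# conformational clustering. Default lambda values (Angstrom): waters 1.5,
# pharmacophores and fragments 2.0, residues 2.5, ligands 5.0; ligand-water
# contact cutoff 1.5, ligand-residue contact cutoff 5.0.

#' Cluster ligand binding sites
#'
#' DP-means over the unweighted ligand centroids (lambda defaults to
#' 5.0 Angstrom). The most populated cluster is flagged as the main site;
#' ties go to the site containing the lexicographically smallest modelId.
#'
#' @param ensemble a [StructureEnsemble-class].
#' @param lam distance penalty in Angstrom.
#' @return A list: `sites` (data.frame with `siteId`, centre, `size`,
#'   `isMain`) and `members` (list of modelId vectors per site).
#' @export
clusterLigandSites <- function(ensemble, lam = 5.0) {
  if (length(ensemble@models) == 0L)
    stop("empty ensemble: no models to assign to sites")
  cen <- t(vapply(ensemble@models, function(m) m@ligand@centroid, numeric(3)))
  ids <- modelIds(ensemble)
  cs <- dpMeans(cen, ids, lam, kind = "ligand",
                nEnsemble = length(ensemble@models))
  tab <- cs@clusters
  members <- lapply(cs@members, function(m) m$modelId)
  maxSize <- max(tab$size)
  cand <- which(tab$size == maxSize)
  mainIdx <- cand[order(vapply(members[cand], min, character(1)))][1L]
  sites <- data.frame(siteId = seq_len(nrow(tab)),
                      x = tab$x, y = tab$y, z = tab$z, size = tab$size,
                      isMain = seq_len(nrow(tab)) == mainIdx)
  list(sites = sites, members = members)
}

#' Cluster ensemble waters
#'
#' DP-means over all water oxygen positions of the ensemble (lambda 1.5
#' Angstrom by default). Conservation of a cluster is the fraction of
#' ensemble models contributing at least one water to it; clusters are
#' returned ordered by conservation, most conserved first.
#'
#' @param ensemble a [StructureEnsemble-class].
#' @param lam distance penalty in Angstrom.
#' @return A [PointClusterSet-class] with `kind = "water"`.
#' @export
clusterWaters <- function(ensemble, lam = 1.5) {
  pts <- do.call(rbind, lapply(ensemble@models, function(m) m@waters))
  ids <- unlist(lapply(ensemble@models, function(m)
    rep(m@modelId, nrow(m@waters))))
  if (is.null(pts) || nrow(pts) == 0L) {
    return(dpMeans(matrix(numeric(0), 0, 3), character(0), lam,
                   kind = "water", nEnsemble = length(ensemble@models)))
  }
  cs <- dpMeans(pts, ids, lam, kind = "water",
                nEnsemble = length(ensemble@models))
  ord <- order(-cs@clusters$conservation, -cs@clusters$size)
  cs@clusters <- cs@clusters[ord, , drop = FALSE]
  rownames(cs@clusters) <- NULL
  cs@members <- cs@members[ord]
  cs
}

.siteLigandCoords <- function(ensemble, siteModels) {
  do.call(rbind, lapply(ensemble@models, function(m) {
    if (m@modelId %in% siteModels)
      as.matrix(m@ligand@atoms[, c("x", "y", "z")])
    else NULL
  }))
}

#' Filter water clusters to those relevant for a binding site
#'
#' Keeps clusters whose centre lies within `contact` (default 1.5 Angstrom)
#' of at least one heavy atom of at least one ligand bound in the site, and
#' whose conservation is strictly greater than `minConservation`. Input
#' order (conservation ranking) is preserved.
#'
#' @param clusters a [PointClusterSet-class] of waters (conservation
#'   ranked).
#' @param ensemble the [StructureEnsemble-class].
#' @param siteModels character vector of modelIds belonging to the site.
#' @param contact ligand-proximity cutoff in Angstrom.
#' @param minConservation strict lower bound on conservation (default 0:
#'   keep everything ligand-proximal).
#' @return The filtered cluster table (data.frame) with an added
#'   `clusterRank` column referring to the input ranking.
#' @export
filterSiteWaters <- function(clusters, ensemble, siteModels, contact = 1.5,
                             minConservation = 0) {
  tab <- clusters@clusters
  if (nrow(tab) == 0L) return(cbind(tab, clusterRank = integer(0)))
  lig <- .siteLigandCoords(ensemble, siteModels)
  keep <- logical(nrow(tab))
  for (k in seq_len(nrow(tab))) {
    d <- sqrt(colSums((t(lig) - c(tab$x[k], tab$y[k], tab$z[k]))^2))
    keep[k] <- min(d) <= contact && tab$conservation[k] > minConservation
  }
  out <- cbind(tab[keep, , drop = FALSE],
               clusterRank = which(keep))
  rownames(out) <- NULL
  out
}

#' Water displacement matrix for a binding site
#'
#' For each ligand-proximal water cluster (row) and each site model
#' (column), `TRUE` marks a displacement: the model contributes no water to
#' the cluster. A fully conserved cluster has an all-`FALSE` row.
#'
#' @param siteWaters filtered water table from [filterSiteWaters()].
#' @param clusters the full water [PointClusterSet-class] the table refers
#'   to.
#' @param siteModels modelIds of the site (column order).
#' @return Logical matrix with cluster rank rownames and modelId colnames.
#' @export
waterDisplacementMatrix <- function(siteWaters, clusters, siteModels) {
  m <- matrix(FALSE, nrow(siteWaters), length(siteModels),
              dimnames = list(siteWaters$clusterRank, siteModels))
  for (r in seq_len(nrow(siteWaters))) {
    contrib <- unique(clusters@members[[siteWaters$clusterRank[r]]]$modelId)
    m[r, ] <- !(siteModels %in% contrib)
  }
  m
}

#' Pharmacophore clusters and presence grid for a binding site
#'
#' Clusters the pharmacophore points of the site's ligands per kind (kinds
#' never co-cluster) with DP-means at lambda 2.0 Angstrom, computes each
#' cluster's conservation over the site ligands, and builds the green/white
#' presence grid: cell `TRUE` when the ligand contributes at least one
#' point to the cluster. Rows are sorted by cluster size, descending.
#'
#' @param points pharmacophore points (from [ensemblePharmacophores()]).
#' @param siteModels modelIds of the site.
#' @param lam distance penalty in Angstrom.
#' @param columnOrder modelId order for the grid columns (defaults to
#'   `siteModels` order).
#' @return A list: `clusters` (data.frame with `kind`, centre, `size`,
#'   `nModels`, `conservation`), `presence` (logical matrix), and
#'   `pointSets` (per-cluster member tables).
#' @export
pharmacophorePresenceMatrix <- function(points, siteModels, lam = 2.0,
                                        columnOrder = NULL) {
  if (is.null(columnOrder)) columnOrder <- siteModels
  pts <- points[points$modelId %in% siteModels, , drop = FALSE]
  allTabs <- list(); allMembers <- list()
  for (kind in .PHARMA_KINDS) {
    kp <- pts[pts$kind == kind, , drop = FALSE]
    if (nrow(kp) == 0L) next
    # deterministic input order: by modelId then source atoms
    kp <- kp[order(kp$modelId, kp$atoms), , drop = FALSE]
    cs <- dpMeans(as.matrix(kp[, c("x", "y", "z")]), kp$modelId, lam,
                  kind = kind, nEnsemble = length(siteModels))
    tab <- cs@clusters
    if (nrow(tab) == 0L) next
    tab$kind <- kind
    allTabs[[kind]] <- tab
    allMembers <- c(allMembers, cs@members)
  }
  if (length(allTabs) == 0L) {
    return(list(clusters = data.frame(), presence =
                  matrix(FALSE, 0L, length(columnOrder),
                         dimnames = list(NULL, columnOrder)),
                pointSets = list()))
  }
  clusters <- do.call(rbind, c(allTabs, make.row.names = FALSE))
  ord <- order(-clusters$size)
  clusters <- clusters[ord, c("kind", "x", "y", "z", "size", "nModels",
                              "conservation")]
  members <- allMembers[ord]
  rownames(clusters) <- NULL
  clusters <- cbind(row = seq_len(nrow(clusters)), clusters)
  presence <- matrix(FALSE, nrow(clusters), length(columnOrder),
                     dimnames = list(seq_len(nrow(clusters)), columnOrder))
  for (r in seq_len(nrow(clusters)))
    presence[r, ] <- columnOrder %in% unique(members[[r]]$modelId)
  list(clusters = clusters, presence = presence, pointSets = members)
}

#' Ranked residue conformational clustering for a binding site
#'
#' Considers every residue identity with at least one heavy atom within
#' `contact` (default 5.0 Angstrom) of at least one heavy atom of any site
#' ligand, in any model (union over models). For each such residue the
#' all-against-all heavy-atom RMSD matrix is clustered with the medoid
#' DP-means at lambda 2.5 Angstrom, and residues are ranked by maximum
#' pairwise RMSD, descending. Residues missing from more than half of the
#' models are excluded with a note.
#'
#' @param ensemble a [StructureEnsemble-class].
#' @param siteModels modelIds of the site.
#' @param contact ligand-residue contact cutoff in Angstrom.
#' @param lam residue clustering penalty in Angstrom (RMSD units).
#' @return A list: `ranking` (data.frame: `residue`, `resname`, `resno`,
#'   `chain`, `maxRmsd`, `nClusters`, `clusterSizes`) and `assignments`
#'   (data.frame: `residue`, `modelId`, `cluster`).
#' @export
bindingSiteResidues <- function(ensemble, siteModels, contact = 5.0,
                                lam = 2.5) {
  lig <- .siteLigandCoords(ensemble, siteModels)
  nTot <- length(ensemble@models)
  # residue identity -> per-model conformations
  confs <- list()
  for (m in ensemble@models) {
    for (key in names(m@residues)) {
      confs[[key]] <- c(confs[[key]],
                        stats::setNames(list(m@residues[[key]]), m@modelId))
    }
  }
  rank <- list(); assignRows <- list()
  for (key in names(confs)) {
    cf <- confs[[key]]
    if (length(cf) < nTot / 2) {
      message("note: residue ", key, " present in only ", length(cf), "/",
              nTot, " models; excluded from the ranking")
      next
    }
    near <- any(vapply(cf, function(r) {
      d2min <- min(vapply(seq_len(nrow(r$coords)), function(i)
        min(colSums((t(lig) - r$coords[i, ])^2)), numeric(1)))
      sqrt(d2min) <= contact
    }, logical(1)))
    if (!near) next
    n <- length(cf)
    D <- matrix(0, n, n)
    if (n > 1L)
      for (i in seq_len(n - 1L))
        for (j in (i + 1L):n)
          D[i, j] <- D[j, i] <- heavyAtomRmsd(cf[[i]], cf[[j]])
    cl <- dpMeansMedoid(D, lam)
    sizes <- tabulate(cl$assign)
    id1 <- cf[[1L]]$identity
    rank[[key]] <- data.frame(
      residue = key,
      resname = id1[["resname"]], resno = as.integer(id1[["resno"]]),
      chain = id1[["chain"]],
      maxRmsd = max(D), nClusters = length(cl$medoids),
      clusterSizes = paste(sort(sizes, decreasing = TRUE), collapse = "/"),
      stringsAsFactors = FALSE)
    assignRows[[key]] <- data.frame(
      residue = key, modelId = names(cf), cluster = cl$assign,
      stringsAsFactors = FALSE)
  }
  if (length(rank) == 0L) {
    return(list(ranking = data.frame(residue = character(0),
                                     maxRmsd = numeric(0)),
                assignments = data.frame(residue = character(0),
                                         modelId = character(0),
                                         cluster = integer(0))))
  }
  ranking <- do.call(rbind, c(rank, make.row.names = FALSE))
  ranking <- ranking[order(-ranking$maxRmsd, ranking$resno), , drop = FALSE]
  rownames(ranking) <- NULL
  list(ranking = ranking,
       assignments = do.call(rbind, c(assignRows, make.row.names = FALSE)))
}

#' Order compounds chemically
#'
#' Morgan (radius 2) fingerprints of the bound ligands, Butina-clustered at
#' a Tanimoto distance threshold (default 0.4); the ordering lists clusters
#' by size descending and members by modelId.
#'
#' @param ensemble a [StructureEnsemble-class].
#' @param modelSubset optional modelIds to restrict the ordering to.
#' @param cutoff Butina Tanimoto-distance threshold.
#' @return Character vector of modelIds in chemical order.
#' @export
orderCompoundsChemically <- function(ensemble, modelSubset = NULL,
                                     cutoff = 0.4) {
  ids <- modelIds(ensemble)
  if (!is.null(modelSubset)) ids <- ids[ids %in% modelSubset]
  if (length(ids) == 0L) return(character(0))
  sm <- vapply(ensemble@models, function(m) m@ligand@smiles, character(1))
  names(sm) <- modelIds(ensemble)
  sm <- sm[ids]
  fps <- morganFingerprints(unname(sm))
  cl <- butinaCluster(fps, cutoff)
  sizes <- tabulate(cl)
  ord <- order(-sizes[cl], cl, ids)
  ids[ord]
}

#' Summarise an ensemble for one binding site
#'
#' Runs the full summary for one site: ligand-proximal conserved waters and
#' the displacement matrix, per-kind pharmacophore clusters with the
#' presence grid, ranked residue conformational clusters, fragment-centroid
#' clusters and the chemical compound ordering.
#'
#' @param ensemble a [StructureEnsemble-class].
#' @param config a [runConfig()] list of parameters.
#' @param siteId site to analyse; `"main"` (default) selects the most
#'   populated ligand cluster.
#' @return An [EnsembleSummary-class].
#' @export
summariseEnsemble <- function(ensemble, config = runConfig(),
                              siteId = "main") {
  sites <- clusterLigandSites(ensemble, lam = config$lamLigand)
  sid <- if (identical(siteId, "main")) which(sites$sites$isMain)
         else as.integer(siteId)
  if (length(sid) != 1L || is.na(sid) || sid < 1L ||
      sid > nrow(sites$sites))
    stop("lookup error: unknown site '", siteId, "'")
  siteModels <- sites$members[[sid]]

  columnOrder <- if (identical(config$order, "chem"))
    orderCompoundsChemically(ensemble, siteModels, config$butinaCutoff)
  else siteModels

  wc <- clusterWaters(ensemble, lam = config$lamWater)
  sw <- filterSiteWaters(wc, ensemble, siteModels,
                         contact = config$waterContact,
                         minConservation = config$minWaterConservation)
  disp <- waterDisplacementMatrix(sw, wc, columnOrder)

  pts <- ensemblePharmacophores(ensemble)
  ph <- pharmacophorePresenceMatrix(pts, siteModels,
                                    lam = config$lamPharma,
                                    columnOrder = columnOrder)

  res <- bindingSiteResidues(ensemble, siteModels,
                             contact = config$residueContact,
                             lam = config$lamResidue)

  frags <- ensembleFragments(ensemble)
  frags <- frags[frags$modelId %in% siteModels, , drop = FALSE]
  fragClusters <- if (nrow(frags))
    dpMeans(as.matrix(frags[, c("x", "y", "z")]), frags$modelId,
            config$lamFragment, kind = "fragment",
            nEnsemble = length(siteModels))@clusters
  else data.frame()

  manifest <- ensemble@manifestPath
  checksums <- if (length(manifest) && !is.na(manifest) &&
                   file.exists(manifest)) {
    pdbs <- file.path(dirname(manifest), ensemble@records$pdb_path)
    pdbs <- pdbs[file.exists(pdbs)]
    cs <- tools::md5sum(c(manifest, pdbs))
    names(cs) <- basename(names(cs))
    as.list(cs)
  } else list()

  provenance <- list(
    tool = "plens",
    version = as.character(utils::packageVersion("plens")),
    lambda = list(water = config$lamWater, pharmacophore = config$lamPharma,
                  fragment = config$lamFragment, residue = config$lamResidue,
                  ligand = config$lamLigand),
    contacts = list(water = config$waterContact,
                    residue = config$residueContact),
    minWaterConservation = config$minWaterConservation,
    butinaCutoff = config$butinaCutoff,
    site = sid,
    nModels = length(ensemble@models),
    inputChecksums = checksums
  )

  methods::new("EnsembleSummary",
               sites = sites$sites, siteMembers = sites$members,
               waterClusters = wc, siteWaters = sw, displacement = disp,
               pharmacophoreClusters = if (nrow(ph$clusters))
                 ph$clusters else data.frame(),
               presence = ph$presence,
               residueRanking = res$ranking,
               residueAssignments = res$assignments,
               fragmentClusters = fragClusters,
               compoundOrder = columnOrder,
               provenance = provenance)
}

#' Analyse one specific binding site
#'
#' Recomputes the summary restricted to one site's ligands: filters,
#' presence columns and residue contacts all use only that site.
#'
#' @param ensemble a [StructureEnsemble-class].
#' @param siteId integer site identifier (row of the site table) or
#'   `"main"`.
#' @param config parameters, see [runConfig()].
#' @return An [EnsembleSummary-class] for that site.
#' @export
analyseSite <- function(ensemble, siteId, config = runConfig()) {
  summariseEnsemble(ensemble, config, siteId = siteId)
}
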