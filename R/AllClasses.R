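#' @import methods
NULL

#' LigandPose: a bound ligand with template-assigned chemistry
#'
#' Heavy-atom crystallographic coordinates of one bound ligand, with bond
#' orders, formal charges and aromaticity transferred from the template
#' SMILES supplied in the manifest. Atom rows are in template atom order so
#' that graph annotations and coordinates align positionally.
#'
#' @slot atoms data.frame with one row per heavy atom: `name` (PDB atom
#'   name), `element`, `x`, `y`, `z` (Angstrom).
#' @slot mol annotated molecular graph from [molFromSmiles()] (template).
#' @slot smiles canonical SMILES of the template.
#' @slot centroid unweighted arithmetic mean of heavy-atom coordinates.
#' @slot modelId owning model identifier.
#' @slot compoundId compound identifier (may be `NA`).
#' @export
setClass("LigandPose", representation(
  atoms = "data.frame",
  mol = "list",
  smiles = "character",
  centroid = "numeric",
  modelId = "character",
  compoundId = "character"
))

setValidity("LigandPose", function(object) {
  msg <- character(0)
  if (nrow(object@atoms) != nrow(object@mol$atoms))
    msg <- c(msg, "atom count differs from template heavy-atom count")
  if (length(object@centroid) != 3L || any(!is.finite(object@centroid)))
    msg <- c(msg, "centroid must be a finite 3-vector")
  co <- colMeans(as.matrix(object@atoms[, c("x", "y", "z")]))
  if (nrow(object@atoms) > 0 && max(abs(co - object@centroid)) > 1e-6)
    msg <- c(msg, "centroid is not the unweighted mean of atom coordinates")
  if (any(object@atoms$element %in% c("H", "D")))
    msg <- c(msg, "hydrogens are not allowed in a LigandPose")
  if (length(msg)) msg else TRUE
})

#' StructureModel: one ligand-bound protein chain
#'
#' The unit of conservation counting: a single pre-aligned protein chain with
#' its waters and exactly one bound ligand, as entered on one manifest row.
#'
#' @slot modelId unique model identifier within the ensemble.
#' @slot chainId chain identifier the model was read from.
#' @slot residues named list of residue conformations; each element is a list
#'   with `identity` (chain, resno, insert, resname), `atomNames` and
#'   `coords` (heavy atoms only).
#' @slot waters numeric matrix (n x 3) of water oxygen positions.
#' @slot ligand a [LigandPose-class].
#' @export
setClass("StructureModel", representation(
  modelId = "character",
  chainId = "character",
  residues = "list",
  waters = "matrix",
  ligand = "LigandPose"
))

setValidity("StructureModel", function(object) {
  msg <- character(0)
  if (length(object@modelId) != 1L || !nzchar(object@modelId))
    msg <- c(msg, "modelId must be a single non-empty string")
  if (ncol(object@waters) != 3L)
    msg <- c(msg, "waters must be an n x 3 matrix")
  if (nrow(object@waters) && any(!is.finite(object@waters)))
    msg <- c(msg, "water positions must be finite")
  if (length(msg)) msg else TRUE
})

#' StructureEnsemble: an ensemble of pre-aligned liganded models
#'
#' @slot models list of [StructureModel-class] objects, manifest order.
#' @slot records the parsed manifest rows (data.frame).
#' @slot manifestPath path of the manifest the ensemble was read from
#'   (may be `NA` for programmatically built ensembles).
#' @export
setClass("StructureEnsemble", representation(
  models = "list",
  records = "data.frame",
  manifestPath = "character"
))

setValidity("StructureEnsemble", function(object) {
  msg <- character(0)
  ok <- vapply(object@models, is, logical(1), class2 = "StructureModel")
  if (length(ok) && !all(ok))
    msg <- c(msg, "all elements of 'models' must be StructureModel objects")
  ids <- vapply(object@models, function(m) m@modelId, character(1))
  if (anyDuplicated(ids))
    msg <- c(msg, "model identifiers must be unique within the ensemble")
  if (length(msg)) msg else TRUE
})

#' PointClusterSet: DP-means clusters of 3-D feature points
#'
#' @slot kind feature kind: one of the pharmacophore kinds, or
#'   `"water"`, `"ligand"`, `"fragment"`.
#' @slot lambda the distance penalty lambda (Angstrom).
#' @slot clusters data.frame, one row per cluster: `cluster`, `x`, `y`, `z`
#'   (centre), `size`, `nModels`, `conservation`.
#' @slot members list (one per cluster) of data.frames with member point
#'   coordinates and their `modelId`.
#' @slot nEnsemble number of models the conservation fraction is taken over.
#' @export
setClass("PointClusterSet", representation(
  kind = "character",
  lambda = "numeric",
  clusters = "data.frame",
  members = "list",
  nEnsemble = "integer"
))

setValidity("PointClusterSet", function(object) {
  msg <- character(0)
  if (object@lambda <= 0) msg <- c(msg, "lambda must be positive")
  if (nrow(object@clusters) != length(object@members))
    msg <- c(msg, "clusters and members are out of step")
  if (nrow(object@clusters)) {
    if (any(object@clusters$conservation <= 0 | object@clusters$conservation > 1))
      msg <- c(msg, "conservation must be in (0, 1]")
    for (k in seq_along(object@members)) {
      m <- object@members[[k]]
      d <- sqrt((m$x - object@clusters$x[k])^2 + (m$y - object@clusters$y[k])^2 +
                  (m$z - object@clusters$z[k])^2)
      if (any(d > object@lambda + 1e-9)) {
        msg <- c(msg, "a member lies farther than lambda from its cluster centre")
        break
      }
    }
  }
  if (length(msg)) msg else TRUE
})

#' EnsembleSummary: the ranked summary tables for one analysed site
#'
#' The end product of the pipeline: site assignments, water conservation and
#' displacement, per-kind pharmacophore presence, ranked residue
#' conformational clusters, fragment clusters and the chemical compound
#' ordering, together with the parameter provenance.
#'
#' @slot sites data.frame of ligand binding-site clusters.
#' @slot siteMembers list of modelId vectors, one per site.
#' @slot waterClusters [PointClusterSet-class] over all waters.
#' @slot siteWaters data.frame of the ligand-proximal water clusters
#'   (conservation ranked) used for the displacement analysis.
#' @slot displacement logical matrix: water cluster x site model, `TRUE`
#'   when the model contributes no water to the cluster.
#' @slot pharmacophoreClusters data.frame over all kinds, size-ranked.
#' @slot presence logical matrix: pharmacophore cluster x site model.
#' @slot residueRanking data.frame ranked by maximum pairwise RMSD.
#' @slot residueAssignments data.frame: model x residue -> cluster index.
#' @slot fragmentClusters data.frame of fragment-centroid clusters.
#' @slot compoundOrder character vector of modelIds in chemical order.
#' @slot provenance list of parameters, versions and input checksums.
#' @export
setClass("EnsembleSummary", representation(
  sites = "data.frame",
  siteMembers = "list",
  waterClusters = "PointClusterSet",
  siteWaters = "data.frame",
  displacement = "matrix",
  pharmacophoreClusters = "data.frame",
  presence = "matrix",
  residueRanking = "data.frame",
  residueAssignments = "data.frame",
  fragmentClusters = "data.frame",
  compoundOrder = "character",
  provenance = "list"
))
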