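#' @include AllClasses.R
NULL

#' Model identifier(s) of an object
#' @param x an object carrying model identifiers.
#' @return Character vector of model identifiers.
#' @export
setGeneric("modelIds", function(x) standardGeneric("modelIds"))

#' Number of models in an ensemble-like object
#' @param x an ensemble-like object.
#' @return Integer count of models.
#' @export
setGeneric("nModels", function(x) standardGeneric("nModels"))

#' Water positions of a model
#' @param x a [StructureModel-class].
#' @return Numeric matrix of water oxygen positions.
#' @export
setGeneric("waters", function(x) standardGeneric("waters"))

#' Ligand pose of a model
#' @param x a [StructureModel-class].
#' @return The [LigandPose-class] bound in the model.
#' @export
setGeneric("ligand", function(x) standardGeneric("ligand"))

#' Residue conformations of a model
#' @param x a [StructureModel-class].
#' @return Named list of residue conformations.
#' @export
setGeneric("residues", function(x) standardGeneric("residues"))

#' Cluster table of a cluster set
#' @param x a [PointClusterSet-class].
#' @return data.frame of clusters (centre, size, nModels, conservation).
#' @export
setGeneric("clusterTable", function(x) standardGeneric("clusterTable"))

#' Conservation fractions of a cluster set
#' @param x a [PointClusterSet-class].
#' @return Numeric vector of per-cluster conservation fractions.
#' @export
setGeneric("conservation", function(x) standardGeneric("conservation"))

#' @describeIn modelIds model identifiers of the ensemble, manifest order
#' @export
setMethod("modelIds", "StructureEnsemble", function(x)
  vapply(x@models, function(m) m@modelId, character(1)))

#' @describeIn modelIds the identifier of a single model
#' @export
setMethod("modelIds", "StructureModel", function(x) x@modelId)

#' @describeIn nModels number of models in the ensemble
#' @export
setMethod("nModels", "StructureEnsemble", function(x) length(x@models))

#' @describeIn waters water oxygen positions of the model
#' @export
setMethod("waters", "StructureModel", function(x) x@waters)

#' @describeIn ligand the bound ligand of the model
#' @export
setMethod("ligand", "StructureModel", function(x) x@ligand)

#' @describeIn residues residue conformations of the model
#' @export
setMethod("residues", "StructureModel", function(x) x@residues)

#' @describeIn clusterTable cluster table of a point cluster set
#' @export
setMethod("clusterTable", "PointClusterSet", function(x) x@clusters)

#' @describeIn conservation per-cluster conservation of a point cluster set
#' @export
setMethod("conservation", "PointClusterSet", function(x)
  x@clusters$conservation)

setMethod("show", "LigandPose", function(object) {
  cat("LigandPose", object@modelId, "\n  ", nrow(object@atoms),
      "heavy atoms, SMILES:", object@smiles, "\n  centroid:",
      sprintf("%.2f %.2f %.2f", object@centroid[1], object@centroid[2],
              object@centroid[3]), "\n")
})

setMethod("show", "StructureModel", function(object) {
  cat("StructureModel", object@modelId, "(chain", object@chainId, ")\n  ",
      length(object@residues), "residues,", nrow(object@waters),
      "waters, ligand", object@ligand@smiles, "\n")
})

setMethod("show", "StructureEnsemble", function(object) {
  cat("StructureEnsemble of", length(object@models), "models\n")
  if (length(object@models))
    cat("  models:", paste(utils::head(modelIds(object), 6), collapse = ", "),
        if (length(object@models) > 6) "..." else "", "\n")
})

setMethod("show", "PointClusterSet", function(object) {
  cat("PointClusterSet kind=", object@kind, " lambda=", object@lambda,
      " A: ", nrow(object@clusters), " clusters over ", object@nEnsemble,
      " models\n", sep = "")
  if (nrow(object@clusters))
    print(utils::head(object@clusters, 8))
})

setMethod("show", "EnsembleSummary", function(object) {
  cat("EnsembleSummary:", nrow(object@sites), "site(s),",
      nrow(object@siteWaters), "ligand-proximal water cluster(s),",
      nrow(object@pharmacophoreClusters), "pharmacophore cluster(s),",
      nrow(object@residueRanking), "ranked residue(s)\n")
})
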