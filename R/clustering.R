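# DP-means clustering under the distance-threshold reading of the penalty:
# lambda is the maximum distance allowed between a member and its cluster
# centre. A point farther than lambda from every current centre spawns a new
# cluster; otherwise it joins its nearest centre. Passes run in deterministic
# input order; centres are recomputed as unweighted means after each pass;
# the algorithm stops when an assignment pass changes nothing.

.dpMeansCore <- function(X, lam, maxPasses = 100L) {
  n <- nrow(X)
  if (n == 0L) return(list(assign = integer(0), centres = matrix(0, 0, 3)))
  centres <- matrix(X[1L, ], nrow = 1L)
  assign <- integer(n)
  assign[1L] <- 1L
  first <- TRUE
  for (pass in seq_len(maxPasses)) {
    changed <- FALSE
    start <- if (first) 2L else 1L
    if (first && n == 1L) { changed <- FALSE }
    for (p in seq.int(start, length.out = n - start + 1L)) {
      d2 <- colSums((t(centres) - X[p, ])^2)
      best <- which.min(d2)                      # ties: lowest index
      if (sqrt(d2[best]) > lam) {
        centres <- rbind(centres, X[p, ])
        newIdx <- nrow(centres)
        if (assign[p] != newIdx) changed <- TRUE
        assign[p] <- newIdx
      } else {
        if (assign[p] != best) changed <- TRUE
        assign[p] <- best
      }
    }
    first <- FALSE
    # recompute centres as unweighted means, drop empty clusters
    sizes <- tabulate(assign, nbins = nrow(centres))
    keep <- which(sizes > 0L)
    remap <- integer(nrow(centres))
    remap[keep] <- seq_along(keep)
    assign <- remap[assign]
    centres <- do.call(rbind, lapply(keep, function(k)
      colMeans(X[assign == remap[k], , drop = FALSE])))
    if (!changed) break
    if (pass == maxPasses)
      warning("DP-means did not reach a fixed point within ", maxPasses,
              " passes; accepting the current assignment")
  }
  list(assign = assign, centres = centres)
}

#' DP-means clustering of 3-D points
#'
#' Clusters Euclidean points (waters, pharmacophore points, fragment or
#' ligand centroids) with a single distance penalty `lam`: the maximum
#' distance allowed between a cluster member and the cluster centre. The
#' number of clusters is data-driven. Clusters are returned sorted by size
#' (descending; ties by first-member input order) and each records the
#' number of distinct contributing models and the conservation fraction.
#'
#' @param points numeric matrix (n x 3) of coordinates, or a data.frame with
#'   columns `x`, `y`, `z`.
#' @param modelId character vector of owning model identifiers, recycled if
#'   length one.
#' @param lam distance penalty lambda in Angstrom (> 0).
#' @param kind label stored on the returned cluster set.
#' @param nEnsemble number of models conservation is computed over; defaults
#'   to the number of distinct `modelId` values.
#' @return A [PointClusterSet-class].
#' @examples
#' pts <- rbind(c(0, 0, 0), c(0.5, 0, 0), c(4, 0, 0))
#' dpMeans(pts, c("a", "b", "c"), lam = 1.5)
#' @export
dpMeans <- function(points, modelId = "m", lam, kind = "point",
                    nEnsemble = NULL) {
  if (!is.numeric(lam) || length(lam) != 1L || !is.finite(lam) || lam <= 0)
    stop("parameter error: lam must be a positive number")
  if (is.data.frame(points))
    points <- as.matrix(points[, c("x", "y", "z")])
  if (is.null(dim(points))) points <- matrix(points, ncol = 3L)
  storage.mode(points) <- "double"
  n <- nrow(points)
  modelId <- rep_len(as.character(modelId), n)
  if (is.null(nEnsemble)) nEnsemble <- length(unique(modelId))
  nEnsemble <- as.integer(max(nEnsemble, 1L))
  res <- .dpMeansCore(points, lam)
  .buildPointClusterSet(points, modelId, res$assign, res$centres, lam, kind,
                        nEnsemble)
}

.buildPointClusterSet <- function(points, modelId, assign, centres, lam,
                                  kind, nEnsemble) {
  k <- nrow(centres)
  if (is.null(k) || k == 0L || length(assign) == 0L) {
    return(methods::new("PointClusterSet", kind = kind, lambda = lam,
               clusters = data.frame(cluster = integer(0), x = numeric(0),
                                     y = numeric(0), z = numeric(0),
                                     size = integer(0), nModels = integer(0),
                                     conservation = numeric(0)),
               members = list(), nEnsemble = nEnsemble))
  }
  sizes <- tabulate(assign, nbins = k)
  firstMember <- vapply(seq_len(k), function(c) min(which(assign == c)),
                        integer(1))
  ord <- order(-sizes, firstMember)
  clusters <- data.frame(
    cluster = seq_len(k),
    x = centres[ord, 1L], y = centres[ord, 2L], z = centres[ord, 3L],
    size = sizes[ord],
    nModels = vapply(ord, function(c) length(unique(modelId[assign == c])),
                     integer(1))
  )
  clusters$conservation <- clusters$nModels / nEnsemble
  members <- lapply(ord, function(c) {
    w <- which(assign == c)
    data.frame(x = points[w, 1L], y = points[w, 2L], z = points[w, 3L],
               modelId = modelId[w], stringsAsFactors = FALSE)
  })
  methods::new("PointClusterSet", kind = kind, lambda = lam,
               clusters = clusters, members = members,
               nEnsemble = nEnsemble)
}

#' DP-means medoid clustering from a dissimilarity matrix
#'
#' The medoid flavour of the DP-means pass for objects with only pairwise
#' dissimilarities (residue conformations compared by heavy-atom RMSD). The
#' cluster centre is the member minimising the sum of dissimilarities to all
#' members (ties broken by lowest index); an item farther than `lam` from
#' every medoid spawns a new cluster.
#'
#' @param D symmetric, zero-diagonal, non-negative dissimilarity matrix.
#' @param lam distance penalty lambda (> 0), same units as `D`.
#' @return A list with `assign` (integer cluster index per item, clusters
#'   numbered by decreasing size) and `medoids` (item index per cluster).
#' @examples
#' D <- as.matrix(dist(c(0, 0.2, 4, 4.3)))
#' dpMeansMedoid(D, lam = 2.5)
#' @export
dpMeansMedoid <- function(D, lam) {
  if (!is.numeric(lam) || length(lam) != 1L || lam <= 0)
    stop("parameter error: lam must be a positive number")
  D <- as.matrix(D)
  if (nrow(D) != ncol(D) || any(abs(D - t(D)) > 1e-9) || any(D < 0) ||
      any(abs(diag(D)) > 1e-9))
    stop("input error: D must be a symmetric, non-negative, zero-diagonal matrix")
  n <- nrow(D)
  if (n == 0L) return(list(assign = integer(0), medoids = integer(0)))
  medoids <- 1L
  assign <- integer(n)
  assign[1L] <- 1L
  first <- TRUE
  for (pass in seq_len(100L)) {
    changed <- FALSE
    start <- if (first) 2L else 1L
    for (p in seq.int(start, length.out = n - start + 1L)) {
      d <- D[p, medoids]
      best <- which.min(d)
      if (d[best] > lam) {
        medoids <- c(medoids, p)
        newIdx <- length(medoids)
        if (assign[p] != newIdx) changed <- TRUE
        assign[p] <- newIdx
      } else {
        if (assign[p] != best) changed <- TRUE
        assign[p] <- best
      }
    }
    first <- FALSE
    sizes <- tabulate(assign, nbins = length(medoids))
    keep <- which(sizes > 0L)
    remap <- integer(length(medoids))
    remap[keep] <- seq_along(keep)
    assign <- remap[assign]
    medoids <- vapply(seq_along(keep), function(c) {
      mem <- which(assign == c)
      tot <- rowSums(D[mem, mem, drop = FALSE])
      mem[which.min(tot)]                      # ties: lowest index
    }, integer(1))
    if (!changed) break
  }
  sizes <- tabulate(assign, nbins = length(medoids))
  firstMember <- vapply(seq_along(medoids), function(c)
    min(which(assign == c)), integer(1))
  ord <- order(-sizes, firstMember)
  remap <- integer(length(medoids))
  remap[ord] <- seq_along(ord)
  list(assign = remap[assign], medoids = medoids[ord])
}

#' Heavy-atom RMSD between two conformations of the same residue
#'
#' Root-mean-square deviation over heavy atoms paired by canonical atom
#' name, computed without re-superposition (structures are pre-aligned).
#' Atoms present in only one conformation are excluded from the pairing.
#'
#' @param a,b residue conformations: lists with `identity` (chain, resno,
#'   insert, resname), `atomNames` and `coords` (n x 3 matrix).
#' @return RMSD in Angstrom.
#' @examples
#' r <- list(identity = c("A", "1", "", "ALA"), atomNames = c("N", "CA"),
#'           coords = rbind(c(0, 0, 0), c(1, 0, 0)))
#' s <- r; s$coords <- r$coords + rep(c(1, 0, 0), each = 2)
#' heavyAtomRmsd(r, s)  # exactly 1
#' @export
heavyAtomRmsd <- function(a, b) {
  if (!identical(a$identity[["resname"]], b$identity[["resname"]]))
    stop("identity error: conformations are of different residues (",
         a$identity[["resname"]], " vs ", b$identity[["resname"]], ")")
  common <- intersect(a$atomNames, b$atomNames)
  if (length(common) == 0L)
    stop("data error: no atoms could be paired by name")
  ia <- match(common, a$atomNames)
  ib <- match(common, b$atomNames)
  d2 <- rowSums((a$coords[ia, , drop = FALSE] - b$coords[ib, , drop = FALSE])^2)
  sqrt(mean(d2))
}

#' Unweighted centroid of a set of 3-D points
#'
#' The plain arithmetic mean per coordinate, with no mass weighting: the
#' representative point used for clustering waters, pharmacophore points,
#' fragments and ligands.
#'
#' @param points numeric matrix (n x 3), n >= 1.
#' @return Numeric 3-vector.
#' @export
unweightedCentroid <- function(points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3L)
  if (nrow(points) == 0L) stop("empty input: no points to average")
  colMeans(points)
}
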