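# Chemical ordering of compounds: circular (Morgan, radius 2) fingerprints
# from Open Babel's ECFP4 implementation, folded to 2048 bits, followed by
# Butina clustering on Tanimoto distance. Butina's algorithm is implemented
# here directly (sphere exclusion on the sorted neighbour lists).

#' Morgan (circular, radius 2) fingerprints for a set of SMILES
#'
#' @param smiles character vector of SMILES strings.
#' @param nBits number of bits after folding (default 2048).
#' @return Logical matrix, one row per molecule.
#' @export
morganFingerprints <- function(smiles, nBits = 2048L) {
  stopifnot(length(smiles) >= 1L)
  src <- paste(smiles, paste0("m", seq_along(smiles)), collapse = "\n")
  mols <- ChemmineOB::forEachMol("SMILES", src, identity)
  fp <- ChemmineOB::fingerprint_OB(mols, "ECFP4")
  if (nrow(fp) != length(smiles))
    stop("featurisation error: fingerprint count mismatch")
  w <- ncol(fp)
  if (w > nBits) {
    folds <- w / nBits
    out <- matrix(FALSE, nrow(fp), nBits)
    for (k in seq_len(folds))
      out <- out | (fp[, (k - 1L) * nBits + seq_len(nBits), drop = FALSE] > 0)
  } else {
    out <- fp > 0
  }
  rownames(out) <- NULL
  out
}

#' Tanimoto similarity between two bit vectors
#' @param a,b logical vectors of equal length.
#' @return Similarity in `[0, 1]` (1 when both vectors are empty).
#' @export
tanimoto <- function(a, b) {
  u <- sum(a | b)
  if (u == 0L) return(1)
  sum(a & b) / u
}

#' Butina clustering of fingerprints at a Tanimoto distance threshold
#'
#' Classic sphere-exclusion clustering: molecules are sorted by neighbour
#' count (neighbours = within `cutoff` Tanimoto distance); the molecule with
#' most neighbours becomes a cluster centroid and claims its unassigned
#' neighbours; repeat until everything is assigned. Ties are broken by the
#' lowest input index.
#'
#' @param fps logical matrix of fingerprints (rows = molecules).
#' @param cutoff Tanimoto distance threshold (default 0.4).
#' @return Integer vector of cluster indices (1 = first-formed cluster).
#' @export
butinaCluster <- function(fps, cutoff = 0.4) {
  n <- nrow(fps)
  if (n == 1L) return(1L)
  sim <- matrix(1, n, n)
  for (i in seq_len(n - 1L))
    for (j in (i + 1L):n)
      sim[i, j] <- sim[j, i] <- tanimoto(fps[i, ], fps[j, ])
  nb <- lapply(seq_len(n), function(i)
    setdiff(which(1 - sim[i, ] <= cutoff), i))
  assigned <- rep(FALSE, n)
  cluster <- integer(n)
  cl <- 0L
  while (!all(assigned)) {
    cnt <- vapply(seq_len(n), function(i)
      if (assigned[i]) -1L else length(setdiff(nb[[i]], which(assigned))),
      integer(1))
    c0 <- which.max(cnt)                       # ties: lowest index
    cl <- cl + 1L
    mem <- c(c0, setdiff(nb[[c0]], which(assigned)))
    cluster[mem] <- cl
    assigned[mem] <- TRUE
  }
  cluster
}
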