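# Pharmacophore typing and matched-pair style fragmentation of bound
# ligands. Typing rules operate on the annotated template graph (element,
# formal charge, hydrogen count, aromaticity, ring membership) and are the
# graph-predicate form of the standard SMARTS pharmacophore definitions:
#   Donor       [$([N;!H0;v3,v4&+1]),$([O,S;H1;+0]),n&H1&+0]
#   Acceptor    [$([O,S;H1;v2;!$(*-*=[O,N,P,S])]),$([O,S;H0;v2]),$([O,S;-]),
#                $([N;v3;!$(N-*=[O,N,P,S])]),n&H0&+0,
#                $([o,s;+0;!$([o,s]:n);!$([o,s]:c:n)])]
#   Aromatic    every smallest aromatic ring, point at the ring centroid
#   Halogen     [F,Cl,Br,I]
#   RingMethyl  [CH3;!$(C=*)]-[R]
#   Hydrophobe  methyl carbon bonded to exactly one heavy neighbour, that
#               neighbour being carbon (singly substituted non-polar carbon)

.PHARMA_KINDS <- c("Donor", "Acceptor", "Aromatic", "Hydrophobe",
                   "Halogen", "RingMethyl")

# does atom i have a neighbour reached by a (Kekule) double bond to O/N/P/S?
.adjacentToHeteroDouble <- function(mol, i) {
  for (j in .neighbours(mol, i)) {
    for (k in .neighbours(mol, j)) {
      if (k == i) next
      if (mol$atoms$element[k] %in% c("O", "N", "P", "S") &&
          identical(.bondOrderBetween(mol, j, k), 2L) &&
          !mol$bonds$aromatic[(mol$bonds$i == j & mol$bonds$j == k) |
                              (mol$bonds$i == k & mol$bonds$j == j)][1L])
        return(TRUE)
    }
  }
  FALSE
}

.donorAtoms <- function(mol) {
  a <- mol$atoms
  v <- .atomValence(mol)
  isN <- a$element == "N" & !a$aromatic & a$nH > 0 &
    ((v == 3 & a$charge == 0) | (v == 4 & a$charge == 1))
  isOS <- a$element %in% c("O", "S") & !a$aromatic & a$nH == 1 & a$charge == 0
  isArN <- a$element == "N" & a$aromatic & a$nH == 1 & a$charge == 0
  which(isN | isOS | isArN)
}

.acceptorAtoms <- function(mol) {
  a <- mol$atoms
  v <- .atomValence(mol)
  out <- logical(nrow(a))
  for (i in seq_len(nrow(a))) {
    el <- a$element[i]
    if (el %in% c("O", "S") && !a$aromatic[i]) {
      if (a$charge[i] < 0) { out[i] <- TRUE; next }
      if (a$charge[i] == 0 && v[i] == 2) {
        if (a$nH[i] == 0) { out[i] <- TRUE; next }
        if (a$nH[i] == 1 && !.adjacentToHeteroDouble(mol, i)) {
          out[i] <- TRUE; next
        }
      }
    }
    if (el == "N" && !a$aromatic[i] && a$charge[i] == 0 && v[i] == 3 &&
        !.adjacentToHeteroDouble(mol, i))
      out[i] <- TRUE
    if (el == "N" && a$aromatic[i] && a$nH[i] == 0 && a$charge[i] == 0)
      out[i] <- TRUE
    if (el %in% c("O", "S") && a$aromatic[i] && a$charge[i] == 0) {
      nb <- .neighbours(mol, i)
      nbArN <- any(a$element[nb] == "N" & a$aromatic[nb])
      orthoN <- FALSE
      for (j in nb) {
        if (a$element[j] == "C" && a$aromatic[j]) {
          for (k in .neighbours(mol, j))
            if (k != i && a$element[k] == "N" && a$aromatic[k]) orthoN <- TRUE
        }
      }
      if (!nbArN && !orthoN) out[i] <- TRUE
    }
  }
  which(out)
}

.halogenAtoms <- function(mol)
  which(mol$atoms$element %in% c("F", "Cl", "Br", "I"))

.methylAtoms <- function(mol) {
  a <- mol$atoms
  which(a$element == "C" & !a$aromatic & a$nH == 3 & a$degree == 1)
}

.ringMethylAtoms <- function(mol, anyRing = TRUE) {
  out <- integer(0)
  a <- mol$atoms
  for (i in .methylAtoms(mol)) {
    nb <- .neighbours(mol, i)
    if (length(nb) != 1L) next
    ok <- if (anyRing) a$inRing[nb] else a$inRing[nb] & a$aromatic[nb]
    if (ok && identical(.bondOrderBetween(mol, i, nb), 1L)) out <- c(out, i)
  }
  out
}

.hydrophobeAtoms <- function(mol) {
  out <- integer(0)
  a <- mol$atoms
  for (i in .methylAtoms(mol)) {
    nb <- .neighbours(mol, i)
    if (length(nb) == 1L && a$element[nb] == "C" &&
        identical(.bondOrderBetween(mol, i, nb), 1L))
      out <- c(out, i)
  }
  out
}

.aromaticRings <- function(mol) {
  Filter(function(r) all(mol$atoms$aromatic[r]), mol$rings)
}

#' Detect typed pharmacophore points on a bound ligand
#'
#' Applies the six kind-specific typing rules (H-bond donor, H-bond
#' acceptor, aromatic ring, hydrophobe, halogen, ring-methyl) to the
#' template-annotated molecular graph and places each match in 3-D using
#' the crystallographic pose: atom-centred kinds at the atom position,
#' aromatic rings at the unweighted ring centroid. Matches on identical
#' atom sets are de-duplicated within a kind; an atom may carry several
#' kinds (a toluene methyl is both Hydrophobe and RingMethyl).
#'
#' @param pose a [LigandPose-class] with assigned bond orders.
#' @param ringMethylAnyRing when `TRUE` (default) a methyl on any ring atom
#'   counts as RingMethyl; when `FALSE`, aromatic rings only.
#' @return data.frame with columns `kind`, `x`, `y`, `z`, `modelId`,
#'   `atoms` (source atom indices, semicolon separated).
#' @examples
#' \donttest{
#' pose <- demoLigandPose("Oc1ccccc1")
#' detectPharmacophores(pose)
#' }
#' @export
detectPharmacophores <- function(pose, ringMethylAnyRing = TRUE) {
  mol <- pose@mol
  xyz <- as.matrix(pose@atoms[, c("x", "y", "z")])
  rows <- list()
  addAtoms <- function(kind, idx) {
    for (i in unique(idx)) {
      rows[[length(rows) + 1L]] <<- data.frame(
        kind = kind, x = xyz[i, 1L], y = xyz[i, 2L], z = xyz[i, 3L],
        modelId = pose@modelId, atoms = as.character(i),
        stringsAsFactors = FALSE)
    }
  }
  addAtoms("Donor", .donorAtoms(mol))
  addAtoms("Acceptor", .acceptorAtoms(mol))
  for (r in .aromaticRings(mol)) {
    ctr <- colMeans(xyz[r, , drop = FALSE])
    rows[[length(rows) + 1L]] <- data.frame(
      kind = "Aromatic", x = ctr[1L], y = ctr[2L], z = ctr[3L],
      modelId = pose@modelId, atoms = paste(sort(r), collapse = ";"),
      stringsAsFactors = FALSE)
  }
  addAtoms("Hydrophobe", .hydrophobeAtoms(mol))
  addAtoms("Halogen", .halogenAtoms(mol))
  addAtoms("RingMethyl", .ringMethylAtoms(mol, anyRing = ringMethylAnyRing))
  if (length(rows) == 0L)
    return(data.frame(kind = character(0), x = numeric(0), y = numeric(0),
                      z = numeric(0), modelId = character(0),
                      atoms = character(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out[!duplicated(paste(out$kind, out$atoms)), , drop = FALSE]
}

#' Fragment a bound ligand at acyclic single bonds
#'
#' Enumerates all single cuts of acyclic (non-ring) single bonds between
#' heavy atoms, emitting both resulting fragments, and all double cuts
#' (unordered pairs of such bonds), emitting the core fragment incident to
#' both cut bonds. Fragment positions are unweighted centroids of the
#' member atoms in the bound pose. A ligand with no cuttable bond yields a
#' single fragment covering the whole molecule.
#'
#' @param pose a [LigandPose-class].
#' @return data.frame with columns `fragId`, `atoms` (semicolon-separated
#'   atom indices), `nAtoms`, `nAttachment`, `x`, `y`, `z`, `modelId`.
#' @export
fragmentLigand <- function(pose) {
  mol <- pose@mol
  xyz <- as.matrix(pose@atoms[, c("x", "y", "z")])
  n <- nrow(mol$atoms)
  cut <- which(!mol$bonds$inRing & mol$bonds$order == 1L &
                 !mol$bonds$aromatic)
  mkRow <- function(idx, nAtt) {
    ctr <- colMeans(xyz[idx, , drop = FALSE])
    data.frame(atoms = paste(sort(idx), collapse = ";"),
               nAtoms = length(idx), nAttachment = nAtt,
               x = ctr[1L], y = ctr[2L], z = ctr[3L],
               modelId = pose@modelId, stringsAsFactors = FALSE)
  }
  compsAfter <- function(dropBonds) {
    keep <- setdiff(seq_len(nrow(mol$bonds)), dropBonds)
    g <- igraph::make_graph(
      edges = rbind(mol$bonds$i[keep], mol$bonds$j[keep]), n = n,
      directed = FALSE)
    split(seq_len(n), igraph::components(g)$membership)
  }
  rows <- list()
  if (length(cut) == 0L) {
    rows[[1L]] <- mkRow(seq_len(n), 0L)
  } else {
    for (b in cut) {
      cs <- compsAfter(b)
      if (all(vapply(cs, length, integer(1)) == 1L)) next  # two lone atoms
      for (cc in cs) rows[[length(rows) + 1L]] <- mkRow(cc, 1L)
    }
    if (length(cut) >= 2L) {
      prs <- utils::combn(cut, 2L)
      for (p in seq_len(ncol(prs))) {
        b1 <- prs[1L, p]; b2 <- prs[2L, p]
        cs <- compsAfter(c(b1, b2))
        e1 <- c(mol$bonds$i[b1], mol$bonds$j[b1])
        e2 <- c(mol$bonds$i[b2], mol$bonds$j[b2])
        core <- Filter(function(cc) any(e1 %in% cc) && any(e2 %in% cc), cs)
        for (cc in core) rows[[length(rows) + 1L]] <- mkRow(cc, 2L)
      }
    }
  }
  out <- do.call(rbind, rows)
  out <- cbind(fragId = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}

#' Pharmacophore points of every model in an ensemble
#'
#' @param ensemble a [StructureEnsemble-class].
#' @param ringMethylAnyRing see [detectPharmacophores()].
#' @return data.frame of all pharmacophore points with their `modelId`.
#' @export
ensemblePharmacophores <- function(ensemble, ringMethylAnyRing = TRUE) {
  do.call(rbind, c(lapply(ensemble@models, function(m)
    detectPharmacophores(m@ligand, ringMethylAnyRing)),
    make.row.names = FALSE))
}

#' Fragment poses of every model in an ensemble
#' @param ensemble a [StructureEnsemble-class].
#' @return data.frame of all fragment poses with their `modelId`.
#' @export
ensembleFragments <- function(ensemble) {
  do.call(rbind, c(lapply(ensemble@models, function(m)
    fragmentLigand(m@ligand)), make.row.names = FALSE))
}
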