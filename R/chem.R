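# Molecular graph layer: SMILES are parsed through Open Babel (via ChemmineOB)
# into an annotated heavy-atom graph. Two conversions are combined: an SDF with
# explicit hydrogens carries Kekule bond orders, formal charges and hydrogen
# counts; a MOL2 of the same molecule carries the aromaticity perception
# (SYBYL ".ar" atom types and "ar" bond records). Open Babel preserves input
# atom order in both formats, so the records align positionally.

.obConvert <- function(from, to, source, opts = NULL) {
  if (is.null(opts))
    opts <- data.frame(names = character(0), args = character(0))
  suppressWarnings(ChemmineOB::convertFormat(from, to, source, options = opts))
}

#' Parse a SMILES string into an annotated heavy-atom graph
#'
#' Builds the internal molecular-graph representation used for pharmacophore
#' typing, fragmentation and template-based bond-order assignment. Hydrogens
#' are counted and then dropped: all downstream analyses are heavy-atom only.
#'
#' @param smiles A single SMILES string with tautomer and charge state
#'   already assigned.
#' @param name Optional molecule title (used in error messages).
#' @return A list with elements `atoms` (data.frame: `element`, `charge`,
#'   `nH`, `aromatic`, `inRing`, `degree`), `bonds` (data.frame: `i`, `j`,
#'   `order`, `aromatic`, `inRing`), `rings` (list of atom-index vectors,
#'   smallest rings), `smiles` (input) and `canonical` (canonical SMILES).
#' @examples
#' m <- molFromSmiles("Oc1ccccc1")
#' m$atoms$element
#' @export
molFromSmiles <- function(smiles, name = "mol") {
  if (!is.character(smiles) || length(smiles) != 1L || !nzchar(smiles))
    stop("featurisation error: 'smiles' must be a single non-empty string (", name, ")")
  src <- paste(smiles, name)
  hopt <- data.frame(names = "h", args = "", stringsAsFactors = FALSE)
  sdf <- .obConvert("SMI", "SDF", src, hopt)
  lines <- strsplit(sdf, "\n", fixed = TRUE)[[1L]]
  if (length(lines) < 5L || !grepl("V2000", lines[4L]))
    stop("SMILES parse error for '", name, "': '", smiles, "' is not a valid SMILES")
  nat <- as.integer(substr(lines[4L], 1L, 3L))
  nbd <- as.integer(substr(lines[4L], 4L, 6L))
  if (is.na(nat) || nat < 1L)
    stop("SMILES parse error for '", name, "': no atoms")
  atl <- lines[4L + seq_len(nat)]
  element <- trimws(substr(atl, 32L, 34L))
  bdl <- if (nbd > 0L) lines[4L + nat + seq_len(nbd)] else character(0)
  bi <- as.integer(substr(bdl, 1L, 3L))
  bj <- as.integer(substr(bdl, 4L, 6L))
  bo <- as.integer(substr(bdl, 7L, 9L))
  charge <- integer(nat)
  for (cl in grep("^M  CHG", lines, value = TRUE)) {
    toks <- as.integer(strsplit(trimws(substr(cl, 7L, nchar(cl))), "\\s+")[[1L]])
    nent <- toks[1L]
    for (k in seq_len(nent)) charge[toks[2L * k]] <- toks[2L * k + 1L]
  }

  # aromaticity from the MOL2 rendering of the same molecule
  mol2 <- .obConvert("SMI", "MOL2", src, hopt)
  tf <- tempfile(fileext = ".mol2")
  on.exit(unlink(tf), add = TRUE)
  writeLines(mol2, tf)
  m2 <- bio3d::read.mol2(tf)
  if (nrow(m2$atom) != nat)
    stop("internal chemistry error: SDF/MOL2 atom count mismatch for '", name, "'")
  aromAtom <- grepl("\\.ar$", m2$atom$elety)
  aromBond <- m2$bond$type == "ar"
  # bond records are in the same order in both formats (same builder), but pair
  # them defensively by endpoint indices
  key <- function(i, j) paste(pmin(i, j), pmax(i, j))
  ab <- key(m2$bond$origin, m2$bond$target)[aromBond]
  bondArom <- key(bi, bj) %in% ab
  # any atom on an aromatic bond is aromatic even if its SYBYL type lacks .ar
  aromAtom[unique(c(bi[bondArom], bj[bondArom]))] <- TRUE

  heavy <- !(element %in% c("H", "D"))
  nH <- integer(nat)
  for (b in seq_along(bi)) {
    if (heavy[bi[b]] && !heavy[bj[b]]) nH[bi[b]] <- nH[bi[b]] + 1L
    if (heavy[bj[b]] && !heavy[bi[b]]) nH[bj[b]] <- nH[bj[b]] + 1L
  }
  idx <- cumsum(heavy)             # old index -> new heavy index
  keepB <- heavy[bi] & heavy[bj]
  atoms <- data.frame(
    element = element[heavy],
    charge = charge[heavy],
    nH = nH[heavy],
    aromatic = aromAtom[heavy],
    stringsAsFactors = FALSE
  )
  bonds <- data.frame(
    i = idx[bi[keepB]], j = idx[bj[keepB]],
    order = bo[keepB], aromatic = bondArom[keepB]
  )
  n <- nrow(atoms)
  deg <- tabulate(c(bonds$i, bonds$j), nbins = n)
  atoms$degree <- deg

  rings <- .smallestRings(n, bonds)
  inRingAtom <- logical(n)
  for (r in rings) inRingAtom[r] <- TRUE
  atoms$inRing <- inRingAtom
  ringKey <- unlist(lapply(rings, function(r) {
    s <- sort(r); paste(s[c(seq_along(s), 1L)][seq_along(s)], collapse = " ")
  }))
  bonds$inRing <- vapply(seq_len(nrow(bonds)), function(b) {
    any(vapply(rings, function(r) all(c(bonds$i[b], bonds$j[b]) %in% r) &&
                 .ringHasEdge(r, bonds$i[b], bonds$j[b]), logical(1)))
  }, logical(1))

  can <- .obConvert("SMI", "CAN", src)
  can <- strsplit(trimws(can), "[ \t]")[[1L]][1L]
  list(atoms = atoms, bonds = bonds, rings = rings,
       smiles = smiles, canonical = can)
}

# TRUE when i-j is an edge of the cyclic ordering stored in ring r
.ringHasEdge <- function(r, i, j) {
  n <- length(r)
  for (k in seq_len(n)) {
    a <- r[k]; b <- r[if (k == n) 1L else k + 1L]
    if ((a == i && b == j) || (a == j && b == i)) return(TRUE)
  }
  FALSE
}

# Smallest set of smallest rings, computed as the deduplicated set of the
# shortest cycle through every non-bridge edge. Exact for the fused ring
# systems found in drug-like molecules.
.smallestRings <- function(n, bonds) {
  if (nrow(bonds) == 0L || n < 3L) return(list())
  g <- igraph::make_graph(edges = rbind(bonds$i, bonds$j), n = n, directed = FALSE)
  br <- igraph::bridges(g)
  cyc <- setdiff(seq_len(nrow(bonds)), as.integer(br))
  rings <- list()
  seen <- character(0)
  for (e in cyc) {
    i <- bonds$i[e]; j <- bonds$j[e]
    g2 <- igraph::delete_edges(g, igraph::get_edge_ids(g, c(i, j)))
    sp <- suppressWarnings(igraph::shortest_paths(g2, from = i, to = j)$vpath[[1L]])
    if (length(sp) == 0L) next
    ring <- as.integer(sp)           # path i..j; closing edge i-j makes the cycle
    k <- paste(sort(ring), collapse = " ")
    if (!(k %in% seen)) {
      seen <- c(seen, k)
      rings[[length(rings) + 1L]] <- ring
    }
  }
  rings
}

#' Canonical SMILES of a molecule
#' @param smiles SMILES string.
#' @return Canonical SMILES string.
#' @export
canonicalSmiles <- function(smiles) {
  molFromSmiles(smiles)$canonical
}

# total valence (sum of bond orders + hydrogens) per heavy atom; aromatic
# bonds contribute their Kekule order, which the SDF rendering provides
.atomValence <- function(mol) {
  v <- mol$atoms$nH
  for (b in seq_len(nrow(mol$bonds))) {
    v[mol$bonds$i[b]] <- v[mol$bonds$i[b]] + mol$bonds$order[b]
    v[mol$bonds$j[b]] <- v[mol$bonds$j[b]] + mol$bonds$order[b]
  }
  v
}

.neighbours <- function(mol, i) {
  c(mol$bonds$j[mol$bonds$i == i], mol$bonds$i[mol$bonds$j == i])
}

.bondOrderBetween <- function(mol, i, j) {
  hit <- (mol$bonds$i == i & mol$bonds$j == j) | (mol$bonds$i == j & mol$bonds$j == i)
  if (!any(hit)) return(NA_integer_)
  mol$bonds$order[which(hit)[1L]]
}

# covalent radii (Angstrom) used for distance-based bond perception on
# crystallographic coordinates that lack CONECT records
.covalentRadius <- function(element) {
  tab <- c(H = 0.31, D = 0.31, B = 0.84, C = 0.76, N = 0.71, O = 0.66,
           F = 0.57, Si = 1.11, P = 1.07, S = 1.05, Cl = 1.02, Se = 1.20,
           Br = 1.20, I = 1.39)
  r <- tab[element]
  r[is.na(r)] <- 1.5
  unname(r)
}

# bond perception from interatomic distances: covalent radii sum + tolerance
.inferBonds <- function(coords, elements, tol = 0.45) {
  n <- nrow(coords)
  if (n < 2L) return(data.frame(i = integer(0), j = integer(0)))
  rad <- .covalentRadius(elements)
  ii <- jj <- integer(0)
  for (a in seq_len(n - 1L)) {
    d <- sqrt(colSums((t(coords[(a + 1L):n, , drop = FALSE]) - coords[a, ])^2))
    hit <- which(d <= rad[a] + rad[(a + 1L):n] + tol & d > 0.4)
    if (length(hit)) {
      ii <- c(ii, rep.int(a, length(hit)))
      jj <- c(jj, a + hit)
    }
  }
  data.frame(i = ii, j = jj)
}
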