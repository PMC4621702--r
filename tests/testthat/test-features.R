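test_that("panel pharmacophore counts equal the hand-derived table", {
  panel <- panelMolecules()
  kinds <- c("Donor", "Acceptor", "Aromatic", "Hydrophobe", "Halogen",
             "RingMethyl")
  for (r in seq_len(nrow(panel))) {
    got <- pharmaCountsFor(panel$smiles[r], panel$name[r])
    expect_equal(got, unlist(panel[r, kinds], use.names = FALSE),
                 info = panel$name[r])
  }
})

test_that("pharmacophore points are placed on their source atoms", {
  pose <- demoLigandPose("Oc1ccccc1", modelId = "ph")
  ph <- detectPharmacophores(pose)
  oPos <- unlist(pose@atoms[pose@atoms$element == "O", c("x", "y", "z")])
  for (k in c("Donor", "Acceptor")) {
    p <- ph[ph$kind == k, ]
    expect_equal(c(p$x, p$y, p$z), unname(oPos))
  }
  # aromatic point at the ring centroid
  ring <- pose@mol$rings[[1]]
  ctr <- colMeans(as.matrix(pose@atoms[ring, c("x", "y", "z")]))
  ar <- ph[ph$kind == "Aromatic", ]
  expect_equal(c(ar$x, ar$y, ar$z), unname(ctr))
  # all points inside the ligand's bounding box
  for (pose2 in list(pose, demoLigandPose("Cc1ccc(Cl)cc1", "ct"))) {
    pp <- detectPharmacophores(pose2)
    for (ax in c("x", "y", "z")) {
      expect_true(all(pp[[ax] ] >= min(pose2@atoms[[ax]]) - 1e-9))
      expect_true(all(pp[[ax] ] <= max(pose2@atoms[[ax]]) + 1e-9))
    }
  }
})

test_that("detection is a pure function of graph and coordinates", {
  a <- detectPharmacophores(demoLigandPose("Cc1ccccc1", "m1"))
  b <- detectPharmacophores(demoLigandPose("Cc1ccccc1", "m1"))
  expect_identical(a, b)
  # a methyl on a ring is both RingMethyl and Hydrophobe at the same atom
  expect_setequal(a$kind[a$atoms == a$atoms[a$kind == "RingMethyl"]],
                  c("RingMethyl", "Hydrophobe"))
})

test_that("single cuts partition the ligand atom set", {
  for (smi in c("CCOc1ccccc1", "CC(=O)Nc1ccccc1", "CCCC")) {
    pose <- demoLigandPose(smi, "f")
    fr <- fragmentLigand(pose)
    singles <- fr[fr$nAttachment == 1L, ]
    n <- nrow(pose@atoms)
    # single-cut fragments come in complementary pairs
    expect_true(nrow(singles) %% 2 == 0)
    sets <- lapply(strsplit(singles$atoms, ";"), as.integer)
    sizes <- vapply(sets, length, integer(1))
    for (i in seq(1, nrow(singles), by = 2))
      expect_setequal(c(sets[[i]], sets[[i + 1]]), seq_len(n))
  }
})

test_that("fragment enumeration matches brute force on n-butane", {
  pose <- demoLigandPose("CCCC", "bu")
  fr <- fragmentLigand(pose)
  # brute-force oracle: enumerate subsets of size <= 2 of the 3 acyclic
  # C-C bonds and collect side fragments (single cuts) and the middle
  # component (double cuts)
  bonds <- list(c(1, 2), c(2, 3), c(3, 4))
  compsOf <- function(drop) {
    g <- igraph::make_graph(
      edges = unlist(bonds[setdiff(1:3, drop)]), n = 4, directed = FALSE)
    split(1:4, igraph::components(g)$membership)
  }
  singles <- list(); cores <- list()
  for (b in 1:3)
    singles <- c(singles, compsOf(b))
  for (p in list(c(1, 2), c(1, 3), c(2, 3))) {
    cs <- compsOf(p)
    touch <- vapply(cs, function(cc)
      any(unlist(bonds[p[1]]) %in% cc) && any(unlist(bonds[p[2]]) %in% cc),
      logical(1))
    cores <- c(cores, cs[touch])
  }
  expect_equal(sum(fr$nAttachment == 1L), length(singles))   # 6
  expect_equal(sum(fr$nAttachment == 2L), length(cores))     # 3
  key <- function(s) vapply(s, function(x) paste(sort(x), collapse = ";"),
                            character(1))
  expect_setequal(fr$atoms[fr$nAttachment == 2L], key(cores))
})

test_that("a ring with no cuttable bond is one whole-ligand fragment", {
  fr <- fragmentLigand(demoLigandPose("c1ccccc1", "bz"))
  expect_equal(nrow(fr), 1L)
  expect_equal(fr$nAttachment, 0L)
  expect_equal(fr$nAtoms, 6L)
  # fragment centres sit at member centroids in the bound pose
  pose <- demoLigandPose("CCO", "eth")
  fr2 <- fragmentLigand(pose)
  whole <- fr2[fr2$nAtoms == 2 & fr2$nAttachment == 1L, ][1, ]
  idx <- as.integer(strsplit(whole$atoms, ";")[[1]])
  expect_equal(c(whole$x, whole$y, whole$z),
               unname(colMeans(as.matrix(pose@atoms[idx, c("x", "y", "z")]))))
})
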