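test_that("ligand site clustering flags the most populated site as main", {
  # two ligands 3 A apart: a single site
  e <- ensembleOf(makeModel("a"), makeModel("b", shift = c(3, 0, 0)))
  s <- clusterLigandSites(e)
  expect_equal(nrow(s$sites), 1L)
  expect_true(s$sites$isMain)
  # five ligands in one pocket, one 15 A away: two sites, majority main
  mods <- c(lapply(1:5, function(i)
    makeModel(sprintf("p%d", i), shift = c(0.2 * i, 0, 0))),
    list(makeModel("allo", shift = c(15, 0, 0))))
  e2 <- do.call(ensembleOf, mods)
  s2 <- clusterLigandSites(e2)
  expect_equal(nrow(s2$sites), 2L)
  expect_equal(s2$sites$size[s2$sites$isMain], 5L)
  expect_false("allo" %in% s2$members[[which(s2$sites$isMain)]])
  # a single model is its own main site
  s3 <- clusterLigandSites(ensembleOf(makeModel("solo")))
  expect_true(s3$sites$isMain)
})

test_that("water conservation counts distinct models", {
  # four models; one contributes two waters to the same cluster
  e <- ensembleOf(
    makeModel("m1", waterPts = c(0, 10, 0, 0.3, 10, 0)),   # two waters
    makeModel("m2", waterPts = c(0.1, 10, 0)),
    makeModel("m3"), makeModel("m4"))
  wc <- clusterWaters(e)
  tab <- clusterTable(wc)
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$size, 3L)        # three waters...
  expect_equal(tab$nModels, 2L)     # ...from two distinct models
  expect_equal(tab$conservation, 0.5)
  # fully conserved cluster over all models
  e2 <- do.call(ensembleOf, lapply(sprintf("w%02d", 1:10), function(id)
    makeModel(id, waterPts = c(4.1, 0, 0) + runif(3, -0.15, 0.15))))
  t2 <- clusterTable(clusterWaters(e2))
  expect_equal(t2$conservation, 1.0)
})

test_that("site-water filtering applies contact and strict conservation", {
  mods <- lapply(sprintf("m%d", 1:10), function(id) makeModel(id))
  # phenol O tip is at (2.75, 0, 0); put one cluster 1.4 A from it,
  # another far away
  near <- c(2.75, 1.4, 0); far <- c(2.75, 8, 0)
  for (i in 1:9) mods[[i]]@waters <- rbind(near + 0.01 * i, far)
  mods[[10]]@waters <- matrix(far, 1)
  e <- do.call(ensembleOf, mods)
  wc <- clusterWaters(e)
  ids <- sprintf("m%d", 1:10)
  # conservation 0.9 > 0.85 and within 1.5 A: kept
  kept <- filterSiteWaters(wc, e, ids, contact = 1.5,
                           minConservation = 0.85)
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$conservation, 0.9)
  # the boundary is strict: conservation 0.9 at threshold 0.9 is dropped
  expect_equal(nrow(filterSiteWaters(wc, e, ids, minConservation = 0.9)), 0L)
  # the far cluster fails the contact test even at full conservation
  expect_false(any(abs(filterSiteWaters(wc, e, ids)$y - 8) < 1))
})

test_that("displacement is the exact complement of contribution", {
  mods <- lapply(sprintf("m%d", 1:6), function(id) makeModel(id))
  for (i in 1:6)
    if (i != 3) mods[[i]]@waters <- matrix(c(2.75, 1.4, 0) + 0.01 * i, 1)
  e <- do.call(ensembleOf, mods)
  wc <- clusterWaters(e)
  ids <- sprintf("m%d", 1:6)
  sw <- filterSiteWaters(wc, e, ids)
  disp <- waterDisplacementMatrix(sw, wc, ids)
  expect_equal(dim(disp), c(1L, 6L))
  expect_equal(unname(disp[1, ]), ids == "m3")
  # duality: displaced XOR present, for every cell
  contrib <- unique(wc@members[[sw$clusterRank[1]]]$modelId)
  expect_true(all(xor(disp[1, ], ids %in% contrib)))
})

test_that("pharmacophore grids separate kinds and expose missing features", {
  # four phenols sharing O position and one benzene lacking it
  mods <- c(lapply(sprintf("p%d", 1:4), function(id)
    makeModel(id, "Oc1ccccc1", shift = c(0, 0, 0.05 * as.integer(substr(id, 2, 2))))),
    list(makeModel("bz", "c1ccccc1")))
  e <- do.call(ensembleOf, mods)
  pts <- ensemblePharmacophores(e)
  ids <- c(sprintf("p%d", 1:4), "bz")
  ph <- pharmacophorePresenceMatrix(pts, ids)
  # aromatic cluster covers everyone; acceptor/donor rows have exactly one
  # white cell (the benzene column)
  arom <- which(ph$clusters$kind == "Aromatic")
  expect_equal(ph$clusters$conservation[arom], 1.0)
  acc <- which(ph$clusters$kind == "Acceptor")
  expect_equal(sum(!ph$presence[acc, ]), 1L)
  expect_false(ph$presence[acc, "bz"])
  # rows are sorted by cluster size, descending
  expect_true(all(diff(ph$clusters$size) <= 0))
  # coincident points of different kinds never co-cluster
  expect_true(all(table(ph$clusters$kind)[c("Donor", "Acceptor")] == 1))
  dn <- which(ph$clusters$kind == "Donor")
  expect_equal(ph$clusters[dn, c("x", "y", "z")],
               ph$clusters[acc, c("x", "y", "z")],
               ignore_attr = TRUE)
})

test_that("residue ranking respects the contact cutoff and RMSD order", {
  # mobile residue near the ligand, rigid residue near it, distant residue
  near1 <- function(z) conf(rbind(c(0, 4.5, 0), c(0, 5.5, z)),
                            names = c("CB", "CG"), resname = "TYR")
  rigid <- conf(rbind(c(4, 2, 0)), names = "CB", resname = "ASN")
  rigid$identity[["resno"]] <- "2"
  # distant residue: closest approach to any ligand atom is 5.3 A -> excluded
  distant <- conf(rbind(c(0, -6.5, 0)), names = "CB", resname = "SER")
  distant$identity[["resno"]] <- "3"
  mods <- lapply(1:6, function(i) {
    res <- list("A|1||TYR" = near1(if (i <= 2) 4 else -4),
                "A|2||ASN" = rigid, "A|3||SER" = distant)
    makeModel(sprintf("m%d", i), residues = res)
  })
  e <- do.call(ensembleOf, mods)
  rk <- bindingSiteResidues(e, sprintf("m%d", 1:6))
  expect_equal(nrow(rk$ranking), 2L)
  expect_false("A|3||SER" %in% rk$ranking$residue)
  # mobile residue first with a 4/2 split; rigid residue last at zero RMSD
  expect_equal(rk$ranking$residue[1], "A|1||TYR")
  expect_equal(rk$ranking$clusterSizes[1], "4/2")
  expect_equal(rk$ranking$maxRmsd[2], 0)
  expect_true(all(diff(rk$ranking$maxRmsd) <= 0))
  # per-model assignments cover every model for each ranked residue
  expect_equal(sort(unique(rk$assignments$modelId)), sprintf("m%d", 1:6))
})

test_that("chemical ordering groups chemotypes, larger cluster first", {
  mods <- c(lapply(c("a1", "a2", "a3"), function(id)
    makeModel(id, "Oc1ccccc1")),
    lapply(c("b1", "b2"), function(id) makeModel(id, "CCCCO")))
  e <- do.call(ensembleOf, mods)
  ord <- orderCompoundsChemically(e)
  expect_equal(ord, c("a1", "a2", "a3", "b1", "b2"))
  # identical SMILES: one cluster, modelId order
  e2 <- ensembleOf(makeModel("z2", "CCO"), makeModel("z1", "CCO"))
  expect_equal(orderCompoundsChemically(e2), c("z1", "z2"))
})

test_that("analysing the main site equals the default bundle", {
  d <- withr::local_tempdir()
  gen <- generateEnsemble(defaultDemoSpec(seed = 3), d)
  e <- readEnsemble(gen$manifest)
  cfg <- runConfig()
  a <- summariseEnsemble(e, cfg)
  b <- analyseSite(e, "main", cfg)
  expect_equal(a@siteWaters, b@siteWaters)
  expect_equal(a@displacement, b@displacement)
  expect_equal(a@presence, b@presence)
  expect_equal(a@residueRanking, b@residueRanking)
})
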