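test_that("the generator is deterministic for a fixed seed", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  g1 <- generateEnsemble(defaultDemoSpec(seed = 17), d1)
  g2 <- generateEnsemble(defaultDemoSpec(seed = 17), d2)
  for (f in c(basename(g1$pdbs), "manifest.csv", "truth.json"))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), info = f)
  # a different seed moves the jitter
  g3 <- generateEnsemble(defaultDemoSpec(seed = 18),
                         withr::local_tempdir())
  expect_false(identical(readLines(g1$pdbs[1]), readLines(g3$pdbs[1])))
})

test_that("the demo spec plants the documented study conditions", {
  spec <- defaultDemoSpec()
  expect_equal(spec$nModels, 20L)
  expect_equal(nrow(spec$waterSites), 5L)
  expect_equal(sort(spec$waterSites$conservation),
               c(0.30, 0.60, 0.90, 0.95, 1.00))
  expect_equal(spec$rotamerMinoritySize, 6L)
  expect_equal(length(unique(spec$ligands$smiles)), 2L)
  d <- withr::local_tempdir()
  g <- generateEnsemble(spec, d)
  # four ligand-proximal pocket sites; exactly one unique displacement
  expect_equal(length(g$truth$ligandProximal), 4L)
  expect_equal(g$truth$uniqueDisplacement$model, "m07")
  expect_equal(g$truth$rotamer$sizes, c(14L, 6L))
  expect_gt(g$truth$rotamer$interRmsd, 4)
  # planted conservations are exact fractions of the ensemble
  cons <- vapply(g$truth$waterClusters, `[[`, numeric(1), "conservation")
  expect_equal(sort(cons), c(0.30, 0.60, 0.90, 0.95, 1.00))
})

test_that("generated ensembles round-trip through the loader cleanly", {
  d <- withr::local_tempdir()
  g <- generateEnsemble(defaultDemoSpec(seed = 29), d)
  expect_no_warning(e <- readEnsemble(g$manifest))
  expect_equal(nModels(e), 20L)
  expect_equal(modelIds(e), g$truth$modelIds)
  # waters per model match the planted contributor sets plus decoys
  for (i in c(1L, 7L, 20L)) {
    id <- sprintf("m%02d", i)
    planted <- sum(vapply(g$truth$waterClusters, function(w)
      id %in% w$models, logical(1)))
    m <- e@models[[match(id, modelIds(e))]]
    expect_equal(nrow(waters(m)), planted + 2L, info = id)
  }
  # every ligand pose carries its template chemistry
  expect_equal(ligand(e@models[[1]])@smiles, canonicalSmiles("Oc1ccccc1"))
  expect_equal(ligand(e@models[[2]])@smiles, canonicalSmiles("Clc1ccccc1"))
})

test_that("infeasible specs are rejected before any file is written", {
  spec <- defaultDemoSpec()
  spec$waterSites$conservation[1] <- 1.2
  expect_error(generateEnsemble(spec, withr::local_tempdir()), "conservation")
  spec2 <- defaultDemoSpec()
  spec2$waterSites$x[2] <- spec2$waterSites$x[1]     # collapse separations
  spec2$waterSites$y[2] <- spec2$waterSites$y[1]
  spec2$waterSites$z[2] <- spec2$waterSites$z[1] - 1
  d <- withr::local_tempdir()
  expect_error(generateEnsemble(spec2, d), "separated")
  spec3 <- defaultDemoSpec()
  spec3$waterSites$sigma <- 0.6                      # jitter too wide
  expect_error(generateEnsemble(spec3, d), "sigma")
})
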