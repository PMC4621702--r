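test_that("SMILES parse into annotated heavy-atom graphs", {
  m <- molFromSmiles("Oc1ccccc1")
  expect_equal(m$atoms$element, c("O", rep("C", 6)))
  expect_equal(sum(m$atoms$aromatic), 6L)
  expect_equal(m$atoms$nH[1], 1L)           # the hydroxyl
  expect_equal(length(m$rings), 1L)
  expect_equal(sort(m$rings[[1]]), 2:7)
  expect_true(all(m$atoms$inRing[2:7]))
  expect_false(m$atoms$inRing[1])
  # formal charges survive
  ac <- molFromSmiles("CC(=O)[O-]")
  expect_equal(ac$atoms$charge, c(0, 0, 0, -1))
  # invalid input is a clean error naming the molecule
  expect_error(molFromSmiles("not_a_smiles", name = "row3"), "row3")
})

test_that("fused aromatic systems yield one ring per smallest cycle", {
  m <- molFromSmiles("c1ccc2ccccc2c1")     # naphthalene
  expect_equal(length(m$rings), 2L)
  expect_true(all(vapply(m$rings, length, integer(1)) == 6L))
  expect_true(all(m$atoms$aromatic))
})

test_that("canonical SMILES is stable across input spellings", {
  expect_identical(canonicalSmiles("OCC"), canonicalSmiles("CCO"))
  expect_identical(canonicalSmiles("c1ccccc1O"), canonicalSmiles("Oc1ccccc1"))
})
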