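test_that("fingerprints separate chemotypes and are spelling-invariant", {
  fp <- morganFingerprints(c("CCO", "OCC", "c1ccccc1", "CCCO"))
  expect_equal(ncol(fp), 2048L)
  expect_identical(fp[1, ], fp[2, ])               # same molecule
  expect_gt(tanimoto(fp[1, ], fp[4, ]),            # alcohols resemble
            tanimoto(fp[1, ], fp[3, ]))            # ... benzene less
})

test_that("tanimoto is bounded and handles the empty case", {
  expect_equal(tanimoto(c(TRUE, FALSE), c(TRUE, FALSE)), 1)
  expect_equal(tanimoto(c(TRUE, FALSE), c(FALSE, TRUE)), 0)
  expect_equal(tanimoto(logical(3), logical(3)), 1)
})

test_that("Butina clusters by sphere exclusion and size", {
  # hand-built fingerprints with a known neighbour structure at cutoff
  # 0.45: {A1,A2,A3} (A1 the best-connected centroid), {B1,B2}, {C}
  fp <- rbind(
    A1 = c(1, 1, 0, 0, 0, 0, 0, 0),
    A2 = c(1, 1, 1, 0, 0, 0, 0, 0),
    A3 = c(1, 1, 0, 1, 0, 0, 0, 0),
    B1 = c(0, 0, 0, 0, 1, 1, 0, 0),
    B2 = c(0, 0, 0, 0, 1, 1, 1, 0),
    C  = c(0, 0, 0, 0, 0, 0, 0, 1)) > 0
  cl <- butinaCluster(fp, cutoff = 0.45)
  expect_equal(unname(cl), c(1L, 1L, 1L, 2L, 2L, 3L))
  expect_equal(butinaCluster(fp[1, , drop = FALSE]), 1L)   # singleton
  # identical molecules always share a cluster
  fp2 <- morganFingerprints(c("CCO", "OCC", "c1ccccc1"))
  cl2 <- butinaCluster(fp2, cutoff = 0.4)
  expect_equal(cl2[1], cl2[2])
  expect_false(cl2[1] == cl2[3])
})
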