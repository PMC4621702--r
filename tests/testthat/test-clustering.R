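test_that("dpMeans handles the elementary geometries", {
  # two points within lambda of their mean: one cluster at the midpoint
  cs <- dpMeans(rbind(c(0, 0, 0), c(0.5, 0, 0)), c("a", "b"), lam = 1.5)
  expect_equal(nrow(clusterTable(cs)), 1L)
  expect_equal(unlist(clusterTable(cs)[1, c("x", "y", "z")],
                      use.names = FALSE), c(0.25, 0, 0))
  # separation beyond lambda forces a spawn
  cs2 <- dpMeans(rbind(c(0, 0, 0), c(4, 0, 0)), c("a", "b"), lam = 1.5)
  expect_equal(nrow(clusterTable(cs2)), 2L)
  expect_equal(clusterTable(cs2)$size, c(1L, 1L))
  # vacuous case
  cs3 <- dpMeans(matrix(numeric(0), 0, 3), character(0), lam = 1.5)
  expect_equal(nrow(clusterTable(cs3)), 0L)
  # invalid penalty
  expect_error(dpMeans(rbind(c(0, 0, 0)), "a", lam = 0), "parameter")
})

test_that("dpMeans recovers well-separated planted components", {
  centres <- rbind(c(0, 0, 0), c(8, 0, 0), c(0, 8, 8))
  set.seed(401)
  lab <- sample(1:3, 60, replace = TRUE)
  X <- centres[lab, ] + matrix(rnorm(180, sd = 0.3), 60, 3)
  cs <- dpMeans(X, paste0("m", 1:60), lam = 1.5)
  expect_equal(nrow(clusterTable(cs)), 3L)
  # membership equals the nearest-generating-centre labelling
  oracle <- nearestCentreLabels(X, centres)
  got <- integer(60)
  for (k in seq_along(cs@members)) {
    idx <- match(cs@members[[k]]$modelId, paste0("m", 1:60))
    got[idx] <- k
  }
  expect_true(samePartition(got, oracle))
})

test_that("every member lies within lambda of its centre (fixed point)", {
  set.seed(77)
  for (rep in 1:20) {
    n <- sample(10:120, 1)
    X <- matrix(runif(3 * n, 0, 12), n, 3)
    lam <- sample(c(1.5, 2.0, 2.5, 5.0), 1)
    cs <- dpMeans(X, paste0("m", seq_len(n)), lam)
    tab <- clusterTable(cs)
    for (k in seq_len(nrow(tab))) {
      m <- cs@members[[k]]
      d <- sqrt((m$x - tab$x[k])^2 + (m$y - tab$y[k])^2 + (m$z - tab$z[k])^2)
      expect_true(all(d <= lam + 1e-9))
    }
    expect_equal(sum(tab$size), n)
  }
})

test_that("partition is input-order invariant for well-separated clusters", {
  set.seed(555)
  centres <- rbind(c(0, 0, 0), c(7, 0, 0), c(0, 7, 0), c(7, 7, 7))
  lam <- 2.0
  lab <- rep(1:4, each = 15)
  X <- centres[lab, ] + matrix(runif(180, -lam / 3 / sqrt(3),
                                     lam / 3 / sqrt(3)), 60, 3)
  ids <- sprintf("p%02d", 1:60)
  base <- dpMeans(X, ids, lam)
  baseAssign <- integer(60)
  for (k in seq_along(base@members))
    baseAssign[match(base@members[[k]]$modelId, ids)] <- k
  for (rep in 1:5) {
    perm <- sample(60)
    cs <- dpMeans(X[perm, ], ids[perm], lam)
    got <- integer(60)
    for (k in seq_along(cs@members))
      got[match(cs@members[[k]]$modelId, ids)] <- k
    expect_true(samePartition(got, baseAssign))
  }
})

test_that("limiting penalties give one cluster and all singletons", {
  set.seed(12)
  X <- matrix(runif(90, 0, 50), 30, 3)
  one <- dpMeans(X, paste0("m", 1:30), lam = 1e6)
  expect_equal(nrow(clusterTable(one)), 1L)
  sing <- dpMeans(X, paste0("m", 1:30), lam = 1e-6)
  expect_equal(nrow(clusterTable(sing)), 30L)
})

test_that("dpMeansMedoid matches its contract on small cases", {
  # identity
  r1 <- dpMeansMedoid(matrix(0, 1, 1), lam = 2.5)
  expect_equal(r1$assign, 1L)
  expect_equal(r1$medoids, 1L)
  # two items beyond lambda
  D <- matrix(c(0, 4, 4, 0), 2, 2)
  r2 <- dpMeansMedoid(D, lam = 2.5)
  expect_equal(length(r2$medoids), 2L)
  # two tight blocks
  pos <- c(0, 0.3, 0.5, 10, 10.2, 10.4)
  D6 <- as.matrix(dist(pos))
  r3 <- dpMeansMedoid(D6, lam = 2.5)
  expect_equal(length(r3$medoids), 2L)
  expect_true(samePartition(r3$assign, rep(1:2, each = 3)))
  # the block partition is a brute-force-valid fixed point and ours
  valid <- validMedoidPartitions(D6, 2.5)
  expect_true(any(vapply(valid, samePartition, logical(1), b = r3$assign)))
  # malformed inputs
  expect_error(dpMeansMedoid(matrix(c(0, 1, 2, 0), 2, 2), 2.5), "symmetric")
})

test_that("heavy-atom RMSD follows its closed forms", {
  a <- conf(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)))
  expect_identical(heavyAtomRmsd(a, a), 0)
  b <- a
  b$coords <- a$coords + rep(c(1, 0, 0), each = 3)
  expect_equal(heavyAtomRmsd(a, b), 1.0)
  # displacements 0, 0, 3 -> sqrt(3)
  c3 <- a
  c3$coords[3, ] <- c3$coords[3, ] + c(0, 3, 0)
  expect_equal(heavyAtomRmsd(a, c3), sqrt(3), tolerance = 1e-12)
  # atoms are paired by name: extra atoms in one conformation are ignored
  d <- conf(rbind(c(0, 0, 0), c(1, 0, 0)), names = c("A1", "A2"))
  expect_equal(heavyAtomRmsd(a, d), 0)
  # different residues cannot be compared
  e <- conf(a$coords, resname = "TYR")
  expect_error(heavyAtomRmsd(a, e), "identity")
  # disjoint atom names
  f <- conf(a$coords, names = c("X1", "X2", "X3"))
  expect_error(heavyAtomRmsd(a, f), "paired")
})

test_that("unweightedCentroid is the plain coordinate mean", {
  expect_equal(unweightedCentroid(rbind(c(0, 0, 0))), c(0, 0, 0))
  expect_equal(unweightedCentroid(rbind(c(0, 0, 0), c(2, 0, 0))), c(1, 0, 0))
  expect_equal(unweightedCentroid(rbind(c(1, 1, 1), c(2, 2, 2), c(3, 3, 3))),
               c(2, 2, 2))
  expect_error(unweightedCentroid(matrix(numeric(0), 0, 3)), "empty")
})
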