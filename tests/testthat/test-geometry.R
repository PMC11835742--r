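test_that("geometry generation is deterministic per seed", {
  g1 <- generateGeometry(50, seed = 1)
  g2 <- generateGeometry(50, seed = 1)
  expect_identical(coords(g1), coords(g2))
  expect_identical(rsnLabels(g1), rsnLabels(g2))
  g3 <- generateGeometry(50, seed = 2)
  expect_false(identical(coords(g1), coords(g3)))
})

test_that("centroid spacing and extent respect construction bounds", {
  g <- generateGeometry(100, seed = 1)
  d <- distances(g)[upper.tri(distances(g))]
  expect_true(all(d >= 3))
  expect_true(all(d <= 200))
})

test_that("stored distances equal a brute-force double loop", {
  g <- generateGeometry(40, seed = 3)
  xy <- coords(g)
  n <- nrow(xy)
  ref <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    ref[i, j] <- sqrt(sum((xy[i, ] - xy[j, ])^2))
  expect_lt(max(abs(ref - distances(g))), 1e-9)
})

test_that("RSN labels form a partition drawn from the canonical names", {
  g <- generateGeometry(80, seed = 4)
  expect_true(all(rsnLabels(g) %in%
    c("CON", "DMN", "TP", "VIS", "SOM", "ATT", "SAL", "LIM")))
  expect_length(rsnLabels(g), 80)
  expect_gte(length(unique(rsnLabels(g))), 7L)
})

test_that("impossible spacing requests fail explicitly", {
  expect_error(generateGeometry(50, seed = 1, minSpacing = 100),
    "could not place")
})

test_that("ParcelGeometry validity rejects inconsistent distance matrices", {
  xy <- matrix(rnorm(30), 10, 3)
  expect_error(new("ParcelGeometry", coords = xy,
    dist = matrix(1, 10, 10), rsnLabels = rep("NA", 10)))
})

test_that("EDR connectome matches the closed-form kernel", {
  g <- line_geometry(12, step = 10)   # distances exactly 10, 20, ... mm
  w <- generateConnectome(g, edrDecay = 0.18, nLongrange = 0L)
  expect_equal(w[1, 2], exp(-1.8), tolerance = 1e-12)
  expect_equal(w, t(w))
  expect_true(all(diag(w) == 0))
  expect_equal(w[upper.tri(w)],
    exp(-0.18 * distances(g))[upper.tri(w)], tolerance = 1e-12)
})

test_that("long-range boosts raise only distant pairs, capped at 1", {
  g <- generateGeometry(60, seed = 5)
  w0 <- generateConnectome(g, nLongrange = 0L, seed = 9)
  w <- generateConnectome(g, nLongrange = 15L, seed = 9)
  changed <- which(abs(w - w0) > 0, arr.ind = TRUE)
  changed <- changed[changed[, 1] < changed[, 2], , drop = FALSE]
  expect_equal(nrow(changed), 15L)
  d <- distances(g)[changed]
  expect_true(all(d > 40))
  expect_true(all(w[changed] >= 0.5 & w[changed] <= 1))
  expect_true(max(w) <= 1)
})

test_that("coupling merges a connectome by elementwise maximum", {
  g <- line_geometry(10, step = 8)
  conn <- matrix(0, 10, 10)
  conn[1, 10] <- conn[10, 1] <- 0.9    # EDR at 72 mm is ~2e-6
  cpl <- buildCoupling(g, conn, edrDecay = 0.18)
  expect_equal(couplingMatrix(cpl)[1, 10], 0.9)
  expect_equal(couplingMatrix(cpl)[1, 2], exp(-0.18 * 8), tolerance = 1e-12)
  # no connectome: pure EDR kernel
  cpl0 <- buildCoupling(g, NULL, edrDecay = 0.18)
  expect_equal(couplingMatrix(cpl0)[upper.tri(diag(10))],
    exp(-0.18 * distances(g))[upper.tri(diag(10))], tolerance = 1e-12)
  expect_equal(couplingMatrix(cpl0)[1, 1], 0)
})

test_that("asymmetric connectomes are rejected", {
  g <- line_geometry(6)
  conn <- matrix(runif(36), 6, 6)
  expect_error(buildCoupling(g, conn), "symmetric")
})
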