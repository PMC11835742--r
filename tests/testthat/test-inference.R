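# Permutation rank-sum inference, effect sizes, FDR, node-level analysis.

test_that("permutation rank-sum p-values follow the add-one convention", {
  x <- c(1.3, 2.2, 0.8, 4.1, 2.0)
  expect_equal(permRanksum(x, x, nPerm = 500, seed = 3), 1)
  # fully separated groups attain the minimum p
  expect_equal(permRanksum(1:10 + 100, 1:10, nPerm = 1000, seed = 4),
    1 / 1001)
  expect_error(permRanksum(rep(1, 5), rep(1, 5)), "constant")
})

test_that("permutation p agrees with exact enumeration at n = 4 + 4", {
  x <- c(1.2, 3.4, 0.5, 2.2)
  y <- c(2.9, 4.1, 3.3, 1.9)
  r <- rank(c(x, y)); e0 <- 4 * 9 / 2
  cmb <- combn(8, 4)
  t_all <- abs(colSums(matrix(r[cmb], 4)) - e0)
  p_exact <- mean(t_all >= abs(sum(r[1:4]) - e0) - 1e-12)
  p_perm <- permRanksum(x, y, nPerm = 1000, seed = 5)
  expect_lt(abs(p_perm - p_exact), 2 / sqrt(1000))
})

test_that("Cohen's d matches hand computations and is antisymmetric", {
  expect_equal(cohensD(c(1, 2, 3), c(3, 4, 5)), -2)
  expect_equal(cohensD(c(1, 2, 3), c(1, 2, 3)), 0)
  set.seed(6)
  x <- rnorm(10); y <- rnorm(12)
  expect_equal(cohensD(x, y), -cohensD(y, x), tolerance = 1e-12)
  expect_error(cohensD(rep(2, 4), rep(2, 4)), "variance")
})

test_that("BH adjustment matches hand values and a step-up oracle", {
  got <- fdrBH(c(0.01, 0.02, 0.03, 0.04))
  expect_equal(got$adjusted, rep(0.04, 4), tolerance = 1e-12)
  expect_equal(fdrBH(0.3)$adjusted, 0.3)
  # independent literal step-up implementation on random vectors
  bh_ref <- function(p) {
    m <- length(p)
    o <- order(p)
    adj_sorted <- numeric(m)
    for (i in seq_len(m)) {
      vals <- vapply(i:m, function(j) m * p[o[j]] / j, 0)
      adj_sorted[i] <- min(1, min(vals))
    }
    adj <- numeric(m); adj[o] <- adj_sorted
    adj
  }
  set.seed(7)
  for (k in 1:100) {
    p <- runif(sample(3:40, 1))
    expect_equal(fdrBH(p)$adjusted, bh_ref(p), tolerance = 1e-12)
  }
  # monotone in the sorted order
  p <- runif(25)
  adj <- fdrBH(p)$adjusted
  expect_true(!is.unsorted(adj[order(p)]))
  expect_error(fdrBH(c(0.5, 0)), "0, 1")
})

test_that("outcome correlation handles exact linear relations", {
  x <- c(1.2, 5.3, 2.2, 8, 4.4, 3.3)
  expect_equal(outcomeCorrelation(x, 2 * x + 1)$rho, 1, tolerance = 1e-12)
  expect_equal(outcomeCorrelation(x, -x)$rho, -1, tolerance = 1e-12)
  expect_error(outcomeCorrelation(rep(1, 6), x), "constant")
})

test_that("node-level analysis controls false positives under the null", {
  set.seed(8)
  groups <- list(a = matrix(rnorm(20 * 50), 20, 50),
                 b = matrix(rnorm(20 * 50), 20, 50))
  geom <- generateGeometry(50, seed = 23)
  rep <- nodeLevelAnalysis(groups, geom, nPerm = 1000, seed = 9)
  expect_equal(sum(rep$a_vs_b$significantMask), 0L)
  expect_equal(sum(rep$a_vs_b$selectedMask), 0L)
})

test_that("node-level analysis recovers planted effects and tallies RSNs", {
  set.seed(10)
  n_nodes <- 150
  affected <- 1:30
  a <- matrix(rnorm(20 * n_nodes), 20, n_nodes)
  b <- matrix(rnorm(20 * n_nodes), 20, n_nodes)
  b[, affected] <- b[, affected] + 1.5
  geom <- generateGeometry(n_nodes, seed = 24)
  rep <- nodeLevelAnalysis(list(a = a, b = b), geom, nPerm = 1000, seed = 11)
  sig <- which(rep$a_vs_b$significantMask)
  expect_gte(length(intersect(sig, affected)), 25L)
  sel <- which(rep$a_vs_b$selectedMask)
  expect_lte(length(setdiff(sel, affected)), 5L)
  expect_equal(sum(rep$a_vs_b$rsnCounts), sum(rep$a_vs_b$selectedMask))
  # selected nodes sit in the bottom quantile of significant raw p-values
  expect_true(all(rep$a_vs_b$nodeP[rep$a_vs_b$selectedMask] <=
    quantile(rep$a_vs_b$nodeP[sig], 0.30)))
})
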