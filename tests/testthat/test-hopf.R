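# Stuart-Landau dynamics against closed forms, and the FC-distance fit.

single_node_coupling <- function() {
  new("CouplingMatrix", weights = matrix(0, 1, 1), edrDecay = 0.18,
    longrangeSource = "none")
}

test_that("simulation is deterministic per seed", {
  anat <- shared_anatomy()
  p <- HopfParams(anat$omegas, G = 1.2, duration = 60, seed = 5L)
  b1 <- simulateHopf(p, anat$coupling)
  b2 <- simulateHopf(p, anat$coupling)
  expect_identical(boldData(b1), boldData(b2))
  p2 <- p; p2@seed <- 6L
  expect_false(identical(boldData(b1), boldData(simulateHopf(p2, anat$coupling))))
})

test_that("subcritical node decays to the fixed point as the ODE predicts", {
  p <- HopfParams(2 * pi * 0.05, G = 0, a = -0.2, noiseSigma = 0,
    dt = 0.001, duration = 60, seed = 1L)
  b <- simulateHopf(p, single_node_coupling(), outTr = 1, init = 0.1,
    transient = 0)
  expect_lt(abs(boldData(b)[1, 60]), 1e-3)
  # radial closed form r(t) = sqrt(a r0^2 e^{2at} / (a + r0^2(e^{2at}-1)))
  # with r0 = |(0.1, 0.1)|; compare the envelope at whole seconds
  r0sq <- 0.02; a <- -0.2
  tt <- 1:50
  r_ref <- sqrt(a * r0sq * exp(2 * a * tt) / (a + r0sq * (exp(2 * a * tt) - 1)))
  expect_true(all(abs(boldData(b)[1, tt]) <= r_ref * 1.02 + 1e-12))
})

test_that("supercritical node settles on the sqrt(a) limit cycle at omega", {
  p <- HopfParams(2 * pi * 0.05, G = 0, a = 0.25, noiseSigma = 0,
    dt = 0.01, duration = 200, seed = 1L)
  b <- simulateHopf(p, single_node_coupling(), outTr = 0.5, init = 0.1,
    transient = 100)
  x <- boldData(b)[1, ]
  r_est <- sqrt(2 * mean(x^2))          # x = r cos: RMS = r / sqrt(2)
  expect_equal(r_est, 0.5, tolerance = 0.01)
  # cycle frequency from the unwrapped analytic-signal phase slope
  ph <- Arg(turbfmri:::.analytic(x))
  dph <- diff(ph[50:350])
  dph <- (dph + pi) %% (2 * pi) - pi
  f_est <- mean(dph) / (2 * pi * 0.5)
  expect_equal(f_est, 0.05, tolerance = 0.01)
})

test_that("strongly coupled identical oscillators synchronize", {
  C <- new("CouplingMatrix", weights = matrix(c(0, 1, 1, 0), 2), edrDecay = 0.18,
    longrangeSource = "none")
  p <- HopfParams(rep(2 * pi * 0.05, 2), G = 10, a = 0.25, noiseSigma = 0,
    dt = 0.01, duration = 100, seed = 1L)
  b <- simulateHopf(p, C, outTr = 0.5, init = c(0.1, -0.1), transient = 100)
  tail_idx <- 150:200
  expect_lt(max(abs(boldData(b)[1, tail_idx] - boldData(b)[2, tail_idx])),
    0.01)
})

test_that("frequency estimation finds spectral peaks inside the band", {
  tt <- (0:299) * 2
  set.seed(3)
  x1 <- cos(2 * pi * 0.04 * tt) + 0.05 * rnorm(300)
  x2 <- cos(2 * pi * 0.06 * tt) + 0.05 * rnorm(300)
  om <- estimateFrequencies(BoldTimeseries(rbind(x1, x2), 2),
    band = c(0.01, 0.1))
  bin <- 1 / 600
  expect_equal(om[1] / (2 * pi), 0.04, tolerance = bin + 1e-9)
  expect_equal(om[2] / (2 * pi), 0.06, tolerance = bin + 1e-9)
  expect_false(om[1] == om[2])
  noise <- BoldTimeseries(matrix(rnorm(600), 2), 2)
  om_n <- estimateFrequencies(noise, band = c(0.04, 0.07))
  expect_true(all(om_n / (2 * pi) >= 0.04 - 1e-9 &
                  om_n / (2 * pi) <= 0.07 + 1e-9))
})

test_that("FC-vs-distance matches an explicit-loop oracle and null bounds", {
  geom <- generateGeometry(20, seed = 14)
  set.seed(15)
  bold <- BoldTimeseries(matrix(rnorm(20 * 100), 20), 2)
  got <- fcVsDistance(bold, geom, binMm = 2)
  n <- 20
  cors <- c(); dd <- c()
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    cors <- c(cors, cor(boldData(bold)[i, ], boldData(bold)[j, ]))
    dd <- c(dd, distances(geom)[i, j])
  }
  bin <- floor(dd / 2)
  for (b in unique(bin)) {
    center <- (b + 0.5) * 2
    expect_equal(got$fc[got$center == center], mean(cors[bin == b]),
      tolerance = 1e-12)
  }
  # identical series: every bin mean is 1
  same <- BoldTimeseries(matrix(rep(rnorm(100), each = 20), 20), 2)
  expect_true(all(abs(fcVsDistance(same, geom)$fc - 1) < 1e-12))
  # independent noise: bin means near zero
  geom50 <- generateGeometry(50, seed = 16)
  noise <- BoldTimeseries(matrix(rnorm(50 * 300), 50), 2)
  expect_true(all(abs(fcVsDistance(noise, geom50)$fc) <= 0.15))
})

test_that("model FC decays with distance under EDR-dominated coupling", {
  anat <- shared_anatomy()
  p <- HopfParams(anat$omegas, G = 1.2, duration = 300, seed = 21L)
  b <- simulateHopf(p, anat$coupling)
  cv <- fcVsDistance(b, anat$geom, binMm = 4)
  expect_lt(cor(cv$center, cv$fc, method = "spearman"), 0)
})

test_that("coupling-fit errors are nonnegative and the optimum is on the grid", {
  anat <- shared_anatomy()
  emp <- lapply(1:2, function(s) simulateHopf(
    HopfParams(anat$omegas, G = 1.2, duration = 300, seed = 8000 + s),
    anat$coupling))
  tmpl <- HopfParams(anat$omegas, G = 1, duration = 300, seed = 77L)
  fit <- fitGlobalCoupling(emp, anat$geom, anat$coupling, tmpl,
    gGrid = c(0.8, 1.2, 1.6), nReps = 2L)
  ec <- errorCurve(fit)
  expect_true(all(ec >= 0))
  expect_true(gOpt(fit) %in% c(0.8, 1.2, 1.6))
  expect_equal(min(ec), unname(ec[as.character(gOpt(fit))]))
})
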