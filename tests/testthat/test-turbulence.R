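# Model-free measures: band-pass, phases, local order parameter, and the
# turbulence-based information-flow statistics.

test_that("band-pass preserves in-band tones and suppresses out-of-band ones", {
  keep <- bandpassBold(tone_bold(0.03, n_vol = 300))
  mid <- 60:240
  expect_equal(max(abs(boldData(keep)[1, mid])), 1, tolerance = 0.01)
  kill <- bandpassBold(tone_bold(0.2, n_vol = 300))
  expect_lt(max(abs(boldData(kill)[1, mid])), 0.2)
  flat <- bandpassBold(BoldTimeseries(matrix(5, 2, 300), 2))
  expect_lt(max(abs(boldData(flat))), 1e-8)
  expect_error(bandpassBold(tone_bold(0.03), lowHz = 0.01, highHz = 0.3),
    "Nyquist|inside")
})

test_that("phases advance at the tone frequency and respect symmetry", {
  b <- bandpassBold(tone_bold(0.03, n_regions = 2, n_vol = 300))
  pf <- boldPhases(b, nTrim = 10)
  dph <- diff(phaseData(pf)[1, 100:180])
  dph <- (dph + pi) %% (2 * pi) - pi
  expect_equal(mean(dph), 2 * pi * 0.03 * 2, tolerance = 0.05)
  # identical regions give identical rows
  expect_identical(phaseData(pf)[1, ], phaseData(pf)[2, ])
  # sign flip offsets phases by pi (mod 2pi)
  flipped <- BoldTimeseries(-boldData(b), 2)
  pf2 <- boldPhases(flipped, nTrim = 10)
  delta <- (phaseData(pf2)[1, ] - phaseData(pf)[1, ]) %% (2 * pi)
  expect_true(all(abs(delta - pi) < 1e-6))
  expect_error(boldPhases(BoldTimeseries(matrix(1., 2, 20), 2), nTrim = 10),
    "fewer than 2")
})

test_that("local order parameter matches closed forms and a brute-force loop", {
  # perfect synchrony
  ph_sync <- new("PhaseField", phases = matrix(0.7, 5, 4), tr = 2,
    nTrimmed = 0L)
  g5 <- line_geometry(5)
  expect_true(all(orderParameter(localOrder(ph_sync, g5, 0.05)) == 1))
  # two antiphase nodes at w12 = 0.5: R = |1 - 0.5| / 1.5 = 1/3
  g2 <- ParcelGeometry(rbind(c(0, 0, 0), c(log(2) / 0.1, 0, 0)))
  ph2 <- new("PhaseField", phases = matrix(c(0, pi), 2, 1), tr = 2,
    nTrimmed = 0L)
  expect_equal(orderParameter(localOrder(ph2, g2, 0.1))[, 1],
    c(1 / 3, 1 / 3), tolerance = 1e-12)
  # brute-force oracle on 30 random nodes
  geom <- generateGeometry(30, seed = 6)
  ph <- random_phases(30, 40, seed = 2)
  f <- localOrder(ph, geom, 0.08)
  w <- exp(-0.08 * distances(geom))
  ref <- matrix(0, 30, 40)
  for (j in 1:30) for (t in 1:40) {
    s <- 0 + 0i
    for (k in 1:30) s <- s + w[j, k] * exp(1i * phaseData(ph)[k, t])
    ref[j, t] <- Mod(s) / sum(w[j, ])
  }
  expect_lt(max(abs(ref - orderParameter(f))), 1e-12)
  expect_error(localOrder(ph, geom, 0), "lambda")
})

test_that("local order limits: self-dominated at large lambda, global at small", {
  geom <- generateGeometry(40, seed = 8)
  ph <- random_phases(40, 30, seed = 3)
  expect_true(all(orderParameter(localOrder(ph, geom, 0.05)) >= 0))
  expect_true(all(orderParameter(localOrder(ph, geom, 0.05)) <= 1))
  expect_gt(mean(orderParameter(localOrder(ph, geom, 10))), 0.99)
  r_small <- orderParameter(localOrder(ph, geom, 1e-8))
  r_global <- apply(phaseData(ph), 2, function(p) Mod(mean(exp(1i * p))))
  expect_lt(max(abs(sweep(r_small, 2, r_global))), 1e-6)
})

test_that("turbulence amplitude is the pooled sample SD", {
  f <- field_with_R(matrix(c(0, 1, 0, 1), 2, 2))
  expect_equal(turbulenceAmplitude(f), sqrt(1 / 3), tolerance = 1e-12)
  expect_equal(turbulenceAmplitude(field_with_R(matrix(0.4, 3, 5))), 0)
  set.seed(4)
  rr <- matrix(runif(200), 10, 20)
  expect_equal(turbulenceAmplitude(field_with_R(rr)), sd(as.vector(rr)),
    tolerance = 1e-12)
  expect_error(turbulenceAmplitude(field_with_R(matrix(0.5, 1, 1))),
    "at least 2")
})

test_that("node metastability is per-region SD, distinct from pooled SD", {
  set.seed(5)
  rr <- matrix(runif(120), 6, 20)
  f <- field_with_R(rr)
  expect_equal(nodeMetastability(f), apply(rr, 1, sd), tolerance = 1e-12)
  rr2 <- rbind(rep(0.2, 10), rep(0.8, 10))   # constant rows, varying means
  f2 <- field_with_R(rr2)
  expect_equal(nodeMetastability(f2), c(0, 0))
  expect_gt(turbulenceAmplitude(f2), 0)      # pooled SD sees between-row spread
  expect_false(isTRUE(all.equal(mean(nodeMetastability(f)),
    turbulenceAmplitude(f))))
})

test_that("cascade flow matches its lagged-correlation definition", {
  set.seed(6)
  hi <- matrix(runif(600), 20, 30)
  lo <- cbind(matrix(runif(20), 20, 1), hi[, -30])  # lo(t+1) = hi(t)
  expect_equal(cascadeFlow(field_with_R(hi, 0.03), field_with_R(lo, 0.01)), 1,
    tolerance = 1e-12)
  # independent fields decorrelate
  big_hi <- field_with_R(matrix(runif(2e4), 100, 200), 0.03)
  big_lo <- field_with_R(matrix(runif(2e4), 100, 200), 0.01)
  expect_lt(abs(cascadeFlow(big_hi, big_lo)), 0.1)
  # flattened-vector oracle
  a <- matrix(runif(200), 10, 20); b <- matrix(runif(200), 10, 20)
  expect_equal(cascadeFlow(field_with_R(a, 0.03), field_with_R(b, 0.01)),
    cor(as.vector(a[, -20]), as.vector(b[, -1])), tolerance = 1e-12)
  expect_error(cascadeFlow(field_with_R(matrix(0.5, 4, 6), 0.03),
    field_with_R(matrix(runif(24), 4, 6), 0.01)), "zero variance")
})

test_that("information cascade is the mean of the flows", {
  expect_equal(informationCascade(c(x = 0.4)), 0.4)
  expect_equal(informationCascade(c(a = 1, b = -1)), 0)
  set.seed(7)
  fl <- runif(10, -1, 1)
  expect_equal(informationCascade(fl), mean(fl), tolerance = 1e-15)
  expect_error(informationCascade(numeric(0)), "empty")
})

test_that("information transfer recovers a planted power law exactly", {
  n <- 20
  geom <- line_geometry(n, step = 3.1)
  d <- distances(geom)
  centers <- (floor(d / 2) + 0.5) * 2       # the binning rule's centers
  P <- ifelse(d == 0, 1, centers^(-0.8))
  L <- chol(P)                               # P must be positive definite
  tt <- 400
  set.seed(8)
  Q <- qr.Q(qr(cbind(1, matrix(rnorm(tt * n), tt, n))))[, -1]
  R <- t(Q %*% L)                            # sample correlation exactly P
  R <- (R - min(R)) / (max(R) - min(R))      # affine map: correlations kept
  stat <- informationTransfer(field_with_R(R), geom, fitRange = c(3, 75))
  expect_equal(stat, 0.8, tolerance = 1e-9)
})

test_that("information transfer: no decay for a shared waveform, loop oracle", {
  geom <- generateGeometry(20, seed = 9)
  shared <- matrix(rep(seq(0.1, 0.9, length.out = 50), each = 20), 20)
  expect_equal(informationTransfer(field_with_R(shared), geom), 0)
  set.seed(10)
  rr <- matrix(runif(20 * 60), 20, 60)
  f <- field_with_R(rr)
  got <- informationTransfer(f, geom, fitRange = c(10, 75), binWidth = 2)
  # independent implementation: explicit loops + closed-form OLS
  n <- 20
  cors <- c(); dd <- c()
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    cors <- c(cors, cor(rr[i, ], rr[j, ]))
    dd <- c(dd, distances(geom)[i, j])
  }
  bin <- floor(dd / 2)
  cen <- (sort(unique(bin)) + 0.5) * 2
  mn <- sapply(sort(unique(bin)), function(b) mean(cors[bin == b]))
  use <- cen >= 10 & cen <= 75 & mn > 0
  lx <- log(cen[use]); ly <- log(mn[use])
  slope <- sum((lx - mean(lx)) * (ly - mean(ly))) / sum((lx - mean(lx))^2)
  expect_equal(got, -slope, tolerance = 1e-12)
  expect_error(informationTransfer(f, geom, fitRange = c(300, 400)),
    "bins")
})

test_that("profile is internally consistent and relabeling-invariant", {
  geom <- generateGeometry(40, seed = 11)
  set.seed(12)
  bold <- BoldTimeseries(matrix(rnorm(40 * 220), 40), 2)
  prof <- computeProfile(bold, geom)
  expect_equal(informationCascade(prof), mean(cascadeFlow(prof)),
    tolerance = 1e-12)
  expect_named(turbulence(prof), format(defaultScales()))
  expect_true(all(c("0.01", "0.03", "0.06") %in% names(turbulence(prof))))
  # simultaneous permutation of regions and geometry leaves scalars unchanged
  perm <- sample(40)
  geom_p <- ParcelGeometry(coords(geom)[perm, ], rsnLabels(geom)[perm])
  bold_p <- BoldTimeseries(boldData(bold)[perm, ], 2)
  prof_p <- computeProfile(bold_p, geom_p)
  expect_equal(turbulence(prof_p), turbulence(prof), tolerance = 1e-12)
  expect_equal(cascadeFlow(prof_p), cascadeFlow(prof), tolerance = 1e-12)
  expect_equal(informationTransfer(prof_p), informationTransfer(prof),
    tolerance = 1e-12)
  expect_equal(nodeMetastability(prof_p), nodeMetastability(prof)[perm, ],
    tolerance = 1e-12)
})

test_that("a fully synchronized subject has exactly zero turbulence", {
  geom <- generateGeometry(30, seed = 13)
  bold <- tone_bold(0.03, n_regions = 30, n_vol = 200)
  ph <- boldPhases(bandpassBold(bold))
  for (lam in c(0.01, 0.03, 0.06)) {
    f <- localOrder(ph, geom, lam)
    expect_true(all(orderParameter(f) == 1))
    expect_identical(turbulenceAmplitude(f), 0)
  }
  # the degenerate constant field makes the cascade correlation undefined,
  # which must surface as an explicit failure rather than NaN
  expect_error(computeProfile(bold, geom, scales = c(0.01, 0.03)),
    "zero variance")
})
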