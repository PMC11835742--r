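# Fixtures are built in code; nothing is read from disk.

# Deterministic line geometry: nodes every `step` mm along x. Useful when
# exact pairwise distances are needed.
line_geometry <- function(n, step = 3.1) {
  ParcelGeometry(cbind(seq_len(n) * step, 0, 0))
}

# Random phase field with a fixed seed.
random_phases <- function(n, tt, seed = 1, tr = 2) {
  set.seed(seed)
  new("PhaseField",
    phases = matrix(stats::runif(n * tt, -pi, pi), n, tt),
    tr = tr, nTrimmed = 0L)
}

# Local order field with prescribed R values (theta zero).
field_with_R <- function(R, lambda = 0.01) {
  new("LocalOrderField", lambda = lambda, R = R,
    theta = matrix(0, nrow(R), ncol(R)))
}

# Single sinusoid BOLD object, regions copies of the same tone.
tone_bold <- function(freq_hz, n_regions = 1, n_vol = 300, tr = 2,
    amplitude = 1) {
  tt <- (seq_len(n_vol) - 1) * tr
  x <- amplitude * cos(2 * pi * freq_hz * tt)
  BoldTimeseries(matrix(rep(x, each = n_regions), n_regions), tr)
}

# Minimal TurbulenceProfile carrying given per-scale values.
tiny_profile <- function(turb, transfer, cascade_flows = c(a = 0.5, b = 0.7)) {
  k <- length(turb)
  new("TurbulenceProfile", turbulence = turb,
    nodeMetastability = matrix(0.1, 2, k), cascadeFlow = cascade_flows,
    informationCascade = mean(cascade_flows),
    informationTransfer = transfer,
    lambdas = as.numeric(names(turb)), tr = 2)
}

# Family of minimal profiles with monotone per-subject offsets.
make_profiles <- function(ids, base = 0.2) {
  prof <- lapply(seq_along(ids), function(i) {
    tiny_profile(
      turb = setNames(base + 0.01 * i + c(0, 0.001, 0.002),
        c("0.01", "0.03", "0.06")),
      transfer = setNames(0.1 * i + c(0, 0.01, 0.02),
        c("0.01", "0.03", "0.06")))
  })
  names(prof) <- ids
  prof
}

# Feature table of two Gaussian classes separated by `sep` SDs.
gaussian_feature_table <- function(n_per_class, sep = 0, seed = 1) {
  set.seed(seed)
  x <- rbind(matrix(stats::rnorm(n_per_class * 7), n_per_class),
             matrix(stats::rnorm(n_per_class * 7, mean = sep), n_per_class))
  tab <- as.data.frame(x)
  names(tab) <- turbfmri:::.feature_cols
  rownames(tab) <- sprintf("P%03d", seq_len(2 * n_per_class))
  tab$label <- factor(rep(c("non_responder", "responder"),
    each = n_per_class), levels = c("non_responder", "responder"))
  tab
}

# Shared 60-region anatomy used by the heavier model-based tests; built
# once per test run.
.anat_cache <- new.env(parent = emptyenv())
shared_anatomy <- function() {
  if (is.null(.anat_cache$geom)) {
    .anat_cache$geom <- generateGeometry(60, seed = 1)
    .anat_cache$conn <- generateConnectome(.anat_cache$geom,
      nLongrange = 40L, seed = 2)
    .anat_cache$coupling <- buildCoupling(.anat_cache$geom, .anat_cache$conn)
    set.seed(7)
    .anat_cache$omegas <- 2 * pi * stats::runif(60, 0.04, 0.07)
  }
  .anat_cache
}
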