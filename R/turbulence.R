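#' Construct a BoldTimeseries
#'
#' @param data numeric matrix, regions x volumes.
#' @param tr repetition time in seconds.
#' @return a [BoldTimeseries-class].
#' @export
BoldTimeseries <- function(data, tr) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  new("BoldTimeseries", data = data, tr = as.numeric(tr))
}

#' Default inverse-distance scale grid
#'
#' Eleven scales spanning lambda = 0.01/mm (kernel length ~100 mm, near
#' whole-brain) to 0.30/mm (~3.3 mm, local neighborhoods).
#'
#' @return ascending numeric vector of lambda values (1/mm).
#' @export
defaultScales <- function() {
  c(0.01, 0.03, 0.06, 0.09, 0.12, 0.15, 0.18, 0.21, 0.24, 0.27, 0.30)
}

#' Band-pass filter a BOLD matrix
#'
#' Removes each region's mean, then applies a zero-phase (forward-backward)
#' second-order Butterworth band-pass.
#'
#' @param bold a [BoldTimeseries-class].
#' @param lowHz,highHz band edges in Hz; must satisfy
#'   0 < lowHz < highHz < Nyquist. Defaults 0.008 and 0.08 Hz, the
#'   conventional resting-state band.
#' @return a filtered [BoldTimeseries-class].
#' @export
bandpassBold <- function(bold, lowHz = 0.008, highHz = 0.08) {
  stopifnot(is(bold, "BoldTimeseries"))
  nyq <- 1 / (2 * bold@tr)
  if (!(lowHz > 0 && lowHz < highHz && highHz < nyq))
    stop("bandpassBold: band [", lowHz, ", ", highHz,
         "] Hz must lie strictly inside (0, ", nyq, ") Hz")
  bf <- signal::butter(2, c(lowHz, highHz) / nyq, type = "pass")
  x <- bold@data - rowMeans(bold@data)
  filt <- t(apply(x, 1L, function(r) signal::filtfilt(bf, r)))
  BoldTimeseries(filt, bold@tr)
}

# Analytic signal of one real series via the FFT half-spectrum construction.
.analytic <- function(x) {
  n <- length(x)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[1L] <- 1; h[n / 2L + 1L] <- 1; h[2L:(n / 2L)] <- 2
  } else {
    h[1L] <- 1; h[2L:((n + 1L) / 2L)] <- 2
  }
  stats::fft(stats::fft(x) * h, inverse = TRUE) / n
}

#' Instantaneous phases of band-passed BOLD
#'
#' Computes the analytic signal of each region's series (Hilbert
#' construction) and takes its argument; the first and last \code{nTrim}
#' volumes are dropped to suppress transform edge artifacts.
#'
#' @param bold a band-passed [BoldTimeseries-class].
#' @param nTrim volumes trimmed at each edge (default 10).
#' @return a [PhaseField-class] with phases in \eqn{(-\pi, \pi]}.
#' @export
boldPhases <- function(bold, nTrim = 10L) {
  stopifnot(is(bold, "BoldTimeseries"), nTrim >= 0)
  tt <- ncol(bold@data)
  if (tt - 2L * nTrim < 2L)
    stop("boldPhases: ", tt, " volumes leave fewer than 2 after trimming ",
         nTrim, " per edge")
  ph <- t(apply(bold@data, 1L, function(r) Arg(.analytic(r))))
  ph[ph <= -pi] <- pi  # canonical branch (-pi, pi]
  keep <- (nTrim + 1L):(tt - nTrim)
  new("PhaseField", phases = ph[, keep, drop = FALSE], tr = bold@tr,
    nTrimmed = as.integer(nTrim))
}

#' Local Kuramoto order parameter at one spatial scale
#'
#' For each region j and volume t,
#' \deqn{R_j(t) e^{i\theta_j(t)} = \frac{\sum_k w_{jk} e^{i\varphi_k(t)}}
#'   {\sum_k w_{jk}}, \qquad w_{jk} = e^{-\lambda d_{jk}},}
#' with the self term included (\eqn{w_{jj} = 1}). R measures the level of
#' local phase synchronization — the brain analogue of a vortex — at
#' characteristic length \eqn{1/\lambda} mm.
#'
#' @param ph a [PhaseField-class].
#' @param geom a [ParcelGeometry-class] with matching region count.
#' @param lambda inverse-distance scale in 1/mm (> 0).
#' @return a [LocalOrderField-class].
#' @export
localOrder <- function(ph, geom, lambda) {
  stopifnot(is(ph, "PhaseField"), is(geom, "ParcelGeometry"))
  if (lambda <= 0) stop("localOrder: lambda must be > 0")
  if (nRegions(geom) != nRegions(ph))
    stop("localOrder: geometry has ", nRegions(geom),
         " regions but phases have ", nRegions(ph))
  w <- exp(-lambda * distances(geom))
  z <- (w %*% exp(1i * ph@phases)) / rowSums(w)
  r <- Mod(z)
  # snap values within kernel-sum rounding error of full synchrony to 1,
  # so perfectly synchronized inputs give R = 1 (and turbulence 0) exactly
  r[r >= 1 - 1e-10] <- 1
  r <- unname(pmin(r, 1))
  dimnames(r) <- NULL
  th <- Arg(z)
  dimnames(th) <- NULL
  new("LocalOrderField", lambda = lambda, R = r, theta = th)
}

#' Amplitude turbulence of a local order field
#'
#' The sample standard deviation (n - 1 denominator) of R pooled jointly
#' over all regions and volumes: the spatiotemporal variability of local
#' synchronization that defines the turbulence level D.
#'
#' @param field a [LocalOrderField-class].
#' @return scalar turbulence value.
#' @export
turbulenceAmplitude <- function(field) {
  stopifnot(is(field, "LocalOrderField"))
  if (length(field@R) < 2L) stop("turbulenceAmplitude: need at least 2 entries")
  stats::sd(as.vector(field@R))
}

#' @rdname accessors
setMethod("turbulence", "LocalOrderField", function(x) turbulenceAmplitude(x))

#' @rdname accessors
setMethod("nodeMetastability", "LocalOrderField", function(x) {
  if (ncol(x@R) < 2L) stop("nodeMetastability: need at least 2 volumes")
  apply(x@R, 1L, stats::sd)
})

.cor_strict <- function(a, b, what) {
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop(what, ": correlation undefined (zero variance)")
  stats::cor(a, b)
}

#' Information cascade flow between two adjacent spatial scales
#'
#' Pearson correlation, pooled over regions and time, between the local
#' order parameter at scale lambda and at the adjacent (smaller) scale one
#' volume later: \eqn{corr(R_\lambda(t), R_{\lambda-\Delta\lambda}(t+1))}.
#' The last volume of the larger-lambda field and the first volume of the
#' smaller-lambda field are dropped to align the lag.
#'
#' @param x the [LocalOrderField-class] at scale lambda (f_hi).
#' @param y the [LocalOrderField-class] at the adjacent smaller scale (f_lo).
#' @return scalar correlation in [-1, 1].
#' @rdname cascadeFlow
#' @export
setMethod("cascadeFlow", signature("LocalOrderField", "LocalOrderField"),
  function(x, y, ...) {
    if (!identical(dim(x@R), dim(y@R)))
      stop("cascadeFlow: fields have different dimensions")
    tt <- ncol(x@R)
    if (tt < 2L) stop("cascadeFlow: need at least 2 volumes")
    a <- as.vector(x@R[, -tt, drop = FALSE])
    b <- as.vector(y@R[, -1L, drop = FALSE])
    .cor_strict(a, b, "cascadeFlow")
  })

#' @rdname accessors
setMethod("cascadeFlow", signature("TurbulenceProfile", "missing"),
  function(x, y, ...) x@cascadeFlow)

#' Information cascade: mean cascade flow across scale pairs
#'
#' @param x named numeric vector of cascade-flow values (one per adjacent
#'   scale pair), or a [TurbulenceProfile-class].
#' @return scalar mean flow.
#' @rdname informationCascade
#' @export
setMethod("informationCascade", "numeric", function(x) {
  if (!length(x)) stop("informationCascade: empty flow set")
  mean(x)
})

#' @rdname accessors
setMethod("informationCascade", "TurbulenceProfile",
  function(x) x@informationCascade)

#' Spatial information transfer at one scale
#'
#' Correlates the local order parameter over time for every region pair,
#' averages the correlations in distance bins, and fits
#' \eqn{\log \bar c(r) \sim \log r} by OLS over the fit range, using only
#' bins with a positive mean correlation. The statistic is the negative of
#' the fitted slope, so larger values mean faster spatial decay of the
#' synchronization correlation (sign convention recorded in the name:
#' a planted power law \eqn{c(r) = r^{-s}} yields the statistic s).
#'
#' @param x a [LocalOrderField-class].
#' @param geom a [ParcelGeometry-class].
#' @param fitRange distance range (mm) for the log-log fit; default
#'   c(10, 75), an inertial-subrange stand-in.
#' @param binWidth distance bin width in mm (default 2).
#' @return scalar decay statistic.
#' @rdname informationTransfer
#' @export
setMethod("informationTransfer", "LocalOrderField",
  function(x, geom, fitRange = c(10, 75), binWidth = 2) {
    stopifnot(is(geom, "ParcelGeometry"))
    if (nRegions(geom) != nRegions(x))
      stop("informationTransfer: geometry/field size mismatch")
    cc <- suppressWarnings(stats::cor(t(x@R)))
    if (any(!is.finite(cc[upper.tri(cc)]))) {
      # constant rows produce NA correlations; a fully constant field is the
      # degenerate perfectly-synchronized case with zero decay
      if (all(apply(x@R, 1L, stats::sd) == 0)) return(0)
      stop("informationTransfer: zero-variance region rows")
    }
    ut <- upper.tri(cc)
    d <- distances(geom)[ut]
    r <- cc[ut]
    bins <- floor(d / binWidth)
    centers <- (unique(bins) + 0.5) * binWidth
    means <- vapply(unique(bins), function(b) mean(r[bins == b]), 0)
    inrange <- centers >= fitRange[1L] & centers <= fitRange[2L]
    usable <- inrange & means > 0
    if (sum(usable) < 5L)
      stop("informationTransfer: fewer than 5 usable distance bins in range")
    # all-ones correlations (full synchrony of a shared waveform): no decay
    if (all(abs(means[usable] - 1) < 1e-12)) return(0)
    fit <- stats::lm.fit(cbind(1, log(centers[usable])), log(means[usable]))
    -unname(fit$coefficients[2L])
  })

#' @rdname accessors
setMethod("informationTransfer", "TurbulenceProfile",
  function(x, ...) x@informationTransfer)

#' Compute the full turbulence profile of one subject
#'
#' Runs the model-free pipeline: band-pass, phases, local order parameter
#' at every scale (each scale computed once), then amplitude turbulence and
#' node metastability per scale, cascade flow per adjacent scale pair with
#' their mean (information cascade), and the spatial information-transfer
#' statistic per scale.
#'
#' @param bold a raw [BoldTimeseries-class].
#' @param geom a [ParcelGeometry-class].
#' @param scales ascending lambda grid (default [defaultScales()]).
#' @param lowHz,highHz band-pass edges in Hz.
#' @param nTrim edge volumes trimmed after the phase transform.
#' @param fitRange,binWidth information-transfer fit controls.
#' @param transferScales scales at which the information-transfer fit is
#'   evaluated (default: all of \code{scales}).
#' @return a [TurbulenceProfile-class].
#' @examples
#' geom <- generateGeometry(40, seed = 2)
#' bold <- BoldTimeseries(matrix(rnorm(40 * 200), 40), tr = 2)
#' prof <- computeProfile(bold, geom)
#' turbulence(prof)[["0.01"]]
#' @export
computeProfile <- function(bold, geom, scales = defaultScales(),
    lowHz = 0.008, highHz = 0.08, nTrim = 10L,
    fitRange = c(10, 75), binWidth = 2, transferScales = scales) {
  stopifnot(is(bold, "BoldTimeseries"), is(geom, "ParcelGeometry"))
  if (is.unsorted(scales, strictly = TRUE) || any(scales <= 0))
    stop("computeProfile: scales must be strictly ascending and positive")
  stage <- "bandpass"
  prof <- tryCatch({
    bp <- bandpassBold(bold, lowHz, highHz)
    stage <- "phases"
    ph <- boldPhases(bp, nTrim)
    stage <- "local order"
    fields <- lapply(scales, function(l) localOrder(ph, geom, l))
    names(fields) <- format(scales)
    stage <- "measures"
    turb <- vapply(fields, turbulenceAmplitude, 0)
    nodem <- vapply(fields, nodeMetastability, numeric(nRegions(geom)))
    k <- length(scales)
    flows <- numeric(0)
    if (k >= 2L) {
      flows <- vapply(2L:k, function(i)
        cascadeFlow(fields[[i]], fields[[i - 1L]]), 0)
      names(flows) <- paste0(format(scales[-1L]), "->", format(scales[-k]))
    }
    tidx <- match(format(transferScales), names(fields))
    if (anyNA(tidx)) stop("transferScales must be a subset of scales")
    transfer <- vapply(fields[tidx], informationTransfer, 0,
      geom = geom, fitRange = fitRange, binWidth = binWidth)
    new("TurbulenceProfile",
      turbulence = stats::setNames(turb, format(scales)),
      nodeMetastability = nodem,
      cascadeFlow = flows,
      informationCascade = if (length(flows)) mean(flows) else NA_real_,
      informationTransfer = stats::setNames(transfer, format(transferScales)),
      lambdas = scales, tr = bold@tr)
  }, error = function(e) {
    stop("computeProfile [stage: ", stage, "]: ", conditionMessage(e),
      call. = FALSE)
  })
  prof
}
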