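#' Construct HopfParams
#'
#' @param omegas intrinsic angular frequencies (rad/s), one per region.
#' @param G global coupling (>= 0).
#' @param a bifurcation parameter, scalar or per region (default -0.02, a
#'   noise-driven operating point just below the oscillation onset).
#' @param noiseSigma additive noise SD (default 0.01).
#' @param dt integration step in seconds (default 0.1).
#' @param duration simulated seconds retained after the transient.
#' @param seed integer seed for the noise stream.
#' @return a [HopfParams-class].
#' @export
HopfParams <- function(omegas, G, a = -0.02, noiseSigma = 0.01, dt = 0.1,
    duration = 600, seed = 1L) {
  new("HopfParams", a = a, omegas = as.numeric(omegas), G = as.numeric(G),
    noiseSigma = noiseSigma, dt = dt, duration = duration,
    seed = as.integer(seed))
}

#' Simulate the Stuart-Landau whole-brain model
#'
#' Euler-Maruyama integration of N coupled Stuart-Landau oscillators
#' \deqn{dx_j = [(a_j - x_j^2 - y_j^2) x_j - \omega_j y_j +
#'   G \sum_k C_{jk} (x_k - x_j)]\,dt + \sigma\sqrt{dt}\,\xi_j}
#' (and the symmetric equation for y with \eqn{+\omega_j x_j}). A 20 s
#' transient is discarded and the x component is recorded every
#' \code{outTr} seconds.
#'
#' @param params a [HopfParams-class].
#' @param coupling a [CouplingMatrix-class].
#' @param outTr output sampling interval in seconds (the simulated TR).
#' @param init initial value given to every x and y (default 0.1).
#' @param transient seconds discarded before recording (default 20).
#' @return a [BoldTimeseries-class] with tr = outTr.
#' @export
simulateHopf <- function(params, coupling, outTr = 2, init = 0.1,
    transient = 20) {
  stopifnot(is(params, "HopfParams"), is(coupling, "CouplingMatrix"))
  C <- params@G * coupling@weights
  n <- nrow(C)
  if (length(params@omegas) != n)
    stop("simulateHopf: omegas length != coupling dimension")
  a <- rep_len(params@a, n)
  w <- params@omegas
  dt <- params@dt
  every <- round(outTr / dt)
  if (abs(every * dt - outTr) > 1e-9)
    stop("simulateHopf: outTr must be an integer multiple of dt")
  n_rec <- floor(params@duration / outTr)
  n_burn <- round(transient / dt)
  sumC <- rowSums(C)
  sn <- params@noiseSigma * sqrt(dt)
  out <- matrix(NA_real_, n, n_rec)
  .with_seed(params@seed, {
    x <- rep_len(init, n)
    y <- rep_len(init, n)
    step <- 0L
    rec <- 0L
    total <- n_burn + n_rec * every
    while (step < total) {
      step <- step + 1L
      rsq <- x * x + y * y
      cx <- drop(C %*% x) - sumC * x
      cy <- drop(C %*% y) - sumC * y
      nx <- if (sn > 0) stats::rnorm(n, 0, sn) else 0
      ny <- if (sn > 0) stats::rnorm(n, 0, sn) else 0
      x1 <- x + ((a - rsq) * x - w * y + cx) * dt + nx
      y1 <- y + ((a - rsq) * y + w * x + cy) * dt + ny
      x <- x1; y <- y1
      if (max(abs(x)) > 1e6)
        stop("simulateHopf: divergence at step ", step)
      if (step > n_burn && (step - n_burn) %% every == 0L) {
        rec <- rec + 1L
        out[, rec] <- x
      }
    }
  })
  BoldTimeseries(out, outTr)
}

#' Estimate intrinsic node frequencies from narrowband BOLD
#'
#' Per-region peak frequency of the periodogram restricted to the given
#' band, returned as angular frequencies \eqn{\omega_j = 2\pi f_j}.
#'
#' @param bold a [BoldTimeseries-class] with at least 64 volumes.
#' @param band two Hz values; clipped to (0, Nyquist).
#' @return numeric vector of angular frequencies, rad/s.
#' @export
estimateFrequencies <- function(bold, band = c(0.04, 0.07)) {
  stopifnot(is(bold, "BoldTimeseries"))
  tt <- ncol(bold@data)
  if (tt < 64L) stop("estimateFrequencies: need >= 64 volumes")
  fs <- 1 / bold@tr
  freqs <- (seq_len(floor(tt / 2)) ) / (tt * bold@tr)
  lo <- max(band[1L], freqs[1L])
  hi <- min(band[2L], fs / 2)
  sel <- which(freqs >= lo & freqs <= hi)
  if (!length(sel))
    stop("estimateFrequencies: band empty after Nyquist clipping")
  unname(apply(bold@data, 1L, function(r) {
    r <- r - mean(r)
    pw <- Mod(stats::fft(r)[seq_len(floor(tt / 2)) + 1L])^2
    2 * pi * freqs[sel[which.max(pw[sel])]]
  }))
}

#' Mean pairwise functional connectivity as a function of distance
#'
#' Full-series Pearson correlation for every region pair, averaged within
#' distance bins.
#'
#' @param bold a [BoldTimeseries-class].
#' @param geom a [ParcelGeometry-class].
#' @param binMm bin width in mm (default 2).
#' @param range distance range (mm) retained; default the full support.
#' @return data.frame with columns \code{center} (bin center, mm),
#'   \code{fc} (mean correlation) and \code{n} (pairs in bin), ordered by
#'   distance.
#' @export
fcVsDistance <- function(bold, geom, binMm = 2, range = c(0, Inf)) {
  stopifnot(is(bold, "BoldTimeseries"), is(geom, "ParcelGeometry"))
  if (nRegions(bold) != nRegions(geom))
    stop("fcVsDistance: size mismatch between BOLD and geometry")
  cc <- stats::cor(t(bold@data))
  ut <- upper.tri(cc)
  d <- distances(geom)[ut]
  r <- cc[ut]
  keep <- d >= range[1L] & d <= range[2L]
  if (!any(keep)) stop("fcVsDistance: no pairs in range")
  bins <- floor(d[keep] / binMm)
  ub <- sort(unique(bins))
  if (length(ub) < 5L)
    stop("fcVsDistance: fewer than 5 populated distance bins")
  out <- data.frame(
    center = (ub + 0.5) * binMm,
    fc = vapply(ub, function(b) mean(r[keep][bins == b]), 0),
    n = vapply(ub, function(b) sum(bins == b), 0L))
  out[order(out$center), , drop = FALSE]
}

#' Fit the global coupling G against empirical FC-vs-distance
#'
#' The empirical target is the subject-averaged FC-vs-distance curve. For
#' each grid value of G the model is simulated \code{nReps} times with
#' derived seeds, its FC-vs-distance curves are averaged, and the fit error
#' is the mean squared difference across distance bins. The optimal G is
#' the grid value with the minimal error (ties broken toward the smallest,
#' more subcritical, G).
#'
#' @param empirical list of [BoldTimeseries-class] (one per subject).
#' @param geom a [ParcelGeometry-class].
#' @param coupling a [CouplingMatrix-class].
#' @param paramsTemplate a [HopfParams-class]; its G is replaced per grid
#'   point and its seed is re-derived per repetition.
#' @param gGrid ascending vector of coupling values to sweep.
#' @param nReps simulated repetitions per grid value (default 3).
#' @param binMm,range FC-vs-distance binning controls.
#' @param outTr simulated sampling interval; defaults to the first
#'   empirical subject's TR.
#' @return a [FitResult-class].
#' @export
fitGlobalCoupling <- function(empirical, geom, coupling, paramsTemplate,
    gGrid, nReps = 3L, binMm = 2, range = c(0, Inf), outTr = NULL) {
  stopifnot(length(empirical) >= 1L, is(paramsTemplate, "HopfParams"),
    length(gGrid) >= 1L, !is.unsorted(gGrid), nReps >= 1L)
  if (is.null(outTr)) outTr <- empirical[[1L]]@tr
  emp_curves <- lapply(empirical, fcVsDistance, geom = geom, binMm = binMm,
    range = range)
  centers <- emp_curves[[1L]]$center
  target <- rowMeans(vapply(emp_curves, function(cv) {
    if (!identical(cv$center, centers))
      stop("fitGlobalCoupling: empirical subjects yield different bins")
    cv$fc
  }, numeric(length(centers))))
  errs <- rep(NA_real_, length(gGrid))
  for (gi in seq_along(gGrid)) {
    model_fc <- NULL
    n_ok <- 0L
    for (rep in seq_len(nReps)) {
      p <- paramsTemplate
      p@G <- gGrid[gi]
      p@seed <- .derive_seed(paramsTemplate@seed, gi * 1000L + rep)
      sim <- tryCatch(simulateHopf(p, coupling, outTr = outTr),
        error = function(e) {
          warning("fitGlobalCoupling: G = ", gGrid[gi], " rep ", rep,
            " failed: ", conditionMessage(e)); NULL
        })
      if (is.null(sim)) next
      cv <- fcVsDistance(sim, geom, binMm = binMm, range = range)
      if (!identical(cv$center, centers)) next
      model_fc <- if (is.null(model_fc)) cv$fc else model_fc + cv$fc
      n_ok <- n_ok + 1L
    }
    if (n_ok > 0L) errs[gi] <- mean((model_fc / n_ok - target)^2)
  }
  if (all(is.na(errs))) stop("fitGlobalCoupling: every grid value failed")
  gopt <- gGrid[which(errs == min(errs, na.rm = TRUE))[1L]]
  new("FitResult", gGrid = as.numeric(gGrid), errorCurve = errs,
    gOpt = gopt, nRepsPerG = as.integer(nReps))
}
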