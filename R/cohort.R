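#' Construct a CohortSpec
#'
#' @param nRegions number of parcels.
#' @param groupSizes counts for (control, responder, non_responder);
#'   default 20 each.
#' @param groupG global coupling per group, same order.
#' @param nVolumes volumes per subject (default 300).
#' @param tr repetition time in seconds (default 2).
#' @param outcomeCorrelation target correlation between baseline turbulence
#'   at lambda = 0.01 and HAMD6 percent change among patients (default 0.4).
#' @param seed master seed.
#' @return a [CohortSpec-class].
#' @export
CohortSpec <- function(nRegions, groupSizes = c(20L, 20L, 20L),
    groupG = c(1.3, 1.5, 0.9), nVolumes = 300L, tr = 2,
    outcomeCorrelation = 0.4, seed = 1L) {
  new("CohortSpec", nRegions = as.integer(nRegions),
    nVolumes = as.integer(nVolumes), tr = tr,
    groupSizes = as.integer(groupSizes), groupG = as.numeric(groupG),
    outcomeCorrelation = outcomeCorrelation, seed = as.integer(seed))
}

#' Intrinsic node frequencies of a synthetic cohort
#'
#' Returns the angular-frequency vector shared by every subject a
#' [generateCohort()] call with this spec simulates (one deterministic
#' draw per spec, uniform in the 0.04-0.07 Hz band). Model-based analyses
#' of synthetic cohorts should build their oscillator models from these
#' frequencies; spectral re-estimation from the simulated series is
#' biased once coupling synchronizes the network.
#'
#' @param spec a [CohortSpec-class].
#' @return numeric vector of angular frequencies (rad/s), length
#'   \code{spec@nRegions}.
#' @export
cohortOmegas <- function(spec) {
  stopifnot(is(spec, "CohortSpec"))
  .with_seed(.derive_seed(spec@seed, 0L),
    2 * pi * stats::runif(spec@nRegions, 0.04, 0.07))
}

# Turbulence at a single scale, used by the outcome generator.
.turbulence_at <- function(bold, geom, lambda, nTrim = 10L) {
  ph <- boldPhases(bandpassBold(bold), nTrim = nTrim)
  turbulenceAmplitude(localOrder(ph, geom, lambda))
}

#' Generate a synthetic three-group cohort
#'
#' Each subject's BOLD is simulated from the Stuart-Landau whole-brain
#' model on the supplied anatomy at its group's global coupling G, with a
#' subject-unique derived seed; group differences are therefore planted
#' through the coupling mechanism rather than through additive signal.
#' Intrinsic node frequencies are drawn once per cohort, uniformly in the
#' 0.04-0.07 Hz band typical of narrowband resting-state BOLD, and shared
#' by all subjects.
#'
#' Patients (responders and non-responders) receive an HAMD6 percent-change
#' outcome built by a Gaussian copula on the rank of their baseline
#' turbulence at lambda = 0.01, so that the population correlation between
#' turbulence and outcome equals \code{spec@outcomeCorrelation}; controls
#' carry NA scores.
#'
#' @param spec a [CohortSpec-class].
#' @param geom a [ParcelGeometry-class] with \code{spec@nRegions} regions.
#' @param connectome optional N x N structural matrix merged on top of the
#'   EDR kernel (see [buildCoupling()]).
#' @param a,noiseSigma,dt Stuart-Landau parameters shared by all subjects.
#' @param edrDecay EDR decay for the coupling kernel (1/mm).
#' @return list of [SubjectRecord-class], controls first, then responders,
#'   then non-responders.
#' @examples
#' geom <- generateGeometry(30, seed = 1)
#' spec <- CohortSpec(30, groupSizes = c(2L, 2L, 2L), nVolumes = 120L)
#' cohort <- generateCohort(spec, geom)
#' vapply(cohort, subjectGroup, "")
#' @export
generateCohort <- function(spec, geom, connectome = NULL, a = -0.02,
    noiseSigma = 0.01, dt = 0.1, edrDecay = 0.18) {
  stopifnot(is(spec, "CohortSpec"), is(geom, "ParcelGeometry"))
  if (nRegions(geom) != spec@nRegions)
    stop("generateCohort: geometry has ", nRegions(geom),
         " regions, spec expects ", spec@nRegions)
  coupling <- buildCoupling(geom, connectome, edrDecay = edrDecay)
  groups <- rep(c("control", "responder", "non_responder"), spec@groupSizes)
  gvals <- rep(spec@groupG, spec@groupSizes)
  n <- length(groups)
  omegas <- cohortOmegas(spec)
  duration <- spec@nVolumes * spec@tr
  subjects <- vector("list", n)
  turb <- numeric(n)
  for (i in seq_len(n)) {
    params <- HopfParams(omegas, G = gvals[i], a = a,
      noiseSigma = noiseSigma, dt = dt, duration = duration,
      seed = .derive_seed(spec@seed, i))
    bold <- simulateHopf(params, coupling, outTr = spec@tr)
    if (!all(is.finite(bold@data)))
      stop("generateCohort: non-finite simulation output for subject ",
           sprintf("S%03d", i))
    subjects[[i]] <- list(id = sprintf("S%03d", i), group = groups[i],
      bold = bold)
    turb[i] <- .turbulence_at(bold, geom, 0.01)
  }
  pat <- which(groups != "control")
  rho <- spec@outcomeCorrelation
  scores <- .with_seed(.derive_seed(spec@seed, n + 1L), {
    np <- length(pat)
    z_turb <- stats::qnorm((rank(turb[pat]) - 0.5) / np)
    z_out <- rho * z_turb + sqrt(1 - rho^2) * stats::rnorm(np)
    list(base = round(stats::runif(np, 12, 22)),
         pct = 50 + 20 * z_out)
  })
  out <- vector("list", n)
  for (i in seq_len(n)) {
    j <- match(i, pat)
    out[[i]] <- new("SubjectRecord", subjectId = subjects[[i]]$id,
      group = subjects[[i]]$group, bold = subjects[[i]]$bold,
      hamd6Baseline = if (is.na(j)) NA_real_ else scores$base[j],
      hamd6PctChange = if (is.na(j)) NA_real_ else scores$pct[j])
  }
  out
}
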