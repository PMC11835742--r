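#' @import methods
NULL

# Shared validity helpers -------------------------------------------------

.is_square <- function(m) is.matrix(m) && nrow(m) == ncol(m)

.check_symmetric_hollow <- function(m, what, tol = 1e-9) {
  msgs <- character()
  if (!.is_square(m)) msgs <- c(msgs, sprintf("%s must be a square matrix", what))
  else {
    if (max(abs(m - t(m))) > tol) msgs <- c(msgs, sprintf("%s must be symmetric", what))
    if (any(abs(diag(m)) > tol)) msgs <- c(msgs, sprintf("%s must have a zero diagonal", what))
  }
  msgs
}

#' ParcelGeometry: centroids, distances and network labels of a parcellation
#'
#' Holds the spatial side of a brain parcellation: region centroid
#' coordinates in mm (MNI-like frame), the full Euclidean distance matrix
#' \eqn{d_{jk}}, and a resting-state-network (RSN) label per region.
#'
#' @slot coords numeric matrix, N x 3, centroid positions in mm.
#' @slot dist numeric matrix, N x N, pairwise Euclidean distances in mm.
#' @slot rsnLabels character vector of length N; canonical names are
#'   CON, DMN, TP, VIS, SOM, ATT, SAL, LIM.
#'
#' @seealso [generateGeometry()], [readGeometry()]
#' @export
setClass("ParcelGeometry",
  representation(coords = "matrix", dist = "matrix", rsnLabels = "character"),
  validity = function(object) {
    msgs <- character()
    n <- nrow(object@coords)
    if (ncol(object@coords) != 3L) msgs <- c(msgs, "coords must have 3 columns (mm)")
    if (!all(is.finite(object@coords))) msgs <- c(msgs, "coords must be finite")
    msgs <- c(msgs, .check_symmetric_hollow(object@dist, "dist"))
    if (.is_square(object@dist) && nrow(object@dist) == n) {
      d2 <- as.matrix(stats::dist(object@coords))
      if (max(abs(object@dist - d2)) > 1e-9)
        msgs <- c(msgs, "dist does not match Euclidean distances of coords (tol 1e-9)")
    } else msgs <- c(msgs, "dist dimension must match coords rows")
    if (length(object@rsnLabels) != n)
      msgs <- c(msgs, "rsnLabels length must equal number of regions")
    if (length(msgs)) msgs else TRUE
  })

#' BoldTimeseries: a parcellated BOLD matrix with its sampling interval
#'
#' @slot data numeric matrix, regions x volumes.
#' @slot tr repetition time in seconds.
#'
#' @export
setClass("BoldTimeseries",
  representation(data = "matrix", tr = "numeric"),
  validity = function(object) {
    msgs <- character()
    if (!all(is.finite(object@data))) msgs <- c(msgs, "BOLD data must contain only finite values")
    if (length(object@tr) != 1L || !is.finite(object@tr) || object@tr <= 0)
      msgs <- c(msgs, "tr must be a single positive number (seconds)")
    if (length(msgs)) msgs else TRUE
  })

#' PhaseField: instantaneous phases of band-passed BOLD
#'
#' Phases \eqn{\varphi_k(t)} in \eqn{(-\pi, \pi]} from the analytic signal
#' of each region's narrowband series, with edge volumes trimmed.
#'
#' @slot phases numeric matrix, regions x retained volumes, radians.
#' @slot tr seconds per volume.
#' @slot nTrimmed volumes dropped at each edge.
#'
#' @export
setClass("PhaseField",
  representation(phases = "matrix", tr = "numeric", nTrimmed = "integer"),
  validity = function(object) {
    msgs <- character()
    p <- object@phases
    if (!all(is.finite(p))) msgs <- c(msgs, "phases must be finite")
    else if (any(p <= -pi - 1e-12) || any(p > pi + 1e-12))
      msgs <- c(msgs, "phases must lie in (-pi, pi]")
    if (object@nTrimmed < 0L) msgs <- c(msgs, "nTrimmed must be >= 0")
    if (length(msgs)) msgs else TRUE
  })

#' LocalOrderField: local Kuramoto order parameter at one spatial scale
#'
#' The modulus \eqn{R_j(t)} and argument \eqn{\theta_j(t)} of the
#' kernel-weighted mean phase vector around each region, at inverse-distance
#' scale \code{lambda} (per mm).
#'
#' @slot lambda inverse-distance scale in 1/mm.
#' @slot R numeric matrix in [0, 1], regions x volumes.
#' @slot theta numeric matrix of mean-phase angles, radians.
#'
#' @export
setClass("LocalOrderField",
  representation(lambda = "numeric", R = "matrix", theta = "matrix"),
  validity = function(object) {
    msgs <- character()
    if (object@lambda <= 0) msgs <- c(msgs, "lambda must be > 0")
    if (!all(is.finite(object@R))) msgs <- c(msgs, "R must be finite")
    else if (min(object@R) < -1e-12 || max(object@R) > 1 + 1e-12)
      msgs <- c(msgs, "R must lie in [0, 1]")
    if (!identical(dim(object@R), dim(object@theta)))
      msgs <- c(msgs, "R and theta must have identical dimensions")
    if (length(msgs)) msgs else TRUE
  })

#' TurbulenceProfile: all turbulence-based information-flow measures
#'
#' Per-subject summary of the model-free framework: amplitude turbulence and
#' node-level metastability per scale, information cascade flow per adjacent
#' scale pair, their mean (information cascade), and the spatial
#' information-transfer decay statistic per scale.
#'
#' @slot turbulence named numeric, one value per scale (names = lambda).
#' @slot nodeMetastability numeric matrix, regions x scales.
#' @slot cascadeFlow named numeric, one value per adjacent scale pair.
#' @slot informationCascade mean of \code{cascadeFlow}.
#' @slot informationTransfer named numeric per scale: negative slope of
#'   log mean correlation vs log distance (larger = faster spatial decay).
#' @slot lambdas the scale grid used (1/mm).
#' @slot tr seconds per volume.
#'
#' @export
setClass("TurbulenceProfile",
  representation(turbulence = "numeric", nodeMetastability = "matrix",
    cascadeFlow = "numeric", informationCascade = "numeric",
    informationTransfer = "numeric", lambdas = "numeric", tr = "numeric"),
  validity = function(object) {
    msgs <- character()
    if (length(object@cascadeFlow) &&
        abs(object@informationCascade - mean(object@cascadeFlow)) > 1e-12)
      msgs <- c(msgs, "informationCascade must equal mean(cascadeFlow) to 1e-12")
    if (any(object@turbulence < 0)) msgs <- c(msgs, "turbulence must be >= 0")
    if (length(msgs)) msgs else TRUE
  })

#' CouplingMatrix: anatomy-constrained oscillator coupling
#'
#' Exponential-distance-rule kernel with optional long-range exceptions
#' merged on top (elementwise maximum with a normalized connectome).
#'
#' @slot weights nonnegative symmetric matrix, zero diagonal, max entry <= 1.
#' @slot edrDecay exponential decay rate in 1/mm.
#' @slot longrangeSource "none", "synthetic" or "file".
#'
#' @export
setClass("CouplingMatrix",
  representation(weights = "matrix", edrDecay = "numeric", longrangeSource = "character"),
  validity = function(object) {
    msgs <- .check_symmetric_hollow(object@weights, "C")
    if (any(object@weights < 0)) msgs <- c(msgs, "C must be nonnegative")
    if (max(object@weights) > 1 + 1e-12) msgs <- c(msgs, "C entries must be <= 1")
    if (object@edrDecay <= 0) msgs <- c(msgs, "edrDecay must be > 0")
    if (length(msgs)) msgs else TRUE
  })

#' HopfParams: parameters of the Stuart-Landau whole-brain model
#'
#' @slot a bifurcation parameter (a < 0: noisy fixed point; a > 0: limit
#'   cycle of radius sqrt(a)). Scalar or one value per region.
#' @slot omegas intrinsic angular frequencies, rad/s, one per region.
#' @slot G global coupling scaling the anatomical matrix.
#' @slot noiseSigma additive noise standard deviation.
#' @slot dt Euler-Maruyama step, seconds.
#' @slot duration simulated seconds after the discarded transient.
#' @slot seed integer RNG seed for the noise stream.
#'
#' @export
setClass("HopfParams",
  representation(a = "numeric", omegas = "numeric", G = "numeric",
    noiseSigma = "numeric", dt = "numeric", duration = "numeric", seed = "integer"),
  validity = function(object) {
    msgs <- character()
    if (object@G < 0) msgs <- c(msgs, "G must be >= 0")
    if (object@noiseSigma < 0) msgs <- c(msgs, "noiseSigma must be >= 0")
    if (object@dt <= 0) msgs <- c(msgs, "dt must be > 0")
    if (object@duration <= 0) msgs <- c(msgs, "duration must be > 0")
    if (length(msgs)) msgs else TRUE
  })

#' FitResult: global-coupling sweep and its optimum
#'
#' @slot gGrid coupling values swept.
#' @slot errorCurve FC-vs-distance fit error per grid value (>= 0).
#' @slot gOpt grid value with minimal error (ties: smallest G).
#' @slot nRepsPerG simulation repetitions averaged per grid value.
#'
#' @export
setClass("FitResult",
  representation(gGrid = "numeric", errorCurve = "numeric", gOpt = "numeric",
    nRepsPerG = "integer"),
  validity = function(object) {
    msgs <- character()
    if (length(object@gGrid) != length(object@errorCurve))
      msgs <- c(msgs, "gGrid and errorCurve lengths differ")
    if (!object@gOpt %in% object@gGrid) msgs <- c(msgs, "gOpt must be a grid value")
    ok <- is.finite(object@errorCurve)
    if (!any(ok)) msgs <- c(msgs, "all fit errors are non-finite")
    else {
      if (any(object@errorCurve[ok] < 0)) msgs <- c(msgs, "errors must be >= 0")
      if (abs(object@errorCurve[match(object@gOpt, object@gGrid)] -
              min(object@errorCurve[ok])) > 1e-12)
        msgs <- c(msgs, "gOpt must attain the minimum error")
    }
    if (length(msgs)) msgs else TRUE
  })

#' PerturbationReport: susceptibility and information encoding capability
#'
#' Per-trial shifts of the spatiotemporally averaged local order parameter
#' under random positive shifts of the bifurcation parameters, and their
#' aggregates: susceptibility = mean absolute shift, information encoding
#' capability = SD of the absolute shifts.
#'
#' @slot perTrialDelta perturbed-minus-unperturbed mean R, one per trial.
#' @slot susceptibility mean(|perTrialDelta|).
#' @slot infoCapability sd(|perTrialDelta|).
#'
#' @export
setClass("PerturbationReport",
  representation(perTrialDelta = "numeric", susceptibility = "numeric",
    infoCapability = "numeric"),
  validity = function(object) {
    msgs <- character()
    if (abs(object@susceptibility - mean(abs(object@perTrialDelta))) > 1e-12)
      msgs <- c(msgs, "susceptibility must equal mean(|perTrialDelta|)")
    if (abs(object@infoCapability - stats::sd(abs(object@perTrialDelta))) > 1e-12)
      msgs <- c(msgs, "infoCapability must equal sd(|perTrialDelta|)")
    if (length(msgs)) msgs else TRUE
  })

#' CohortSpec: design of a synthetic three-group cohort
#'
#' @slot nRegions number of parcels.
#' @slot nVolumes volumes per subject (default 300).
#' @slot tr repetition time, seconds (default 2).
#' @slot groupSizes counts for (control, responder, non_responder).
#' @slot groupG global coupling per group, same order.
#' @slot outcomeCorrelation target Pearson correlation between baseline
#'   turbulence (lambda = 0.01) and HAMD6 percent change among patients.
#' @slot seed master seed; all subject seeds derive from it.
#'
#' @export
setClass("CohortSpec",
  representation(nRegions = "integer", nVolumes = "integer", tr = "numeric",
    groupSizes = "integer", groupG = "numeric", outcomeCorrelation = "numeric",
    seed = "integer"),
  validity = function(object) {
    msgs <- character()
    if (object@nVolumes < 50L) msgs <- c(msgs, "nVolumes must be >= 50")
    if (object@tr <= 0) msgs <- c(msgs, "tr must be > 0")
    if (length(object@groupSizes) != 3L || length(object@groupG) != 3L)
      msgs <- c(msgs, "groupSizes and groupG must each have 3 entries")
    if (any(object@groupG < 0)) msgs <- c(msgs, "groupG must be >= 0")
    if (abs(object@outcomeCorrelation) > 1)
      msgs <- c(msgs, "outcomeCorrelation must be in [-1, 1]")
    if (length(msgs)) msgs else TRUE
  })

#' SubjectRecord: one simulated subject of a synthetic cohort
#'
#' @slot subjectId identifier, unique within a cohort.
#' @slot group "control", "responder" or "non_responder".
#' @slot bold the subject's [BoldTimeseries-class].
#' @slot hamd6Baseline baseline severity score (patients only; NA controls).
#' @slot hamd6PctChange percent change at week 8 (patients only; NA controls).
#'
#' @export
setClass("SubjectRecord",
  representation(subjectId = "character", group = "character",
    bold = "BoldTimeseries", hamd6Baseline = "numeric", hamd6PctChange = "numeric"),
  validity = function(object) {
    msgs <- character()
    if (!object@group %in% c("control", "responder", "non_responder"))
      msgs <- c(msgs, "group must be control, responder or non_responder")
    if (length(msgs)) msgs else TRUE
  })

#' ClassifierReport: repeated-split SVM evaluation summary
#'
#' @slot aucMean,aucSd mean and SD of validation ROC-AUC over repetitions.
#' @slot accMean,accSd mean and SD of validation accuracy.
#' @slot pAuc,pAcc label-permutation p-values (NA until
#'   [permutationSignificance()] is run).
#' @slot nRepetitions repetitions evaluated.
#'
#' @export
setClass("ClassifierReport",
  representation(aucMean = "numeric", aucSd = "numeric", accMean = "numeric",
    accSd = "numeric", pAuc = "numeric", pAcc = "numeric",
    nRepetitions = "integer"),
  validity = function(object) {
    msgs <- character()
    if (object@aucMean < 0 || object@aucMean > 1 ||
        object@accMean < 0 || object@accMean > 1)
      msgs <- c(msgs, "mean AUC/accuracy must lie in [0, 1]")
    if (object@aucSd < 0 || object@accSd < 0)
      msgs <- c(msgs, "SDs must be >= 0")
    if (length(msgs)) msgs else TRUE
  })

# Show methods ------------------------------------------------------------

setMethod("show", "ParcelGeometry", function(object) {
  cat(sprintf("ParcelGeometry: %d regions, extent %.0f mm, %d RSNs\n",
    nrow(object@coords), max(object@dist), length(unique(object@rsnLabels))))
})

setMethod("show", "BoldTimeseries", function(object) {
  cat(sprintf("BoldTimeseries: %d regions x %d volumes, TR = %g s\n",
    nrow(object@data), ncol(object@data), object@tr))
})

setMethod("show", "PhaseField", function(object) {
  cat(sprintf("PhaseField: %d regions x %d volumes (trimmed %d per edge), TR = %g s\n",
    nrow(object@phases), ncol(object@phases), object@nTrimmed, object@tr))
})

setMethod("show", "LocalOrderField", function(object) {
  cat(sprintf("LocalOrderField: lambda = %g /mm, %d regions x %d volumes, mean R = %.3f\n",
    object@lambda, nrow(object@R), ncol(object@R), mean(object@R)))
})

setMethod("show", "TurbulenceProfile", function(object) {
  cat("TurbulenceProfile\n")
  cat("  turbulence:", paste(sprintf("%s=%.4f", names(object@turbulence),
    object@turbulence), collapse = " "), "\n")
  cat(sprintf("  information cascade: %.4f over %d scale pairs\n",
    object@informationCascade, length(object@cascadeFlow)))
  cat("  information transfer:", paste(sprintf("%s=%.4f",
    names(object@informationTransfer), object@informationTransfer),
    collapse = " "), "\n")
})

setMethod("show", "CouplingMatrix", function(object) {
  cat(sprintf("CouplingMatrix: %d x %d, EDR decay %g /mm, long-range source: %s\n",
    nrow(object@weights), ncol(object@weights), object@edrDecay, object@longrangeSource))
})

setMethod("show", "FitResult", function(object) {
  cat(sprintf("FitResult: G grid [%g, %g] (%d points, %d reps each), G_opt = %g\n",
    min(object@gGrid), max(object@gGrid), length(object@gGrid),
    object@nRepsPerG, object@gOpt))
})

setMethod("show", "PerturbationReport", function(object) {
  cat(sprintf("PerturbationReport: %d trials, susceptibility = %.4g, info capability = %.4g\n",
    length(object@perTrialDelta), object@susceptibility, object@infoCapability))
})

setMethod("show", "ClassifierReport", function(object) {
  cat(sprintf("ClassifierReport: AUC %.3f +/- %.3f (p = %s), accuracy %.3f +/- %.3f (p = %s), %d repetitions\n",
    object@aucMean, object@aucSd,
    ifelse(is.na(object@pAuc), "NA", format(object@pAuc, digits = 3)),
    object@accMean, object@accSd,
    ifelse(is.na(object@pAcc), "NA", format(object@pAcc, digits = 3)),
    object@nRepetitions))
})

setMethod("show", "SubjectRecord", function(object) {
  cat(sprintf("SubjectRecord %s (%s): %d x %d BOLD\n", object@subjectId,
    object@group, nrow(object@bold@data), ncol(object@bold@data)))
})
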