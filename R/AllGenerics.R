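# Accessor generics ------------------------------------------------------

#' Accessors for turbfmri objects
#'
#' Small accessor family used across the package's S4 classes: region
#' counts, coordinate/distance matrices, RSN labels, BOLD matrices and
#' repetition times, and the per-scale measure maps of a
#' [TurbulenceProfile-class].
#'
#' @param x an object of one of the package's S4 classes.
#' @return the requested slot content; see each class for units.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("nRegions", function(x) standardGeneric("nRegions"))

#' @rdname accessors
#' @export
setGeneric("coords", function(x) standardGeneric("coords"))

#' @rdname accessors
#' @export
setGeneric("distances", function(x) standardGeneric("distances"))

#' @rdname accessors
#' @export
setGeneric("rsnLabels", function(x) standardGeneric("rsnLabels"))

#' @rdname accessors
#' @export
setGeneric("boldData", function(x) standardGeneric("boldData"))

#' @rdname accessors
#' @export
setGeneric("repetitionTime", function(x) standardGeneric("repetitionTime"))

#' @rdname accessors
#' @export
setGeneric("phaseData", function(x) standardGeneric("phaseData"))

#' @rdname accessors
#' @export
setGeneric("orderParameter", function(x) standardGeneric("orderParameter"))

#' @rdname accessors
#' @export
setGeneric("turbulence", function(x) standardGeneric("turbulence"))

#' @rdname accessors
#' @export
setGeneric("nodeMetastability", function(x) standardGeneric("nodeMetastability"))

#' @rdname accessors
#' @export
setGeneric("cascadeFlow", function(x, y, ...) standardGeneric("cascadeFlow"))

#' @rdname accessors
#' @export
setGeneric("informationCascade", function(x) standardGeneric("informationCascade"))

#' @rdname accessors
#' @export
setGeneric("informationTransfer", function(x, ...) standardGeneric("informationTransfer"))

#' @rdname accessors
#' @export
setGeneric("couplingMatrix", function(x) standardGeneric("couplingMatrix"))

#' @rdname accessors
#' @export
setGeneric("gOpt", function(x) standardGeneric("gOpt"))

#' @rdname accessors
#' @export
setGeneric("errorCurve", function(x) standardGeneric("errorCurve"))

#' @rdname accessors
#' @export
setGeneric("susceptibility", function(x) standardGeneric("susceptibility"))

#' @rdname accessors
#' @export
setGeneric("infoCapability", function(x) standardGeneric("infoCapability"))

#' @rdname accessors
#' @export
setGeneric("perTrialDelta", function(x) standardGeneric("perTrialDelta"))

#' @rdname accessors
#' @export
setGeneric("subjectGroup", function(x) standardGeneric("subjectGroup"))

# Methods -----------------------------------------------------------------

#' @rdname accessors
setMethod("nRegions", "ParcelGeometry", function(x) nrow(x@coords))
#' @rdname accessors
setMethod("nRegions", "BoldTimeseries", function(x) nrow(x@data))
#' @rdname accessors
setMethod("nRegions", "PhaseField", function(x) nrow(x@phases))
#' @rdname accessors
setMethod("nRegions", "LocalOrderField", function(x) nrow(x@R))

#' @rdname accessors
setMethod("coords", "ParcelGeometry", function(x) x@coords)
#' @rdname accessors
setMethod("distances", "ParcelGeometry", function(x) x@dist)
#' @rdname accessors
setMethod("rsnLabels", "ParcelGeometry", function(x) x@rsnLabels)

#' @rdname accessors
setMethod("boldData", "BoldTimeseries", function(x) x@data)
#' @rdname accessors
setMethod("boldData", "SubjectRecord", function(x) x@bold@data)
#' @rdname accessors
setMethod("repetitionTime", "BoldTimeseries", function(x) x@tr)
#' @rdname accessors
setMethod("repetitionTime", "PhaseField", function(x) x@tr)
#' @rdname accessors
setMethod("phaseData", "PhaseField", function(x) x@phases)
#' @rdname accessors
setMethod("orderParameter", "LocalOrderField", function(x) x@R)

#' @rdname accessors
setMethod("turbulence", "TurbulenceProfile", function(x) x@turbulence)
#' @rdname accessors
setMethod("nodeMetastability", "TurbulenceProfile", function(x) x@nodeMetastability)

#' @rdname accessors
setMethod("couplingMatrix", "CouplingMatrix", function(x) x@weights)
#' @rdname accessors
setMethod("gOpt", "FitResult", function(x) x@gOpt)
#' @rdname accessors
setMethod("errorCurve", "FitResult", function(x)
  stats::setNames(x@errorCurve, x@gGrid))

#' @rdname accessors
setMethod("susceptibility", "PerturbationReport", function(x) x@susceptibility)
#' @rdname accessors
setMethod("infoCapability", "PerturbationReport", function(x) x@infoCapability)
#' @rdname accessors
setMethod("perTrialDelta", "PerturbationReport", function(x) x@perTrialDelta)
#' @rdname accessors
setMethod("subjectGroup", "SubjectRecord", function(x) x@group)
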