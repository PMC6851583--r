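## Accessor generics. Slots are never touched directly by user code.

#' @name accessors
#' @title Accessors for picovir result objects
#' @description Small accessor generics for the S4 containers: MPN point
#'   estimate and interval bounds, censoring state, infectivity, MOI,
#'   fluorescence events, gating fractions and simulated-experiment pieces.
#' @param object an S4 object from this package.
#' @return The corresponding slot value (see individual methods).
#' @examples
#' est <- estimateMPN(DilutionAssay(10^-(4:8), c(24, 24, 18, 4, 0), 24, 0.05))
#' mpn(est); ciLow(est); ciHigh(est)
NULL

#' @rdname accessors
#' @export
setGeneric("mpn", function(object) standardGeneric("mpn"))
#' @rdname accessors
#' @export
setGeneric("ciLow", function(object) standardGeneric("ciLow"))
#' @rdname accessors
#' @export
setGeneric("ciHigh", function(object) standardGeneric("ciHigh"))
#' @rdname accessors
#' @export
setGeneric("censoring", function(object) standardGeneric("censoring"))
#' @rdname accessors
#' @export
setGeneric("infectivityValue", function(object)
  standardGeneric("infectivityValue"))
#' @rdname accessors
#' @export
setGeneric("moi", function(object) standardGeneric("moi"))
#' @rdname accessors
#' @export
setGeneric("moiCI", function(object) standardGeneric("moiCI"))
#' @rdname accessors
#' @export
setGeneric("fluorescence", function(object) standardGeneric("fluorescence"))
#' @rdname accessors
#' @export
setGeneric("fG1", function(object) standardGeneric("fG1"))
#' @rdname accessors
#' @export
setGeneric("fGtG1", function(object) standardGeneric("fGtG1"))
#' @rdname accessors
#' @export
setGeneric("g1Mode", function(object) standardGeneric("g1Mode"))
#' @rdname accessors
#' @export
setGeneric("g2Mode", function(object) standardGeneric("g2Mode"))
#' @rdname accessors
#' @export
setGeneric("fInfected", function(object) standardGeneric("fInfected"))
#' @rdname accessors
#' @export
setGeneric("scalingFactor", function(object)
  standardGeneric("scalingFactor"))
#' @rdname accessors
#' @export
setGeneric("abundance", function(object) standardGeneric("abundance"))
#' @rdname accessors
#' @export
setGeneric("flowSamples", function(object) standardGeneric("flowSamples"))
#' @rdname accessors
#' @export
setGeneric("groundTruth", function(object) standardGeneric("groundTruth"))
#' @rdname accessors
#' @export
setGeneric("simConfig", function(object) standardGeneric("simConfig"))

#' @rdname accessors
#' @export
setMethod("mpn", "MPNEstimate", function(object) object@mpn)
#' @rdname accessors
#' @export
setMethod("ciLow", "MPNEstimate", function(object) object@ciLow)
#' @rdname accessors
#' @export
setMethod("ciHigh", "MPNEstimate", function(object) object@ciHigh)
#' @rdname accessors
#' @export
setMethod("censoring", "MPNEstimate", function(object) object@censored)
#' @rdname accessors
#' @export
setMethod("ciLow", "InfectivityResult", function(object) object@ciLow)
#' @rdname accessors
#' @export
setMethod("ciHigh", "InfectivityResult", function(object) object@ciHigh)
#' @rdname accessors
#' @export
setMethod("censoring", "InfectivityResult", function(object) object@censored)
#' @rdname accessors
#' @export
setMethod("infectivityValue", "InfectivityResult",
          function(object) object@infectivity)
#' @rdname accessors
#' @export
setMethod("moi", "InfectivityResult", function(object) object@moi)
#' @rdname accessors
#' @export
setMethod("moiCI", "InfectivityResult",
          function(object) c(low = object@moiCiLow, high = object@moiCiHigh))
#' @rdname accessors
#' @export
setMethod("fluorescence", "FlowSample", function(object) object@fluorescence)
#' @rdname accessors
#' @export
setMethod("fG1", "CellCycleFractions", function(object) object@fG1)
#' @rdname accessors
#' @export
setMethod("fGtG1", "CellCycleFractions", function(object) object@fGtG1)
#' @rdname accessors
#' @export
setMethod("g1Mode", "CellCycleFractions", function(object) object@g1Mode)
#' @rdname accessors
#' @export
setMethod("g2Mode", "CellCycleFractions", function(object) object@g2Mode)
#' @rdname accessors
#' @export
setMethod("fInfected", "InfectedFractionResult",
          function(object) object@fInfected)
#' @rdname accessors
#' @export
setMethod("scalingFactor", "InfectedFractionResult",
          function(object) object@scaling)
#' @rdname accessors
#' @export
setMethod("abundance", "SimExperiment", function(object) object@abundance)
#' @rdname accessors
#' @export
setMethod("flowSamples", "SimExperiment", function(object) object@flowSamples)
#' @rdname accessors
#' @export
setMethod("groundTruth", "SimExperiment", function(object) object@truth)
#' @rdname accessors
#' @export
setMethod("simConfig", "SimExperiment", function(object) object@config)

#' @rdname gateG1
#' @export
setGeneric("gateG1", function(sample, ...) standardGeneric("gateG1"))
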