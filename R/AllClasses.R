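#' @import methods
NULL

## ---------------------------------------------------------------------------
## SimConfig
## ---------------------------------------------------------------------------

#' Configuration of a synthetic infection experiment
#'
#' \code{SimConfig} holds the full parameterization of the stochastic
#' discrete-time simulator: the experimental clock (hours relative to virus
#' addition at \code{t = 0}, dawn at \code{-3.5} h), diel-synchronized host
#' growth, viral adsorption/latency/burst with optional reinfection, the
#' DNA-content (flow cytometry) observation model and multiplicative
#' lognormal count noise. Defaults reproduce the standard-light (SL)
#' batch-culture infection: hosts at \eqn{3.2 \times 10^6} cells/mL growing at
#' 0.76/d, a target multiplicity of infection (MOI) of 3 given 32\% virion
#' infectivity, a 7 h latent period and a mean burst of 500 progeny per cell.
#'
#' @slot seed integer RNG seed; every random draw in the simulator derives
#'   from it, so identical configurations give bit-identical output.
#' @slot dt time step (h).
#' @slot tStart,tEnd experiment window (h); virus is added at \code{t = 0}.
#' @slot sampleTimes sampling grid (h), aligned to the \code{dt} grid.
#' @slot light \code{"SL"} or \code{"LL"} (standard vs limited light).
#' @slot dawn clock time of lights-on relative to virus addition (h).
#' @slot photoperiod hours of light per 24 h cycle (14:10 cycle by default).
#' @slot muMax host specific growth rate (1/d) for this light condition.
#' @slot divisionWindow diel interval (h after lights-on) during which
#'   division occurs; the within-window hazard is calibrated so growth over
#'   one full diel cycle equals \code{exp(muMax)}.
#' @slot N0Host initial host concentration (cells/mL).
#' @slot V0 virion inoculum concentration (virions/mL).
#' @slot infectivityTrue fraction of virions able to complete an infection.
#' @slot kAds adsorption rate constant (mL/virion/h... i.e. per-virion hazard
#'   \code{kAds * S} and per-cell infection hazard
#'   \code{kAds * infectivityTrue * V}).
#' @slot latentPeriodTrue time from entry to lysis (h).
#' @slot burstMean,burstCV progeny per lysed cell (mean and CV).
#' @slot arrestMode \code{"immediate"} or \code{"delayed"} cell-cycle arrest
#'   of infected cells; \code{arrestDelay} (h) applies to the delayed mode.
#' @slot arrestDelay hours post-infection during which delayed-arrest
#'   infected cells keep dividing.
#' @slot reinfection logical; if \code{FALSE} progeny virions never adsorb
#'   (classical one-step conditions).
#' @slot adsorptionStop time (h) after which all adsorption ceases
#'   (\code{Inf} by default; finite values emulate post-adsorption dilution).
#' @slot genomeRatio viral genome length / host genome length.
#' @slot noiseCVCounts CV of the multiplicative lognormal measurement noise
#'   on observed concentrations.
#' @slot eventsPerSample flow-cytometry events drawn per sample.
#' @slot fluorCV per-cell fluorescence CV.
#' @slot nReplicates biological replicates per treatment.
#' @slot phaseEntryRate G1 -> S entry hazard (1/h) inside the division
#'   window; \code{NA} auto-calibrates to 1.6x the division-window hazard.
#' @slot phaseTransitRate S -> G2M and G2M -> G1 transit hazard (1/h).
#'
#' @seealso [runExperiment()], [stepSim()], [emitFlowSample()]
#' @export
setClass("SimConfig", representation(
  seed = "numeric", dt = "numeric", tStart = "numeric", tEnd = "numeric",
  sampleTimes = "numeric", light = "character", dawn = "numeric",
  photoperiod = "numeric", muMax = "numeric", divisionWindow = "numeric",
  N0Host = "numeric", V0 = "numeric", infectivityTrue = "numeric",
  kAds = "numeric", latentPeriodTrue = "numeric", burstMean = "numeric",
  burstCV = "numeric", arrestMode = "character", arrestDelay = "numeric",
  reinfection = "logical", adsorptionStop = "numeric",
  genomeRatio = "numeric", noiseCVCounts = "numeric",
  eventsPerSample = "numeric", fluorCV = "numeric", nReplicates = "numeric",
  phaseEntryRate = "numeric", phaseTransitRate = "numeric"
))

setValidity("SimConfig", function(object) {
  msg <- character()
  chk <- function(cond, m) if (!isTRUE(cond)) msg <<- c(msg, m)
  chk(object@dt > 0, "dt must be > 0")
  chk(object@tStart < 0 && 0 < object@tEnd, "tStart < 0 < tEnd required")
  chk(object@infectivityTrue >= 0 && object@infectivityTrue <= 1,
      "infectivityTrue must lie in [0, 1]")
  chk(object@burstMean > 0, "burstMean must be > 0")
  chk(object@burstCV >= 0, "burstCV must be >= 0")
  chk(object@latentPeriodTrue > 0, "latentPeriodTrue must be > 0")
  chk(object@N0Host > 0, "N0Host must be > 0")
  chk(object@V0 >= 0, "V0 must be >= 0")
  chk(object@kAds >= 0, "kAds must be >= 0")
  chk(object@muMax >= 0, "muMax must be >= 0")
  chk(object@noiseCVCounts >= 0 && object@fluorCV >= 0,
      "noise CVs must be >= 0")
  chk(object@eventsPerSample >= 1, "eventsPerSample must be >= 1")
  chk(object@nReplicates >= 1, "nReplicates must be >= 1")
  chk(object@arrestMode %in% c("immediate", "delayed"),
      "arrestMode must be 'immediate' or 'delayed'")
  chk(length(object@divisionWindow) == 2 &&
        object@divisionWindow[1] < object@divisionWindow[2],
      "divisionWindow must be an increasing interval")
  chk(all(object@sampleTimes >= object@tStart) &&
        all(object@sampleTimes <= object@tEnd),
      "sampleTimes must lie within [tStart, tEnd]")
  offs <- (object@sampleTimes - object@tStart) / object@dt
  chk(all(abs(offs - round(offs)) < 1e-8),
      "sampleTimes must align to the dt grid")
  ## tau-leap preconditions: per-step probabilities well below 1
  chk(object@kAds * object@N0Host * object@dt < 1,
      "dt too large: per-virion adsorption probability per step reaches 1")
  chk(object@kAds * object@infectivityTrue * object@V0 * object@dt < 1,
      "dt too large: per-cell infection probability per step reaches 1")
  if (object@V0 > 0) {
    moi <- object@infectivityTrue * object@V0 / object@N0Host
    chk(moi <= 100,
        "configured MOI exceeds 100 infectious virions per host cell")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a simulation configuration
#'
#' Builds a [SimConfig-class] with experiment-anchored defaults. Growth-rate
#' defaults depend on the light condition: 0.76/d for \code{"SL"} and
#' 0.091/d for \code{"LL"}. When \code{V0} is \code{NULL} it is set to
#' \code{moiTarget * N0Host / infectivityTrue}, i.e. the inoculum achieving
#' the target MOI given the stock's infectivity.
#'
#' @param seed integer RNG seed.
#' @param light \code{"SL"} or \code{"LL"}.
#' @param muMax host growth rate (1/d); defaults by light condition.
#' @param V0 virion inoculum (virions/mL) or \code{NULL} to derive from
#'   \code{moiTarget}.
#' @param moiTarget target MOI used only when \code{V0} is \code{NULL}.
#' @param dt,tStart,tEnd,sampleTimes,dawn,photoperiod,divisionWindow,N0Host
#'   see [SimConfig-class].
#' @param infectivityTrue,kAds,latentPeriodTrue,burstMean,burstCV see
#'   [SimConfig-class].
#' @param arrestMode,arrestDelay,reinfection,adsorptionStop,genomeRatio see
#'   [SimConfig-class].
#' @param noiseCVCounts,eventsPerSample,fluorCV,nReplicates see
#'   [SimConfig-class].
#' @param phaseEntryRate,phaseTransitRate cell-cycle conveyor hazards (1/h).
#' @return A validated [SimConfig-class] object.
#' @examples
#' cfg <- SimConfig(seed = 1)
#' cfg
#' @export
SimConfig <- function(seed = 1L, light = c("SL", "LL"), muMax = NULL,
                      V0 = NULL, moiTarget = 3,
                      dt = 0.05, tStart = -3.5, tEnd = 24.5,
                      sampleTimes = c(-3.5, 0.5, 2.5, 4.5, 6.5, 8.5, 10.5,
                                      12.5, 14.5, 18.5, 24.5),
                      dawn = -3.5, photoperiod = 14,
                      divisionWindow = c(6, 14), N0Host = 3.2e6,
                      infectivityTrue = 0.32, kAds = 1.5e-8,
                      latentPeriodTrue = 7, burstMean = 500, burstCV = 0.1,
                      arrestMode = "immediate", arrestDelay = 6,
                      reinfection = TRUE, adsorptionStop = Inf,
                      genomeRatio = 0.015, noiseCVCounts = 0.08,
                      eventsPerSample = 5000, fluorCV = 0.05,
                      nReplicates = 3, phaseEntryRate = NA_real_,
                      phaseTransitRate = 0.5) {
  light <- match.arg(light)
  if (is.null(muMax)) muMax <- if (light == "SL") 0.76 else 0.091
  if (is.null(V0)) {
    if (infectivityTrue <= 0) stop("cannot derive V0 from moiTarget when ",
                                   "infectivityTrue is 0; supply V0")
    V0 <- moiTarget * N0Host / infectivityTrue
  }
  new("SimConfig", seed = as.numeric(seed), dt = dt, tStart = tStart,
      tEnd = tEnd, sampleTimes = sampleTimes, light = light, dawn = dawn,
      photoperiod = photoperiod, muMax = muMax,
      divisionWindow = divisionWindow, N0Host = N0Host, V0 = V0,
      infectivityTrue = infectivityTrue, kAds = kAds,
      latentPeriodTrue = latentPeriodTrue, burstMean = burstMean,
      burstCV = burstCV, arrestMode = arrestMode, arrestDelay = arrestDelay,
      reinfection = reinfection, adsorptionStop = adsorptionStop,
      genomeRatio = genomeRatio, noiseCVCounts = noiseCVCounts,
      eventsPerSample = eventsPerSample, fluorCV = fluorCV,
      nReplicates = nReplicates, phaseEntryRate = phaseEntryRate,
      phaseTransitRate = phaseTransitRate)
}

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig (", object@light, ")\n", sep = "")
  cat("  window      : [", object@tStart, ", ", object@tEnd, "] h, dt = ",
      object@dt, " h, dawn at ", object@dawn, " h\n", sep = "")
  cat("  host        : N0 =", format(object@N0Host, digits = 3),
      "cells/mL, mu =", object@muMax, "/d, division window",
      paste(object@divisionWindow, collapse = "-"), "h after lights-on\n")
  cat("  virus       : V0 =", format(object@V0, digits = 3),
      "virions/mL, infectivity =", object@infectivityTrue,
      ", MOI =", format(object@infectivityTrue * object@V0 / object@N0Host,
                        digits = 3), "\n")
  cat("  infection   : k_ads =", object@kAds, "mL/h, latent =",
      object@latentPeriodTrue, "h, burst =", object@burstMean,
      "(CV", object@burstCV, "), arrest =", object@arrestMode,
      ", reinfection =", object@reinfection, "\n")
  cat("  observation :", object@eventsPerSample, "events/sample, count CV =",
      object@noiseCVCounts, ", fluor CV =", object@fluorCV,
      ",", object@nReplicates, "replicates, seed =", object@seed, "\n")
})

## ---------------------------------------------------------------------------
## SimExperiment
## ---------------------------------------------------------------------------

#' A simulated infection experiment
#'
#' Container returned by [runExperiment()]: tidy abundance series (latent,
#' i.e. noiseless, and observed), per-sample flow-cytometry event tables,
#' latent-state snapshots at every sampling time, and the generative ground
#' truth for parameter-recovery assertions.
#'
#' @slot config the [SimConfig-class] used.
#' @slot abundance data.frame with columns \code{treatment}, \code{light},
#'   \code{replicate}, \code{time_h}, \code{target} (\code{"host"} or
#'   \code{"virus"}), \code{value_per_ml} (observed) and
#'   \code{latent_per_ml} (noiseless).
#' @slot flowSamples named list of [FlowSample-class] objects (empty when
#'   flow emission was disabled).
#' @slot snapshots nested list (per treatment, per sampling time) of latent
#'   simulator states as used by [emitFlowSample()].
#' @slot truth list of generative parameters and the true infected-fraction
#'   trajectory; immutable record of what the estimators should recover.
#' @export
setClass("SimExperiment", representation(
  config = "SimConfig", abundance = "data.frame", flowSamples = "list",
  snapshots = "list", truth = "list"
))

setMethod("show", "SimExperiment", function(object) {
  ab <- object@abundance
  cat("SimExperiment:", length(unique(ab$treatment)), "treatment(s) x",
      object@config@nReplicates, "replicates x",
      length(unique(ab$time_h)), "timepoints (", object@config@light,
      ", seed", object@config@seed, ")\n")
  cat("  flow samples:", length(object@flowSamples), "\n")
  cat("  true infectivity =", object@truth$infectivityTrue,
      ", latent =", object@truth$latentPeriodTrue,
      "h, burst =", object@truth$burstMean, "\n")
})

## ---------------------------------------------------------------------------
## DilutionAssay / MPNEstimate / InfectivityResult
## ---------------------------------------------------------------------------

#' Serial-dilution assay well outcomes
#'
#' Positive/total well counts per dilution level with inoculum volumes; the
#' input to most-probable-number (MPN) inference under the Poisson
#' single-hit model.
#'
#' @slot dilution dilution factors (dimensionless, e.g. \code{1e-6}).
#' @slot positive number of lysed (infection-positive) wells per level.
#' @slot total number of wells per level.
#' @slot volume inoculum volume per well (mL).
#' @export
setClass("DilutionAssay", representation(
  dilution = "numeric", positive = "numeric", total = "numeric",
  volume = "numeric"
))

setValidity("DilutionAssay", function(object) {
  n <- length(object@dilution)
  msg <- character()
  if (length(object@positive) != n || length(object@total) != n ||
      length(object@volume) != n)
    msg <- c(msg, "all fields must have equal length")
  if (any(object@dilution <= 0)) msg <- c(msg, "dilutions must be > 0")
  if (anyDuplicated(object@dilution))
    msg <- c(msg, "dilution factors must be distinct")
  if (any(object@positive < 0) || any(object@positive > object@total))
    msg <- c(msg, "need 0 <= positive <= total at every level")
  if (any(object@total < 1)) msg <- c(msg, "total wells must be >= 1")
  if (any(object@volume <= 0)) msg <- c(msg, "volumes must be > 0")
  if (length(msg)) msg else TRUE
})

#' @rdname DilutionAssay-class
#' @param dilution,positive,total,volume see slots.
#' @return A validated \code{DilutionAssay}.
#' @examples
#' DilutionAssay(dilution = 10^-(4:8), positive = c(24, 24, 18, 4, 0),
#'               total = 24, volume = 0.05)
#' @export
DilutionAssay <- function(dilution, positive, total, volume) {
  n <- length(dilution)
  new("DilutionAssay", dilution = as.numeric(dilution),
      positive = as.numeric(rep_len(positive, n)),
      total = as.numeric(rep_len(total, n)),
      volume = as.numeric(rep_len(volume, n)))
}

setMethod("show", "DilutionAssay", function(object) {
  cat("DilutionAssay with", length(object@dilution), "levels\n")
  print(data.frame(dilution = object@dilution, positive = object@positive,
                   total = object@total, volume_ml = object@volume),
        row.names = FALSE)
})

#' Most-probable-number estimate
#'
#' Maximum-likelihood infectious-unit concentration under the Poisson
#' single-hit model, with a 95\% Wald interval on \code{log(c)}. Assays with
#' all wells negative (or all positive) yield one-sided censored estimates.
#'
#' @slot mpn MLE of the infectious concentration (units/mL).
#' @slot ciLow,ciHigh confidence bounds (units/mL).
#' @slot logLik maximized log-likelihood.
#' @slot nLevels number of dilution levels used.
#' @slot censored \code{"none"}, \code{"allNegative"} or \code{"allPositive"}.
#' @slot conf confidence level of the interval.
#' @export
setClass("MPNEstimate", representation(
  mpn = "numeric", ciLow = "numeric", ciHigh = "numeric",
  logLik = "numeric", nLevels = "numeric", censored = "character",
  conf = "numeric"
))

setValidity("MPNEstimate", function(object) {
  if (object@censored == "none" && is.finite(object@ciLow) &&
      is.finite(object@ciHigh) &&
      !(object@ciLow <= object@mpn && object@mpn <= object@ciHigh))
    return("ciLow <= mpn <= ciHigh violated")
  TRUE
})

setMethod("show", "MPNEstimate", function(object) {
  cat("MPN estimate: ", format(object@mpn, digits = 3), " /mL  (",
      100 * object@conf, "% CI ", format(object@ciLow, digits = 3), "-",
      format(object@ciHigh, digits = 3), ")\n", sep = "")
  if (object@censored != "none")
    cat("  censored:", object@censored, "(one-sided bound only)\n")
})

#' Infectivity and multiplicity of infection
#'
#' The infectious fraction of a virus stock (MPN titre over total
#' SYBR-counted virions) with its scaled confidence interval; after
#' [computeMOI()], also the virus:host ratio and the MOI with its interval
#' (MOI = virus:host ratio x infectivity).
#'
#' @slot infectivity infectious fraction (0-1).
#' @slot ciLow,ciHigh confidence bounds on the fraction.
#' @slot totalVirions total virion concentration used (virions/mL).
#' @slot censored censoring state inherited from the MPN estimate.
#' @slot virusHostRatio total virions per host cell (NA until
#'   [computeMOI()]).
#' @slot moi,moiCiLow,moiCiHigh infectious virions per host cell with
#'   confidence bounds (NA until [computeMOI()]).
#' @export
setClass("InfectivityResult", representation(
  infectivity = "numeric", ciLow = "numeric", ciHigh = "numeric",
  totalVirions = "numeric", censored = "character",
  virusHostRatio = "numeric", moi = "numeric", moiCiLow = "numeric",
  moiCiHigh = "numeric"
))

setMethod("show", "InfectivityResult", function(object) {
  cat("Infectivity: ", format(100 * object@infectivity, digits = 3), "% (",
      format(100 * object@ciLow, digits = 3), "%-",
      format(100 * object@ciHigh, digits = 3), "%)\n", sep = "")
  if (!is.na(object@moi))
    cat("MOI: ", format(signif(object@moi, 2)), " (",
        format(signif(object@moiCiLow, 2)), "-",
        format(signif(object@moiCiHigh, 2)), ") at virus:host = ",
        format(object@virusHostRatio, digits = 3), "\n", sep = "")
  if (object@censored != "none") cat("  censored:", object@censored, "\n")
  if (!is.na(object@infectivity) && object@infectivity > 1)
    cat("  NOTE: infectivity > 1 (MPN exceeds total virion count)\n")
})

## ---------------------------------------------------------------------------
## FlowSample / CellCycleFractions / InfectedFractionResult
## ---------------------------------------------------------------------------

#' Per-cell DNA-stain fluorescence events for one sample
#'
#' One flow-cytometry sample: per-event SYBR (DNA) fluorescence intensities
#' on a linear scale, plus sample metadata. Fluorescence is expressed in
#' arbitrary units; the gating in [gateG1()] is gain-invariant.
#'
#' @slot sampleId sample identifier.
#' @slot treatment e.g. \code{"control"} or \code{"virus"}.
#' @slot light light condition label.
#' @slot replicate replicate index.
#' @slot timeH hours since virus addition.
#' @slot fluorescence per-event intensities (> 0).
#' @export
setClass("FlowSample", representation(
  sampleId = "character", treatment = "character", light = "character",
  replicate = "numeric", timeH = "numeric", fluorescence = "numeric"
))

setValidity("FlowSample", function(object) {
  if (any(object@fluorescence <= 0))
    return("all fluorescence intensities must be > 0")
  TRUE
})

#' @rdname FlowSample-class
#' @param fluorescence per-event intensities.
#' @param sampleId,treatment,light,replicate,timeH metadata.
#' @return A validated \code{FlowSample}.
#' @export
FlowSample <- function(fluorescence, sampleId = "sample",
                       treatment = "control", light = "SL", replicate = 1,
                       timeH = 0) {
  new("FlowSample", sampleId = sampleId, treatment = treatment,
      light = light, replicate = replicate, timeH = timeH,
      fluorescence = as.numeric(fluorescence))
}

setMethod("show", "FlowSample", function(object) {
  cat("FlowSample '", object@sampleId, "': ",
      length(object@fluorescence), " events (", object@treatment, ", ",
      object@light, ", rep ", object@replicate, ", t = ", object@timeH,
      " h)\n", sep = "")
})

#' Cell-cycle gating fractions
#'
#' Result of [gateG1()]: the G1 gate placed around the major DNA-fluorescence
#' peak and the fraction of events above it (dividing and/or virally
#' replicating cells, \eqn{F^{>G1}}).
#'
#' @slot fG1 fraction of (non-debris) events inside the G1 gate.
#' @slot fGtG1 fraction of events above the G1 gate's upper edge.
#' @slot g1Mode fluorescence of the G1 peak.
#' @slot g2Mode fluorescence of the secondary (2x) peak, NA if absent.
#' @slot nEvents total events in the sample.
#' @slot nUsed events above the debris floor used as denominator.
#' @export
setClass("CellCycleFractions", representation(
  fG1 = "numeric", fGtG1 = "numeric", g1Mode = "numeric",
  g2Mode = "numeric", nEvents = "numeric", nUsed = "numeric"
))

setValidity("CellCycleFractions", function(object) {
  if (is.finite(object@fG1) && is.finite(object@fGtG1) &&
      object@fG1 + object@fGtG1 > 1 + 1e-8)
    return("fG1 + fGtG1 must not exceed 1")
  TRUE
})

setMethod("show", "CellCycleFractions", function(object) {
  cat("CellCycleFractions: fG1 = ", round(object@fG1, 3),
      ", f>G1 = ", round(object@fGtG1, 3),
      ", G1 mode = ", format(object@g1Mode, digits = 3),
      ", 2x peak = ", format(object@g2Mode, digits = 3),
      " (", object@nUsed, "/", object@nEvents, " events)\n", sep = "")
})

#' Infected-fraction correction result
#'
#' Result of [infectedFraction()]: the inferred frequency of infected cells
#' \eqn{F_I = F^{>G1} - F^D} where the dividing-cell frequency
#' \eqn{F^D = F^D_C \times s} rescales the mean control dividing fraction by
#' \eqn{s = n_I / n_C}, the ratio of generations since dawn in infected vs
#' control cultures, clamped to [0, 1].
#'
#' @slot fInfected inferred infected fraction (floored at 0).
#' @slot fDividing inferred dividing fraction of the infected culture.
#' @slot fDividingControl mean control dividing fraction used.
#' @slot scaling the clamped scaling factor s.
#' @slot nInfected,nControl generations since dawn in the infected and
#'   control cultures.
#' @slot clamped whether s was clamped (or the nControl = 0 convention
#'   applied).
#' @export
setClass("InfectedFractionResult", representation(
  fInfected = "numeric", fDividing = "numeric",
  fDividingControl = "numeric", scaling = "numeric", nInfected = "numeric",
  nControl = "numeric", clamped = "logical"
))

setMethod("show", "InfectedFractionResult", function(object) {
  cat("InfectedFractionResult: F_I = ", round(object@fInfected, 3),
      " (F^D = ", round(object@fDividing, 3), ", s = ",
      round(object@scaling, 3),
      if (object@clamped) ", clamped" else "", ")\n", sep = "")
})
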