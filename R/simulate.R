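## Stochastic discrete-time simulator of a lytic infection experiment in a
## diel-synchronized picophytoplankton batch culture. Concentrations are
## continuous densities (tau-leap updates); stochasticity enters through
## burst-size draws, measurement noise, flow-event sampling and MPN well
## outcomes. All randomness derives from the config seed.

## Deterministic seed mixing; result stays inside 32-bit integer range.
.mixSeed <- function(...) {
  ints <- as.numeric(c(...))
  as.integer(Reduce(function(a, b) (a * 69069 + b + 1) %% 2147483629,
                    ints, accumulate = FALSE) + 1)
}

## Division hazard (1/h) inside the diel window: calibrated so that growth
## over one full dawn-to-dawn cycle equals exp(muMax [1/d]).
.windowHazard <- function(config) {
  W <- diff(config@divisionWindow)
  config@muMax / W
}

.phaseEntryRate <- function(config) {
  if (is.na(config@phaseEntryRate)) 1.6 * .windowHazard(config)
  else config@phaseEntryRate
}

.inWindow <- function(t, config) {
  h <- (t - config@dawn) %% 24
  ## tolerance guards the window edges against accumulated float drift in t
  h >= config@divisionWindow[1] - 1e-6 & h < config@divisionWindow[2] - 1e-6
}

.nAgeBins <- function(config) {
  max(1L, as.integer(round(config@latentPeriodTrue / config@dt)))
}

#' Initialize a simulator state
#'
#' All hosts start in G1 (the dawn-synchronized condition); the virion pools
#' are empty until the inoculum is added at \code{t = 0} by
#' [runExperiment()].
#'
#' @param config a [SimConfig-class].
#' @return A state list with clock time \code{t}, susceptible hosts by
#'   cell-cycle phase \code{sPhase} (G1, S, G2M; cells/mL), infected hosts
#'   by infection age \code{iAge} (one bin per \code{dt}), virion pools
#'   \code{vInoc}/\code{vProg}, and cumulative mass-balance counters
#'   (\code{cumLysed}, \code{cumDivisions}, \code{cumBurst},
#'   \code{cumAdsorbed}).
#' @export
newSimState <- function(config) {
  list(t = config@tStart,
       sPhase = c(G1 = config@N0Host, S = 0, G2M = 0),
       iAge = numeric(.nAgeBins(config)),
       vInoc = 0, vProg = 0,
       cumLysed = 0, cumDivisions = 0, cumBurst = 0, cumAdsorbed = 0,
       hostN0 = config@N0Host)
}

#' Advance the simulator by one time step
#'
#' Applies, in order: (1) adsorption -- every virion adsorbs to susceptible
#' cells at per-virion hazard \code{kAds * S}; the infectious subset drives
#' new infections at per-cell hazard \code{kAds * infectivityTrue * V},
#' moving hosts from \code{sPhase} into the youngest infection-age bin;
#' (2) aging of infected cohorts; (3) lysis of the cohort reaching the
#' latent period, releasing a burst with mean \code{burstMean} and CV
#' \code{burstCV} (a gamma draw; degenerate at \code{burstMean} when the CV
#' is 0) into the progeny pool; (4) diel division of uninfected cells (and
#' of pre-arrest infected cells under delayed arrest) inside the division
#' window, as an exact exponential factor so realized growth matches the
#' configured rate; (5) cell-cycle conveyor flows G1 -> S -> G2M -> G1
#' (entry into S only inside the window; S and G2M drain back to G1 around
#' the clock, emulating completion of division by dawn).
#'
#' Mass balance is maintained exactly: hosts destroyed equal lysed cells,
#' virions created equal the sum of burst draws, virions removed equal
#' adsorption. The only RNG consumption is the burst draw, and only on
#' steps where lysis occurs with a positive burst CV.
#'
#' @param state a state list from [newSimState()] (or a previous step).
#' @param config a [SimConfig-class].
#' @return The updated state list, with \code{t} advanced by \code{dt}.
#' @examples
#' cfg <- SimConfig(seed = 1)
#' st <- newSimState(cfg)
#' st <- stepSim(st, cfg)
#' @export
stepSim <- function(state, config) {
  dt <- config@dt
  t <- state$t
  sTot <- sum(state$sPhase)
  adsorbable <- state$vInoc + if (config@reinfection) state$vProg else 0

  ## (1) adsorption and infection
  newInf <- 0
  if (t < config@adsorptionStop && config@kAds > 0 && adsorbable > 0) {
    if (sTot > 0) {
      vRemoved <- adsorbable * -expm1(-config@kAds * sTot * dt)
      if (config@reinfection && state$vProg > 0) {
        shareInoc <- state$vInoc / adsorbable
        state$vInoc <- state$vInoc - vRemoved * shareInoc
        state$vProg <- state$vProg - vRemoved * (1 - shareInoc)
      } else {
        state$vInoc <- state$vInoc - vRemoved
      }
      state$cumAdsorbed <- state$cumAdsorbed + vRemoved
      if (config@infectivityTrue > 0) {
        pInf <- -expm1(-config@kAds * config@infectivityTrue *
                         adsorbable * dt)
        newInf <- sTot * pInf
        state$sPhase <- state$sPhase * (1 - pInf)
      }
    }
  }

  ## (2) aging, (3) lysis of the cohort completing the latent period
  iAge <- state$iAge
  nB <- length(iAge)
  lysing <- iAge[nB]
  iAge <- c(newInf, iAge[-nB])
  if (lysing > 0) {
    b <- config@burstMean
    if (config@burstCV > 0) {
      shape <- 1 / config@burstCV^2
      b <- stats::rgamma(1L, shape = shape, rate = shape / config@burstMean)
    }
    state$vProg <- state$vProg + lysing * b
    state$cumBurst <- state$cumBurst + lysing * b
    state$cumLysed <- state$cumLysed + lysing
  }

  ## (4) diel division pulse
  inWin <- .inWindow(t, config)
  if (inWin && config@muMax > 0) {
    g <- exp(.windowHazard(config) * dt)
    grew <- sum(state$sPhase) * (g - 1)
    state$sPhase <- state$sPhase * g
    if (config@arrestMode == "delayed") {
      young <- (seq_len(nB) * dt) < config@arrestDelay
      grew <- grew + sum(iAge[young]) * (g - 1)
      iAge[young] <- iAge[young] * g
    }
    state$cumDivisions <- state$cumDivisions + grew
  }

  ## (5) cell-cycle conveyor
  pT <- -expm1(-config@phaseTransitRate * dt)
  f2 <- state$sPhase[2] * pT                     # S -> G2M
  f3 <- state$sPhase[3] * pT                     # G2M -> G1 (post-mitosis)
  f1 <- if (inWin) state$sPhase[1] * -expm1(-.phaseEntryRate(config) * dt)
        else 0                                   # G1 -> S, window only
  state$sPhase <- state$sPhase + c(f3 - f1, f1 - f2, f2 - f3)

  state$iAge <- iAge
  state$t <- t + dt

  if (any(state$sPhase < -1e-9) || any(state$iAge < -1e-9) ||
      state$vInoc < -1e-9 || state$vProg < -1e-9)
    stop("internal error: negative state encountered")
  state
}

.snapshot <- function(state) {
  hostTotal <- sum(state$sPhase) + sum(state$iAge)
  list(t = state$t, sPhase = state$sPhase, iAge = state$iAge,
       V = state$vInoc + state$vProg, hostTotal = hostTotal,
       infectedFraction = if (hostTotal > 0) sum(state$iAge) / hostTotal
                          else NA_real_,
       cumLysed = state$cumLysed, cumDivisions = state$cumDivisions,
       cumBurst = state$cumBurst, cumAdsorbed = state$cumAdsorbed)
}

## Forward-simulate one culture; the caller seeds the burst-draw stream.
.simulateDynamics <- function(config, V0) {
  state <- newSimState(config)
  nSteps <- round((config@tEnd - config@tStart) / config@dt)
  sampleIdx <- round((config@sampleTimes - config@tStart) / config@dt)
  snaps <- vector("list", length(config@sampleTimes))
  inoculated <- FALSE
  for (k in 0:nSteps) {
    if (!inoculated && state$t >= -config@dt / 2) {
      state$vInoc <- state$vInoc + V0
      inoculated <- TRUE
    }
    hit <- which(sampleIdx == k)
    if (length(hit)) {
      snaps[[hit]] <- .snapshot(state)
      snaps[[hit]]$t <- config@sampleTimes[hit]  # undo float drift in t
    }
    if (k < nSteps) state <- stepSim(state, config)
  }
  list(snapshots = snaps, finalState = state)
}

.lnormFactors <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  s2 <- log(1 + cv^2)
  stats::rlnorm(n, meanlog = -s2 / 2, sdlog = sqrt(s2))
}

#' Run a full synthetic infection experiment
#'
#' Simulates the control (no virus) and virus-amended cultures on the
#' configured sampling grid, then overlays per-replicate multiplicative
#' lognormal measurement noise and draws per-sample flow-cytometry event
#' tables. Noise and flow-event random streams are derived from
#' \code{(seed, replicate, timepoint)} and shared across treatments (common
#' random numbers), so a virus treatment with \code{V0 = 0} reproduces the
#' control bit-for-bit. The full run is deterministic given the config.
#'
#' @param config a [SimConfig-class].
#' @param treatments subset of \code{c("control", "virus")} to simulate.
#' @param flow logical; draw flow-cytometry samples? (Disable for speed in
#'   replicate Monte-Carlo runs that only need abundance series.)
#' @return A [SimExperiment-class]; see that class for the layout.
#' @examples
#' exp <- runExperiment(SimConfig(seed = 1, eventsPerSample = 500))
#' head(abundance(exp))
#' @export
runExperiment <- function(config, treatments = c("control", "virus"),
                          flow = TRUE) {
  validObject(config)
  treatments <- match.arg(treatments, several.ok = TRUE)
  dyn <- list()
  for (tr in treatments) {
    trIdx <- match(tr, c("control", "virus"))
    V0 <- if (tr == "control") 0 else config@V0
    set.seed(.mixSeed(config@seed, 11, trIdx))
    dyn[[tr]] <- .simulateDynamics(config, V0)
  }

  nT <- length(config@sampleTimes)
  nR <- config@nReplicates
  rows <- list()
  fsamples <- list()
  for (tr in treatments) {
    snaps <- dyn[[tr]]$snapshots
    for (r in seq_len(nR)) {
      for (j in seq_len(nT)) {
        sn <- snaps[[j]]
        set.seed(.mixSeed(config@seed, 101, r, j))
        fac <- .lnormFactors(2, config@noiseCVCounts)
        rows[[length(rows) + 1L]] <- data.frame(
          treatment = tr, light = config@light, replicate = r,
          time_h = sn$t, target = c("host", "virus"),
          value_per_ml = c(sn$hostTotal * fac[1], sn$V * fac[2]),
          latent_per_ml = c(sn$hostTotal, sn$V),
          stringsAsFactors = FALSE)
        if (flow) {
          set.seed(.mixSeed(config@seed, 202, r, j))
          id <- sprintf("%s_%s_r%d_t%g", tr, config@light, r, sn$t)
          fsamples[[id]] <- emitFlowSample(
            sn, config, sampleId = id, treatment = tr, replicate = r)
        }
      }
    }
  }
  ab <- do.call(rbind, rows)
  rownames(ab) <- NULL

  truth <- list(
    infectivityTrue = config@infectivityTrue,
    latentPeriodTrue = config@latentPeriodTrue,
    burstMean = config@burstMean,
    mu = config@muMax, light = config@light,
    moi = config@infectivityTrue * config@V0 / config@N0Host,
    infectedFractionTrue = if ("virus" %in% treatments)
      data.frame(time_h = config@sampleTimes,
                 f_infected = vapply(dyn[["virus"]]$snapshots,
                                     function(s) s$infectedFraction,
                                     numeric(1)))
    else NULL)

  new("SimExperiment", config = config, abundance = ab,
      flowSamples = fsamples,
      snapshots = lapply(dyn, `[[`, "snapshots"), truth = truth)
}

#' Draw a flow-cytometry sample from a simulator state
#'
#' Draws \code{eventsPerSample} cells multinomially in proportion to class
#' abundance (G1, S, G2M and each infection-age cohort) and assigns each a
#' DNA-stain fluorescence in host-genome units times a mean-one lognormal
#' factor with CV \code{fluorCV}: G1 cells at 1.0, S cells uniform on
#' (1, 2), G2M cells at 2.0, and infected cells at
#' \code{1 + genomeRatio * burstMean * age / latentPeriodTrue} (viral
#' genome copies accumulate linearly over the latent period). The G1 mode
#' therefore sits at half the G2M mode in expectation. The caller controls
#' the RNG state.
#'
#' @param state a snapshot list with elements \code{sPhase}, \code{iAge}
#'   and \code{t} (as produced by [newSimState()]/[stepSim()] or stored in
#'   a [SimExperiment-class]).
#' @param config a [SimConfig-class].
#' @param sampleId,treatment,replicate metadata for the returned sample.
#' @return A [FlowSample-class].
#' @examples
#' cfg <- SimConfig(seed = 1, eventsPerSample = 1000)
#' set.seed(1)
#' fs <- emitFlowSample(newSimState(cfg), cfg)
#' @export
emitFlowSample <- function(state, config, sampleId = "sample",
                           treatment = "control", replicate = 1) {
  w <- c(state$sPhase, state$iAge)
  if (sum(w) <= 0) stop("emitFlowSample: no cells in state")
  nEv <- as.integer(config@eventsPerSample)
  if (nEv < 100)
    warning("fewer than 100 events requested; histogram unreliable")
  counts <- as.vector(stats::rmultinom(1L, nEv, w))
  nB <- length(state$iAge)
  ages <- seq_len(nB) * config@dt
  dnaInf <- 1 + config@genomeRatio * config@burstMean *
    pmin(ages, config@latentPeriodTrue) / config@latentPeriodTrue
  dna <- c(rep(1, counts[1]),
           if (counts[2] > 0) stats::runif(counts[2], 1, 2) else numeric(0),
           rep(2, counts[3]),
           rep(dnaInf, counts[-(1:3)]))
  fl <- dna * .lnormFactors(length(dna), config@fluorCV)
  FlowSample(fl, sampleId = sampleId, treatment = treatment,
             light = config@light, replicate = replicate, timeH = state$t)
}

#' Simulate a serial-dilution MPN assay
#'
#' Each well receives \code{titerInfectious * dilution * inoculumVolume}
#' infectious units in expectation and turns positive with probability
#' \code{1 - exp(-titer * dilution * volume)} (Poisson single-hit model).
#'
#' @param titerInfectious infectious-unit concentration of the undiluted
#'   stock (units/mL).
#' @param dilutions strictly decreasing dilution factors.
#' @param wells replicate wells per dilution level.
#' @param inoculumVolume volume of diluted stock per well (mL).
#' @param seed RNG seed for the well outcomes.
#' @return A [DilutionAssay-class] of positive counts per level.
#' @examples
#' simulateMPNAssay(1e9, seed = 1)
#' @export
simulateMPNAssay <- function(titerInfectious, dilutions = 10^-(3:10),
                             wells = 24, inoculumVolume = 0.05, seed = 1) {
  if (titerInfectious < 0) stop("titerInfectious must be >= 0")
  if (any(diff(dilutions) >= 0))
    stop("dilutions must be strictly decreasing")
  if (wells < 1) stop("wells must be >= 1")
  set.seed(.mixSeed(seed, 301))
  p <- -expm1(-titerInfectious * dilutions * inoculumVolume)
  pos <- stats::rbinom(length(dilutions), wells, p)
  DilutionAssay(dilution = dilutions, positive = pos, total = wells,
                volume = inoculumVolume)
}
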