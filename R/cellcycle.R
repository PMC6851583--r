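## DNA-content (SYBR) cell-cycle gating and the infected-fraction
## correction. Gating is performed on the log-fluorescence kernel density
## estimate and is invariant to instrument gain.

## local maxima of a density object, ordered by x
.kdeModes <- function(d, minFrac = 0.05) {
  y <- d$y
  n <- length(y)
  isMax <- c(FALSE, y[2:(n - 1)] > y[1:(n - 2)] &
               y[2:(n - 1)] >= y[3:n], FALSE)
  keep <- isMax & y >= minFrac * max(y)
  list(x = d$x[keep], y = y[keep])
}

#' Gate the G1 peak of a DNA-fluorescence histogram
#'
#' Identifies the G1 population as the major low-fluorescence mode of the
#' log-fluorescence kernel density estimate (Silverman bandwidth) and
#' places a geometric gate of half-width \code{gateWidth} around it, so the
#' upper gate edge lies halfway (in log space) to the 2x peak of
#' G2/M cells. Events below \code{debrisFloor * g1Mode} are treated as
#' sub-G1 debris and excluded from all denominators. \code{fGtG1} is the
#' fraction of retained events at or above the upper gate edge -- cells
#' with more DNA than one host genome (dividing and/or virally
#' replicating).
#'
#' When at least 5\% of events exceed the gate, a secondary mode at
#' 1.8-2.2x the G1 mode is looked for; a control-like sample lacking it
#' triggers a warning (the doubled-DNA peak is the internal calibration
#' that the G1 peak sits at half the G2 fluorescence).
#'
#' For infected samples, whose DNA continuum can dominate the histogram,
#' pass \code{g1Mode} from a matched non-infected control instead of
#' re-detecting it (the approach used with real samples).
#'
#' @param sample a [FlowSample-class] or a numeric vector of linear-scale
#'   fluorescence intensities.
#' @param g1Mode optional fixed G1 peak position (from a control sample);
#'   when \code{NULL} the major peak is detected.
#' @param gateWidth geometric half-width of the G1 gate (default
#'   \code{sqrt(2)}).
#' @param debrisFloor events below this multiple of the G1 mode are
#'   excluded as debris.
#' @param checkSecondary verify the 2x secondary peak (disable for
#'   infected samples).
#' @param ... passed between methods.
#' @return A [CellCycleFractions-class].
#' @examples
#' fl <- c(rnorm(3500, 0, 0.05), rnorm(1500, log(2), 0.05))
#' cc <- gateG1(exp(fl))
#' fGtG1(cc)
#' @name gateG1
NULL

.gateG1Core <- function(fl, g1Mode = NULL, gateWidth = sqrt(2),
                        debrisFloor = 0.5, checkSecondary = TRUE) {
  if (length(fl) < 100)
    stop("gateG1 requires at least 100 events")
  if (any(fl <= 0)) stop("fluorescence intensities must be > 0")
  lf <- log(fl)
  d <- stats::density(lf, bw = "nrd0", n = 1024)
  if (is.null(g1Mode)) {
    modes <- .kdeModes(d, minFrac = 0.05)
    if (!length(modes$x)) stop("no detectable fluorescence mode")
    ## major peak rule, reading from the low-fluorescence side: the first
    ## prominent mode is G1 (higher modes are G2/M or infected continuum)
    g1Mode <- exp(modes$x[1])
  }
  lo <- g1Mode / gateWidth
  hi <- g1Mode * gateWidth
  used <- fl[fl >= debrisFloor * g1Mode]
  if (!length(used)) stop("all events fall below the debris floor")
  fg1 <- mean(used >= lo & used < hi)
  fgt <- mean(used >= hi)

  g2 <- NA_real_
  if (checkSecondary && fgt >= 0.05) {
    inBand <- d$x > log(1.5 * g1Mode) & d$x < log(2.5 * g1Mode)
    if (any(inBand)) {
      db <- list(x = d$x[inBand], y = d$y[inBand])
      ## local max within the band
      yy <- db$y
      k <- which.max(yy)
      if (k > 1 && k < length(yy)) g2 <- exp(db$x[k])
    }
    ratio <- g2 / g1Mode
    if (is.na(g2) || ratio < 1.8 || ratio > 2.2) {
      warning("no secondary DNA peak at ~2x the G1 mode (ratio ",
              if (is.na(g2)) "not found" else round(ratio, 2),
              "); expected for non-infected controls")
      if (!is.na(g2) && (ratio < 1.8 || ratio > 2.2)) g2 <- NA_real_
    }
  }
  new("CellCycleFractions", fG1 = fg1, fGtG1 = fgt, g1Mode = g1Mode,
      g2Mode = g2, nEvents = length(fl), nUsed = length(used))
}

#' @rdname gateG1
#' @export
setMethod("gateG1", "FlowSample", function(sample, g1Mode = NULL,
                                           gateWidth = sqrt(2),
                                           debrisFloor = 0.5,
                                           checkSecondary = TRUE, ...) {
  .gateG1Core(sample@fluorescence, g1Mode = g1Mode, gateWidth = gateWidth,
              debrisFloor = debrisFloor, checkSecondary = checkSecondary)
})

#' @rdname gateG1
#' @export
setMethod("gateG1", "numeric", function(sample, g1Mode = NULL,
                                        gateWidth = sqrt(2),
                                        debrisFloor = 0.5,
                                        checkSecondary = TRUE, ...) {
  .gateG1Core(sample, g1Mode = g1Mode, gateWidth = gateWidth,
              debrisFloor = debrisFloor, checkSecondary = checkSecondary)
})

#' Infected fraction from above-G1 fractions and growth scaling
#'
#' Separates virally replicating cells from ordinarily dividing cells in
#' the above-G1 DNA signal: \eqn{F_I = F^{>G1} - F^D}, where the expected
#' dividing fraction \eqn{F^D = F^D_C \times s} rescales the mean control
#' dividing fraction by \eqn{s = n_I / n_C}, the ratio of generations since
#' dawn in the infected vs control cultures. \eqn{s} is clamped to [0, 1]
#' (a shrinking infected culture implies no ordinary division, not a
#' negative amount), and \eqn{F_I} is floored at 0. When \eqn{n_C = 0}
#' (control did not grow), \eqn{s} is defined as 1 if \eqn{n_I \ge 0} and
#' 0 otherwise, and the result is flagged.
#'
#' Passing a control sample through with itself as its control and equal
#' generation counts returns \eqn{F_I = 0}: for non-infected cultures
#' \eqn{F^{>G1} = F^D} by construction.
#'
#' @param fGtG1 above-G1 fraction of the infected sample ([gateG1()]), a
#'   [CellCycleFractions-class] or a plain fraction.
#' @param controlFGtG1 above-G1 fraction(s) of the matched non-infected
#'   control replicates at the same timepoint (numeric vector or list of
#'   [CellCycleFractions-class]); the mean is used as \eqn{F^D_C}.
#' @param nInfected,nControl generations since dawn (host log2 fold change
#'   with the dawn reference) in the infected culture and the control mean.
#' @return An [InfectedFractionResult-class].
#' @examples
#' infectedFraction(0.5, c(0.28, 0.30, 0.32), nInfected = 0.4,
#'                  nControl = 0.8)
#' @export
infectedFraction <- function(fGtG1, controlFGtG1, nInfected, nControl) {
  val <- function(x) if (is(x, "CellCycleFractions")) x@fGtG1 else x
  f <- val(fGtG1)
  fc <- if (is.list(controlFGtG1)) vapply(controlFGtG1, val, numeric(1))
        else vapply(controlFGtG1, val, numeric(1))
  fdc <- mean(fc)

  clamped <- FALSE
  if (nControl == 0) {
    s <- if (nInfected >= 0) 1 else 0
    clamped <- TRUE
  } else {
    s <- nInfected / nControl
    if (s < 0 || s > 1) clamped <- TRUE
    s <- min(max(s, 0), 1)
  }
  fd <- fdc * s
  fi <- max(f - fd, 0)
  new("InfectedFractionResult", fInfected = fi, fDividing = fd,
      fDividingControl = fdc, scaling = s, nInfected = nInfected,
      nControl = nControl, clamped = clamped)
}
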