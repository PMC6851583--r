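## Most Probable Number inference under the Poisson single-hit model.
##
## A well inoculated with volume v of stock diluted by factor d is positive
## with probability 1 - exp(-c v d), where c is the infectious-unit
## concentration of the undiluted stock. The log-likelihood over levels is
##   l(c) = sum_i [ p_i log(1 - exp(-m_i)) - (n_i - p_i) m_i ],  m_i = c v_i d_i.

## log-likelihood in theta = log(c); vectorized over theta
.mpnLogLik <- function(theta, assay) {
  vd <- assay@volume * assay@dilution
  vapply(theta, function(th) {
    m <- exp(th) * vd
    sum(assay@positive * log(-expm1(-m)) -
          (assay@total - assay@positive) * m)
  }, numeric(1))
}

## analytic second derivative of l w.r.t. theta = log(c)
.mpnHessLog <- function(theta, assay) {
  vd <- assay@volume * assay@dilution
  m <- exp(theta) * vd
  em <- exp(-m)
  q <- em / -expm1(-m)                       # e^-m / (1 - e^-m)
  fp <- assay@positive * q - (assay@total - assay@positive)  # f'(m)
  fpp <- -assay@positive * q * (1 + q)                       # f''(m)
  sum(m * fp + m^2 * fpp)
}

#' Maximum-likelihood MPN estimation from dilution-series well outcomes
#'
#' Estimates the infectious-unit concentration of an undiluted stock from
#' the pattern of positive wells across serial dilutions, maximizing the
#' Poisson single-hit log-likelihood over all levels (fully positive and
#' fully negative levels are retained; they are informative). The
#' confidence interval is a Wald interval on \code{log(c)} using the
#' observed Fisher information, exponentiated back to the concentration
#' scale.
#'
#' Degenerate assays yield censored estimates: with every well negative the
#' MLE is 0 and only a one-sided upper bound is reported (the concentration
#' at which seeing no positive well has probability \code{1 - conf});
#' with every well positive the MLE is infinite with a one-sided lower
#' bound.
#'
#' @param assay a [DilutionAssay-class].
#' @param conf confidence level (default 0.95).
#' @return An [MPNEstimate-class].
#' @examples
#' assay <- DilutionAssay(10^-(4:8), c(24, 24, 18, 4, 0), 24, 0.05)
#' estimateMPN(assay)
#' @export
estimateMPN <- function(assay, conf = 0.95) {
  validObject(assay)
  vd <- assay@volume * assay@dilution
  nPos <- sum(assay@positive)
  nTot <- sum(assay@total)
  nLev <- length(assay@dilution)

  if (nPos == 0) {
    upper <- -log(1 - conf) / sum(assay@total * vd)
    return(new("MPNEstimate", mpn = 0, ciLow = 0, ciHigh = upper,
               logLik = 0, nLevels = nLev, censored = "allNegative",
               conf = conf))
  }
  if (nPos == nTot) {
    ## lower bound: concentration at which an all-positive outcome still has
    ## probability 1 - conf
    f <- function(logc) {
      m <- exp(logc) * vd
      sum(assay@total * log(-expm1(-m))) - log(1 - conf)
    }
    lo <- log(1e-12 / max(vd)); hi <- log(1e12 / min(vd))
    lower <- exp(stats::uniroot(f, c(lo, hi), tol = 1e-10)$root)
    return(new("MPNEstimate", mpn = Inf, ciLow = lower, ciHigh = Inf,
               logLik = 0, nLevels = nLev, censored = "allPositive",
               conf = conf))
  }

  opt <- stats::optimize(function(th) -.mpnLogLik(th, assay),
                         interval = c(log(1e-8 / max(vd)),
                                      log(1e8 / min(vd))),
                         tol = 1e-10)
  thetaHat <- opt$minimum
  H <- .mpnHessLog(thetaHat, assay)
  if (is.finite(H) && H < 0) {
    se <- sqrt(-1 / H)
    z <- stats::qnorm(1 - (1 - conf) / 2)
    ciL <- exp(thetaHat - z * se)
    ciH <- exp(thetaHat + z * se)
  } else {
    ciL <- NA_real_; ciH <- NA_real_
  }
  new("MPNEstimate", mpn = exp(thetaHat), ciLow = ciL, ciHigh = ciH,
      logLik = -opt$objective, nLevels = nLev, censored = "none",
      conf = conf)
}

#' Infectious fraction of a virus stock
#'
#' Divides the MPN-estimated infectious titre by the total (stain-counted)
#' virion concentration; the confidence bounds scale identically. Values
#' above 1 are possible when the MPN exceeds the particle count and are
#' flagged with a warning.
#'
#' @param est an [MPNEstimate-class].
#' @param totalVirions total virion concentration (virions/mL), > 0.
#' @return An [InfectivityResult-class] (MOI slots unset; see
#'   [computeMOI()]).
#' @examples
#' est <- estimateMPN(DilutionAssay(10^-(4:8), c(24, 24, 18, 4, 0), 24, 0.05))
#' infectivity(est, totalVirions = 2e9)
#' @export
infectivity <- function(est, totalVirions) {
  if (!is(est, "MPNEstimate")) stop("est must be an MPNEstimate")
  if (totalVirions <= 0) stop("totalVirions must be > 0")
  frac <- est@mpn / totalVirions
  if (is.finite(frac) && frac > 1)
    warning("infectivity exceeds 1: MPN titre above total virion count")
  new("InfectivityResult", infectivity = frac,
      ciLow = est@ciLow / totalVirions, ciHigh = est@ciHigh / totalVirions,
      totalVirions = totalVirions, censored = est@censored,
      virusHostRatio = NA_real_, moi = NA_real_, moiCiLow = NA_real_,
      moiCiHigh = NA_real_)
}

#' Multiplicity of infection from virus:host ratio and infectivity
#'
#' MOI (infectious virions per host cell) is the total virus:host ratio
#' multiplied by the infectious fraction; the confidence bounds scale with
#' the infectivity bounds. Raw values are stored; \code{show()} rounds to 2
#' significant figures for reporting.
#'
#' @param virusHostRatio total virions per host cell (> 0).
#' @param infectivityResult an [InfectivityResult-class], or a plain
#'   numeric infectious fraction (in which case \code{ci} may supply
#'   bounds).
#' @param ci optional length-2 bounds when \code{infectivityResult} is
#'   numeric.
#' @return An [InfectivityResult-class] with the MOI slots filled.
#' @examples
#' computeMOI(4.8, 0.32, ci = c(0.20, 0.52))
#' @export
computeMOI <- function(virusHostRatio, infectivityResult,
                       ci = c(NA_real_, NA_real_)) {
  if (virusHostRatio <= 0) stop("virusHostRatio must be > 0")
  if (is.numeric(infectivityResult)) {
    infectivityResult <- new("InfectivityResult",
                             infectivity = infectivityResult,
                             ciLow = ci[1], ciHigh = ci[2],
                             totalVirions = NA_real_, censored = "none",
                             virusHostRatio = NA_real_, moi = NA_real_,
                             moiCiLow = NA_real_, moiCiHigh = NA_real_)
  }
  stopifnot(is(infectivityResult, "InfectivityResult"))
  res <- infectivityResult
  res@virusHostRatio <- virusHostRatio
  res@moi <- virusHostRatio * res@infectivity
  res@moiCiLow <- virusHostRatio * res@ciLow
  res@moiCiHigh <- virusHostRatio * res@ciHigh
  res
}
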