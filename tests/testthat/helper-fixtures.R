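# Shared fixtures: small, fast simulator configurations and builders for
# synthetic abundance tables and flow-event mixtures.

# default experiment at reduced event count (gating still reliable)
fastConfig <- function(seed = 1, ...) {
  SimConfig(seed = seed, eventsPerSample = 2000, ...)
}

# tidy replicate series data.frame
seriesDF <- function(times, valuesByRep) {
  do.call(rbind, lapply(seq_along(valuesByRep), function(r)
    data.frame(time_h = times, replicate = r, value = valuesByRep[[r]])))
}

# lognormal mixture of DNA-content classes (linear fluorescence)
mixEvents <- function(n, means, weights, cv = 0.05) {
  cls <- sample(seq_along(means), n, replace = TRUE, prob = weights)
  s <- sqrt(log(1 + cv^2))
  means[cls] * exp(stats::rnorm(n, -s^2 / 2, s))
}

# deduplicated latent series for one treatment/target
latentSeries <- function(ex, treatment, target) {
  ab <- abundance(ex)
  unique(ab[ab$treatment == treatment & ab$target == target,
            c("time_h", "latent_per_ml")])
}

# observed tidy series (columns time_h, replicate, value)
observedSeries <- function(ex, treatment, target) {
  ab <- abundance(ex)
  d <- ab[ab$treatment == treatment & ab$target == target,
          c("time_h", "replicate", "value_per_ml")]
  names(d)[3] <- "value"
  d
}

# brute-force grid-search oracle for the MPN likelihood (independent of
# the estimator's optimizer): argmax over a log10 grid
mpnGridOracle <- function(assay, lo = 4, hi = 11, res = 1e-3) {
  grid <- seq(lo, hi, by = res)
  vd <- assay@volume * assay@dilution
  ll <- vapply(grid, function(g) {
    m <- 10^g * vd
    sum(assay@positive * log(-expm1(-m)) -
          (assay@total - assay@positive) * m)
  }, numeric(1))
  10^grid[which.max(ll)]
}
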