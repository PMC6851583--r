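test_that("log2 fold change counts generations", {
  expect_equal(log2FoldChange(2e6, 1e6), 1)
  expect_equal(log2FoldChange(1e6, 1e6), 0)
  expect_equal(log2FoldChange(5e6, 1e6), log2(5))
  expect_equal(log2FoldChange(c(1e6, 4e6), reference = -3.5,
                              times = c(-3.5, 0.5)), c(0, 2))
  expect_warning(out <- log2FoldChange(c(1e6, 0), 1e6), "non-positive")
  expect_true(is.na(out[2]))
  expect_error(log2FoldChange(1e6, 0))
})

test_that("growth rate recovers known exponential rates", {
  expect_equal(growthRate(c(1e6, 2e6), c(0, 24), 0, 24), log(2))
  expect_equal(growthRate(c(1e6, 1e6), c(0, 24), 0, 24), 0)
  # net mortality is negative
  expect_lt(growthRate(c(1e6, 5e5), c(0, 24), 0, 24), 0)
  # noiseless simulated SL control over a full diel cycle
  cfg <- SimConfig(seed = 1, sampleTimes = c(-3.5, 0.5, 20.5, 24.5))
  ex <- runExperiment(cfg, treatments = "control", flow = FALSE)
  h <- latentSeries(ex, "control", "host")
  expect_equal(growthRate(h$latent_per_ml, h$time_h, -3.5, 20.5), 0.76,
               tolerance = 0.01)
})

test_that("viral production equals two to the log2 fold change", {
  ex <- runExperiment(fastConfig(seed = 4), flow = FALSE)
  vs <- observedSeries(ex, "virus", "virus")
  vs <- vs[vs$time_h >= 0.5, ]
  vp <- viralProduction(vs, referenceTime = 0.5)
  for (r in unique(vp$replicate)) {
    d <- vp[vp$replicate == r, ]
    lfc <- log2FoldChange(d$value, reference = 0.5, times = d$time_h)
    expect_equal(d$vp, 2^lfc, tolerance = 1e-12)
  }
})

test_that("latent period brackets the first significant virion increase", {
  df <- seriesDF(c(0.5, 2.5, 6.5, 8.5),
                 list(c(1, 1, 1, 2^1.0), c(1, 1, 1, 2^1.1),
                      c(1, 1, 1, 2^0.9)))
  lp <- latentPeriod(df, referenceTime = 0.5)
  expect_true(lp$detected)
  expect_equal(lp$interval, c(6.5, 8.5))
  # direct check: the closing t test is overwhelmingly significant
  expect_lt(lp$table$p_value[lp$table$time_h == 8.5], 0.01)

  # flat replicate series: nothing to detect
  flat <- seriesDF(c(0.5, 6.5, 8.5), list(rep(1, 3), rep(1, 3), rep(1, 3)))
  lpf <- latentPeriod(flat)
  expect_false(lpf$detected)
  expect_identical(lpf$interval[2], Inf)

  # a significant *decrease* must not close the interval
  dec <- seriesDF(c(0.5, 6.5, 8.5),
                  list(c(1, 0.50, 2.0), c(1, 0.52, 2.1), c(1, 0.48, 1.9)))
  lpd <- latentPeriod(dec)
  expect_equal(lpd$interval, c(6.5, 8.5))
  firstPos <- min(lpd$table$time_h[lpd$table$mean_log2fc > 0])
  expect_gte(lpd$interval[2], firstPos)
})

test_that("latent period detection recovers the generative 7 h latency", {
  hits <- vapply(1:25, function(s) {
    ex <- runExperiment(SimConfig(seed = 600 + s), treatments = "virus",
                        flow = FALSE)
    lp <- latentPeriod(observedSeries(ex, "virus", "virus"))
    lp$detected && lp$interval[1] < 7 && 7 <= lp$interval[2]
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("burst size is virion gain over host loss", {
  v <- seriesDF(c(18.5, 24.5), list(c(1e6, 1e6 + 1e5)))
  h <- seriesDF(c(18.5, 24.5), list(c(2e3, 1e3)))
  b <- burstSize(v, h)
  expect_equal(b$mean, 100)
  # zero virion change gives zero burst
  v0 <- seriesDF(c(18.5, 24.5), list(c(1e6, 1e6)))
  expect_equal(burstSize(v0, h)$mean, 0)
  # invariance to concentration units
  b2 <- burstSize(transform(v, value = value / 1000),
                  transform(h, value = value / 1000))
  expect_equal(b2$mean, b$mean)
  # replicates with host gain are excluded with a warning
  v3 <- seriesDF(c(18.5, 24.5), list(c(1e6, 2e6), c(1e6, 2e6)))
  h3 <- seriesDF(c(18.5, 24.5), list(c(1e3, 5e2), c(1e3, 2e3)))
  expect_warning(b3 <- burstSize(v3, h3), "gained hosts")
  expect_identical(b3$excluded, 2L)
  expect_equal(b3$mean, 2e3)
})

test_that("burst size recovers the generative mean on simulator output", {
  # noiseless, reinfection off, deterministic burst: exact recovery
  cfg <- SimConfig(seed = 1, muMax = 0, noiseCVCounts = 0, burstCV = 0,
                   fluorCV = 0, reinfection = FALSE, adsorptionStop = 2)
  ex <- runExperiment(cfg, treatments = "virus", flow = FALSE)
  b <- burstSize(observedSeries(ex, "virus", "virus"),
                 observedSeries(ex, "virus", "host"),
                 window = c(6.5, 10.5))
  expect_equal(b$mean, 500, tolerance = 1e-12)

  # default noise and reinfection, over the simulated lysis window
  ests <- vapply(1:10, function(s) {
    e <- runExperiment(SimConfig(seed = 1200 + s), treatments = "virus",
                       flow = FALSE)
    burstSize(observedSeries(e, "virus", "virus"),
              observedSeries(e, "virus", "host"),
              window = c(10.5, 14.5))$mean
  }, numeric(1))
  expect_lt(abs(mean(ests) - 500) / 500, 0.3)
})

test_that("sensitivity ratio compares production across light conditions", {
  vp1 <- data.frame(time_h = rep(c(8.5, 24.5), each = 3),
                    replicate = rep(1:3, 2),
                    vp = c(3, 3.1, 2.9, 16.5, 16.7, 16.6))
  vp2 <- data.frame(time_h = rep(c(8.5, 24.5), each = 3),
                    replicate = rep(1:3, 2),
                    vp = c(3, 3.1, 2.9, 48.5, 48.7, 48.6))
  sr <- sensitivityRatio(vp1, vp2, afterH = 8.5)
  expect_equal(sr$ratio[sr$time_h == 24.5], 16.6 / 48.6, tolerance = 1e-6)
  # identical conditions: ratio exactly 1
  sr1 <- sensitivityRatio(vp2, vp2)
  expect_true(all(sr1$ratio == 1))
  # degenerate denominator guarded
  vp0 <- transform(vp2, vp = 0)
  expect_true(all(is.na(sensitivityRatio(vp1, vp0)$ratio)))
  # timepoints before progeny release are excluded
  expect_false(any(sr$time_h < 8.5))
})

test_that("the per-timepoint testing protocol flags real treatment effects", {
  d <- data.frame(time_h = 1,
                  treatment = rep(c("none", "v1", "v2"), each = 3),
                  replicate = rep(1:3, 3),
                  value = c(0, 0, 0, 5, 5.1, 4.9, 5, 5, 5.2))
  tp <- testProtocol(d)
  expect_lt(tp$anova$p_value, 0.001)
  tk <- tp$tukey
  expect_lt(tk$p_adj[tk$contrast == "v1-none"], 0.01)
  expect_lt(tk$p_adj[tk$contrast == "v2-none"], 0.01)
  expect_gt(tk$p_adj[tk$contrast == "v2-v1"], 0.5)

  # identical group means: no effect detected
  d2 <- data.frame(time_h = 1, treatment = rep(c("a", "b"), each = 3),
                   replicate = rep(1:3, 2), value = c(1, 2, 3, 1, 2, 3))
  expect_gt(testProtocol(d2)$anova$p_value, 0.9)

  # zero variance everywhere: degenerate, flagged
  d3 <- data.frame(time_h = 1, treatment = rep(c("a", "b"), each = 2),
                   replicate = rep(1:2, 2), value = rep(2, 4))
  tp3 <- testProtocol(d3)
  expect_true(tp3$anova$degenerate)
  expect_true(is.na(tp3$anova$p_value))
})

test_that("Type II sums of squares equal Type I in a balanced one-way layout", {
  set.seed(9)
  d <- data.frame(time_h = 1,
                  treatment = rep(c("a", "b", "c"), each = 4),
                  replicate = rep(1:4, 3), value = rnorm(12))
  tp <- testProtocol(d)
  fit <- stats::aov(value ~ treatment, data = d)
  p1 <- summary(fit)[[1]]$`Pr(>F)`[1]
  expect_equal(tp$anova$p_value, p1, tolerance = 1e-12)
})
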