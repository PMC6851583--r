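test_that("identical configurations give bit-identical experiments", {
  e1 <- runExperiment(SimConfig(seed = 3, eventsPerSample = 300))
  e2 <- runExperiment(SimConfig(seed = 3, eventsPerSample = 300))
  expect_identical(abundance(e1), abundance(e2))
  expect_identical(lapply(flowSamples(e1), fluorescence),
                   lapply(flowSamples(e2), fluorescence))
})

test_that("a V0 = 0 virus treatment reproduces the control exactly", {
  ex <- runExperiment(SimConfig(seed = 7, V0 = 0, infectivityTrue = 0.32,
                                eventsPerSample = 500))
  ab <- abundance(ex)
  ctl <- ab[ab$treatment == "control", -1]
  vir <- ab[ab$treatment == "virus", -1]
  rownames(ctl) <- rownames(vir) <- NULL
  expect_identical(ctl, vir)
  fs <- flowSamples(ex)
  fc <- fs[grep("^control", names(fs))]
  fv <- fs[grep("^virus", names(fs))]
  expect_true(all(mapply(function(a, b)
    identical(fluorescence(a), fluorescence(b)), fc, fv)))
})

test_that("mass balance holds to machine precision over a full run", {
  cfg <- fastConfig(seed = 5)
  ex <- runExperiment(cfg, flow = FALSE)
  for (tr in c("control", "virus")) {
    last <- ex@snapshots[[tr]][[length(cfg@sampleTimes)]]
    hostResid <- (cfg@N0Host + last$cumDivisions - last$cumLysed) -
      last$hostTotal
    expect_lt(abs(hostResid) / cfg@N0Host, 1e-12)
    V0 <- if (tr == "virus") cfg@V0 else 0
    virResid <- (V0 - last$cumAdsorbed + last$cumBurst) - last$V
    expect_lt(abs(virResid) / max(V0, 1), 1e-12)
  }
})

test_that("uninfected growth matches the closed form", {
  # division window spanning all hours: continuous exponential growth
  cfg <- SimConfig(seed = 1, divisionWindow = c(0, 24), V0 = 0,
                   infectivityTrue = 0.32,
                   sampleTimes = c(-3.5, 0.5, 24.5))
  ex <- runExperiment(cfg, treatments = "control", flow = FALSE)
  h <- latentSeries(ex, "control", "host")
  mu <- growthRate(h$latent_per_ml, h$time_h, -3.5, 24.5)
  expect_equal(mu, 0.76, tolerance = 0.01)
  # diel pulse: exact over a full dawn-to-dawn cycle
  cfg2 <- SimConfig(seed = 1, sampleTimes = c(-3.5, 0.5, 20.5, 24.5))
  ex2 <- runExperiment(cfg2, treatments = "control", flow = FALSE)
  h2 <- latentSeries(ex2, "control", "host")
  expect_equal(growthRate(h2$latent_per_ml, h2$time_h, -3.5, 20.5), 0.76,
               tolerance = 1e-6)
})

test_that("zero infectivity leaves hosts indistinguishable from controls", {
  ex <- runExperiment(SimConfig(seed = 2, infectivityTrue = 0, V0 = 3e7),
                      flow = FALSE)
  tru <- groundTruth(ex)
  expect_true(all(tru$infectedFractionTrue$f_infected == 0))
  hv <- latentSeries(ex, "virus", "host")
  hc <- latentSeries(ex, "control", "host")
  expect_equal(hv$latent_per_ml, hc$latent_per_ml)
  # virions still adsorb (and are lost) even when none are infectious
  vv <- latentSeries(ex, "virus", "virus")
  expect_lt(vv$latent_per_ml[vv$time_h == 6.5],
            vv$latent_per_ml[vv$time_h == 0.5])
})

test_that("no adsorption means constant virions and no infection", {
  ex <- runExperiment(SimConfig(seed = 2, kAds = 0), flow = FALSE)
  vv <- latentSeries(ex, "virus", "virus")
  post <- vv[vv$time_h >= 0.5, ]
  expect_equal(post$latent_per_ml, rep(post$latent_per_ml[1], nrow(post)))
  expect_true(all(groundTruth(ex)$infectedFractionTrue$f_infected == 0))
})

test_that("a deterministic burst releases exactly burstMean per lysed cell", {
  cfg <- SimConfig(seed = 1, burstMean = 100, burstCV = 0, muMax = 0,
                   kAds = 0)
  st <- newSimState(cfg)
  nB <- length(st$iAge)
  st$sPhase <- c(G1 = 0, S = 0, G2M = 0)
  st$iAge[nB] <- 1000          # one cohort reaching the latent period
  st2 <- stepSim(st, cfg)
  expect_equal(st2$vProg, 1e5)
  expect_equal(st2$cumLysed, 1000)
  # with no susceptible cells, virions change only through bursts
  expect_equal(st2$cumAdsorbed, 0)
})

test_that("free-virion log2FC first turns positive in the (6.5, 8.5] interval", {
  # burst 500, latent 7 h, MOI ~ 3: progeny release starts 7 h post-addition
  ex <- runExperiment(SimConfig(seed = 1), treatments = "virus",
                      flow = FALSE)
  vv <- latentSeries(ex, "virus", "virus")
  vv <- vv[vv$time_h >= 0.5, ]
  lfc <- log2FoldChange(vv$latent_per_ml, reference = 0.5,
                        times = vv$time_h)
  firstPos <- vv$time_h[which(lfc > 0)[1]]
  expect_identical(firstPos, 8.5)
  expect_true(all(lfc[vv$time_h <= 6.5] <= 0))
})

test_that("flow samples realize the DNA-content observation model", {
  cfg <- SimConfig(seed = 1, fluorCV = 1e-6, eventsPerSample = 2000)
  # all cells in G1: a spike at 1.0
  st <- list(t = 0, sPhase = c(1e6, 0, 0), iAge = numeric(140))
  set.seed(1)
  fs <- emitFlowSample(st, cfg)
  expect_equal(range(fluorescence(fs)), c(1, 1), tolerance = 1e-4)

  # 50/50 G1 and G2M: two spikes with fluorescence ratio exactly 2
  st2 <- list(t = 0, sPhase = c(5e5, 0, 5e5), iAge = numeric(140))
  set.seed(1)
  f2 <- fluorescence(emitFlowSample(st2, cfg))
  expect_setequal(round(sort(unique(round(f2, 3))), 3), c(1, 2))

  # infected cells at the end of the latent period: 1 + genomeRatio*burst
  cfg3 <- SimConfig(seed = 1, fluorCV = 0.05, eventsPerSample = 5000)
  st3 <- list(t = 7, sPhase = c(0, 0, 0),
              iAge = c(numeric(139), 1000))
  set.seed(2)
  f3 <- fluorescence(emitFlowSample(st3, cfg3))
  expect_equal(mean(f3), 1 + 0.015 * 500,
               tolerance = 3 * stats::sd(f3) / sqrt(length(f3)) / 8.5)
  expect_warning(
    emitFlowSample(st3, SimConfig(seed = 1, eventsPerSample = 50)),
    "100 events")
})

test_that("invalid configurations are rejected", {
  expect_error(SimConfig(seed = 1, dt = -1), "dt")
  expect_error(SimConfig(seed = 1, infectivityTrue = 1.2), "infectivityTrue")
  expect_error(SimConfig(seed = 1, tStart = 1), "tStart")
  expect_error(SimConfig(seed = 1, burstMean = 0), "burstMean")
  expect_error(SimConfig(seed = 1, latentPeriodTrue = -2), "latentPeriod")
  # infection demand grossly exceeding available hosts
  expect_error(SimConfig(seed = 1, V0 = 1e12), "MOI")
  expect_error(simulateMPNAssay(1e9, dilutions = c(1e-3, 1e-2)),
               "decreasing")
})
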