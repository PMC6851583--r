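test_that("single-level MLE inverts the single-hit model in closed form", {
  # positive fraction 1 - e^-1 with v*d = 1 mL inverts to exactly 1 /mL
  a <- DilutionAssay(1, 24 * (1 - exp(-1)), 24, 1)
  expect_equal(mpn(estimateMPN(a)), 1, tolerance = 1e-6)
})

test_that("MLE matches the brute-force likelihood grid on a realistic assay", {
  a <- DilutionAssay(10^-(4:8), c(24, 24, 18, 4, 0), 24, 0.05)
  est <- estimateMPN(a)
  oracle <- mpnGridOracle(a, lo = 5, hi = 10, res = 1e-4)
  expect_equal(log10(mpn(est)), log10(oracle), tolerance = 2e-4)
  expect_true(ciLow(est) <= mpn(est) && mpn(est) <= ciHigh(est))
})

test_that("MLE equals the grid-search oracle on random assays", {
  set.seed(101)
  for (k in 1:20) {
    titer <- 10^runif(1, 6, 10)
    a <- simulateMPNAssay(titer, seed = 5000 + k)
    est <- estimateMPN(a)
    if (censoring(est) != "none") next
    expect_equal(log10(mpn(est)), log10(mpnGridOracle(a)),
                 tolerance = 2e-3)
  }
})

test_that("adding a positive well never decreases the MLE", {
  set.seed(7)
  for (k in 1:15) {
    a <- simulateMPNAssay(10^runif(1, 7, 9), seed = 900 + k)
    est <- estimateMPN(a)
    if (censoring(est) != "none") next
    lev <- sample(which(a@positive < a@total), 1)
    pos2 <- a@positive
    pos2[lev] <- pos2[lev] + 1
    a2 <- DilutionAssay(a@dilution, pos2, a@total, a@volume)
    est2 <- estimateMPN(a2)
    if (censoring(est2) != "none") next
    expect_gte(mpn(est2), mpn(est) * (1 - 1e-8))
  }
})

test_that("MLE is equivariant under inoculum-volume rescaling", {
  a <- DilutionAssay(10^-(4:8), c(24, 24, 18, 4, 0), 24, 0.05)
  for (k in c(0.1, 2, 20)) {
    ak <- DilutionAssay(a@dilution, a@positive, a@total, a@volume * k)
    expect_equal(mpn(estimateMPN(ak)), mpn(estimateMPN(a)) / k,
                 tolerance = 1e-6)
    expect_equal(ciHigh(estimateMPN(ak)), ciHigh(estimateMPN(a)) / k,
                 tolerance = 1e-6)
  }
})

test_that("degenerate assays give censored one-sided estimates", {
  neg <- DilutionAssay(10^-(3:6), 0, 24, 0.05)
  en <- estimateMPN(neg)
  expect_identical(mpn(en), 0)
  expect_identical(ciLow(en), 0)
  expect_gt(ciHigh(en), 0)
  expect_identical(censoring(en), "allNegative")

  pos <- DilutionAssay(10^-(3:6), 24, 24, 0.05)
  ep <- estimateMPN(pos)
  expect_identical(mpn(ep), Inf)
  expect_gt(ciLow(ep), 0)
  expect_identical(censoring(ep), "allPositive")
  # titer 0 yields all-negative wells at every dilution
  a0 <- simulateMPNAssay(0, seed = 3)
  expect_true(all(a0@positive == 0))
})

test_that("simulated wells follow the single-hit positive probability", {
  # titer * dilution * volume = ln 2  =>  positive fraction 1/2
  a <- simulateMPNAssay(log(2) / 0.05, dilutions = 1, wells = 4000,
                        inoculumVolume = 0.05, seed = 11)
  phat <- a@positive / a@total
  expect_lt(abs(phat - 0.5), 3 * sqrt(0.25 / 4000))
})

test_that("MPN recovers a known titre on average (simulator round trip)", {
  ests <- vapply(1:200, function(s)
    mpn(estimateMPN(simulateMPNAssay(1e9, seed = s))), numeric(1))
  expect_lt(abs(mean(ests) - 1e9) / 1e9, 0.10)
})

test_that("infectivity scales the MPN estimate and its interval", {
  tot <- 5e9
  est <- new("MPNEstimate", mpn = 0.14 * tot, ciLow = 0.08 * tot,
             ciHigh = 0.23 * tot, logLik = 0, nLevels = 8,
             censored = "none", conf = 0.95)
  inf <- infectivity(est, tot)
  expect_equal(infectivityValue(inf), 0.14)
  expect_equal(c(ciLow(inf), ciHigh(inf)), c(0.08, 0.23))
  # mpn equal to the particle count gives infectivity exactly 1
  est1 <- new("MPNEstimate", mpn = tot, ciLow = 0.9 * tot,
              ciHigh = 1.1 * tot, logLik = 0, nLevels = 8,
              censored = "none", conf = 0.95)
  expect_equal(infectivityValue(infectivity(est1, tot)), 1)
  # censoring propagates
  cen <- estimateMPN(DilutionAssay(10^-(3:6), 0, 24, 0.05))
  expect_identical(censoring(infectivity(cen, tot)), "allNegative")
})

test_that("MOI is the virus:host ratio times infectivity, CI included", {
  r <- computeMOI(4.8, 0.32, ci = c(0.20, 0.52))
  expect_equal(signif(moi(r), 2), 1.5)
  expect_equal(signif(moiCI(r)[["high"]], 2), 2.5)
  expect_equal(moi(computeMOI(1, 1, ci = c(1, 1))), 1)
  expect_error(computeMOI(0, 0.5))
})

test_that("simulated assays recover the generative infectivity", {
  # stock with known infectious fraction, total count known exactly
  total <- 3e9
  infTrue <- 0.32
  ests <- vapply(1:60, function(s) {
    a <- simulateMPNAssay(infTrue * total, seed = 40000 + s)
    infectivityValue(infectivity(estimateMPN(a), total))
  }, numeric(1))
  expect_lt(abs(stats::median(ests) - infTrue) / infTrue, 0.15)
})
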