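test_that("a pure G1 population gates almost entirely into the G1 gate", {
  set.seed(1)
  fl <- mixEvents(5000, means = 1, weights = 1, cv = 0.01)
  cc <- suppressWarnings(gateG1(fl))
  expect_gt(fG1(cc), 0.99)
  expect_lt(fGtG1(cc), 0.01)
  expect_equal(g1Mode(cc), 1, tolerance = 0.05)
})

test_that("a 70/30 G1-G2M mixture yields the constructed above-G1 fraction", {
  set.seed(2)
  fl <- mixEvents(5000, means = c(1, 2), weights = c(0.7, 0.3), cv = 0.05)
  cc <- gateG1(fl)
  # binomial SE at 5000 events is ~0.0065; spec tolerance 0.02
  expect_equal(fGtG1(cc), 0.30, tolerance = 0.02)
  expect_equal(g2Mode(cc) / g1Mode(cc), 2, tolerance = 0.1)
  expect_lte(fG1(cc) + fGtG1(cc), 1)
})

test_that("gating is invariant under global fluorescence rescaling", {
  set.seed(3)
  fl <- mixEvents(4000, means = c(1, 1.5, 2), weights = c(0.6, 0.1, 0.3),
                  cv = 0.05)
  cc <- gateG1(fl)
  for (gain in c(0.01, 37.4, 1e4)) {
    cg <- gateG1(fl * gain)
    expect_identical(fGtG1(cg), fGtG1(cc))
    expect_identical(fG1(cg), fG1(cc))
  }
})

test_that("a heavily infected sample is almost entirely above the gate", {
  cfg <- SimConfig(seed = 1, eventsPerSample = 5000)
  st <- list(t = 7, sPhase = c(100, 0, 0), iAge = c(numeric(139), 1e4))
  set.seed(4)
  fs <- emitFlowSample(st, cfg)
  # gate anchored at the control G1 position, as for real infected samples
  cc <- gateG1(fs, g1Mode = 1, checkSecondary = FALSE)
  expect_gt(fGtG1(cc), 0.9)
})

test_that("a missing 2x secondary peak in a control-like sample warns", {
  set.seed(5)
  fl <- mixEvents(5000, means = c(1, 3.1), weights = c(0.6, 0.4), cv = 0.05)
  expect_warning(gateG1(fl), "secondary")
  expect_error(gateG1(fl[1:50]), "100 events")
})

test_that("infected fraction subtracts the scaled dividing fraction", {
  r <- infectedFraction(0.5, c(0.3, 0.3, 0.3), nInfected = 0.8,
                        nControl = 0.8)
  expect_equal(scalingFactor(r), 1)
  expect_equal(fInfected(r), 0.2)

  # shrinking infected culture: no ordinary division is expected
  r2 <- infectedFraction(0.5, 0.3, nInfected = -0.4, nControl = 0.8)
  expect_equal(scalingFactor(r2), 0)
  expect_equal(fInfected(r2), 0.5)
  expect_true(r2@clamped)

  # faster-growing "infected" culture clamps s at 1
  r3 <- infectedFraction(0.5, 0.3, nInfected = 1.6, nControl = 0.8)
  expect_equal(scalingFactor(r3), 1)
  expect_true(r3@clamped)

  # control passed through as infected against itself: F_I = 0
  r4 <- infectedFraction(0.31, c(0.31, 0.31), nInfected = 0.7,
                         nControl = 0.7)
  expect_equal(fInfected(r4), 0)

  # degenerate control growth convention
  r5 <- infectedFraction(0.4, 0.3, nInfected = 0.2, nControl = 0)
  expect_equal(scalingFactor(r5), 1)
  expect_true(r5@clamped)
  r6 <- infectedFraction(0.4, 0.3, nInfected = -0.2, nControl = 0)
  expect_equal(scalingFactor(r6), 0)

  # F_I floored at zero
  r7 <- infectedFraction(0.1, 0.3, nInfected = 0.8, nControl = 0.8)
  expect_equal(fInfected(r7), 0)
})

test_that("CellCycleFractions accessors round-trip the gate geometry", {
  set.seed(6)
  fl <- mixEvents(3000, means = c(1, 2), weights = c(0.8, 0.2), cv = 0.05)
  cc <- gateG1(fl, gateWidth = sqrt(2))
  # upper gate edge at sqrt(2) x mode: events in (mode*sqrt2, inf) counted
  used <- fl[fl >= 0.5 * g1Mode(cc)]
  expect_equal(fGtG1(cc), mean(used >= g1Mode(cc) * sqrt(2)))
})
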