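test_that("band trajectories honour the catalogue trend labels", {
  cat13 <- referencePeaks()
  for (nm in c("no_stress", "inh_stress")) {
    sc <- defaultScenario(nm)
    col <- if (nm == "no_stress") cat13$trend_no_stress else cat13$trend_inh
    for (i in seq_len(nrow(cat13))) {
      p <- cat13$position_cm1[i]
      a0 <- peakAmplitudeAt(sc, p, 0)
      a8 <- peakAmplitudeAt(sc, p, 8)
      expect_equal(unname(sign(a8 - a0)),
                   switch(col[i], increasing = 1, decreasing = -1,
                          stable = 0),
                   info = sprintf("%s %g cm-1", nm, p))
    }
  }
})

test_that("stable bands stay at baseline; carotenoids nearly vanish", {
  sc <- defaultScenario("no_stress")
  base1007 <- peakAmplitudeAt(sc, 1007, 0)
  for (t in c(0, 2.5, 8))
    expect_equal(peakAmplitudeAt(sc, 1007, t), base1007)
  for (p in carotenoidPeaks())
    expect_lt(peakAmplitudeAt(sc, p, 8), 0.1 * peakAmplitudeAt(sc, p, 0))
  expect_error(peakAmplitudeAt(sc, 999, 1), "unknown band")
  expect_error(peakAmplitudeAt(sc, 1007, 9), "outside")
})

test_that("isoniazid delays and slows the tyrosine/carbohydrate rises", {
  scN <- defaultScenario("no_stress")
  scI <- defaultScenario("inh_stress")
  for (p in c(635, 1040, 1130, 1606)) {
    # no change before the onset delay, and a shallower rise after it
    expect_equal(peakAmplitudeAt(scI, p, 2), peakAmplitudeAt(scI, p, 0))
    gainI <- peakAmplitudeAt(scI, p, 8) - peakAmplitudeAt(scI, p, 0)
    gainN <- peakAmplitudeAt(scN, p, 8) - peakAmplitudeAt(scN, p, 0)
    expect_lt(gainI, gainN)
    expect_gt(gainI, 0)
  }
})

test_that("optional collapse caps trajectories after the collapse time", {
  sc <- defaultScenario("inh_stress", collapseAtH = 5)
  expect_lt(peakAmplitudeAt(sc, 1303, 7), peakAmplitudeAt(sc, 1303, 5))
  # tyrosine bands stabilise rather than decline
  expect_equal(peakAmplitudeAt(sc, 635, 7), peakAmplitudeAt(sc, 635, 5))
})

test_that("raw spectrum forward model behaves at its edge cases", {
  empty <- lineDf(numeric(0), numeric(0), numeric(0))
  s <- simulateRawSpectrum(empty, NULL, 785, noise = FALSE)
  expect_true(all(intensityValues(s) == 0))
  expect_error(simulateRawSpectrum(empty, NULL, 785, detectorNm = numeric(0)),
               "empty")
  expect_error(
    simulateRawSpectrum(empty, function(l) rep(-1, length(l)), 785,
                        noise = FALSE),
    "non-negative")
})

test_that("a line lands at the same wavenumber for every excitation step", {
  lines <- lineDf(1443)
  for (lex in c(784.25, 785.75)) {
    s <- simulateRawSpectrum(lines, NULL, lex, noise = FALSE)
    peakNm <- spectralAxis(s)[which.max(intensityValues(s))]
    expect_lt(abs(wavelengthToWavenumber(peakNm, lex) - 1443), 1.5)
  }
  # but at different detection wavelengths
  nmAt <- vapply(c(784.25, 785.75), function(lex) {
    s <- simulateRawSpectrum(lines, NULL, lex, noise = FALSE)
    spectralAxis(s)[which.max(intensityValues(s))]
  }, numeric(1))
  expect_gt(abs(diff(nmAt)), 0.5)
})

test_that("background is identical across steps so step differences are pure Raman", {
  lines <- lineDf(c(900, 1443))
  bg <- function(l) 4e4 * exp(-((l - 860) / 60)^2)
  withBg <- tinyModSet(lines, bg)
  noBg <- tinyModSet(lines, NULL)
  d1 <- intensityValues(withBg[[5]]) - intensityValues(withBg[[1]])
  d2 <- intensityValues(noBg[[5]]) - intensityValues(noBg[[1]])
  expect_equal(d1, d2, tolerance = 1e-12)
})

test_that("shot noise is Poisson and seeded draws are reproducible", {
  empty <- lineDf(numeric(0), numeric(0), numeric(0))
  flat <- function(l) rep(1000, length(l))
  s <- simulateRawSpectrum(empty, flat, 785, noise = TRUE, seed = 42)
  v <- var(intensityValues(s))
  n <- length(intensityValues(s))
  expect_lt(abs(v - 1000), 3 * 1000 * sqrt(2 / (n - 1)))
  s2 <- simulateRawSpectrum(empty, flat, 785, noise = TRUE, seed = 42)
  expect_identical(intensityValues(s), intensityValues(s2))
  # noise-free mode returns the expectation exactly
  s3 <- simulateRawSpectrum(empty, flat, 785, noise = FALSE)
  expect_true(all(intensityValues(s3) == 1000))
})

test_that("simulated experiments are shaped by the schedule and reproducible", {
  sc <- defaultScenario("no_stress")
  run <- simulateExperiment(sc, scheduleH = 1:8, seed = 7)
  expect_length(modulationSets(run), 8)
  expect_length(modulationSets(run)[[1]], 5)
  one <- simulateExperiment(sc, scheduleH = 3, seed = 7)
  expect_length(modulationSets(one), 1)
  rerun <- simulateExperiment(sc, scheduleH = 1:8, seed = 7)
  expect_identical(
    lapply(modulationSets(run), function(s) lapply(s, intensityValues)),
    lapply(modulationSets(rerun), function(s) lapply(s, intensityValues)))
  expect_error(simulateExperiment(sc, scheduleH = numeric(0)), "empty")
  expect_error(simulateExperiment(sc, scheduleH = c(1, 10)), "outside")
})
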