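test_that("resampling returns identity for identical axes", {
  ms <- tinyModSet(lineDf(1200))
  rs <- resampleToCommonGrid(ms)
  expect_identical(rs$grid, spectralAxis(ms[[1]]))
  expect_equal(rs$counts[3, ], intensityValues(ms[[3]]))
  one <- resampleToCommonGrid(ms[1])
  expect_equal(dim(one$counts), c(1L, length(one$grid)))
})

test_that("resampling shifted axes interpolates close to the analytic line", {
  grid <- detectionGrid()
  halfBin <- diff(grid)[1] / 2
  s1 <- simulateRawSpectrum(lineDf(1200), NULL, 785, detectorNm = grid,
                            noise = FALSE)
  s2 <- simulateRawSpectrum(lineDf(1200), NULL, 785,
                            detectorNm = grid + halfBin, noise = FALSE)
  rs <- resampleToCommonGrid(list(s1, s2))
  truth <- simulateRawSpectrum(lineDf(1200), NULL, 785,
                               detectorNm = rs$grid, noise = FALSE)
  # linear-interpolation error bound h^2/8 * max|f''|, curvature 2A/g^2 at
  # the line top, h ~ one bin in wavenumber units
  h <- abs(diff(wavelengthToWavenumber(grid[1:2], 785)))
  bound <- h^2 / 8 * 2 * 5000 / 6^2
  expect_lt(max(abs(rs$counts[2, ] - intensityValues(truth))), bound)
  d1 <- RawSpectrum(grid, rep(1, length(grid)), 785)
  d2 <- RawSpectrum(grid + 1000, rep(1, length(grid)), 785)
  expect_error(resampleToCommonGrid(list(d1, d2)), "overlap")
})

test_that("background-only input reconstructs to zero (both methods)", {
  empty <- lineDf(numeric(0), numeric(0), numeric(0))
  polyBg <- function(l) 5e4 * (1 + 0.5 * ((l - 860) / 60) +
                                 0.2 * ((l - 860) / 60)^2)
  expBg <- function(l) 8e4 * exp(-(l - 820) / 90)
  for (bg in list(polyBg, expBg)) {
    ms <- tinyModSet(empty, bg)
    for (m in c("recentred", "ols")) {
      w <- reconstructWMR(ms, method = m)
      expect_lt(max(abs(intensityValues(w))), 1e-10)
    }
  }
})

test_that("adding any step-constant background changes no differential value", {
  lines <- lineDf(c(783, 1443))
  bare <- tinyModSet(lines, NULL)
  bg <- function(l) 3e4 * (2 + sin((l - 800) / 25))
  dressed <- tinyModSet(lines, bg)
  for (m in c("recentred", "ols")) {
    w0 <- intensityValues(reconstructWMR(bare, method = m))
    w1 <- intensityValues(reconstructWMR(dressed, method = m))
    expect_lt(max(abs(w1 - w0)) / max(abs(w0)), 1e-10)
  }
})

test_that("an isolated line reconstructs as a derivative with the right crossing", {
  ms <- tinyModSet(lineDf(1443))
  for (m in c("recentred", "ols")) {
    w <- reconstructWMR(ms, method = m)
    ax <- spectralAxis(w); y <- intensityValues(w)
    expect_true(all(ax >= 600 & ax <= 1800))
    # positive lobe below the centre, negative above
    expect_gt(y[which.min(abs(ax - 1435))], 0)
    expect_lt(y[which.min(abs(ax - 1451))], 0)
    i <- which(y[-length(y)] > 0 & y[-1] < 0 & abs(ax[-length(ax)] - 1443) < 10)
    x0 <- ax[i] + y[i] * (ax[i + 1] - ax[i]) / (y[i] - y[i + 1])
    expect_lt(abs(x0 - 1443), diff(ax)[1])  # within one bin
  }
})

test_that("reconstruction is linear: doubled amplitudes double the output", {
  ms1 <- tinyModSet(lineDf(c(1007, 1658)))
  ms2 <- tinyModSet(lineDf(c(1007, 1658), amplitude = 10000))
  for (m in c("recentred", "ols"))
    expect_equal(intensityValues(reconstructWMR(ms2, method = m)),
                 2 * intensityValues(reconstructWMR(ms1, method = m)),
                 tolerance = 1e-10)
})

test_that("the OLS route matches a brute-force per-bin lm fit", {
  ms <- tinyModSet(lineDf(c(1080, 1523)),
                   background = function(l) rep(2e4, length(l)))
  w <- reconstructWMR(ms, method = "ols")
  lex <- vapply(ms, excitationNm, numeric(1))
  x <- 1e7 / lex
  counts <- do.call(rbind, lapply(ms, intensityValues))
  nu <- wavelengthToWavenumber(spectralAxis(ms[[1]]), stats::median(lex))
  keep <- which(nu >= 600 & nu <= 1800)
  idx <- keep[seq(1, length(keep), by = 37)]
  oracle <- vapply(idx, function(b)
    unname(coef(lm(counts[, b] ~ x))[2]), numeric(1))
  got <- intensityValues(w)[match(nu[idx], spectralAxis(w))]
  expect_equal(got, oracle, tolerance = 1e-10)
})

test_that("reconstruction guards reject degenerate modulation sets", {
  ms <- tinyModSet(lineDf(1200))
  expect_error(reconstructWMR(ms[1:2]), "at least 3")
  same <- lapply(1:3, function(i)
    simulateRawSpectrum(lineDf(1200), NULL, 785, noise = FALSE))
  expect_error(reconstructWMR(same), "zero design variance")
})

test_that("averaging is pointwise and shrinks noise like 1/sqrt(k)", {
  ms <- tinyModSet(lineDf(1303))
  w <- reconstructWMR(ms)
  avg <- averageWMR(list(w, w, w))
  expect_equal(intensityValues(avg), intensityValues(w))
  expect_equal(nSourceSpectra(avg), 15L)
  neg <- WMRSpectrum(spectralAxis(w), -intensityValues(w))
  expect_true(all(intensityValues(averageWMR(list(w, neg))) == 0))
  other <- WMRSpectrum(spectralAxis(w) + 1, intensityValues(w))
  expect_error(averageWMR(list(w, other)), "axis mismatch")

  # Monte-Carlo: averaging k noisy replicates shrinks the residual sd
  truth <- intensityValues(w)
  noisy <- function(seed) {
    set.seed(seed)
    ms <- tinyModSet(lineDf(1303), function(l) rep(5e4, length(l)),
                     noise = TRUE)
    reconstructWMR(ms)
  }
  resid1 <- sapply(1:6, function(s) sd(intensityValues(noisy(s)) - truth))
  resid9 <- sapply(1:6, function(s) {
    avg <- averageWMR(lapply(9 * s + 1:9, noisy))
    sd(intensityValues(avg) - truth)
  })
  ratio <- mean(resid1) / mean(resid9)
  expect_gt(ratio, 2)   # ideal 3 for k = 9
  expect_lt(ratio, 4.5)
})

test_that("normalisation yields unit norm and is scale invariant", {
  w <- reconstructWMR(tinyModSet(lineDf(1007)))
  n1 <- normalizeWMR(w)
  expect_equal(sqrt(sum(intensityValues(n1)^2)), 1, tolerance = 1e-12)
  w7 <- WMRSpectrum(spectralAxis(w), 7 * intensityValues(w))
  expect_equal(intensityValues(normalizeWMR(w7)), intensityValues(n1))
  zero <- WMRSpectrum(spectralAxis(w), rep(0, length(spectralAxis(w))))
  expect_error(normalizeWMR(zero), "all-zero")
})
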