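# brute-force S statistic by explicit pair enumeration
bruteS <- function(x) {
  s <- 0
  for (i in seq_along(x))
    for (j in seq_along(x))
      if (j > i) s <- s + sign(x[j] - x[i])
  s
}

test_that("Mann-Kendall S matches exhaustive pair enumeration", {
  expect_equal(mannKendall(1:8)$S, 28)  # all 28 pairs concordant
  expect_equal(mannKendall(rep(2, 5))$S, 0)
  expect_equal(mannKendall(rep(2, 5))$p_value, 1)
  set.seed(3)
  for (n in c(4, 6, 9, 15)) {
    x <- rnorm(n)
    expect_equal(mannKendall(x)$S, bruteS(x))
  }
  x4 <- c(1, 3, 2, 4)
  expect_equal(mannKendall(x4)$S, bruteS(x4))  # = 4 over the 6 pairs
  expect_equal(mannKendall(x4)$S, 4)
  expect_error(mannKendall(1:3), "at least 4")
  expect_error(mannKendall(c(1, NA, 2, 3)), "missing")
})

test_that("exact small-n p-values agree with the independent Kendall test", {
  set.seed(9)
  for (n in c(5, 7, 8)) {
    x <- sample(seq_len(n) * 1.3)  # tie-free
    ours <- mannKendall(x)$p_value
    ref <- suppressWarnings(
      stats::cor.test(x, seq_len(n), method = "kendall"))$p.value
    expect_equal(ours, ref, tolerance = 1e-12)
  }
  # strictly increasing length-8: p = 2/8!
  expect_equal(mannKendall(1:8)$p_value, 2 / factorial(8))
})

test_that("tie-corrected normal approximation is used for longer series", {
  set.seed(5)
  x <- round(rnorm(20), 1)  # ties likely
  mk <- mannKendall(x)
  expect_equal(mk$S, bruteS(x))
  expect_gte(mk$p_value, 0)
  expect_lte(mk$p_value, 1)
  # a long clean trend is overwhelmingly significant
  expect_lt(mannKendall(seq(0, 2, length.out = 20) + 0)$p_value, 1e-6)
})

test_that("Theil-Sen slope is the median pairwise slope", {
  expect_equal(theilSen(c(0, 1, 2, 3), c(0, 1, 2, 3)), 1)
  expect_equal(theilSen(rep(4, 6)), 0)
  # enumeration oracle: slopes {1, 1, 100/3, 1, 49.5, 98}, median 17.1667
  x <- c(0, 1, 2, 100); t <- c(0, 1, 2, 3)
  slopes <- c()
  for (i in 1:3) for (j in (i + 1):4)
    slopes <- c(slopes, (x[j] - x[i]) / (t[j] - t[i]))
  expect_equal(theilSen(x, t), median(slopes))
  expect_equal(theilSen(x, t), (1 + 100 / 3) / 2)
  expect_error(theilSen(c(1, 2, 3), c(0, 0, 1)), "duplicate")
})

test_that("trend classification labels ramps, flats and noise sensibly", {
  t <- 1:8
  up <- 1 + 0.10 * (t - 1)
  expect_equal(classifyTrend(up, t)$label, "increasing")
  expect_equal(classifyTrend(rep(1, 8), t)$label, "stable")
  expect_equal(classifyTrend(rev(up), t)$label, "decreasing")
  # significant but negligible slope stays stable
  tiny <- 1 + 0.001 * (t - 1)
  expect_equal(classifyTrend(tiny, t)$label, "stable")
})

test_that("negating a series flips increasing/decreasing and keeps stable", {
  set.seed(21)
  for (i in 1:20) {
    x <- 1 + cumsum(rnorm(8, sd = 0.1))
    a <- classifyTrend(x, 1:8)
    b <- classifyTrend(-x, 1:8)
    expect_equal(b$label, switch(a$label, increasing = "decreasing",
                                 decreasing = "increasing",
                                 stable = "stable"))
    expect_equal(b$sen_slope, -a$sen_slope)
  }
})

test_that("false-positive rate for flat noisy series stays near alpha", {
  set.seed(77)
  labs <- replicate(200, classifyTrend(1 + rnorm(8, sd = 0.05), 1:8)$label)
  expect_lte(mean(labs != "stable"), 0.05 + 0.05)
})

test_that("noise-free runs reproduce the full catalogue label pattern", {
  for (nm in c("no_stress", "inh_stress")) {
    q <- quantifyScenario(nm, noise = FALSE)
    tt <- buildTrendTable(q, nm)
    expect_equal(agreementFraction(tt), 1.0, info = nm)
    expect_equal(nrow(trendResults(tt)), 13)
  }
})

test_that("characteristic single-band calls come out of full runs", {
  qN <- quantifyScenario("no_stress", noise = FALSE)
  ttN <- buildTrendTable(qN, "no_stress")
  rN <- trendResults(ttN)
  expect_equal(rN$label[rN$reference_cm1 %in% c(1150, 1523)],
               c("decreasing", "decreasing"))
  qI <- quantifyScenario("inh_stress", noise = FALSE)
  rI <- trendResults(buildTrendTable(qI, "inh_stress"))
  expect_equal(rI$label[rI$reference_cm1 == 1303], "increasing")
})

test_that("shuffling time order destroys the recovered agreement", {
  q <- quantifyScenario("no_stress", noise = FALSE)
  set.seed(4)
  perm <- sample(unique(q$timestamp_h))
  q$timestamp_h <- perm[match(q$timestamp_h, sort(unique(q$timestamp_h)))]
  q <- q[order(q$reference_cm1, q$timestamp_h), ]
  # renormalise to the (new) first time point
  for (p in unique(q$reference_cm1)) {
    i <- which(q$reference_cm1 == p & !is.na(q$peak_to_valley))
    q$normalized[i] <- q$peak_to_valley[i] / q$peak_to_valley[i][1]
  }
  tt <- buildTrendTable(q, "no_stress")
  expect_lt(agreementFraction(tt), 0.7)
})

test_that("bands missing everywhere are labelled stable with a flag", {
  q <- quantifyScenario("no_stress", noise = FALSE)
  q$peak_to_valley[q$reference_cm1 == 635] <- NA
  q$normalized[q$reference_cm1 == 635] <- NA
  tt <- buildTrendTable(q, "no_stress")
  r <- trendResults(tt)
  expect_equal(r$label[r$reference_cm1 == 635], "stable")
  expect_true(r$missing_data[r$reference_cm1 == 635])
  expect_false(r$agree[r$reference_cm1 == 635])
})

test_that("majority vote across replicates settles disagreements", {
  q <- quantifyScenario("no_stress", noise = FALSE)
  tt <- buildTrendTable(q, "no_stress")
  vote <- majorityVoteTrends(list(tt, tt, tt))
  expect_equal(vote$label, trendResults(tt)$label)
  # a single dissenting run is outvoted
  flip <- tt
  flip@results$label[1] <- "decreasing"
  vote2 <- majorityVoteTrends(list(tt, tt, flip))
  expect_equal(vote2$label[1], trendResults(tt)$label[1])
})

test_that("too few usable time points abort trend building", {
  q <- quantifyScenario("no_stress", noise = FALSE)
  q3 <- q[q$timestamp_h <= 3, ]
  expect_error(buildTrendTable(q3, "no_stress"), "insufficient time points")
})
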