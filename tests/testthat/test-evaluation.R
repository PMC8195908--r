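# bad-channel injection, metrics and the assessment protocol

test_that("bad-channel counts follow round(fraction * N) with clamping", {
  mon <- fixtureMontage62()
  set.seed(1)
  expect_length(selectBadChannels(mon, 0.10, "scattered"), 6L)
  expect_length(selectBadChannels(mon, 0.02, "scattered"), 1L)
  expect_length(selectBadChannels(mon, 0.85, "scattered"), 53L)
  expect_error(selectBadChannels(mon, 0.99, "scattered"), "fewer than 3")
  expect_error(selectBadChannels(mon, 0, "scattered"), "strictly")
})

test_that("single bad channels are drawn uniformly over the montage", {
  mon <- fixtureMontage62()
  set.seed(2026)
  draws <- replicate(10000, selectBadChannels(mon, 1 / 62, "scattered"))
  counts <- table(factor(draws, levels = channelLabels(mon)))
  # chi-square uniformity over 10,000 single draws
  p <- stats::chisq.test(as.vector(counts))$p.value
  expect_gt(p, 0.001)
})

test_that("adjacent bad sets are connected patches in the 4-NN graph", {
  mon <- fixtureMontage62()
  set.seed(7)
  for (trial in 1:50) {
    f <- runif(1, 0.05, 0.5)
    bads <- selectBadChannels(mon, f, "adjacent")
    expect_true(isConnectedIn4nnGraph(mon, bads))
  }
})

test_that("bad-channel draws are reproducible from the RNG state", {
  mon <- fixtureMontage62()
  set.seed(99)
  a <- selectBadChannels(mon, 0.25, "adjacent")
  set.seed(99)
  b <- selectBadChannels(mon, 0.25, "adjacent")
  expect_identical(a, b)
})

test_that("metrics match long-hand arithmetic on a 2-channel, 3-sample case", {
  lab <- c("b1", "b2", "g1", "g2")
  vt <- rbind(c(1, 2, 3), c(2, 0, -2), c(0, 0, 0), c(1, 1, 1))
  ve <- rbind(c(1.5, 1, 3), c(2, 1, -1), c(0, 0, 0), c(1, 1, 1))
  rownames(vt) <- rownames(ve) <- lab
  truth <- eegRecording(vt, sfreq = 100)
  est <- eegRecording(ve, sfreq = 100)
  m <- interpMetrics(truth, est, c("b1", "b2"))
  # |errors| are (0.5, 1, 0) and (0, 1, 1): mean 3.5/6, sum 3.5 over
  # sum |truth| = 10; correlations worked out long-hand below
  expect_equal(m[["mae"]], 3.5 / 6, tolerance = 1e-15)
  expect_equal(m[["rae"]], 0.35, tolerance = 1e-15)
  r1 <- 0.75 / (1 * sqrt(39 / 36))
  r2 <- 3 / (2 * sqrt(7 / 3))
  expect_equal(m[["r"]], (r1 + r2) / 2, tolerance = 1e-12)
})

test_that("metrics on identical inputs are (0, 0, 1)", {
  sim <- simulateEEG(fixtureModel(), fixtureMontage62(), seed = 8,
                     duration = 0.2, reference = "average")
  rec <- sim$recording
  m0 <- interpMetrics(rec, rec, c("Cz", "P3"))
  expect_identical(unname(m0), c(0, 0, 1))
})

test_that("metric homogeneity: joint scaling by 10 scales mae only", {
  set.seed(12)
  lab <- c("b1", "g1", "g2")
  vt <- matrix(rnorm(3 * 20), 3, dimnames = list(lab, NULL))
  ve <- vt + 0.3 * matrix(rnorm(3 * 20), 3)
  rownames(ve) <- lab
  m1 <- interpMetrics(eegRecording(vt, sfreq = 10),
                      eegRecording(ve, sfreq = 10), "b1")
  m10 <- interpMetrics(eegRecording(10 * vt, sfreq = 10),
                       eegRecording(10 * ve, sfreq = 10), "b1")
  expect_equal(m10[["mae"]], 10 * m1[["mae"]], tolerance = 1e-12)
  expect_equal(m10[["rae"]], m1[["rae"]], tolerance = 1e-12)
  expect_equal(m10[["r"]], m1[["r"]], tolerance = 1e-12)
})

test_that("metrics are invariant to channel ordering", {
  set.seed(13)
  lab <- c("a", "b", "c", "d")
  vt <- matrix(rnorm(4 * 15), 4, dimnames = list(lab, NULL))
  ve <- vt + 0.2 * matrix(rnorm(4 * 15), 4)
  rownames(ve) <- lab
  perm <- c(3, 1, 4, 2)
  m1 <- interpMetrics(eegRecording(vt, sfreq = 10),
                      eegRecording(ve, sfreq = 10), c("b", "d"))
  m2 <- interpMetrics(eegRecording(vt[perm, ], sfreq = 10),
                      eegRecording(ve[perm, ], sfreq = 10), c("d", "b"))
  expect_equal(m1, m2, tolerance = 1e-14)
})

test_that("zero-variance true channels are excluded from mean r with a warning", {
  lab <- c("flat", "ok", "g")
  vt <- rbind(rep(1, 10), sin(1:10), rep(0, 10))
  ve <- rbind(rep(1, 10), sin(1:10) + 0.1, rep(0, 10))
  rownames(vt) <- rownames(ve) <- lab
  expect_warning(
    m <- interpMetrics(eegRecording(vt, sfreq = 10),
                       eegRecording(ve, sfreq = 10), c("flat", "ok")),
    "zero-variance")
  expect_equal(m[["r"]], cor(sin(1:10), sin(1:10) + 0.1))
})

test_that("the protocol run is deterministic and composes from its parts", {
  mon <- fixtureMontage62()
  lf <- fixtureLeadField62()
  sim <- simulateEEG(fixtureModel(), mon, seed = 14, duration = 0.4,
                     snr = 5, reference = "average")
  rec <- sim$recording
  resA <- runAssessment(rec, mon, lf, fractions = 0.1, case = "scattered",
                        nRepeats = 2, seed = 77)
  resB <- runAssessment(rec, mon, lf, fractions = 0.1, case = "scattered",
                        nRepeats = 2, seed = 77)
  expect_identical(assessmentResults(resA), assessmentResults(resB))
  expect_identical(nrow(assessmentFailures(resA)), 0L)
  # manual composition with the same RNG stream, one repeat, one method
  resNi <- runAssessment(rec, mon, leadfield = NULL, fractions = 0.25,
                         case = "adjacent", nRepeats = 1, methods = "ni",
                         seed = 123)
  set.seed(123)
  bads <- selectBadChannels(mon, 0.25, "adjacent")
  x <- eegData(rec)
  x[bads, ] <- 0
  dirty <- suppressWarnings(
    eegRecording(x, sfreq = 500, reference = "infinity", bad = bads))
  dirty <- resit:::.remake(dirty, reference = "average")
  est <- niInterpolate(dirty, mon)
  manual <- interpMetrics(rec, est, bads)
  row <- assessmentResults(resNi)
  expect_identical(row$k, length(bads))
  expect_equal(c(row$mae, row$rae, row$r), unname(manual),
               tolerance = 1e-14)
})

test_that("assessment summary aggregates means and standard errors per cell", {
  mon <- fixtureMontage62()
  sim <- simulateEEG(fixtureModel(), mon, seed = 15, duration = 0.3,
                     snr = 5, reference = "average")
  res <- runAssessment(sim$recording, mon, fractions = c(0.1, 0.25),
                       case = "scattered", nRepeats = 3,
                       methods = c("ni", "ssi"), seed = 5)
  s <- assessmentSummary(res)
  expect_identical(nrow(s), 4L) # 2 methods x 2 fractions
  r <- assessmentResults(res)
  cell <- r[r$method == "ni" & r$fraction == 0.1, ]
  expect_equal(s$maeMean[s$method == "ni" & s$fraction == 0.1],
               mean(cell$mae))
  expect_equal(s$maeSe[s$method == "ni" & s$fraction == 0.1],
               sd(cell$mae) / sqrt(3))
})
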