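# the three interpolators: neighbor averaging, spherical splines, RESIT

.simAvgRec <- function(seed = 5, duration = 0.4, snr = NULL, ...) {
  simulateEEG(fixtureModel(), fixtureMontage62(), seed = seed,
              duration = duration, snr = snr, reference = "average", ...)
}

test_that("neighbor interpolation averages the 4 nearest good channels", {
  mon <- fixtureMontage62()
  sim <- .simAvgRec()
  rec <- sim$recording
  bads <- c("Cz", "P3", "O1")
  badChannels(rec) <- bads
  out <- niInterpolate(rec, mon)
  expect_identical(badChannels(out), character(0))
  d <- angularDistances(mon)
  x <- eegData(rec)
  good <- setdiff(rownames(rec), bads)
  for (b in bads) {
    # brute-force neighbor oracle: sort all good channels by angle
    nb <- good[order(d[b, good], good)][1:4]
    expect_equal(eegData(out)[b, ], colMeans(x[nb, ]), tolerance = 1e-12)
    # equivalent weight vector: 4 entries of 1/4, zeros elsewhere
    w <- setNames(rep(0, length(good)), good)
    w[nb] <- 1 / 4
    expect_equal(eegData(out)[b, ], drop(w %*% x[good, ]),
                 tolerance = 1e-12)
  }
  # good channels untouched
  expect_identical(eegData(out)[good, ], x[good, ])
})

test_that("neighbor interpolation of constant data returns the constant", {
  mon <- fixtureMontage62()
  x <- matrix(7, 62, 10, dimnames = list(channelLabels(mon), NULL))
  rec <- eegRecording(x, sfreq = 500, reference = "infinity",
                      bad = c("Fz", "FT9"))
  out <- niInterpolate(rec, mon)
  expect_true(all(eegData(out) == 7))
})

test_that("neighbor interpolation needs enough good channels", {
  mon <- standardMontage(19)
  x <- matrix(rnorm(19 * 5), 19, dimnames = list(channelLabels(mon), NULL))
  rec <- eegRecording(x, sfreq = 500, bad = channelLabels(mon)[1:16])
  expect_error(niInterpolate(rec, mon), "at least 4 good")
})

test_that("the spline kernel matches an independent Legendre evaluation", {
  skip_if_not_installed("pracma")
  mon <- electrodeMontage(
    c("up", "fr", "le", "ba"),
    rbind(c(0, 0, 1), c(1, 0, 0), c(0, 1, 0), c(-1, 0, 0)))
  sys <- ssiBuild(mon, badChannels = "ba", orderM = 4, nLegendre = 50)
  # diagonal = g(1), orthogonal pairs = g(0)
  expect_equal(unname(diag(sys@gGood)), rep(oracleSplineKernel(1), 3),
               tolerance = 1e-8)
  expect_equal(unname(sys@gGood[1, 2]), oracleSplineKernel(0),
               tolerance = 1e-12)
})

test_that("g(1) equals the direct series sum and a 7-term hand sum at x = 0", {
  mon <- electrodeMontage(
    c("up", "fr", "le"), rbind(c(0, 0, 1), c(1, 0, 0), c(0, 1, 0)))
  sys <- ssiBuild(mon, badChannels = character(0))
  n <- 1:50
  g1 <- sum((2 * n + 1) / (n^4 * (n + 1)^4)) / (4 * pi)
  expect_equal(unname(diag(sys@gGood)), rep(g1, 3), tolerance = 1e-14)
  # 7-term kernel at x = 0: P_n(0) is 0 for odd n, -1/2, 3/8, -5/16 for
  # n = 2, 4, 6
  sys7 <- ssiBuild(mon, badChannels = character(0), nLegendre = 7)
  hand <- (5 / 6^4 * (-1 / 2) + 9 / 20^4 * (3 / 8) +
             13 / 42^4 * (-5 / 16)) / (4 * pi)
  expect_equal(unname(sys7@gGood[1, 2]), hand, tolerance = 1e-15)
})

test_that("coincident good electrodes are rejected", {
  mon <- electrodeMontage(
    c("a", "b", "c", "d"),
    rbind(c(0, 0, 1), c(0, 0, 1), c(1, 0, 0), c(0, 1, 0)))
  expect_error(ssiBuild(mon, badChannels = character(0)), "[Cc]oincident")
})

test_that("spherical splines recover spline-generated data at held-out sites", {
  mon <- fixtureMontage62()
  labels <- channelLabels(mon)
  set.seed(17)
  for (trial in 1:5) {
    bads <- sample(labels, 6)
    good <- setdiff(labels, bads)
    sys <- ssiBuild(mon, bads)
    # generating spline: zero-sum coefficients over the good sites
    nT <- 4
    coefC <- matrix(rnorm(length(good) * nT), length(good))
    coefC <- sweep(coefC, 2, colMeans(coefC))
    c0 <- rnorm(nT)
    pos <- electrodePositions(mon)
    cosAll <- pmin(pmax(tcrossprod(pos, pos[match(good, labels), ]), -1), 1)
    gAll <- matrix(resit:::.splineKernel(cosAll, 4, 50L), nrow = 62)
    truthAll <- gAll %*% coefC + rep(1, 62) %o% c0
    rownames(truthAll) <- labels
    rec <- eegRecording(truthAll, sfreq = 500, bad = bads)
    out <- ssiInterpolate(rec, sys)
    err <- abs(eegData(out)[bads, ] - truthAll[bads, ])
    expect_lt(max(err) / max(abs(truthAll[bads, ])), 1e-6)
    # zero-sum constraint holds post hoc: re-solve and inspect
    aug <- rbind(cbind(sys@gGood, 1), c(rep(1, length(good)), 0))
    sol <- solve(aug, rbind(truthAll[good, ], 0))
    expect_lt(max(abs(colSums(sol[seq_along(good), ]))),
              1e-8 * max(abs(sol[seq_along(good), ])))
    # good-channel fit is exact to solver precision
    fit <- sys@gGood %*% sol[seq_along(good), ] +
      rep(1, length(good)) %o% sol[length(good) + 1, ]
    expect_lt(max(abs(fit - truthAll[good, ])) / max(abs(truthAll[good, ])),
              1e-6)
  }
})

test_that("spherical splines pass constant data through unchanged", {
  mon <- fixtureMontage62()
  x <- matrix(3.5, 62, 6, dimnames = list(channelLabels(mon), NULL))
  rec <- eegRecording(x, sfreq = 500, bad = c("Cz", "Oz"))
  out <- ssiInterpolate(rec, ssiBuild(mon, c("Cz", "Oz")))
  expect_equal(eegData(out), x, tolerance = 1e-9)
})

test_that("RESIT with no bad channels is exactly reference standardization", {
  sim <- .simAvgRec(seed = 31)
  lf <- fixtureLeadField62()
  viaInterp <- resitInterpolate(sim$recording, lf)
  viaRest <- restStandardize(sim$recording, lf)
  expect_identical(eegData(viaInterp), eegData(viaRest))
  expect_identical(eegReference(viaInterp), "infinity")
  # re-referencing the standardized output to AVG is centering-consistent
  backAvg <- rereference(viaInterp, "average")
  expect_true(all(abs(colMeans(eegData(backAvg))) < 1e-10))
})

test_that("RESIT on grid-sourced data: k = 0 is exact, held-out channels are faithful", {
  lf <- fixtureLeadField62()
  sim <- simulateEEG(fixtureModel(), fixtureMontage62(), nSources = 8,
                     duration = 0.3, sensorNoiseSd = 0,
                     reference = "average", seed = 41,
                     sourceGrid = fixtureGrid(), inverseCrime = TRUE)
  rec <- sim$recording
  # k = 0: the data lies in the column space of the referenced lead
  # field, so standardize-then-re-average reproduces it essentially
  # exactly (the only loss is the pseudoinverse cutoff)
  clean <- rereference(resitInterpolate(rec, lf), "average")
  expect_lt(max(abs(eegData(clean) - eegData(rec))) /
              max(abs(eegData(rec))), 1e-6)
  # k > 0: good channels stay near-exact; held-out channels track the
  # truth closely (extrapolation is not exact even in an inverse crime)
  set.seed(42)
  bads <- selectBadChannels(fixtureMontage62(), 0.1, "scattered")
  eegDirty <- eegData(rec)
  eegDirty[bads, ] <- 0
  dirty <- eegRecording(sweep(eegDirty, 2, colMeans(eegDirty)),
                        sfreq = 500, reference = "average", bad = bads)
  out <- resitInterpolate(dirty, lf, outputReference = "average")
  truthAvg <- rereference(sim$groundTruth, "average")
  good <- setdiff(rownames(rec), bads)
  expect_lt(max(abs(eegData(out)[good, ] - eegData(truthAvg)[good, ])) /
              max(abs(eegData(truthAvg)[good, ])), 0.02)
  for (b in bads)
    expect_gt(cor(eegData(out)[b, ], eegData(truthAvg)[b, ]), 0.95)
})

test_that("RESIT is linear and maps zero data to zero", {
  lf <- fixtureLeadField62()
  simA <- .simAvgRec(seed = 51)
  simB <- .simAvgRec(seed = 52)
  bads <- c("Fp1", "C3", "PO8")
  mk <- function(x) eegRecording(x, sfreq = 500, reference = "average",
                                 bad = bads)
  xa <- eegData(simA$recording)
  xb <- eegData(simB$recording)
  outA <- eegData(resitInterpolate(mk(xa), lf))
  outB <- eegData(resitInterpolate(mk(xb), lf))
  outMix <- eegData(resitInterpolate(mk(2 * xa - 0.5 * xb), lf))
  expect_equal(outMix, 2 * outA - 0.5 * outB,
               tolerance = 1e-9)
  z <- eegData(resitInterpolate(mk(matrix(0, 62, ncol(xa),
                                          dimnames = dimnames(xa))), lf))
  expect_true(all(z == 0))
})

test_that("all three interpolators are linear in the data", {
  mon <- fixtureMontage62()
  lf <- fixtureLeadField62()
  bads <- c("T7", "CP1", "Oz", "AF8")
  xa <- eegData(.simAvgRec(seed = 61)$recording)
  xb <- eegData(.simAvgRec(seed = 62)$recording)
  mk <- function(x) eegRecording(x, sfreq = 500, reference = "average",
                                 bad = bads)
  sys <- ssiBuild(mon, bads)
  for (interp in list(
    function(r) niInterpolate(r, mon),
    function(r) ssiInterpolate(r, sys),
    function(r) resitInterpolate(r, lf))) {
    ya <- eegData(interp(mk(xa)))
    yb <- eegData(interp(mk(xb)))
    ymix <- eegData(interp(mk(0.3 * xa + 1.6 * xb)))
    expect_equal(ymix, 0.3 * ya + 1.6 * yb, tolerance = 1e-9)
  }
})

test_that("RESIT input validation catches degenerate bad masks", {
  lf <- fixtureLeadField62()
  sim <- .simAvgRec(seed = 71)
  x <- eegData(sim$recording)
  rec <- eegRecording(x, sfreq = 500, reference = "average",
                      bad = rownames(x)[seq_len(61)])
  expect_error(resitInterpolate(rec, lf), "at least 2 good")
})

test_that("RESIT with a point-referenced recording uses the matching lead field row", {
  lf <- fixtureLeadField62()
  sim <- simulateEEG(fixtureModel(), fixtureMontage62(), seed = 81,
                     duration = 0.3, reference = "point", refChannel = "Cz")
  rec <- sim$recording
  badChannels(rec) <- c("O1", "F3")
  out <- resitInterpolate(rec, lf, outputReference = "average")
  truthAvg <- rereference(sim$groundTruth, "average")
  for (b in c("O1", "F3"))
    expect_gt(cor(eegData(out)[b, ], eegData(truthAvg)[b, ]), 0.95)
  # the reference electrode itself must be good
  badChannels(rec) <- c("Cz", "F3")
  expect_error(resitInterpolate(rec, lf), "good channel")
})
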