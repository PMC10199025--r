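test_that("volume trace reproduces the generator's prescribed volume curve", {
  p <- subjectParams(seed = 2, nFrames = 12L)
  seqc <- generateSubject(p)
  vt <- volumeTrace(seqc)
  expect_length(vt$values, 12L)
  v <- volumeShape(p)
  expect_equal(vt$values, p$edvTarget * v(seqc@phases), tolerance = 1e-8)
  # constant geometry gives a constant trace
  g <- lvSurfaceGrid()
  st <- staticSequence(halfSpheroidPoints(70, 30, g),
                       halfSpheroidPoints(78, 38, g), g)
  expect_equal(diff(volumeTrace(st)$values), 0)
})

test_that("global indices follow their defining arithmetic", {
  vt <- lvTrace(c(150, 100, 60, 100, 140), c(0, 0.2, 0.4, 0.6, 0.8), 1)
  gi <- globalIndices(vt, massAtED = 120)
  expect_identical(gi$EDV, 150)
  expect_identical(gi$ESV, 60)
  expect_equal(gi$EF, 60.0)
  expect_identical(gi$LVM, 120)
  # constant trace: EF = 0
  expect_equal(globalIndices(lvTrace(rep(80, 4), (0:3) / 4, 1))$EF, 0)
  # ESV is the global minimum sample of a dipping trace
  vt2 <- lvTrace(c(100, 70, 40, 55, 90), (0:4) / 5, 1)
  expect_equal(globalIndices(vt2)$ESV, 40)
  expect_error(globalIndices(lvTrace(c(1e-12, 1, 2) - 1e-12, (0:2) / 3, 1)),
               "non-positive")
})

test_that("EF identity holds and EF is scale invariant on full index sets", {
  seqc <- generateSubject(subjectParams(seed = 4, nFrames = 10L))
  idx <- computeIndices(seqc)
  expect_equal(idx$EF, 100 * (idx$EDV - idx$ESV) / idx$EDV, tolerance = 1e-9)
  scaled <- seqc
  scaled@endo <- seqc@endo * 1.3
  scaled@epi <- seqc@epi * 1.3
  scaled@landmarks <- lapply(seqc@landmarks, function(p) p * 1.3)
  expect_equal(computeIndices(scaled)$EF, idx$EF, tolerance = 1e-9)
})

test_that("GLS responds exactly to affine scaling and ignores rotation", {
  g <- lvSurfaceGrid()
  endo <- halfSpheroidPoints(75, 30, g)
  epi <- halfSpheroidPoints(83, 38, g)
  seqc <- staticSequence(endo, epi, g)
  # identity motion: strain identically zero
  expect_equal(glsTrace(seqc)$values, c(0, 0))
  # frame 2 scaled by 0.8: strain exactly -20 percent there
  sc <- seqc
  sc@endo[, , 2L] <- endo * 0.8
  sc@epi[, , 2L] <- epi * 0.8
  expect_equal(glsTrace(sc)$values, c(0, -20), tolerance = 1e-12)
  # pure rotation about the long axis leaves arc lengths unchanged
  ang <- 0.31
  R <- rbind(c(1, 0, 0), c(0, cos(ang), -sin(ang)), c(0, sin(ang), cos(ang)))
  rot <- seqc
  rot@endo[, , 2L] <- endo %*% t(R)
  expect_lt(max(abs(glsTrace(rot)$values)), 1e-9)
})

test_that("rate indices recover the analytic sinusoid derivative", {
  # V(t) = 105 - 45 sin(2 pi t), T = 1 s: dV/dt extremum -2 pi 45 at t = 0
  ph <- seq(0, 1, length.out = 201)[1:200]
  vt <- lvTrace(105 - 45 * sin(2 * pi * ph), ph, 1)
  ri60 <- rateIndices(vt, nSamples = 60L)
  expect_equal(ri60$PER, -2 * pi * 45, tolerance = 0.02)
  expect_equal(ri60$PFR_E, 2 * pi * 45, tolerance = 0.02)
  expect_true(is.na(ri60$PFR_A))   # monophasic filling
  # constant trace: rates zero / absent
  ric <- rateIndices(lvTrace(rep(100, 8), (0:7) / 8, 1))
  expect_equal(ric$PER, 0)
  expect_equal(ric$PFR_E, 0)
  expect_true(is.na(ric$PFR_A))
})

test_that("generator E- and A-wave peak rates are recovered at 30 samples", {
  for (sd in c(1, 6)) {
    p <- subjectParams(seed = sd, nFrames = 33L)
    seqc <- generateSubject(p)
    vt <- volumeTrace(seqc)
    # dense-sampling oracle on the analytic volume function
    v <- volumeShape(p)
    phiD <- seq(0, 1, length.out = 8001)
    h <- phiD[2]
    vol <- p$edvTarget * v(phiD)
    dV <- (vol[c(2:8001, 2)] - vol[c(8000, 1:8000)]) / (2 * h) /
      p$cycleDuration
    es <- which.min(vol)
    dia <- (es + 1):8000
    eWin <- dia[phiD[dia] < 0.75]
    aWin <- dia[phiD[dia] >= 0.75]
    trueE <- max(dV[eWin]); trueA <- max(dV[aWin])
    truePer <- min(dV[1:es])
    ri <- rateIndices(vt, nSamples = 30L)
    expect_equal(ri$PER, truePer, tolerance = 0.05)
    expect_equal(ri$PFR_E, trueE, tolerance = 0.05)
    expect_equal(ri$PFR_A, trueA, tolerance = 0.05)
  }
})

test_that("rate signs are physiological and central differences converge", {
  pops <- lapply(c(21, 22, 23, 24, 25), function(s)
    generateSubject(subjectParams(seed = s, efTarget = 55 + (s %% 5),
                                  nFrames = 28L)))
  for (seqc in pops) {
    st <- glsTrace(seqc)
    vt <- volumeTrace(seqc)
    ri <- rateIndices(vt, st)
    expect_lte(ri$PER, 0)
    expect_lte(ri$PSR, 0)
    expect_gte(ri$PFR_E, 0)
  }
  # convergence: 60-sample derivative closer to the dense oracle than 15
  p <- subjectParams(seed = 31, nFrames = 33L)
  seqc <- generateSubject(p)
  vt <- volumeTrace(seqc)
  v <- volumeShape(p)
  phiD <- seq(0, 1, length.out = 8001)
  vol <- p$edvTarget * v(phiD)
  dV <- (vol[c(2:8001, 2)] - vol[c(8000, 1:8000)]) /
    (2 * phiD[2]) / p$cycleDuration
  truePer <- min(dV[1:which.min(vol)])
  e15 <- abs(rateIndices(vt, nSamples = 15L)$PER - truePer)
  e60 <- abs(rateIndices(vt, nSamples = 60L)$PER - truePer)
  expect_lt(e60, e15)
})

test_that("peak GLS is taken over systole with the expected sign", {
  seqc <- generateSubject(subjectParams(seed = 8, nFrames = 20L))
  st <- glsTrace(seqc)
  vt <- volumeTrace(seqc)
  gls <- peakGls(st, vt)
  expect_lt(gls, 0)
  # the strain trough is flat around end-systole, so the systolic peak sits
  # within a whisker of the whole-cycle minimum
  expect_lt(abs(gls - min(st$values)), 0.2)
})
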