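test_that("grid topology is a closed orientable surface with the right counts", {
  g <- lvSurfaceGrid()
  expect_equal(nGridPoints(g), 145L)
  # index bijection over rings x meridians
  idx <- c(apexIndex(g),
           as.vector(vapply(1:9, function(r) gridIndex(g, r, 1:16),
                            integer(16L))))
  expect_equal(sort(idx), 1:145)
  # closure: every edge of the capped triangulation shared by exactly 2
  # triangles
  tri <- rbind(g@triangles, g@capTriangles)
  edges <- rbind(tri[, 1:2], tri[, 2:3], tri[, c(3, 1)])
  key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  expect_true(all(table(key) == 2L))
  # Euler characteristic V - E + F = 2 (sphere topology, cap centroid incl.)
  V <- 145L + 1L
  E <- length(unique(key))
  F <- nrow(tri)
  expect_equal(V - E + F, 2L)
})

test_that("cavity volume matches the analytic half-spheroid and scales cubically", {
  g <- lvSurfaceGrid()
  P <- halfSpheroidPoints(80, 30, g)
  v <- cavityVolume(P, g)
  expect_lt(abs(v - halfSpheroidVolumeMl(80, 30)) / halfSpheroidVolumeMl(80, 30),
            0.02)
  # exact scaling law: doubling all coordinates multiplies the volume by 8
  expect_equal(cavityVolume(2 * P, g), 8 * v, tolerance = 1e-12)
})

test_that("hemisphere volume error shrinks with order >= 1.8 under refinement", {
  vtrue <- halfSpheroidVolumeMl(30, 30)
  errs <- vapply(c(1L, 2L, 4L), function(f) {
    g <- lvSurfaceGrid(16L * f, 9L * f)
    abs(cavityVolume(halfSpheroidPoints(30, 30, g), g) - vtrue) / vtrue
  }, numeric(1L))
  expect_true(all(diff(errs) < 0))   # monotone decrease
  orders <- log2(errs[-length(errs)] / errs[-1L])
  expect_true(all(orders >= 1.8))
})

test_that("cavity volume is invariant under rigid motion and flags inversion", {
  g <- lvSurfaceGrid()
  P <- halfSpheroidPoints(70, 32, g)
  v0 <- cavityVolume(P, g)
  set.seed(42)
  for (r in 1:5) {
    R <- randomRotation()
    Pm <- P %*% t(R) + matrix(rnorm(3, 0, 50), nrow(P), 3L, byrow = TRUE)
    expect_equal(cavityVolume(Pm, g), v0, tolerance = 1e-9)
  }
  # a reflection (swapping y and z) flips the orientation: the signed
  # volume becomes negative and is flagged
  expect_error(cavityVolume(P[, c(1L, 3L, 2L)], g), "inverted")
})

test_that("wall mass matches analytic concentric shells and is linear in density", {
  g <- lvSurfaceGrid()
  endo <- halfSpheroidPoints(80, 30, g)
  epi <- halfSpheroidPoints(88, 39, g)
  expected <- 1.05 * (halfSpheroidVolumeMl(88, 39) - halfSpheroidVolumeMl(80, 30))
  m <- wallMass(endo, epi, g)
  expect_lt(abs(m - expected) / expected, 0.02)
  expect_equal(wallMass(endo, epi, g, density = 2.1), 2 * m,
               tolerance = 1e-12)
  expect_equal(wallMass(endo, endo, g), 0)
  expect_error(wallMass(epi, endo, g), "smaller")
})

test_that("cardiac-frame alignment is idempotent and removes rigid motion", {
  seqc <- generateSubject(subjectParams(seed = 11, nFrames = 6L))
  a1 <- alignToCardiacFrame(seqc)
  expect_lt(max(abs(a1@endo - seqc@endo)), 1e-9)   # already canonical
  set.seed(7)
  for (r in 1:100) {
    moved <- rigidlyMove(seqc, randomRotation(), rnorm(3, 0, 40))
    re <- alignToCardiacFrame(moved)
    expect_lt(max(abs(re@endo - a1@endo)), 1e-6)
    expect_lt(max(abs(re@epi - a1@epi)), 1e-6)
  }
})

test_that("alignment places base at -L/3 and apex at +2L/3 on the long axis", {
  seqc <- generateSubject(subjectParams(seed = 3, nFrames = 4L))
  moved <- rigidlyMove(seqc, randomRotation(), c(10, -20, 5))
  al <- alignToCardiacFrame(moved)
  lm <- al@landmarks
  L <- sqrt(sum((lm$apex - lm$basalCentroid)^2))
  expect_equal(lm$basalCentroid, c(-L / 3, 0, 0), tolerance = 1e-8)
  expect_equal(lm$apex, c(2 * L / 3, 0, 0), tolerance = 1e-8)
})

test_that("degenerate landmarks raise alignment errors", {
  expect_error(cardiacFrame(c(0, 0, 0), c(0, 0, 0), c(1, 1, 0)),
               "coincides")
  expect_error(cardiacFrame(c(10, 0, 0), c(0, 0, 0), c(5, 0, 0)),
               "long axis")
})

test_that("AHA labelling partitions every point exactly once", {
  seqc <- generateSubject(subjectParams(seed = 5, nFrames = 4L))
  lab <- assignAhaSegments(seqc)
  expect_true(is.na(lab$endo[1L]))
  expect_equal(lab$epi[1L], 17L)
  expect_true(all(lab$endo[-1L] %in% 1:16))
  expect_true(all(lab$epi[-1L] %in% 1:16))
  # thirds: rings 1-3 apical (13-16), 4-6 mid (7-12), 7-9 basal (1-6)
  g <- seqc@grid
  for (r in 1:9) {
    ids <- lab$endo[gridIndex(g, r, 1:16)]
    rng <- if (r <= 3) 13:16 else if (r <= 6) 7:12 else 1:6
    expect_true(all(ids %in% rng))
  }
})

test_that("rotating the geometry by one meridian spacing preserves segment counts", {
  seqc <- generateSubject(subjectParams(seed = 5, nFrames = 4L,
                                        regionalSd = 0))
  lab0 <- assignAhaSegments(seqc)
  ang <- 2 * pi / 16
  R <- rbind(c(1, 0, 0), c(0, cos(ang), -sin(ang)), c(0, sin(ang), cos(ang)))
  rot <- seqc
  for (f in seq_len(dim(rot@endo)[3L])) {
    rot@endo[, , f] <- seqc@endo[, , f] %*% t(R)
    rot@epi[, , f] <- seqc@epi[, , f] %*% t(R)
  }
  lab1 <- assignAhaSegments(rot)
  expect_false(identical(lab0$endo, lab1$endo))  # membership permutes
  expect_equal(table(lab0$endo), table(lab1$endo))
  expect_equal(table(lab0$epi), table(lab1$epi))
})

test_that("segment point counts match independent enumeration from boundary angles", {
  seqc <- generateSubject(subjectParams(seed = 9, nFrames = 4L))
  g <- seqc@grid
  lab <- assignAhaSegments(seqc)
  # independent enumeration: meridian angles are multiples of 22.5 degrees;
  # count meridians falling in each sector directly
  thIns <- -70
  merAngles <- (0:15) * 22.5
  basalOrder <- c(3, 4, 5, 6, 1, 2)
  apicalOrder <- c(14, 15, 16, 13)
  sector6 <- floor(((merAngles - thIns) %% 360) / 60) + 1
  sector4 <- floor(((merAngles - (thIns - 45)) %% 360) / 90) + 1
  expected <- integer(17)
  for (m in 1:16) {
    expected[basalOrder[sector6[m]]] <- expected[basalOrder[sector6[m]]] + 3L
    expected[basalOrder[sector6[m]] + 6] <-
      expected[basalOrder[sector6[m]] + 6] + 3L
    expected[apicalOrder[sector4[m]]] <- expected[apicalOrder[sector4[m]]] + 3L
  }
  endoCounts <- tabulate(lab$endo[-1L], 17)
  expect_equal(endoCounts[1:16], expected[1:16])
  epiCounts <- tabulate(lab$epi, 17)
  expect_equal(epiCounts[1:16], expected[1:16])
  expect_equal(epiCounts[17], 1L)
})

test_that("unaligned sequences are rejected by the AHA labeller", {
  seqc <- generateSubject(subjectParams(seed = 5, nFrames = 4L))
  set.seed(1)
  moved <- rigidlyMove(seqc, randomRotation(), c(100, 50, -30))
  expect_error(assignAhaSegments(moved), "cardiac coordinates")
})
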