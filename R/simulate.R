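# Synthetic paired-population generator. Produces ground-truth dynamic LV
# geometries under a "target" protocol (CMR-like) and derives a biased
# "source" protocol counterpart (3DE-like) with a known, recoverable
# systematic bias: global volume underestimation, reduced apparent
# contraction, apical foreshortening, a smooth regional offset field peaking
# in the basal anterolateral wall, a monotone temporal warp with a
# heart-rate change, and point noise. Every component of the bias is stored
# so downstream tests can compare recovered quantities to the truth.

#' Parameters describing one synthetic subject
#'
#' The ventricle is modelled as a truncated half prolate spheroid (long
#' semi-axis along the long axis, base plane at the equator) whose semi-axes
#' are modulated over the cycle so the cavity volume follows a prescribed
#' physiological trace (ejection to end-systole, early (E) filling,
#' diastasis, atrial (A) filling) hitting the EDV and EF targets exactly at
#' the discretised surface.
#'
#' @param edvTarget end-diastolic volume target, ml.
#' @param efTarget ejection fraction target, percent (between 10 and 80).
#' @param aspectRatio ratio of long to short endocardial semi-axis.
#' @param wallThickness basal wall thickness, mm.
#' @param eFraction fraction of the stroke volume restored by the early
#'   filling wave (the remainder fills during the atrial wave).
#' @param esPhase cycle fraction of end-systole (default 0.35).
#' @param alpha partition of volume change between longitudinal shortening
#'   (`a ~ s^alpha`) and radial narrowing (`b ~ s^((1-alpha)/2)`).
#' @param regionalSd standard deviation of the random low-order harmonic
#'   radial modulation giving each subject a non-axisymmetric shape.
#' @param cycleDuration cycle length, s.
#' @param nFrames acquisition frames per cycle for the target protocol.
#' @param seed integer seed; all randomness for this subject flows from it.
#' @return list of class `subject_params`.
#' @export
subjectParams <- function(edvTarget = 150, efTarget = 60, aspectRatio = 2.4,
                          wallThickness = 8, eFraction = 0.72,
                          esPhase = 0.35, alpha = 0.2, regionalSd = 0.02,
                          cycleDuration = 0.92, nFrames = 30L, seed = 1L) {
  stopIfNot(edvTarget > 0 && wallThickness > 0 && aspectRatio > 0,
            "lengths and volumes must be positive")
  stopIfNot(efTarget > 10 && efTarget < 80, "efTarget must be in (10, 80)")
  structure(list(edvTarget = edvTarget, efTarget = efTarget,
                 aspectRatio = aspectRatio, wallThickness = wallThickness,
                 eFraction = eFraction, esPhase = esPhase, alpha = alpha,
                 regionalSd = regionalSd, cycleDuration = cycleDuration,
                 nFrames = as.integer(nFrames), seed = as.integer(seed)),
            class = "subject_params")
}

#' Normalised cavity-volume shape over one cycle
#'
#' Returns the subject's ground-truth normalised volume function `v(phase)`
#' (1 at end-diastole, `1 - EF/100` at end-systole), built as a monotone
#' cubic Hermite spline through physiological keyframes: ejection, E-wave,
#' diastasis, A-wave. Used by the generator and, densely sampled, as the
#' oracle for rate-index tests.
#'
#' @param params a `subject_params` list.
#' @return function of phase in `[0, 1]`.
#' @export
volumeShape <- function(params) {
  minv <- 1 - params$efTarget / 100
  refill <- 1 - minv
  e <- min(params$eFraction, 0.92)
  es <- params$esPhase
  aOnset <- 0.75                       # start of the atrial wave
  dd <- 0.02                           # slow diastasis fill fraction
  we <- min(0.26, aOnset - es - 0.02)  # E-wave width
  eEnd <- es + we
  # analytic raised-cosine limbs: smooth ED peak and ES trough, peak
  # filling rates wide enough to be resolved by a 30-sample derivative
  function(phase) {
    p <- phase
    out <- numeric(length(p))
    sys <- p <= es
    out[sys] <- minv + refill * (1 + cos(pi * p[sys] / es)) / 2
    ew <- p > es & p <= eEnd
    out[ew] <- minv + e * refill * (1 - cos(pi * (p[ew] - es) / we)) / 2
    di <- p > eEnd & p <= aOnset
    out[di] <- minv + refill *
      (e + dd * (p[di] - eEnd) / (aOnset - eEnd))
    aw <- p > aOnset
    out[aw] <- minv + refill *
      ((e + dd) + (1 - e - dd) *
         (1 - cos(pi * (p[aw] - aOnset) / (1 - aOnset))) / 2)
    out
  }
}

# per-subject non-axisymmetric radial modulation g(ring, meridian); zero
# coefficients give an exact surface of revolution
regionalModulation <- function(params, grid) {
  if (params$regionalSd <= 0)
    return(matrix(0, grid@nRings, grid@nMeridians))
  coef <- withSeed(params$seed, stats::rnorm(4L, 0, params$regionalSd))
  th <- 2 * pi * (seq_len(grid@nMeridians) - 1L) / grid@nMeridians
  rw <- (seq_len(grid@nRings) / grid@nRings)
  outer(rw, th, function(r, t)
    r * (coef[1L] * cos(t) + coef[2L] * sin(t) +
           coef[3L] * cos(2 * t) + coef[4L] * sin(2 * t)))
}

# assemble one surface frame from semi-axes and modulation; canonical pose
# (long axis x, apex toward +x, base plane of the construction at x = 0,
# then shifted so the coordinate origin sits at 1/3 base->apex of the ED
# epicardial long axis)
spheroidSurface <- function(a, b, grid, gmod, xShift) {
  nM <- grid@nMeridians; nR <- grid@nRings
  th <- 2 * pi * (seq_len(nM) - 1L) / nM
  P <- matrix(0, nGridPoints(grid), 3L)
  P[1L, ] <- c(a - xShift, 0, 0)
  psi <- (seq_len(nR) / nR) * (pi / 2)
  for (r in seq_len(nR)) {
    rho <- b * sin(psi[r]) * (1 + gmod[r, ])
    idx <- gridIndex(grid, r, seq_len(nM))
    P[idx, 1L] <- a * cos(psi[r]) - xShift
    P[idx, 2L] <- rho * cos(th)
    P[idx, 3L] <- rho * sin(th)
  }
  P
}

# geometric volume constants: discretised volume = c * a * b^2 exactly
# (the refinement operators are linear, so affine scalings pass through)
volumeConstant <- function(grid, gmod, subdivide = 4L) {
  P <- spheroidSurface(1, 1, grid, gmod, 0)
  cavityVolume(P, grid, subdivide) * 1000   # mm^3 per unit a*b^2
}

#' Generate the ground-truth (target-protocol) sequence for one subject
#'
#' Builds the dynamic LV geometry on the canonical grid: truncated-spheroid
#' endo- and epicardial surfaces whose semi-axes follow the subject's
#' volume-shape function, with the short semi-axis calibrated against the
#' discretised surface so the measured EDV and EF match their targets
#' essentially exactly. Wall volume is held constant over the cycle
#' (incompressible myocardium), so mass is time-invariant. The sequence is
#' produced in canonical cardiac coordinates with landmarks at end-diastole;
#' `pose = "random"` applies a seeded rigid motion (for testing alignment).
#'
#' @param params a [subjectParams()] list.
#' @param grid a [SurfaceGrid-class].
#' @param protocol protocol label (default "target").
#' @param pose `"canonical"` or `"random"`.
#' @param subdivide surface refinement used for calibration.
#' @return an [LVSequence-class] with the generator parameters in
#'   `@metadata$params`.
#' @export
generateSubject <- function(params, grid = lvSurfaceGrid(),
                            protocol = "target",
                            pose = c("canonical", "random"),
                            subdivide = 4L) {
  pose <- match.arg(pose)
  v <- volumeShape(params)
  minv <- 1 - params$efTarget / 100
  if (minv <= 0.05)
    stop("infeasible EF target for the spheroid model", call. = FALSE)
  gmod <- regionalModulation(params, grid)
  cEndo <- volumeConstant(grid, gmod, subdivide)
  a0 <- (params$edvTarget * 1000 * params$aspectRatio^2 / cEndo)^(1 / 3)
  b0 <- a0 / params$aspectRatio
  th <- params$wallThickness
  aEpi0 <- a0 + th
  cEpi <- cEndo                     # same angular sampling and modulation
  wallVol <- cEpi * aEpi0 * (b0 + th)^2 - params$edvTarget * 1000
  xShift <- aEpi0 / 3               # origin at 1/3 base->apex (epicardial)
  nF <- params$nFrames
  phases <- (seq_len(nF) - 1L) / nF
  np <- nGridPoints(grid)
  endo <- array(0, c(np, 3L, nF))
  epi <- array(0, c(np, 3L, nF))
  for (f in seq_len(nF)) {
    s <- v(phases[f])
    aE <- a0 * s^params$alpha
    bE <- b0 * s^((1 - params$alpha) / 2)
    vEndo <- cEndo * aE * bE^2
    aP <- aE + th
    bP <- sqrt((vEndo + wallVol) / (cEpi * aP))
    endo[, , f] <- spheroidSurface(aE, bE, grid, gmod, xShift)
    epi[, , f] <- spheroidSurface(aP, bP, grid, gmod, xShift)
  }
  bEpi0 <- b0 + th
  lm <- list(apex = c(aEpi0 - xShift, 0, 0),
             basalCentroid = c(-xShift, 0, 0),
             rvInsertion = c(-xShift, bEpi0 * cos(-70 * pi / 180),
                             bEpi0 * sin(-70 * pi / 180)))
  seq <- newLVSequence(
    subjectId = sprintf("S%06d", params$seed), protocol = protocol,
    endo = endo, epi = epi, phases = phases,
    cycleDuration = params$cycleDuration, landmarks = lm, grid = grid,
    metadata = list(params = params,
                    calibration = list(cEndo = cEndo, a0 = a0, b0 = b0,
                                       wallVol = wallVol, xShift = xShift)))
  if (pose == "random") {
    rt <- withSeed(params$seed + 104729L, {
      ax <- stats::rnorm(3L); ax <- ax / sqrt(sum(ax^2))
      ang <- stats::runif(1L, 0, 2 * pi)
      K <- matrix(c(0, -ax[3L], ax[2L], ax[3L], 0, -ax[1L],
                    -ax[2L], ax[1L], 0), 3L, 3L, byrow = TRUE)
      R <- diag(3L) + sin(ang) * K + (1 - cos(ang)) * K %*% K
      list(R = R, t = stats::rnorm(3L, 0, 30))
    })
    seq <- applyRigidMotion(seq, rt$R, rt$t)
  }
  seq
}

#' Inter-protocol bias model
#'
#' Defines the systematic differences injected between the target and the
#' derived source protocol. The default preset is tuned so that, over a
#' default population, the before-mapping biases (source minus target) fall
#' near EDV -16 ml, ESV +13 ml, EF -14 percentage points, LVM -11 g and GLS
#' +5 points, with the regional error peaking toward the basal anterolateral
#' wall - the sign/region pattern typical of 3DE-vs-CMR comparisons.
#'
#' @param volumeScale multiplicative EDV factor of the source protocol
#'   (in (0.5, 1.5)).
#' @param contractilityScale factor shrinking the source's relative volume
#'   excursion (lower apparent EF).
#' @param foreshortening long-axis scale factor of the source geometry
#'   (apical foreshortening; volume is preserved by radial re-inflation).
#' @param wallScale factor on the source wall volume (lower apparent mass).
#' @param regionalAmplitude amplitude (mm) of the smooth outward offset
#'   field, largest in the basal anterolateral region.
#' @param warpRange range of the temporal-warp amplitude `A` in
#'   `u(phase) = phase + A sin(2 pi phase) / (2 pi)` (sign randomised per
#'   subject; strictly monotone for |A| < 1, endpoints fixed).
#' @param hrDeltaMean,hrDeltaSd per-subject heart-rate change (bpm) between
#'   protocols.
#' @param sourceFrameRange integer range of source acquisition frame counts.
#' @param noiseSd isotropic Gaussian point noise, mm.
#' @param seed bias-stream seed (combined with each subject's seed).
#' @return list of class `bias_model`.
#' @export
biasModel <- function(volumeScale = 0.86, contractilityScale = 0.765,
                      foreshortening = 0.95, wallScale = 0.92,
                      regionalAmplitude = 2, warpRange = c(0.1, 0.25),
                      hrDeltaMean = -1, hrDeltaSd = 6,
                      sourceFrameRange = c(30L, 45L), noiseSd = 0.5,
                      seed = 1L) {
  stopIfNot(volumeScale > 0.5 && volumeScale < 1.5,
            "volumeScale must lie in (0.5, 1.5)")
  stopIfNot(all(abs(warpRange) < 1), "warp amplitudes must satisfy |A| < 1")
  structure(list(volumeScale = volumeScale,
                 contractilityScale = contractilityScale,
                 foreshortening = foreshortening, wallScale = wallScale,
                 regionalAmplitude = regionalAmplitude,
                 warpRange = warpRange, hrDeltaMean = hrDeltaMean,
                 hrDeltaSd = hrDeltaSd,
                 sourceFrameRange = as.integer(sourceFrameRange),
                 noiseSd = noiseSd, seed = as.integer(seed)),
            class = "bias_model")
}

#' @rdname biasModel
#' @export
identityBias <- function(seed = 1L) {
  biasModel(volumeScale = 1, contractilityScale = 1, foreshortening = 1,
            wallScale = 1, regionalAmplitude = 0, warpRange = c(0, 0),
            hrDeltaMean = 0, hrDeltaSd = 0, sourceFrameRange = c(NA, NA),
            noiseSd = 0, seed = seed)
}

#' Derive the biased source-protocol sequence
#'
#' Regenerates the subject's geometry under the bias model: the underlying
#' cycle state is evaluated at the warped phase, the volume trace is scaled
#' globally and its excursion compressed, the long axis is foreshortened
#' (with radial compensation so the prescribed source volume is hit
#' exactly), the wall volume is scaled, a smooth regional outward offset is
#' added, and finally isotropic point noise is applied. The heart rate and
#' frame count change according to the bias model. The injected truth (warp
#' samples, realised bias draws) is stored in `@metadata$truth`.
#'
#' @param seq a target-protocol [LVSequence-class] produced by
#'   [generateSubject()] (carries its generator parameters).
#' @param bias a [biasModel()] list.
#' @param subdivide surface refinement for internal calibration.
#' @return a source-protocol [LVSequence-class].
#' @export
applyModalityBias <- function(seq, bias, subdivide = 4L) {
  params <- seq@metadata$params
  stopIfNot(!is.null(params), "sequence does not carry generator parameters")
  cal <- seq@metadata$calibration
  grid <- seq@grid
  v <- volumeShape(params)
  gmod <- regionalModulation(params, grid)
  subSeed <- (params$seed %% 1000000L) * 1000L + (bias$seed %% 1000L)
  draws <- withSeed(subSeed, {
    A <- stats::runif(1L, bias$warpRange[1L], bias$warpRange[2L]) *
      sample(c(-1, 1), 1L)
    hrD <- stats::rnorm(1L, bias$hrDeltaMean, bias$hrDeltaSd)
    mSrc <- if (anyNA(bias$sourceFrameRange)) params$nFrames
            else sample(bias$sourceFrameRange[1L]:bias$sourceFrameRange[2L], 1L)
    list(A = A, hrD = hrD, mSrc = mSrc)
  })
  if (diff(bias$warpRange) == 0) draws$A <- bias$warpRange[1L]
  warp <- function(phi) phi + draws$A * sin(2 * pi * phi) / (2 * pi)
  hrTarget <- 60 / params$cycleDuration
  cdSrc <- 60 / max(hrTarget + draws$hrD, 30)
  vs <- bias$volumeScale; beta <- bias$contractilityScale
  fs <- bias$foreshortening
  srcVol <- function(phi)           # ml, source cavity volume at phase phi
    params$edvTarget * vs * (1 - beta * (1 - v(warp(phi))))
  th <- params$wallThickness
  wallVolS <- bias$wallScale * cal$wallVol
  nF <- draws$mSrc
  phases <- (seq_len(nF) - 1L) / nF
  np <- nGridPoints(grid)
  endo <- array(0, c(np, 3L, nF))
  epi <- array(0, c(np, 3L, nF))
  # regional outward offset (mm), basal-anterolateral weighted, time-constant
  thAngles <- 2 * pi * (seq_len(grid@nMeridians) - 1L) / grid@nMeridians
  thIns <- -70 * pi / 180
  thAl <- thIns + 210 * pi / 180
  offField <- bias$regionalAmplitude *
    outer((seq_len(grid@nRings) / grid@nRings)^2,
          (1 + cos(thAngles - thAl)) / 2)
  addOffset <- function(P) {
    for (r in seq_len(grid@nRings)) {
      idx <- gridIndex(grid, r, seq_len(grid@nMeridians))
      rho <- sqrt(P[idx, 2L]^2 + P[idx, 3L]^2)
      sc <- ifelse(rho > 0, (rho + offField[r, ]) / rho, 1)
      P[idx, 2L] <- P[idx, 2L] * sc
      P[idx, 3L] <- P[idx, 3L] * sc
    }
    P
  }
  aEpi0S <- fs * (cal$a0 + th)
  xShiftS <- aEpi0S / 3
  for (f in seq_len(nF)) {
    psi <- warp(phases[f])
    s <- v(psi)
    aT <- cal$a0 * s^params$alpha
    aS <- fs * aT
    bS <- sqrt(srcVol(phases[f]) * 1000 / (cal$cEndo * aS))
    aPS <- fs * (aT + th)
    bPS <- sqrt((srcVol(phases[f]) * 1000 + wallVolS) / (cal$cEndo * aPS))
    endo[, , f] <- addOffset(spheroidSurface(aS, bS, grid, gmod, xShiftS))
    epi[, , f] <- addOffset(spheroidSurface(aPS, bPS, grid, gmod, xShiftS))
  }
  if (bias$noiseSd > 0) {
    noise <- withSeed(subSeed + 1L,
                      stats::rnorm(2L * length(endo), 0, bias$noiseSd))
    endo <- endo + array(noise[seq_along(endo)], dim(endo))
    epi <- epi + array(noise[length(endo) + seq_along(epi)], dim(epi))
  }
  bEpi0S <- sqrt((srcVol(0) * 1000 + wallVolS) / (cal$cEndo * aEpi0S))
  lm <- list(apex = c(aEpi0S - xShiftS, 0, 0),
             basalCentroid = c(-xShiftS, 0, 0),
             rvInsertion = c(-xShiftS, bEpi0S * cos(thIns),
                             bEpi0S * sin(thIns)))
  phiDense <- seq(0, 1, length.out = 201L)
  newLVSequence(
    subjectId = seq@subjectId, protocol = "source",
    endo = endo, epi = epi, phases = phases, cycleDuration = cdSrc,
    landmarks = lm, grid = grid,
    metadata = list(
      params = params, bias = bias,
      truth = list(warpAmplitude = draws$A, hrDelta = draws$hrD,
                   sourceFrames = draws$mSrc,
                   warpPhases = phiDense, warpValues = warp(phiDense),
                   sourceEDV = srcVol(0),
                   sourceESV = min(srcVol(phiDense)))))
}

#' Generate a paired synthetic population
#'
#' Draws `nSubjects` subjects from a mixture of a control-like stratum and a
#' disease-like stratum (larger volumes, thicker walls, lower EF), generates
#' each subject's ground-truth target sequence and its biased source
#' counterpart, and returns them with the full truth records. All
#' randomness flows from `seed` through named per-subject sub-seeds, so the
#' same seed reproduces the population exactly.
#'
#' @param nSubjects number of subjects (default 138).
#' @param seed master seed.
#' @param bias a [biasModel()].
#' @param diseaseFraction fraction of subjects in the disease-like stratum
#'   (default 54/138).
#' @param grid a [SurfaceGrid-class].
#' @param pose pose of generated sequences, see [generateSubject()].
#' @return list of class `lv_population` with elements `subjects` (each a
#'   list with `source`, `target`, `params`), `grid`, `bias`, `seed`.
#' @export
generatePopulation <- function(nSubjects = 138L, seed = 1L,
                               bias = biasModel(),
                               diseaseFraction = 54 / 138,
                               grid = lvSurfaceGrid(),
                               pose = "canonical") {
  stopIfNot(nSubjects >= 3L, "population needs at least 3 subjects")
  cfg <- withSeed(seed, {
    subSeeds <- sample.int(2^31 - 2L, nSubjects)
    disease <- stats::runif(nSubjects) < diseaseFraction
    list(subSeeds = subSeeds, disease = disease)
  })
  clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)
  subjects <- vector("list", nSubjects)
  for (i in seq_len(nSubjects)) {
    dz <- cfg$disease[i]
    pr <- withSeed(cfg$subSeeds[i], {
      list(
        edv = clip(stats::rnorm(1L, if (dz) 160 else 141, if (dz) 41 else 33),
                   85, 320),
        ef = clip(stats::rnorm(1L, if (dz) 50 else 62, if (dz) 10 else 5),
                  25, 75),
        thick = clip(stats::rnorm(1L, if (dz) 11 else 8, if (dz) 2 else 1),
                     5, 16),
        aspect = clip(stats::rnorm(1L, 2.4, 0.25), 1.9, 3.0),
        eFrac = clip(stats::rnorm(1L, 0.72, 0.06), 0.5, 0.9),
        esPhase = clip(stats::rnorm(1L, 0.35, 0.02), 0.28, 0.42),
        hr = clip(stats::rnorm(1L, 65, 8), 45, 95),
        nFrames = sample(25:35, 1L))
    })
    params <- subjectParams(
      edvTarget = pr$edv, efTarget = pr$ef, aspectRatio = pr$aspect,
      wallThickness = pr$thick, eFraction = pr$eFrac, esPhase = pr$esPhase,
      cycleDuration = 60 / pr$hr, nFrames = pr$nFrames,
      seed = cfg$subSeeds[i])
    target <- generateSubject(params, grid, pose = pose)
    source <- applyModalityBias(target, bias)
    subjects[[i]] <- list(source = source, target = target, params = params,
                          stratum = if (dz) "disease" else "control")
  }
  structure(list(subjects = subjects, grid = grid, bias = bias, seed = seed),
            class = "lv_population")
}

#' @export
print.lv_population <- function(x, ...) {
  strata <- table(vapply(x$subjects, `[[`, character(1L), "stratum"))
  cat(sprintf("lv_population: %d subjects (%s), seed %d\n",
              length(x$subjects),
              paste(names(strata), strata, sep = " = ", collapse = ", "),
              x$seed))
  invisible(x)
}
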