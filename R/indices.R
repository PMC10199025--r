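# Clinical index derivation: volume and strain traces, EDV/ESV/EF/LVM/GLS,
# and the rate indices PER, PFR_E, PFR_A, PSR.

#' Construct a trace object
#'
#' A trace is a per-frame scalar signal over one cardiac cycle: values,
#' cycle-fraction phases (strictly increasing from 0), the cycle duration in
#' seconds and a unit label. Traces are treated as periodic with period 1
#' when resampled.
#'
#' @param values numeric vector.
#' @param phases cycle fractions, same length, first must be 0.
#' @param cycleDuration seconds.
#' @param units unit label (e.g. `"ml"`, `"%"`).
#' @return object of class `lv_trace`.
#' @export
lvTrace <- function(values, phases, cycleDuration, units = "ml") {
  stopIfNot(length(values) == length(phases), "values/phases length mismatch")
  stopIfNot(phases[1L] == 0 && all(diff(phases) > 0),
            "phases must increase strictly from 0")
  stopIfNot(cycleDuration > 0, "cycleDuration must be positive")
  structure(list(values = as.numeric(values), phases = as.numeric(phases),
                 cycleDuration = cycleDuration, units = units),
            class = "lv_trace")
}

#' @export
print.lv_trace <- function(x, ...) {
  cat(sprintf("lv_trace: %d samples over %.3f s, range [%.2f, %.2f] %s\n",
              length(x$values), x$cycleDuration, min(x$values),
              max(x$values), x$units))
  invisible(x)
}

#' Cavity volume trace of a sequence
#'
#' Per-frame endocardial cavity volume ([cavityVolume()]) in acquisition
#' frame order.
#'
#' @param seq an [LVSequence-class].
#' @param grid a [SurfaceGrid-class] (defaults to the sequence's own).
#' @param subdivide surface refinement factor, see [cavityVolume()].
#' @return an `lv_trace` in ml.
#' @export
volumeTrace <- function(seq, grid = seq@grid, subdivide = 4L) {
  nf <- dim(seq@endo)[3L]
  v <- vapply(seq_len(nf), function(f)
    cavityVolume(seq@endo[, , f], grid, subdivide), numeric(1L))
  lvTrace(v, seq@phases, seq@cycleDuration, units = "ml")
}

#' Global longitudinal strain trace from endocardial arc lengths
#'
#' For each meridian, the longitudinal arc length is the summed segment
#' length along the endocardial points from the apex to the basal ring. The
#' global length L(t) is the mean over meridians, and strain is
#' `100 * (L(t) - L(ED)) / L(ED)` (zero at end-diastole, negative during
#' systole).
#'
#' @inheritParams volumeTrace
#' @return an `lv_trace` in percent.
#' @export
glsTrace <- function(seq, grid = seq@grid) {
  nf <- dim(seq@endo)[3L]
  meanArc <- function(P) {
    tot <- 0
    for (m in seq_len(grid@nMeridians)) {
      idx <- c(apexIndex(grid), gridIndex(grid, seq_len(grid@nRings), m))
      d <- diff(P[idx, , drop = FALSE])
      tot <- tot + sum(sqrt(rowSums(d^2)))
    }
    tot / grid@nMeridians
  }
  L <- vapply(seq_len(nf), function(f) meanArc(seq@endo[, , f]), numeric(1L))
  lvTrace(100 * (L - L[1L]) / L[1L], seq@phases, seq@cycleDuration,
          units = "%")
}

#' Resample a trace to a uniform phase grid
#'
#' Linear interpolation (periodic, period 1) onto `n` uniformly spaced
#' phases spanning the closed cycle `[0, 1]`; the first and last samples
#' both map to end-diastole.
#'
#' @param trace an `lv_trace`.
#' @param n number of samples (>= 2).
#' @return an `lv_trace` with `n` samples at phases `seq(0, 1, length.out = n)`.
#' @export
resampleTrace <- function(trace, n) {
  stopIfNot(n >= 2, "resampling needs at least 2 samples")
  ph <- seq(0, 1, length.out = n)
  v <- interpPeriodic(trace$phases, trace$values, ph)
  out <- trace
  out$values <- v
  out$phases <- ph
  out
}

#' Volume-derived global indices
#'
#' EDV is the cavity volume at end-diastole (phase 0), ESV the minimum over
#' the cycle, EF = 100 (EDV - ESV) / EDV, and LVM is the wall mass at ED
#' supplied by the caller.
#'
#' @param vt volume `lv_trace` (ml).
#' @param massAtED wall mass at ED in g (optional, `NA` if not computed).
#' @return list with `EDV`, `ESV`, `EF`, `LVM`.
#' @export
globalIndices <- function(vt, massAtED = NA_real_) {
  edv <- vt$values[1L]
  if (!(edv > 0)) stop("non-positive end-diastolic volume", call. = FALSE)
  esv <- min(vt$values)
  list(EDV = edv, ESV = esv, EF = 100 * (edv - esv) / edv, LVM = massAtED)
}

#' Rate indices from volume and strain traces
#'
#' Both traces are resampled to `nSamples` uniform phases and differentiated
#' by central differences (periodic, scaled to absolute time through the
#' cycle duration). Systole spans end-diastole to the global volume minimum;
#' diastole is the remainder of the cycle. Reported indices:
#' peak ejection rate `PER` = signed minimum of dV/dt during systole (ml/s);
#' `PFR_E` and `PFR_A` = the earlier and later of the two most prominent
#' local maxima of dV/dt during diastole (ml/s; `PFR_A` is `NA` for
#' monophasic filling); peak systolic strain rate `PSR` = signed minimum of
#' d(strain)/dt / 100 during systole (1/s).
#'
#' @param vt volume `lv_trace` (ml).
#' @param st strain `lv_trace` in percent (optional; `PSR` is `NA` without it).
#' @param nSamples uniform samples used for differentiation (default 30,
#'   matching the mapping pipeline's temporal grid).
#' Discrete extrema are refined by the vertex of the parabola through the
#' extremal sample and its two cyclic neighbours, which removes the
#' first-order error made when the true peak falls between samples.
#'
#' @return list with `PER`, `PFR_E`, `PFR_A`, `PSR`.
#' @export
rateIndices <- function(vt, st = NULL, nSamples = 30L) {
  stopIfNot(length(vt$values) >= 5L, "rate indices need at least 5 frames")
  n <- as.integer(nSamples)
  rv <- resampleTrace(vt, n)
  # samples 1..n span the closed cycle; sample n duplicates sample 1
  u <- rv$values[seq_len(n - 1L)]
  dt <- vt$cycleDuration / (n - 1L)
  m <- length(u)
  dV <- (u[c(2:m, 1L)] - u[c(m, 1:(m - 1L))]) / (2 * dt)
  # parabolic refinement of a discrete extremum at cyclic index i
  refine <- function(x, i) {
    y1 <- x[(i - 2L) %% m + 1L]; y2 <- x[i]; y3 <- x[i %% m + 1L]
    den <- y1 - 2 * y2 + y3
    if (abs(den) < 1e-12) return(y2)
    y2 - (y1 - y3)^2 / (8 * den)
  }
  esIdx <- which.min(rv$values[seq_len(m)])
  sys <- seq_len(esIdx)
  dia <- if (esIdx < m) (esIdx + 1L):m else integer()
  per <- if (length(sys)) {
    iMin <- sys[which.min(dV[sys])]
    min(refine(dV, iMin), dV[iMin])
  } else 0
  pfrE <- 0; pfrA <- NA_real_
  if (length(dia) >= 3L) {
    pk <- localMaximaProminence(dV, candidates = dia)
    pk <- pk[pk$value > 0, , drop = FALSE]
    if (nrow(pk) >= 2L) {
      pk <- pk[order(-pk$prominence, pk$index), , drop = FALSE]
      two <- pk[1:2, ]
      two <- two[order(two$index), ]
      pfrE <- max(refine(dV, two$index[1L]), two$value[1L])
      pfrA <- max(refine(dV, two$index[2L]), two$value[2L])
    } else if (nrow(pk) == 1L) {
      pfrE <- max(refine(dV, pk$index[1L]), pk$value[1L])
    } else {
      pfrE <- max(c(dV[dia], 0))
    }
  }
  psr <- NA_real_
  if (!is.null(st)) {
    rs <- resampleTrace(st, n)
    us <- rs$values[seq_len(m)]
    dS <- (us[c(2:m, 1L)] - us[c(m, 1:(m - 1L))]) / (2 * dt)
    iMin <- sys[which.min(dS[sys])]
    psr <- min(refine(dS, iMin), dS[iMin]) / 100
  }
  list(PER = per, PFR_E = pfrE, PFR_A = pfrA, PSR = psr)
}

#' Peak systolic global longitudinal strain
#'
#' Signed minimum of the strain trace over systole (end-diastole to the
#' volume minimum identified on the paired volume trace).
#'
#' @param st strain `lv_trace` (percent).
#' @param vt volume `lv_trace` used to delimit systole.
#' @return GLS in percent (negative for normal contraction).
#' @export
peakGls <- function(st, vt) {
  # dense resampling localises the end-systolic phase well below the frame
  # spacing, so the systolic window never clips the strain trough
  rv <- resampleTrace(vt, 300L)
  esPhase <- rv$phases[which.min(rv$values)]
  sys <- st$phases <= esPhase + 1e-12
  min(st$values[sys])
}

#' Full clinical index set for one sequence
#'
#' Convenience wrapper deriving every index the pipeline evaluates from one
#' sequence: EDV, ESV, EF, LVM (wall mass at ED), peak systolic GLS, and the
#' rate indices PER, PFR_E, PFR_A, PSR.
#'
#' @param seq an [LVSequence-class].
#' @param grid a [SurfaceGrid-class].
#' @param density myocardial density, g/ml.
#' @param nSamples uniform samples for rate differentiation.
#' @param subdivide surface refinement factor.
#' @return one-row `data.frame` with columns `EDV, ESV, LVM, EF, GLS, PER,
#'   PFR_E, PFR_A, PSR`.
#' @export
computeIndices <- function(seq, grid = seq@grid, density = 1.05,
                           nSamples = 30L, subdivide = 4L) {
  vt <- volumeTrace(seq, grid, subdivide)
  st <- glsTrace(seq, grid)
  lvm <- wallMass(seq@endo[, , 1L], seq@epi[, , 1L], grid, density, subdivide)
  gi <- globalIndices(vt, lvm)
  ri <- rateIndices(vt, st, nSamples)
  data.frame(EDV = gi$EDV, ESV = gi$ESV, LVM = gi$LVM, EF = gi$EF,
             GLS = peakGls(st, vt), PER = ri$PER, PFR_E = ri$PFR_E,
             PFR_A = ri$PFR_A, PSR = ri$PSR)
}
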