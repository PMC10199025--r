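# Temporal alignment: uniform resampling, amplitude normalisation, and
# penalty-modified dynamic time warping between the two protocols' volume
# traces. Index conventions in this file are 1-based, mirroring the
# mathematical formulation; on-disk formats use their own documented base.

#' Resample a sequence to uniformly spaced phases
#'
#' Linear interpolation in phase applied coordinate-wise to every surface
#' point (periodic with period 1, so phase 1 wraps to the end-diastolic
#' geometry). The output phase grid is `seq(0, 1, length.out = n)`.
#'
#' @param seq an [LVSequence-class].
#' @param n number of output frames (>= 2; default 30).
#' @return an [LVSequence-class] with `n` frames.
#' @export
resampleSequence <- function(seq, n = 30L) {
  stopIfNot(n >= 2, "resampling needs at least 2 frames")
  ph <- seq(0, 1, length.out = n)
  evaluateSequenceAtPhases(seq, ph)
}

# evaluate sequence geometry at arbitrary phases (periodic linear interp)
evaluateSequenceAtPhases <- function(seq, phases) {
  np <- dim(seq@endo)[1L]
  nf <- length(phases)
  flat <- function(A) t(matrix(A, np * 3L, dim(A)[3L]))   # frames x (np*3)
  endoF <- interpPeriodic(seq@phases, flat(seq@endo), phases)
  epiF <- interpPeriodic(seq@phases, flat(seq@epi), phases)
  unflat <- function(M) array(t(M), c(np, 3L, nf))
  out <- seq
  out@endo <- unflat(endoF)
  out@epi <- unflat(epiF)
  # stored phases are the uniform template grid; callers needing the true
  # warped phases keep them alongside (see alignPair)
  out@phases <- seq(0, 1, length.out = nf)
  out
}

#' Normalise a signal to the unit interval
#'
#' `(v - min) / (max - min)`; the minimum maps to 0 and the maximum to 1.
#'
#' @param values numeric vector, non-constant.
#' @return normalised numeric vector.
#' @export
normalizeAmplitude <- function(values) {
  r <- range(values)
  if (r[2L] - r[1L] <= 0)
    stop("cannot normalise a constant signal", call. = FALSE)
  (values - r[1L]) / (r[2L] - r[1L])
}

#' Time-expansion penalty for the warping cost
#'
#' The penalty `p` equals the maximum absolute difference between the two
#' normalised signals at any given time step. With unequal lengths the
#' comparison is made on the template's `n` uniform phases, with the
#' secondary signal linearly interpolated onto those phases.
#'
#' @param tvals template signal (normalised, uniform over `[0, 1]`).
#' @param svals secondary signal (normalised, uniform over `[0, 1]`).
#' @return scalar penalty `p >= 0`.
#' @export
penaltyValue <- function(tvals, svals) {
  n <- length(tvals); m <- length(svals)
  phT <- seq(0, 1, length.out = n)
  phS <- seq(0, 1, length.out = m)
  sAtT <- stats::approx(phS, svals, xout = phT)$y
  max(abs(tvals - sAtT))
}

#' Discrepancy and cumulative cost matrices for penalty-modified DTW
#'
#' The discrepancy matrix is `d(i, j) = (t_i - s_j)^2`. The cumulative cost
#' follows the dynamic-programming recursion
#' `gamma(i, j) = d(i, j) + min(gamma(i-1, j), gamma(i-1, j-1),
#' gamma(i, j-1) + p)`, with boundary cells using only their admissible
#' predecessors. Two penalty placements are supported: `"equation"` adds `p`
#' to the `(i, j-1)` predecessor as above, while `"text"` adds it to the
#' `(i-1, j)` predecessor (penalising a step forward in `i` but not `j`).
#'
#' @param tvals,svals normalised template (length n) and secondary
#'   (length m) signals.
#' @param p penalty, see [penaltyValue()].
#' @param variant `"equation"` (default) or `"text"`.
#' @return object of class `dtw_cost`: list with `d` (n x m), `gamma`
#'   (n x m), `p`, `variant`.
#' @export
dtwCost <- function(tvals, svals, p, variant = c("equation", "text")) {
  variant <- match.arg(variant)
  n <- length(tvals); m <- length(svals)
  d <- outer(tvals, svals, function(a, b) (a - b)^2)
  g <- matrix(NA_real_, n, m)
  pUp <- if (variant == "text") p else 0      # predecessor (i-1, j)
  pLeft <- if (variant == "equation") p else 0  # predecessor (i, j-1)
  g[1L, 1L] <- d[1L, 1L]
  if (m > 1L) for (j in 2:m) g[1L, j] <- d[1L, j] + g[1L, j - 1L] + pLeft
  if (n > 1L) for (i in 2:n) {
    g[i, 1L] <- d[i, 1L] + g[i - 1L, 1L] + pUp
    if (m > 1L) for (j in 2:m) {
      g[i, j] <- d[i, j] + min(g[i - 1L, j] + pUp,
                               g[i - 1L, j - 1L],
                               g[i, j - 1L] + pLeft)
    }
  }
  structure(list(d = d, gamma = g, p = p, variant = variant),
            class = "dtw_cost")
}

#' Optimal warping path by backtracking
#'
#' Backtracks from `(n, m)` to `(1, 1)` choosing at each cell the
#' predecessor of minimum accumulated cost under the same penalty
#' accounting as [dtwCost()]. Ties are broken deterministically: diagonal
#' `(i-1, j-1)` first, then `(i-1, j)`, then `(i, j-1)`.
#'
#' @param cm a `dtw_cost` object.
#' @return integer matrix (o x 2) of `(i, j)` pairs from `(1, 1)` to
#'   `(n, m)`; steps are in `{(1,0), (0,1), (1,1)}`.
#' @export
optimalPath <- function(cm) {
  g <- cm$gamma
  n <- nrow(g); m <- ncol(g)
  pUp <- if (cm$variant == "text") cm$p else 0
  pLeft <- if (cm$variant == "equation") cm$p else 0
  path <- matrix(NA_integer_, n + m, 2L)
  k <- 1L
  i <- n; j <- m
  path[k, ] <- c(i, j)
  while (i > 1L || j > 1L) {
    if (i == 1L) { j <- j - 1L }
    else if (j == 1L) { i <- i - 1L }
    else {
      cand <- c(diag = g[i - 1L, j - 1L],
                up = g[i - 1L, j] + pUp,
                left = g[i, j - 1L] + pLeft)
      pick <- which.min(cand)   # ties resolve to the first (diagonal)
      if (pick == 1L) { i <- i - 1L; j <- j - 1L }
      else if (pick == 2L) { i <- i - 1L }
      else { j <- j - 1L }
    }
    k <- k + 1L
    path[k, ] <- c(i, j)
  }
  path <- path[k:1, , drop = FALSE]
  colnames(path) <- c("i", "j")
  path
}

#' Forward cost of a warping path
#'
#' Recomputes the accumulated cost of an explicit path: the sum of
#' discrepancies along the path plus `p` for every penalised step
#' (`(0, 1)` steps under the `"equation"` placement, `(1, 0)` steps under
#' `"text"`).
#'
#' @param path integer matrix (o x 2) of `(i, j)` pairs.
#' @param d discrepancy matrix.
#' @param p penalty.
#' @param variant penalty placement, see [dtwCost()].
#' @return scalar cost.
#' @export
dtwPathCost <- function(path, d, p, variant = c("equation", "text")) {
  variant <- match.arg(variant)
  cost <- sum(d[path])
  if (nrow(path) > 1L) {
    steps <- diff(path)
    nPen <- if (variant == "equation")
      sum(steps[, 1L] == 0L & steps[, 2L] == 1L)
    else
      sum(steps[, 1L] == 1L & steps[, 2L] == 0L)
    cost <- cost + p * nPen
  }
  cost
}

#' Warped fractional indices from a warping path
#'
#' For each template index `i`, the warped index is the mean of all
#' secondary indices `j` paired with `i` on the path, yielding a one-to-one
#' (fractional) mapping of length `n`.
#'
#' @param path integer matrix (o x 2) of `(i, j)` pairs.
#' @param n template length.
#' @return numeric vector of length `n`, weakly non-decreasing, in `[1, m]`.
#' @export
warpedIndices <- function(path, n) {
  out <- as.numeric(tapply(path[, 2L], factor(path[, 1L], levels = seq_len(n)),
                           mean))
  stopIfNot(!anyNA(out), "path does not cover every template index")
  out
}

#' Temporally align a source/target sequence pair
#'
#' Implements the per-subject temporal-alignment stage: both volume traces
#' are uniformly resampled (template length `n` for the source, `m = 2n` by
#' default for the secondary/target), normalised to `[0, 1]`, and aligned by
#' penalty-modified DTW. The source geometry is resampled to the `n` uniform
#' template phases and the target geometry is evaluated, by linear
#' interpolation of its `m`-frame resampling, at the warped fractional
#' indices, giving `n` corresponding frames. No between-subject alignment is
#' performed.
#'
#' @param source,target [LVSequence-class] objects for the same subject.
#' @param n template sample count (default 30).
#' @param m secondary sample count (default 60).
#' @param variant penalty placement, see [dtwCost()].
#' @param subdivide surface refinement for the volume traces.
#' @return an [AlignedPair-class].
#' @export
alignPair <- function(source, target, n = 30L, m = 60L,
                      variant = c("equation", "text"), subdivide = 4L) {
  variant <- match.arg(variant)
  stopIfNot(m >= n, "secondary sample count m must be >= n")
  vtS <- resampleTrace(volumeTrace(source, subdivide = subdivide), n)
  vtT <- resampleTrace(volumeTrace(target, subdivide = subdivide), m)
  tn <- normalizeAmplitude(vtS$values)
  sn <- normalizeAmplitude(vtT$values)
  p <- penaltyValue(tn, sn)
  cm <- dtwCost(tn, sn, p, variant)
  path <- optimalPath(cm)
  jprime <- warpedIndices(path, n)
  warpedPhases <- (jprime - 1) / (m - 1)
  srcU <- resampleSequence(source, n)
  tgtM <- resampleSequence(target, m)
  tgtW <- evaluateSequenceAtPhases(tgtM, warpedPhases)
  tgtW@phases <- srcU@phases
  # discrepancy of naive uniform pairing vs the warped pairing (normalised
  # amplitudes, template grid)
  phT <- seq(0, 1, length.out = n)
  sAtT <- stats::approx(seq(0, 1, length.out = m), sn, xout = phT)$y
  sAtW <- stats::approx(seq_len(m), sn, xout = jprime)$y
  new("AlignedPair", source = srcU, target = tgtW,
      path = path, warpedIndices = jprime, penalty = p, variant = variant,
      finalCost = cm$gamma[n, m],
      preDiscrepancy = sum((tn - sAtT)^2),
      postDiscrepancy = sum((tn - sAtW)^2))
}
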