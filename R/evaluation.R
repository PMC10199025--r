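# Agreement and similarity metrics: geometry RMSE (global and per AHA
# segment), Bland-Altman, paired t-tests, ICC(A,1), and the cumulative DTW
# distance between traces.

#' Root mean squared error between two sequences
#'
#' Pooled RMSE of corresponding surface points: each point contributes its
#' squared Euclidean distance, pooled over both surfaces and all frames
#' (`scope = "global"`) or restricted to the points of each AHA segment
#' (`scope = "segments"`, which needs `labels`). When segment labels are in
#' play the endocardial apex carries no label; set `excludeEndoApex = TRUE`
#' to drop it from the global pool as well, which makes the global value the
#' exact point-count-weighted pooling of the per-segment values.
#'
#' @param a,b [LVSequence-class] objects sharing frame count and grid.
#' @param scope `"global"` or `"segments"`.
#' @param labels segment labels from [assignAhaSegments()] (required for
#'   `scope = "segments"`).
#' @param frames frame indices to pool over (default: all).
#' @param excludeEndoApex drop the unlabelled endocardial apex point from
#'   the global pool.
#' @return `scope = "global"`: scalar RMSE in mm. `scope = "segments"`:
#'   `data.frame` with `surface`, `segment`, `nPoints`, `rmse`.
#' @export
geometryRmse <- function(a, b, scope = c("global", "segments"),
                         labels = NULL, frames = NULL,
                         excludeEndoApex = FALSE) {
  scope <- match.arg(scope)
  stopIfNot(identical(dim(a@endo), dim(b@endo)) &&
              identical(dim(a@epi), dim(b@epi)),
            "sequences must share point and frame dimensions")
  frames <- frames %||% seq_len(dim(a@endo)[3L])
  sqd <- function(A, B) {
    d2 <- (A[, , frames, drop = FALSE] - B[, , frames, drop = FALSE])^2
    apply(d2, c(1L, 3L), sum)    # points x frames squared distances
  }
  endoD <- sqd(a@endo, b@endo)
  epiD <- sqd(a@epi, b@epi)
  if (scope == "global") {
    if (excludeEndoApex) endoD <- endoD[-1L, , drop = FALSE]
    return(sqrt(mean(c(endoD, epiD))))
  }
  stopIfNot(!is.null(labels), "segment scope needs AHA labels")
  rows <- list()
  for (surf in c("endo", "epi")) {
    lab <- labels[[surf]]
    D <- if (surf == "endo") endoD else epiD
    for (s in sort(unique(lab[!is.na(lab)]))) {
      idx <- which(lab == s)
      rows[[length(rows) + 1L]] <- data.frame(
        surface = surf, segment = s, nPoints = length(idx),
        rmse = sqrt(mean(D[idx, , drop = FALSE])))
    }
  }
  do.call(rbind, rows)
}

#' Per-segment RMSE report at end-diastole and end-systole
#'
#' Convenience wrapper producing the regional agreement table: RMSE per AHA
#' segment (16 endocardial, 17 epicardial) at the aligned ED frame (frame 1)
#' and at end-systole, identified as the minimum-volume frame of the
#' reference sequence `b`.
#'
#' @param a,b aligned [LVSequence-class] objects (`b` is the reference used
#'   to locate ES).
#' @param labels output of [assignAhaSegments()].
#' @param grid a [SurfaceGrid-class].
#' @param subdivide surface refinement for the ES search.
#' @return `data.frame` with `surface`, `segment`, `phase` (ED/ES), `rmse`.
#' @export
segmentRmseReport <- function(a, b, labels, grid = b@grid, subdivide = 4L) {
  vt <- volumeTrace(b, grid, subdivide)
  esFrame <- which.min(vt$values)
  out <- list()
  for (ph in c(ED = 1L, ES = esFrame)) {
    r <- geometryRmse(a, b, scope = "segments", labels = labels, frames = ph)
    r$phase <- names(which(c(ED = 1L, ES = esFrame) == ph))[1L]
    out[[length(out) + 1L]] <- r
  }
  res <- do.call(rbind, out)
  res$phase <- rep(c("ED", "ES"), each = nrow(res) / 2L)
  res[, c("surface", "segment", "phase", "nPoints", "rmse")]
}

#' Bland-Altman agreement analysis
#'
#' Differences are `y - x`; reports their mean (bias), sample standard
#' deviation, and the 95% limits of agreement `bias +/- 1.96 sd`, together
#' with the per-pair means for plotting. To follow the source-minus-target
#' reporting convention, pass the target (reference) measurements as `x`
#' and the source measurements as `y`.
#'
#' @param x,y paired numeric vectors of equal length >= 2.
#' @return list with `bias`, `sd`, `loa` (length-2 vector), `means`,
#'   `differences`, `n`.
#' @export
blandAltman <- function(x, y) {
  stopIfNot(length(x) == length(y), "x and y must have equal length")
  stopIfNot(length(x) >= 2L, "need at least 2 pairs")
  d <- y - x
  bias <- mean(d); s <- stats::sd(d)
  list(bias = bias, sd = s, loa = c(bias - 1.96 * s, bias + 1.96 * s),
       means = (x + y) / 2, differences = d, n = length(x))
}

#' Intraclass correlation for absolute agreement, ICC(A,1)
#'
#' Single-measurement ICC from the two-way model with absolute agreement
#' (the same quantity under the mixed- and random-effects formulations):
#' `(MSR - MSE) / (MSR + (k-1) MSE + (k/n)(MSC - MSE))` with `k = 2` raters,
#' where MSR, MSC and MSE are the subject, rater and error mean squares of
#' the two-way ANOVA.
#'
#' @param x,y paired measurements from the two raters/methods (n >= 3).
#' @return scalar ICC in `[-1, 1]`.
#' @export
iccAbsoluteAgreement <- function(x, y) {
  stopIfNot(length(x) == length(y), "x and y must have equal length")
  n <- length(x)
  stopIfNot(n >= 3L, "ICC needs at least 3 paired measurements")
  k <- 2
  M <- cbind(x, y)
  gm <- mean(M)
  if (sum((M - gm)^2) <= 0) stop("zero total variance", call. = FALSE)
  rowM <- rowMeans(M); colM <- colMeans(M)
  ssr <- k * sum((rowM - gm)^2)
  ssc <- n * sum((colM - gm)^2)
  sst <- sum((M - gm)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

#' Paired-sample t-test
#'
#' Two-tailed paired t-test on the differences `x - y` (delegating to
#' [stats::t.test()]). Zero-variance differences are handled explicitly: a
#' nonzero constant difference is reported as infinite `t` with `p = 0`; an
#' identically zero difference has no defined statistic (`t = NA`).
#'
#' @param x,y paired numeric vectors (n >= 2).
#' @return list with `t`, `p`, `df`, `meanDiff`, `n`.
#' @export
pairedTTest <- function(x, y) {
  stopIfNot(length(x) == length(y), "x and y must have equal length")
  n <- length(x)
  stopIfNot(n >= 2L, "need at least 2 pairs")
  d <- x - y
  # treat numerically constant differences explicitly (t.test rejects them)
  if (stats::sd(d) <= 1e-10 * max(abs(mean(d)), .Machine$double.eps)) {
    if (mean(d) == 0)
      return(list(t = NA_real_, p = NA_real_, df = n - 1, meanDiff = 0, n = n))
    return(list(t = sign(mean(d)) * Inf, p = 0, df = n - 1,
                meanDiff = mean(d), n = n))
  }
  tt <- stats::t.test(x, y, paired = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value, df = unname(tt$parameter),
       meanDiff = unname(tt$estimate), n = n)
}

#' Cumulative DTW distance between two traces
#'
#' Similarity of two cyclic traces, quantified as the accumulated cost of
#' the optimal warping path between their 30-sample uniform resamplings.
#' By default the raw (un-normalised) amplitudes are compared with the
#' squared discrepancy and the same penalty scheme as the alignment stage
#' (`p` = maximum per-sample absolute difference); flags expose amplitude
#' normalisation and an absolute-difference accumulation instead.
#'
#' @param a,b `lv_trace` objects in the same units.
#' @param n uniform sample count (default 30).
#' @param variant penalty placement, see [dtwCost()].
#' @param usePenalty apply the time-expansion penalty (default TRUE).
#' @param discrepancy `"squared"` (default) or `"absolute"` per-cell cost.
#' @param normalize normalise both traces to `[0, 1]` first.
#' @return scalar accumulated distance (units^2 for `"squared"`, trace units
#'   for `"absolute"`).
#' @export
cumulativeDtwDistance <- function(a, b, n = 30L,
                                  variant = c("equation", "text"),
                                  usePenalty = TRUE,
                                  discrepancy = c("squared", "absolute"),
                                  normalize = FALSE) {
  variant <- match.arg(variant)
  discrepancy <- match.arg(discrepancy)
  av <- resampleTrace(a, n)$values
  bv <- resampleTrace(b, n)$values
  if (normalize) { av <- normalizeAmplitude(av); bv <- normalizeAmplitude(bv) }
  p <- if (usePenalty) max(abs(av - bv)) else 0
  cm <- dtwCost(av, bv, p, variant)
  if (discrepancy == "absolute") {
    cm2 <- cm
    cm2$d <- abs(outer(av, bv, "-"))
    # rebuild the cumulative matrix with the absolute discrepancy
    g <- matrix(NA_real_, n, n)
    pUp <- if (variant == "text") p else 0
    pLeft <- if (variant == "equation") p else 0
    g[1L, 1L] <- cm2$d[1L, 1L]
    for (j in 2:n) g[1L, j] <- cm2$d[1L, j] + g[1L, j - 1L] + pLeft
    for (i in 2:n) {
      g[i, 1L] <- cm2$d[i, 1L] + g[i - 1L, 1L] + pUp
      for (j in 2:n)
        g[i, j] <- cm2$d[i, j] + min(g[i - 1L, j] + pUp, g[i - 1L, j - 1L],
                                     g[i, j - 1L] + pLeft)
    }
    return(g[n, n])
  }
  cm$gamma[n, n]
}
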