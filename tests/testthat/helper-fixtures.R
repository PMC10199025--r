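# Shared fixtures and independent oracles, all built in code.

# Analytic sampling of a half prolate spheroid (long semi-axis a along +x,
# apex at x = a, flat base plane at x = 0) onto the canonical grid
# parameterisation: ring r at polar angle (r / nRings) * pi/2 from the apex.
halfSpheroidPoints <- function(a, b, grid = lvSurfaceGrid()) {
  nM <- grid@nMeridians; nR <- grid@nRings
  th <- 2 * pi * (seq_len(nM) - 1L) / nM
  P <- matrix(0, nGridPoints(grid), 3L)
  P[1L, ] <- c(a, 0, 0)
  for (r in seq_len(nR)) {
    psi <- (r / nR) * pi / 2
    idx <- gridIndex(grid, r, seq_len(nM))
    P[idx, 1L] <- a * cos(psi)
    P[idx, 2L] <- b * sin(psi) * cos(th)
    P[idx, 3L] <- b * sin(psi) * sin(th)
  }
  P
}

halfSpheroidVolumeMl <- function(a, b) (2 / 3) * pi * a * b^2 / 1000

# static two-frame sequence from fixed surfaces (canonical pose landmarks)
staticSequence <- function(endo, epi, grid = lvSurfaceGrid(),
                           cycleDuration = 1) {
  nM <- grid@nMeridians
  baseIdx <- gridIndex(grid, grid@nRings, seq_len(nM))
  bc <- colMeans(epi[baseIdx, , drop = FALSE])
  apx <- epi[apexIndex(grid), ]
  R <- sqrt(max(rowSums(epi[baseIdx, 2:3, drop = FALSE]^2)))
  lm <- list(apex = apx, basalCentroid = bc,
             rvInsertion = bc + c(0, R * cos(-70 * pi / 180),
                                  R * sin(-70 * pi / 180)))
  newLVSequence("fixture", "target",
                array(rep(endo, 2L), c(nrow(endo), 3L, 2L)),
                array(rep(epi, 2L), c(nrow(epi), 3L, 2L)),
                phases = c(0, 0.5), cycleDuration = cycleDuration,
                landmarks = lm, grid = grid)
}

randomRotation <- function() {
  ax <- stats::rnorm(3L); ax <- ax / sqrt(sum(ax^2))
  ang <- stats::runif(1L, 0, 2 * pi)
  K <- matrix(c(0, -ax[3L], ax[2L], ax[3L], 0, -ax[1L], -ax[2L], ax[1L], 0),
              3L, 3L, byrow = TRUE)
  diag(3L) + sin(ang) * K + (1 - cos(ang)) * K %*% K
}

rigidlyMove <- function(seq, R, tr) {
  out <- seq
  for (f in seq_len(dim(seq@endo)[3L])) {
    out@endo[, , f] <- seq@endo[, , f] %*% t(R) +
      matrix(tr, nrow(seq@endo), 3L, byrow = TRUE)
    out@epi[, , f] <- seq@epi[, , f] %*% t(R) +
      matrix(tr, nrow(seq@epi), 3L, byrow = TRUE)
  }
  out@landmarks <- lapply(seq@landmarks, function(p)
    if (is.null(p)) NULL else drop(R %*% p) + tr)
  out
}

# ---- DTW oracles ----------------------------------------------------------

# exhaustive enumeration of every monotonic continuous warping path from
# (1, 1) to (n, m) with steps {(1,0), (0,1), (1,1)}; returns the minimal
# accumulated cost under the given penalty accounting
enumerateMinDtwCost <- function(d, p, variant) {
  n <- nrow(d); m <- ncol(d)
  best <- Inf
  recur <- function(i, j, cost) {
    if (cost >= best) return(invisible())
    if (i == n && j == m) { best <<- cost; return(invisible()) }
    if (i < n && j < m) recur(i + 1L, j + 1L, cost + d[i + 1L, j + 1L])
    if (i < n) recur(i + 1L, j,
                     cost + d[i + 1L, j] + if (variant == "text") p else 0)
    if (j < m) recur(i, j + 1L,
                     cost + d[i, j + 1L] + if (variant == "equation") p else 0)
  }
  recur(1L, 1L, d[1L, 1L])
  best
}

# naive double-loop RMSE oracle over two sequences
naiveRmse <- function(a, b) {
  tot <- 0; cnt <- 0L
  for (f in seq_len(dim(a@endo)[3L])) {
    for (surf in c("endo", "epi")) {
      A <- slot(a, surf)[, , f]; B <- slot(b, surf)[, , f]
      for (i in seq_len(nrow(A))) {
        tot <- tot + sum((A[i, ] - B[i, ])^2)
        cnt <- cnt + 1L
      }
    }
  }
  sqrt(tot / cnt)
}

# ICC(A,1) oracle via the fitted two-way ANOVA (stats::aov mean squares)
iccOracleAov <- function(x, y) {
  n <- length(x)
  df <- data.frame(value = c(x, y),
                   subject = factor(rep(seq_len(n), 2L)),
                   rater = factor(rep(1:2, each = n)))
  ms <- summary(stats::aov(value ~ subject + rater, data = df))[[1L]][["Mean Sq"]]
  msr <- ms[1L]; msc <- ms[2L]; mse <- ms[3L]
  k <- 2
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

# small synthetic population shortcut (fast subjects: fewer frames)
tinyPopulation <- function(n, seed = 1, bias = biasModel(), ...) {
  generatePopulation(nSubjects = n, seed = seed, bias = bias, ...)
}
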