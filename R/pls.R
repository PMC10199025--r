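# Partial least squares (NIPALS, PLS2) mapping between flattened
# spatiotemporal geometry matrices, with cross-validated component selection
# and a leave-one-out evaluation driver.

#' Column-wise standardization
#'
#' Mean-centres and z-normalises every column (sample standard deviation).
#' Constant columns are masked: their standardized values are 0 and the mask
#' is recorded so the inverse transform restores them exactly.
#'
#' @param X numeric matrix with at least 2 rows.
#' @return list with `X` (standardized matrix), `center`, `scale`
#'   (per-column), and `constMask` (logical).
#' @export
standardizeColumns <- function(X) {
  stopIfNot(nrow(X) >= 2L, "standardization needs at least 2 rows")
  center <- colMeans(X)
  Xc <- sweep(X, 2L, center)
  s <- sqrt(colSums(Xc^2) / (nrow(X) - 1L))
  constMask <- s <= 0
  s[constMask] <- 1
  list(X = sweep(Xc, 2L, s, "/"), center = center, scale = s,
       constMask = constMask)
}

# inverse of standardizeColumns
destandardizeColumns <- function(Xs, center, scale) {
  sweep(sweep(Xs, 2L, scale, "*"), 2L, center, "+")
}

#' Fit a NIPALS PLS2 regression
#'
#' Standardizes `X` and `Y` column-wise and extracts `nComponents` latent
#' components with the nonlinear iterative partial least squares algorithm
#' (PLS2, multi-target, with X- and Y-deflation in regression mode). A
#' component converges when the X-weight vector changes by less than `tol`
#' between iterations; non-convergence raises an error naming the component.
#' Successive X-score vectors are mutually orthogonal by construction.
#'
#' @param X source matrix (subjects x features).
#' @param Y target matrix, same row count and row order.
#' @param nComponents number of latent components (>= 1, at most
#'   `min(nrow(X) - 1, ncol(X))`).
#' @param tol convergence tolerance on the change of the normalised score
#'   vector between iterations (default 1e-10).
#' @param maxIter maximum NIPALS iterations per component (default 5000;
#'   late components on noise-dominated residuals converge slowly because
#'   the residual spectrum is nearly degenerate, and each iteration only
#'   involves n x n products).
#' @param foldSeed seed recorded in the model when components were chosen by
#'   cross-validation (bookkeeping only).
#' @return a [PLSModel-class].
#' @export
fitPls <- function(X, Y, nComponents, tol = 1e-10, maxIter = 5000L,
                   foldSeed = NA_real_) {
  stopIfNot(nrow(X) == nrow(Y), "X and Y must have the same number of rows")
  k <- as.integer(nComponents)
  stopIfNot(k >= 1L, "nComponents must be >= 1")
  stopIfNot(k <= min(nrow(X) - 1L, ncol(X)),
            "nComponents exceeds min(N - 1, ncol(X))")
  sx <- standardizeColumns(X)
  sy <- standardizeColumns(Y)
  Xs <- sx$X; Ys <- sy$X
  n <- nrow(X)
  W <- matrix(0, ncol(X), k); P <- matrix(0, ncol(X), k)
  Q <- matrix(0, ncol(Y), k)
  Tm <- matrix(0, n, k); Um <- matrix(0, n, k)
  beta <- numeric(k); iters <- integer(k)
  # The power iteration for each component is run through the n x n Gram
  # matrices of the deflated data (t = Xd Xd' u / |Xd' u| and the u-update
  # likewise only involve Xd Xd' and Yd Yd'), which is algebraically
  # identical to iterating the p-dimensional weight vector but avoids
  # repeated passes over the wide matrices. The deflated matrices are never
  # formed: the Grams are deflated incrementally, the residual column sums
  # of squares are updated in closed form, and loadings are recovered from
  # the original matrices through the orthogonality of successive scores
  # (p_a = X' t_a / t_a't_a because t_b't_a = 0 for b < a).
  Gx <- tcrossprod(Xs)
  Gy <- tcrossprod(Ys)
  csY <- colSums(Ys^2)
  csY0 <- max(csY, 1)
  trX0 <- max(sum(diag(Gx)), 1)
  kUsed <- 0L
  for (a in seq_len(k)) {
    # stop extracting when the residual X or Y variance is numerically
    # exhausted (degenerate, low-rank input)
    if (max(csY) <= csY0 * 1e-12) break
    if (sum(diag(Gx)) <= trX0 * 1e-12) break
    jmax <- which.max(csY)
    u <- Ys[, jmax]
    if (a > 1L) {
      prev <- seq_len(a - 1L)
      u <- u - drop(Tm[, prev, drop = FALSE] %*% Q[jmax, prev])
    }
    tOld <- rep(0, n)
    converged <- FALSE
    for (it in seq_len(maxIter)) {
      gu <- drop(Gx %*% u)
      nw2 <- sum(u * gu)                 # |Xd' u|^2
      if (nw2 <= .Machine$double.eps)
        stop(sprintf("component %d collapsed (zero X weight)", a),
             call. = FALSE)
      tt <- gu / sqrt(nw2)               # = Xd w with w normalised
      gyt <- drop(Gy %*% tt)
      t2 <- sum(tt^2)
      tgyt <- sum(tt * gyt)              # = t2^2 |c|^2
      if (tgyt <= .Machine$double.eps)
        stop(sprintf("component %d collapsed (zero Y loading)", a),
             call. = FALSE)
      u <- gyt * t2 / tgyt               # = Yd c / |c|^2
      tn <- tt / sqrt(t2)
      if (sqrt(sum((tn - tOld)^2)) < tol) {
        converged <- TRUE; iters[a] <- it; break
      }
      tOld <- tn
    }
    if (!converged)
      stop(sprintf("NIPALS did not converge for component %d within %d iterations",
                   a, maxIter), call. = FALSE)
    gu <- drop(Gx %*% u)
    tt <- gu / sqrt(sum(u * gu))
    t2 <- sum(tt^2)
    # loadings from the undeflated matrices (scores are orthogonal)
    p <- drop(crossprod(Xs, tt)) / t2
    q <- drop(crossprod(Ys, tt)) / t2
    # weight vector: Xd' u = Xs' u - P (T' u) for the deflated Xd
    w <- drop(crossprod(Xs, u))
    if (a > 1L) {
      prev <- seq_len(a - 1L)
      w <- w - drop(P[, prev, drop = FALSE] %*%
                      crossprod(Tm[, prev, drop = FALSE], u))
    }
    w <- w / sqrt(sum(w^2))
    gyt <- drop(Gy %*% tt)
    uFinal <- gyt * t2 / sum(tt * gyt)
    beta[a] <- sum(uFinal * tt) / t2
    # incremental Gram deflation: (Xd - t p')(Xd - t p')' from the old Gram
    xp <- drop(Gx %*% tt) / t2           # = Xd p
    pp <- sum(tt * xp) / t2              # = p' p
    Gx <- Gx - tcrossprod(xp, tt) - tcrossprod(tt, xp) + pp * tcrossprod(tt)
    yq <- gyt / t2
    qq <- sum(tt * yq) / t2
    Gy <- Gy - tcrossprod(yq, tt) - tcrossprod(tt, yq) + qq * tcrossprod(tt)
    csY <- csY - q^2 * t2                # residual column sums of squares
    W[, a] <- w; P[, a] <- p; Q[, a] <- q
    Tm[, a] <- tt; Um[, a] <- uFinal
    kUsed <- a
  }
  if (kUsed < k) {
    # fewer informative components than requested (degenerate data); keep
    # the extracted ones
    keep <- seq_len(kUsed)
    W <- W[, keep, drop = FALSE]; P <- P[, keep, drop = FALSE]
    Q <- Q[, keep, drop = FALSE]
    Tm <- Tm[, keep, drop = FALSE]; Um <- Um[, keep, drop = FALSE]
    beta <- beta[keep]; iters <- iters[keep]
    k <- kUsed
  }
  new("PLSModel", nComponents = k, xWeights = W, xLoadings = P,
      yLoadings = Q, beta = beta, scores = Tm, uScores = Um,
      xCenter = sx$center, xScale = sx$scale,
      yCenter = sy$center, yScale = sy$scale,
      xConstMask = sx$constMask, yConstMask = sy$constMask,
      iterations = iters, foldSeed = as.numeric(foldSeed))
}

#' Predict target geometry for new source rows
#'
#' Standardizes `newdata` with the training X parameters, projects onto the
#' latent space (`T = X W (P' W)^-1`), applies the latent regression and
#' Y-loadings, and de-standardizes with the training Y parameters.
#'
#' @param object a [PLSModel-class].
#' @param newdata matrix with the model's X column count (a single row may
#'   be given as a vector).
#' @param ncomp number of components to use (default: all fitted).
#' @return predicted target matrix on the original Y scale.
#' @export
setMethod("predict", "PLSModel", function(object, newdata, ncomp = NULL) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1L)
  stopIfNot(ncol(newdata) == length(object@xCenter),
            "newdata column count does not match the model")
  k <- if (is.null(ncomp)) object@nComponents else as.integer(ncomp)
  stopIfNot(k >= 0L && k <= object@nComponents, "invalid ncomp")
  if (k == 0L)   # degenerate model: predict the training mean
    return(matrix(object@yCenter, nrow(newdata), length(object@yCenter),
                  byrow = TRUE))
  Xs <- sweep(sweep(newdata, 2L, object@xCenter), 2L, object@xScale, "/")
  Xs[, object@xConstMask] <- 0
  W <- object@xWeights[, seq_len(k), drop = FALSE]
  P <- object@xLoadings[, seq_len(k), drop = FALSE]
  Q <- object@yLoadings[, seq_len(k), drop = FALSE]
  R <- W %*% solve(crossprod(P, W))
  Ys <- (Xs %*% R) %*% t(Q)
  Ys[, object@yConstMask] <- 0
  destandardizeColumns(Ys, object@yCenter, object@yScale)
})

#' Select the number of PLS components by k-fold cross-validation
#'
#' Rows are shuffled with a fixed seed, split into `folds` contiguous
#' blocks, and for every candidate component count the mean squared
#' prediction error over held-out rows is accumulated (components are nested
#' in NIPALS, so each fold is fitted once at the largest candidate). The
#' selected count minimises the CV MSE; ties resolve to the smaller count.
#'
#' @param X,Y paired matrices (same rows).
#' @param kMax largest candidate component count (default
#'   `min(nrow(X) - 2, 10)`).
#' @param folds number of folds (default 5).
#' @param foldSeed seed for the fold shuffle (default 1).
#' @return list with `nComponents` (selected), `cvMse` (per candidate), and
#'   `foldSeed`.
#' @export
selectComponents <- function(X, Y, kMax = NULL, folds = 5L, foldSeed = 1) {
  n <- nrow(X)
  stopIfNot(n >= folds, "need at least as many rows as folds")
  kMax <- as.integer(kMax %||% max(1L, min(n - 2L, 10L)))
  ord <- withSeed(foldSeed, sample.int(n))
  # contiguous blocks of the shuffled order
  foldId <- integer(n)
  splits <- split(ord, cut(seq_len(n), folds, labels = FALSE))
  for (f in seq_along(splits)) foldId[splits[[f]]] <- f
  sse <- matrix(0, kMax, 1L)
  nObs <- 0
  for (f in seq_len(folds)) {
    test <- which(foldId == f)
    train <- setdiff(seq_len(n), test)
    kFit <- min(kMax, length(train) - 1L)
    model <- fitPls(X[train, , drop = FALSE], Y[train, , drop = FALSE], kFit)
    for (k in seq_len(kMax)) {
      kk <- min(k, model@nComponents)
      Yh <- predict(model, X[test, , drop = FALSE], ncomp = kk)
      sse[k] <- sse[k] + sum((Yh - Y[test, , drop = FALSE])^2)
    }
    nObs <- nObs + length(test) * ncol(Y)
  }
  cvMse <- drop(sse) / nObs
  list(nComponents = which.min(cvMse), cvMse = cvMse, foldSeed = foldSeed)
}

#' Leave-one-out mapped predictions
#'
#' For each row `i`, fits the PLS mapping on the remaining rows and predicts
#' the held-out source row, producing an approximately unbiased estimate of
#' mapping performance. The component count is selected once on the full
#' dataset by default (set `reselectPerFold = TRUE` to re-run component
#' selection inside every fold, which avoids the mild information leak of
#' the single selection at extra cost).
#'
#' @param X,Y paired geometry matrices (subjects x columns).
#' @param nComponents fixed component count; `NULL` (default) selects by
#'   5-fold CV via [selectComponents()].
#' @param foldSeed seed for CV fold assignment.
#' @param kMax candidate range upper bound for selection.
#' @param reselectPerFold logical, re-select components within each
#'   leave-one-out fold.
#' @return list with `predictions` (matrix like `Y`), `nComponents`, and
#'   `perFoldComponents`.
#' @export
looPredict <- function(X, Y, nComponents = NULL, foldSeed = 1, kMax = NULL,
                       reselectPerFold = FALSE) {
  n <- nrow(X)
  stopIfNot(n >= 3L, "leave-one-out needs at least 3 subjects")
  kGlobal <- nComponents %||%
    selectComponents(X, Y, kMax = kMax, foldSeed = foldSeed)$nComponents
  Yhat <- matrix(NA_real_, n, ncol(Y), dimnames = dimnames(Y))
  perFold <- integer(n)
  for (i in seq_len(n)) {
    Xi <- X[-i, , drop = FALSE]; Yi <- Y[-i, , drop = FALSE]
    k <- if (reselectPerFold)
      selectComponents(Xi, Yi, kMax = kMax, foldSeed = foldSeed)$nComponents
    else kGlobal
    k <- min(k, nrow(Xi) - 1L)
    model <- fitPls(Xi, Yi, k, foldSeed = foldSeed)
    Yhat[i, ] <- predict(model, X[i, , drop = FALSE])
    perFold[i] <- k
  }
  list(predictions = Yhat, nComponents = kGlobal, perFoldComponents = perFold)
}
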