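# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

# Linear interpolation of a periodic signal sampled at `phases` (subset of
# [0,1), first phase 0). `values` may be a vector or a matrix with one row
# per phase; the signal wraps with period 1 (value at 1 equals value at 0).
interpPeriodic <- function(phases, values, newPhases) {
  vec <- is.null(dim(values))
  V <- if (vec) matrix(values, ncol = 1L) else values
  stopifnot(nrow(V) == length(phases))
  if (abs(phases[length(phases)] - 1) < 1e-12) {
    # grid already spans the closed cycle [0, 1]
    xe <- phases
    Ve <- V
  } else {
    xe <- c(phases, phases[1L] + 1)
    Ve <- rbind(V, V[1L, , drop = FALSE])
  }
  np <- newPhases %% 1
  np[newPhases == 1] <- 1  # keep exact endpoint on the duplicated node
  idx <- findInterval(np, xe, rightmost.closed = TRUE)
  idx[idx < 1L] <- 1L
  idx[idx >= length(xe)] <- length(xe) - 1L
  x0 <- xe[idx]; x1 <- xe[idx + 1L]
  w <- (np - x0) / (x1 - x0)
  out <- Ve[idx, , drop = FALSE] * (1 - w) + Ve[idx + 1L, , drop = FALSE] * w
  if (vec) out[, 1L] else out
}

# Rodrigues rotation of 3-vector(s) v about unit axis by angle (radians).
rotateAboutAxis <- function(v, axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  if (is.null(dim(v))) v <- matrix(v, ncol = 3L)
  ca <- cos(angle); sa <- sin(angle)
  cross <- cbind(
    axis[2L] * v[, 3L] - axis[3L] * v[, 2L],
    axis[3L] * v[, 1L] - axis[1L] * v[, 3L],
    axis[1L] * v[, 2L] - axis[2L] * v[, 1L])
  dotp <- drop(v %*% axis)
  out <- v * ca + cross * sa + outer(dotp * (1 - ca), axis)
  if (nrow(out) == 1L) drop(out) else out
}

# run expr with a private RNG stream seeded by `seed`, restoring the caller's
# RNG state afterwards
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# local maxima (cyclic neighbours) of a numeric vector restricted to the
# index window `candidates`; prominence = height above the higher of the two
# flanking valleys (walking outwards until a strictly higher sample).
localMaximaProminence <- function(x, candidates = seq_along(x)) {
  n <- length(x)
  if (n < 3L) return(data.frame(index = integer(), value = numeric(),
                                prominence = numeric()))
  nb <- function(i, d) ((i - 1L + d) %% n) + 1L
  isMax <- vapply(candidates, function(i) {
    x[i] > x[nb(i, -1L)] && x[i] >= x[nb(i, 1L)]
  }, logical(1L))
  peaks <- candidates[isMax]
  prom <- vapply(peaks, function(i) {
    lv <- x[i]; j <- i; valleyL <- x[i]
    for (s in seq_len(n - 1L)) {
      j <- nb(j, -1L)
      valleyL <- min(valleyL, x[j])
      if (x[j] > lv) break
    }
    j <- i; valleyR <- x[i]
    for (s in seq_len(n - 1L)) {
      j <- nb(j, 1L)
      valleyR <- min(valleyR, x[j])
      if (x[j] > lv) break
    }
    lv - max(valleyL, valleyR)
  }, numeric(1L))
  data.frame(index = peaks, value = x[peaks], prominence = prom)
}

stopIfNot <- function(cond, ...) if (!isTRUE(cond)) stop(..., call. = FALSE)
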