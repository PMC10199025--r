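#' Build the canonical LV surface grid
#'
#' Constructs the fixed sampling topology used for every surface in the
#' package: one apical point plus `nRings` rings of `nMeridians` points each,
#' ordered apex to base (145 points per surface at the default 16 x 9
#' layout). The factorisation into 9 rings and 16 meridians supports the
#' apical/mid/basal thirds and circumferential sectors of the AHA model
#' exactly.
#'
#' @param nMeridians circumferential samples per ring (default 16).
#' @param nRings rings from apex (ring 1) to base (ring `nRings`), default 9.
#' @return A [SurfaceGrid-class] object.
#' @examples
#' g <- lvSurfaceGrid()
#' nGridPoints(g)  # 145
#' @export
lvSurfaceGrid <- function(nMeridians = 16L, nRings = 9L) {
  nMeridians <- as.integer(nMeridians); nRings <- as.integer(nRings)
  id <- function(r, m) {
    m <- (m - 1L) %% nMeridians + 1L
    ifelse(r == 0L, 1L, 1L + (r - 1L) * nMeridians + m)
  }
  tris <- vector("list", nMeridians * (2L * nRings - 1L))
  k <- 0L
  for (m in seq_len(nMeridians)) {
    k <- k + 1L; tris[[k]] <- c(1L, id(1L, m), id(1L, m + 1L))
  }
  if (nRings > 1L) for (r in seq_len(nRings - 1L)) for (m in seq_len(nMeridians)) {
    k <- k + 1L; tris[[k]] <- c(id(r, m), id(r + 1L, m), id(r + 1L, m + 1L))
    k <- k + 1L; tris[[k]] <- c(id(r, m), id(r + 1L, m + 1L), id(r, m + 1L))
  }
  np <- 1L + nRings * nMeridians
  cap <- t(vapply(seq_len(nMeridians), function(m)
    c(id(nRings, m + 1L), id(nRings, m), np + 1L), integer(3L)))
  new("SurfaceGrid", nMeridians = nMeridians, nRings = nRings,
      triangles = do.call(rbind, tris), capTriangles = cap)
}

#' Point index for a (ring, meridian) position
#'
#' Bijection between the (ring, meridian) parameterisation and the 1-based
#' point index within a surface. The apex is index 1; ring `r`, meridian `m`
#' maps to `1 + (r-1) * nMeridians + m`. On-disk formats use 0-based indices
#' (apex = 0); the offset is applied at the I/O boundary.
#'
#' @param grid a [SurfaceGrid-class].
#' @param ring ring number, 1 (apical) .. `nRings` (basal).
#' @param meridian meridian number, 1 .. `nMeridians`.
#' @return integer point index in `1 .. nGridPoints(grid)`.
#' @export
gridIndex <- function(grid, ring, meridian) {
  stopIfNot(all(ring >= 1L & ring <= grid@nRings), "ring out of range")
  stopIfNot(all(meridian >= 1L & meridian <= grid@nMeridians),
            "meridian out of range")
  1L + (ring - 1L) * grid@nMeridians + meridian
}

#' @rdname gridIndex
#' @export
apexIndex <- function(grid) 1L

#' Number of points per surface
#' @param grid a [SurfaceGrid-class].
#' @export
nGridPoints <- function(grid) 1L + grid@nRings * grid@nMeridians

# ---- spline surface refinement (cached linear operators) -------------------

refinementCache <- new.env(parent = emptyenv())

# Interpolation matrix for a periodic cubic spline through `n` uniform nodes,
# evaluated at `n * f` uniform fine positions.
periodicSplineMatrix <- function(n, f) {
  x <- 0:n
  xf <- seq(0, n, length.out = n * f + 1L)[seq_len(n * f)]
  M <- matrix(0, n * f, n)
  for (j in seq_len(n)) {
    y <- rep(0, n + 1L); y[j] <- 1; if (j == 1L) y[n + 1L] <- 1
    M[, j] <- stats::spline(x, y, method = "periodic", xout = xf)$y
  }
  M
}

# Interpolation matrix for a natural cubic spline through nodes 0..nRings
# (node 0 is the apex), evaluated at nRings*f + 1 uniform fine positions.
naturalSplineMatrix <- function(nRings, f) {
  x <- 0:nRings
  xf <- seq(0, nRings, length.out = nRings * f + 1L)
  M <- matrix(0, length(xf), nRings + 1L)
  for (j in seq_len(nRings + 1L)) {
    y <- rep(0, nRings + 1L); y[j] <- 1
    M[, j] <- stats::spline(x, y, method = "natural", xout = xf)$y
  }
  M
}

getRefinement <- function(nMeridians, nRings, subdivide) {
  key <- paste(nMeridians, nRings, subdivide, sep = "_")
  ref <- refinementCache[[key]]
  if (!is.null(ref)) return(ref)
  Tq <- periodicSplineMatrix(nMeridians, subdivide)
  B <- naturalSplineMatrix(nRings, subdivide)
  nM <- nMeridians * subdivide
  nP <- nrow(B)                     # fine rows incl. apex row
  id <- function(r, m) {            # fine point index, r = 1..nP
    m <- (m - 1L) %% nM + 1L
    ifelse(r == 1L, 1L, 1L + (r - 2L) * nM + m)
  }
  tris <- vector("list", nM * (2L * (nP - 1L) - 1L) + nM)
  k <- 0L
  for (m in seq_len(nM)) { k <- k + 1L; tris[[k]] <- c(1L, id(2L, m), id(2L, m + 1L)) }
  for (r in 2L:(nP - 1L)) for (m in seq_len(nM)) {
    k <- k + 1L; tris[[k]] <- c(id(r, m), id(r + 1L, m), id(r + 1L, m + 1L))
    k <- k + 1L; tris[[k]] <- c(id(r, m), id(r + 1L, m + 1L), id(r, m + 1L))
  }
  npF <- 1L + (nP - 1L) * nM
  for (m in seq_len(nM)) { k <- k + 1L; tris[[k]] <- c(id(nP, m + 1L), id(nP, m), npF + 1L) }
  tri <- do.call(rbind, tris[seq_len(k)])
  ref <- list(Tq = Tq, B = B, nMerF = nM, nPhiF = nP, tri = tri,
              baseIdx = vapply(seq_len(nM), function(m) id(nP, m), integer(1L)))
  refinementCache[[key]] <- ref
  ref
}

# Refined fine point set for one surface. `points` is nGridPoints x 3.
refineSurface <- function(points, grid, subdivide) {
  ref <- getRefinement(grid@nMeridians, grid@nRings, subdivide)
  nMer <- grid@nMeridians; nRings <- grid@nRings
  ptsF <- matrix(0, 1L + (ref$nPhiF - 1L) * ref$nMerF, 3L)
  for (cc in 1:3) {
    G <- rbind(rep(points[1L, cc], nMer),
               matrix(points[-1L, cc], nRings, nMer, byrow = TRUE))
    GF <- ref$B %*% G %*% t(ref$Tq)      # (nPhiF x nMerF)
    ptsF[1L, cc] <- GF[1L, 1L]
    ptsF[-1L, cc] <- as.vector(t(GF[-1L, , drop = FALSE]))
  }
  list(points = ptsF, ref = ref)
}

signedClosedVolume <- function(ptsF, tri, baseIdx) {
  cen <- colMeans(ptsF[baseIdx, , drop = FALSE])
  P <- rbind(ptsF, cen)
  p1 <- P[tri[, 1L], , drop = FALSE]
  p2 <- P[tri[, 2L], , drop = FALSE]
  p3 <- P[tri[, 3L], , drop = FALSE]
  sum(p1[, 1L] * (p2[, 2L] * p3[, 3L] - p2[, 3L] * p3[, 2L]) -
      p1[, 2L] * (p2[, 1L] * p3[, 3L] - p2[, 3L] * p3[, 1L]) +
      p1[, 3L] * (p2[, 1L] * p3[, 2L] - p2[, 2L] * p3[, 1L])) / 6
}

#' Cavity volume of one surface frame
#'
#' Volume enclosed by a surface point set, computed with the divergence
#' theorem over a closed triangulation: the open basal end is closed by a
#' flat fan to the basal-ring centroid. To remove the first-order chord
#' deficit of a flat triangulation of the coarse 145-point grid, the sum is
#' evaluated on a spline-refined surface (periodic cubic circumferentially,
#' natural cubic apex-to-base; both are fixed linear operators, so the
#' refined volume scales exactly like the underlying geometry under affine
#' scaling). Set `subdivide = 1` for the raw flat-triangle sum.
#'
#' @param points numeric matrix `nGridPoints(grid) x 3`, coordinates in mm.
#' @param grid a [SurfaceGrid-class].
#' @param subdivide integer refinement factor per direction (default 4).
#' @return volume in ml (1 ml = 1000 mm^3).
#' @examples
#' g <- lvSurfaceGrid()
#' # half prolate spheroid, semi-axes 80 x 30 x 30 mm: (2/3) pi a b c
#' @export
cavityVolume <- function(points, grid, subdivide = 4L) {
  stopIfNot(is.matrix(points) && nrow(points) == nGridPoints(grid) &&
              ncol(points) == 3L, "points must be an nGridPoints x 3 matrix")
  stopIfNot(all(is.finite(points)), "points must be finite")
  if (subdivide <= 1L) {
    baseIdx <- gridIndex(grid, grid@nRings, seq_len(grid@nMeridians))
    v <- signedClosedVolume(points, rbind(grid@triangles, grid@capTriangles),
                            baseIdx)
  } else {
    rf <- refineSurface(points, grid, as.integer(subdivide))
    v <- signedClosedVolume(rf$points, rf$ref$tri, rf$ref$baseIdx)
  }
  if (v <= 0) stop("non-positive signed volume: surface is inverted or self-intersecting",
                   call. = FALSE)
  v / 1000
}

#' Myocardial wall mass at one frame
#'
#' Mass of the wall between the epicardial and endocardial surfaces:
#' (epicardial enclosed volume - endocardial cavity volume) x density.
#'
#' @param endo,epi point matrices (`nGridPoints x 3`, mm).
#' @param grid a [SurfaceGrid-class].
#' @param density myocardial density in g/ml (default 1.05, the conventional
#'   value).
#' @param subdivide surface refinement factor, see [cavityVolume()].
#' @return mass in g.
#' @export
wallMass <- function(endo, epi, grid, density = 1.05, subdivide = 4L) {
  ve <- cavityVolume(epi, grid, subdivide)
  vi <- cavityVolume(endo, grid, subdivide)
  if (ve < vi - 1e-9) stop("epicardial volume smaller than cavity volume",
                           call. = FALSE)
  max(ve - vi, 0) * density
}

# ---- cardiac coordinate frame ---------------------------------------------

#' Cardiac coordinate frame from anatomical landmarks
#'
#' Builds the standard cardiac frame: `x` along the long axis pointing from
#' the basal centroid toward the apex, origin at one-third of the
#' base-to-apex distance (so the base sits at `x = -L/3` and the apex at
#' `x = +2L/3`), and `y` obtained by rotating the (projected) inferior
#' RV-insertion direction by `angleDeg` about the long axis; `z = x cross y`.
#' The rotation sense is a convention: `ySense = +1` (default) rotates
#' right-handedly about `+x`.
#'
#' @param apex,basalCentroid,rvInsertion numeric(3) landmark coordinates, mm.
#' @param ySense +1 or -1, rotation sense of the 70 degree offset.
#' @param angleDeg angle between the RV-insertion direction and `y`
#'   (default 70).
#' @return list with `origin` (numeric(3)) and `axes` (3 x 3 matrix whose
#'   columns are the unit `x`, `y`, `z` axes).
#' @export
cardiacFrame <- function(apex, basalCentroid, rvInsertion,
                         ySense = 1, angleDeg = 70) {
  v <- apex - basalCentroid
  L <- sqrt(sum(v^2))
  if (L < 1e-6) stop("degenerate landmarks: apex coincides with basal centroid",
                     call. = FALSE)
  xhat <- v / L
  origin <- basalCentroid + (L / 3) * xhat
  w <- rvInsertion - origin
  wperp <- w - sum(w * xhat) * xhat
  nw <- sqrt(sum(wperp^2))
  if (nw < 1e-6 * L) stop("degenerate landmarks: RV insertion lies on the long axis",
                          call. = FALSE)
  yhat <- rotateAboutAxis(wperp / nw, xhat, ySense * angleDeg * pi / 180)
  zhat <- c(xhat[2L] * yhat[3L] - xhat[3L] * yhat[2L],
            xhat[3L] * yhat[1L] - xhat[1L] * yhat[3L],
            xhat[1L] * yhat[2L] - xhat[2L] * yhat[1L])
  list(origin = origin, axes = cbind(x = xhat, y = yhat, z = zhat))
}

#' Rigidly align a sequence to its cardiac coordinate frame
#'
#' Canonicalises the pose of an [LVSequence-class] using its end-diastolic
#' landmarks: every frame and the landmarks themselves are rigidly
#' transformed into the frame returned by [cardiacFrame()]. The operation is
#' idempotent and removes any rigid motion applied to the input.
#'
#' @param seq an [LVSequence-class] with `apex`, `basalCentroid` and
#'   `rvInsertion` landmarks.
#' @inheritParams cardiacFrame
#' @return the aligned [LVSequence-class].
#' @export
alignToCardiacFrame <- function(seq, ySense = 1, angleDeg = 70) {
  lm <- seq@landmarks
  stopIfNot(!is.null(lm$apex) && !is.null(lm$basalCentroid) &&
              !is.null(lm$rvInsertion),
            "alignment needs apex, basalCentroid and rvInsertion landmarks")
  fr <- cardiacFrame(lm$apex, lm$basalCentroid, lm$rvInsertion,
                     ySense = ySense, angleDeg = angleDeg)
  R <- fr$axes
  xform <- function(P) sweep(P, 2L, fr$origin) %*% R
  out <- seq
  for (f in seq_len(dim(seq@endo)[3L])) {
    out@endo[, , f] <- xform(seq@endo[, , f])
    out@epi[, , f] <- xform(seq@epi[, , f])
  }
  out@landmarks <- lapply(seq@landmarks, function(p)
    if (is.null(p)) NULL else as.numeric(xform(matrix(p, 1L))))
  out
}

# rigid motion helper (used by the generator and tests)
applyRigidMotion <- function(seq, rotation, translation) {
  out <- seq
  for (f in seq_len(dim(seq@endo)[3L])) {
    out@endo[, , f] <- seq@endo[, , f] %*% t(rotation) +
      matrix(translation, nrow(seq@endo), 3L, byrow = TRUE)
    out@epi[, , f] <- seq@epi[, , f] %*% t(rotation) +
      matrix(translation, nrow(seq@epi), 3L, byrow = TRUE)
  }
  out@landmarks <- lapply(seq@landmarks, function(p)
    if (is.null(p)) NULL else drop(rotation %*% p) + translation)
  out
}

# ---- AHA 17-segment labelling ---------------------------------------------

#' Assign AHA segments to grid points
#'
#' Partitions the surface points of an aligned sequence into the segments of
#' the AHA 17-segment model. Rings are split into apical (rings 1-3), mid
#' (4-6) and basal (7-9) thirds. Circumferential sectors are measured by each
#' point's angle about the long axis at end-diastole: basal and mid levels
#' use six 60-degree sectors with the inferoseptal/anteroseptal boundary at
#' the inferior RV-insertion direction; the apical level uses four 90-degree
#' sectors offset by 45 degrees. The endocardial apex point is excluded
#' (`NA`); the epicardial apex labels the apical cap, segment 17.
#'
#' Segment ids follow the standard numbering (basal 1-6, mid 7-12, apical
#' 13-16 plus cap 17), with ids ordered inferoseptal -> inferior ->
#' inferolateral -> anterolateral -> anterior -> anteroseptal as the angle
#' increases from the RV-insertion direction.
#'
#' @param seq an aligned [LVSequence-class] (cardiac coordinates).
#' @param grid the [SurfaceGrid-class] (defaults to the sequence's grid).
#' @param ySense rotation sense used during alignment (fixes the expected
#'   RV-insertion angle of -`angleDeg` x `ySense` about the long axis).
#' @param angleDeg angle between RV insertion and the `y` axis (default 70).
#' @param poseTolerance relative tolerance (fraction of the long-axis length)
#'   for the cardiac-coordinates check on the ED basal centroid.
#' @return list with integer vectors `endo` (values 1-16, apex `NA`) and
#'   `epi` (values 1-17).
#' @export
assignAhaSegments <- function(seq, grid = seq@grid, ySense = 1, angleDeg = 70,
                              poseTolerance = 0.05) {
  ed <- 1L
  endo <- seq@endo[, , ed]; epi <- seq@epi[, , ed]
  baseIdx <- gridIndex(grid, grid@nRings, seq_len(grid@nMeridians))
  bc <- colMeans(epi[baseIdx, , drop = FALSE])
  apx <- epi[apexIndex(grid), ]
  L <- apx[1L] - bc[1L]
  if (!(L > 0) || sqrt(sum(bc[2:3]^2)) > poseTolerance * abs(L) ||
      sqrt(sum(apx[2:3]^2)) > poseTolerance * abs(L))
    stop("sequence is not in cardiac coordinates; run alignToCardiacFrame() first",
         call. = FALSE)
  thIns <- -ySense * angleDeg * pi / 180
  basalOrder <- c(3L, 4L, 5L, 6L, 1L, 2L)
  apicalOrder <- c(14L, 15L, 16L, 13L)
  labelSurface <- function(P, isEndo) {
    lab <- rep(NA_integer_, nGridPoints(grid))
    lab[apexIndex(grid)] <- if (isEndo) NA_integer_ else 17L
    nR <- grid@nRings
    third <- ceiling(3 * seq_len(nR) / nR)    # 1 apical, 2 mid, 3 basal
    for (r in seq_len(nR)) {
      idx <- gridIndex(grid, r, seq_len(grid@nMeridians))
      th <- atan2(P[idx, 3L], P[idx, 2L])
      if (third[r] == 1L) {
        k <- floor(((th - (thIns - pi / 4)) %% (2 * pi)) / (pi / 2))
        lab[idx] <- apicalOrder[k + 1L]
      } else {
        k <- floor(((th - thIns) %% (2 * pi)) / (pi / 3))
        lab[idx] <- basalOrder[k + 1L] + if (third[r] == 2L) 6L else 0L
      }
    }
    lab
  }
  list(endo = labelSurface(endo, TRUE), epi = labelSurface(epi, FALSE))
}
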