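#' @import methods
NULL

#' Standardized LV surface sampling grid
#'
#' The left-ventricular myocardium is represented by two surfaces
#' (endocardium and epicardium), each sampled at 145 points: a single apical
#' point plus `nRings` rings of `nMeridians` points, ordered apex to base.
#' The grid carries a fixed, outward-oriented triangulation of each surface;
#' the open basal end is closed by a flat fan of cap triangles to the basal
#' ring centroid (a virtual vertex indexed `nPoints + 1`), so that
#' divergence-theorem volumes are well defined.
#'
#' @slot nMeridians integer, number of circumferential samples per ring.
#' @slot nRings integer, number of rings between apex and base.
#' @slot triangles integer matrix (k x 3) of 1-based point indices covering
#'   the open surface (apex fan plus inter-ring strips).
#' @slot capTriangles integer matrix (nMeridians x 3); index `nPoints + 1`
#'   denotes the basal-ring centroid.
#' @seealso [lvSurfaceGrid()], [gridIndex()], [cavityVolume()]
#' @export
setClass("SurfaceGrid",
  representation(
    nMeridians = "integer",
    nRings = "integer",
    triangles = "matrix",
    capTriangles = "matrix"
  )
)

setValidity("SurfaceGrid", function(object) {
  msg <- character()
  if (length(object@nMeridians) != 1L || object@nMeridians < 3L)
    msg <- c(msg, "nMeridians must be a single integer >= 3")
  if (length(object@nRings) != 1L || object@nRings < 2L)
    msg <- c(msg, "nRings must be a single integer >= 2")
  np <- 1L + object@nRings * object@nMeridians
  if (ncol(object@triangles) != 3L || ncol(object@capTriangles) != 3L)
    msg <- c(msg, "triangle tables must have 3 columns")
  else {
    if (any(object@triangles < 1L) || any(object@triangles > np))
      msg <- c(msg, "surface triangle indices out of range")
    if (any(apply(object@triangles, 1L, anyDuplicated) > 0L))
      msg <- c(msg, "degenerate surface triangle (repeated vertex)")
    if (any(object@capTriangles > np + 1L))
      msg <- c(msg, "cap triangle indices out of range")
  }
  if (length(msg)) msg else TRUE
})

#' Time-varying LV geometry for one subject and one protocol
#'
#' Ordered frames of paired endocardial/epicardial point sets (mm) over one
#' cardiac cycle, with frame phases (cycle fractions, first frame at phase 0
#' taken as end-diastole), the cycle duration in seconds, and optional
#' anatomical landmarks (epicardial apex, basal centroid, inferior
#' right-ventricular insertion) used to establish the cardiac coordinate
#' frame.
#'
#' @slot subjectId character scalar.
#' @slot protocol character scalar, e.g. `"source"` or `"target"`.
#' @slot endo,epi numeric arrays `nPoints x 3 x nFrames`, coordinates in mm.
#' @slot phases numeric vector of cycle fractions, strictly increasing from 0.
#' @slot cycleDuration numeric scalar, seconds (> 0).
#' @slot landmarks list with elements `apex`, `basalCentroid`, `rvInsertion`
#'   (each `numeric(3)` in mm, or `NULL` when unavailable).
#' @slot grid the [SurfaceGrid-class] the point indices refer to.
#' @slot metadata free-form list (the synthetic generator stores its
#'   ground-truth parameters here).
#' @export
setClass("LVSequence",
  representation(
    subjectId = "character",
    protocol = "character",
    endo = "array",
    epi = "array",
    phases = "numeric",
    cycleDuration = "numeric",
    landmarks = "list",
    grid = "SurfaceGrid",
    metadata = "list"
  )
)

setValidity("LVSequence", function(object) {
  msg <- character()
  np <- 1L + object@grid@nRings * object@grid@nMeridians
  de <- dim(object@endo); dp <- dim(object@epi)
  if (length(de) != 3L || length(dp) != 3L)
    return("endo and epi must be nPoints x 3 x nFrames arrays")
  if (de[1L] != np || dp[1L] != np)
    msg <- c(msg, sprintf("point count must be %d per surface", np))
  if (de[2L] != 3L || dp[2L] != 3L)
    msg <- c(msg, "coordinate dimension must be 3")
  nf <- de[3L]
  if (dp[3L] != nf) msg <- c(msg, "endo and epi frame counts differ")
  if (nf < 2L) msg <- c(msg, "a sequence needs at least 2 frames")
  if (length(object@phases) != nf)
    msg <- c(msg, "phases length must equal the frame count")
  else {
    if (object@phases[1L] != 0) msg <- c(msg, "first phase must be 0")
    if (any(diff(object@phases) <= 0))
      msg <- c(msg, "phases must be strictly increasing")
    if (any(object@phases < 0 | object@phases > 1))
      msg <- c(msg, "phases must lie in [0, 1]")
  }
  if (!all(is.finite(object@endo)) || !all(is.finite(object@epi)))
    msg <- c(msg, "coordinates must be finite")
  if (length(object@cycleDuration) != 1L || !is.finite(object@cycleDuration) ||
      object@cycleDuration <= 0)
    msg <- c(msg, "cycleDuration must be a positive scalar (seconds)")
  if (length(msg)) msg else TRUE
})

#' Fitted partial least squares mapping between geometry datasets
#'
#' Result of NIPALS PLS2 regression of a target geometry matrix on a source
#' geometry matrix (both standardized column-wise internally). Stores the
#' per-component X-weights, X- and Y-loadings, latent regression
#' coefficients, training scores, and the standardization parameters needed
#' to map new source rows into target space.
#'
#' @slot nComponents integer, number of latent components extracted.
#' @slot xWeights,xLoadings numeric matrices, columns per component.
#' @slot yLoadings numeric matrix, columns per component.
#' @slot beta numeric vector of latent regression coefficients (one per
#'   component, regression of Y-scores on X-scores).
#' @slot scores,uScores numeric matrices of training X- and Y-scores.
#' @slot xCenter,xScale,yCenter,yScale numeric vectors of column means and
#'   sample standard deviations used for standardization.
#' @slot xConstMask,yConstMask logical vectors flagging constant columns
#'   (masked to zero in standardized space, restored exactly on inversion).
#' @slot iterations integer vector, NIPALS iterations used per component.
#' @slot foldSeed numeric, seed used for cross-validated component selection
#'   (NA when components were fixed by the caller).
#' @export
setClass("PLSModel",
  representation(
    nComponents = "integer",
    xWeights = "matrix",
    xLoadings = "matrix",
    yLoadings = "matrix",
    beta = "numeric",
    scores = "matrix",
    uScores = "matrix",
    xCenter = "numeric",
    xScale = "numeric",
    yCenter = "numeric",
    yScale = "numeric",
    xConstMask = "logical",
    yConstMask = "logical",
    iterations = "integer",
    foldSeed = "numeric"
  )
)

setValidity("PLSModel", function(object) {
  k <- object@nComponents
  if (ncol(object@xWeights) != k || ncol(object@xLoadings) != k ||
      ncol(object@yLoadings) != k || length(object@beta) != k)
    return("component dimensions are inconsistent")
  TRUE
})

#' A temporally aligned source/target sequence pair
#'
#' Output of [alignPair()]: the source sequence resampled to `n` uniform
#' phases and the target sequence evaluated (by linear interpolation) at the
#' warped fractional indices produced by the penalty-modified dynamic time
#' warping of the two normalised volume traces. Both members share the same
#' uniform phase grid, giving a one-to-one frame correspondence.
#'
#' @slot source,target [LVSequence-class] objects with identical phase grids.
#' @slot path integer matrix (o x 2) of warping-path index pairs (i, j).
#' @slot warpedIndices numeric vector of length n: fractional indices of the
#'   secondary signal paired with each template sample (weakly increasing).
#' @slot penalty numeric, the time-expansion penalty p used in the cost
#'   recursion.
#' @slot variant character, penalty placement: `"equation"` (penalty on the
#'   (i, j-1) predecessor) or `"text"` (penalty on the (i-1, j) predecessor).
#' @slot finalCost numeric, accumulated cost at (n, m).
#' @slot preDiscrepancy,postDiscrepancy numeric, summed squared discrepancy
#'   between the normalised traces under naive uniform pairing and under the
#'   warped pairing.
#' @export
setClass("AlignedPair",
  representation(
    source = "LVSequence",
    target = "LVSequence",
    path = "matrix",
    warpedIndices = "numeric",
    penalty = "numeric",
    variant = "character",
    finalCost = "numeric",
    preDiscrepancy = "numeric",
    postDiscrepancy = "numeric"
  )
)

setValidity("AlignedPair", function(object) {
  msg <- character()
  if (dim(object@source@endo)[3L] != dim(object@target@endo)[3L])
    msg <- c(msg, "source and target must have equal frame counts")
  if (!isTRUE(all.equal(object@source@phases, object@target@phases)))
    msg <- c(msg, "source and target must share one phase grid")
  if (any(diff(object@warpedIndices) < -1e-12))
    msg <- c(msg, "warped indices must be weakly non-decreasing")
  if (length(msg)) msg else TRUE
})

#' Construct an LVSequence
#'
#' @param subjectId,protocol character scalars.
#' @param endo,epi numeric arrays `nPoints x 3 x nFrames` (mm).
#' @param phases cycle fractions, strictly increasing from 0.
#' @param cycleDuration cycle length in seconds.
#' @param landmarks optional list with `apex`, `basalCentroid`,
#'   `rvInsertion`.
#' @param grid a [SurfaceGrid-class] (default: the canonical 16 x 9 grid).
#' @param metadata optional free-form list.
#' @return an [LVSequence-class].
#' @export
newLVSequence <- function(subjectId, protocol, endo, epi, phases,
                          cycleDuration, landmarks = list(),
                          grid = lvSurfaceGrid(), metadata = list()) {
  new("LVSequence", subjectId = as.character(subjectId),
      protocol = as.character(protocol), endo = endo, epi = epi,
      phases = as.numeric(phases), cycleDuration = cycleDuration,
      landmarks = landmarks, grid = grid, metadata = metadata)
}

#' Basic accessors for LVSequence
#' @param seq an [LVSequence-class].
#' @export
nFrames <- function(seq) dim(seq@endo)[3L]

#' @rdname nFrames
#' @export
framePhases <- function(seq) seq@phases

#' @rdname nFrames
#' @export
cycleDuration <- function(seq) seq@cycleDuration

#' @rdname nFrames
#' @export
subjectId <- function(seq) seq@subjectId

#' @rdname nFrames
#' @export
protocolLabel <- function(seq) seq@protocol

#' @rdname nFrames
#' @param frame frame index.
#' @export
endoPoints <- function(seq, frame) seq@endo[, , frame]

#' @rdname nFrames
#' @export
epiPoints <- function(seq, frame) seq@epi[, , frame]

#' @rdname nFrames
#' @export
landmarks <- function(seq) seq@landmarks

setMethod("show", "SurfaceGrid", function(object) {
  np <- 1L + object@nRings * object@nMeridians
  cat(sprintf(
    "SurfaceGrid: %d points/surface (apex + %d rings x %d meridians), %d surface + %d cap triangles\n",
    np, object@nRings, object@nMeridians,
    nrow(object@triangles), nrow(object@capTriangles)))
})

setMethod("show", "LVSequence", function(object) {
  cat(sprintf(
    "LVSequence '%s' [%s]: %d frames, %d points/surface, cycle %.3f s\n",
    object@subjectId, object@protocol, dim(object@endo)[3L],
    dim(object@endo)[1L], object@cycleDuration))
  lm <- object@landmarks
  have <- names(lm)[!vapply(lm, is.null, logical(1L))]
  if (length(have)) cat("  landmarks:", paste(have, collapse = ", "), "\n")
})

setMethod("show", "PLSModel", function(object) {
  cat(sprintf(
    "PLSModel: %d components, %d -> %d columns, %d training rows\n",
    object@nComponents, nrow(object@xWeights), nrow(object@yLoadings),
    nrow(object@scores)))
  cat("  NIPALS iterations per component:",
      paste(object@iterations, collapse = ", "), "\n")
})

setMethod("show", "AlignedPair", function(object) {
  cat(sprintf(
    "AlignedPair '%s': %d aligned frames, p = %.4f (%s), cost %.4g, discrepancy %.4g -> %.4g\n",
    object@source@subjectId, dim(object@source@endo)[3L], object@penalty,
    object@variant, object@finalCost, object@preDiscrepancy,
    object@postDiscrepancy))
})
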