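# Population-level pipeline: flattening aligned sequences into geometry
# matrices, the leave-one-out mapping evaluation, and the agreement report.

#' Flatten a sequence into one dataset row
#'
#' Fixed flattening order (versioned in the on-disk dataset header):
#' frame-major, then point index (endocardium 1..145 followed by epicardium
#' 1..145), then x, y, z. With 30 frames and the canonical grid this yields
#' 290 x 3 x 30 = 26,100 values.
#'
#' @param seq an [LVSequence-class].
#' @return numeric vector of length `nFrames * 2 * nPoints * 3`.
#' @export
sequenceToRow <- function(seq) {
  nf <- dim(seq@endo)[3L]
  unlist(lapply(seq_len(nf), function(f)
    as.vector(t(rbind(seq@endo[, , f], seq@epi[, , f])))), use.names = FALSE)
}

#' Rebuild a sequence from one dataset row
#'
#' Inverse of [sequenceToRow()]; frame phases, cycle duration, grid and
#' identifiers are taken from `template`.
#'
#' @param row numeric vector as produced by [sequenceToRow()].
#' @param template an [LVSequence-class] providing the non-coordinate slots.
#' @param protocol optional protocol relabel.
#' @return an [LVSequence-class].
#' @export
rowToSequence <- function(row, template, protocol = template@protocol) {
  np <- dim(template@endo)[1L]
  nf <- dim(template@endo)[3L]
  stopIfNot(length(row) == nf * 2L * np * 3L,
            "row length does not match the template dimensions")
  endo <- array(0, c(np, 3L, nf))
  epi <- array(0, c(np, 3L, nf))
  per <- 2L * np * 3L
  for (f in seq_len(nf)) {
    M <- matrix(row[(f - 1L) * per + seq_len(per)], 2L * np, 3L, byrow = TRUE)
    endo[, , f] <- M[seq_len(np), ]
    epi[, , f] <- M[np + seq_len(np), ]
  }
  newLVSequence(template@subjectId, protocol, endo, epi, template@phases,
                template@cycleDuration, template@landmarks, template@grid)
}

#' Temporally align every subject of a population
#'
#' @param pop an `lv_population` (or any list of `source`/`target` pairs).
#' @inheritParams alignPair
#' @return list of [AlignedPair-class] objects.
#' @export
alignPopulation <- function(pop, n = 30L, m = 60L, variant = "equation",
                            subdivide = 4L) {
  lapply(pop$subjects, function(s)
    alignPair(s$source, s$target, n = n, m = m, variant = variant,
              subdivide = subdivide))
}

#' Assemble the population geometry matrix
#'
#' Stacks the flattened aligned sequences into the subjects x columns
#' matrix consumed by the PLS mapping (26,100 columns for the default
#' 30-frame, 145-points-per-surface configuration). Row order is identical
#' for the source (X) and target (Y) matrices.
#'
#' @param aligned list of [AlignedPair-class] objects.
#' @param which `"source"` or `"target"`.
#' @return numeric matrix with subject ids as row names.
#' @export
buildGeometryDataset <- function(aligned, which = c("source", "target")) {
  which <- match.arg(which)
  rows <- lapply(aligned, function(ap) sequenceToRow(slot(ap, which)))
  X <- do.call(rbind, rows)
  rownames(X) <- vapply(aligned, function(ap) ap@source@subjectId,
                        character(1L))
  X
}

indexNames <- c("EDV", "ESV", "LVM", "EF", "GLS", "PER", "PFR_E", "PFR_A",
                "PSR")

#' Agreement summary over a set of indices
#'
#' For each clinical index and each mapping phase, computes the
#' source-minus-target bias, SD of differences, 95% limits of agreement,
#' ICC(A,1), and the paired t-test. Pairs where either value is missing
#' (e.g. absent atrial filling peaks) are dropped for that index.
#'
#' @param target data.frame of target-protocol indices (one row per
#'   subject).
#' @param byPhase named list of data.frames with identical layout, e.g.
#'   `list(before = ..., after = ...)`.
#' @param indices character vector of index columns to summarise.
#' @return `data.frame` with columns `index`, `phase`, `bias`, `sd`,
#'   `loa_low`, `loa_high`, `icc`, `t`, `p`, `n`.
#' @export
agreementSummary <- function(target, byPhase,
                             indices = intersect(indexNames,
                                                 colnames(target))) {
  rows <- list()
  for (idx in indices) {
    for (ph in names(byPhase)) {
      xs <- byPhase[[ph]][[idx]]
      xt <- target[[idx]]
      ok <- is.finite(xs) & is.finite(xt)
      if (sum(ok) < 3L) next
      ba <- blandAltman(xt[ok], xs[ok])
      icc <- iccAbsoluteAgreement(xt[ok], xs[ok])
      tt <- pairedTTest(xs[ok], xt[ok])
      rows[[length(rows) + 1L]] <- data.frame(
        index = idx, phase = ph, bias = ba$bias, sd = ba$sd,
        loa_low = ba$loa[1L], loa_high = ba$loa[2L], icc = icc,
        t = tt$t, p = tt$p, n = tt$n)
    }
  }
  do.call(rbind, rows)
}

#' End-to-end mapping evaluation with leave-one-out cross-validation
#'
#' Runs the full pipeline on a paired population: per-subject temporal
#' alignment, assembly of the geometry matrices, component selection,
#' leave-one-out PLS mapping, and the agreement evaluation of clinical
#' indices, global geometry RMSE, and cumulative DTW trace distances before
#' and after mapping. "Before" indices come from the native (unaligned)
#' source acquisitions, target indices from the native target acquisitions;
#' "after" indices are derived from the mapped geometries (30 uniform
#' frames on the source cycle).
#'
#' @param pop an `lv_population`.
#' @param nComponents fixed PLS component count, or `NULL` to select by
#'   5-fold cross-validation on the full dataset.
#' @param foldSeed seed for fold assignment.
#' @param kMax largest candidate component count.
#' @param n,m template and secondary resampling lengths.
#' @param variant DTW penalty placement.
#' @param density myocardial density g/ml.
#' @param subdivide surface refinement.
#' @param reselectPerFold re-select the component count inside every
#'   leave-one-out fold (see [looPredict()]).
#' @return list of class `lv_mapping_eval`: `agreement` (data.frame),
#'   `indices` (list of data.frames `target`, `before`, `after`), `rmse`
#'   (per-subject data.frame), `dtw` (per-subject data.frame),
#'   `nComponents`, `aligned`, `predictions`.
#' @export
evaluateMapping <- function(pop, nComponents = NULL, foldSeed = 1,
                            kMax = 10L, n = 30L, m = 60L,
                            variant = "equation", density = 1.05,
                            subdivide = 4L, reselectPerFold = FALSE) {
  aligned <- alignPopulation(pop, n = n, m = m, variant = variant,
                             subdivide = subdivide)
  X <- buildGeometryDataset(aligned, "source")
  Y <- buildGeometryDataset(aligned, "target")
  loo <- looPredict(X, Y, nComponents = nComponents, foldSeed = foldSeed,
                    kMax = kMax, reselectPerFold = reselectPerFold)
  nSubj <- length(pop$subjects)
  idxT <- idxB <- idxA <- vector("list", nSubj)
  rmseB <- rmseA <- numeric(nSubj)
  dtwRows <- vector("list", nSubj)
  mapped <- vector("list", nSubj)
  for (i in seq_len(nSubj)) {
    s <- pop$subjects[[i]]
    map <- rowToSequence(loo$predictions[i, ], aligned[[i]]@target,
                         protocol = "mapped")
    map@cycleDuration <- s$source@cycleDuration
    mapped[[i]] <- map
    idxT[[i]] <- computeIndices(s$target, density = density,
                                subdivide = subdivide)
    idxB[[i]] <- computeIndices(s$source, density = density,
                                subdivide = subdivide)
    idxA[[i]] <- computeIndices(map, density = density,
                                subdivide = subdivide)
    srcAligned <- aligned[[i]]@source
    tgtAligned <- aligned[[i]]@target
    rmseB[i] <- geometryRmse(srcAligned, tgtAligned)
    rmseA[i] <- geometryRmse(map, tgtAligned)
    vtT <- volumeTrace(tgtAligned, subdivide = subdivide)
    vtB <- volumeTrace(srcAligned, subdivide = subdivide)
    vtA <- volumeTrace(map, subdivide = subdivide)
    stT <- glsTrace(tgtAligned); stB <- glsTrace(srcAligned)
    stA <- glsTrace(map)
    dtwRows[[i]] <- data.frame(
      subject = s$target@subjectId,
      volume_before = cumulativeDtwDistance(vtB, vtT, n = n,
                                            variant = variant),
      volume_after = cumulativeDtwDistance(vtA, vtT, n = n,
                                           variant = variant),
      strain_before = cumulativeDtwDistance(stB, stT, n = n,
                                            variant = variant),
      strain_after = cumulativeDtwDistance(stA, stT, n = n,
                                           variant = variant))
  }
  bindIdx <- function(lst) {
    df <- do.call(rbind, lst)
    df$subject <- vapply(pop$subjects, function(s) s$target@subjectId,
                         character(1L))
    df
  }
  target <- bindIdx(idxT); before <- bindIdx(idxB); after <- bindIdx(idxA)
  agreement <- agreementSummary(target,
                                list(before = before, after = after))
  structure(list(
    agreement = agreement,
    indices = list(target = target, before = before, after = after),
    rmse = data.frame(subject = target$subject, before = rmseB,
                      after = rmseA),
    dtw = do.call(rbind, dtwRows),
    nComponents = loo$nComponents,
    aligned = aligned,
    mapped = mapped,
    predictions = loo$predictions), class = "lv_mapping_eval")
}

#' @export
print.lv_mapping_eval <- function(x, ...) {
  cat(sprintf("lv_mapping_eval: %d subjects, %d PLS components\n",
              nrow(x$rmse), x$nComponents))
  cat(sprintf("  global RMSE: %.2f +/- %.2f -> %.2f +/- %.2f mm\n",
              mean(x$rmse$before), stats::sd(x$rmse$before),
              mean(x$rmse$after), stats::sd(x$rmse$after)))
  ag <- x$agreement
  for (idx in unique(ag$index)) {
    b <- ag[ag$index == idx & ag$phase == "before", ]
    a <- ag[ag$index == idx & ag$phase == "after", ]
    if (nrow(b) && nrow(a))
      cat(sprintf("  %-5s bias %7.2f -> %7.2f   ICC %.3f -> %.3f\n",
                  idx, b$bias, a$bias, b$icc, a$icc))
  }
  invisible(x)
}
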