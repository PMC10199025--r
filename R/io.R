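# On-disk formats: a sequence is a CSV point table plus a JSON sidecar
# header. Point indices are 0-based in files (apex = 0) and 1-based in the
# R API; coordinates are serialized at full double precision.

formatVersion <- "1.0"

#' Write a sequence to disk
#'
#' Writes `<base>.csv` (columns `frame`, `surface`, `point`, `x`, `y`, `z`;
#' frames 0-based contiguous, surfaces `endo`/`epi`, points 0..144) and
#' `<base>.json` (format version, subject id, protocol, cycle duration,
#' frame count, phases, grid spec, landmarks). Coordinates round-trip at
#' full double precision.
#'
#' @param seq an [LVSequence-class].
#' @param base path without extension.
#' @return `base`, invisibly.
#' @export
writeSequence <- function(seq, base) {
  np <- nGridPoints(seq@grid)
  nf <- dim(seq@endo)[3L]
  rows <- vector("list", 2L * nf)
  k <- 0L
  for (f in seq_len(nf)) for (surf in c("endo", "epi")) {
    P <- slot(seq, surf)[, , f]
    k <- k + 1L
    rows[[k]] <- data.frame(frame = f - 1L, surface = surf,
                            point = seq_len(np) - 1L,
                            x = P[, 1L], y = P[, 2L], z = P[, 3L])
  }
  tab <- do.call(rbind, rows)
  out <- data.frame(frame = tab$frame, surface = tab$surface,
                    point = tab$point,
                    x = formatC(tab$x, digits = 17, format = "g"),
                    y = formatC(tab$y, digits = 17, format = "g"),
                    z = formatC(tab$z, digits = 17, format = "g"))
  utils::write.csv(out, paste0(base, ".csv"), row.names = FALSE,
                   quote = FALSE)
  header <- list(
    format_version = formatVersion,
    subject_id = seq@subjectId,
    protocol = seq@protocol,
    cycle_duration_s = seq@cycleDuration,
    n_frames = nf,
    phases = seq@phases,
    grid = list(n_meridians = seq@grid@nMeridians,
                n_rings = seq@grid@nRings),
    landmarks = lapply(seq@landmarks, function(p)
      if (is.null(p)) NULL else as.numeric(p)))
  jsonlite::write_json(header, paste0(base, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(base)
}

#' Read a sequence from disk
#'
#' Parses and validates the `<base>.csv` / `<base>.json` pair written by
#' [writeSequence()]. Every `(frame, surface)` block must contain exactly
#' the grid's point count and frames must be contiguous from 0; violations
#' raise an error naming the offending block.
#'
#' @param base path without extension.
#' @return an [LVSequence-class].
#' @export
readSequence <- function(base) {
  csvPath <- paste0(base, ".csv"); jsonPath <- paste0(base, ".json")
  stopIfNot(file.exists(csvPath), "missing point table: ", csvPath)
  stopIfNot(file.exists(jsonPath), "missing header: ", jsonPath)
  hdr <- jsonlite::read_json(jsonPath, simplifyVector = TRUE)
  grid <- lvSurfaceGrid(hdr$grid$n_meridians, hdr$grid$n_rings)
  np <- nGridPoints(grid)
  tab <- utils::read.csv(csvPath, colClasses = c("integer", "character",
                                                 "integer", "numeric",
                                                 "numeric", "numeric"))
  nf <- hdr$n_frames
  frames <- sort(unique(tab$frame))
  if (!identical(frames, 0:(nf - 1L)))
    stop(sprintf("frames are not contiguous 0..%d in %s", nf - 1L, csvPath),
         call. = FALSE)
  endo <- array(NA_real_, c(np, 3L, nf))
  epi <- array(NA_real_, c(np, 3L, nf))
  for (f in 0:(nf - 1L)) for (surf in c("endo", "epi")) {
    blk <- tab[tab$frame == f & tab$surface == surf, ]
    if (nrow(blk) != np)
      stop(sprintf("block (frame %d, %s) has %d rows, expected %d",
                   f, surf, nrow(blk), np), call. = FALSE)
    if (!identical(sort(blk$point), 0:(np - 1L)))
      stop(sprintf("block (frame %d, %s) has invalid point indices",
                   f, surf), call. = FALSE)
    blk <- blk[order(blk$point), ]
    M <- as.matrix(blk[, c("x", "y", "z")])
    dimnames(M) <- NULL
    if (surf == "endo") endo[, , f + 1L] <- M else epi[, , f + 1L] <- M
  }
  lmIn <- hdr$landmarks
  lm <- list(apex = NULL, basalCentroid = NULL, rvInsertion = NULL)
  for (nmL in names(lm))
    if (!is.null(lmIn[[nmL]])) lm[[nmL]] <- as.numeric(lmIn[[nmL]])
  newLVSequence(hdr$subject_id, hdr$protocol, endo, epi,
                as.numeric(hdr$phases), hdr$cycle_duration_s, lm, grid)
}

#' Write / read a paired population directory
#'
#' The directory holds `manifest.json`, per-subject sequence pairs
#' (`<id>_source.*`, `<id>_target.*`) and `truth.json` with the injected
#' bias records of the generator.
#'
#' @param pop an `lv_population`.
#' @param dir output directory (created if needed).
#' @return `dir` / the population, invisibly.
#' @export
writePopulation <- function(pop, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ids <- vapply(pop$subjects, function(s) s$target@subjectId, character(1L))
  for (s in pop$subjects) {
    writeSequence(s$source, file.path(dir, paste0(s$source@subjectId,
                                                  "_source")))
    writeSequence(s$target, file.path(dir, paste0(s$target@subjectId,
                                                  "_target")))
  }
  manifest <- list(format_version = formatVersion, seed = pop$seed,
                   subjects = ids,
                   strata = vapply(pop$subjects, `[[`, character(1L),
                                   "stratum"))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  truth <- lapply(pop$subjects, function(s)
    c(list(subject = s$target@subjectId),
      s$source@metadata$truth,
      list(params = unclass(s$params), bias = unclass(pop$bias))))
  names(truth) <- ids
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname writePopulation
#' @export
readPopulation <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  subjects <- lapply(seq_along(manifest$subjects), function(i) {
    id <- manifest$subjects[i]
    list(source = readSequence(file.path(dir, paste0(id, "_source"))),
         target = readSequence(file.path(dir, paste0(id, "_target"))),
         stratum = if (!is.null(manifest$strata)) manifest$strata[i]
                   else NA_character_)
  })
  structure(list(subjects = subjects,
                 grid = subjects[[1L]]$target@grid,
                 bias = NULL, seed = manifest$seed),
            class = "lv_population")
}

#' Serialize a fitted PLS model
#'
#' Single JSON container with format version, standardization parameters,
#' weights, loadings, latent coefficients and seeds.
#'
#' @param model a [PLSModel-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeModel <- function(model, path) {
  obj <- list(format_version = formatVersion,
              n_components = model@nComponents,
              x_weights = model@xWeights, x_loadings = model@xLoadings,
              y_loadings = model@yLoadings, beta = model@beta,
              x_center = model@xCenter, x_scale = model@xScale,
              y_center = model@yCenter, y_scale = model@yScale,
              x_const_mask = model@xConstMask,
              y_const_mask = model@yConstMask,
              fold_seed = model@foldSeed)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' @rdname writeModel
#' @export
readModel <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  k <- o$n_components
  asM <- function(x) matrix(unlist(x), ncol = k)
  new("PLSModel", nComponents = as.integer(k),
      xWeights = asM(o$x_weights), xLoadings = asM(o$x_loadings),
      yLoadings = asM(o$y_loadings), beta = as.numeric(o$beta),
      scores = matrix(0, 0L, k), uScores = matrix(0, 0L, k),
      xCenter = as.numeric(o$x_center), xScale = as.numeric(o$x_scale),
      yCenter = as.numeric(o$y_center), yScale = as.numeric(o$y_scale),
      xConstMask = as.logical(o$x_const_mask),
      yConstMask = as.logical(o$y_const_mask),
      iterations = integer(k),
      foldSeed = if (is.null(o$fold_seed)) NA_real_
                 else as.numeric(o$fold_seed))
}

#' Export a frame as a Wavefront OBJ mesh
#'
#' Optional visualization helper: writes the triangulated surface (mm
#' coordinates) of one frame of one surface.
#'
#' @param seq an [LVSequence-class].
#' @param frame frame index.
#' @param surface `"endo"` or `"epi"`.
#' @param path output `.obj` file.
#' @return `path`, invisibly.
#' @export
writeObj <- function(seq, frame, surface = c("endo", "epi"), path) {
  surface <- match.arg(surface)
  P <- slot(seq, surface)[, , frame]
  tri <- seq@grid@triangles
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("v %.10g %.10g %.10g", P[, 1L], P[, 2L], P[, 3L]), con)
  writeLines(sprintf("f %d %d %d", tri[, 1L], tri[, 2L], tri[, 3L]), con)
  invisible(path)
}
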