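#' Seed voxels of the callosal areas
#'
#' One seed per CC-area voxel on the midsagittal plane of the volume.
#'
#' @param template a \code{\linkS4class{CCLabelMap}} (midsagittal labels).
#' @param xIndex index of the midsagittal plane along the x axis.
#' @return data.frame with columns \code{x}, \code{y}, \code{z},
#'   \code{area}.
#' @export
ccSeedVoxels <- function(template, xIndex) {
  stopifnot(is(template, "CCLabelMap"))
  idx <- which(ccLabels(template) > 0L, arr.ind = TRUE)
  data.frame(x = as.integer(xIndex), y = idx[, 1], z = idx[, 2],
             area = ccLabels(template)[idx])
}

# principal eigenvector of the tensor at a voxel, with memoization
principalDirection <- function(flat, lin, cache) {
  key <- as.character(lin)
  v <- cache[[key]]
  if (!is.null(v)) return(v)
  D <- matrix(c(flat[lin, 1], flat[lin, 4], flat[lin, 5],
                flat[lin, 4], flat[lin, 2], flat[lin, 6],
                flat[lin, 5], flat[lin, 6], flat[lin, 3]), 3, 3)
  v <- eigen(D, symmetric = TRUE)$vectors[, 1]
  cache[[key]] <- v
  v
}

#' Deterministic streamline tractography from callosal seeds
#'
#' Conventional streamline tracking on a (typically control-averaged)
#' tensor volume: from every seed, bidirectional integration along the
#' principal eigenvector with nearest-neighbor tensor lookup, the
#' eigenvector sign chosen to continue the previous direction. A
#' trajectory terminates when the local FA falls below
#' \code{faThreshold}, when the dot product of consecutive unit step
#' directions falls below \code{dotThreshold} (a curvature limit of
#' arccos(0.9) ~ 25.8 degrees per step at the default), at the volume
#' boundary, or after \code{maxSteps} steps per direction. Streamlines
#' shorter than two steps are discarded.
#'
#' @param tensor a \code{\linkS4class{TensorVolume}}.
#' @param seeds data.frame with columns \code{x}, \code{y}, \code{z} (and
#'   optionally \code{area}), as from \code{\link{ccSeedVoxels}}; voxel
#'   indices must lie inside the volume.
#' @param faThreshold FA stopping threshold (default 0.2).
#' @param dotThreshold minimum dot product of consecutive unit step
#'   directions (default 0.9).
#' @param stepMm step size in mm; must be positive and no larger than the
#'   smallest voxel dimension.
#' @param maxSteps maximum number of steps per direction.
#' @return a named list of \code{\linkS4class{TractSet}} objects, one per
#'   area present in \code{seeds} (a single unnamed entry with area code 1
#'   when \code{seeds} has no \code{area} column).
#' @export
trackStreamlines <- function(tensor, seeds, faThreshold = 0.2,
                             dotThreshold = 0.9, stepMm = 1,
                             maxSteps = 300L) {
  stopifnot(is(tensor, "TensorVolume"))
  seeds <- as.data.frame(seeds)
  if (!nrow(seeds)) stop("empty seed set")
  if (is.null(seeds$area)) seeds$area <- 1L
  dims <- dim(tensor@D)[1:3]
  pix <- tensor@pixdim
  if (stepMm <= 0 || stepMm > min(pix))
    stop("stepMm must be positive and no larger than the voxel size")
  if (any(seeds$x < 1 | seeds$x > dims[1] | seeds$y < 1 |
          seeds$y > dims[2] | seeds$z < 1 | seeds$z > dims[3]))
    stop("seeds must lie inside the volume")
  nvox <- prod(dims)
  flat <- matrix(tensor@D, nvox, 6)
  fa <- as.vector(faValues(computeFA(tensor)))
  cache <- new.env(parent = emptyenv())
  linOf <- function(v) (v[3] - 1) * dims[1] * dims[2] + (v[2] - 1) * dims[1] + v[1]
  nearest <- function(posMm) floor(posMm / pix) + 1
  inGrid <- function(v) all(v >= 1) && all(v <= dims)

  trackOneSide <- function(startMm, dir0) {
    pts <- matrix(numeric(0), 0, 3)
    pos <- startMm
    dir <- dir0
    reason <- "max_steps"
    for (s in seq_len(maxSteps)) {
      cand <- pos + stepMm * dir
      vox <- nearest(cand)
      if (!inGrid(vox)) { reason <- "boundary"; break }
      lin <- linOf(vox)
      if (is.na(fa[lin]) || fa[lin] < faThreshold) { reason <- "low_fa"; break }
      pts <- rbind(pts, cand)
      newDir <- principalDirection(flat, lin, cache)
      if (sum(newDir * dir) < 0) newDir <- -newDir
      if (sum(newDir * dir) < dotThreshold) { reason <- "curvature"; break }
      pos <- cand
      dir <- newDir
    }
    list(pts = pts, reason = reason)
  }

  out <- list()
  for (a in sort(unique(seeds$area))) {
    sa <- seeds[seeds$area == a, , drop = FALSE]
    lines <- list()
    reasons <- matrix(character(0), 0, 2)
    for (i in seq_len(nrow(sa))) {
      vox <- c(sa$x[i], sa$y[i], sa$z[i])
      lin <- linOf(vox)
      if (is.na(fa[lin]) || fa[lin] < faThreshold) next
      startMm <- (vox - 0.5) * pix
      dir0 <- principalDirection(flat, lin, cache)
      fwd <- trackOneSide(startMm, dir0)
      bwd <- trackOneSide(startMm, -dir0)
      if (nrow(fwd$pts) + nrow(bwd$pts) < 2L) next
      pts <- rbind(bwd$pts[rev(seq_len(nrow(bwd$pts))), , drop = FALSE],
                   matrix(startMm, 1, 3), fwd$pts)
      lines[[length(lines) + 1L]] <- unname(pts)
      reasons <- rbind(reasons, c(bwd$reason, fwd$reason))
    }
    visited <- matrix(integer(0), 0, 3)
    if (length(lines)) {
      allPts <- do.call(rbind, lines)
      vox <- floor(sweep(allPts, 2, pix, "/")) + 1
      visited <- unique(matrix(as.integer(vox), ncol = 3))
    }
    colnames(visited) <- c("x", "y", "z")
    out[[as.character(a)]] <- new("TractSet", area = as.integer(a),
                                  streamlines = lines,
                                  terminations = reasons, visited = visited,
                                  stepMm = stepMm)
  }
  out
}

#' Per-subject tract FA means (TFAS first stage)
#'
#' Mean FA over a tract's visited voxels, not considering FA values below
#' \code{faThreshold} (cortical gray matter reaches FA values up to 0.2,
#' hence the default cut at 0.2). Subjects without any supra-threshold
#' voxel in a tract get NA with a warning.
#'
#' @param faMaps named list of \code{\linkS4class{FAMap}} objects, one per
#'   subject.
#' @param tracts list of \code{\linkS4class{TractSet}} objects (one per
#'   area) defined on the same grid.
#' @param faThreshold exclusion threshold (default 0.2).
#' @return data.frame with columns \code{subject_id}, \code{area},
#'   \code{fa_tract}, \code{n_voxels}.
#' @export
tfasSubjectMeans <- function(faMaps, tracts, faThreshold = 0.2) {
  ids <- names(faMaps)
  if (is.null(ids)) ids <- as.character(seq_along(faMaps))
  areaNames <- c("I", "II", "III", "IV", "V")
  rows <- list()
  for (t in tracts) {
    vis <- visitedVoxels(t)
    for (i in seq_along(faMaps)) {
      vals <- faValues(faMaps[[i]])[vis]
      vals <- vals[!is.na(vals) & vals >= faThreshold]
      if (!length(vals))
        warning("subject ", ids[i], " has no supra-threshold voxel in ",
                "area ", areaNames[t@area], "; mean set to missing")
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = ids[i], area = areaNames[t@area],
        fa_tract = if (length(vals)) mean(vals) else NA_real_,
        n_voxels = length(vals))
    }
  }
  do.call(rbind, rows)
}

#' Tractwise fractional anisotropy statistics (TFAS)
#'
#' Combines the per-subject tract FA means with Bonferroni-corrected
#' two-sample Student's t-tests per area for each group contrast.
#'
#' @inheritParams tfasSubjectMeans
#' @param subjects data.frame with columns \code{subject_id} and
#'   \code{group}.
#' @param contrasts contrast list as in \code{\link{groupCompare}}.
#' @param m Bonferroni family size (default: contrasts x areas).
#' @return list with \code{subjectMeans} and the test table \code{tests}.
#' @export
tfas <- function(faMaps, tracts, subjects, faThreshold = 0.2,
                 contrasts = defaultContrasts(), m = NULL) {
  means <- tfasSubjectMeans(faMaps, tracts, faThreshold)
  panel <- merge(means, subjects[, c("subject_id", "group")],
                 by = "subject_id")
  panel$value <- panel$fa_tract
  tests <- groupCompare(panel, contrasts = contrasts, m = m)
  list(subjectMeans = means, tests = tests)
}
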