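#' Align a volume to the AC/PC line
#'
#' Rigid + isotropic-scale alignment from anatomical landmarks: the
#' anterior commissure (AC) to posterior commissure (PC) direction is
#' mapped onto the anterior-posterior image axis (second array axis,
#' anterior at low index) and the interhemispheric plane onto the
#' midsagittal coordinate plane of the first axis. The volume is
#' resampled trilinearly onto its own grid; the applied transform is
#' stored with the result.
#'
#' @param volume numeric 3-D array (x = left-right, y = AP, z = IS).
#' @param pixdim numeric(3) voxel spacing in mm.
#' @param acPoint,pcPoint mm coordinates (numeric(3)) of the anterior and
#'   posterior commissures; must differ.
#' @param normal unit normal of the interhemispheric plane; must not be
#'   parallel to the AC-PC direction.
#' @param targetAcpcMm optional AC-PC distance to scale to (isotropic);
#'   NULL keeps the native distance (scale 1).
#' @return an \code{\linkS4class{AlignedVolume}}.
#' @export
alignACPC <- function(volume, pixdim, acPoint, pcPoint, normal = c(1, 0, 0),
                      targetAcpcMm = NULL) {
  acPoint <- as.numeric(acPoint); pcPoint <- as.numeric(pcPoint)
  v <- pcPoint - acPoint
  len <- sqrt(sum(v^2))
  if (len < 1e-9) stop("degenerate landmarks: AC and PC coincide")
  ey <- v / len
  nrm <- as.numeric(normal)
  nlen <- sqrt(sum(nrm^2))
  if (nlen < 1e-9) stop("degenerate landmarks: zero interhemispheric normal")
  nrm <- nrm / nlen
  ex <- nrm - sum(nrm * ey) * ey
  exlen <- sqrt(sum(ex^2))
  if (exlen < 1e-6)
    stop("degenerate landmarks: normal parallel to the AC-PC direction")
  ex <- ex / exlen
  ez <- c(ex[2] * ey[3] - ex[3] * ey[2],
          ex[3] * ey[1] - ex[1] * ey[3],
          ex[1] * ey[2] - ex[2] * ey[1])
  R <- rbind(ex, ey, ez)
  s <- if (is.null(targetAcpcMm)) 1 else targetAcpcMm / len
  d <- dim(volume)
  centerMm <- (d - 1) / 2 * pixdim
  midMm <- (acPoint + pcPoint) / 2
  # forward map: p_aligned = s R (p - mid) + center
  A <- s * R
  tvec <- centerMm - A %*% midMm
  Tm <- rbind(cbind(A, tvec), c(0, 0, 0, 1))
  # resample: input coordinate for each output voxel via the inverse map
  grid <- as.matrix(expand.grid(x = seq_len(d[1]), y = seq_len(d[2]),
                                z = seq_len(d[3])))
  outMm <- sweep(grid - 1, 2, pixdim, "*")
  inMm <- t(solve(A) %*% (t(outMm) - as.vector(tvec)))
  inVox <- sweep(inMm, 2, pixdim, "/") + 1
  vals <- trilinearSample(volume, inVox, outside = 0)
  new("AlignedVolume", data = array(vals, d), pixdim = pixdim,
      transform = Tm)
}

#' Extract the midsagittal slice
#'
#' Returns the sagittal slice at the interhemispheric plane: the central
#' slice along the first (left-right) axis, or the mean of the two
#' central slices when that axis has even length.
#'
#' @param volume an \code{\linkS4class{AlignedVolume}} or a 3-D array.
#' @return numeric matrix (AP x IS).
#' @export
extractMidsagittal <- function(volume) {
  arr <- if (is(volume, "AlignedVolume")) volume@data else volume
  d <- dim(arr)
  if (length(d) != 3 || d[1] < 3)
    stop("volume must be 3-D with at least 3 sagittal slices")
  if (d[1] %% 2 == 1) {
    arr[(d[1] + 1) / 2, , ]
  } else {
    (arr[d[1] / 2, , ] + arr[d[1] / 2 + 1, , ]) / 2
  }
}

#' Segment the corpus callosum on a midsagittal slice
#'
#' Otsu's threshold is estimated within a region of interest (by default
#' the central 50 percent of each image dimension); the mask is the largest
#' 8-connected supra-threshold component of the whole slice, with
#' enclosed holes of up to \code{holeMax} voxels filled. If the component
#' touches the image border the result carries a \code{"border_contact"}
#' flag.
#'
#' @param image numeric matrix (AP x IS).
#' @param roiHint optional integer(4) bounding box (row1, row2, col1,
#'   col2) replacing the default central ROI.
#' @param roiFrac fraction of each dimension covered by the default ROI.
#' @param holeMax largest enclosed hole (voxels) that is filled.
#' @param fixedThreshold optional numeric threshold overriding Otsu.
#' @return logical matrix with attributes \code{threshold} and
#'   \code{flags}.
#' @export
segmentCC <- function(image, roiHint = NULL, roiFrac = 0.5, holeMax = 3L,
                      fixedThreshold = NULL) {
  d <- dim(image)
  if (is.null(roiHint)) {
    half <- roiFrac / 2
    roiHint <- c(floor(d[1] * (0.5 - half)) + 1L, ceiling(d[1] * (0.5 + half)),
                 floor(d[2] * (0.5 - half)) + 1L, ceiling(d[2] * (0.5 + half)))
  }
  roi <- image[roiHint[1]:roiHint[2], roiHint[3]:roiHint[4]]
  if (is.null(fixedThreshold)) {
    rng <- range(roi)
    if (diff(rng) <= 0)
      stop("no intensity threshold separates classes in the ROI ",
           "(constant image)")
    thr <- EBImage::otsu(EBImage::Image((roi - rng[1]) / diff(rng)),
                         range = c(0, 1), levels = 256)
    thr <- rng[1] + thr * diff(rng)
  } else thr <- fixedThreshold
  supra <- image > thr
  if (!any(supra)) stop("empty supra-threshold set")
  lab <- label8Connected(supra)
  sizes <- tabulate(lab[lab > 0L])
  mask <- lab == which.max(sizes)
  # fill enclosed holes of up to holeMax voxels (4-connected background
  # components not touching the image border, the dual of 8-connected
  # foreground)
  bg <- label8Connected(!mask)  # 8-connectivity is conservative for holes
  if (max(bg) > 1L) {
    border <- unique(c(bg[1, ], bg[d[1], ], bg[, 1], bg[, d[2]]))
    border <- border[border > 0L]
    holeSizes <- tabulate(bg[bg > 0L])
    for (h in setdiff(seq_along(holeSizes), border))
      if (holeSizes[h] <= holeMax) mask[bg == h] <- TRUE
  }
  flags <- character(0)
  if (any(mask[1, ]) || any(mask[d[1], ]) || any(mask[, 1]) ||
      any(mask[, d[2]]))
    flags <- "border_contact"
  attr(mask, "threshold") <- thr
  attr(mask, "flags") <- flags
  mask
}

#' Subdivide a CC mask into Hofer-Frahm areas I-V
#'
#' Cuts orthogonal to the anterior-posterior axis at fractions 1/6, 1/2,
#' 2/3 and 3/4 of the bounding-box AP extent (anterior = 0). A voxel
#' belongs to the stripe containing its column center; a center falling
#' exactly on a cut goes to the anterior stripe.
#'
#' @param mask logical matrix (AP x IS), anterior at row 1.
#' @param pixdim numeric(2) in-plane voxel size in mm.
#' @param fractions the four cut fractions.
#' @return a \code{\linkS4class{CCLabelMap}}.
#' @export
subdivideHoferFrahm <- function(mask, pixdim = c(1, 1),
                                fractions = c(1/6, 1/2, 2/3, 3/4)) {
  if (!is.logical(mask)) mask <- mask > 0
  if (!any(mask)) stop("empty mask")
  rows <- which(rowSums(mask) > 0)
  if (diff(range(rows)) + 1 < 12)
    stop("mask anterior-posterior extent below 12 voxels; ",
         "fraction boundaries would collide")
  flags <- attr(mask, "flags")
  labels <- hfAssignLabels(mask, fractions)
  attributes(mask) <- list(dim = dim(mask))
  new("CCLabelMap", mask = mask, labels = labels, pixdim = pixdim,
      fractions = fractions,
      flags = if (is.null(flags)) character(0) else flags)
}

#' Planimetry of a labeled CC mask
#'
#' Per-area voxel counts, physical areas and ratios of area voxels to the
#' total CC voxel count.
#'
#' @param labelMap a \code{\linkS4class{CCLabelMap}}.
#' @return data.frame with columns \code{area}, \code{count}, \code{mm2},
#'   \code{ratio}; total CC area in attribute \code{total_mm2}, empty
#'   areas flagged in attribute \code{flags}.
#' @export
planimetry <- function(labelMap) {
  stopifnot(is(labelMap, "CCLabelMap"))
  counts <- tabulate(ccLabels(labelMap)[ccMask(labelMap)], 5L)
  total <- sum(counts)
  voxArea <- prod(labelMap@pixdim)
  out <- data.frame(area = c("I", "II", "III", "IV", "V"),
                    count = counts, mm2 = counts * voxArea,
                    ratio = counts / total)
  attr(out, "total_mm2") <- total * voxArea
  if (any(counts == 0L)) {
    attr(out, "flags") <- "empty_area"
    warning("at least one callosal area contains no voxels")
  }
  out
}
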