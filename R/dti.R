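#' Fit diffusion tensors by log-linear least squares
#'
#' Voxelwise ordinary least-squares fit of
#' \eqn{\ln S = \ln S_0 - b\, g^T D g} across all volumes. Requires at
#' least six non-zero-b volumes and one b = 0 volume. Voxels with any
#' non-positive signal are flagged and excluded (their tensor is NA).
#'
#' @param dwi 4-D array (x, y, z, volume).
#' @param bvals,bvecs b-table (FSL dialect: b-values vector, n x 3 unit
#'   vectors).
#' @param mask optional logical 3-D array restricting the fit.
#' @param pixdim numeric(3) voxel size in mm.
#' @return a \code{\linkS4class{TensorVolume}}; the number of excluded
#'   voxels is in attribute \code{n_excluded}.
#' @export
fitTensor <- function(dwi, bvals, bvecs, mask = NULL, pixdim = c(1, 1, 1)) {
  d <- dim(dwi)
  stopifnot(length(d) == 4)
  bvecs <- as.matrix(bvecs)
  if (sum(bvals > 0) < 6)
    stop("at least 6 non-zero-b volumes are required")
  if (sum(bvals == 0) < 1)
    stop("at least one b = 0 volume is required")
  nvox <- prod(d[1:3])
  S <- matrix(dwi, nvox, d[4])
  keep <- if (is.null(mask)) rep(TRUE, nvox) else as.vector(mask)
  pos <- rowSums(S <= 0) == 0L
  excl <- keep & !pos
  keep <- keep & pos
  # design: ln S = X beta with X = [1, -b gx^2, -b gy^2, -b gz^2,
  #                                 -2 b gx gy, -2 b gx gz, -2 b gy gz]
  X <- cbind(1, -bvals * bvecs[, 1]^2, -bvals * bvecs[, 2]^2,
             -bvals * bvecs[, 3]^2, -2 * bvals * bvecs[, 1] * bvecs[, 2],
             -2 * bvals * bvecs[, 1] * bvecs[, 3],
             -2 * bvals * bvecs[, 2] * bvecs[, 3])
  pinv <- solve(crossprod(X), t(X))
  flat <- matrix(NA_real_, nvox, 6)
  if (any(keep)) {
    beta <- pinv %*% t(log(S[keep, , drop = FALSE]))
    flat[keep, ] <- t(beta[2:7, , drop = FALSE])
  }
  D <- array(flat, c(d[1:3], 6L))
  out <- new("TensorVolume", D = D, pixdim = pixdim)
  attr(out, "n_excluded") <- sum(excl)
  out
}

#' Fractional anisotropy map of a tensor volume
#'
#' \eqn{FA = \sqrt{3/2}\,\lVert\lambda - \bar\lambda\rVert / \lVert\lambda\rVert}
#' from the tensor eigenvalues; negative eigenvalues are clamped to zero
#' (counted in the result) and the FA of an all-zero tensor is defined
#' as 0. Voxels with NA tensors give NA.
#'
#' @param tensor a \code{\linkS4class{TensorVolume}}.
#' @return an \code{\linkS4class{FAMap}}.
#' @export
computeFA <- function(tensor) {
  stopifnot(is(tensor, "TensorVolume"))
  d <- dim(tensor@D)
  nvox <- prod(d[1:3])
  flat <- matrix(tensor@D, nvox, 6)
  ok <- rowSums(is.na(flat)) == 0L
  fa <- rep(NA_real_, nvox)
  if (any(ok)) {
    ev <- symEigenvalues3(flat[ok, 1], flat[ok, 2], flat[ok, 3],
                          flat[ok, 4], flat[ok, 5], flat[ok, 6])
    nClamped <- sum(ev$l3 < 0 | ev$l2 < 0 | ev$l1 < 0)
    fa[ok] <- faFromEigenvalues(pmax(ev$l1, 0), pmax(ev$l2, 0),
                                pmax(ev$l3, 0))
  } else nClamped <- 0L
  new("FAMap", values = array(fa, d[1:3]), pixdim = tensor@pixdim,
      smoothed = FALSE, ageCorrected = FALSE, nClamped = as.integer(nClamped))
}

#' Gaussian smoothing of an FA map
#'
#' Separable Gaussian convolution with \eqn{\sigma = FWHM / (2\sqrt{2\ln 2})}
#' per axis in mm (converted to voxels via the voxel spacing), reflective
#' boundary; values are re-clamped to the unit interval.
#'
#' @param fa an \code{\linkS4class{FAMap}}.
#' @param fwhmMm full width at half maximum in mm (default 8).
#' @return the smoothed \code{\linkS4class{FAMap}}.
#' @export
smoothFA <- function(fa, fwhmMm = 8) {
  stopifnot(is(fa, "FAMap"))
  if (fwhmMm <= 0) stop("FWHM must be positive")
  sigmaMm <- fwhmMm / (2 * sqrt(2 * log(2)))
  sm <- smoothGaussianArray(fa@values, sigmaMm / fa@pixdim)
  sm <- pmin(pmax(sm, 0), 1)
  initialize(fa, values = sm, smoothed = TRUE)
}

#' Correct FA maps for the covariate age
#'
#' Fits the voxelwise ordinary least-squares slope of FA on age in the
#' control subjects only, then replaces every subject's voxel value by
#' its residual plus the prediction at the cohort mean age (i.e. subtracts
#' \eqn{\beta(v)\,(age_i - \bar{age})}).
#'
#' @param faMaps list of \code{\linkS4class{FAMap}} objects (one per
#'   subject, common grid).
#' @param ages numeric vector of ages (years), one per subject.
#' @param controlIdx integer indices of the control subjects; at least 3
#'   controls with distinct ages are required.
#' @return list of corrected \code{\linkS4class{FAMap}} objects.
#' @export
ageCorrect <- function(faMaps, ages, controlIdx) {
  stopifnot(length(faMaps) == length(ages))
  if (length(controlIdx) < 3)
    stop("at least 3 controls are required for the age fit")
  aC <- ages[controlIdx]
  if (stats::sd(aC) == 0) stop("control ages are constant")
  d <- dim(faMaps[[1]]@values)
  Fc <- vapply(faMaps[controlIdx], function(m) as.vector(m@values),
               numeric(prod(d)))
  aCc <- aC - mean(aC)
  beta <- (Fc %*% aCc) / sum(aCc^2)
  meanAge <- mean(ages)
  lapply(seq_along(faMaps), function(i) {
    v <- faMaps[[i]]@values - array(beta * (ages[i] - meanAge), d)
    initialize(faMaps[[i]], values = pmin(pmax(v, 0), 1),
               ageCorrected = TRUE)
  })
}

#' Average tensor dataset of the control group
#'
#' Component-wise arithmetic mean of the control tensor volumes; the
#' result is the dataset streamline tracking operates on.
#'
#' @param tensors list of \code{\linkS4class{TensorVolume}} objects
#'   sharing one grid.
#' @return a \code{\linkS4class{TensorVolume}}.
#' @export
averageControlDataset <- function(tensors) {
  stopifnot(length(tensors) >= 1)
  d <- dim(tensors[[1]]@D)
  pix <- tensors[[1]]@pixdim
  for (t in tensors)
    if (!all(dim(t@D) == d) || !all(t@pixdim == pix))
      stop("tensor volumes do not share one grid")
  acc <- array(0, d)
  for (t in tensors) acc <- acc + t@D
  new("TensorVolume", D = acc / length(tensors), pixdim = pix)
}
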