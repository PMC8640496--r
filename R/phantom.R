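#' Phantom geometry for the synthetic corpus callosum cohort
#'
#' Describes the simulated volume: an arch-shaped midsagittal CC (half
#' elliptical annulus) in the y (anterior-posterior) / z (inferior-
#' superior) plane, plus one U-shaped commissural fiber bundle per
#' Hofer-Frahm area sweeping left-right through the volume. Axis order is
#' \code{[x, y, z]} with x the left-right axis (midsagittal plane at the
#' central x index) and anterior at low y.
#'
#' @param dims integer(3) volume dimensions; the x dimension should be odd
#'   so the midsagittal plane coincides with a voxel plane.
#' @param pixdim numeric(3) voxel spacing in mm (isotropic default 2 mm,
#'   the in-plane resolution typical of clinical DTI).
#' @param apLength anterior-posterior extent of the CC arch in voxels.
#' @param height arch height in voxels (outer ellipse semi-axis).
#' @param thickness arch thickness in voxels; must be >= 2.
#' @param center optional numeric(2) (y, z) of the arch base center;
#'   defaults to the y middle and 20 percent of the z extent.
#' @param bundleRadiusZ tube cross-section semi-axis (voxels) in z.
#' @param bundleDroop how far (voxels) each bundle arcs downward towards
#'   the lateral volume faces; controls the (gentle) curvature tracked
#'   streamlines must follow.
#' @return an object of class \code{"phantomGeometry"} (a validated list).
#' @export
phantomGeometry <- function(dims = c(15L, 56L, 36L), pixdim = c(2, 2, 2),
                            apLength = 44, height = 16, thickness = 6,
                            center = NULL, bundleRadiusZ = 2.5,
                            bundleDroop = 4) {
  if (thickness < 2)
    stop("degenerate geometry: arch thickness must be at least 2 voxels")
  if (height <= thickness)
    stop("degenerate geometry: arch height must exceed its thickness")
  if (length(dims) != 3 || any(dims < 3))
    stop("dims must be three dimensions of at least 3 voxels")
  if (dims[1] %% 2 == 0)
    stop("the x (left-right) dimension must be odd so the midsagittal ",
         "plane falls on a voxel plane")
  if (any(pixdim <= 0)) stop("pixdim must be positive")
  if (is.null(center))
    center <- c((dims[2] + 1) / 2, max(2, round(dims[3] * 0.2)))
  g <- list(dims = as.integer(dims), pixdim = as.numeric(pixdim),
            apLength = apLength, height = height, thickness = thickness,
            center = center, bundleRadiusZ = bundleRadiusZ,
            bundleDroop = bundleDroop)
  class(g) <- "phantomGeometry"
  g
}

# Shared Hofer-Frahm column labeling: a voxel belongs to the stripe whose
# half-open interval contains its column center; exact ties go anterior.
hfAssignLabels <- function(mask, fractions = c(1/6, 1/2, 2/3, 3/4)) {
  rows <- which(rowSums(mask) > 0)
  r1 <- min(rows)
  extent <- max(rows) - r1 + 1
  bounds <- extent * fractions
  lab <- matrix(0L, nrow(mask), ncol(mask))
  idx <- which(mask, arr.ind = TRUE)
  x <- idx[, 1] - r1 + 0.5
  lab[idx] <- 1L + as.integer(rowSums(outer(x, bounds, ">")))
  lab
}

#' Build the midsagittal CC template of a phantom geometry
#'
#' Rasterizes the arch-shaped CC mask on the midsagittal plane and labels
#' every mask voxel with its Hofer-Frahm area (cuts at fractions 1/6, 1/2,
#' 2/3, 3/4 of the anterior-posterior bounding-box extent).
#'
#' @param geometry a \code{\link{phantomGeometry}}.
#' @return a \code{\linkS4class{CCLabelMap}}.
#' @export
makeCCTemplate <- function(geometry) {
  stopifnot(inherits(geometry, "phantomGeometry"))
  ny <- geometry$dims[2]; nz <- geometry$dims[3]
  y0 <- geometry$center[1]; z0 <- geometry$center[2]
  aOut <- geometry$apLength / 2
  bOut <- geometry$height
  aIn <- aOut - geometry$thickness
  bIn <- geometry$height - geometry$thickness
  dy <- matrix(seq_len(ny) - y0, ny, nz)
  dz <- matrix(rep(seq_len(nz) - z0, each = ny), ny, nz)
  mask <- dz >= 0 &
    (dy / aOut)^2 + (dz / bOut)^2 <= 1 &
    (dy / aIn)^2 + (dz / bIn)^2 >= 1
  if (!any(mask)) stop("degenerate geometry: empty CC mask")
  rows <- which(rowSums(mask) > 0)
  if (diff(range(rows)) + 1 < 30)
    stop("degenerate geometry: CC anterior-posterior extent below 30 voxels")
  new("CCLabelMap", mask = mask, labels = hfAssignLabels(mask),
      pixdim = geometry$pixdim[2:3], fractions = c(1/6, 1/2, 2/3, 3/4),
      flags = character(0))
}

# Per-area U-shaped bundle: voxel list + unit tangents. Anchored at the
# per-column centroid of the area's middle column so the anchor is inside
# the mask; the y half-width stays inside the area's own column range so
# each bundle meets its area and no other.
makePhantomBundles <- function(geometry, template = makeCCTemplate(geometry)) {
  dims <- geometry$dims
  nx <- dims[1]
  xmid <- (nx + 1) / 2
  halfSpan <- (nx - 1) / 2
  lab <- ccLabels(template)
  bundles <- vector("list", 5L)
  for (a in 1:5) {
    idx <- which(lab == a, arr.ind = TRUE)
    yr <- range(idx[, 1])
    ycol <- round(mean(yr))
    zc <- mean(idx[idx[, 1] == ycol, 2])
    ry <- max(0.8, min(3, min(ycol - yr[1], yr[2] - ycol) + 0.49))
    rz <- geometry$bundleRadiusZ
    ys <- seq(max(1, floor(ycol - ry)), min(dims[2], ceiling(ycol + ry)))
    zs <- seq(max(1, floor(zc - rz - geometry$bundleDroop)),
              min(dims[3], ceiling(zc + rz)))
    grid <- expand.grid(x = seq_len(nx), y = ys, z = zs)
    u <- (grid$x - xmid) / halfSpan
    zCurve <- zc - geometry$bundleDroop * u^2
    inside <- ((grid$y - ycol) / ry)^2 + ((grid$z - zCurve) / rz)^2 <= 1
    vox <- as.matrix(grid[inside, , drop = FALSE])
    slope <- -2 * geometry$bundleDroop * u[inside] / halfSpan
    tan <- cbind(geometry$pixdim[1], 0, geometry$pixdim[3] * slope)
    tan <- tan / sqrt(rowSums(tan^2))
    onPlane <- vox[, 1] == xmid
    hit <- lab[vox[onPlane, 2:3, drop = FALSE]]
    hit <- hit[hit > 0L]
    if (!length(hit) || any(hit != a))
      stop("bundle construction violated area exclusivity for area ", a)
    bundles[[a]] <- list(area = a, voxels = vox, tangents = tan)
  }
  bundles
}

#' Synthesize a midsagittal T1-weighted slice
#'
#' Draws CC voxels as \code{baseIntensity} plus an area-specific zero-mean
#' texture perturbation plus Gaussian noise; the background is darker by
#' \code{contrastMargin} of the base intensity. The texture perturbation
#' has a rough (voxelwise white) component scaled per area by
#' \code{amplitude}, optionally riding on a fixed-amplitude smooth
#' low-frequency component (\code{smoothAmplitude}); the smooth component
#' sets a stable intensity range so that increasing the rough amplitude
#' strictly increases co-occurrence inhomogeneity even under per-area
#' min-max quantization.
#'
#' @param template a \code{\linkS4class{CCLabelMap}}.
#' @param baseIntensity mean CC intensity (arbitrary units).
#' @param amplitude per-area rough perturbation amplitude; scalar or
#'   length-5 vector, all values >= 0.
#' @param noiseSd global Gaussian noise SD (>= 0).
#' @param seed optional RNG seed (the draw is deterministic given it).
#' @param smoothAmplitude SD of the fixed smooth intensity component
#'   inside the CC (default 0).
#' @param smoothScale correlation length (voxels) of the smooth component.
#' @param contrastMargin background intensity deficit as a fraction of
#'   \code{baseIntensity}.
#' @return numeric matrix (same dimensions as the template).
#' @export
synthesizeT1wSlice <- function(template, baseIntensity = 120,
                               amplitude = 0, noiseSd = 0, seed = NULL,
                               smoothAmplitude = 0, smoothScale = 3,
                               contrastMargin = 0.5) {
  stopifnot(is(template, "CCLabelMap"))
  if (any(amplitude < 0)) stop("perturbation amplitudes must be >= 0")
  if (noiseSd < 0) stop("noiseSd must be >= 0")
  if (length(amplitude) == 1) amplitude <- rep(amplitude, 5)
  stopifnot(length(amplitude) == 5)
  if (!is.null(seed)) set.seed(seed)
  mask <- ccMask(template)
  lab <- ccLabels(template)
  d <- dim(mask)
  img <- matrix(baseIntensity * (1 - contrastMargin), d[1], d[2])
  img[mask] <- baseIntensity
  if (smoothAmplitude > 0) {
    field <- smoothGaussianArray(matrix(stats::rnorm(prod(d)), d[1], d[2]),
                                 c(smoothScale, smoothScale))
    field <- field - mean(field[mask])
    s <- stats::sd(field[mask])
    if (s > 0) field <- field / s
    img[mask] <- img[mask] + smoothAmplitude * field[mask]
  }
  if (any(amplitude > 0)) {
    rough <- matrix(stats::rnorm(prod(d)), d[1], d[2])
    img[mask] <- img[mask] + amplitude[lab[mask]] * rough[mask]
  }
  if (noiseSd > 0) img <- img + matrix(stats::rnorm(prod(d), sd = noiseSd),
                                       d[1], d[2])
  img
}

#' Synthesize a diffusion tensor volume with callosal bundles
#'
#' Voxels inside a bundle receive a prolate (cigar-shaped) tensor whose
#' principal axis follows the local bundle tangent and whose eigenvalues
#' hit the requested per-area FA at mean diffusivity \code{md}; background
#' voxels receive an axially symmetric tensor with \code{backgroundFa}
#' (exactly isotropic when 0). Optional zero-mean Gaussian noise on the
#' six tensor components models measurement variability.
#'
#' @param geometry a \code{\link{phantomGeometry}}.
#' @param faByArea numeric(5) target FA per bundle, each in [0, 1).
#' @param backgroundFa background FA (default 0.05, below the 0.2 tracking
#'   stop threshold).
#' @param md mean diffusivity in mm^2/s.
#' @param noiseSd SD of component noise (mm^2/s), default 0.
#' @param seed optional RNG seed for the noise.
#' @param bundles optional precomputed \code{makePhantomBundles} output.
#' @return a \code{\linkS4class{TensorVolume}}.
#' @export
synthesizeTensorVolume <- function(geometry, faByArea, backgroundFa = 0.05,
                                   md = 7e-4, noiseSd = 0, seed = NULL,
                                   bundles = NULL) {
  stopifnot(inherits(geometry, "phantomGeometry"))
  if (length(faByArea) == 1) faByArea <- rep(faByArea, 5)
  stopifnot(length(faByArea) == 5)
  if (any(faByArea < 0) || any(faByArea >= 1) ||
      backgroundFa < 0 || backgroundFa >= 1)
    stop("requested FA unreachable with positive-definite eigenvalues")
  if (is.null(bundles)) bundles <- makePhantomBundles(geometry)
  dims <- geometry$dims
  D <- array(0, c(dims, 6L))
  nvox <- prod(dims)
  flat <- matrix(0, nvox, 6)
  if (backgroundFa == 0) {
    flat[, 1:3] <- md
  } else {
    bg <- axialEigenvalues(backgroundFa, md)
    flat[, 1] <- bg$radial; flat[, 2] <- bg$radial; flat[, 3] <- bg$axial
  }
  for (b in bundles) {
    ev <- axialEigenvalues(faByArea[b$area], md)
    lin <- (b$voxels[, 3] - 1) * dims[1] * dims[2] +
      (b$voxels[, 2] - 1) * dims[1] + b$voxels[, 1]
    t <- b$tangents
    dl <- ev$axial - ev$radial
    flat[lin, 1] <- ev$radial + dl * t[, 1]^2
    flat[lin, 2] <- ev$radial + dl * t[, 2]^2
    flat[lin, 3] <- ev$radial + dl * t[, 3]^2
    flat[lin, 4] <- dl * t[, 1] * t[, 2]
    flat[lin, 5] <- dl * t[, 1] * t[, 3]
    flat[lin, 6] <- dl * t[, 2] * t[, 3]
  }
  if (noiseSd > 0) {
    if (!is.null(seed)) set.seed(seed)
    flat <- flat + matrix(stats::rnorm(nvox * 6, sd = noiseSd), nvox, 6)
  }
  D[] <- flat
  new("TensorVolume", D = D, pixdim = geometry$pixdim)
}

#' Diffusion-weighted acquisition protocol
#'
#' The default protocol: 48 unit gradient directions at b = 1000 s/mm^2
#' (deterministic spherical Fibonacci lattice, well-spread) plus 4
#' b = 0 volumes, FSL-style b-table.
#'
#' @param nDirections number of diffusion-weighted directions.
#' @param b b-value in s/mm^2 for the weighted volumes.
#' @param nB0 number of b = 0 volumes.
#' @return list with \code{bvals} (numeric) and \code{bvecs} (n x 3).
#' @export
dwiProtocol <- function(nDirections = 48L, b = 1000, nB0 = 4L) {
  dirs <- fibonacciDirections(nDirections)
  bvecs <- rbind(matrix(0, nB0, 3), dirs)
  colnames(bvecs) <- c("x", "y", "z")
  list(bvals = c(rep(0, nB0), rep(b, nDirections)), bvecs = bvecs)
}

#' Synthesize diffusion-weighted images from a tensor volume
#'
#' Monoexponential signal S = S0 exp(-b g' D g) per gradient, with
#' optional Rician noise (the magnitude-MRI standard) at the stated SNR;
#' noiseless when \code{snr} is NULL.
#'
#' @param tensor a \code{\linkS4class{TensorVolume}}.
#' @param bvals,bvecs b-table; non-zero-b vectors must be unit norm.
#' @param snr signal-to-noise ratio S0 / sigma, or NULL for noiseless.
#' @param s0 baseline signal.
#' @param seed optional RNG seed for the noise.
#' @return list with \code{dwi} (4-D array), \code{bvals}, \code{bvecs}.
#' @export
synthesizeDWI <- function(tensor, bvals, bvecs, snr = NULL, s0 = 1000,
                          seed = NULL) {
  stopifnot(is(tensor, "TensorVolume"))
  bvecs <- as.matrix(bvecs)
  stopifnot(length(bvals) == nrow(bvecs))
  nz <- bvals > 0
  norms <- sqrt(rowSums(bvecs[nz, , drop = FALSE]^2))
  if (any(abs(norms - 1) > 1e-6))
    stop("non-unit gradient vectors in the b-table")
  dims <- dim(tensor@D)[1:3]
  nvox <- prod(dims)
  flat <- matrix(tensor@D, nvox, 6)
  # quadratic form coefficients per volume: b * (gx^2, gy^2, gz^2,
  # 2 gx gy, 2 gx gz, 2 gy gz)
  Q <- cbind(bvecs^2, 2 * bvecs[, 1] * bvecs[, 2],
             2 * bvecs[, 1] * bvecs[, 3], 2 * bvecs[, 2] * bvecs[, 3]) *
    bvals
  S <- s0 * exp(-flat %*% t(Q))
  if (!is.null(snr)) {
    if (snr <= 0) stop("snr must be positive")
    if (!is.null(seed)) set.seed(seed)
    sigma <- s0 / snr
    e1 <- matrix(stats::rnorm(length(S), sd = sigma), nrow(S))
    e2 <- matrix(stats::rnorm(length(S), sd = sigma), nrow(S))
    S <- sqrt((S + e1)^2 + e2^2)
  }
  list(dwi = array(S, c(dims, length(bvals))), bvals = bvals, bvecs = bvecs)
}
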