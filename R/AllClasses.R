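#' @import methods
NULL

#' Midsagittal corpus callosum label map
#'
#' Binary midsagittal CC mask together with the Hofer-Frahm area labels
#' (1-5 for areas I-V, 0 outside the mask). The first matrix dimension is
#' the anterior-posterior axis with anterior at index 1; the second is
#' inferior-superior.
#'
#' @slot mask logical matrix, the segmented CC.
#' @slot labels integer matrix of the same dimension; area codes 1-5
#'   inside the mask, 0 outside.
#' @slot pixdim numeric(2), in-plane voxel size in mm.
#' @slot fractions numeric(4), anterior-posterior cut fractions of the
#'   bounding-box extent (anterior = 0).
#' @slot flags character, diagnostic flags (e.g. \code{"border_contact"}).
#' @export
setClass("CCLabelMap",
  representation(mask = "matrix", labels = "matrix", pixdim = "numeric",
                 fractions = "numeric", flags = "character"),
  validity = function(object) {
    msg <- character(0)
    if (!is.logical(object@mask)) msg <- c(msg, "mask must be logical")
    if (!all(dim(object@mask) == dim(object@labels)))
      msg <- c(msg, "mask and labels must share dimensions")
    if (length(object@pixdim) != 2 || any(object@pixdim <= 0))
      msg <- c(msg, "pixdim must be two positive lengths (mm)")
    lab <- object@labels[object@mask]
    if (length(lab) && (any(lab < 1L) || any(lab > 5L)))
      msg <- c(msg, "labels inside the mask must be in 1..5")
    if (any(object@labels[!object@mask] != 0L))
      msg <- c(msg, "labels outside the mask must be 0")
    if (length(msg)) msg else TRUE
  })

#' Voxelwise diffusion tensor volume
#'
#' Symmetric diffusion tensors stored as a 4-D array \code{[x, y, z, 6]}
#' with component order \code{xx, yy, zz, xy, xz, yz} in mm^2/s. Symmetry
#' is guaranteed by storage.
#'
#' @slot D numeric 4-D array, last dimension 6.
#' @slot pixdim numeric(3), voxel size in mm.
#' @export
setClass("TensorVolume",
  representation(D = "array", pixdim = "numeric"),
  validity = function(object) {
    msg <- character(0)
    if (length(dim(object@D)) != 4 || dim(object@D)[4] != 6)
      msg <- c(msg, "D must be a 4-D array with 6 tensor components")
    if (length(object@pixdim) != 3 || any(object@pixdim <= 0))
      msg <- c(msg, "pixdim must be three positive lengths (mm)")
    if (length(msg)) msg else TRUE
  })

#' Fractional anisotropy map
#'
#' Scalar FA per voxel in the unit interval (NA where undefined), with provenance
#' flags recording smoothing and age correction.
#'
#' @slot values numeric 3-D array of FA values.
#' @slot pixdim numeric(3), voxel size in mm.
#' @slot smoothed logical flag.
#' @slot ageCorrected logical flag.
#' @slot nClamped integer, number of voxels whose negative eigenvalues
#'   were clamped to zero during FA computation.
#' @export
setClass("FAMap",
  representation(values = "array", pixdim = "numeric", smoothed = "logical",
                 ageCorrected = "logical", nClamped = "integer"),
  validity = function(object) {
    msg <- character(0)
    if (length(dim(object@values)) != 3)
      msg <- c(msg, "values must be a 3-D array")
    v <- object@values[!is.na(object@values)]
    if (length(v) && (min(v) < -1e-9 || max(v) > 1 + 1e-9))
      msg <- c(msg, "FA values must lie in the unit interval")
    if (length(object@pixdim) != 3 || any(object@pixdim <= 0))
      msg <- c(msg, "pixdim must be three positive lengths (mm)")
    if (length(msg)) msg else TRUE
  })

#' Streamline bundle for one callosal area
#'
#' Streamlines tracked from the seeds of one CC area, plus the set of
#' voxels any of them visits. Streamline points are mm coordinates; each
#' streamline carries its termination reasons for the two directions
#' (one of \code{low_fa}, \code{curvature}, \code{boundary}, \code{max_steps}).
#'
#' @slot area integer area label in 1..5.
#' @slot streamlines list of numeric matrices (n x 3, mm).
#' @slot terminations character matrix (one row per streamline, 2 columns).
#' @slot visited integer matrix (m x 3) of unique voxel indices.
#' @slot stepMm numeric step size used.
#' @export
setClass("TractSet",
  representation(area = "integer", streamlines = "list",
                 terminations = "matrix", visited = "matrix",
                 stepMm = "numeric"),
  validity = function(object) {
    msg <- character(0)
    if (object@area < 1L || object@area > 5L)
      msg <- c(msg, "area must be in 1..5")
    if (length(object@streamlines) &&
        nrow(object@terminations) != length(object@streamlines))
      msg <- c(msg, "terminations must have one row per streamline")
    if (any(vapply(object@streamlines, nrow, 1L) < 2L))
      msg <- c(msg, "every streamline must have at least 2 points")
    if (length(msg)) msg else TRUE
  })

#' Gray-level co-occurrence matrix
#'
#' Joint frequency table of quantized gray levels at voxel pairs separated
#' by the stored offsets (pooled over offsets).
#'
#' @slot counts numeric L x L matrix.
#' @slot levels integer, number of quantization levels L.
#' @slot offsets integer matrix (k x 2) of per-axis displacements.
#' @slot symmetric logical, whether the transpose was accumulated too.
#' @slot normalized logical, whether entries sum to 1.
#' @export
setClass("GLCMatrix",
  representation(counts = "matrix", levels = "integer", offsets = "matrix",
                 symmetric = "logical", normalized = "logical"),
  validity = function(object) {
    msg <- character(0)
    if (nrow(object@counts) != object@levels ||
        ncol(object@counts) != object@levels)
      msg <- c(msg, "counts must be levels x levels")
    if (any(object@counts < 0)) msg <- c(msg, "counts must be non-negative")
    if (object@normalized &&
        abs(sum(object@counts) - 1) > 1e-12)
      msg <- c(msg, "normalized counts must sum to 1")
    if (object@symmetric &&
        max(abs(object@counts - t(object@counts))) > 1e-12)
      msg <- c(msg, "symmetric GLCM must equal its transpose")
    if (length(msg)) msg else TRUE
  })

#' ROC curve with AUC
#'
#' Full ROC curve over all unique score thresholds plus the trapezoidal
#' AUC (identical to the midrank Mann-Whitney statistic U / (n1 n0)).
#'
#' @slot thresholds numeric, descending score thresholds.
#' @slot fpr,tpr numeric, curve coordinates from (0,0) to (1,1).
#' @slot auc numeric scalar in the unit interval.
#' @slot contrast character label.
#' @slot positiveClass character, the class scored as positive.
#' @export
setClass("ROCResult",
  representation(thresholds = "numeric", fpr = "numeric", tpr = "numeric",
                 auc = "numeric", contrast = "character",
                 positiveClass = "character"),
  validity = function(object) {
    msg <- character(0)
    if (length(object@fpr) != length(object@tpr))
      msg <- c(msg, "fpr and tpr must have equal length")
    if (is.unsorted(object@fpr) || is.unsorted(object@tpr))
      msg <- c(msg, "fpr and tpr must be non-decreasing")
    if (object@auc < 0 || object@auc > 1)
      msg <- c(msg, "auc must lie in the unit interval")
    n <- length(object@fpr)
    trap <- sum(diff(object@fpr) * (object@tpr[-1] + object@tpr[-n]) / 2)
    if (abs(trap - object@auc) > 1e-12)
      msg <- c(msg, "auc must equal the trapezoidal integral of the curve")
    if (length(msg)) msg else TRUE
  })

#' Aligned intensity volume
#'
#' 3-D volume after AC/PC alignment: the anterior-posterior direction is
#' the second array axis and the midsagittal plane is a coordinate plane
#' of the first axis. The applied voxel-to-voxel transform is stored.
#'
#' @slot data numeric 3-D array.
#' @slot pixdim numeric(3), mm.
#' @slot transform numeric 4 x 4 matrix (mm coordinates, forward map).
#' @export
setClass("AlignedVolume",
  representation(data = "array", pixdim = "numeric", transform = "matrix"),
  validity = function(object) {
    msg <- character(0)
    if (length(dim(object@data)) != 3) msg <- c(msg, "data must be 3-D")
    if (!all(dim(object@transform) == c(4, 4)))
      msg <- c(msg, "transform must be 4 x 4")
    if (length(msg)) msg else TRUE
  })

# ---- accessors ----

#' @describeIn CCLabelMap-class the binary mask.
#' @param x,object an object of the documented class.
#' @export
ccMask <- function(x) x@mask

#' @describeIn CCLabelMap-class the integer area label image.
#' @export
ccLabels <- function(x) x@labels

#' @describeIn CCLabelMap-class anterior-posterior bounding-box extent in
#'   voxels.
#' @export
apExtent <- function(x) {
  rows <- which(rowSums(x@mask) > 0)
  if (!length(rows)) 0L else diff(range(rows)) + 1L
}

#' @describeIn TensorVolume-class the raw component array.
#' @export
tensorArray <- function(x) x@D

#' @describeIn FAMap-class the FA value array.
#' @export
faValues <- function(x) x@values

#' @describeIn TractSet-class list of streamline point matrices.
#' @export
streamlines <- function(x) x@streamlines

#' @describeIn TractSet-class unique visited voxel indices (m x 3).
#' @export
visitedVoxels <- function(x) x@visited

#' @describeIn TractSet-class per-streamline termination reasons.
#' @export
terminationReasons <- function(x) x@terminations

#' @describeIn ROCResult-class area under the curve.
#' @export
aucValue <- function(x) x@auc

# ---- show methods ----

setMethod("show", "CCLabelMap", function(object) {
  cat("CCLabelMap:", sum(object@mask), "voxels,",
      "AP extent", apExtent(object), "voxels\n")
  counts <- tabulate(object@labels[object@mask], 5L)
  cat("  area voxels I-V:", paste(counts, collapse = "/"), "\n")
  if (length(object@flags)) cat("  flags:", paste(object@flags, collapse = ", "), "\n")
})

setMethod("show", "TensorVolume", function(object) {
  d <- dim(object@D)
  cat("TensorVolume:", paste(d[1:3], collapse = " x "), "voxels,",
      "pixdim", paste(object@pixdim, collapse = " x "), "mm\n")
})

setMethod("show", "FAMap", function(object) {
  cat("FAMap:", paste(dim(object@values), collapse = " x "),
      sprintf("voxels; smoothed=%s, ageCorrected=%s, clamped=%d\n",
              object@smoothed, object@ageCorrected, object@nClamped))
})

setMethod("show", "TractSet", function(object) {
  cat(sprintf("TractSet area %d: %d streamlines, %d visited voxels\n",
              object@area, length(object@streamlines), nrow(object@visited)))
})

setMethod("show", "ROCResult", function(object) {
  cat(sprintf("ROCResult [%s]: AUC = %.3f (positive class: %s)\n",
              object@contrast, object@auc, object@positiveClass))
})

setMethod("show", "AlignedVolume", function(object) {
  cat("AlignedVolume:", paste(dim(object@data), collapse = " x "), "voxels\n")
})
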