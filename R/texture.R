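#' Quantize gray levels within a mask
#'
#' Linear binning of the masked intensities between their minimum and
#' maximum into \code{levels} equal-width bins (codes 0 to levels - 1).
#' A constant region maps entirely to bin 0. Min-max binning makes all
#' downstream co-occurrence features invariant to intensity shifts and
#' global scaling.
#'
#' @param image numeric matrix.
#' @param mask logical matrix; must contain at least one voxel.
#' @param levels number of bins L >= 2.
#' @return integer matrix with codes inside the mask and NA outside.
#' @export
quantizeGrayLevels <- function(image, mask, levels = 32L) {
  if (levels < 2) stop("levels must be at least 2")
  if (!any(mask)) stop("empty mask")
  q <- matrix(NA_integer_, nrow(image), ncol(image))
  v <- image[mask]
  rng <- range(v)
  if (diff(rng) == 0) {
    q[mask] <- 0L
  } else {
    q[mask] <- pmin(as.integer(floor((v - rng[1]) / diff(rng) * levels)),
                    levels - 1L)
  }
  q
}

#' Gray-level co-occurrence matrix
#'
#' Accumulates joint counts of quantized gray levels at voxel pairs
#' separated by each offset (pooled over offsets); only pairs with both
#' voxels inside the mask count. In symmetric mode the transpose is added
#' before normalization.
#'
#' @param quantized integer matrix of codes 0..levels-1 (NA outside mask).
#' @param mask logical matrix; defaults to the non-NA entries.
#' @param offsets integer matrix (k x 2) of (row, col) displacements; the
#'   default pools the four distance-1 directions (0,1), (1,0), (1,1),
#'   (1,-1).
#' @param levels number of gray levels L.
#' @param symmetric logical.
#' @param normalize logical.
#' @return a \code{\linkS4class{GLCMatrix}}.
#' @export
computeGLCM <- function(quantized, mask = !is.na(quantized),
                        offsets = rbind(c(0, 1), c(1, 0), c(1, 1), c(1, -1)),
                        levels = max(quantized, na.rm = TRUE) + 1L,
                        symmetric = TRUE, normalize = TRUE) {
  offsets <- matrix(as.integer(offsets), ncol = 2)
  if (any(offsets[, 1] == 0 & offsets[, 2] == 0))
    stop("offsets must be non-zero")
  d <- dim(quantized)
  counts <- matrix(0, levels, levels)
  npairs <- 0L
  for (k in seq_len(nrow(offsets))) {
    dr <- offsets[k, 1]; dc <- offsets[k, 2]
    if (max(1L, 1L - dr) > min(d[1], d[1] - dr) ||
        max(1L, 1L - dc) > min(d[2], d[2] - dc)) next
    r1 <- max(1L, 1L - dr):min(d[1], d[1] - dr)
    c1 <- max(1L, 1L - dc):min(d[2], d[2] - dc)
    a <- quantized[r1, c1, drop = FALSE]
    b <- quantized[r1 + dr, c1 + dc, drop = FALSE]
    inb <- mask[r1, c1, drop = FALSE] & mask[r1 + dr, c1 + dc, drop = FALSE]
    ai <- a[inb]; bi <- b[inb]
    if (!length(ai)) next
    npairs <- npairs + length(ai)
    tab <- tabulate(ai * levels + bi + 1L, levels * levels)
    counts <- counts + matrix(tab, levels, levels, byrow = TRUE)
  }
  if (npairs == 0L) stop("no valid voxel pair inside the mask")
  if (symmetric) counts <- counts + t(counts)
  if (normalize) counts <- counts / sum(counts)
  g <- new("GLCMatrix", counts = counts, levels = as.integer(levels),
           offsets = offsets, symmetric = symmetric, normalized = normalize)
  attr(g, "n_pairs") <- npairs
  g
}

#' Co-occurrence entropy
#'
#' \eqn{-\sum_{ij} p_{ij} \log p_{ij}} over the non-zero cells of a
#' normalized GLCM; zero exactly when all co-occurrence mass sits on a
#' single cell (a constant image). Base-2 logarithm (bits) by default.
#'
#' @param g a normalized \code{\linkS4class{GLCMatrix}}.
#' @param base logarithm base; 2 for bits, \code{exp(1)} for nats.
#' @return non-negative scalar.
#' @export
glcmEntropy <- function(g, base = 2) {
  stopifnot(is(g, "GLCMatrix"))
  if (!g@normalized) stop("entropy requires a normalized GLCM")
  p <- g@counts[g@counts > 0]
  -sum(p * log(p, base = base))
}

#' Co-occurrence inhomogeneity
#'
#' \eqn{\sum_{ij} p_{ij} (i-j)^2} over a normalized GLCM (the contrast
#' form): it rises when gray-level differences between neighboring voxels
#' increase and is zero for a diagonal matrix. The conventional GLCM
#' feature named "homogeneity" moves in the opposite direction; this
#' package reports the contrast form under the name inhomogeneity, with
#' homogeneity accepted as an alias in tabulated outputs.
#'
#' @param g a normalized \code{\linkS4class{GLCMatrix}}.
#' @return non-negative scalar.
#' @export
glcmInhomogeneity <- function(g) {
  stopifnot(is(g, "GLCMatrix"))
  if (!g@normalized) stop("inhomogeneity requires a normalized GLCM")
  L <- g@levels
  i <- matrix(seq_len(L) - 1L, L, L)
  sum(g@counts * (i - t(i))^2)
}

#' Per-area texture features of the midsagittal CC
#'
#' Quantization (min-max within each area's own mask, so features are
#' comparable across subjects with different global brightness), GLCM and
#' both features are computed independently per Hofer-Frahm area, using
#' only voxel pairs lying within the same area.
#'
#' @param image numeric matrix (midsagittal slice).
#' @param labelMap a \code{\linkS4class{CCLabelMap}} aligned to the image.
#' @param levels quantization levels.
#' @param offsets offset matrix, as in \code{\link{computeGLCM}}.
#' @param base entropy logarithm base.
#' @return data.frame with one row per area: \code{area}, \code{entropy},
#'   \code{inhomogeneity}, \code{n_pairs}, \code{levels}. Areas with
#'   fewer than 2 valid pairs get NA features with a warning.
#' @export
areaTexture <- function(image, labelMap, levels = 32L,
                        offsets = rbind(c(0, 1), c(1, 0), c(1, 1), c(1, -1)),
                        base = 2) {
  stopifnot(is(labelMap, "CCLabelMap"))
  if (!all(dim(image) == dim(ccMask(labelMap))))
    stop("label map is not aligned to the image")
  lab <- ccLabels(labelMap)
  out <- data.frame(area = c("I", "II", "III", "IV", "V"),
                    entropy = NA_real_, inhomogeneity = NA_real_,
                    n_pairs = 0L, levels = as.integer(levels))
  for (a in 1:5) {
    m <- lab == a
    if (!any(m)) next
    q <- quantizeGrayLevels(image, m, levels)
    g <- tryCatch(computeGLCM(q, m, offsets, levels), error = function(e) NULL)
    if (is.null(g) || attr(g, "n_pairs") < 2L) {
      warning("area ", out$area[a], " has fewer than 2 valid pairs; ",
              "features set to missing")
      next
    }
    out$entropy[a] <- glcmEntropy(g, base)
    out$inhomogeneity[a] <- glcmInhomogeneity(g)
    out$n_pairs[a] <- attr(g, "n_pairs")
  }
  out
}
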