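# Shared fixtures, all built in code.

# rectangular "CC": extent x thick voxels, anterior at row 1
rectMask <- function(extent = 60L, thick = 10L, pad = 2L) {
  m <- matrix(FALSE, extent + 2L * pad, thick + 2L * pad)
  m[pad + seq_len(extent), pad + seq_len(thick)] <- TRUE
  m
}

# small phantom geometry for faster tests
smallGeometry <- function(dims = c(11L, 44L, 30L)) {
  phantomGeometry(dims = dims, apLength = 34, height = 13, thickness = 5)
}

# reduced geometry for replicated pipeline runs
nullGeometry <- function() {
  phantomGeometry(dims = c(11L, 40L, 26L), apLength = 32, height = 12,
                  thickness = 5)
}

# uniform tensor field with one principal direction everywhere
uniformTensorField <- function(dims, dir, fa, md = 7e-4, pixdim = c(1, 1, 1)) {
  dir <- dir / sqrt(sum(dir^2))
  ev <- callosalMRI:::axialEigenvalues(fa, md)
  dl <- ev$axial - ev$radial
  comp <- c(ev$radial + dl * dir[1]^2, ev$radial + dl * dir[2]^2,
            ev$radial + dl * dir[3]^2, dl * dir[1] * dir[2],
            dl * dir[1] * dir[3], dl * dir[2] * dir[3])
  D <- array(rep(comp, each = prod(dims)), c(dims, 6L))
  new("TensorVolume", D = D, pixdim = pixdim)
}

# naive pair-enumeration texture oracle: loops over every voxel and
# offset, fully independent of the package's vectorized path
naiveTexture <- function(image, mask, offsets, levels, base = 2) {
  v <- image[mask]
  rng <- range(v)
  q <- matrix(NA_integer_, nrow(image), ncol(image))
  q[mask] <- if (diff(rng) == 0) 0L else
    pmin(as.integer(floor((v - rng[1]) / diff(rng) * levels)), levels - 1L)
  counts <- matrix(0, levels, levels)
  for (r in seq_len(nrow(image))) for (cc in seq_len(ncol(image))) {
    if (!mask[r, cc]) next
    for (k in seq_len(nrow(offsets))) {
      rr <- r + offsets[k, 1]; c2 <- cc + offsets[k, 2]
      if (rr < 1 || rr > nrow(image) || c2 < 1 || c2 > ncol(image)) next
      if (!mask[rr, c2]) next
      counts[q[r, cc] + 1L, q[rr, c2] + 1L] <-
        counts[q[r, cc] + 1L, q[rr, c2] + 1L] + 1
    }
  }
  counts <- counts + t(counts)
  p <- counts / sum(counts)
  pn <- p[p > 0]
  ij <- outer(0:(levels - 1), 0:(levels - 1), "-")
  list(entropy = -sum(pn * log(pn, base)), inhomogeneity = sum(p * ij^2))
}

# hand subdivision oracle by column-center counting
naiveSubdivide <- function(mask, fractions = c(1/6, 1/2, 2/3, 3/4)) {
  rows <- which(rowSums(mask) > 0)
  r1 <- min(rows); extent <- max(rows) - r1 + 1
  lab <- matrix(0L, nrow(mask), ncol(mask))
  for (r in seq_len(nrow(mask))) for (cc in seq_len(ncol(mask))) {
    if (!mask[r, cc]) next
    x <- r - r1 + 0.5
    lab[r, cc] <- 1L + sum(x > extent * fractions)
  }
  lab
}
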