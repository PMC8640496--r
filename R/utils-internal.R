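# Internal numerical helpers shared across modules.

# Normalized 1-D Gaussian kernel; radius covers +/- 3 sigma.
gaussianKernel1d <- function(sigmaVox) {
  stopifnot(sigmaVox > 0)
  r <- max(1L, as.integer(ceiling(3 * sigmaVox)))
  k <- stats::dnorm(seq(-r, r), sd = sigmaVox)
  k / sum(k)
}

# Mirror-with-repeat reflection of 1-based indices into [1, n].
reflectIndex <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  j <- (i - 1L) %% (2L * n)
  j <- ifelse(j < 0L, j + 2L * n, j)
  ifelse(j >= n, 2L * n - 1L - j, j) + 1L
}

# Dense banded convolution matrix with reflective boundary; n is small
# for the volumes handled here, so a dense matrix + BLAS is fastest.
convMatrix1d <- function(n, kernel) {
  r <- (length(kernel) - 1L) %/% 2L
  C <- matrix(0, n, n)
  for (t in seq(-r, r)) {
    src <- reflectIndex(seq_len(n) + t, n)
    w <- kernel[t + r + 1L]
    C[cbind(seq_len(n), src)] <- C[cbind(seq_len(n), src)] + w
  }
  C
}

# Separable Gaussian smoothing of a 2-D or 3-D array, sigma per axis in
# voxels. Axes with sigma = 0 are left untouched.
smoothGaussianArray <- function(arr, sigmaVox) {
  d <- dim(arr)
  nd <- length(d)
  stopifnot(length(sigmaVox) == nd)
  for (ax in seq_len(nd)) {
    if (sigmaVox[ax] <= 0) next
    C <- convMatrix1d(d[ax], gaussianKernel1d(sigmaVox[ax]))
    perm <- c(ax, setdiff(seq_len(nd), ax))
    m <- aperm(arr, perm)
    dm <- dim(m)
    m <- C %*% matrix(m, nrow = d[ax])
    dim(m) <- dm
    arr <- aperm(m, order(perm))
  }
  arr
}

# Eigenvalues of many symmetric 3x3 matrices at once (Cardano / trigonometric
# form). Inputs are component vectors; returns a list with l1 >= l2 >= l3.
symEigenvalues3 <- function(dxx, dyy, dzz, dxy, dxz, dyz) {
  q <- (dxx + dyy + dzz) / 3
  p2 <- (dxx - q)^2 + (dyy - q)^2 + (dzz - q)^2 + 2 * (dxy^2 + dxz^2 + dyz^2)
  p <- sqrt(pmax(p2, 0) / 6)
  l1 <- l2 <- l3 <- q
  ok <- p > .Machine$double.eps * pmax(abs(q), 1e-300)
  if (any(ok)) {
    b11 <- (dxx[ok] - q[ok]) / p[ok]
    b22 <- (dyy[ok] - q[ok]) / p[ok]
    b33 <- (dzz[ok] - q[ok]) / p[ok]
    b12 <- dxy[ok] / p[ok]; b13 <- dxz[ok] / p[ok]; b23 <- dyz[ok] / p[ok]
    detB <- b11 * (b22 * b33 - b23^2) - b12 * (b12 * b33 - b23 * b13) +
      b13 * (b12 * b23 - b22 * b13)
    r <- pmin(pmax(detB / 2, -1), 1)
    phi <- acos(r) / 3
    e1 <- q[ok] + 2 * p[ok] * cos(phi)
    e3 <- q[ok] + 2 * p[ok] * cos(phi + 2 * pi / 3)
    l1[ok] <- e1
    l3[ok] <- e3
    l2[ok] <- 3 * q[ok] - e1 - e3
  }
  list(l1 = l1, l2 = l2, l3 = l3)
}

# FA from eigenvalues; all-zero tensors map to 0.
faFromEigenvalues <- function(l1, l2, l3) {
  m <- (l1 + l2 + l3) / 3
  num <- (l1 - m)^2 + (l2 - m)^2 + (l3 - m)^2
  den <- l1^2 + l2^2 + l3^2
  fa <- sqrt(1.5) * sqrt(pmax(num, 0) / ifelse(den > 0, den, 1))
  fa[den <= 0] <- 0
  pmin(pmax(fa, 0), 1)
}

# Eigenvalues of an axially symmetric (prolate) tensor hitting a target FA
# at a given mean diffusivity. delta = FA / sqrt(3 - 2 FA^2); the axial
# eigenvalue is md (1 + 2 delta), the radial pair md (1 - delta).
axialEigenvalues <- function(fa, md) {
  if (any(fa < 0) || any(fa >= 1))
    stop("target FA must lie in [0, 1) for positive-definite eigenvalues")
  delta <- fa / sqrt(3 - 2 * fa^2)
  list(axial = md * (1 + 2 * delta), radial = md * (1 - delta))
}

# Deterministic, well-spread unit directions (spherical Fibonacci lattice).
fibonacciDirections <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(1 - z^2, 0))
  golden <- pi * (3 - sqrt(5))
  th <- golden * (seq_len(n) - 1)
  cbind(x = r * cos(th), y = r * sin(th), z = z)
}

# 8-connected component labeling of a logical matrix. EBImage::bwlabel is
# 4-connected, which splits diagonal runs, hence this small flood fill.
label8Connected <- function(mask) {
  d <- dim(mask)
  lab <- matrix(0L, d[1], d[2])
  idx <- which(mask)
  if (!length(idx)) return(lab)
  cur <- 0L
  nb <- expand.grid(dr = -1:1, dc = -1:1)
  nb <- nb[!(nb$dr == 0 & nb$dc == 0), ]
  for (start in idx) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      v <- queue
      queue <- integer(0)
      r <- (v - 1L) %% d[1] + 1L
      c <- (v - 1L) %/% d[1] + 1L
      for (k in seq_len(nrow(nb))) {
        rr <- r + nb$dr[k]; cc <- c + nb$dc[k]
        keep <- rr >= 1L & rr <= d[1] & cc >= 1L & cc <= d[2]
        if (!any(keep)) next
        w <- (cc[keep] - 1L) * d[1] + rr[keep]
        w <- w[mask[w] & lab[w] == 0L]
        if (length(w)) {
          lab[w] <- cur
          queue <- c(queue, w)
        }
      }
      queue <- unique(queue)
    }
  }
  lab
}

# Trilinear interpolation of a 3-D array at fractional voxel coordinates
# (1-based, n x 3 matrix). Coordinates outside the grid return `outside`.
trilinearSample <- function(vol, coords, outside = 0) {
  d <- dim(vol)
  x <- coords[, 1]; y <- coords[, 2]; z <- coords[, 3]
  ok <- x >= 1 & x <= d[1] & y >= 1 & y <= d[2] & z >= 1 & z <= d[3]
  out <- rep(outside, nrow(coords))
  if (!any(ok)) return(out)
  x <- x[ok]; y <- y[ok]; z <- z[ok]
  x0 <- pmin(pmax(floor(x), 1), d[1] - 1L); fx <- x - x0
  y0 <- pmin(pmax(floor(y), 1), d[2] - 1L); fy <- y - y0
  z0 <- pmin(pmax(floor(z), 1), d[3] - 1L); fz <- z - z0
  if (d[1] == 1L) { x0 <- rep(1, length(x)); fx <- 0 }
  if (d[2] == 1L) { y0 <- rep(1, length(y)); fy <- 0 }
  if (d[3] == 1L) { z0 <- rep(1, length(z)); fz <- 0 }
  at <- function(i, j, k) vol[cbind(i, j, k)]
  v <- at(x0, y0, z0) * (1 - fx) * (1 - fy) * (1 - fz)
  if (d[1] > 1L) v <- v + at(x0 + 1, y0, z0) * fx * (1 - fy) * (1 - fz)
  if (d[2] > 1L) v <- v + at(x0, y0 + 1, z0) * (1 - fx) * fy * (1 - fz)
  if (d[3] > 1L) v <- v + at(x0, y0, z0 + 1) * (1 - fx) * (1 - fy) * fz
  if (d[1] > 1L && d[2] > 1L) v <- v + at(x0 + 1, y0 + 1, z0) * fx * fy * (1 - fz)
  if (d[1] > 1L && d[3] > 1L) v <- v + at(x0 + 1, y0, z0 + 1) * fx * (1 - fy) * fz
  if (d[2] > 1L && d[3] > 1L) v <- v + at(x0, y0 + 1, z0 + 1) * (1 - fx) * fy * fz
  if (d[1] > 1L && d[2] > 1L && d[3] > 1L)
    v <- v + at(x0 + 1, y0 + 1, z0 + 1) * fx * fy * fz
  out[ok] <- v
  out
}

# Derive per-subject integer seeds from a master seed, reproducibly.
deriveSeeds <- function(masterSeed, n) {
  old <- if (exists(".Random.seed", envir = .GlobalEnv))
    get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = .GlobalEnv))
        rm(".Random.seed", envir = .GlobalEnv)
    } else assign(".Random.seed", old, envir = .GlobalEnv)
  })
  set.seed(masterSeed)
  sample.int(.Machine$integer.max - 1L, n)
}
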