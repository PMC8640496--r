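test_that("AC/PC alignment is the identity for canonical landmarks", {
  set.seed(1)
  vol <- array(rnorm(20 * 24 * 16), c(20, 24, 16))
  pix <- c(1, 1, 1)
  ctr <- (dim(vol) - 1) / 2
  ac <- c(ctr[1], ctr[2] - 5, ctr[3])
  pc <- c(ctr[1], ctr[2] + 5, ctr[3])
  al <- alignACPC(vol, pix, ac, pc, normal = c(1, 0, 0))
  expect_lt(max(abs(al@data - vol)), 1e-6)
  expect_equal(al@transform[1:3, 1:3], diag(3), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_error(alignACPC(vol, pix, ac, ac, c(1, 0, 0)), "coincide")
  expect_error(alignACPC(vol, pix, ac, pc, normal = c(0, 1, 0)), "parallel")
})

test_that("alignment undoes a 10-degree rotation about the left-right axis", {
  # analytic smooth intensity sampled on a rotated grid; aligning the
  # rotated volume with rotated landmarks must recover the canonical one
  d <- c(21, 30, 24)
  pix <- c(1, 1, 1)
  ctr <- (d - 1) / 2
  f <- function(p) {
    q <- sweep(p, 2, ctr)
    100 * exp(-rowSums(sweep(q, 2, c(6, 8, 5), "/")^2))
  }
  grid <- as.matrix(expand.grid(x = seq_len(d[1]), y = seq_len(d[2]),
                                z = seq_len(d[3]))) - 1
  canonical <- array(f(grid), d)
  th <- 10 * pi / 180
  R <- rbind(c(1, 0, 0), c(0, cos(th), -sin(th)), c(0, sin(th), cos(th)))
  # rotated volume: intensity of the canonical scene at R^-1 (p - ctr) + ctr
  rotGrid <- sweep(sweep(grid, 2, ctr) %*% R, 2, ctr, "+")
  rotated <- array(f(rotGrid), d)
  acC <- ctr + c(0, -6, 0); pcC <- ctr + c(0, 6, 0)
  rot <- function(p) as.vector(R %*% (p - ctr) + ctr)
  al <- alignACPC(rotated, pix, rot(acC), rot(pcC),
                  normal = R %*% c(1, 0, 0))
  interior <- array(FALSE, d)
  interior[4:(d[1] - 3), 4:(d[2] - 3), 4:(d[3] - 3)] <- TRUE
  err <- mean(abs(al@data[interior] - canonical[interior]))
  expect_lt(err, 0.02 * diff(range(canonical)))
})

test_that("midsagittal extraction follows the slice-count tie rule", {
  vol <- array(seq_len(5 * 4 * 3), c(5, 4, 3))
  expect_identical(extractMidsagittal(vol), vol[3, , ])
  vol6 <- array(seq_len(6 * 4 * 3), c(6, 4, 3))
  expect_equal(extractMidsagittal(vol6), (vol6[3, , ] + vol6[4, , ]) / 2)
  expect_error(extractMidsagittal(array(0, c(2, 4, 3))), "3 sagittal")
})

test_that("midsagittal slice of the phantom contains the CC template", {
  g <- smallGeometry()
  tpl <- makeCCTemplate(g)
  slice <- synthesizeT1wSlice(tpl, amplitude = 2, noiseSd = 1, seed = 3,
                              smoothAmplitude = 6)
  vol <- array(rep(slice, each = g$dims[1]), c(g$dims[1], dim(slice)))
  mid <- extractMidsagittal(vol)
  expect_equal(mid, slice, ignore_attr = TRUE)
})

test_that("segmentation recovers the phantom mask and handles edge cases", {
  tpl <- makeCCTemplate(smallGeometry())
  slice <- synthesizeT1wSlice(tpl, amplitude = 3, noiseSd = 2, seed = 11,
                              smoothAmplitude = 6)
  seg <- segmentCC(slice)
  dice <- 2 * sum(seg & ccMask(tpl)) / (sum(seg) + sum(ccMask(tpl)))
  expect_gte(dice, 0.98)
  expect_error(segmentCC(matrix(7, 32, 32)), "threshold")
  # largest-component rule: 500-voxel blob wins over a 40-voxel blob
  img <- matrix(0, 60, 60)
  img[5:29, 5:24] <- 100    # 500 voxels
  img[40:47, 40:44] <- 100  # 40 voxels
  seg2 <- segmentCC(img, roiHint = c(1L, 60L, 1L, 60L))
  expect_identical(sum(seg2), 500L)
  expect_true(all(which(seg2, arr.ind = TRUE)[, 1] < 30))
})

test_that("small enclosed holes are filled, larger ones kept", {
  img <- matrix(0, 40, 40)
  img[8:33, 8:33] <- 100
  img[15, 15] <- 0                 # 1-voxel hole -> filled
  img[24:25, 24:26] <- 0           # 6-voxel hole -> kept
  seg <- segmentCC(img, roiHint = c(1L, 40L, 1L, 40L))
  expect_true(seg[15, 15])
  expect_false(any(seg[24:25, 24:26]))
})

test_that("subdivision boundaries follow the floor-of-fraction rule", {
  m <- rectMask(12L, 6L)
  lm <- subdivideHoferFrahm(m)
  lab <- ccLabels(lm)
  r1 <- min(which(rowSums(ccMask(lm)) > 0))
  colLab <- vapply(0:11, function(cc) unique(lab[r1 + cc, lab[r1 + cc, ] > 0]),
                   integer(1))
  # 0-based first columns of stripes II..V at 2/6/8/9
  expect_identical(colLab, rep(1:5, c(2L, 4L, 2L, 1L, 3L)))
  expect_error(subdivideHoferFrahm(rectMask(11L, 5L)), "extent below 12")
  expect_error(subdivideHoferFrahm(matrix(FALSE, 5, 5)), "empty")
})

test_that("subdivision matches a voxelwise oracle on random masks", {
  set.seed(42)
  for (rep in 1:10) {
    m <- matrix(FALSE, 40, 25)
    ext <- sample(13:36, 1)
    r0 <- sample(1:(40 - ext), 1)
    for (r in r0:(r0 + ext - 1))
      m[r, sample(25, sample(3:12, 1))] <- TRUE
    lm <- subdivideHoferFrahm(m)
    expect_identical(ccLabels(lm), naiveSubdivide(m))
    expect_identical(sum(tabulate(ccLabels(lm)[m], 5L)), sum(m))
  }
})

test_that("flipping the mask mirrors labels under complementary fractions", {
  # cut fractions are not symmetric about 1/2, so the mirrored subdivision
  # uses the complementary fractions 1 - rev(f); extents divisible by 12
  # keep voxel centers off the cuts so the anterior-wins tie rule is inert
  set.seed(7)
  f <- c(1/6, 1/2, 2/3, 3/4)
  for (rep in 1:10) {
    ext <- sample(c(12L, 24L, 36L, 48L), 1)
    m <- matrix(FALSE, ext + 6L, 20)
    for (r in 4:(3 + ext)) m[r, sample(20, sample(3:10, 1))] <- TRUE
    lab <- ccLabels(subdivideHoferFrahm(m, fractions = f))
    flipped <- m[rev(seq_len(nrow(m))), ]
    labFlip <- ccLabels(subdivideHoferFrahm(flipped,
                                            fractions = 1 - rev(f)))
    mirrored <- labFlip[rev(seq_len(nrow(labFlip))), ]
    relabel <- ifelse(mirrored > 0L, 6L - mirrored, 0L)
    expect_identical(lab, relabel)
  }
})

test_that("upsampling preserves planimetry ratios within 2 percent", {
  tpl <- makeCCTemplate(smallGeometry())
  m <- ccMask(tpl)
  up <- m[rep(seq_len(nrow(m)), each = 2), rep(seq_len(ncol(m)), each = 2)]
  p1 <- planimetry(subdivideHoferFrahm(m))
  p2 <- planimetry(subdivideHoferFrahm(up))
  expect_true(all(abs(p2$count / p1$count - 4) < 0.5))
  expect_true(all(abs(p2$ratio - p1$ratio) <= 0.02))
})

test_that("planimetry reports exact fractions and flags empty areas", {
  p <- planimetry(subdivideHoferFrahm(rectMask(60L, 10L)))
  expect_identical(p$ratio, c(1/6, 1/3, 1/6, 1/12, 1/4))
  expect_equal(sum(p$ratio), 1, tolerance = 1e-12)
  expect_equal(attr(p, "total_mm2"), 600)
  # pathological map with an empty area
  m <- rectMask(20L, 4L)
  lm <- subdivideHoferFrahm(m)
  lab <- ccLabels(lm); msk <- ccMask(lm)
  msk[lab == 4L] <- FALSE; lab[lab == 4L] <- 0L
  lm2 <- new("CCLabelMap", mask = msk, labels = lab, pixdim = c(1, 1),
             fractions = lm@fractions, flags = character(0))
  expect_warning(p2 <- planimetry(lm2), "no voxels")
  expect_identical(p2$ratio[4], 0)
})
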