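test_that("Hofer-Frahm labels of a rectangular mask match hand-derived sizes", {
  # 60-column rectangle, 10 voxels thick: cuts at columns 10/30/40/45
  # give 10/20/10/5/15 columns -> 100/200/100/50/150 voxels
  m <- rectMask(60L, 10L)
  lm <- subdivideHoferFrahm(m)
  counts <- tabulate(ccLabels(lm)[ccMask(lm)], 5L)
  expect_identical(counts, c(100L, 200L, 100L, 50L, 150L))
})

test_that("arch template partitions its mask and respects the anterior sixth", {
  g <- phantomGeometry(dims = c(11L, 96L, 40L), apLength = 90, height = 16,
                       thickness = 6)
  tpl <- makeCCTemplate(g)
  mask <- ccMask(tpl); lab <- ccLabels(tpl)
  # partition: every mask voxel labeled exactly once
  expect_identical(sum(tabulate(lab[mask], 5L)), sum(mask))
  expect_true(all(lab[mask] %in% 1:5))
  expect_true(all(lab[!mask] == 0L))
  expect_identical(apExtent(tpl), 90L)
  # label 1 occupies exactly the anterior 15 columns (90 / 6) of the box
  rows <- which(rowSums(mask) > 0)
  lab1rows <- which(rowSums(lab == 1L) > 0)
  expect_identical(lab1rows, seq(min(rows), min(rows) + 14L))
})

test_that("degenerate phantom geometry is rejected with a diagnostic", {
  expect_error(phantomGeometry(thickness = 1), "thickness")
  expect_error(phantomGeometry(dims = c(10L, 56L, 36L)), "odd")
  expect_error(makeCCTemplate(phantomGeometry(dims = c(11L, 40L, 30L),
                                              apLength = 20, height = 10,
                                              thickness = 4)),
               "extent below 30")
})

test_that("T1w slice synthesis is deterministic and constant when silent", {
  tpl <- makeCCTemplate(smallGeometry())
  s0 <- synthesizeT1wSlice(tpl, amplitude = 0, noiseSd = 0)
  expect_equal(length(unique(s0[ccMask(tpl)])), 1L)
  lm <- subdivideHoferFrahm(ccMask(tpl))
  tex <- areaTexture(s0, lm, levels = 8)
  expect_equal(tex$entropy, rep(0, 5))
  s1 <- synthesizeT1wSlice(tpl, amplitude = 3, noiseSd = 2, seed = 42,
                           smoothAmplitude = 6)
  s2 <- synthesizeT1wSlice(tpl, amplitude = 3, noiseSd = 2, seed = 42,
                           smoothAmplitude = 6)
  expect_identical(s1, s2)
  expect_error(synthesizeT1wSlice(tpl, noiseSd = -1), "noiseSd")
  expect_error(synthesizeT1wSlice(tpl, amplitude = -2), "amplitude")
})

test_that("doubling one area's amplitude raises only that area's texture", {
  tpl <- makeCCTemplate(smallGeometry())
  amp <- c(2, 2, 2, 2, 2)
  amp2 <- c(2, 4, 2, 2, 2)
  s1 <- synthesizeT1wSlice(tpl, amplitude = amp, noiseSd = 0, seed = 9,
                           smoothAmplitude = 6)
  s2 <- synthesizeT1wSlice(tpl, amplitude = amp2, noiseSd = 0, seed = 9,
                           smoothAmplitude = 6)
  t1 <- areaTexture(s1, tpl)
  t2 <- areaTexture(s2, tpl)
  expect_gt(t2$inhomogeneity[2], t1$inhomogeneity[2])
  expect_equal(t2$inhomogeneity[4:5], t1$inhomogeneity[4:5])
  expect_equal(t2$entropy[4:5], t1$entropy[4:5])
})

test_that("tensor phantom hits requested FA and separates from background", {
  g <- smallGeometry()
  fa <- c(0.6, 0.6, 0.6, 0.6, 0.6)
  tv <- synthesizeTensorVolume(g, fa, backgroundFa = 0.05)
  bundles <- callosalMRI:::makePhantomBundles(g)
  famap <- faValues(computeFA(tv))
  vox3 <- bundles[[3]]$voxels
  expect_true(all(abs(famap[vox3] - 0.6) < 0.01))
  # {FA > 0.2} is exactly the union of bundle voxels
  allBundle <- unique(do.call(rbind, lapply(bundles, `[[`, "voxels")))
  supra <- which(famap > 0.2, arr.ind = TRUE)
  expect_setequal(paste(supra[, 1], supra[, 2], supra[, 3]),
                  paste(allBundle[, 1], allBundle[, 2], allBundle[, 3]))
  # exactly isotropic background at backgroundFa = 0
  tv0 <- synthesizeTensorVolume(g, fa, backgroundFa = 0)
  fa0 <- faValues(computeFA(tv0))
  bg <- array(TRUE, g$dims)
  bg[allBundle] <- FALSE
  expect_true(all(fa0[bg] == 0))
  expect_error(synthesizeTensorVolume(g, c(1, .5, .5, .5, .5)),
               "positive-definite")
})

test_that("DWI synthesis follows the monoexponential model", {
  g <- smallGeometry()
  prot <- dwiProtocol()
  expect_equal(nrow(prot$bvecs), 52L)
  expect_equal(sum(prot$bvals == 0), 4L)
  # isotropic tensor: all 48 attenuated signals equal S0 exp(-b d)
  dims <- c(3L, 4L, 4L)
  md <- 7e-4
  iso <- uniformTensorField(dims, c(1, 0, 0), fa = 0, md = md)
  out <- synthesizeDWI(iso, prot$bvals, prot$bvecs, s0 = 1000)
  dw <- matrix(out$dwi, prod(dims), 52)[, prot$bvals > 0]
  expect_equal(as.vector(dw), rep(1000 * exp(-1000 * md), length(dw)),
               tolerance = 1e-12)
  b0 <- matrix(out$dwi, prod(dims), 52)[, prot$bvals == 0]
  expect_true(all(b0 == 1000))
  bad <- prot$bvecs; bad[10, ] <- c(2, 0, 0)
  expect_error(synthesizeDWI(iso, prot$bvals, bad), "unit")
})

test_that("cohort generation is reproducible and injects the FA effects", {
  cfg <- cohortConfig(n_psp_rs = 2L, n_psp_p = 2L, n_pd = 2L,
                      n_control = 3L, geometry = smallGeometry(), seed = 5L)
  co1 <- generateCohort(cfg)
  co2 <- generateCohort(cfg)
  expect_identical(co1$subjects, co2$subjects)
  expect_identical(co1$images[[1]]$t1w, co2$images[[1]]$t1w)
  expect_identical(tensorArray(co1$images[[4]]$tensor),
                   tensorArray(co2$images[[4]]$tensor))
  # injected effect: PSP mean bundle FA in area II below the control mean
  vox2 <- co1$bundles[[2]]$voxels
  meanFa <- vapply(seq_len(nrow(co1$subjects)), function(i)
    mean(faValues(computeFA(co1$images[[i]]$tensor))[vox2]), 0)
  grp <- co1$subjects$group
  expect_lt(mean(meanFa[grp %in% c("PSP-RS", "PSP-P")]),
            mean(meanFa[grp == "control"]))
  expect_error(cohortConfig(n_control = 1L), "n >= 2")
  expect_error(cohortConfig(fa_effect = list(
    "PSP-RS" = c(0.5, 0, 0, 0, 0), "PSP-P" = rep(0, 5), "PD" = rep(0, 5))),
    "0.25")
})

test_that("planimetry geometry is conserved across generated subjects", {
  cfg <- cohortConfig(n_psp_rs = 2L, n_psp_p = 2L, n_pd = 2L,
                      n_control = 2L, geometry = smallGeometry(), seed = 2L)
  co <- generateCohort(cfg)
  ratios <- lapply(co$images, function(im) {
    planimetry(subdivideHoferFrahm(segmentCC(im$t1w)))$ratio
  })
  for (r in ratios[-1]) expect_identical(r, ratios[[1]])
})
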