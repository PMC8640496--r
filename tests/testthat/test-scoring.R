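test_that("tract means apply the FA exclusion rule", {
  vals <- array(NA_real_, c(3, 1, 1))
  vals[, 1, 1] <- c(0.1, 0.3, 0.5)
  fa <- new("FAMap", values = vals, pixdim = c(1, 1, 1), smoothed = TRUE,
            ageCorrected = TRUE, nClamped = 0L)
  tract <- new("TractSet", area = 2L,
               streamlines = list(cbind(c(0.5, 1.5, 2.5), 0.5, 0.5)),
               terminations = matrix(c("boundary", "boundary"), 1),
               visited = cbind(x = 1:3, y = rep(1L, 3), z = rep(1L, 3)),
               stepMm = 1)
  m <- tfasSubjectMeans(list(A = fa), list(tract))
  expect_equal(m$fa_tract, 0.4)  # 0.1 excluded, mean(0.3, 0.5)
  expect_identical(m$n_voxels, 2L)
  # all voxels below threshold: missing with a warning
  lowVals <- vals; lowVals[, 1, 1] <- c(0.1, 0.15, 0.19)
  low <- new("FAMap", values = lowVals, pixdim = c(1, 1, 1),
             smoothed = TRUE, ageCorrected = TRUE, nClamped = 0L)
  expect_warning(m2 <- tfasSubjectMeans(list(A = low), list(tract)),
                 "no supra-threshold")
  expect_true(is.na(m2$fa_tract))
})

test_that("tract means equal a naive loop over the voxel list", {
  set.seed(12)
  for (rep in 1:20) {
    d <- c(6L, 6L, 6L)
    vals <- array(runif(prod(d)), d)
    fa <- new("FAMap", values = vals, pixdim = c(1, 1, 1), smoothed = TRUE,
              ageCorrected = TRUE, nClamped = 0L)
    nv <- sample(3:20, 1)
    vis <- cbind(x = sample(6, nv, TRUE), y = sample(6, nv, TRUE),
                 z = sample(6, nv, TRUE))
    vis <- unique(vis)
    tract <- new("TractSet", area = 1L,
                 streamlines = list(cbind(0:1, 0.5, 0.5)),
                 terminations = matrix(c("low_fa", "low_fa"), 1),
                 visited = vis, stepMm = 1)
    got <- suppressWarnings(tfasSubjectMeans(list(S = fa), list(tract)))
    acc <- c()
    for (i in seq_len(nrow(vis))) {
      v <- vals[vis[i, 1], vis[i, 2], vis[i, 3]]
      if (v >= 0.2) acc <- c(acc, v)
    }
    if (length(acc)) expect_equal(got$fa_tract, mean(acc),
                                  tolerance = 1e-12)
    else expect_true(is.na(got$fa_tract))
  }
})

test_that("identical groups give t = 0 and p = 1 in every area", {
  panel <- expand.grid(subject_id = sprintf("S%02d", 1:12),
                       area = c("I", "II", "III", "IV", "V"))
  panel$group <- rep(c("PSP-RS", "control"), each = 6)
  panel$value <- rep(c(0.4, 0.5, 0.6, 0.4, 0.5, 0.6), 10)
  res <- groupCompare(panel, contrasts = defaultContrasts()["PSP vs control"])
  expect_true(all(res$t == 0))
  expect_true(all(res$p == 1))
  expect_true(all(res$stars == ""))
})

test_that("z-normalization is control-referenced with sample SD", {
  v <- c(1, 2, 3, 10, -4)
  z <- zNormalize(v, 1:3)
  expect_equal(z[2], 0)   # center of {1, 2, 3}
  expect_equal(z[3], 1)   # sd = 1 by hand
  expect_error(zNormalize(v, 1), "2 controls")
  expect_error(zNormalize(c(2, 2, 2, 5), 1:3), "zero control variance")
  # idempotence on controls: re-normalizing is the identity
  expect_equal(zNormalize(z, 1:3), z, tolerance = 1e-9)
})

test_that("the combined score follows the 1:0.5:0.5 weighting", {
  expect_equal(combinedScore(0, 0, 0), 0)
  expect_equal(combinedScore(1, 1, 1), 1)
  expect_equal(combinedScore(-2, 1, 1), -0.5)
  # linearity in the z-scores
  z <- c(0.3, -1.2, 2)
  expect_equal(combinedScore(3 * z[1], 3 * z[2], 3 * z[3]),
               3 * combinedScore(z[1], z[2], z[3]))
  expect_equal(combinedScore(-2, 1, 1, flipTexture = TRUE), -1.5)
  expect_warning(combinedScore(NA, 1, 1), "missing")
})

test_that("group comparison has power and respects Bonferroni", {
  set.seed(31)
  hits <- 0
  for (i in 1:300) {
    panel <- data.frame(subject_id = sprintf("S%02d", 1:60),
                        group = rep(c("PSP-RS", "control"), each = 30),
                        area = "II",
                        value = c(rnorm(30, 2, 1), rnorm(30, 0, 1)))
    res <- groupCompare(panel,
                        contrasts = defaultContrasts()["PSP vs control"],
                        m = 15)
    if (res$p_corrected < 0.05) hits <- hits + 1
  }
  expect_gt(hits / 300, 0.99)
  expect_equal(unique(res$m), 15)
})

test_that("degenerate constant groups are handled deterministically", {
  panel <- data.frame(subject_id = sprintf("S%02d", 1:8),
                      group = rep(c("PD", "control"), each = 4),
                      area = "I", value = c(rep(1, 4), rep(2, 4)))
  res <- groupCompare(panel, contrasts = defaultContrasts()["PD vs control"])
  expect_true(is.infinite(res$t))
  expect_equal(res$p, 0)
})

test_that("AUC equals the Mann-Whitney statistic on random instances", {
  set.seed(77)
  for (rep in 1:30) {
    n1 <- sample(2:50, 1); n0 <- sample(2:50, 1)
    scores <- c(round(rnorm(n1, 0.5), 2), round(rnorm(n0), 2))  # ties likely
    labels <- rep(c("case", "ref"), c(n1, n0))
    r <- rocCurve(scores, labels, "case")
    # brute-force pair counting with half-credit for ties
    cs <- scores[labels == "case"]; rs <- scores[labels == "ref"]
    U <- sum(outer(cs, rs, ">")) + 0.5 * sum(outer(cs, rs, "=="))
    expect_equal(aucValue(r), U / (n1 * n0), tolerance = 1e-12)
  }
})

test_that("ROC handles degenerate scores and matches pROC", {
  expect_equal(aucValue(rocCurve(rep(1, 10), rep(c("a", "b"), 5), "a")),
               0.5)
  expect_equal(aucValue(rocCurve(c(1, 2, 3, 4), c("b", "b", "a", "a"),
                                 "a")), 1)
  expect_error(rocCurve(1:4, rep("a", 4), "a"), "both classes")
  skip_if_not_installed("pROC")
  set.seed(5)
  scores <- rnorm(60)
  labels <- rep(c("case", "ref"), each = 30)
  mine <- aucValue(rocCurve(scores, labels, "case"))
  ref <- suppressMessages(as.numeric(
    pROC::auc(pROC::roc(labels, scores, levels = c("ref", "case"),
                        direction = "<"))))
  expect_equal(mine, ref, tolerance = 1e-12)
})

test_that("ROC curve is a valid staircase consistent with its AUC", {
  set.seed(8)
  scores <- c(rnorm(20, 1), rnorm(25))
  labels <- rep(c("case", "ref"), c(20, 25))
  r <- rocCurve(scores, labels, "case")
  expect_equal(r@fpr[1], 0); expect_equal(r@tpr[1], 0)
  expect_equal(r@fpr[length(r@fpr)], 1)
  expect_equal(r@tpr[length(r@tpr)], 1)
  expect_true(!is.unsorted(r@fpr) && !is.unsorted(r@tpr))
})
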