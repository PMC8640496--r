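#' Full pipeline configuration
#'
#' Bundles the cohort configuration with the analysis parameters of every
#' stage: segmentation, texture, FA smoothing (8 mm FWHM), tractography
#' (FA threshold 0.2, dot-product/curvature threshold 0.9), TFAS (FA
#' exclusion below 0.2), statistics (Bonferroni family 15 = 3 contrasts x
#' 5 areas) and ROC (combined score of area II).
#'
#' @param cohort a \code{\link{cohortConfig}}.
#' @param levels GLCM quantization levels.
#' @param fwhm_mm FA smoothing kernel FWHM in mm.
#' @param fa_threshold tracking FA stop threshold.
#' @param dot_threshold tracking curvature (dot product) threshold.
#' @param step_mm tracking step size in mm.
#' @param max_steps tracking step cap per direction.
#' @param tfas_threshold TFAS FA exclusion threshold.
#' @param flip_texture negate texture z-scores in the combined score (see
#'   \code{\link{combinedScore}}); TRUE by default so that affected
#'   subjects get uniformly reduced scores.
#' @param bonferroni_m Bonferroni family size; NULL = contrasts x areas.
#' @param roc_area callosal area whose combined score enters the ROC
#'   analysis.
#' @return list of class \code{"pipelineConfig"}.
#' @export
pipelineConfig <- function(cohort = cohortConfig(), levels = 32L,
                           fwhm_mm = 8, fa_threshold = 0.2,
                           dot_threshold = 0.9, step_mm = 1,
                           max_steps = 300L, tfas_threshold = 0.2,
                           flip_texture = TRUE, bonferroni_m = NULL,
                           roc_area = "II") {
  cfg <- list(cohort = cohort, levels = as.integer(levels),
              fwhm_mm = fwhm_mm, fa_threshold = fa_threshold,
              dot_threshold = dot_threshold, step_mm = step_mm,
              max_steps = as.integer(max_steps),
              tfas_threshold = tfas_threshold,
              flip_texture = flip_texture, bonferroni_m = bonferroni_m,
              roc_area = roc_area)
  class(cfg) <- "pipelineConfig"
  cfg
}

#' Read a pipeline configuration from JSON or YAML
#'
#' Values present in the document override the defaults of
#' \code{\link{pipelineConfig}} / \code{\link{cohortConfig}}; the
#' \code{cohort} block is passed to \code{cohortConfig}.
#'
#' @param path file path ending in .json, .yaml or .yml.
#' @return a \code{"pipelineConfig"}.
#' @export
readPipelineConfig <- function(path) {
  doc <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::fromJSON(path, simplifyVector = TRUE)
  cohortArgs <- doc$cohort
  doc$cohort <- NULL
  cohort <- do.call(cohortConfig, as.list(cohortArgs))
  do.call(pipelineConfig, c(list(cohort = cohort), doc))
}

stageTry <- function(stage, subject = NULL, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", stage, "'",
         if (!is.null(subject)) paste0(" (subject ", subject, ")"),
         " failed: ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full corpus callosum analysis cascade
#'
#' Executes simulate -> segment -> subdivide -> planimetry -> texture ->
#' FA mapping -> smoothing -> age correction -> control averaging ->
#' tractography -> TFAS -> z-normalization -> combined score -> group
#' comparisons -> ROC on a synthetic cohort. Every stage runs with the
#' parameters recorded in the configuration; the run is bit-reproducible
#' from the configuration (including its seed).
#'
#' @param config a \code{\link{pipelineConfig}}.
#' @param cohort optionally a pre-generated \code{\link{generateCohort}}
#'   result (must match \code{config$cohort}); NULL generates it.
#' @return list of class \code{"ccAnalysis"} with \code{subjects},
#'   \code{planimetry}, \code{texture}, \code{tfasMeans}, \code{panel},
#'   \code{tests} (one table per marker family), \code{roc} (one
#'   \code{\linkS4class{ROCResult}} per contrast), \code{tracts} and the
#'   \code{config}.
#' @export
runPipeline <- function(config, cohort = NULL) {
  stopifnot(inherits(config, "pipelineConfig"))
  if (is.null(cohort))
    cohort <- stageTry("simulate", NULL, generateCohort(config$cohort))
  subjects <- cohort$subjects
  n <- nrow(subjects)
  areaNames <- c("I", "II", "III", "IV", "V")
  pix2 <- cohort$config$geometry$pixdim[2:3]

  # midsagittal morphometry and texture per subject
  planRows <- texRows <- vector("list", n)
  for (i in seq_len(n)) {
    id <- subjects$subject_id[i]
    seg <- stageTry("segment", id, segmentCC(cohort$images[[i]]$t1w))
    lm <- stageTry("subdivide", id, subdivideHoferFrahm(seg, pix2))
    pl <- stageTry("planimetry", id, planimetry(lm))
    pl <- data.frame(subject_id = id, pl,
                     total_mm2 = attr(pl, "total_mm2"))
    planRows[[i]] <- pl
    tx <- stageTry("texture", id,
                   areaTexture(cohort$images[[i]]$t1w, lm,
                               levels = config$levels))
    texRows[[i]] <- data.frame(subject_id = id, tx)
  }
  planTab <- do.call(rbind, planRows)
  texTab <- do.call(rbind, texRows)

  # FA maps: compute, smooth, age-correct
  faMaps <- lapply(seq_len(n), function(i)
    stageTry("fa_map", subjects$subject_id[i], {
      smoothFA(computeFA(cohort$images[[i]]$tensor), config$fwhm_mm)
    }))
  controlIdx <- which(subjects$group == "control")
  faMaps <- stageTry("age_correct", NULL,
                     ageCorrect(faMaps, subjects$age, controlIdx))
  names(faMaps) <- subjects$subject_id

  # tracking on the averaged control dataset
  meanTensor <- stageTry("average_controls", NULL,
    averageControlDataset(lapply(controlIdx,
                                 function(i) cohort$images[[i]]$tensor)))
  xmid <- (cohort$config$geometry$dims[1] + 1) / 2
  seeds <- ccSeedVoxels(cohort$template, xmid)
  tracts <- stageTry("track", NULL,
    trackStreamlines(meanTensor, seeds, config$fa_threshold,
                     config$dot_threshold, config$step_mm,
                     config$max_steps))

  # TFAS subject means
  tfasMeans <- stageTry("tfas", NULL,
    tfasSubjectMeans(faMaps, tracts, config$tfas_threshold))

  # marker panel: merge, z-normalize against controls, combined score
  panel <- merge(tfasMeans[, c("subject_id", "area", "fa_tract")],
                 texTab[, c("subject_id", "area", "entropy",
                            "inhomogeneity")],
                 by = c("subject_id", "area"), all = TRUE)
  panel <- merge(subjects, panel, by = "subject_id")
  panel <- panel[order(panel$area, match(panel$subject_id,
                                         subjects$subject_id)), ]
  rownames(panel) <- NULL
  panel$z_fa <- panel$z_entropy <- panel$z_inhomogeneity <- NA_real_
  for (a in areaNames) {
    sel <- panel$area == a
    ctrl <- which(panel$group[sel] == "control")
    panel$z_fa[sel] <- zNormalize(panel$fa_tract[sel], ctrl)
    panel$z_entropy[sel] <- zNormalize(panel$entropy[sel], ctrl)
    panel$z_inhomogeneity[sel] <- zNormalize(panel$inhomogeneity[sel], ctrl)
  }
  panel$c_score <- combinedScore(panel$z_fa, panel$z_entropy,
                                 panel$z_inhomogeneity,
                                 flipTexture = config$flip_texture)

  # group comparisons per marker family
  families <- c(c_score = "c_score", fa_tract = "fa_tract",
                entropy = "entropy", inhomogeneity = "inhomogeneity")
  tests <- lapply(families, function(col) {
    d <- panel[, c("subject_id", "group", "area")]
    d$value <- panel[[col]]
    groupCompare(d, m = config$bonferroni_m)
  })
  planPanel <- data.frame(subject_id = planTab$subject_id,
                          area = planTab$area,
                          value = planTab$ratio)
  planPanel <- merge(planPanel, subjects[, c("subject_id", "group")],
                     by = "subject_id")
  tests$area_ratio <- groupCompare(planPanel, m = config$bonferroni_m)

  # ROC of the combined score in the configured area; affected subjects
  # have reduced scores, so the negated score ranks patients higher
  rocs <- list()
  sel <- panel$area == config$roc_area
  for (cn in names(defaultContrasts())) {
    ct <- defaultContrasts()[[cn]]
    keep <- sel & panel$group %in% c(ct$a, ct$b)
    lab <- ifelse(panel$group[keep] %in% ct$a, "case", "reference")
    rocs[[cn]] <- stageTry("roc", NULL,
      rocCurve(-panel$c_score[keep], lab, "case", contrast = cn))
  }

  out <- list(subjects = subjects, planimetry = planTab, texture = texTab,
              tfasMeans = tfasMeans, panel = panel, tests = tests,
              roc = rocs, tracts = tracts, config = config)
  class(out) <- "ccAnalysis"
  out
}

#' @export
print.ccAnalysis <- function(x, ...) {
  cat("ccAnalysis of", nrow(x$subjects), "subjects\n")
  sig <- x$tests$c_score
  sig <- sig[sig$p_corrected < 0.05, c("area", "contrast", "p_corrected")]
  if (nrow(sig)) {
    cat("combined score: corrected p < 0.05 in:\n")
    print(sig, row.names = FALSE)
  } else cat("combined score: no corrected significance\n")
  for (cn in names(x$roc))
    cat(sprintf("AUC [%s, area %s] = %.3f\n", cn, x$config$roc_area,
                aucValue(x$roc[[cn]])))
  invisible(x)
}

#' Write pipeline results to disk
#'
#' Tab-separated tables for every tabulated result, the ROC curves as
#' JSON and the configuration as JSON, mirroring the in-memory bundle.
#'
#' @param result a \code{"ccAnalysis"}.
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of files written.
#' @export
writePipelineResults <- function(result, dir) {
  stopifnot(inherits(result, "ccAnalysis"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(d, f) {
    path <- file.path(dir, f)
    utils::write.table(d, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    path
  }
  files <- c(
    wt(result$subjects, "subjects.tsv"),
    wt(result$planimetry, "planimetry.tsv"),
    wt(result$texture, "texture.tsv"),
    wt(result$tfasMeans, "tfas_subject_means.tsv"),
    wt(result$panel, "marker_panel.tsv"))
  testTab <- do.call(rbind, lapply(names(result$tests), function(f) {
    cbind(marker = f, result$tests[[f]])
  }))
  files <- c(files, wt(testTab, "group_tests.tsv"))
  rocJson <- lapply(result$roc, function(r)
    list(contrast = r@contrast, auc = r@auc, fpr = r@fpr, tpr = r@tpr,
         positive_class = r@positiveClass))
  rocPath <- file.path(dir, "roc.json")
  jsonlite::write_json(rocJson, rocPath, auto_unbox = TRUE, digits = NA)
  cfg <- result$config
  cfg$cohort$geometry <- unclass(cfg$cohort$geometry)
  cfg$cohort <- unclass(cfg$cohort)
  cfgPath <- file.path(dir, "config.json")
  jsonlite::write_json(unclass(cfg), cfgPath, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(c(files, rocPath, cfgPath))
}
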