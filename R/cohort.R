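#' Synthetic cohort configuration
#'
#' Defines a phantom study population. Group sizes and ages default to
#' the study demographics (46 PSP-RS, 20 PSP-P, 66 PD, 44 controls; age
#' 71 +/- 9 years). Group-level effects are confined to callosal areas
#' I-III by default, larger in PSP than PD, with the FA reduction in PD
#' restricted to area III; areas IV and V carry no effect. The CC
#' geometry is identical across subjects, so template planimetry shows no
#' group differences by construction.
#'
#' @param n_psp_rs,n_psp_p,n_pd,n_control group sizes, each >= 2.
#' @param age_mean,age_sd age distribution (years).
#' @param geometry a \code{\link{phantomGeometry}}.
#' @param base_fa bundle FA in controls.
#' @param background_fa FA of the (near-isotropic) background.
#' @param fa_effect named list (\code{"PSP-RS"}, \code{"PSP-P"},
#'   \code{"PD"}) of length-5 additive FA reductions per area; values
#'   must leave bundle FA >= 0.25 so tracking through affected bundles
#'   remains possible.
#' @param texture_effect named list of length-5 additive shifts of the
#'   rough texture amplitude per area.
#' @param base_amplitude rough texture amplitude in controls (intensity
#'   units).
#' @param smooth_amplitude fixed smooth intensity component of the CC.
#' @param base_intensity,contrast_margin,noise_sd T1w intensity model.
#' @param fa_subject_sd between-subject SD of each area's bundle FA.
#' @param tensor_noise_sd voxelwise SD of tensor component noise
#'   (mm^2/s).
#' @param age_slope FA change per year applied to all bundles (0 by
#'   default; a non-zero value makes the age correction testable).
#' @param md mean diffusivity of all tensors (mm^2/s).
#' @param seed master RNG seed; the cohort is bit-reproducible given it.
#' @return a validated list of class \code{"cohortConfig"}.
#' @export
cohortConfig <- function(n_psp_rs = 46L, n_psp_p = 20L, n_pd = 66L,
                         n_control = 44L, age_mean = 71, age_sd = 9,
                         geometry = phantomGeometry(),
                         base_fa = 0.7, background_fa = 0.05,
                         fa_effect = list(
                           "PSP-RS" = c(0.06, 0.11, 0.10, 0, 0),
                           "PSP-P"  = c(0.05, 0.08, 0.08, 0, 0),
                           "PD"     = c(0, 0, 0.05, 0, 0)),
                         texture_effect = list(
                           "PSP-RS" = c(3.5, 5.0, 4.0, 0, 0),
                           "PSP-P"  = c(2.5, 3.5, 3.0, 0, 0),
                           "PD"     = c(2.0, 2.5, 2.5, 0, 0)),
                         base_amplitude = 3, smooth_amplitude = 6,
                         base_intensity = 120, contrast_margin = 0.5,
                         noise_sd = 2, fa_subject_sd = 0.03,
                         tensor_noise_sd = 2e-5, age_slope = 0,
                         md = 7e-4, seed = 1L) {
  n <- c(n_psp_rs, n_psp_p, n_pd, n_control)
  if (any(n < 2)) stop("every group needs n >= 2 (group statistics ",
                       "are undefined otherwise)")
  for (g in c("PSP-RS", "PSP-P", "PD")) {
    fe <- fa_effect[[g]]
    te <- texture_effect[[g]]
    if (length(fe) != 5 || length(te) != 5)
      stop("effects must have one value per area (5)")
    if (any(base_fa - fe < 0.25))
      stop("fa_effect must leave bundle FA >= 0.25 for group ", g)
    if (any(te < 0) || any(base_amplitude + te < 0))
      stop("texture amplitudes must remain >= 0")
  }
  cfg <- list(n_psp_rs = n_psp_rs, n_psp_p = n_psp_p, n_pd = n_pd,
              n_control = n_control, age_mean = age_mean, age_sd = age_sd,
              geometry = geometry, base_fa = base_fa,
              background_fa = background_fa, fa_effect = fa_effect,
              texture_effect = texture_effect,
              base_amplitude = base_amplitude,
              smooth_amplitude = smooth_amplitude,
              base_intensity = base_intensity,
              contrast_margin = contrast_margin, noise_sd = noise_sd,
              fa_subject_sd = fa_subject_sd,
              tensor_noise_sd = tensor_noise_sd, age_slope = age_slope,
              md = md, seed = as.integer(seed))
  class(cfg) <- "cohortConfig"
  cfg
}

#' Generate a synthetic cohort
#'
#' Builds the CC template and fiber bundles once (the geometry is shared
#' by every subject) and synthesizes one midsagittal T1w slice and one
#' diffusion tensor volume per subject with the configured group-level
#' effects, between-subject variability and noise. Fully reproducible
#' from the configuration seed.
#'
#' @param config a \code{\link{cohortConfig}}.
#' @return a list of class \code{"ccCohort"}: \code{subjects} (table with
#'   subject_id, group, age, sex), \code{template}, \code{bundles},
#'   \code{images} (per subject: \code{t1w} matrix and \code{tensor}
#'   \code{\linkS4class{TensorVolume}}), and the \code{config}.
#' @export
generateCohort <- function(config) {
  stopifnot(inherits(config, "cohortConfig"))
  geom <- config$geometry
  template <- makeCCTemplate(geom)
  bundles <- makePhantomBundles(geom, template)
  groups <- c(rep("PSP-RS", config$n_psp_rs), rep("PSP-P", config$n_psp_p),
              rep("PD", config$n_pd), rep("control", config$n_control))
  n <- length(groups)
  set.seed(config$seed)
  ages <- round(stats::rnorm(n, config$age_mean, config$age_sd), 1)
  sex <- sample(c("m", "f"), n, replace = TRUE)
  subjSeeds <- sample.int(.Machine$integer.max - 1L, n)
  subjects <- data.frame(
    subject_id = sprintf("S%03d", seq_len(n)),
    group = groups, age = ages, sex = sex, stringsAsFactors = FALSE)
  zero <- rep(0, 5)
  images <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed(subjSeeds[i])
    fe <- if (groups[i] == "control") zero else config$fa_effect[[groups[i]]]
    te <- if (groups[i] == "control") zero else
      config$texture_effect[[groups[i]]]
    faBy <- config$base_fa - fe +
      stats::rnorm(5, sd = config$fa_subject_sd) +
      config$age_slope * (ages[i] - config$age_mean)
    faBy <- pmin(pmax(faBy, 0.25), 0.95)
    t1w <- synthesizeT1wSlice(
      template, baseIntensity = config$base_intensity,
      amplitude = config$base_amplitude + te, noiseSd = config$noise_sd,
      smoothAmplitude = config$smooth_amplitude,
      contrastMargin = config$contrast_margin)
    tensor <- synthesizeTensorVolume(
      geom, faBy, backgroundFa = config$background_fa, md = config$md,
      noiseSd = config$tensor_noise_sd, bundles = bundles)
    images[[i]] <- list(t1w = t1w, tensor = tensor)
  }
  names(images) <- subjects$subject_id
  out <- list(subjects = subjects, template = template, bundles = bundles,
              images = images, config = config)
  class(out) <- "ccCohort"
  out
}

#' @export
print.ccCohort <- function(x, ...) {
  cat("ccCohort:", nrow(x$subjects), "subjects (",
      paste(names(table(x$subjects$group)), table(x$subjects$group),
            sep = "=", collapse = ", "), ")\n")
  invisible(x)
}
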