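#' Control-referenced z-normalization
#'
#' \eqn{z = (x - \bar{x}_{ctrl}) / sd_{ctrl}} with the sample (n - 1)
#' standard deviation of the control subjects; applied per area and per
#' marker by the callers.
#'
#' @param values numeric vector over subjects.
#' @param controlIdx indices of the control subjects (at least 2, with
#'   non-zero variance).
#' @return numeric vector of z-scores.
#' @export
zNormalize <- function(values, controlIdx) {
  if (length(controlIdx) < 2)
    stop("at least 2 controls are required for z-normalization")
  ctrl <- values[controlIdx]
  s <- stats::sd(ctrl, na.rm = TRUE)
  if (is.na(s) || s == 0) stop("zero control variance")
  (values - mean(ctrl, na.rm = TRUE)) / s
}

#' Combined score C
#'
#' \eqn{C = (z_{FA} + 0.5\, z_{entropy} + 0.5\, z_{homogeneity}) / 2}:
#' microstructure (FA, weight 1) and texture (entropy and
#' homogeneity/inhomogeneity, weight 0.5 each) contribute equally. The
#' formula is computed verbatim; because FA decreases while the texture
#' z-scores increase in patients, the verbatim sum partially cancels, and
#' \code{flipTexture = TRUE} negates the texture z-scores so that
#' affected subjects get uniformly reduced scores.
#'
#' @param zFa,zEntropy,zHomogeneity numeric vectors of z-scores.
#' @param flipTexture negate the texture z-scores before combining.
#' @return numeric vector; missing inputs give NA with a warning.
#' @export
combinedScore <- function(zFa, zEntropy, zHomogeneity, flipTexture = FALSE) {
  if (flipTexture) {
    zEntropy <- -zEntropy
    zHomogeneity <- -zHomogeneity
  }
  C <- (zFa + 0.5 * zEntropy + 0.5 * zHomogeneity) / 2
  if (anyNA(C)) warning("missing marker inputs; combined score set to NA")
  C
}

#' Default group contrasts
#'
#' PSP vs. controls, PD vs. controls and PSP vs. PD, with PSP pooling the
#' PSP-RS and PSP-P subtypes. Subtype contrasts can be added by the same
#' mechanism.
#'
#' @return named list; each element has \code{a} and \code{b} character
#'   vectors of group labels.
#' @export
defaultContrasts <- function() {
  psp <- c("PSP-RS", "PSP-P")
  list("PSP vs control" = list(a = psp, b = "control"),
       "PD vs control" = list(a = "PD", b = "control"),
       "PSP vs PD" = list(a = psp, b = "PD"))
}

# pooled-variance two-sample Student's t with deterministic handling of
# degenerate (zero-variance) inputs: equal constant groups give t = 0,
# p = 1; different constant groups give |t| = Inf, p = 0.
studentT <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  nx <- length(x); ny <- length(y)
  if (nx < 2 || ny < 2) stop("each group needs at least 2 observations")
  dx <- mean(x) - mean(y)
  sp2 <- ((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) /
    (nx + ny - 2)
  se <- sqrt(sp2 * (1 / nx + 1 / ny))
  if (se == 0) {
    t <- if (dx == 0) 0 else sign(dx) * Inf
    p <- if (dx == 0) 1 else 0
  } else {
    t <- dx / se
    p <- 2 * stats::pt(-abs(t), df = nx + ny - 2)
  }
  c(delta = dx, t = t, p = p)
}

#' Bonferroni-corrected group comparisons per callosal area
#'
#' Two-sample pooled-variance Student's t-test per area and contrast,
#' with Bonferroni correction over the declared family (by default
#' #contrasts x #areas = 15). Significance stars follow corrected
#' p < 0.01 (*) and p < 0.001 (**).
#'
#' @param panel data.frame with columns \code{subject_id}, \code{group},
#'   \code{area} and \code{value}.
#' @param contrasts named list as from \code{\link{defaultContrasts}}.
#' @param m Bonferroni family size; NULL uses contrasts x areas.
#' @param welch use Welch's t-test instead of the pooled-variance form.
#' @return data.frame with one row per area x contrast: \code{delta},
#'   \code{t}, \code{p}, \code{p_corrected} (= min(1, p m)), \code{m},
#'   \code{stars}.
#' @export
groupCompare <- function(panel, contrasts = defaultContrasts(), m = NULL,
                         welch = FALSE) {
  stopifnot(all(c("group", "area", "value") %in% names(panel)))
  areas <- unique(panel$area)
  if (is.null(m)) m <- length(contrasts) * length(areas)
  rows <- list()
  for (cn in names(contrasts)) {
    ct <- contrasts[[cn]]
    for (a in areas) {
      x <- panel$value[panel$area == a & panel$group %in% ct$a]
      y <- panel$value[panel$area == a & panel$group %in% ct$b]
      if (!length(x) || !length(y)) stop("empty group in contrast ", cn)
      if (welch) {
        tt <- stats::t.test(x, y, var.equal = FALSE)
        res <- c(delta = unname(diff(rev(tt$estimate))),
                 t = unname(tt$statistic), p = tt$p.value)
      } else {
        res <- studentT(x, y)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        area = a, contrast = cn, delta = res["delta"], t = res["t"],
        p = res["p"], p_corrected = min(1, res["p"] * m), m = m,
        row.names = NULL)
    }
  }
  out <- do.call(rbind, rows)
  out$stars <- ifelse(out$p_corrected < 0.001, "**",
                      ifelse(out$p_corrected < 0.01, "*", ""))
  out
}

#' ROC curve and AUC
#'
#' ROC curve over all unique score thresholds (positives are subjects of
#' \code{positiveClass}, called positive when their score is at or above
#' the threshold). Ties are handled by grouping, so the trapezoidal AUC
#' equals the midrank Mann-Whitney statistic U / (n1 n0).
#'
#' @param scores numeric vector.
#' @param labels vector of class labels.
#' @param positiveClass the label scored as positive.
#' @param contrast optional contrast name stored with the result.
#' @return a \code{\linkS4class{ROCResult}}.
#' @export
rocCurve <- function(scores, labels, positiveClass, contrast = "") {
  pos <- labels == positiveClass
  if (!any(pos) || all(pos)) stop("both classes must be present")
  if (anyNA(scores)) {
    keep <- !is.na(scores)
    scores <- scores[keep]; pos <- pos[keep]
    if (!any(pos) || all(pos)) stop("both classes must be present")
  }
  n1 <- sum(pos); n0 <- sum(!pos)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; p <- pos[ord]
  thresholds <- unique(s)
  tp <- fp <- numeric(length(thresholds))
  i <- 1L
  cumTp <- cumFp <- 0
  for (k in seq_along(thresholds)) {
    while (i <= length(s) && s[i] == thresholds[k]) {
      if (p[i]) cumTp <- cumTp + 1 else cumFp <- cumFp + 1
      i <- i + 1L
    }
    tp[k] <- cumTp; fp[k] <- cumFp
  }
  tpr <- c(0, tp / n1); fpr <- c(0, fp / n0)
  n <- length(fpr)
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-n]) / 2)
  new("ROCResult", thresholds = thresholds, fpr = fpr, tpr = tpr,
      auc = auc, contrast = contrast,
      positiveClass = as.character(positiveClass))
}
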