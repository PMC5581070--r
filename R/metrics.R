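#' Basic SUV metrics over a lesion VOI
#'
#' SUVmax, SUVmean, SUV standard deviation, metabolic tumor volume (MTV, ml)
#' and total lesion glycolysis (TLG = MTV x SUVmean) over the masked voxels.
#' The SD uses the population denominator \code{n} by default (recorded in the
#' provenance; switchable to the sample denominator \code{n - 1}).
#'
#' @param volume an \code{\link{suv_volume}}.
#' @param mask an aligned \code{\link{voi_mask}} (same grid and spacing).
#' @param sd_denominator \code{"n"} (population, default) or \code{"n-1"}.
#' @return A list of class \code{lesion_metrics} with fields \code{suv_max},
#'   \code{suv_mean}, \code{suv_sd}, \code{mtv}, \code{tlg}, \code{n_voxels}
#'   and a \code{provenance} list; heterogeneity fields (\code{inv_cov},
#'   \code{auc_csh}) and \code{diameter} are filled by
#'   \code{\link{lesion_metrics}}.
#' @export
compute_basic <- function(volume, mask, sd_denominator = c("n", "n-1")) {
  sd_denominator <- match.arg(sd_denominator)
  check_alignment(volume, mask)
  vals <- volume$values[mask$mask]
  n <- length(vals)
  m <- mean(vals)
  ss <- sum((vals - m)^2)
  s <- sqrt(ss / if (sd_denominator == "n") n else max(n - 1, 1))
  mtv <- n * voxel_volume_ml(mask)
  structure(list(suv_max = max(vals), suv_mean = m, suv_sd = s,
                 mtv = mtv, tlg = mtv * m, n_voxels = n,
                 diameter = NA_real_, inv_cov = NA_real_, auc_csh = NA_real_,
                 heterogeneity_eligible = NA,
                 provenance = list(segmentation = mask$method,
                                   segmentation_params = mask$params,
                                   sd_denominator = sd_denominator)),
            class = "lesion_metrics")
}

#' Cumulative SUV-volume histogram
#'
#' The curve of the fraction of VOI volume with SUV strictly above a
#' threshold, as the threshold sweeps from 0 to 100\% of SUVmax. Uniform
#' uptake gives a flat curve at 1; heterogeneous uptake pulls the curve (and
#' its area, \code{\link{auc_csh}}) down.
#'
#' @inheritParams compute_basic
#' @param n_thresholds number of uniform threshold steps on
#'   \code{[0, 1] * SUVmax} (>= 2; default 1000, giving quadrature error well
#'   below the 2-decimal reporting precision).
#' @return A list of class \code{csh_curve}: \code{thresholds} (fractions of
#'   SUVmax) and \code{volume_fractions}, both length \code{n_thresholds + 1},
#'   with \code{volume_fractions} non-increasing and equal to 1 at threshold 0
#'   for any positive-uptake lesion.
#' @export
compute_csh <- function(volume, mask, n_thresholds = 1000) {
  check_alignment(volume, mask)
  if (n_thresholds < 2) stop("'n_thresholds' must be >= 2")
  vals <- volume$values[mask$mask]
  smax <- max(vals)
  if (smax <= 0) stop("no uptake: SUVmax is 0 in the VOI")
  th <- seq(0, 1, length.out = n_thresholds + 1)
  # fraction with SUV strictly above t * SUVmax, via the empirical CDF
  vf <- 1 - stats::ecdf(vals / smax)(th)
  structure(list(thresholds = th, volume_fractions = vf, suv_max = smax),
            class = "csh_curve")
}

#' Area under the cumulative SUV-volume histogram (AUC-CSH)
#'
#' Trapezoidal integral of the CSH over threshold fraction in [0, 1]. A
#' perfectly uniform lesion scores 1; lower values correspond to increased
#' uptake heterogeneity.
#'
#' @param curve a \code{\link{compute_csh}} result.
#' @return A number in (0, 1].
#' @export
auc_csh <- function(curve) {
  t <- curve$thresholds; f <- curve$volume_fractions
  if (is.unsorted(t)) stop("thresholds must be increasing")
  sum(diff(t) * (f[-length(f)] + f[-1]) / 2)
}

#' Inverse coefficient of variation (1/COV)
#'
#' SUVmean / SUV-SD over the VOI: a homogeneity score (higher = more
#' homogeneous uptake). Undefined for a perfectly homogeneous lesion (SD = 0),
#' in which case \code{NA} is returned with a warning.
#'
#' @param suv_mean,suv_sd lesion SUVmean and SUV standard deviation.
#' @return \code{suv_mean / suv_sd}, or \code{NA} when \code{suv_sd == 0}.
#' @export
inv_cov <- function(suv_mean, suv_sd) {
  if (any(suv_sd < 0, na.rm = TRUE)) stop("'suv_sd' must be >= 0")
  out <- suv_mean / suv_sd
  zero <- !is.na(suv_sd) & suv_sd == 0
  if (any(zero)) {
    warning("homogeneous lesion: 1/COV undefined (SD = 0)")
    out[zero] <- NA_real_
  }
  out
}

#' Apply the minimum-size rule for heterogeneity metrics
#'
#' Heterogeneity analyses are only meaningful with an adequate number of
#' voxels: lesions with a metabolic tumor diameter below \code{min_diameter}
#' (default 10 mm) have their heterogeneity fields (SUV-SD as a heterogeneity
#' index, 1/COV, AUC-CSH) set to \code{NA} and are flagged ineligible. A
#' diameter of exactly 10 mm is eligible.
#'
#' @param metrics a \code{lesion_metrics} object with \code{diameter} filled.
#' @param min_diameter eligibility cutoff in mm.
#' @return The metrics with \code{heterogeneity_eligible} set and, when
#'   ineligible, \code{suv_sd}, \code{inv_cov} and \code{auc_csh} set to NA.
#' @export
apply_eligibility <- function(metrics, min_diameter = 10) {
  if (is.na(metrics$diameter)) stop("diameter must be computed first")
  eligible <- metrics$diameter >= min_diameter
  metrics$heterogeneity_eligible <- eligible
  if (!eligible) {
    metrics$suv_sd <- NA_real_
    metrics$inv_cov <- NA_real_
    metrics$auc_csh <- NA_real_
  }
  metrics
}

#' All per-lesion metrics for a segmented lesion
#'
#' Convenience wrapper running \code{\link{compute_basic}},
#' \code{\link{metabolic_diameter}}, \code{\link{compute_csh}} /
#' \code{\link{auc_csh}}, \code{\link{inv_cov}} and
#' \code{\link{apply_eligibility}} in sequence.
#'
#' @inheritParams compute_basic
#' @inheritParams compute_csh
#' @param diameter_mode \code{"3d"} or \code{"axial"}, see
#'   \code{\link{metabolic_diameter}}.
#' @param min_diameter heterogeneity eligibility cutoff, mm.
#' @return A complete \code{lesion_metrics} object.
#' @export
lesion_metrics <- function(volume, mask, n_thresholds = 1000,
                           sd_denominator = c("n", "n-1"),
                           diameter_mode = c("3d", "axial"),
                           min_diameter = 10) {
  met <- compute_basic(volume, mask, sd_denominator)
  diam <- metabolic_diameter(mask, match.arg(diameter_mode))
  met$diameter <- as.numeric(diam)
  met$provenance$diameter_mode <- attr(diam, "mode")
  met$auc_csh <- auc_csh(compute_csh(volume, mask, n_thresholds))
  met$inv_cov <- if (met$suv_sd > 0) met$suv_mean / met$suv_sd else NA_real_
  met$provenance$n_thresholds <- n_thresholds
  apply_eligibility(met, min_diameter)
}

#' @export
print.lesion_metrics <- function(x, ...) {
  cat("Lesion metrics (", x$provenance$segmentation, "):\n", sep = "")
  cat(sprintf("  SUVmax %.2f  SUVmean %.2f  SD %s\n", x$suv_max, x$suv_mean,
              if (is.na(x$suv_sd)) "NA" else sprintf("%.2f", x$suv_sd)))
  cat(sprintf("  MTV %.2f ml  TLG %.2f  diameter %.1f mm\n",
              x$mtv, x$tlg, x$diameter))
  cat(sprintf("  1/COV %s  AUC-CSH %s  heterogeneity eligible: %s\n",
              if (is.na(x$inv_cov)) "NA" else sprintf("%.2f", x$inv_cov),
              if (is.na(x$auc_csh)) "NA" else sprintf("%.2f", x$auc_csh),
              x$heterogeneity_eligible))
  invisible(x)
}
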