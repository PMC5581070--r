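#' Published reference counts for the NSCLC cohort
#'
#' The printed summary tables of the 131-patient surgical adenocarcinoma
#' cohort this package's simulator is calibrated to: one-way patient counts
#' (gender, smoking status, stage, mutation calls), the EGFR-by-covariate and
#' KRAS-by-covariate cross counts, normal-lung background uptake per field,
#' and the printed ranges of the lesion metrics. These counts are data inputs
#' (not computed results) and are the anchors for the arithmetic
#' reproductions in the test-suite and acceptance script.
#'
#' @return A list:
#' \describe{
#'   \item{gender}{named counts, male/female.}
#'   \item{smoking}{named counts, current/former/never.}
#'   \item{stage}{named counts, IA..IV and undefined.}
#'   \item{egfr, kras}{named counts pos/neg/na.}
#'   \item{egfr_by_gender, egfr_by_smoking, kras_by_gender, kras_by_smoking}{
#'     2-column matrices of (pos, neg) counts per covariate level.}
#'   \item{background}{data.frame of per-field normal-lung SUVmean, SD and
#'     range (six lung fields plus blood pool).}
#'   \item{metric_ranges}{data.frame of printed mean, SD, min, max per lesion
#'     metric over the whole cohort.}
#' }
#' @export
reference_counts <- function() {
  list(
    n_patients = 131L,
    gender = c(male = 86L, female = 45L),
    smoking = c(current = 22L, former = 77L, never = 32L),
    stage = c(IA = 66L, IB = 26L, IIA = 12L, IIB = 10L, IIIA = 12L,
              IV = 2L, undefined = 3L),
    egfr = c(pos = 32L, neg = 95L, na = 4L),
    kras = c(pos = 31L, neg = 95L, na = 5L),
    egfr_by_gender = matrix(c(16L, 66L, 16L, 29L), nrow = 2, byrow = TRUE,
                            dimnames = list(c("male", "female"), c("pos", "neg"))),
    egfr_by_smoking = matrix(c(1L, 20L, 13L, 62L, 18L, 13L), nrow = 3, byrow = TRUE,
                             dimnames = list(c("current", "former", "never"),
                                             c("pos", "neg"))),
    kras_by_gender = matrix(c(25L, 59L, 6L, 36L), nrow = 2, byrow = TRUE,
                            dimnames = list(c("male", "female"), c("pos", "neg"))),
    kras_by_smoking = matrix(c(8L, 14L, 20L, 54L, 3L, 27L), nrow = 3, byrow = TRUE,
                             dimnames = list(c("current", "former", "never"),
                                             c("pos", "neg"))),
    background = data.frame(
      field = c("ruf", "luf", "rmf", "lmf", "rlf", "llf", "blood_pool"),
      suv_mean = c(0.5, 0.5, 0.4, 0.5, 0.6, 0.6, 1.7),
      suv_sd = c(0.1, 0.1, 0.2, 0.2, 0.3, 0.2, 0.4),
      min = c(0.2, 0.2, 0.1, 0.2, 0.1, 0.3, 0.8),
      max = c(0.9, 1.1, 1.3, 1.2, 1.8, 1.3, 2.9)),
    metric_ranges = data.frame(
      metric = c("diameter", "suv_max", "suv_mean", "tlg", "mtv",
                 "suv_sd_gt10", "inv_cov_gt10", "auc_csh_gt10"),
      mean = c(33, 6.3, 3.8, 109.2, 14.5, 1.20, 4.24, 0.61),
      sd = c(27, 5.9, 2.7, 530.8, 38.8, 1.16, 2.01, 0.12),
      min = c(8, 0.7, 0.7, 0.4, 0.3, 0.08, 1.51, 0.28),
      max = c(230, 36.7, 18.9, 5577.5, 295.1, 6.07, 17.91, 0.86)))
}

# distribute 'counts' (named vector) as a character vector of labels over n
# slots, in order; counts must sum to n
spread_counts <- function(counts, n) {
  stopifnot(sum(counts) == n)
  rep(names(counts), times = counts)
}

#' Patient-level table reconstructed from the published counts
#'
#' Builds one 131-row patient table consistent with the published one-way
#' margins (gender, smoking, stage, EGFR and KRAS call counts) and with the
#' EGFR-by-gender and EGFR-by-smoking two-way margins. The three-way joint
#' structure, and the joints of KRAS with the covariates, are not determined
#' by the published tables and are filled arbitrarily (KRAS enters only
#' through its pos/neg/NA totals). Ages, pack-years and lesion metrics are
#' not reconstructable per patient and are left NA.
#'
#' @return A \code{cohort_table} with 131 rows.
#' @export
cohort_from_counts <- function() {
  rc <- reference_counts()
  blocks <- list()
  # EGFR classes in order pos, neg, NA; within each, gender and smoking
  # sequences satisfying the published EGFR cross tables
  eg_gender <- list(pos = c(male = 16L, female = 16L),
                    neg = c(male = 66L, female = 29L),
                    na = c(male = 4L, female = 0L))
  eg_smoking <- list(pos = c(current = 1L, former = 13L, never = 18L),
                     neg = c(current = 20L, former = 62L, never = 13L),
                     na = c(current = 1L, former = 2L, never = 1L))
  for (cls in c("pos", "neg", "na")) {
    k <- rc$egfr[[cls]]
    blocks[[cls]] <- data.frame(
      gender = spread_counts(eg_gender[[cls]], k),
      smoking_status = spread_counts(eg_smoking[[cls]], k),
      egfr = if (cls == "na") NA_character_ else cls,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, blocks)
  n <- nrow(out)
  out$kras <- spread_counts(rc$kras, n)
  out$kras[out$kras == "na"] <- NA_character_
  out$stage <- spread_counts(rc$stage, n)
  out$patient_id <- sprintf("R%04d", seq_len(n))
  out$age <- NA_real_
  out$pack_years <- ifelse(out$smoking_status == "never", 0, NA_real_)
  for (m in c("diameter", "suv_max", "suv_mean", "suv_sd", "mtv", "tlg",
              "inv_cov", "auc_csh"))
    out[[m]] <- NA_real_
  out$heterogeneity_eligible <- NA
  rownames(out) <- NULL
  out <- out[, c("patient_id", "age", "gender", "smoking_status", "pack_years",
                 "stage", "egfr", "kras", "diameter", "suv_max", "suv_mean",
                 "suv_sd", "mtv", "tlg", "inv_cov", "auc_csh",
                 "heterogeneity_eligible")]
  class(out) <- c("cohort_table", "data.frame")
  out
}
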