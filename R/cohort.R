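#' Cohort simulation specification
#'
#' Describes a synthetic NSCLC surgical cohort: covariate marginals,
#' a logistic model linking covariates to EGFR+ and KRAS+ probabilities,
#' lesion-metric distributions, and per-field missingness. Defaults are
#' calibrated to a 131-patient adenocarcinoma cohort: 86/131 male; smoking
#' current/former/never 22/77/32 with gender-specific composition (males
#' 17/56/13, females 5/21/19); age ~ Normal(67, 10) truncated to 24-86;
#' pack-years 0 for never-smokers, Gamma-distributed otherwise; stage
#' IA/IB/IIA/IIB/IIIA/IV/undefined at 66/26/12/10/12/2/3 of 131; EGFR+
#' probability 18/31 in never-smokers vs 14/96 in ever-smokers, KRAS+ 3/30 vs
#' 28/96 (intercept + never-smoker logistic coefficients derived from those
#' odds); EGFR missing in 4/131, KRAS in 5/131.
#'
#' Lesion-metric distributions are keyed on smoking status by default
#' (\code{metric_link = "smoking"}): ever-smokers draw higher SUVmax and lower
#' 1/COV than never-smokers, so PET metrics associate with mutation status
#' through the smoking confounder - the structure that makes metrics
#' significant univariately yet non-significant in a joint model with smoking.
#' \code{metric_link = "mutation"} keys the same distributions on EGFR class
#' instead (direct effect), and \code{metric_link = "none"} gives every
#' patient the same distributions (a null cohort for calibration checks,
#' together with \code{null_mutation_model}).
#'
#' @param n_patients number of patients (>= 1).
#' @param male_prop proportion male.
#' @param smoking_probs list with \code{male} and \code{female} probability
#'   vectors over (current, former, never); each sums to 1.
#' @param age_mean,age_sd,age_range age distribution (years).
#' @param pack_year_shape,pack_year_mean Gamma parameters for ever-smokers.
#' @param stage_probs named probability vector over stage categories.
#' @param mutation_model list with \code{egfr} and \code{kras} coefficient
#'   vectors (named: \code{intercept}, \code{never_smoker}, optionally
#'   \code{female}, \code{age}, \code{suv_max}, \code{inv_cov}) on the logit
#'   scale. Metric coefficients require \code{metric_link != "mutation"}.
#' @param metric_link \code{"smoking"}, \code{"mutation"} or \code{"none"}.
#' @param metric_params list of per-group lesion-metric distribution
#'   parameters; see defaults in the function body.
#' @param missingness named NA probabilities (\code{egfr}, \code{kras}).
#' @param seed integer RNG seed.
#' @return An object of class \code{cohort_spec}.
#' @export
cohort_spec <- function(n_patients = 131,
                        male_prop = 86 / 131,
                        smoking_probs = list(male = c(17, 56, 13) / 86,
                                             female = c(5, 21, 19) / 45),
                        age_mean = 67, age_sd = 10, age_range = c(24, 86),
                        pack_year_shape = 2, pack_year_mean = 30,
                        stage_probs = c(IA = 66, IB = 26, IIA = 12, IIB = 10,
                                        IIIA = 12, IV = 2, undefined = 3) / 131,
                        mutation_model = list(
                          egfr = c(intercept = log(14 / 82),
                                   never_smoker = log(18 / 13) - log(14 / 82)),
                          kras = c(intercept = log(28 / 68),
                                   never_smoker = log(3 / 27) - log(28 / 68))),
                        metric_link = c("smoking", "mutation", "none"),
                        metric_params = NULL,
                        missingness = c(egfr = 4 / 131, kras = 5 / 131),
                        seed = 1L) {
  metric_link <- match.arg(metric_link)
  if (n_patients < 1) stop("n_patients must be >= 1")
  for (p in smoking_probs)
    if (abs(sum(p) - 1) > 1e-8 || any(p < 0) || any(p > 1))
      stop("smoking probabilities must be in [0,1] and sum to 1")
  if (abs(sum(stage_probs) - 1) > 1e-8) stop("stage_probs must sum to 1")
  if (is.null(metric_params)) {
    # lognormal / gamma parameters per group; group 1 = ever-smoker (or
    # mutation-negative), group 2 = never-smoker (or mutation-positive)
    metric_params <- list(
      diameter = list(meanlog = 3.24, sdlog = 0.72),           # shared
      suv_max = list(g1 = c(mean = 7.0, sd = 5.5),
                     g2 = c(mean = 4.0, sd = 3.0)),            # lognormal
      inv_cov = list(g1 = c(mean = 4.1, sd = 2.1),
                     g2 = c(mean = 5.1, sd = 1.9)),            # gamma
      mean_ratio = c(shape1 = 12, shape2 = 8),                 # SUVmean/SUVmax
      auc = list(scale = 1.5, noise_sd = 0.75))
  }
  structure(list(n_patients = as.integer(n_patients), male_prop = male_prop,
                 smoking_probs = smoking_probs, age_mean = age_mean,
                 age_sd = age_sd, age_range = age_range,
                 pack_year_shape = pack_year_shape,
                 pack_year_mean = pack_year_mean, stage_probs = stage_probs,
                 mutation_model = mutation_model, metric_link = metric_link,
                 metric_params = metric_params, missingness = missingness,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' A null cohort specification
#'
#' Intercept-only mutation model (no covariate or metric effects) and
#' group-independent lesion metrics: nothing is associated with anything, so
#' the scan's rejection rate at level 0.05 estimates its type-I error.
#'
#' @param n_patients,seed passed to \code{\link{cohort_spec}}.
#' @param egfr_prev,kras_prev marginal mutation prevalences.
#' @return A \code{cohort_spec} with \code{metric_link = "none"}.
#' @export
null_cohort_spec <- function(n_patients = 131, egfr_prev = 0.25,
                             kras_prev = 0.25, seed = 1L) {
  cohort_spec(n_patients = n_patients,
              mutation_model = list(egfr = c(intercept = stats::qlogis(egfr_prev)),
                                    kras = c(intercept = stats::qlogis(kras_prev))),
              metric_link = "none", seed = seed)
}

rlnorm_ms <- function(n, mean, sd) {
  # lognormal parameterised by its own mean and SD
  s2 <- log(1 + (sd / mean)^2)
  stats::rlnorm(n, log(mean) - s2 / 2, sqrt(s2))
}

rgamma_ms <- function(n, mean, sd) {
  shape <- (mean / sd)^2
  stats::rgamma(n, shape = shape, rate = shape / mean)
}

#' Generate a synthetic patient cohort
#'
#' Draws covariates from the specified marginals, lesion metrics from the
#' group-keyed distributions, mutation status from the logistic model, and
#' injects missingness. Reproducible for a fixed \code{spec$seed}. Lesion
#' metrics respect the package's definitional identities exactly:
#' \code{tlg = mtv * suv_mean}, \code{suv_sd = suv_mean / inv_cov}, and
#' heterogeneity fields are NA below the 10 mm eligibility diameter.
#'
#' @param spec a \code{\link{cohort_spec}}.
#' @return A data.frame of class \code{cohort_table} with columns patient_id,
#'   age, gender, smoking_status, pack_years, stage, egfr, kras, diameter,
#'   suv_max, suv_mean, suv_sd, mtv, tlg, inv_cov, auc_csh,
#'   heterogeneity_eligible. A degenerate logistic model (all fitted
#'   probabilities 0 or 1) raises a warning, not an error.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n_patients
  gender <- ifelse(stats::runif(n) < spec$male_prop, "male", "female")
  smoking <- character(n)
  lev <- c("current", "former", "never")
  for (g in c("male", "female")) {
    idx <- gender == g
    if (any(idx))
      smoking[idx] <- sample(lev, sum(idx), replace = TRUE,
                             prob = spec$smoking_probs[[g]])
  }
  age <- round(pmin(pmax(stats::rnorm(n, spec$age_mean, spec$age_sd),
                         spec$age_range[1]), spec$age_range[2]))
  pack_years <- ifelse(smoking == "never", 0,
                       round(rgamma_ms(n, spec$pack_year_mean,
                                       spec$pack_year_mean /
                                         sqrt(spec$pack_year_shape)), 1))
  stage <- sample(names(spec$stage_probs), n, replace = TRUE,
                  prob = spec$stage_probs)

  mp <- spec$metric_params
  diameter <- pmax(stats::rlnorm(n, mp$diameter$meanlog, mp$diameter$sdlog), 3)
  draw_metrics <- function(group2) {
    sx <- numeric(n); ic <- numeric(n)
    for (g2 in c(FALSE, TRUE)) {
      idx <- group2 == g2
      if (!any(idx)) next
      pg <- if (g2) "g2" else "g1"
      sx[idx] <- pmax(rlnorm_ms(sum(idx), mp$suv_max[[pg]]["mean"],
                                mp$suv_max[[pg]]["sd"]), 0.5)
      ic[idx] <- pmax(rgamma_ms(sum(idx), mp$inv_cov[[pg]]["mean"],
                                mp$inv_cov[[pg]]["sd"]), 1.2)
    }
    list(suv_max = sx, inv_cov = ic)
  }

  logistic_draw <- function(coefs, met) {
    co <- function(nm) if (nm %in% names(coefs)) coefs[[nm]] else NA_real_
    coefs <- vapply(c("intercept", "never_smoker", "female", "age",
                      "suv_max", "inv_cov"), co, numeric(1))
    eta <- rep(coefs[["intercept"]], n)
    if (!is.na(coefs[["never_smoker"]]))
      eta <- eta + coefs[["never_smoker"]] * (smoking == "never")
    if (!is.na(coefs[["female"]]))
      eta <- eta + coefs[["female"]] * (gender == "female")
    if (!is.na(coefs[["age"]]))
      eta <- eta + coefs[["age"]] * age
    if (!is.na(coefs[["suv_max"]]) || !is.na(coefs[["inv_cov"]])) {
      if (is.null(met))
        stop("metric coefficients in the mutation model require metric_link != \"mutation\"")
      if (!is.na(coefs[["suv_max"]])) eta <- eta + coefs[["suv_max"]] * met$suv_max
      if (!is.na(coefs[["inv_cov"]])) eta <- eta + coefs[["inv_cov"]] * met$inv_cov
    }
    p <- stats::plogis(eta)
    if (all(p < 1e-12) || all(p > 1 - 1e-12))
      warning("degenerate logistic mutation model: all probabilities 0 or 1")
    ifelse(stats::runif(n) < p, "pos", "neg")
  }

  if (spec$metric_link == "mutation") {
    egfr <- logistic_draw(spec$mutation_model$egfr, NULL)
    kras <- logistic_draw(spec$mutation_model$kras, NULL)
    met <- draw_metrics(egfr == "pos")
  } else {
    grp2 <- if (spec$metric_link == "smoking") smoking == "never"
            else rep(FALSE, n)
    if (spec$metric_link == "none") {
      # pool the two groups' parameters: same distribution for everyone
      met <- draw_metrics(rep(FALSE, n))
    } else met <- draw_metrics(grp2)
    egfr <- logistic_draw(spec$mutation_model$egfr, met)
    kras <- logistic_draw(spec$mutation_model$kras, met)
  }

  suv_mean <- met$suv_max *
    stats::rbeta(n, mp$mean_ratio[["shape1"]], mp$mean_ratio[["shape2"]])
  suv_sd <- suv_mean / met$inv_cov
  mtv <- pi / 6 * (diameter / 10)^3 * stats::rlnorm(n, 0, 0.25)
  tlg <- mtv * suv_mean
  auc <- 0.28 + 0.58 * stats::plogis((met$inv_cov - 4.3) / mp$auc$scale +
                                       stats::rnorm(n, 0, mp$auc$noise_sd))

  eligible <- diameter >= 10
  suv_sd[!eligible] <- NA_real_
  ic_out <- met$inv_cov; ic_out[!eligible] <- NA_real_
  auc[!eligible] <- NA_real_

  egfr[stats::runif(n) < spec$missingness[["egfr"]]] <- NA
  kras[stats::runif(n) < spec$missingness[["kras"]]] <- NA

  out <- data.frame(patient_id = sprintf("P%04d", seq_len(n)),
                    age = age, gender = gender, smoking_status = smoking,
                    pack_years = pack_years, stage = stage,
                    egfr = egfr, kras = kras,
                    diameter = diameter, suv_max = met$suv_max,
                    suv_mean = suv_mean, suv_sd = suv_sd, mtv = mtv,
                    tlg = tlg, inv_cov = ic_out, auc_csh = auc,
                    heterogeneity_eligible = eligible,
                    stringsAsFactors = FALSE)
  attr(out, "seed") <- spec$seed
  class(out) <- c("cohort_table", "data.frame")
  out
}

#' Build a two-compartment lesion matching a patient's sampled metrics
#'
#' For image-based (phantom) runs of the pipeline: constructs a
#' \code{\link{lesion_spec}} whose analytic SUVmax, diameter and AUC-CSH match
#' a cohort row. The lesion is two-compartment with secondary level
#' \code{s = 0.3} and peak-volume fraction solved from the target AUC-CSH
#' (clamped to [0.05, 0.95]); when the row's AUC is NA (sub-resolution
#' lesion) a uniform lesion is built.
#'
#' @param row a single-row slice of a \code{cohort_table}.
#' @param center lesion centre in world mm.
#' @return A \code{lesion_spec}.
#' @export
lesion_from_metrics <- function(row, center) {
  if (is.na(row$auc_csh)) {
    up <- list(model = "uniform", peak = row$suv_max)
  } else {
    s <- 0.3
    f <- min(max((row$auc_csh - s) / (1 - s), 0.05), 0.95)
    up <- list(model = "two_compartment", peak = row$suv_max, f = f, s = s)
  }
  lesion_spec(center = center, diameter = row$diameter, uptake = up)
}
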