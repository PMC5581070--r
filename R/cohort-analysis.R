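#' Mann-Whitney comparison of a PET metric between two groups
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test, the comparison used for
#' PET parameters between mutation-positive and -negative groups. The p-value
#' is exact (by enumeration of rank assignments) when the smaller group has at
#' most 8 observations and there are no ties, otherwise the normal
#' approximation with tie and continuity correction is used.
#'
#' @param x,y numeric samples (NAs dropped).
#' @param group_names length-2 labels used in output and error messages.
#' @return A list of class \code{assoc_result}: \code{index}, \code{test},
#'   \code{groups} (per-group n, mean, sd, median, range), \code{statistic}
#'   (the U statistic for the first group), \code{p} and \code{direction}.
#' @export
mannwhitney <- function(x, y, group_names = c("x", "y")) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) == 0) stop("group '", group_names[1], "' is empty after NA removal")
  if (length(y) == 0) stop("group '", group_names[2], "' is empty after NA removal")
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- min(length(x), length(y)) <= 8 && !ties
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                            correct = TRUE, conf.int = FALSE))
  gs <- function(v, nm) data.frame(group = nm, n = length(v), mean = mean(v),
                                   sd = stats::sd(v), median = stats::median(v),
                                   min = min(v), max = max(v))
  direction <- if (stats::median(x) > stats::median(y)) {
    paste("higher in", group_names[1])
  } else if (stats::median(x) < stats::median(y)) {
    paste("higher in", group_names[2])
  } else "none"
  structure(list(index = paste(group_names, collapse = " vs "),
                 test = if (exact) "Mann-Whitney (exact)"
                        else "Mann-Whitney (normal approximation)",
                 groups = rbind(gs(x, group_names[1]), gs(y, group_names[2])),
                 statistic = unname(wt$statistic), p = wt$p.value,
                 direction = direction),
            class = "assoc_result")
}

#' @export
print.assoc_result <- function(x, ...) {
  cat(x$index, " - ", x$test, "\n", sep = "")
  if (!is.null(x$groups)) print(x$groups, row.names = FALSE)
  cat(sprintf("statistic = %.4g, two-sided p = %.4g (%s)\n",
              x$statistic, x$p, x$direction))
  invisible(x)
}

#' Categorical association in a contingency table
#'
#' Pearson chi-square without continuity correction (default; the convention
#' that reproduces the published univariate gender p-value from the cross
#' counts), or Fisher's exact test; both two-sided.
#'
#' @param counts contingency matrix of non-negative counts (2x2 for Fisher).
#' @param method \code{"chisq"} or \code{"fisher"}.
#' @return An \code{assoc_result} with \code{statistic} (chi-square, or the
#'   odds ratio for Fisher), \code{df} and \code{p}. Errors on a zero margin.
#' @export
categorical_assoc <- function(counts, method = c("chisq", "fisher")) {
  method <- match.arg(method)
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("zero margin in contingency table")
  if (method == "chisq") {
    ct <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
    structure(list(index = "contingency", test = "Pearson chi-square (uncorrected)",
                   counts = counts, statistic = unname(ct$statistic),
                   df = unname(ct$parameter), p = ct$p.value,
                   direction = NA_character_),
              class = "assoc_result")
  } else {
    ft <- stats::fisher.test(counts)
    structure(list(index = "contingency", test = "Fisher exact",
                   counts = counts,
                   statistic = if (!is.null(ft$estimate)) unname(ft$estimate) else NA_real_,
                   df = NA_real_, p = ft$p.value, direction = NA_character_),
              class = "assoc_result")
  }
}

#' Size-stratified cohort subset
#'
#' Patients whose metabolic tumor diameter strictly exceeds \code{threshold}
#' mm (the "> 1 cm / > 2 cm / > 3 cm" strata). The 10 mm heterogeneity
#' eligibility rule itself is inclusive (>= 10 mm) and lives in
#' \code{\link{apply_eligibility}}; set \code{strict = FALSE} to use >= here.
#'
#' @param cohort a \code{cohort_table}.
#' @param threshold diameter threshold in mm (10, 20, 30 conventionally).
#' @param strict logical; strict > (default) or >=.
#' @return The subset, with attributes \code{threshold} and \code{n}. Errors
#'   if the subset is empty.
#' @export
size_stratified <- function(cohort, threshold, strict = TRUE) {
  keep <- !is.na(cohort$diameter) &
    (if (strict) cohort$diameter > threshold else cohort$diameter >= threshold)
  if (!any(keep))
    stop("empty stratum: no lesion with diameter ",
         if (strict) "> " else ">= ", threshold, " mm")
  out <- cohort[keep, , drop = FALSE]
  attr(out, "threshold") <- threshold
  attr(out, "n") <- nrow(out)
  class(out) <- class(cohort)
  out
}

# two-sided score (Rao) test p for a single continuous predictor in a
# univariate logistic model; NA when not estimable
logistic_score_p <- function(y01, x) {
  ok <- !is.na(y01) & !is.na(x)
  y01 <- y01[ok]; x <- x[ok]
  if (length(unique(y01)) < 2 || length(unique(x)) < 2) return(NA_real_)
  fit <- suppressWarnings(stats::glm(y01 ~ x, family = stats::binomial()))
  an <- suppressWarnings(stats::anova(fit, test = "Rao"))
  an[["Pr(>Chi)"]][2]
}

#' Univariate association screen of covariates and PET metrics
#'
#' One row per index: age, gender, cancer staging (IA/IB vs higher), smoking
#' status (never vs current/former), pack-years, metabolic tumor diameter,
#' SUVmax, MTV, TLG, and the heterogeneity indices (SUV-SD, 1/COV, AUC-CSH)
#' within the > 1 cm, > 2 cm and > 3 cm size strata (the 1 cm stratum is the
#' inclusive >= 10 mm eligibility set). Continuous indices are tested two
#' ways and both p-values reported: Mann-Whitney (\code{p_mw}) and the
#' univariate logistic score test (\code{p_score}); categorical indices by
#' uncorrected Pearson chi-square (\code{p_chisq}). The primary column
#' \code{p} is the score test for continuous rows and the chi-square for
#' categorical rows. Complete cases per row; group sizes are recorded.
#' A Benjamini-Hochberg column \code{p_bh} is appended as supplementary
#' output only - the reproduced analysis applies no multiplicity correction.
#'
#' @param cohort a \code{cohort_table}.
#' @param outcome \code{"egfr"} or \code{"kras"}.
#' @return A data.frame with columns index, type, n_pos, n_neg, p_mw,
#'   p_score, p_chisq, p, note, p_bh. Rows that cannot be evaluated (empty
#'   stratum, single-class outcome in the stratum, constant index) carry NA
#'   p-values and an explanatory note.
#' @export
univariate_scan <- function(cohort, outcome = c("egfr", "kras")) {
  outcome <- match.arg(outcome)
  yall <- cohort[[outcome]]
  if (length(unique(stats::na.omit(yall))) < 2)
    stop("outcome '", outcome, "' has fewer than two classes")

  cont_row <- function(label, x, y) {
    ok <- !is.na(x) & !is.na(y)
    x <- x[ok]; y <- y[ok]
    n_pos <- sum(y == "pos"); n_neg <- sum(y == "neg")
    if (n_pos == 0 || n_neg == 0 || length(unique(x)) < 2)
      return(data.frame(index = label, type = "continuous", n_pos = n_pos,
                        n_neg = n_neg, p_mw = NA_real_, p_score = NA_real_,
                        p_chisq = NA_real_, p = NA_real_,
                        note = "not evaluable"))
    mw <- mannwhitney(x[y == "pos"], x[y == "neg"], c("pos", "neg"))
    ps <- logistic_score_p(as.integer(y == "pos"), x)
    data.frame(index = label, type = "continuous", n_pos = n_pos,
               n_neg = n_neg, p_mw = mw$p, p_score = ps, p_chisq = NA_real_,
               p = ps, note = "")
  }
  cat_row <- function(label, x, y) {
    ok <- !is.na(x) & !is.na(y)
    x <- x[ok]; y <- y[ok]
    n_pos <- sum(y == "pos"); n_neg <- sum(y == "neg")
    tab <- table(factor(x), factor(y, levels = c("pos", "neg")))
    res <- tryCatch(categorical_assoc(tab), error = function(e) NULL)
    if (is.null(res))
      return(data.frame(index = label, type = "categorical", n_pos = n_pos,
                        n_neg = n_neg, p_mw = NA_real_, p_score = NA_real_,
                        p_chisq = NA_real_, p = NA_real_,
                        note = "not evaluable"))
    data.frame(index = label, type = "categorical", n_pos = n_pos,
               n_neg = n_neg, p_mw = NA_real_, p_score = NA_real_,
               p_chisq = res$p, p = res$p, note = "")
  }

  y <- yall
  early <- ifelse(cohort$stage %in% c("IA", "IB"), "IA/IB",
                  ifelse(cohort$stage == "undefined", NA, "II+"))
  never <- ifelse(cohort$smoking_status == "never", "never", "current/former")
  rows <- list(
    cont_row("age", cohort$age, y),
    cat_row("gender", cohort$gender, y),
    cat_row("cancer staging (IA/IB vs II+)", early, y),
    cat_row("smoking status (never vs current/former)", never, y),
    cont_row("pack-years", cohort$pack_years, y),
    cont_row("metabolic tumor diameter", cohort$diameter, y),
    cont_row("SUVmax", cohort$suv_max, y),
    cont_row("MTV", cohort$mtv, y),
    cont_row("TLG", cohort$tlg, y))
  for (thr in c(10, 20, 30)) {
    lab <- sprintf("(> %d mm)", thr)
    sub <- tryCatch(size_stratified(cohort, thr, strict = thr != 10),
                    error = function(e) NULL)
    for (m in c("suv_sd", "inv_cov", "auc_csh")) {
      label <- paste(switch(m, suv_sd = "SD", inv_cov = "1/COV",
                            auc_csh = "AUC-CSH"), lab)
      if (is.null(sub)) {
        rows[[length(rows) + 1]] <-
          data.frame(index = label, type = "continuous", n_pos = 0L,
                     n_neg = 0L, p_mw = NA_real_, p_score = NA_real_,
                     p_chisq = NA_real_, p = NA_real_,
                     note = "not evaluable: empty stratum")
      } else {
        rows[[length(rows) + 1]] <- cont_row(label, sub[[m]], sub[[outcome]])
      }
    }
  }
  out <- do.call(rbind, rows)
  out$p_bh <- stats::p.adjust(out$p, method = "BH")  # supplementary only
  rownames(out) <- NULL
  out
}

#' Multivariate logistic model for mutation status
#'
#' Maximum-likelihood logistic regression of mutation status on a set of
#' predictors (default: the published model shape - gender, smoking status,
#' SUVmax and 1/COV in the > 1 cm stratum), with Wald two-sided p-values.
#' Categorical predictors are coded as indicators (female; never-smoker).
#' Complete-case analysis; a warning is issued when there are fewer than 10
#' complete cases per predictor. (Quasi-)complete separation is detected and
#' flagged - coefficients are returned but p-values are suppressed rather
#' than reporting Wald statistics from a divergent fit.
#'
#' @param cohort a \code{cohort_table}.
#' @param outcome \code{"egfr"} or \code{"kras"}.
#' @param predictors character vector of cohort columns; \code{"gender"} and
#'   \code{"smoking_status"} are recoded to \code{female} and
#'   \code{never_smoker} indicators.
#' @return A data.frame (term, estimate, std_error, z, p, or_) with
#'   attributes \code{n}, \code{converged} and \code{separation}.
#' @export
multivariate_logistic <- function(cohort, outcome = c("egfr", "kras"),
                                  predictors = c("gender", "smoking_status",
                                                 "suv_max", "inv_cov")) {
  outcome <- match.arg(outcome)
  df <- data.frame(y = as.integer(cohort[[outcome]] == "pos"))
  for (p in predictors) {
    df[[switch(p, gender = "female", smoking_status = "never_smoker", p)]] <-
      switch(p,
             gender = as.integer(cohort$gender == "female"),
             smoking_status = as.integer(cohort$smoking_status == "never"),
             cohort[[p]])
  }
  df <- df[stats::complete.cases(df), , drop = FALSE]
  n <- nrow(df)
  if (n < 10 * length(predictors))
    warning(sprintf("only %d complete cases for %d predictors", n,
                    length(predictors)))
  if (length(unique(df$y)) < 2) stop("outcome single-class in complete cases")
  sep_warn <- FALSE
  fit <- withCallingHandlers(
    stats::glm(y ~ ., data = df, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep_warn <<- TRUE
      invokeRestart("muffleWarning")
    })
  co <- summary(fit)$coefficients
  # (quasi-)complete separation: the likelihood diverges, which shows up as
  # huge coefficients with blown-up Wald SEs, or as the 0/1 fitted-probability
  # warning together with a divergent coefficient
  separation <- any(co[-1, 2] > 50 & abs(co[-1, 1]) > 10) ||
    (sep_warn && any(abs(stats::coef(fit)[-1]) > 10, na.rm = TRUE)) ||
    !fit$converged
  out <- data.frame(term = rownames(co), estimate = co[, 1],
                    std_error = co[, 2], z = co[, 3],
                    p = if (separation) NA_real_ else co[, 4],
                    or_ = exp(co[, 1]), row.names = NULL)
  attr(out, "n") <- n
  attr(out, "converged") <- fit$converged
  attr(out, "separation") <- separation
  out
}

fmt_msr <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return("not evaluable")
  sprintf("%.2f ± %.2f (%.2f–%.2f)", mean(x), stats::sd(x),
          min(x), max(x))
}

#' Cohort summary report tables
#'
#' The descriptive tables of the analysis: patient characteristics (counts
#' and percentages), mutation prevalences among evaluable patients, lesion
#' metrics as mean +/- SD (range) split by each mutation status with the
#' Mann-Whitney p, and per-index complete-case counts.
#'
#' @param cohort a \code{cohort_table}.
#' @return A list of data.frames: \code{characteristics}, \code{prevalence}
#'   (percent positive among pos+neg; \code{NA} with a note when a mutation
#'   column is entirely missing), \code{metrics_by_mutation} and
#'   \code{complete_case_counts}.
#' @export
summarize_cohort <- function(cohort) {
  n <- nrow(cohort)
  char_block <- function(category, x) {
    tab <- table(x, useNA = "no")
    data.frame(category = category, level = names(tab),
               n = as.integer(tab),
               percent = round(100 * as.integer(tab) / n, 1))
  }
  early <- ifelse(cohort$stage %in% c("IA", "IB"), "IA/IB", "other")
  characteristics <- rbind(
    char_block("gender", cohort$gender),
    char_block("smoking status", cohort$smoking_status),
    char_block("stage", cohort$stage),
    char_block("stage group", early))

  prev_row <- function(gene) {
    v <- cohort[[gene]]
    n_pos <- sum(v == "pos", na.rm = TRUE)
    n_neg <- sum(v == "neg", na.rm = TRUE)
    n_na <- sum(is.na(v))
    ev <- n_pos + n_neg
    data.frame(gene = gene, n_pos = n_pos, n_neg = n_neg, n_na = n_na,
               prevalence_pct = if (ev > 0) round(100 * n_pos / ev, 1) else NA_real_,
               note = if (ev > 0) "" else "not evaluable: all calls missing")
  }
  prevalence <- rbind(prev_row("egfr"), prev_row("kras"))

  metric_cols <- c("diameter", "suv_max", "suv_mean", "suv_sd", "mtv", "tlg",
                   "inv_cov", "auc_csh")
  met_rows <- list()
  for (gene in c("egfr", "kras")) for (m in metric_cols) {
    xp <- cohort[[m]][cohort[[gene]] == "pos" & !is.na(cohort[[gene]])]
    xn <- cohort[[m]][cohort[[gene]] == "neg" & !is.na(cohort[[gene]])]
    p <- tryCatch(mannwhitney(xp, xn, c("pos", "neg"))$p,
                  error = function(e) NA_real_)
    met_rows[[paste(gene, m)]] <- data.frame(
      gene = gene, metric = m, all = fmt_msr(cohort[[m]]),
      pos = fmt_msr(xp), neg = fmt_msr(xn), p_mw = p)
  }

  cc_row <- function(label, idx_ok) {
    data.frame(index = label,
               egfr_pos = sum(idx_ok & cohort$egfr == "pos", na.rm = TRUE),
               egfr_neg = sum(idx_ok & cohort$egfr == "neg", na.rm = TRUE),
               kras_pos = sum(idx_ok & cohort$kras == "pos", na.rm = TRUE),
               kras_neg = sum(idx_ok & cohort$kras == "neg", na.rm = TRUE))
  }
  cc <- rbind(cc_row("age", !is.na(cohort$age)),
              cc_row("pack-years", !is.na(cohort$pack_years)),
              cc_row("diameter", !is.na(cohort$diameter)),
              cc_row("SUVmax", !is.na(cohort$suv_max)),
              cc_row("MTV", !is.na(cohort$mtv)),
              cc_row("TLG", !is.na(cohort$tlg)),
              cc_row("SD (> 1 cm)", !is.na(cohort$suv_sd)),
              cc_row("1/COV (> 1 cm)", !is.na(cohort$inv_cov)),
              cc_row("AUC-CSH (> 1 cm)", !is.na(cohort$auc_csh)))

  list(characteristics = characteristics, prevalence = prevalence,
       metrics_by_mutation = do.call(rbind, met_rows),
       complete_case_counts = cc)
}
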