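test_that("Mann-Whitney exact p equals enumeration (exhaustive small samples)", {
  expect_equal(mannwhitney(1:3, 4:6)$p, 0.1)
  expect_equal(mannwhitney(1:3, 4:6)$statistic, 0)
  expect_equal(mannwhitney(1:3, 4:6)$p, mw_enum_p(1:3, 4:6))

  set.seed(7)
  for (i in 1:25) {
    nx <- sample(2:6, 1); ny <- sample(2:8, 1)
    pool <- sample(seq(0.1, 50, by = 0.1), nx + ny)  # tie-free
    x <- pool[1:nx]; y <- pool[-(1:nx)]
    r <- mannwhitney(x, y)
    expect_match(r$test, "exact")
    expect_equal(r$p, mw_enum_p(x, y))
  }
})

test_that("Mann-Whitney: symmetry, approximation accuracy, and empty-group errors", {
  expect_equal(mannwhitney(c(1, 2, 3), c(1, 2, 3))$p, 1.0)

  # normal approximation vs exact p at n = 8 vs 8: compare over every
  # attainable U value (deterministic, covers all tie-free draws)
  diffs <- vapply(0:64, function(u) {
    p_exact <- min(1, 2 * min(stats::pwilcox(u, 8, 8),
                              1 - stats::pwilcox(u - 1, 8, 8)))
    z <- (u - 32 + ifelse(u < 32, 0.5, -0.5)) / sqrt(8 * 8 * 17 / 12)
    abs(p_exact - min(1, 2 * stats::pnorm(-abs(z))))
  }, numeric(1))
  expect_lt(mean(diffs), 0.01)  # typical-draw agreement
  expect_lt(max(diffs), 0.05)   # worst case over all U

  expect_error(mannwhitney(numeric(0), 1:3, c("pos", "neg")), "'pos' is empty")
  expect_error(mannwhitney(1:3, c(NA_real_, NA_real_), c("pos", "neg")),
               "'neg' is empty")
})

test_that("chi-square equals the hand-computed statistic and handles degenerate tables", {
  fixtures <- list(matrix(c(16, 66, 16, 29), 2, byrow = TRUE),
                   matrix(c(18, 13, 14, 82), 2, byrow = TRUE),
                   matrix(c(3, 27, 28, 68), 2, byrow = TRUE),
                   matrix(c(5, 1, 2, 9), 2, byrow = TRUE))
  for (tab in fixtures) {
    r <- categorical_assoc(tab)
    expect_equal(r$statistic, chisq_by_hand(tab))
    expect_equal(r$p, stats::pchisq(r$statistic, 1, lower.tail = FALSE))
  }

  flat <- categorical_assoc(matrix(10, 2, 2))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p, 1.0)

  expect_error(categorical_assoc(matrix(c(0, 0, 5, 5), 2, byrow = TRUE)),
               "zero margin")
  fish <- categorical_assoc(matrix(c(5, 1, 2, 9), 2), method = "fisher")
  expect_equal(fish$p, stats::fisher.test(matrix(c(5, 1, 2, 9), 2))$p.value)
})

test_that("size strata: counting, nesting, and the empty-stratum error", {
  co <- generate_cohort(cohort_spec(n_patients = 40, seed = 2))
  co$diameter[1:4] <- c(8, 15, 25, 35)
  sub <- co[1:4, ]
  expect_equal(nrow(size_stratified(sub, 10)), 3)
  expect_equal(nrow(size_stratified(sub, 20)), 2)
  expect_equal(nrow(size_stratified(sub, 30)), 1)
  expect_error(size_stratified(sub, 40), "empty stratum")

  s10 <- size_stratified(co, 10); s20 <- size_stratified(co, 20)
  s30 <- size_stratified(co, 30)
  expect_true(all(s30$patient_id %in% s20$patient_id))
  expect_true(all(s20$patient_id %in% s10$patient_id))
})

test_that("univariate scan reports both tests, valid p-values, and eligibility propagation", {
  co <- generate_cohort(cohort_spec(n_patients = 200, seed = 3))
  sc <- univariate_scan(co, "egfr")
  expect_true(all(sc$p[!is.na(sc$p)] >= 0 & sc$p[!is.na(sc$p)] <= 1))
  cont <- sc[sc$type == "continuous" & sc$note == "", ]
  expect_true(all(!is.na(cont$p_mw) & !is.na(cont$p_score)))
  expect_true(all(is.na(sc$p_chisq[sc$type == "continuous"])))
  expect_true("p_bh" %in% names(sc))

  # all lesions below 10 mm: every stratum row reported as not evaluable
  tiny <- co
  tiny$diameter <- runif(nrow(tiny), 4, 9)
  tiny$suv_sd <- tiny$inv_cov <- tiny$auc_csh <- NA_real_
  sct <- univariate_scan(tiny, "egfr")
  strat <- grepl("> \\d+ mm", sct$index)
  expect_true(all(grepl("not evaluable", sct$note[strat])))

  allpos <- co; allpos$egfr <- "pos"
  expect_error(univariate_scan(allpos, "egfr"), "fewer than two classes")
})

test_that("smoking effect is detected with high power in the univariate scan", {
  hits <- sapply(1:40, function(s) {
    co <- generate_cohort(cohort_spec(
      n_patients = 500,
      mutation_model = list(egfr = c(intercept = -1.5, never_smoker = 2),
                            kras = c(intercept = -1.1)), seed = 4000 + s))
    sc <- univariate_scan(co, "egfr")
    sc$p[grepl("smoking", sc$index)] < 0.001
  })
  expect_gte(mean(hits), 0.95)
})

test_that("multivariate logistic: coefficient recovery and separation flagging", {
  co <- generate_cohort(cohort_spec(
    n_patients = 1000,
    mutation_model = list(egfr = c(intercept = -2, never_smoker = 2),
                          kras = c(intercept = -1.1)),
    missingness = c(egfr = 0, kras = 0), seed = 6))
  fit <- multivariate_logistic(co, "egfr",
                               predictors = c("smoking_status", "suv_max"))
  b <- fit$estimate[fit$term == "never_smoker"]
  se <- fit$std_error[fit$term == "never_smoker"]
  expect_lt(abs(b - 2), 3 * se)
  expect_true(attr(fit, "converged"))
  expect_false(attr(fit, "separation"))

  # predictor identical to the outcome: perfect separation, p suppressed
  sep <- co
  sep$suv_max <- as.numeric(sep$egfr == "pos")
  fit2 <- suppressWarnings(multivariate_logistic(sep, "egfr",
                                                 predictors = "suv_max"))
  expect_true(attr(fit2, "separation"))
  expect_true(all(is.na(fit2$p[fit2$term != "(Intercept)"])))

  expect_warning(multivariate_logistic(co[1:25, ], "egfr"), "complete cases")
})

test_that("logistic CI coverage is near nominal as n grows", {
  cover <- function(n, reps) {
    mean(sapply(seq_len(reps), function(s) {
      co <- generate_cohort(cohort_spec(
        n_patients = n,
        mutation_model = list(egfr = c(intercept = -1.5, never_smoker = 1.5),
                              kras = c(intercept = -1.1)),
        missingness = c(egfr = 0, kras = 0), seed = 70000 + s))
      fit <- suppressWarnings(
        multivariate_logistic(co, "egfr", predictors = "smoking_status"))
      b <- fit$estimate[fit$term == "never_smoker"]
      se <- fit$std_error[fit$term == "never_smoker"]
      abs(b - 1.5) <= qnorm(0.975) * se
    }))
  }
  cov200 <- cover(200, 60)
  band <- qbinom(c(0.005, 0.995), 60, 0.95) / 60
  expect_gte(cov200, band[1])
  expect_lte(cov200, band[2])
})

test_that("summary tables: prevalence arithmetic, normalization, bookkeeping", {
  co <- cohort_from_counts()
  s <- summarize_cohort(co)
  expect_equal(s$prevalence$prevalence_pct[s$prevalence$gene == "egfr"], 25.2)
  expect_equal(s$prevalence$prevalence_pct[s$prevalence$gene == "kras"], 24.6)

  for (cat in c("gender", "smoking status", "stage group")) {
    pct <- s$characteristics$percent[s$characteristics$category == cat]
    expect_lt(abs(sum(pct) - 100), 0.2)   # rounding only
  }

  none <- co; none$egfr <- NA_character_
  sn <- summarize_cohort(none)
  expect_true(is.na(sn$prevalence$prevalence_pct[sn$prevalence$gene == "egfr"]))
  expect_match(sn$prevalence$note[sn$prevalence$gene == "egfr"], "not evaluable")

  # complete-case bookkeeping reproduces a known missingness pattern
  sim <- generate_cohort(cohort_spec(n_patients = 300, seed = 8))
  cc <- summarize_cohort(sim)$complete_case_counts
  full <- cc[cc$index == "SUVmax", ]
  het <- cc[cc$index == "1/COV (> 1 cm)", ]
  expect_equal(full$egfr_pos + full$egfr_neg,
               sum(!is.na(sim$egfr) & !is.na(sim$suv_max)))
  expect_equal(het$egfr_pos + het$egfr_neg,
               sum(!is.na(sim$egfr) & !is.na(sim$inv_cov)))
  expect_lte(het$egfr_pos, full$egfr_pos)
})
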