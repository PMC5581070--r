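test_that("uniform sphere ground truth matches analytic volume and is homogeneous", {
  ph <- one_lesion_phantom(20, list(model = "uniform", peak = 5), spacing = 1)
  tr <- ph$truth
  expect_equal(tr$mtv, pi / 6 * 2^3, tolerance = 1e-12)   # 4.19 ml
  expect_lt(abs(tr$mtv_voxel - tr$mtv) / tr$mtv, 0.02)    # voxel counting
  expect_equal(tr$auc_csh, 1.0)
  expect_equal(tr$suv_sd, 0)
  expect_true(is.na(tr$inv_cov))
  expect_equal(tr$tlg, tr$mtv * tr$suv_mean)
})

test_that("two-compartment closed forms: AUC-CSH = s + (1-s)f, 1/COV from moments", {
  ph <- one_lesion_phantom(24, list(model = "two_compartment", peak = 10,
                                    f = 0.5, s = 0.5))
  tr <- ph$truth
  expect_equal(tr$auc_csh, 0.75)
  expect_equal(tr$inv_cov, 3.0)
  expect_equal(tr$suv_mean, 7.5)
  expect_equal(tr$suv_sd, 2.5)
  # general f, s against direct weighted moments of the two levels
  for (f in c(0.2, 0.7)) for (s in c(0, 0.4)) {
    ph2 <- one_lesion_phantom(20, list(model = "two_compartment", peak = 8,
                                       f = f, s = s))
    m <- f * 8 + (1 - f) * s * 8
    v <- f * 64 + (1 - f) * (s * 8)^2 - m^2
    expect_equal(ph2$truth$suv_mean, m)
    expect_equal(ph2$truth$suv_sd, sqrt(v), tolerance = 1e-12)
    expect_equal(ph2$truth$auc_csh, s + (1 - s) * f)
  }
})

test_that("voxelized MTV error strictly decreases as spacing shrinks", {
  errs <- vapply(c(2, 1, 0.5), function(sp) {
    ph <- one_lesion_phantom(20, list(model = "uniform", peak = 5), spacing = sp)
    abs(ph$truth$mtv_voxel - ph$truth$mtv) / ph$truth$mtv
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
})

test_that("lesions outside the grid or overlapping are rejected by name", {
  expect_error(generate_phantom(phantom_spec(
    grid_shape = c(20, 20, 20), voxel_spacing = 1, noise_sigma = 0,
    lesions = list(lesion_spec(c(18, 10, 10), 10,
                               list(model = "uniform", peak = 5))))),
    "lesion 1 extends outside")
  expect_error(generate_phantom(phantom_spec(
    grid_shape = c(40, 40, 40), voxel_spacing = 1, noise_sigma = 0,
    lesions = list(
      lesion_spec(c(18, 20, 20), 12, list(model = "uniform", peak = 5)),
      lesion_spec(c(24, 20, 20), 12, list(model = "uniform", peak = 4))))),
    "lesion 2 overlaps")
})

test_that("phantom generation is deterministic for a fixed seed", {
  sp <- phantom_spec(grid_shape = c(24, 24, 24), voxel_spacing = 2,
                     noise_sigma = 0.2, seed = 42)
  expect_identical(generate_phantom(sp)$volume$values,
                   generate_phantom(sp)$volume$values)
})

test_that("background-field means are recovered by 10 mm ROIs within 3 SE", {
  spec <- phantom_spec(seed = 1)
  geo <- pethet:::phantom_field_regions(spec)
  fields <- rownames(geo$roi_centers)
  n_seeds <- 15
  per_seed <- sapply(seq_len(n_seeds), function(s) {
    spec$seed <- 1000 + s
    ph <- generate_phantom(spec)
    vapply(fields, function(f) {
      ctr <- geo$roi_centers[f, ]
      r <- circular_roi(ph$volume, ctr[1:2],
                        round(ctr[3] / spec$voxel_spacing[3]))
      c(r$mean, r$n)
    }, numeric(2))
  })
  means <- per_seed[seq(1, by = 2, length.out = length(fields)), ]
  ns <- per_seed[seq(2, by = 2, length.out = length(fields)), ]
  grand <- rowMeans(means)
  se <- spec$noise_sigma / sqrt(rowSums(ns))
  target <- spec$background_fields[fields]
  expect_true(all(abs(grand - target) <= 3 * se))
})

test_that("noise strictly raises lesion SD and lowers 1/COV and AUC-CSH on average", {
  sigmas <- c(0, 0.2, 0.5, 1.0)
  stats <- sapply(sigmas, function(sg) {
    res <- sapply(1:20, function(s) {
      ph <- one_lesion_phantom(16, list(model = "uniform", peak = 5),
                               spacing = 2, noise = sg, seed = 100 + s)
      m <- lesion_metrics(ph$volume, ph$masks[[1]])
      c(sd = m$suv_sd, ic = if (is.na(m$inv_cov)) 200 else m$inv_cov,
        auc = m$auc_csh)
    })
    rowMeans(res)
  })
  expect_true(all(diff(stats["sd", ]) > 0))
  expect_true(all(diff(stats["ic", ]) < 0))
  expect_true(all(diff(stats["auc", ]) < 0))
})

test_that("cohort generation is deterministic and honours an intercept-only prevalence", {
  sp <- cohort_spec(n_patients = 50, seed = 9)
  expect_identical(generate_cohort(sp), generate_cohort(sp))

  co <- generate_cohort(null_cohort_spec(n_patients = 2000, egfr_prev = 0.25,
                                         seed = 3))
  k <- sum(co$egfr == "pos", na.rm = TRUE)
  n <- sum(!is.na(co$egfr))
  band <- qbinom(c(0.005, 0.995), n, 0.25)
  expect_gte(k, band[1])
  expect_lte(k, band[2])
})

test_that("a +2 never-smoker log-odds effect yields an empirical OR near e^2", {
  sp <- cohort_spec(n_patients = 2000,
                    mutation_model = list(
                      egfr = c(intercept = -1.5, never_smoker = 2),
                      kras = c(intercept = -1.1)),
                    metric_link = "none",
                    missingness = c(egfr = 0, kras = 0), seed = 5)
  co <- generate_cohort(sp)
  tab <- table(co$smoking_status == "never", co$egfr)
  or_hat <- (tab["TRUE", "pos"] * tab["FALSE", "neg"]) /
            (tab["TRUE", "neg"] * tab["FALSE", "pos"])
  se <- sqrt(sum(1 / tab))
  expect_lt(abs(log(or_hat) - 2), 3 * se)
})

test_that("degenerate mutation models warn rather than error", {
  sp <- cohort_spec(n_patients = 20,
                    mutation_model = list(egfr = c(intercept = -60),
                                          kras = c(intercept = -1)),
                    metric_link = "none", seed = 1)
  expect_warning(generate_cohort(sp), "degenerate logistic")
})

test_that("lesion and phantom specs enforce their invariants", {
  expect_error(lesion_spec(c(0, 0, 0), -5), "diameter")
  expect_error(lesion_spec(c(0, 0, 0), 10,
                           list(model = "two_compartment", peak = 5, f = 1.2)),
               "'f'")
  expect_error(phantom_spec(voxel_spacing = 0), "spacing")
  expect_error(phantom_spec(noise_sigma = -1), "noise_sigma")
  expect_error(cohort_spec(n_patients = 0), "n_patients")
})
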