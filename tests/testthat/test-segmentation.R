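test_that("gradient delineation recovers a noiseless high-contrast sphere (Dice >= 0.95)", {
  ph <- one_lesion_phantom(20, list(model = "uniform", peak = 5), spacing = 1)
  ctr <- ph$spec$lesions[[1]]$center
  seg <- petedge_segment(ph$volume, ctr)
  gt <- ph$masks[[1]]$mask
  dice <- 2 * sum(seg$mask & gt) / (sum(seg$mask) + sum(gt))
  expect_gte(dice, 0.95)
  expect_identical(seg$method, "petedge")
  expect_false(seg$border_warning)
})

test_that("delineated boundary lies within 1 voxel of the analytic sphere surface", {
  ph <- one_lesion_phantom(20, list(model = "uniform", peak = 5), spacing = 1)
  ctr <- ph$spec$lesions[[1]]$center
  seg <- petedge_segment(ph$volume, ctr)
  bnd <- pethet:::boundary_voxels(seg$mask)
  pts <- pethet:::mask_centers(bnd, seg$spacing)
  r <- sqrt(rowSums(sweep(pts, 2, ctr)^2))
  expect_true(all(abs(r - 10) <= sqrt(3)))  # one voxel diagonal at 1 mm
})

test_that("a seed in uniform background raises 'no lesion at seed'", {
  v <- suv_volume(array(0.5, c(30, 30, 30)), 2)
  expect_error(petedge_segment(v, c(30, 30, 30)), "no lesion at seed")
})

test_that("segmenter masks are one 26-connected component", {
  ph <- one_lesion_phantom(18, list(model = "radial_gradient", peak = 6,
                                    rim_fraction = 0.4), spacing = 1)
  ctr <- ph$spec$lesions[[1]]$center
  for (seg in list(petedge_segment(ph$volume, ctr),
                   threshold_segment(ph$volume, ctr, 0.5))) {
    start <- which(seg$mask)[1]
    comp <- pethet:::connected_component_26(seg$mask, start)
    expect_identical(comp, seg$mask)
  }
})

test_that("threshold segmentation covers compartments by construction", {
  ph <- one_lesion_phantom(24, list(model = "two_compartment", peak = 10,
                                    f = 0.5, s = 0.5))
  ctr <- ph$spec$lesions[[1]]$center
  gt <- ph$masks[[1]]$mask
  both <- threshold_segment(ph$volume, ctr, 0.4)   # 0.5 >= 0.4: both compartments
  expect_identical(both$mask, gt)
  core <- threshold_segment(ph$volume, ctr, 0.6)   # only the peak compartment
  expect_lt(sum(core$mask), sum(gt))
  expect_true(all(ph$volume$values[core$mask] == 10))
})

test_that("threshold fraction near 0 on an isolated lesion captures every lesion voxel", {
  n <- 32
  vals <- array(0, c(n, n, n))
  ctr <- rep(n / 2, 3)
  ph <- generate_phantom(phantom_spec(
    grid_shape = rep(n, 3), voxel_spacing = 1,
    background_fields = c(ruf = 0, luf = 0, rmf = 0, lmf = 0, rlf = 0,
                          llf = 0, blood_pool = 0),
    noise_sigma = 0,
    lesions = list(lesion_spec(ctr, 14, list(model = "radial_gradient",
                                             peak = 5, rim_fraction = 0.2)))))
  seg <- threshold_segment(ph$volume, ctr, 1e-6)
  expect_identical(seg$mask, ph$masks[[1]]$mask)
})

test_that("gradient and 42% threshold delineations agree on high-contrast spheres", {
  for (d in c(16, 24)) {
    ph <- one_lesion_phantom(d, list(model = "uniform", peak = 8), spacing = 1)
    ctr <- ph$spec$lesions[[1]]$center
    a <- petedge_segment(ph$volume, ctr)$mask
    b <- threshold_segment(ph$volume, ctr, 0.42)$mask
    expect_gte(2 * sum(a & b) / (sum(a) + sum(b)), 0.90)
  }
})

test_that("segmentation is invariant to positive SUV rescaling", {
  ph <- one_lesion_phantom(18, list(model = "radial_gradient", peak = 6,
                                    rim_fraction = 0.4), spacing = 1)
  ctr <- ph$spec$lesions[[1]]$center
  scaled <- suv_volume(ph$volume$values * 3.7, ph$volume$spacing)
  expect_identical(petedge_segment(ph$volume, ctr)$mask,
                   petedge_segment(scaled, ctr)$mask)
  expect_identical(threshold_segment(ph$volume, ctr, 0.5)$mask,
                   threshold_segment(scaled, ctr, 0.5)$mask)
})

test_that("10 mm circular ROI statistics behave on constant and noisy fields", {
  v <- suv_volume(array(0.5, c(30, 30, 10)), 1)
  r <- circular_roi(v, c(15, 15), 5)
  expect_equal(r$mean, 0.5)
  expect_equal(r$sd, 0)
  expect_gte(r$n, 1)
  expect_true(r$min <= r$mean && r$mean <= r$max)
  expect_error(circular_roi(v, c(3, 15), 5), "exceeds the grid")

  # blood pool at 1.7 with noise: grand mean within 3 SE over 50 seeds
  ms <- sapply(1:50, function(s) {
    set.seed(s)
    vv <- suv_volume(pmax(array(rnorm(30 * 30 * 10, 1.7, 0.1), c(30, 30, 10)), 0), 1)
    r <- circular_roi(vv, c(15, 15), 5)
    c(r$mean, r$n)
  })
  se <- 0.1 / sqrt(sum(ms[2, ]))
  expect_lt(abs(mean(ms[1, ]) - 1.7), 3 * se)
})

test_that("metabolic diameter: two-point, sphere, degenerate and brute-force cases", {
  # two voxels 5 mm apart
  m <- array(FALSE, c(10, 10, 10)); m[2, 2, 2] <- m[7, 2, 2] <- TRUE
  expect_equal(as.numeric(metabolic_diameter(voi_mask(m, 1))), 5)

  # single voxel: 0 mm, flagged sub-resolution
  m1 <- array(FALSE, c(5, 5, 5)); m1[3, 3, 3] <- TRUE
  d1 <- metabolic_diameter(voi_mask(m1, 1))
  expect_equal(as.numeric(d1), 0)
  expect_true(attr(d1, "sub_resolution"))

  # 30 mm sphere at 1 mm spacing: 30 mm within one voxel diagonal
  ph <- one_lesion_phantom(30, list(model = "uniform", peak = 5), spacing = 1)
  d30 <- as.numeric(metabolic_diameter(ph$masks[[1]]))
  expect_lt(abs(d30 - 30), sqrt(3))
  # equals the exhaustive all-pairs maximum
  small <- one_lesion_phantom(10, list(model = "uniform", peak = 5), spacing = 1)
  expect_lte(sum(small$masks[[1]]$mask), 5000)
  expect_equal(as.numeric(metabolic_diameter(small$masks[[1]])),
               brute_diameter(small$masks[[1]]$mask, small$masks[[1]]$spacing))

  # anisotropic voxels use physical spacing
  m2 <- array(FALSE, c(10, 10, 10)); m2[2, 2, 2] <- m2[2, 2, 6] <- TRUE
  expect_equal(as.numeric(metabolic_diameter(voi_mask(m2, c(1, 1, 3.75)))),
               4 * 3.75)

  # axial mode never exceeds the 3-D diameter
  da <- as.numeric(metabolic_diameter(ph$masks[[1]], mode = "axial"))
  expect_lte(da, d30 + 1e-9)
})
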