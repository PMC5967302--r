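# Morphometry: moment-ellipse metrics against analytic oracles, nucleus
# assignment, the three indices on enumerated examples, invariance
# properties, and round-trip equality against generator ground truth.

test_that("ellipse metrics match the moment-tensor oracle", {
  disk <- oracle_ellipse_mask(60, 60, c(30, 30), c(20, 20))
  em <- ellipse_metrics(disk, pixel_size = 1)
  expect_equal(em$aspect_ratio, 1, tolerance = 0.02)
  expect_equal(em$area_um2, sum(disk))

  # at a 20-px minor axis the rasterization itself carries ~2% moment error
  # (any moment implementation sees the same pixel set); at 40 px it is <1%
  ell <- oracle_ellipse_mask(120, 120, c(60, 60), c(40, 10), theta = 0)
  expect_equal(ellipse_metrics(ell, 1)$aspect_ratio, 4, tolerance = 0.03)
  fine <- oracle_ellipse_mask(240, 240, c(120, 120), c(80, 20))
  expect_equal(ellipse_metrics(fine, 1)$aspect_ratio, 4, tolerance = 0.02)

  rot <- oracle_ellipse_mask(120, 120, c(60, 60), c(40, 10), theta = pi / 6)
  expect_equal(ellipse_metrics(rot, 1)$aspect_ratio,
               ellipse_metrics(ell, 1)$aspect_ratio, tolerance = 0.03)

  # translation invariance of the aspect ratio, pixel-size scaling of area
  shifted <- oracle_ellipse_mask(150, 150, c(90, 75), c(40, 10), pi / 6)
  expect_equal(ellipse_metrics(shifted, 1)$aspect_ratio,
               ellipse_metrics(rot, 1)$aspect_ratio, tolerance = 0.01)
  expect_equal(ellipse_metrics(ell, 0.5)$area_um2, sum(ell) * 0.25)

  expect_error(ellipse_metrics(matrix(FALSE, 5, 5)), "empty")
})

test_that("ellipse axes agree with the independent EBImage moment features", {
  ell <- oracle_ellipse_mask(120, 120, c(55, 65), c(35, 12), theta = 0.7)
  em <- ellipse_metrics(ell, 1)
  ft <- EBImage::computeFeatures.moment(ell * 1)
  expect_equal(em$major_um / 2, unname(ft[1, "m.majoraxis"]) / 2,
               tolerance = 0.01)
  expect_equal(em$aspect_ratio, 1 / (1 - unname(ft[1, "m.eccentricity"])^2)^0.5,
               tolerance = 0.01)
})

test_that("nucleus assignment is by centroid pixel containment", {
  m <- matrix(0L, 20, 20)
  m[3:8, 3:8] <- 1L
  m[12:18, 12:18] <- 2L
  nuc <- data.frame(x_px = c(4, 5, 14, 0), y_px = c(4, 6, 13, 0))
  asn <- assign_nuclei(m, nuc)
  expect_identical(asn$counts, c(`1` = 2L, `2` = 1L))
  expect_identical(asn$unassigned, 1L)

  expect_error(assign_nuclei(m, data.frame(x_px = 25, y_px = 3)),
               "outside image bounds.*1")
  # zero-count labels are reported, not dropped
  asn2 <- assign_nuclei(m, data.frame(x_px = 4, y_px = 4))
  expect_identical(asn2$counts, c(`1` = 1L, `2` = 0L))
})

test_that("fusion index counts nuclei in large MyHC+ syncytia", {
  r <- data.frame(nucleus_count = c(60, 10, 5), is_differentiated = TRUE)
  expect_equal(fusion_index(r, morphometry_config(50)), 80)
  r2 <- data.frame(nucleus_count = c(20, 10), is_differentiated = TRUE)
  expect_equal(fusion_index(r2, morphometry_config(16)), 100 * 20 / 30)
  mono <- data.frame(nucleus_count = rep(1, 5), is_differentiated = TRUE)
  expect_equal(fusion_index(mono, morphometry_config(16)), 0)

  # MyHC- records are excluded from numerator and denominator
  mixed <- data.frame(nucleus_count = c(60, 10, 5, 100),
                      is_differentiated = c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(fusion_index(mixed, morphometry_config(50)), 80)

  none <- data.frame(nucleus_count = 10, is_differentiated = FALSE)
  expect_error(fusion_index(none, morphometry_config(16)), "undefined")
})

test_that("elongation index is the area share of high-aspect MyHC+ cells", {
  r <- data.frame(area_um2 = c(300, 700), aspect_ratio = c(5, 2),
                  is_differentiated = TRUE, nucleus_count = c(10, 10))
  expect_equal(elongation_index(r), 30)
  all_high <- transform(r, aspect_ratio = c(5, 4))
  expect_equal(elongation_index(all_high), 100)
  all_low <- transform(r, aspect_ratio = c(2, 2.5))
  expect_equal(elongation_index(all_low), 0)

  # multinucleated-only switch drops mononucleated objects
  sw <- data.frame(area_um2 = c(300, 700), aspect_ratio = c(5, 2),
                   is_differentiated = TRUE, nucleus_count = c(1, 10))
  cfg <- morphometry_config(multinucleated_only = TRUE)
  expect_equal(elongation_index(sw, cfg), 0)

  none <- data.frame(area_um2 = 1, aspect_ratio = 5,
                     is_differentiated = FALSE)
  expect_error(elongation_index(none), "undefined")
})

test_that("differentiation index is the MyHC+ share of all nuclei", {
  r <- data.frame(nucleus_count = c(60, 15), is_differentiated = TRUE)
  expect_equal(differentiation_index(r, 100), 75)
  expect_equal(differentiation_index(r, 75), 100)
  none <- data.frame(nucleus_count = 10, is_differentiated = FALSE)
  expect_equal(differentiation_index(none, 50), 0)
  expect_error(differentiation_index(r, 0), "undefined")
})

test_that("indices stay in [0, 100] and decrease in their thresholds", {
  for (s in 1:20) {
    r <- withr::with_seed(s, data.frame(
      nucleus_count = sample(1:80, 6, replace = TRUE),
      area_um2 = runif(6, 50, 2000),
      aspect_ratio = runif(6, 1, 8),
      is_differentiated = c(TRUE, sample(c(TRUE, FALSE), 5, replace = TRUE))))
    fi <- vapply(c(5L, 16L, 26L, 50L), function(th)
      fusion_index(r, morphometry_config(th)), numeric(1))
    ei <- vapply(c(1.5, 3, 5), function(th)
      elongation_index(r, morphometry_config(elongation_ar_threshold = th)),
      numeric(1))
    di <- differentiation_index(r, sum(r$nucleus_count) + 10)
    expect_true(all(c(fi, ei, di) >= 0 & c(fi, ei, di) <= 100))
    expect_true(all(diff(fi) <= 0))
    expect_true(all(diff(ei) <= 0))
  }
})

test_that("pipeline morphometry reproduces generator ground truth", {
  fld <- three_cell_field(seed = 21)
  cfg <- morphometry_config(50L, pixel_size = 0.5)
  res <- analyze_field(fld$label_mask, fld$nuclei, cfg)

  expect_identical(res$records$nucleus_count, fld$truth_cells$nucleus_count)
  expect_equal(res$summary$fusion_index, fld$truth_summary$fusion_index)
  expect_equal(res$summary$differentiation_index,
               fld$truth_summary$differentiation_index)
  expect_equal(res$summary$elongation_index,
               fld$truth_summary$elongation_index)
  expect_equal(res$records$aspect_ratio, fld$truth_cells$aspect_ratio,
               tolerance = 0.02)
  expect_equal(res$records$area_um2, fld$truth_cells$area_um2)

  # MyHC channel classification recovers the flags
  fld2 <- generate_syncytium_field(
    cells = list(cell_spec(c(35, 35), c(20, 5), 0.5, 30, TRUE),
                 cell_spec(c(100, 100), c(18, 9), 1.0, 8, FALSE)),
    image_shape = c(300L, 300L), pixel_size = 0.5,
    background_level = 10, cell_level = 100, noise_sd = 2, seed = 3)
  cfg2 <- morphometry_config(16L, pixel_size = 0.5, myhc_threshold = 55)
  res2 <- analyze_field(fld2$label_mask, fld2$nuclei, cfg2,
                        channel = fld2$channel)
  expect_identical(res2$records$is_differentiated, c(TRUE, FALSE))
  expect_equal(res2$summary$differentiation_index, 100 * 30 / 38)
})

test_that("field indices are invariant under 90-degree field rotation", {
  fld <- three_cell_field(seed = 33)
  cfg <- morphometry_config(50L, pixel_size = 0.5)
  base <- analyze_field(fld$label_mask, fld$nuclei, cfg)$summary

  rot_mask <- t(fld$label_mask)[ncol(fld$label_mask):1, ]
  # (x, y) -> (y, n_cols - 1 - x) under the same rotation
  rot_nuc <- data.frame(x_px = fld$nuclei$y_px,
                        y_px = ncol(fld$label_mask) - 1 - fld$nuclei$x_px)
  rot <- analyze_field(rot_mask, rot_nuc, cfg)$summary
  expect_equal(rot$fusion_index, base$fusion_index)
  expect_equal(rot$elongation_index, base$elongation_index)
  expect_equal(rot$differentiation_index, base$differentiation_index)
})
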