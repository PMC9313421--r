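flat_spec <- function(..., seed = 11) {
  image_phantom_spec(width = 96, height = 96, roi_params = list(radius = 30),
                     background_noise = "flat", seed = seed, ...)
}

test_that("zero-coverage phantoms are pure greyscale with zero ground truth", {
  ph <- generate_doppler_image(flat_spec(target_coverage_peripheral = 0,
                                         target_coverage_central = 0))
  expect_equal(unname(ph$ground_truth), c(0L, 0L))
  px <- ph$image$pixels
  expect_true(all(px[, , 1] == px[, , 2] & px[, , 2] == px[, , 3]))
  expect_false(any(detect_colour_pixels(ph$image)))
})

test_that("identical spec and seed reproduce the phantom bit-for-bit", {
  spec <- image_phantom_spec(width = 128, height = 128,
                             roi_shape = "blob", roi_params = list(radius = 38),
                             target_coverage_peripheral = 0.35,
                             target_coverage_central = 0.15, seed = 99)
  a <- generate_doppler_image(spec)
  b <- generate_doppler_image(spec)
  expect_identical(a$image$pixels, b$image$pixels)
  expect_identical(a$ground_truth, b$ground_truth)
  c2 <- generate_doppler_image(image_phantom_spec(width = 128, height = 128,
    roi_shape = "blob", roi_params = list(radius = 38),
    target_coverage_peripheral = 0.35, target_coverage_central = 0.15,
    seed = 100))
  expect_false(identical(a$image$pixels, c2$image$pixels))
})

test_that("ground truth equals an exhaustive recount with the chroma rule, per region", {
  for (pal in c("red_blue", "orange")) {
    ph <- generate_doppler_image(flat_spec(target_coverage_peripheral = 0.3,
                                           target_coverage_central = 0.1,
                                           colour_palette = pal))
    expect_equal(ph$ground_truth[["peripheral"]],
                 oracle_colour_count(ph$image$pixels, ph$partition$peripheral))
    expect_equal(ph$ground_truth[["central"]],
                 oracle_colour_count(ph$image$pixels, ph$partition$central))
    # no colour outside the ROI
    expect_equal(oracle_colour_count(ph$image$pixels, !ph$roi_mask), 0L)
    # detected mask equals the painted set exactly
    expect_equal(sum(detect_colour_pixels(ph$image)), sum(ph$ground_truth))
  }
})

test_that("measured VIs equal 100 * ground truth / region area and recover targets", {
  spec <- image_phantom_spec(width = 220, height = 220,
                             roi_params = list(radius = 100),
                             target_coverage_peripheral = 0.25,
                             target_coverage_central = 0.4, seed = 21)
  ph <- generate_doppler_image(spec)
  cm <- detect_colour_pixels(ph$image)
  a <- region_areas(ph$partition)
  vi_p <- compute_vi(cm, ph$partition$peripheral)
  vi_c <- compute_vi(cm, ph$partition$central)
  expect_equal(vi_p, 100 * ph$ground_truth[["peripheral"]] / a[["peripheral"]])
  expect_equal(vi_c, 100 * ph$ground_truth[["central"]] / a[["central"]])
  # coverage is met and exceeded by at most one painting primitive
  expect_gte(vi_p, 25); expect_lt(vi_p, 26)
  expect_gte(vi_c, 40); expect_lt(vi_c, 41)
})

test_that("infeasible ROI geometry is rejected with the offending parameter named", {
  expect_error(generate_doppler_image(
    image_phantom_spec(width = 64, height = 64,
                       roi_params = list(radius = 40))), "radius")
  expect_error(image_phantom_spec(target_coverage_central = 1.2),
               "target_coverage_central")
})

test_that("fixture bundles materialise images, masks, tables and a manifest", {
  tmp <- withr::local_tempdir()
  specs <- lapply(1:4, function(i) flat_spec(seed = i))
  man <- write_fixture_bundle(tmp, specs,
                              cohort_spec(n_total = 20, n_malignant = 8,
                                          n_equivocal_malignant = 3,
                                          n_equivocal_benign = 5, seed = 2))
  expect_equal(man$n_images, 4)
  files <- vapply(man$files, `[[`, "", "file")
  expect_length(files, 4 + 4 + 2)  # images + masks + ground truth + cohort
  expect_true(all(file.exists(file.path(tmp, files))))
  # re-run reproduces identical bytes
  tmp2 <- withr::local_tempdir()
  write_fixture_bundle(tmp2, specs,
                       cohort_spec(n_total = 20, n_malignant = 8,
                                   n_equivocal_malignant = 3,
                                   n_equivocal_benign = 5, seed = 2))
  for (f in files)
    expect_identical(unname(tools::md5sum(file.path(tmp, f))),
                     unname(tools::md5sum(file.path(tmp2, f))), label = f)
  # empty spec list: cohort only
  tmp3 <- withr::local_tempdir()
  man3 <- write_fixture_bundle(tmp3, list(),
                               cohort_spec(n_total = 20, n_malignant = 8,
                                           n_equivocal_malignant = 3,
                                           n_equivocal_benign = 5, seed = 2))
  expect_equal(man3$n_images, 0)
  expect_length(man3$files, 1)
})

test_that("cohorts realise the requested class and equivocal structure exactly", {
  spec <- cohort_spec(seed = 7)
  cohort <- generate_cohort(spec)
  expect_equal(nrow(cohort), 94)
  expect_equal(sum(cohort$truth == "malignant"), 30)
  expect_equal(sum(cohort$truth == "benign"), 64)
  expect_equal(sum(cohort$equivocal), 40)
  expect_equal(sum(cohort$equivocal & cohort$truth == "malignant"), 9)
  expect_equal(sum(cohort$equivocal & cohort$truth == "benign"), 31)
  expect_identical(generate_cohort(spec), cohort)
  expect_false(identical(generate_cohort(cohort_spec(seed = 8)), cohort))
})

test_that("cohort feature records are consistent with their drawn TIRADS category", {
  cohort <- generate_cohort(cohort_spec(seed = 13))
  expect_equal(eu_tirads_category(cohort), cohort$tirads_category)
})

test_that("simulated replicate VIs realise their nodule's RVI side", {
  cohort <- generate_cohort(cohort_spec(seed = 5))
  for (m in c("CFI", "ACFI", "PDI", "APDI")) {
    reps_p <- as.matrix(cohort[paste0("vi_p_", m, "_r", 1:3)])
    reps_c <- as.matrix(cohort[paste0("vi_c_", m, "_r", 1:3)])
    expect_equal(rowMeans(reps_p), cohort[[paste0("vi_p_", m)]])
    expect_equal(rowMeans(reps_c), cohort[[paste0("vi_c_", m)]])
    expect_equal(cohort[[paste0("rvi_", m)]],
                 cohort[[paste0("vi_p_", m)]] / cohort[[paste0("vi_c_", m)]])
    expect_true(all(reps_p >= 0 & reps_p <= 100 & reps_c >= 0 & reps_c <= 100))
  }
})

test_that("simulated indicators converge to their per-mode operating points", {
  spec <- cohort_spec(n_total = 100000, n_malignant = 30000,
                      n_equivocal_malignant = 9000, n_equivocal_benign = 31000,
                      seed = 17)
  cohort <- generate_cohort(spec)
  mal <- cohort$truth == "malignant"
  sus <- classify_qualitative(cohort$grade_APDI) == "malignant_suspicious"
  expect_lt(abs(mean(sus[mal]) - 0.833), 0.01)
  expect_lt(abs(mean(!sus[!mal]) - 0.813), 0.01)
  rvi_sus <- classify_rvi(cohort$rvi_APDI) == "malignant_suspicious"
  expect_lt(abs(mean(rvi_sus[mal]) - 0.667), 0.01)
  expect_lt(abs(mean(!rvi_sus[!mal]) - 0.734), 0.01)
})

test_that("infeasible cohort counts are rejected", {
  expect_error(cohort_spec(n_total = 10, n_malignant = 12), "infeasible")
  expect_error(cohort_spec(n_total = 94, n_malignant = 30,
                           n_equivocal_malignant = 31), "infeasible")
  expect_error(cohort_spec(tirads_probs_benign = c(`2` = 1, `3` = 1,
                                                   `4` = 0, `5` = 0)),
               "sum to 1")
})
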