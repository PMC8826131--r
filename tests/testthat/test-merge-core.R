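# Unit tests for the merge core: range conversion, overlap estimation,
# high-pass matching, blending, and the pairwise/pipeline merges.

test_that("convert_dynamic_range maps endpoints, rounds half up and clamps", {
  st <- image_stack(array(c(0, 1, 0.5, -0.2, 1.7, 0.25), c(1, 2, 3)),
                    voxel_size_um = 10)
  out <- convert_dynamic_range(st, range_scaling(0, 1))
  v <- as.vector(out$data)
  expect_identical(out$dtype, "uint16")
  expect_identical(v[1:2], c(0L, 65535L))          # lo -> 0, hi -> 65535
  expect_identical(v[3], 32768L)                   # 32767.5 rounds half up
  expect_identical(v[4:5], c(0L, 65535L))          # clamping
  expect_identical(v[6], 16384L)               # round(65535 * 0.25 = 16383.75)
  expect_error(range_scaling(2, 2), "hi > lo")
})

test_that("convert_dynamic_range preserves intensity ordering", {
  set.seed(31)
  vals <- sort(rnorm(500, 0, 2))
  st <- image_stack(array(vals, c(10, 10, 5)), voxel_size_um = 10)
  out <- convert_dynamic_range(st, range_scaling(-2, 2))
  expect_true(all(diff(as.vector(out$data)) >= 0))
})

test_that("coarse_overlap counts shared slice positions from motor data", {
  mb <- acquisition_meta(0, 1, 100, label = "bottom")
  mt <- acquisition_meta(80, 1, 100, label = "top")
  # oracle: shared integer z positions are 80..99
  expect_identical(coarse_overlap(mb, mt), 20L)
  # identical metas -> full overlap, capped
  expect_identical(coarse_overlap(mb, mb), 100L)
  # disjoint spans -> 0 with warning
  far <- acquisition_meta(500, 1, 100, label = "far")
  expect_warning(o <- coarse_overlap(mb, far), "do not overlap")
  expect_identical(o, 0L)
  # spacing mismatch -> geometry error
  expect_error(coarse_overlap(mb, acquisition_meta(80, 2, 100)),
               "spacing mismatch")
  # non-integer offsets round to the nearest whole slice
  expect_identical(coarse_overlap(mb, acquisition_meta(80.4, 1, 100)), 20L)
})

test_that("reference/target selection follows the floor-centred construction", {
  s <- select_reference_and_targets(100, 100, 20, 30)
  expect_identical(s$reference_index_top, 9L)
  expect_identical(s$candidates, 74:99)   # 74..103 clipped to the stack
  expect_true(s$at_window_edge)
  # deep overlap: ref 19, centre 100-40+19 = 79, window 64..93 fits fully
  s2 <- select_reference_and_targets(60, 100, 40, 30)
  expect_identical(length(s2$candidates), 30L)
  expect_identical(s2$candidates, 64:93)
  expect_false(s2$at_window_edge)
  # window 1 degenerates to the coarse prediction itself
  s3 <- select_reference_and_targets(100, 100, 20, 1)
  expect_identical(s3$candidates, 100L - 20L + 9L)
  # coarse 0 cannot be refined
  expect_error(select_reference_and_targets(100, 100, 0), "manual offset")
})

test_that("highpass removes constants and matches a brute-force convolution", {
  # constant image -> all-zero output
  expect_equal(highpass(matrix(7.3, 16, 16)), matrix(0, 16, 16),
               tolerance = 1e-10)
  set.seed(5)
  img <- matrix(rnorm(81), 9, 9)
  # additive-constant invariance
  expect_equal(highpass(img + 3.14, sigma_px = 2), highpass(img, sigma_px = 2),
               tolerance = 1e-9)
  # independent oracle: direct convolution with edge replication
  expect_equal(highpass(img, sigma_px = 1.5),
               oracle_highpass(img, 1.5), tolerance = 1e-9)
  # impulse: centre value is 1 minus the kernel peak
  imp <- matrix(0, 15, 15); imp[8, 8] <- 1
  k <- oracle_gaussian_kernel(2)
  expect_equal(highpass(imp, sigma_px = 2)[8, 8], 1 - k[7, 7],
               tolerance = 1e-9)
  expect_error(highpass(img, sigma_px = 0), "positive")
})

test_that("match_score is the population SD of the filtered difference", {
  set.seed(9)
  a <- matrix(rnorm(16), 4, 4)
  b <- matrix(rnorm(16), 4, 4)
  # self-match and constant offsets score zero
  expect_identical(match_score(a, a), 0)
  expect_equal(match_score(a, a + 7.3), 0, tolerance = 1e-9)
  # brute-force arithmetic oracle on the 16 pixels
  d <- oracle_highpass(b, 4) - oracle_highpass(a, 4)
  expect_equal(match_score(a, b), oracle_sd_pop(d), tolerance = 1e-9)
  expect_error(match_score(a, matrix(0, 3, 3)), "shape")
})

test_that("refine_overlap recovers the exact overlap from a sliced phantom", {
  ph <- small_phantom()
  sp <- split_two(ph$stack, o = 20)
  co <- coarse_overlap(sp$meta_bottom, sp$meta_top)
  expect_identical(co, 20L)
  est <- refine_overlap(sp$bottom, sp$top, co)
  expect_identical(est$refined_overlap_slices, 20L)
  expect_identical(min(est$score_table$score), 0)
  expect_identical(est$score_table$score[est$score_table$candidate ==
                                           est$best_target_index_bottom],
                   min(est$score_table$score))
})

test_that("refine_overlap corrects motor-position errors inside the window", {
  ph <- small_phantom(seed = 202)
  sp <- split_two(ph$stack, o = 20, motor_error_slices = -5)
  co <- coarse_overlap(sp$meta_bottom, sp$meta_top)
  expect_identical(co, 25L)  # corrupted metadata over-estimates
  est <- refine_overlap(sp$bottom, sp$top, co)
  expect_identical(est$refined_overlap_slices, 20L)
})

test_that("window 1 degenerates to the coarse prediction", {
  ph <- small_phantom(seed = 303)
  sp <- split_two(ph$stack, o = 10)
  suppressWarnings(est <- refine_overlap(sp$bottom, sp$top, 10, window = 1))
  expect_identical(est$refined_overlap_slices, 10L)
})

test_that("blend weights form the linear ramp and pair-sum to one", {
  expect_equal(blend_weights(1)$w_bottom, 0.5)
  expect_equal(blend_weights(3)$w_bottom, c(0.25, 0.5, 0.75))
  for (n in c(1, 2, 7, 30)) {
    w <- blend_weights(n)$w_bottom
    expect_true(all(w > 0 & w < 1))
    expect_true(all(diff(w) > 0))
    expect_identical(w + (1 - w), rep(1, n))
  }
  expect_error(blend_weights(0), "positive")
})

test_that("merge_vertical obeys the counting identity and the fixed point", {
  ph <- small_phantom(seed = 404)
  sp <- split_two(ph$stack, o = 20)
  m <- merge_vertical(sp$bottom, sp$top, 20)
  nb <- n_slices(sp$bottom); nt <- n_slices(sp$top)
  expect_identical(n_slices(m), nb + nt - 20L)
  # identical overlap slices (noise-free cut) -> merge equals the phantom
  expect_identical(m$data, ph$stack$data)
  # physical span conservation: merged span equals the union of spans
  expect_equal(n_slices(m), n_slices(ph$stack))
})

test_that("merged boundary slices stay closest to their source stack", {
  ph <- small_phantom(seed = 505)
  sp <- split_two(ph$stack, o = 20, noise_sigma = 0.05, seed_noise = 71)
  m <- merge_vertical(sp$bottom, sp$top, 20)
  nb <- n_slices(sp$bottom)
  first_ov <- m$data[, , nb - 20 + 1]   # bottom edge of the band
  last_ov <- m$data[, , nb]             # top edge of the band
  mad <- function(a, b) mean(abs(a - b))
  expect_lt(mad(first_ov, sp$bottom$data[, , nb - 20 + 1]),
            mad(first_ov, sp$top$data[, , 1]))
  expect_lt(mad(last_ov, sp$top$data[, , 20]),
            mad(last_ov, sp$bottom$data[, , nb]))
})

test_that("merge_vertical rejects geometry/dtype mismatches and zero overlap", {
  a <- image_stack(array(1, c(4, 4, 5)), voxel_size_um = 10)
  b <- image_stack(array(1, c(4, 5, 5)), voxel_size_um = 10)
  expect_error(merge_vertical(a, b, 2), "in-plane shape")
  c16 <- convert_dynamic_range(a, range_scaling(0, 2))
  expect_error(merge_vertical(a, c16, 2), "dtype")
  expect_error(merge_vertical(a, a, 0), "allow_zero_overlap")
  cc <- merge_vertical(a, a, 0, allow_zero_overlap = TRUE)
  expect_identical(n_slices(cc), 10L)
})

test_that("merge_pipeline folds three acquisitions and reports overlaps", {
  ph <- small_phantom(shape = c(120, 24, 24), seed = 606)
  sim <- simulate_acquisitions(ph$stack, list(
    acquisition_sim(0, 50, seed = 1),
    acquisition_sim(30, 50, seed = 2),
    acquisition_sim(65, 55, seed = 3)))
  rng <- range(ph$stack$data)
  cfg <- list(
    acquisitions = lapply(sim$acquisitions, function(a)
      list(stack = a$stack, motor_z_mm = a$meta$motor_z_mm,
           slice_spacing_mm = a$meta$slice_spacing_mm,
           label = a$meta$label)),
    scaling = list(lo = rng[1], hi = rng[2]))
  res <- merge_pipeline(cfg)
  expect_identical(n_slices(res$stack), 50L + 50L + 55L - 20L - 15L)
  got <- vapply(res$report$merges, function(m) m$refined_overlap_slices, 0L)
  expect_identical(got, sim$truth$true_overlap_slices)
  expect_identical(res$report$output$dtype, "uint16")
})

test_that("merge_pipeline degenerates to scaling for a single acquisition", {
  ph <- small_phantom(shape = c(20, 16, 16), seed = 707)
  cfg <- list(acquisitions = list(list(stack = ph$stack, motor_z_mm = 0)),
              scaling = list(lo = min(ph$stack$data),
                             hi = max(ph$stack$data)))
  res <- merge_pipeline(cfg)
  expect_identical(res$stack$data,
                   convert_dynamic_range(
                     ph$stack, range_scaling(min(ph$stack$data),
                                             max(ph$stack$data)))$data)
  expect_length(res$report$merges, 0)
})

test_that("merge_pipeline with zero physical overlap names both labels", {
  ph <- small_phantom(shape = c(100, 16, 16), seed = 808)
  sim <- simulate_acquisitions(ph$stack, list(
    acquisition_sim(0, 40, seed = 1),
    acquisition_sim(60, 40, seed = 2)))
  cfg <- list(
    acquisitions = lapply(sim$acquisitions, function(a)
      list(stack = a$stack, motor_z_mm = a$meta$motor_z_mm,
           slice_spacing_mm = a$meta$slice_spacing_mm,
           label = a$meta$label)))
  expect_error(merge_pipeline(cfg), "acq_01.*acq_02")
})

test_that("identical inputs produce bit-identical merges", {
  ph <- small_phantom(seed = 909)
  sp <- split_two(ph$stack, o = 15, noise_sigma = 0.02, seed_noise = 3)
  r1 <- refine_overlap(sp$bottom, sp$top, 15)
  r2 <- refine_overlap(sp$bottom, sp$top, 15)
  expect_identical(r1, r2)
  m1 <- merge_vertical(sp$bottom, sp$top, r1)
  m2 <- merge_vertical(sp$bottom, sp$top, r2)
  expect_identical(m1$data, m2$data)
})
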