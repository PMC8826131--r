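# Rigid transform algebra, resampling exactness, flip-alignment search and
# the registered merge.

test_that("rigid_transform validates rotations and inverts exactly", {
  expect_error(rigid_transform(matrix(1, 3, 3), c(0, 0, 0)), "orthonormal")
  expect_error(rigid_transform(diag(c(1, 1, -1)), c(0, 0, 0)), "proper")
  t1 <- rigid_transform(flip_rotation("x"), c(1.5, -2, 3))
  ti <- invert_rigid(t1)
  p <- c(0.3, -1.2, 7)
  fwd <- as.numeric(t1$rotation %*% p + t1$translation_mm)
  back <- as.numeric(ti$rotation %*% fwd + ti$translation_mm)
  expect_equal(back, p, tolerance = 1e-6)
})

test_that("apply_rigid with the identity on the same grid is exact", {
  ph <- small_phantom(shape = c(20, 12, 12), seed = 11)
  g <- ref_geometry(dim(ph$stack$data), ph$stack$voxel_size_um)
  out <- apply_rigid(ph$stack, rigid_transform(diag(3), c(0, 0, 0)), g)
  expect_identical(out$data, ph$stack$data)
  expect_true(all(out$mask))
})

test_that("a lattice-aligned 180-degree flip applied twice is an involution", {
  ph <- small_phantom(shape = c(21, 13, 12), seed = 12)  # odd dims too
  v <- ph$stack$voxel_size_um / 1000
  d <- dim(ph$stack$data)
  for (ax in c("x", "y", "z")) {
    r0 <- switch(ax,
                 x = c(0, d[1] - 1, d[3] - 1),
                 y = c(d[2] - 1, 0, d[3] - 1),
                 z = c(d[2] - 1, d[1] - 1, 0))
    t1 <- rigid_transform(flip_rotation(ax), v * r0)
    g <- ref_geometry(d, ph$stack$voxel_size_um)
    once <- apply_rigid(ph$stack, t1, g)
    twice <- apply_rigid(once, t1, g)
    expect_lt(max(abs(twice$data - ph$stack$data)), 1e-6)
    expect_true(all(once$mask))
  }
})

test_that("integer-voxel translations shift exactly, no interpolation blur", {
  ph <- small_phantom(shape = c(16, 10, 10), seed = 13)
  v <- ph$stack$voxel_size_um / 1000
  sh <- c(2, -1, 3)  # (dx, dy, dz)
  t1 <- rigid_transform(diag(3), v * sh)
  g <- ref_geometry(dim(ph$stack$data), ph$stack$voxel_size_um)
  out <- apply_rigid(ph$stack, t1, g)
  # index-shift oracle
  d <- dim(ph$stack$data)
  for (k in 1:3) {
    src_z <- k - sh[3]
    if (src_z < 1 || src_z > d[3]) next
    expect_identical(out$data[3:10, 3:9, k],
                     ph$stack$data[(3:10) - sh[2], (3:9) - sh[1], src_z])
  }
  # voxels mapping outside the source are masked out
  expect_false(all(out$mask))
  expect_true(all(out$data[!out$mask] == 0))
})

test_that("transform round-trip through resampling is bounded", {
  ph <- small_phantom(shape = c(24, 14, 14), seed = 14)
  v <- ph$stack$voxel_size_um / 1000
  t1 <- rigid_transform(flip_rotation("y"), v * c(13 + 2, 0, 23 + 1))
  g <- ref_geometry(dim(ph$stack$data), ph$stack$voxel_size_um)
  fwd <- apply_rigid(ph$stack, t1, g)
  back <- apply_rigid(fwd, invert_rigid(t1), g)
  common <- back$mask & fwd$mask
  expect_lt(max(abs(back$data[common] - ph$stack$data[common])), 1e-6)
})

test_that("search_flip_alignment recovers a known flip and shift exactly", {
  ph <- small_phantom(shape = c(90, 24, 24), seed = 15)
  sim <- simulate_acquisitions(ph$stack, list(
    acquisition_sim(0, 70, seed = 1),
    acquisition_sim(58, 32, flip_axis = "x", seed = 2)))
  fixed <- sim$acquisitions[[1]]$stack
  moving <- sim$acquisitions[[2]]$stack
  tr <- search_flip_alignment(fixed, moving, axis = "x",
                              z_window_slices = 8, z_offset_hint = 55)
  off <- attr(tr, "offset_voxels")
  expect_identical(unname(off), c(0L, 0L, 58L))
  expect_identical(tr$rotation, flip_rotation("x"))
  expect_false(attr(tr, "at_edge"))
  # the recovered transform places the moving series on the phantom exactly
  g <- ref_geometry(c(24, 24, 90), ph$stack$voxel_size_um)
  moved <- apply_rigid(moving, tr, g)
  expect_true(all(moved$mask[, , 59:90]))
  expect_true(all(!moved$mask[, , 1:58]))
  expect_identical(moved$data[, , 59:90], ph$stack$data[, , 59:90])
})

test_that("self-alignment with the flip disabled returns the identity", {
  ph <- small_phantom(shape = c(40, 20, 20), seed = 16)
  tr <- search_flip_alignment(ph$stack, ph$stack, axis = "none",
                              z_window_slices = 5)
  expect_identical(tr$rotation, diag(3))
  expect_identical(unname(attr(tr, "offset_voxels")), c(0L, 0L, 0L))
})

test_that("a true shift outside the window is reported at the edge", {
  ph <- small_phantom(shape = c(60, 20, 20), seed = 17)
  sim <- simulate_acquisitions(ph$stack, list(
    acquisition_sim(0, 40, seed = 1),
    acquisition_sim(25, 35, flip_axis = "x", seed = 2)))
  expect_warning(
    tr <- search_flip_alignment(sim$acquisitions[[1]]$stack,
                                sim$acquisitions[[2]]$stack,
                                axis = "x", z_window_slices = 5,
                                z_offset_hint = 10),
    "window boundary")
  expect_true(attr(tr, "at_edge"))
})

test_that("merge_registered unions disjoint and fixes identical volumes", {
  ph <- small_phantom(shape = c(30, 12, 12), seed = 18)
  d <- dim(ph$stack$data)
  mk <- function(zs) {
    m <- array(FALSE, d); m[, , zs] <- TRUE
    dat <- array(0, d); dat[, , zs] <- ph$stack$data[, , zs]
    image_stack(dat, voxel_size_um = ph$stack$voxel_size_um, mask = m)
  }
  # disjoint footprints -> exact union, no blending
  u <- merge_registered(mk(1:10), mk(21:30))
  expect_identical(u$data[, , c(1:10, 21:30)],
                   ph$stack$data[, , c(1:10, 21:30)])
  expect_identical(sum(u$mask), length(ph$stack$data[, , 1]) * 20L)
  # identical volumes -> output identical to either
  i2 <- merge_registered(ph$stack, ph$stack)
  expect_identical(i2$data, ph$stack$data)
  # overlapping footprints leave no empty voxels inside the union
  o2 <- merge_registered(mk(1:20), mk(15:30))
  expect_true(all(o2$mask))
  expect_error(merge_registered(mk(integer(0)), mk(integer(0))), "empty")
})

test_that("flip-merge round-trips a phantom within the injected noise", {
  ph <- small_phantom(shape = c(80, 24, 24), seed = 19)
  sigma <- 0.02
  sim <- simulate_acquisitions(ph$stack, list(
    acquisition_sim(0, 60, noise_sigma = sigma, seed = 5),
    acquisition_sim(45, 35, noise_sigma = sigma, flip_axis = "y", seed = 6)))
  res <- merge_flip(sim$acquisitions[[1]]$stack, sim$acquisitions[[2]]$stack,
                    axis = "y", z_window_slices = 6, z_offset_hint = 45)
  expect_identical(n_slices(res$stack), 80L)
  mae <- mean(abs(res$stack$data - ph$stack$data))
  expect_lt(mae, sigma)
  expect_true(all(res$stack$mask))
})
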