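test_that("mean slice spacing averages the endpoint gap", {
  expect_equal(mean_slice_spacing(c(0, 1, 2)), 1.0)
  expect_equal(mean_slice_spacing(c(0, 0.8, 1.7)), 0.85)
  expect_error(mean_slice_spacing(5), "degenerate")
})

test_that("replication coefficients are the smallest odd integers reaching the target", {
  plan <- resampling_coefficients(0.75, 0.75, 0.80, 0.10)
  expect_equal(plan$C, c(9L, 9L, 9L))
  expect_equal(resampling_coefficients(1, 1, 1, 1)$C, c(1L, 1L, 1L))
  plan2 <- resampling_coefficients(0.5, 0.6, 1.25, 0.2)
  expect_equal(plan2$C, c(3L, 3L, 7L))
  # resampled spacing reaches the target on every axis
  expect_true(all(plan2$spacing / plan2$C <= 0.2))
  expect_true(all(plan2$C %% 2 == 1))
  expect_error(resampling_coefficients(-1, 1, 1, 0.1), "positive")
  expect_error(resampling_coefficients(1, 1, 1, 0), "positive")
})

test_that("replicate_mask turns each voxel into a block of its value", {
  set.seed(1)
  m <- array(runif(8) < 0.5, c(2, 2, 2))
  r <- replicate_mask(m, 3, 3, 3)
  expect_equal(dim(r), c(6L, 6L, 6L))
  for (i in 1:2) for (j in 1:2) for (k in 1:2) {
    block <- r[(i - 1) * 3 + 1:3, (j - 1) * 3 + 1:3, (k - 1) * 3 + 1:3]
    expect_true(all(block == m[i, j, k]))
  }
  expect_identical(replicate_mask(m, 1, 1, 1), m)

  single <- array(FALSE, c(3, 1, 1)); single[2, 1, 1] <- TRUE
  row <- replicate_mask(single, 3, 1, 1)
  expect_equal(which(row), 4:6)

  expect_error(replicate_mask(m, 2, 1, 1), "odd")
  expect_error(replicate_mask(m, 0, 1, 1), "odd")
})

test_that("resampled geometry recomputes spacings, origin and slice z exactly", {
  g <- mask_volume(array(TRUE, c(4, 4, 4)), spacing = c(0.75, 0.75, 0.8),
                   origin = c(0, 0, 0))
  plan <- resampling_coefficients(0.75, 0.75, 0.8, 0.10)
  geo <- resampled_geometry(g, plan)
  expect_equal(geo$spacing_fine[1], 0.75 / 9)

  # three sub-centres of a 0.75 mm voxel at 0 are -0.25, 0, +0.25
  plan3 <- resampling_coefficients(0.75, 0.75, 0.8, 0.3)
  expect_equal(plan3$C[1], 3L)
  g3 <- mask_volume(array(TRUE, c(2, 2, 2)), spacing = c(0.75, 0.75, 0.8),
                    origin = c(0, 0, 0))
  geo3 <- resampled_geometry(g3, plan3)
  expect_equal(geo3$origin_fine[1], -0.25)

  # two-slice stack: 2*C_z uniformly spaced positions with kept endpoints
  g2 <- mask_volume(array(TRUE, c(2, 2, 2)), spacing = c(1, 1),
                    slice_z = c(0, 0.85), origin = c(0, 0))
  plan_z3 <- resampling_coefficients(1, 1, 0.85, 0.4)
  expect_equal(plan_z3$C[3], 3L)
  geo2 <- resampled_geometry(g2, plan_z3)
  expect_equal(geo2$slice_z_fine, seq(0, 0.85, by = 0.17))
})

test_that("resample_grid preserves content, footprint and the target bound", {
  p <- random_mask_pair(11, max_dim = 8)
  g <- p$bone
  # identity when the target is no smaller than every spacing
  ident <- resample_grid(g, target = max(p$spacing) + 0.1)
  expect_equal(ident$occupancy, g$occupancy)
  expect_equal(ident$slice_z, g$slice_z)

  fine <- resample_grid(g, target = 0.3)
  plan <- attr(fine, "plan")
  sfine <- attr(fine, "spacing_fine")
  # spacing bound (uniform z here)
  expect_true(all(sfine <= 0.3))
  # true-voxel count multiplies exactly
  expect_equal(sum(fine$occupancy), sum(g$occupancy) * prod(plan$C))
  # content-neutrality: fraction of true voxels invariant
  expect_equal(mean(fine$occupancy), mean(g$occupancy))
  # in-plane footprint: coarse extent shrunk by half a fine voxel per side
  d <- dim(g$occupancy)
  expect_equal(
    range(grid_to_points(mask_volume(array(TRUE, dim(fine$occupancy)),
                                     spacing = c(fine$spacing_x, fine$spacing_y),
                                     slice_z = fine$slice_z,
                                     origin = c(fine$origin_x, fine$origin_y)))[, "x"]),
    c(g$origin_x - (plan$C[1] - 1) / 2 * sfine[1],
      g$origin_x + (d[1] - 1) * g$spacing_x + (plan$C[1] - 1) / 2 * sfine[1])
  )
  # z endpoints preserved
  expect_equal(fine$slice_z[1], g$slice_z[1])
  expect_equal(fine$slice_z[length(fine$slice_z)], g$slice_z[d[3]])
})

test_that("fine voxel centres stay in-plane within their parent voxel", {
  p <- random_mask_pair(13, max_dim = 6)
  g <- p$bone
  fine <- resample_grid(g, target = 0.35)
  plan <- attr(fine, "plan")
  d <- dim(g$occupancy)
  df <- dim(fine$occupancy)
  idx <- which(array(TRUE, df), arr.ind = TRUE)
  centers <- voxel_center(fine, idx[, 1], idx[, 2], idx[, 3])
  parent <- cbind((idx[, 1] - 1) %/% plan$C[1] + 1,
                  (idx[, 2] - 1) %/% plan$C[2] + 1,
                  (idx[, 3] - 1) %/% plan$C[3] + 1)
  pc <- voxel_center(g, parent[, 1], parent[, 2], parent[, 3])
  # exact in-plane containment
  expect_true(all(abs(centers[, 1] - pc[, 1]) <= g$spacing_x / 2 + 1e-12))
  expect_true(all(abs(centers[, 2] - pc[, 2]) <= g$spacing_y / 2 + 1e-12))
  # z: uniform layout drifts from the block centre by less than one gap
  gap <- mean_slice_spacing(g$slice_z)
  expect_true(all(abs(centers[, 3] - pc[, 3]) < gap))
  # occupancy equals the parent voxel's value everywhere
  fv <- fine$occupancy[cbind(idx[, 1], idx[, 2], idx[, 3])]
  gv <- g$occupancy[parent]
  expect_identical(as.vector(fv), as.vector(gv))
})
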