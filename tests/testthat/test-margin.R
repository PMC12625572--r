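test_that("anisotropic distance map matches direct substitutions", {
  occ <- array(FALSE, c(3, 3, 3)); occ[2, 2, 2] <- TRUE
  g <- mask_volume(occ, spacing = c(1, 2, 3), origin = c(0, 0, 0))
  D <- anisotropic_distance_map(g, spacing = c(1, 2, 3))
  expect_equal(D$values[2, 2, 2], 0)
  expect_equal(D$values[3, 2, 2], 1)   # +x axis step
  expect_equal(D$values[2, 3, 2], 2)   # +y axis step
  expect_equal(D$values[1, 1, 1], sqrt(1 + 4 + 9))
  expect_error(
    anisotropic_distance_map(
      mask_volume(array(FALSE, c(2, 2, 2)), spacing = c(1, 1, 1),
                  origin = c(0, 0, 0))
    ),
    "empty foreground"
  )
})

test_that("distance map is exact against all-pairs brute force", {
  for (seed in 1:6) {
    p <- random_mask_pair(seed, max_dim = 12)
    sp <- c(p$bone$spacing_x, p$bone$spacing_y,
            mean_slice_spacing(p$bone$slice_z))
    D <- anisotropic_distance_map(p$tumor, spacing = sp)
    # brute force in physical coordinates (uniform z in these fixtures)
    bf <- r_distance_map(p$tumor, sp)
    expect_lt(max(abs(D$values - bf)), 1e-9)
  }
})

test_that("distance map is 1-Lipschitz across 6-adjacent voxels", {
  p <- random_mask_pair(21, max_dim = 12)
  sp <- c(1.1, 0.7, 0.9)
  D <- anisotropic_distance_map(p$tumor, spacing = sp)$values
  d <- dim(D)
  expect_true(all(abs(D[-1, , ] - D[-d[1], , ]) <= sp[1] + 1e-12))
  expect_true(all(abs(D[, -1, ] - D[, -d[2], ]) <= sp[2] + 1e-12))
  expect_true(all(abs(D[, , -1] - D[, , -d[3]]) <= sp[3] + 1e-12))
})

test_that("margin threshold is inclusive and zero-margin recovers the tumor", {
  occ <- array(FALSE, c(5, 1, 2)); occ[1, 1, 1] <- TRUE
  g <- mask_volume(occ, spacing = c(1, 1, 1), origin = c(0, 0, 0))
  D <- anisotropic_distance_map(g, spacing = c(1, 1, 1))
  m <- threshold_margin(D, 2)        # distances 0,1,2,3,4 along the row
  expect_equal(as.vector(m$occupancy[, 1, 1]), c(TRUE, TRUE, TRUE, FALSE, FALSE))
  m_eps <- threshold_margin(D, 2 - 1e-9)
  expect_false(m_eps$occupancy[3, 1, 1])
  m0 <- threshold_margin(D, 0)
  expect_equal(m0$occupancy, g$occupancy)
})

test_that("clip_to_bone is the voxelwise AND", {
  p <- random_mask_pair(5)
  m <- clip_to_bone(p$tumor, p$bone)
  expect_equal(m$occupancy, p$tumor$occupancy & p$bone$occupancy)
  allb <- p$bone; allb$occupancy[] <- TRUE
  expect_equal(clip_to_bone(p$tumor, allb)$occupancy, p$tumor$occupancy)
  none <- p$bone; none$occupancy[] <- FALSE
  expect_false(any(clip_to_bone(p$tumor, none)$occupancy))
  expect_error(clip_to_bone(p$tumor, mask_volume(p$bone$occupancy,
                                                 spacing = c(9, 9, 9),
                                                 origin = c(0, 0, 0))),
               "incompatible")
})

test_that("ring band is inclusive on both edges", {
  occ <- array(FALSE, c(9, 1, 2)); occ[1, 1, 1] <- TRUE; occ[1, 1, 2] <- TRUE
  g <- mask_volume(occ, spacing = c(1, 1, 1), origin = c(0, 0, 0))
  D <- anisotropic_distance_map(g, spacing = c(1, 0.5, 0.5))
  # distances along the row: 0..8; band = 2*max(spacing) = 2
  ring <- extract_ring(D, d_s = 5, spacing = c(1, 0.5, 0.5))
  expect_equal(which(ring$occupancy[, 1, 1]), 4:6)    # D in [3, 5]
  expect_error(extract_ring(D, d_s = 1.5, spacing = c(1, 0.5, 0.5)),
               "must exceed")
})

test_that("margin masks are monotone in the safe margin", {
  p <- random_mask_pair(9, max_dim = 14)
  refined <- refine_tumor(p$bone, p$tumor)
  D <- anisotropic_distance_map(refined)
  for (pair in list(c(1, 2), c(2, 3.5), c(0.5, 4))) {
    small <- clip_to_bone(threshold_margin(D, pair[1]), p$bone)
    large <- clip_to_bone(threshold_margin(D, pair[2]), p$bone)
    expect_true(all(large$occupancy[small$occupancy]))
  }
})

test_that("full pipeline fuses a bone-contained margin point set", {
  p <- small_phantom()
  d_s <- 3
  res <- generate_safe_margin_volume(p$bone, p$tumor, d_s, target = 0.4, xi = 2)
  s_max <- max(res$params$spacing_fine)

  # every fused point is inside the bone box
  hw <- p$descriptor$half_widths
  expect_true(all(abs(res$fused_points[, 1]) <= hw[1] + 1e-9))
  expect_true(all(abs(res$fused_points[, 2]) <= hw[2] + 1e-9))
  expect_true(all(abs(res$fused_points[, 3]) <= hw[3] + 1e-9))

  # every fused point lies within d_s + a voxel diagonal of the fine tumor
  ref <- grid_to_points(res$fine_tumor)
  d <- as.numeric(RANN::nn2(ref, res$fused_points, k = 1)$nn.dists)
  expect_true(all(d <= d_s + sqrt(3) * max(p$descriptor$spacing) + 1e-9))

  # ring distances are inside the stated band
  ring_d <- res$fine_distance$values[res$ring$occupancy]
  expect_true(all(ring_d <= d_s + 1e-12))
  expect_true(all(ring_d >= d_s - 2 * s_max - 1e-12))
  # ring is a subset of the fine margin mask
  fine_margin <- threshold_margin(res$fine_distance, d_s)
  expect_true(all(fine_margin$occupancy[res$ring$occupancy]))

  # disjoint tumor errors out
  far <- p$tumor
  far$occupancy[] <- FALSE
  far$occupancy[1, 1, 1] <- TRUE   # outside the bone box corner? inside bone
  none <- p$bone; none$occupancy[] <- FALSE
  expect_error(generate_safe_margin_volume(none, p$tumor, d_s), "empty")
})

test_that("coarse mask equals the brute-force point-cloud oracle", {
  for (seed in 1:8) {
    p <- random_mask_pair(seed, max_dim = 14)
    d_s <- runif(1, 0.8, 3)
    coarse <- coarse_only_method(p$bone, p$tumor, d_s)
    oracle <- pointwise_oracle(p$bone, p$tumor, d_s)
    expect_equal(grid_to_points(coarse), oracle)
  }
})

test_that("surface reconstruction triangulates the point-cloud boundary", {
  tet <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  m <- reconstruct_surface(tet)
  expect_equal(nrow(m$faces), 4L)
  cube <- as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1))
  m2 <- reconstruct_surface(cube)
  expect_equal(nrow(m2$faces), 12L)
  # outward orientation: signed volume of the hull is positive
  vol <- sum(apply(m2$faces, 1, function(f) {
    a <- m2$vertices[f[1], ]; b <- m2$vertices[f[2], ]; c3 <- m2$vertices[f[3], ]
    det(rbind(a, b, c3)) / 6
  }))
  expect_equal(vol, 1)
  expect_error(reconstruct_surface(tet[1:3, ]), "at least 4")
  flat <- cbind(runif(10), runif(10), 0)
  expect_error(reconstruct_surface(flat), "degenerate|coplanar")
})
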