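# Shared in-code fixtures: everything is generated at test time.

# Small phantom that exercises the full pipeline in well under a second.
small_phantom <- function(spacing = c(0.5, 0.5, 0.6), r = 2, d_s = 3) {
  make_sphere_phantom(spacing = spacing,
                      bone_half_widths = rep(r + d_s + 2 * max(spacing) + 1, 3),
                      r = r, d_s_max = d_s)
}

# Plain-R exhaustive nearest-distance oracle (independent of the compiled
# paths and of RANN).
r_min_dist <- function(query, ref) {
  apply(rbind(query), 1, function(p) {
    min(sqrt((ref[, 1] - p[1])^2 + (ref[, 2] - p[2])^2 + (ref[, 3] - p[3])^2))
  })
}

# Plain-R brute-force anisotropic distance map over all (voxel, foreground)
# pairs.
r_distance_map <- function(grid, spacing) {
  d <- dim(grid$occupancy)
  fg <- grid_to_points(grid)
  idx <- which(array(TRUE, d), arr.ind = TRUE)
  centers <- voxel_center(grid, idx[, 1], idx[, 2], idx[, 3])
  out <- r_min_dist(centers, fg)
  array(out, d)
}

# Random co-registered bone/tumor pair on a uniform-z anisotropic grid with
# a guaranteed non-empty intersection.
random_mask_pair <- function(seed, max_dim = 20) {
  set.seed(seed)
  d <- sample(4:max_dim, 3, replace = TRUE)
  sp <- round(runif(3, 0.5, 1.4), 2)
  bone <- array(runif(prod(d)) < 0.6, d)
  tumor <- array(FALSE, d)
  # tumor blob near the centre
  c0 <- pmax(2, round(d / 2))
  rr <- pmax(1, round(min(d) / 3))
  for (a in 1:3) c0[a] <- min(c0[a], d[a] - 1)
  idx <- which(array(TRUE, d), arr.ind = TRUE)
  inside <- rowSums(((t(t(idx) - c0)) / rr)^2) <= 1
  tumor[idx[inside, , drop = FALSE]] <- TRUE
  bone[c0[1], c0[2], c0[3]] <- TRUE
  tumor[c0[1], c0[2], c0[3]] <- TRUE
  org <- round(runif(3, -5, 5), 2)
  list(
    bone = mask_volume(bone, spacing = sp, origin = org),
    tumor = mask_volume(tumor, spacing = sp, origin = org),
    spacing = sp
  )
}

# One shared full-resolution default-phantom run for the acceptance suite
# (cached across test blocks; ~30 s, ~1 GB).
default_phantom_run <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ph <- make_sphere_phantom()
      res <- generate_safe_margin_volume(ph$bone, ph$tumor, d_s = 10,
                                         target = 0.10, xi = 2)
      pts <- outward_boundary_points(res)
      ref <- surface_points(res$fine_tumor)
      errs <- signed_errors(pts, ref, 10)
      cache <<- list(phantom = ph, result = res, errors = errs)
    }
    cache
  }
})
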