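#' Brute-force point-cloud safe-margin volume (predecessor method / oracle)
#'
#' The bone points located within the safe margin of each and every refined
#' tumor point, found by explicit nearest-distance search over point pairs —
#' deliberately independent of the distance-transform path, so it can serve
#' as a correctness oracle for it. A KD-tree engine is available to
#' accelerate the search without changing results.
#'
#' @param bone,tumor co-registered [mask_volume()] objects.
#' @param d_s safe margin in mm (`>= 0`).
#' @param engine `"brute"` (exhaustive all-pairs, the reference) or
#'   `"kdtree"` (RANN).
#' @return Point matrix (columns x, y, z in mm) of the selected bone voxel
#'   centres, in [grid_to_points()] order.
#' @export
pointwise_oracle <- function(bone, tumor, d_s,
                             engine = c("brute", "kdtree")) {
  engine <- match.arg(engine)
  if (d_s < 0) stop("`d_s` must be non-negative")
  refined <- refine_tumor(bone, tumor)
  p_b <- grid_to_points(bone)
  p_int <- grid_to_points(refined)
  d <- if (engine == "brute") {
    min_dist_brute_cpp(p_b, p_int)
  } else {
    as.numeric(RANN::nn2(p_int, p_b, k = 1)$nn.dists)
  }
  p_b[d <= d_s, , drop = FALSE]
}

#' Coarse-only anisotropic distance-transform comparator
#'
#' The distance-transform method on the original grid without resampling:
#' fast, but its boundary is only accurate to about one voxel. Equivalent, as
#' a voxel-centre point set, to [pointwise_oracle()].
#'
#' @inheritParams pointwise_oracle
#' @return A [mask_volume()] on the bone geometry.
#' @export
coarse_only_method <- function(bone, tumor, d_s) {
  refined <- refine_tumor(bone, tumor)
  D <- anisotropic_distance_map(refined)
  clip_to_bone(threshold_margin(D, d_s), bone)
}

#' Morphological-dilation baseline
#'
#' Binary dilation of the refined tumor with a discrete ball structuring
#' element of radius `round(d_s / S_x)` voxels — isotropic in index space,
#' deliberately ignoring the anisotropic spacing, which is exactly the
#' behaviour that makes voxel-unit dilation inaccurate on clinical grids —
#' then clipped to bone.
#'
#' @inheritParams pointwise_oracle
#' @return A [mask_volume()] on the bone geometry.
#' @export
dilation_baseline <- function(bone, tumor, d_s) {
  refined <- refine_tumor(bone, tumor)
  r_vox <- round(d_s / bone$spacing_x)
  # dilation by the discrete ball {d : ||d|| <= r_vox} equals thresholding
  # the unit-spacing (index-metric) distance transform at r_vox
  D_idx <- anisotropic_distance_map(refined, spacing = c(1, 1, 1))
  clip_to_bone(threshold_margin(D_idx, r_vox), bone)
}
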