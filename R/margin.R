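#' Exact anisotropic Euclidean distance map of a foreground mask
#'
#' For every voxel, the minimum over foreground voxels of
#' `sqrt(S_x^2 d_x^2 + S_y^2 d_y^2 + S_z^2 d_z^2)` where `(d_x, d_y, d_z)`
#' are index offsets: the exact (not chamfer) Euclidean metric, computed by a
#' separable lower-envelope transform in compiled code. Distances are 0
#' exactly on the foreground.
#'
#' @param fg a [mask_volume()] with non-empty occupancy (the foreground).
#' @param spacing length-3 spacings (mm) of the metric; defaults to
#'   [dt_spacing()] of the grid (in-plane spacings plus mean slice spacing).
#' @return An object of class `distance_map`: the value lattice plus the
#'   source geometry and the spacings used.
#' @export
anisotropic_distance_map <- function(fg, spacing = dt_spacing(fg)) {
  if (!any(fg$occupancy)) stop("empty foreground: no distances to compute")
  if (length(spacing) != 3L || any(spacing <= 0)) {
    stop("`spacing` must be three positive lengths in mm")
  }
  d <- grid_dim(fg)
  values <- edt3d_cpp(as.logical(fg$occupancy), as.integer(d),
                      as.numeric(spacing))
  dim(values) <- d
  structure(
    list(
      values = values,
      spacing = as.numeric(spacing),
      spacing_x = fg$spacing_x, spacing_y = fg$spacing_y,
      slice_z = fg$slice_z, origin_x = fg$origin_x, origin_y = fg$origin_y
    ),
    class = "distance_map"
  )
}

#' @export
print.distance_map <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf(
    "<distance_map> %d x %d x %d voxels, metric spacing (%.4g, %.4g, %.4g) mm, max %.3f mm\n",
    d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3], max(x$values)
  ))
  invisible(x)
}

# mask_volume sharing a distance map's geometry
dmap_mask <- function(D, occ) {
  mask_volume(occ, spacing = c(D$spacing_x, D$spacing_y),
              slice_z = D$slice_z, origin = c(D$origin_x, D$origin_y))
}

#' Threshold a distance map at the safe margin
#'
#' Voxels whose distance to the tumor is no greater than `d_s` (inclusive).
#'
#' @param D a [anisotropic_distance_map()].
#' @param d_s safe margin in mm (`>= 0`).
#' @return A [mask_volume()] on the map's geometry.
#' @export
threshold_margin <- function(D, d_s) {
  stopifnot(inherits(D, "distance_map"))
  if (d_s < 0) stop("`d_s` must be non-negative")
  occ <- D$values <= d_s
  dmap_mask(D, occ)
}

#' Clip a margin mask to the bone
#'
#' The safe-margin volume grows along the bone only: voxelwise AND of the
#' thresholded margin with the bone mask.
#'
#' @param margin,bone [mask_volume()] objects on the same geometry.
#' @return A [mask_volume()].
#' @export
clip_to_bone <- function(margin, bone) {
  if (!same_geometry(margin, bone)) {
    stop("margin and bone masks have incompatible grids")
  }
  out <- margin
  out$occupancy <- margin$occupancy & bone$occupancy
  out
}

#' Extract the dangerous ring band of a fine distance map
#'
#' The thin shell with distances in `[d_s - 2*max(spacing), d_s]` (both ends
#' inclusive): the accurate outer skin of the fine safe-margin volume that is
#' fused with the coarse volume.
#'
#' @param D a [anisotropic_distance_map()] on the fine grid.
#' @param d_s safe margin in mm; must exceed the band width
#'   `2*max(spacing)`.
#' @param spacing metric spacings; defaults to those stored in `D`.
#' @return A [mask_volume()] on the map's geometry.
#' @export
extract_ring <- function(D, d_s, spacing = D$spacing) {
  stopifnot(inherits(D, "distance_map"))
  band <- 2 * max(spacing)
  if (d_s <= band) {
    stop(sprintf(
      "safe margin (%.3g mm) must exceed the ring band width 2*max(spacing) = %.3g mm",
      d_s, band
    ))
  }
  occ <- D$values >= (d_s - band) & D$values <= d_s
  dmap_mask(D, occ)
}

#' Generate a patient-specific safe-margin volume (coarse + fine ring fusion)
#'
#' Full pipeline: refine the tumor by bone intersection; crop both masks to a
#' region of interest `d_s + xi` beyond the tumor bounding box; compute the
#' coarse safe-margin volume on the original cropped grid (anisotropic
#' distance transform with the in-plane spacings and mean slice spacing,
#' inclusive threshold at `d_s`, clip to bone); resample both ROIs to the
#' target spacing by odd-integer replication and extract the fine dangerous
#' ring (distances in `[d_s - 2*max(S_hat), d_s]`), clipped to the resampled
#' bone; and fuse the two voxel-centre point sets.
#'
#' @param bone,tumor co-registered [mask_volume()] objects (the tumor may be
#'   unrefined; intersection with bone is always applied first).
#' @param d_s safe margin in mm (must exceed the fine band width).
#' @param target target fine spacing `S_t` in mm (default 0.10).
#' @param xi cropping slack in mm (default 2).
#' @param keep_fine keep the fine-grid bone/tumor masks and distance map in
#'   the result (needed for boundary-point evaluation; costs memory).
#' @param dedupe drop duplicate fused points (off by default; near-duplicates
#'   where ring and coarse sets overlap are harmless for triangulation).
#' @return An object of class `safe_margin_result` with elements `coarse`
#'   (coarse-grid mask), `ring` (fine-grid mask), `fused_points` (point
#'   matrix), `params`, `plan`, and — when `keep_fine` — `fine_bone`,
#'   `fine_tumor`, `fine_distance`, plus `coarse_distance` and `roi`.
#' @export
generate_safe_margin_volume <- function(bone, tumor, d_s, target = 0.10,
                                        xi = 2, keep_fine = TRUE,
                                        dedupe = FALSE) {
  if (d_s <= 0) stop("`d_s` must be positive")
  refined <- refine_tumor(bone, tumor)
  roi <- expand_bbox(tumor_bbox(refined), d_s, xi)
  cropped <- crop_pair(bone, refined, roi)

  # coarse path: original grid, scalar spacings (S_x, S_y, D_bar)
  D_coarse <- anisotropic_distance_map(cropped$tumor)
  V_d <- clip_to_bone(threshold_margin(D_coarse, d_s), cropped$bone)

  # fine path: replicated grid, scalar spacings (S_hat_x, S_hat_y, S_hat_z)
  plan <- resampling_coefficients(cropped$tumor$spacing_x,
                                  cropped$tumor$spacing_y,
                                  mean_slice_spacing(cropped$tumor$slice_z),
                                  target)
  fine_tumor <- resample_grid(cropped$tumor, target, plan = plan)
  fine_bone <- resample_grid(cropped$bone, target, plan = plan)
  spacing_fine <- attr(fine_tumor, "spacing_fine")
  D_fine <- anisotropic_distance_map(fine_tumor, spacing = spacing_fine)
  V_r <- clip_to_bone(extract_ring(D_fine, d_s, spacing_fine), fine_bone)

  fused <- rbind(grid_to_points(V_d), grid_to_points(V_r))
  if (dedupe) fused <- unique(fused)

  out <- list(
    coarse = V_d,
    ring = V_r,
    fused_points = fused,
    params = list(d_s = d_s, target = target, xi = xi,
                  band = 2 * max(spacing_fine),
                  spacing_fine = spacing_fine),
    plan = plan,
    roi = roi
  )
  if (keep_fine) {
    out$fine_bone <- fine_bone
    out$fine_tumor <- fine_tumor
    out$fine_distance <- D_fine
    out$coarse_distance <- D_coarse
    out$coarse_bone <- cropped$bone
    out$coarse_tumor <- cropped$tumor
  }
  structure(out, class = "safe_margin_result")
}

#' @export
print.safe_margin_result <- function(x, ...) {
  cat(sprintf(
    "<safe_margin_result> d_s = %g mm, target %g mm: %d coarse + %d ring voxels, %d fused points\n",
    x$params$d_s, x$params$target, sum(x$coarse$occupancy),
    sum(x$ring$occupancy), nrow(x$fused_points)
  ))
  invisible(x)
}

#' Boundary surface mesh of a point set
#'
#' Triangulated boundary of the Delaunay tetrahedralization of the points,
#' i.e. their convex hull: watertight for convex inputs. Intended for export
#' and visualization only; no evaluation metric depends on it.
#'
#' @param points numeric matrix with columns x, y, z (mm); at least 4
#'   non-coplanar points.
#' @return An object of class `triangle_mesh`: list with `vertices` (the
#'   input points) and `faces` (1-based triangle indices, outward oriented).
#' @export
reconstruct_surface <- function(points) {
  points <- rbind(points)
  if (nrow(points) < 4L) {
    stop("surface reconstruction requires at least 4 points")
  }
  faces <- convex_hull_cpp(points)
  structure(list(vertices = points, faces = faces), class = "triangle_mesh")
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("<triangle_mesh> %d vertices, %d triangles\n",
              nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}
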