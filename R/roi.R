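#' Refine a tumor mask by intersection with the bone mask
#'
#' Only the intraosseous part of the tumor drives margin growth: tumor voxels
#' outside the bone do not contact bone and are discarded before any margin
#' computation. Both masks must share the same lattice and physical geometry.
#'
#' @param bone,tumor co-registered [mask_volume()] objects.
#' @return A [mask_volume()]: the voxelwise AND, on the same geometry.
#' @export
refine_tumor <- function(bone, tumor) {
  if (!same_geometry(bone, tumor)) {
    stop("bone and tumor masks have incompatible grids")
  }
  refined <- bone
  refined$occupancy <- bone$occupancy & tumor$occupancy
  if (!any(refined$occupancy)) {
    stop("refined tumor is empty: tumor does not intersect bone (nothing to protect)")
  }
  refined
}

#' Bounding box of the true voxels of a mask (voxel-centre coordinates)
#'
#' @param tumor a [mask_volume()] with at least one true voxel.
#' @return A [physical_box()] spanning the min/max voxel-centre coordinates
#'   per axis.
#' @export
tumor_bbox <- function(tumor) {
  idx <- which(tumor$occupancy, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("empty mask: no bounding box")
  lo <- voxel_center(tumor, min(idx[, 1]), min(idx[, 2]), min(idx[, 3]))
  hi <- voxel_center(tumor, max(idx[, 1]), max(idx[, 2]), max(idx[, 3]))
  physical_box(lo, hi)
}

#' Expand a physical box symmetrically by the safe margin plus slack
#'
#' Grows the tumor bounding box by `d_s + xi` on every side so that the whole
#' safe-margin volume fits inside the cropped region of interest.
#'
#' @param box a [physical_box()] (typically [tumor_bbox()]).
#' @param d_s safe margin in mm (`>= 0`).
#' @param xi positive cropping slack in mm; the default 2 mm exceeds any
#'   discretization slack at clinical spacings.
#' @return A [physical_box()].
#' @export
expand_bbox <- function(box, d_s, xi = 2) {
  stopifnot(inherits(box, "physical_box"))
  if (d_s < 0) stop("`d_s` must be non-negative")
  if (xi <= 0) stop("`xi` must be positive")
  physical_box(box$min - (d_s + xi), box$max + (d_s + xi))
}

#' Crop a co-registered bone/tumor pair to a physical region of interest
#'
#' Both masks are cropped to the same index box (via [mm_box_to_index_box()],
#' clamped to the grid with a warning when the requested box overruns it).
#' Origin and the `slice_z` sublist are updated so that [voxel_center()] is
#' invariant for every surviving voxel.
#'
#' @param bone,tumor co-registered [mask_volume()] objects.
#' @param roi a [physical_box()] overlapping the grid.
#' @return List with elements `bone` and `tumor` (cropped [mask_volume()]s).
#' @export
crop_pair <- function(bone, tumor, roi) {
  if (!same_geometry(bone, tumor)) {
    stop("bone and tumor masks have incompatible grids")
  }
  ib <- mm_box_to_index_box(bone, roi)
  list(bone = crop_volume(bone, ib), tumor = crop_volume(tumor, ib))
}

crop_volume <- function(grid, ib) {
  stopifnot(inherits(ib, "index_box"))
  occ <- grid$occupancy[ib$lo[1]:ib$hi[1], ib$lo[2]:ib$hi[2],
                        ib$lo[3]:ib$hi[3], drop = FALSE]
  mask_volume(
    occ,
    spacing = c(grid$spacing_x, grid$spacing_y),
    slice_z = grid$slice_z[ib$lo[3]:ib$hi[3]],
    origin = c(grid$origin_x + (ib$lo[1] - 1) * grid$spacing_x,
               grid$origin_y + (ib$lo[2] - 1) * grid$spacing_y)
  )
}
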