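#' Construct a binary mask volume on an anisotropic voxel grid
#'
#' A `mask_volume` couples a 3D logical occupancy lattice with its physical
#' geometry: in-plane spacings (mm), per-slice z positions (mm, possibly
#' non-uniform), and the in-plane origin, i.e. the physical coordinates of the
#' centre of the first voxel of each slice. Voxel indices are 1-based in all
#' exported functions.
#'
#' @param occupancy 3D logical array of dimensions `(H_x, H_y, H_z)`.
#' @param spacing numeric of length 2 or 3: in-plane spacings `S_x`, `S_y`
#'   in mm (a third element, if given, is the uniform z spacing used to build
#'   `slice_z` when `slice_z` is `NULL`).
#' @param slice_z strictly increasing numeric vector of `H_z` slice z
#'   positions in mm. Defaults to `origin_z + (0:(H_z-1)) * spacing[3]`.
#' @param origin numeric of length 2 or 3: physical x/y (and, when `slice_z`
#'   is `NULL`, z) coordinates of the first voxel centre, in mm.
#' @return An object of class `mask_volume`.
#' @export
mask_volume <- function(occupancy, spacing = c(1, 1, 1), slice_z = NULL,
                        origin = c(0, 0, 0)) {
  if (!is.logical(occupancy)) {
    storage.mode(occupancy) <- "logical"
  }
  if (length(dim(occupancy)) != 3L) {
    stop("`occupancy` must be a 3D array")
  }
  if (is.null(slice_z)) {
    if (length(spacing) < 3L || length(origin) < 3L) {
      stop("either `slice_z` or a z spacing and z origin must be given")
    }
    slice_z <- origin[3] + (seq_len(dim(occupancy)[3]) - 1) * spacing[3]
  }
  vol <- structure(
    list(
      occupancy = occupancy,
      spacing_x = as.numeric(spacing[1]),
      spacing_y = as.numeric(spacing[2]),
      slice_z = as.numeric(slice_z),
      origin_x = as.numeric(origin[1]),
      origin_y = as.numeric(origin[2])
    ),
    class = "mask_volume"
  )
  validate_mask_volume(vol)
  vol
}

#' @export
print.mask_volume <- function(x, ...) {
  d <- dim(x$occupancy)
  cat(sprintf(
    "<mask_volume> %d x %d x %d voxels, spacing %.4g x %.4g mm in-plane,\n",
    d[1], d[2], d[3], x$spacing_x, x$spacing_y
  ))
  cat(sprintf(
    "  z in [%.4g, %.4g] mm (%d slices), origin (%.4g, %.4g), %d true voxels\n",
    x$slice_z[1], x$slice_z[length(x$slice_z)], d[3],
    x$origin_x, x$origin_y, sum(x$occupancy)
  ))
  invisible(x)
}

validate_mask_volume <- function(vol) {
  d <- dim(vol$occupancy)
  if (length(vol$slice_z) != d[3]) {
    stop("length of `slice_z` must equal the number of slices")
  }
  if (d[3] > 1 && any(diff(vol$slice_z) <= 0)) {
    stop("`slice_z` must be strictly increasing")
  }
  if (vol$spacing_x <= 0 || vol$spacing_y <= 0) {
    stop("in-plane spacings must be positive")
  }
  if (anyNA(vol$occupancy)) stop("`occupancy` must not contain NA")
  invisible(vol)
}

grid_dim <- function(grid) dim(grid$occupancy)

#' Same lattice and physical geometry?
#' @noRd
same_geometry <- function(a, b, tol = 1e-9) {
  identical(dim(a$occupancy), dim(b$occupancy)) &&
    abs(a$spacing_x - b$spacing_x) < tol &&
    abs(a$spacing_y - b$spacing_y) < tol &&
    abs(a$origin_x - b$origin_x) < tol &&
    abs(a$origin_y - b$origin_y) < tol &&
    max(abs(a$slice_z - b$slice_z)) < tol
}

#' Physical coordinates of voxel centres
#'
#' Maps 1-based voxel indices `(i, j, k)` to physical mm coordinates:
#' `x = (i - 1) * S_x + P_x`, `y = (j - 1) * S_y + P_y`, `z = slice_z[k]`.
#'
#' @param grid a [mask_volume()].
#' @param i,j,k equal-length vectors of 1-based voxel indices.
#' @return Numeric matrix with columns `x`, `y`, `z` (mm).
#' @export
voxel_center <- function(grid, i, j, k) {
  d <- grid_dim(grid)
  if (any(i < 1L | i > d[1]) || any(j < 1L | j > d[2]) ||
      any(k < 1L | k > d[3])) {
    stop("voxel index out of range")
  }
  out <- cbind(
    x = (i - 1) * grid$spacing_x + grid$origin_x,
    y = (j - 1) * grid$spacing_y + grid$origin_y,
    z = grid$slice_z[k]
  )
  rownames(out) <- NULL
  out
}

#' Convert the true voxels of a mask to a 3D point set
#'
#' One point per true voxel, at the voxel centre. Ordering is deterministic:
#' ascending slice `k`, then `j`, then `i` fastest (column-major order of the
#' occupancy array).
#'
#' @param grid a [mask_volume()].
#' @return Numeric matrix with columns `x`, `y`, `z` (mm); zero rows when the
#'   mask is empty.
#' @export
grid_to_points <- function(grid) {
  idx <- which(grid$occupancy, arr.ind = TRUE)
  if (nrow(idx) == 0L) {
    return(matrix(numeric(0), ncol = 3, dimnames = list(NULL, c("x", "y", "z"))))
  }
  voxel_center(grid, idx[, 1], idx[, 2], idx[, 3])
}

#' Nearest voxel index of physical points
#'
#' Inverse of [voxel_center()] under nearest-centre rounding; used for
#' round-trip checks. z is matched to the nearest entry of `slice_z`.
#'
#' @param grid a [mask_volume()].
#' @param points numeric matrix with columns x, y, z (mm).
#' @return Integer matrix of 1-based indices `(i, j, k)`.
#' @export
nearest_voxel_index <- function(grid, points) {
  points <- rbind(points)
  d <- grid_dim(grid)
  i <- pmin(pmax(round((points[, 1] - grid$origin_x) / grid$spacing_x) + 1, 1), d[1])
  j <- pmin(pmax(round((points[, 2] - grid$origin_y) / grid$spacing_y) + 1, 1), d[2])
  k <- vapply(points[, 3], function(z) which.min(abs(grid$slice_z - z)), integer(1))
  cbind(i = as.integer(i), j = as.integer(j), k = as.integer(k))
}

#' Axis-aligned physical box (mm)
#'
#' @param min_corner,max_corner numeric length-3 mm triples with
#'   `min_corner <= max_corner` per axis.
#' @return An object of class `physical_box`.
#' @export
physical_box <- function(min_corner, max_corner) {
  min_corner <- as.numeric(min_corner)
  max_corner <- as.numeric(max_corner)
  if (length(min_corner) != 3L || length(max_corner) != 3L) {
    stop("box corners must be length-3 mm triples")
  }
  if (any(!is.finite(min_corner)) || any(!is.finite(max_corner))) {
    stop("box corners must be finite")
  }
  if (any(min_corner > max_corner)) {
    stop("`min_corner` must not exceed `max_corner` on any axis")
  }
  structure(list(min = min_corner, max = max_corner), class = "physical_box")
}

#' Inclusive index box
#' @param lo,hi integer length-3 vectors of 1-based inclusive index bounds.
#' @return An object of class `index_box`.
#' @export
index_box <- function(lo, hi) {
  lo <- as.integer(lo); hi <- as.integer(hi)
  if (any(lo > hi)) stop("`lo` must not exceed `hi` on any axis")
  structure(list(lo = lo, hi = hi), class = "index_box")
}

#' Convert a physical box to the index box of covering voxels
#'
#' Selects, per axis, the 1-based index range `floor((coord - origin)/spacing)
#' + 1` for both bounds: the voxel whose centre is nearest at or below each
#' bound. Along z the (possibly non-uniform) `slice_z` positions are searched
#' directly. The range is clamped to the grid with a warning; a box with no
#' voxel in range is an error.
#'
#' @param grid a [mask_volume()].
#' @param box a [physical_box()].
#' @return An [index_box()].
#' @export
mm_box_to_index_box <- function(grid, box) {
  stopifnot(inherits(box, "physical_box"))
  d <- grid_dim(grid)
  nz <- d[3]
  half_gap <- if (nz > 1) diff(grid$slice_z) / 2 else grid$spacing_x / 2
  ext_lo <- c(grid$origin_x - grid$spacing_x / 2,
              grid$origin_y - grid$spacing_y / 2,
              grid$slice_z[1] - half_gap[1])
  ext_hi <- c(grid$origin_x + (d[1] - 1) * grid$spacing_x + grid$spacing_x / 2,
              grid$origin_y + (d[2] - 1) * grid$spacing_y + grid$spacing_y / 2,
              grid$slice_z[nz] + half_gap[length(half_gap)])
  if (any(box$max < ext_lo) || any(box$min > ext_hi)) {
    stop("physical box does not overlap the grid: empty selection")
  }
  lo_i <- floor((box$min[1] - grid$origin_x) / grid$spacing_x) + 1
  hi_i <- floor((box$max[1] - grid$origin_x) / grid$spacing_x) + 1
  lo_j <- floor((box$min[2] - grid$origin_y) / grid$spacing_y) + 1
  hi_j <- floor((box$max[2] - grid$origin_y) / grid$spacing_y) + 1
  # number of slice positions at or below each z bound (floor analogue)
  lo_k <- findInterval(box$min[3], grid$slice_z)
  hi_k <- findInterval(box$max[3], grid$slice_z)
  lo <- c(lo_i, lo_j, lo_k)
  hi <- c(hi_i, hi_j, hi_k)
  if (any(hi < 1) || any(lo > d)) {
    stop("physical box does not overlap the grid: empty selection")
  }
  clamped_lo <- pmax(lo, 1L)
  clamped_hi <- pmin(hi, d)
  if (any(clamped_lo != lo) || any(clamped_hi != hi)) {
    warning("requested box extends beyond the volume; clamped to grid extent")
  }
  index_box(clamped_lo, clamped_hi)
}
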