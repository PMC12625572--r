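#' Mean slice spacing of a (possibly non-uniform) slice stack
#'
#' `D_bar = (P_z^n - P_z^1) / (n - 1)`: the average gap between adjacent
#' slices, used both to choose the z replication coefficient and as the scalar
#' z spacing of the coarse-grid distance transform.
#'
#' @param slice_z strictly increasing z positions (mm) of at least two slices.
#' @return Mean spacing in mm.
#' @export
mean_slice_spacing <- function(slice_z) {
  n <- length(slice_z)
  if (n < 2L) stop("degenerate stack: at least two slices are required")
  (slice_z[n] - slice_z[1]) / (n - 1)
}

#' Odd-integer replication coefficients for a target spacing
#'
#' Each axis is replicated an odd number of times `C = 2*ceil((S/S_t + 1)/2)
#' - 1`, the smallest odd integer with `S / C <= S_t`, so that the resampled
#' spacing reaches the target and the sub-voxel centres straddle the original
#' centre symmetrically in plane. The z axis uses the mean slice spacing.
#'
#' @param spacing_x,spacing_y in-plane spacings in mm.
#' @param mean_z mean slice spacing in mm (see [mean_slice_spacing()]).
#' @param target target spacing `S_t` in mm (default 0.10).
#' @return An object of class `resample_plan` with the per-axis coefficients
#'   `C`, the underlying integers `k`, the target spacing and the nominal
#'   resampled spacings.
#' @export
resampling_coefficients <- function(spacing_x, spacing_y, mean_z,
                                    target = 0.10) {
  if (spacing_x <= 0 || spacing_y <= 0 || mean_z <= 0 || target <= 0) {
    stop("spacings and target spacing must be positive")
  }
  k <- ceiling((c(spacing_x, spacing_y, mean_z) / target + 1) / 2)
  C <- as.integer(2 * k - 1)
  structure(
    list(
      C = C, k = as.integer(k), target = target, mean_z = mean_z,
      spacing = c(spacing_x, spacing_y, mean_z),
      nominal_fine = c(spacing_x, spacing_y, mean_z) / C
    ),
    class = "resample_plan"
  )
}

#' @export
print.resample_plan <- function(x, ...) {
  cat(sprintf(
    "<resample_plan> C = (%d, %d, %d), target %.4g mm, fine spacing ~ (%.4g, %.4g, %.4g) mm\n",
    x$C[1], x$C[2], x$C[3], x$target,
    x$nominal_fine[1], x$nominal_fine[2], x$nominal_fine[3]
  ))
  invisible(x)
}

#' Block-replicate a 3D logical lattice
#'
#' Nearest-neighbour upsampling by replication: each voxel becomes a
#' `C_x x C_y x C_z` block of its value. Replication is two-stage (in-plane
#' first, then z) to bound peak memory.
#'
#' @param mask 3D logical array.
#' @param C_x,C_y,C_z positive odd replication factors.
#' @return 3D logical array of dimensions `dim(mask) * c(C_x, C_y, C_z)`.
#' @export
replicate_mask <- function(mask, C_x, C_y, C_z) {
  for (C in c(C_x, C_y, C_z)) {
    if (C < 1 || C != as.integer(C) || C %% 2 == 0) {
      stop("replication factors must be positive odd integers")
    }
  }
  d <- dim(mask)
  if (length(d) != 3L) stop("`mask` must be a 3D array")
  out <- mask
  if (C_x > 1 || C_y > 1) {
    out <- out[rep(seq_len(d[1]), each = C_x),
               rep(seq_len(d[2]), each = C_y), , drop = FALSE]
  }
  if (C_z > 1) {
    out <- out[, , rep(seq_len(d[3]), each = C_z), drop = FALSE]
  }
  out
}

#' Geometry of a replication-resampled grid
#'
#' Recomputes the exact fine spacings, in-plane origin and slice z positions
#' after replication. In plane, `S_hat = S / C` and the origin shifts to the
#' centre of the first sub-voxel, `P_hat = P + (-C/2 + 0.5) * S_hat`. Along z
#' the `H_z * C_z` resampled slices are laid out uniformly from the first to
#' the last original slice position with spacing `S_hat_z = (P_z^n - P_z^1) /
#' (H_z * C_z - 1)`; for a two-slice stack this is exactly the per-pair
#' interpolation with step `D / (2 C_z - 1)` and preserved endpoints, and it
#' keeps the point coordinates consistent with the scalar-spacing metric of
#' the distance transform (see the package vignette for the rationale).
#' When `C_z = 1` the original (possibly non-uniform) slice positions are
#' kept unchanged.
#'
#' @param grid a [mask_volume()] with at least two slices.
#' @param plan a [resampling_coefficients()] plan.
#' @return List with `spacing_fine` (length-3, mm), `origin_fine` (x, y) and
#'   `slice_z_fine`.
#' @export
resampled_geometry <- function(grid, plan) {
  stopifnot(inherits(plan, "resample_plan"))
  d <- grid_dim(grid)
  nz <- d[3]
  if (nz < 2L) stop("degenerate stack: at least two slices are required")
  C <- plan$C
  s_hat_x <- grid$spacing_x / C[1]
  s_hat_y <- grid$spacing_y / C[2]
  nz_fine <- nz * C[3]
  s_hat_z <- (grid$slice_z[nz] - grid$slice_z[1]) / (nz_fine - 1)
  if (C[3] == 1L) {
    slice_z_fine <- grid$slice_z
  } else {
    slice_z_fine <- grid$slice_z[1] + (seq_len(nz_fine) - 1) * s_hat_z
  }
  list(
    spacing_fine = c(s_hat_x, s_hat_y, s_hat_z),
    origin_fine = c(grid$origin_x + (-C[1] / 2 + 0.5) * s_hat_x,
                    grid$origin_y + (-C[2] / 2 + 0.5) * s_hat_y),
    slice_z_fine = slice_z_fine
  )
}

#' Resample a mask volume to a target spacing by odd-integer replication
#'
#' Composite of [resampling_coefficients()], [replicate_mask()] and
#' [resampled_geometry()]. When the target spacing is no smaller than every
#' original spacing all coefficients are 1 and the volume is returned
#' unchanged.
#'
#' @param grid a [mask_volume()] with at least two slices.
#' @param target target spacing `S_t` in mm.
#' @param plan optionally a precomputed [resampling_coefficients()] plan.
#' @return A [mask_volume()] with attribute `"plan"` (the resample plan) and
#'   `"spacing_fine"` (the exact length-3 fine spacings of the distance
#'   metric).
#' @export
resample_grid <- function(grid, target = 0.10, plan = NULL) {
  if (is.null(plan)) {
    plan <- resampling_coefficients(grid$spacing_x, grid$spacing_y,
                                    mean_slice_spacing(grid$slice_z), target)
  }
  geo <- resampled_geometry(grid, plan)
  occ <- replicate_mask(grid$occupancy, plan$C[1], plan$C[2], plan$C[3])
  out <- mask_volume(occ,
                     spacing = c(geo$spacing_fine[1], geo$spacing_fine[2]),
                     slice_z = geo$slice_z_fine,
                     origin = geo$origin_fine)
  attr(out, "plan") <- plan
  attr(out, "spacing_fine") <- geo$spacing_fine
  out
}

#' Scalar distance-transform spacings of a mask volume
#'
#' In-plane spacings plus the mean slice spacing: the metric used by the
#' anisotropic distance transform on either the original or resampled grid.
#'
#' @param grid a [mask_volume()].
#' @return Numeric length-3 (mm).
#' @export
dt_spacing <- function(grid) {
  c(grid$spacing_x, grid$spacing_y, mean_slice_spacing(grid$slice_z))
}
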