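#' Deterministic sphere phantom: tumor ball embedded in a cuboid bone
#'
#' Synthetic stand-in for clinical bone/tumor masks, with an analytic
#' descriptor enabling exact ground-truth distances. The tumor is a ball of
#' radius `r` (a voxel is tumor iff its centre lies within `r` of the
#' centre); the bone is an axis-aligned box of the given half-widths. The
#' grid is padded one voxel beyond the bone box so the bone surface is
#' resolved. The bone box must contain the margin ball of radius
#' `r + d_s_max` with at least two coarse voxels of clearance, so that the
#' margin boundary is never clipped by bone unless requested.
#'
#' @param spacing length-3 voxel spacings in mm; the default emulates
#'   clinical CT spacing near (0.75, 0.75, 0.80).
#' @param bone_half_widths length-3 half-widths (mm) of the bone box.
#' @param r tumor radius in mm (`> 2 * max(spacing)`).
#' @param center tumor centre (mm), default the origin.
#' @param d_s_max largest safe margin the phantom must accommodate (mm).
#' @return An object of class `phantom`: `bone` and `tumor`
#'   [mask_volume()]s plus the analytic `descriptor`.
#' @export
make_sphere_phantom <- function(spacing = c(0.75, 0.75, 0.80),
                                bone_half_widths = c(16, 16, 16),
                                r = 4, center = c(0, 0, 0), d_s_max = 10) {
  if (r <= 2 * max(spacing)) {
    stop("tumor radius must exceed twice the largest spacing")
  }
  clearance <- r + d_s_max + 2 * max(spacing)
  if (any(bone_half_widths < clearance)) {
    stop(sprintf(
      "bone box too small: half-widths must be at least r + d_s_max + 2*max(spacing) = %.2f mm",
      clearance
    ))
  }
  pad <- max(spacing)
  n_half <- ceiling((bone_half_widths + pad) / spacing)
  ax <- lapply(1:3, function(a) {
    center[a] + (-n_half[a]:n_half[a]) * spacing[a]
  })
  H <- 2 * n_half + 1
  bone_occ <- array(FALSE, H)
  tumor_occ <- array(FALSE, H)
  in_box <- lapply(1:3, function(a) {
    abs(ax[[a]] - center[a]) <= bone_half_widths[a]
  })
  bone_occ[in_box[[1]], in_box[[2]], in_box[[3]]] <- TRUE
  dx2 <- (ax[[1]] - center[1])^2
  dy2 <- (ax[[2]] - center[2])^2
  dz2 <- (ax[[3]] - center[3])^2
  d2 <- outer(outer(dx2, dy2, `+`), dz2, `+`)
  tumor_occ[d2 <= r^2] <- TRUE
  origin <- c(ax[[1]][1], ax[[2]][1])
  bone <- mask_volume(bone_occ, spacing = spacing[1:2], slice_z = ax[[3]],
                      origin = origin)
  tumor <- mask_volume(tumor_occ, spacing = spacing[1:2], slice_z = ax[[3]],
                       origin = origin)
  structure(
    list(bone = bone, tumor = tumor,
         descriptor = list(center = center, radius = r,
                           half_widths = bone_half_widths,
                           spacing = spacing),
         seed = NULL),
    class = "phantom"
  )
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf(
    "<phantom> tumor ball r = %g mm at (%g, %g, %g), bone half-widths (%g, %g, %g) mm\n",
    x$descriptor$radius, x$descriptor$center[1], x$descriptor$center[2],
    x$descriptor$center[3], x$descriptor$half_widths[1],
    x$descriptor$half_widths[2], x$descriptor$half_widths[3]
  ))
  print(x$bone)
  invisible(x)
}

#' Perturb a phantom's slice positions with deterministic jitter
#'
#' Emulates the slightly unequal slice gaps of clinical stacks (scanner speed
#' is not perfectly constant): interior slice z positions are shifted by
#' seeded uniform jitter, clamped so the stack stays strictly increasing;
#' endpoints are kept, so the mean slice spacing is unchanged.
#'
#' @param phantom a [make_sphere_phantom()] phantom.
#' @param jitter_frac jitter amplitude as a fraction of the mean gap
#'   (`< 0.3`).
#' @param seed integer seed; the same seed always yields the same stack.
#' @return A `phantom` with perturbed `slice_z` in both masks.
#' @export
make_nonuniform_z_phantom <- function(phantom, jitter_frac, seed) {
  stopifnot(inherits(phantom, "phantom"))
  if (jitter_frac < 0 || jitter_frac >= 0.3) {
    stop("`jitter_frac` must be in [0, 0.3)")
  }
  z <- phantom$bone$slice_z
  n <- length(z)
  if (n > 2L && jitter_frac > 0) {
    d_bar <- mean_slice_spacing(z)
    old_seed <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
    })
    set.seed(seed)
    delta <- stats::runif(n - 2, -1, 1) * jitter_frac * d_bar
    znew <- z
    znew[2:(n - 1)] <- z[2:(n - 1)] + delta
    # clamp any ordering violation back towards the midpoint of its gap
    for (i in 2:(n - 1)) {
      lo <- znew[i - 1] + 0.05 * d_bar
      hi <- z[i + 1] - 0.05 * d_bar
      znew[i] <- min(max(znew[i], lo), hi)
    }
    z <- znew
  }
  phantom$bone$slice_z <- z
  phantom$tumor$slice_z <- z
  phantom$seed <- seed
  validate_mask_volume(phantom$bone)
  phantom
}

#' Analytic distance from points to the phantom tumor surface
#'
#' `max(0, ||p - c|| - r)` for the sphere descriptor: the continuous
#' reference used for coarse sanity checks (the primary evaluation reference
#' is the voxel-centre set, which digitizes the sphere to within half a voxel
#' diagonal).
#'
#' @param points point matrix (columns x, y, z in mm).
#' @param phantom a [make_sphere_phantom()] phantom.
#' @return Distances in mm (0 inside the ball).
#' @export
analytic_distance <- function(points, phantom) {
  stopifnot(inherits(phantom, "phantom"))
  points <- rbind(points)
  c0 <- phantom$descriptor$center
  d <- sqrt((points[, 1] - c0[1])^2 + (points[, 2] - c0[2])^2 +
              (points[, 3] - c0[3])^2)
  pmax(0, d - phantom$descriptor$radius)
}
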