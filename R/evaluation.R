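#' Outward boundary points of a generated safe-margin volume
#'
#' Centres of ring voxels having at least one 6-neighbour whose distance
#' exceeds the safe margin and which lies inside the bone. Restricting to
#' in-bone neighbours excludes bone-clipped faces — where the volume is
#' truncated by the cortex, not by the margin — from geometric evaluation.
#'
#' @param result a [generate_safe_margin_volume()] result with fine fields
#'   kept, or a fine-grid ring [mask_volume()] (then `bone`, `D` and `d_s`
#'   are required).
#' @param bone fine-grid bone [mask_volume()].
#' @param D fine-grid [anisotropic_distance_map()].
#' @param d_s safe margin in mm.
#' @return Point matrix (columns x, y, z in mm).
#' @export
outward_boundary_points <- function(result, bone = NULL, D = NULL,
                                    d_s = NULL) {
  if (inherits(result, "safe_margin_result")) {
    if (is.null(result$fine_distance)) {
      stop("result was generated with `keep_fine = FALSE`; fine fields are required")
    }
    ring <- result$ring
    bone <- if (is.null(bone)) result$fine_bone else bone
    D <- if (is.null(D)) result$fine_distance else D
    d_s <- if (is.null(d_s)) result$params$d_s else d_s
  } else {
    ring <- result
    if (is.null(bone) || is.null(D) || is.null(d_s)) {
      stop("`bone`, `D` and `d_s` are required when not passing a result object")
    }
  }
  if (!any(ring$occupancy)) stop("empty ring mask: nothing to evaluate")
  dims <- grid_dim(ring)
  sel <- outward_boundary_cpp(as.logical(ring$occupancy),
                              as.numeric(D$values),
                              as.logical(bone$occupancy),
                              as.integer(dims), d_s)
  if (!any(sel)) {
    stop("no outward boundary voxels: ring is fully clipped by the bone surface")
  }
  dim(sel) <- dims
  grid_to_points(dmap_mask(D, sel))
}

#' Surface shell points of a mask volume
#'
#' Centres of true voxels with at least one false 6-neighbour. For query
#' points outside the mask, the nearest true-voxel centre is always on this
#' shell, so it is a loss-free reduction of the reference set for
#' nearest-distance evaluation.
#'
#' @param grid a [mask_volume()].
#' @return Point matrix (columns x, y, z in mm).
#' @export
surface_points <- function(grid) {
  dims <- grid_dim(grid)
  shell <- boundary6_cpp(as.logical(grid$occupancy), as.integer(dims))
  dim(shell) <- dims
  out <- grid
  out$occupancy <- shell
  grid_to_points(out)
}

#' Signed geometric errors of surface points against a tumor reference
#'
#' For each point, the exact nearest Euclidean distance to the reference
#' tumor point set minus the safe margin: negative errors lie inside the true
#' offset surface (conservative), positive errors beyond it. Nearest
#' distances use a KD-tree spatial index by default; the exhaustive engine is
#' the independent oracle for small inputs.
#'
#' @param points evaluation point matrix (columns x, y, z in mm).
#' @param tumor_ref reference tumor point matrix (voxel centres), non-empty.
#' @param d_s safe margin in mm.
#' @param engine `"kdtree"` (RANN) or `"brute"` (exhaustive all-pairs).
#' @return Numeric vector of signed errors (mm).
#' @export
signed_errors <- function(points, tumor_ref, d_s,
                          engine = c("kdtree", "brute")) {
  engine <- match.arg(engine)
  points <- rbind(points)
  tumor_ref <- rbind(tumor_ref)
  if (nrow(points) == 0L) stop("empty evaluation point set")
  if (nrow(tumor_ref) == 0L) stop("empty reference point set")
  d <- if (engine == "kdtree") {
    as.numeric(RANN::nn2(tumor_ref, points, k = 1)$nn.dists)
  } else {
    min_dist_brute_cpp(points, tumor_ref)
  }
  d - d_s
}

#' Summary statistics of signed geometric errors
#'
#' @param errors numeric vector of signed errors (mm), non-empty.
#' @return An object of class `error_report`: `n`, `mean`, `sd`, `ci95`
#'   (normal-approximation `mean +/- 1.96 sd / sqrt(n)`), `max_abs`, and the
#'   raw errors.
#' @export
error_summary <- function(errors) {
  n <- length(errors)
  if (n < 1L) stop("no errors to summarise")
  m <- mean(errors)
  s <- if (n > 1) stats::sd(errors) else 0
  half <- 1.96 * s / sqrt(n)
  structure(
    list(errors = errors, n = n, mean = m, sd = s,
         ci95 = c(m - half, m + half), max_abs = max(abs(errors))),
    class = "error_report"
  )
}

#' @export
print.error_report <- function(x, ...) {
  cat(sprintf(
    "<error_report> n = %d, mean %.4f mm (95%% CI [%.4f, %.4f]), max |err| %.4f mm\n",
    x$n, x$mean, x$ci95[1], x$ci95[2], x$max_abs
  ))
  invisible(x)
}

#' Cross-method comparison of error samples
#'
#' Anderson-Darling normality p-value per sample, one-sided Wilcoxon rank-sum
#' test (normal approximation with continuity and tie correction; alternative:
#' sample `a` stochastically smaller than `b`), and the mean difference
#' `mean(b) - mean(a)` with a pooled-variance t-based 95% confidence
#' interval.
#'
#' @param err_a errors of the method under test (expected smaller).
#' @param err_b errors of the comparator.
#' @return An object of class `comparison_report`.
#' @export
compare_methods <- function(err_a, err_b) {
  if (length(err_a) < 3L || length(err_b) < 3L) {
    stop("both samples must have at least 3 values")
  }
  ad_p <- function(x) {
    if (length(unique(x)) < 2L || length(x) < 8L) return(NA_real_)
    nortest::ad.test(x)$p.value
  }
  all_ties <- length(unique(c(err_a, err_b))) == 1L
  ranksum_p <- if (all_ties) {
    1.0
  } else {
    suppressWarnings(
      stats::wilcox.test(err_a, err_b, alternative = "less",
                         exact = FALSE, correct = TRUE)$p.value
    )
  }
  mean_diff <- mean(err_b) - mean(err_a)
  # with (near-)constant samples the t interval degenerates to a point
  tt <- tryCatch(stats::t.test(err_b, err_a, var.equal = TRUE),
                 error = function(e) NULL)
  ci <- if (is.null(tt)) c(mean_diff, mean_diff) else as.numeric(tt$conf.int)
  structure(
    list(
      ad_p_a = ad_p(err_a), ad_p_b = ad_p(err_b),
      ranksum_p = ranksum_p,
      mean_diff = mean_diff,
      mean_diff_ci95 = ci,
      degenerate = all_ties
    ),
    class = "comparison_report"
  )
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf(
    "<comparison_report> rank-sum p = %.4g (one-sided), mean diff %.4f mm (95%% CI [%.4f, %.4f])\n",
    x$ranksum_p, x$mean_diff, x$mean_diff_ci95[1], x$mean_diff_ci95[2]
  ))
  invisible(x)
}

#' Kaplan-Meier survival curve from right-censored follow-up data
#'
#' Product-limit estimator (deaths processed before censorings at tied
#' times), with Greenwood standard errors and log-scale 95% confidence
#' intervals.
#'
#' @param times positive follow-up times (months).
#' @param events logical (or 0/1): `TRUE` for death, `FALSE` for censoring.
#' @return An object of class `survival_curve`: step times, survival
#'   estimates, per-step 95% CI, and the underlying `survfit` fit.
#' @export
kaplan_meier <- function(times, events) {
  if (length(times) == 0L) stop("no follow-up data")
  if (length(times) != length(events)) {
    stop("`times` and `events` must be aligned")
  }
  if (any(times <= 0)) stop("follow-up times must be positive")
  fit <- survival::survfit(
    survival::Surv(times, as.integer(events)) ~ 1,
    conf.type = "log"
  )
  structure(
    list(time = fit$time, surv = fit$surv,
         ci95 = cbind(lower = fit$lower, upper = fit$upper),
         fit = fit),
    class = "survival_curve"
  )
}

#' Evaluate a survival curve at given times
#'
#' Right-continuous step-function evaluation; `S(0) = 1`.
#'
#' @param curve a [kaplan_meier()] curve.
#' @param t times (months).
#' @return Survival probabilities.
#' @export
surv_at <- function(curve, t) {
  stopifnot(inherits(curve, "survival_curve"))
  idx <- findInterval(t, curve$time)
  ifelse(idx == 0L, 1.0, curve$surv[pmax(idx, 1L)])
}

#' @export
print.survival_curve <- function(x, ...) {
  cat(sprintf("<survival_curve> %d time points, final S = %.4f\n",
              length(x$time), x$surv[length(x$surv)]))
  invisible(x)
}
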