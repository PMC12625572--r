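test_that("outward boundary selection matches a direct neighbourhood scan", {
  p <- small_phantom()
  res <- generate_safe_margin_volume(p$bone, p$tumor, d_s = 3, target = 0.45)
  pts <- outward_boundary_points(res)
  # direct R scan over ring voxels
  ring <- res$ring$occupancy
  D <- res$fine_distance$values
  bone <- res$fine_bone$occupancy
  d <- dim(ring)
  idx <- which(ring, arr.ind = TRUE)
  sel <- logical(nrow(idx))
  offs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                c(0, 0, 1), c(0, 0, -1))
  for (r in seq_len(nrow(idx))) {
    for (o in 1:6) {
      nb <- idx[r, ] + offs[o, ]
      if (any(nb < 1) || any(nb > d)) next
      if (bone[nb[1], nb[2], nb[3]] && D[nb[1], nb[2], nb[3]] > 3) {
        sel[r] <- TRUE; break
      }
    }
  }
  ref <- voxel_center(res$ring, idx[sel, 1], idx[sel, 2], idx[sel, 3])
  expect_equal(nrow(pts), nrow(ref))
  expect_equal(sort(pts[, 1] * 1e6 + pts[, 2] * 1e3 + pts[, 3]),
               sort(ref[, 1] * 1e6 + ref[, 2] * 1e3 + ref[, 3]))
  # single isolated selected voxel is kept
  expect_error(
    outward_boundary_points(res$ring, bone = res$fine_bone,
                            D = res$fine_distance, d_s = NULL),
    "required"
  )
})

test_that("signed errors carry the analytic sign convention", {
  ref <- rbind(c(0, 0, 0))
  expect_equal(signed_errors(rbind(c(5, 0, 0)), ref, 5), 0)
  expect_equal(signed_errors(rbind(c(0, 5.5, 0)), ref, 5), 0.5)
  expect_equal(signed_errors(rbind(c(0, 0, 4)), ref, 5), -1)
  # kdtree and exhaustive engines agree
  set.seed(8)
  q <- matrix(rnorm(300), ncol = 3)
  r <- matrix(rnorm(150), ncol = 3)
  expect_equal(signed_errors(q, r, 1, engine = "kdtree"),
               signed_errors(q, r, 1, engine = "brute"))
  # and both match the plain-R oracle
  expect_equal(signed_errors(q, r, 1, engine = "brute"),
               r_min_dist(q, r) - 1)
})

test_that("error summaries match their definitions and a bootstrap check", {
  s <- error_summary(c(0, 0, 0))
  expect_equal(s$mean, 0); expect_equal(s$ci95, c(0, 0)); expect_equal(s$max_abs, 0)
  s2 <- error_summary(c(-1, 1))
  expect_equal(s2$mean, 0); expect_equal(s2$max_abs, 1)
  expect_true(s2$ci95[1] <= s2$mean && s2$mean <= s2$ci95[2])

  set.seed(99)
  x <- rnorm(1000, mean = -0.05, sd = 0.03)
  s3 <- error_summary(x)
  boot <- replicate(2000, mean(sample(x, replace = TRUE)))
  bci <- unname(quantile(boot, c(0.025, 0.975)))
  halfwidth <- diff(s3$ci95) / 2
  expect_lt(abs(diff(bci) / 2 - halfwidth), 0.1 * halfwidth)
  expect_lt(abs(mean(bci) - s3$mean), 0.1 * halfwidth)
  expect_error(error_summary(numeric(0)), "no errors")
})

test_that("rank-sum comparison reproduces complete-separation p-values", {
  # untied, completely separated samples, n = m = 20
  a <- seq(0.01, 0.20, by = 0.01)
  b <- a + 100
  cmp <- compare_methods(a, b)
  z <- (0 - 200 + 0.5) / sqrt(20 * 20 * 41 / 12)
  expect_equal(cmp$ranksum_p, pnorm(z))
  expect_lt(abs(cmp$ranksum_p - 3.3882e-8) / 3.3882e-8, 0.01)

  # identical samples: one-sided p at or above one half
  cmp2 <- compare_methods(a, a)
  expect_gte(cmp2$ranksum_p, 0.5)

  # large shift: below 1e-6, cross-checked by a permutation oracle
  set.seed(123)
  x <- rnorm(20, 0, 0.1); y <- rnorm(20, 10, 0.1)
  cmp3 <- compare_methods(x, y)
  expect_lt(cmp3$ranksum_p, 1e-6)
  pooled <- c(x, y)
  obs <- mean(x) - mean(y)
  perm <- replicate(10000, {
    s <- sample(40, 20)
    mean(pooled[s]) - mean(pooled[-s])
  })
  expect_lt(mean(perm <= obs), 1e-3)

  # degenerate all-tied samples are flagged
  cmp4 <- compare_methods(rep(1, 5), rep(1, 5))
  expect_true(cmp4$degenerate)
  expect_equal(cmp4$ranksum_p, 1.0)
})

test_that("reported per-patient errors reproduce the published statistics", {
  e <- method_max_abs_errors()
  expect_equal(mean(e$dilation), 3.5753, tolerance = 1e-4)
  expect_equal(mean(e$coarse_adt), 1.4071, tolerance = 1e-4)
  expect_equal(mean(e$fused), 0.1818, tolerance = 1e-4)

  cd <- compare_methods(e$fused, e$dilation)
  ca <- compare_methods(e$fused, e$coarse_adt)
  expect_equal(cd$ranksum_p, 3.3882e-8, tolerance = 1e-3)
  expect_equal(ca$ranksum_p, 3.3882e-8, tolerance = 1e-3)
  expect_equal(cd$mean_diff, 3.39, tolerance = 0.01)
  expect_equal(cd$mean_diff_ci95, c(0.96, 5.82), tolerance = 0.01)
  expect_equal(ca$mean_diff, 1.23, tolerance = 0.01)
  expect_equal(ca$mean_diff_ci95, c(1.08, 1.37), tolerance = 0.01)
})

test_that("Kaplan-Meier estimator handles censoring and ties", {
  # no events: survival stays at 1
  km1 <- kaplan_meier(c(5, 10, 15), c(FALSE, FALSE, FALSE))
  expect_true(all(km1$surv == 1))
  expect_equal(surv_at(km1, 0), 1)

  # single subject dying at t drops survival to 0
  km2 <- kaplan_meier(7, TRUE)
  expect_equal(surv_at(km2, 7), 0)
  expect_equal(surv_at(km2, 6.9), 1)

  # death processed before censoring at a tied time
  km3 <- kaplan_meier(c(5, 5, 8), c(TRUE, FALSE, FALSE))
  expect_equal(surv_at(km3, 5), 2 / 3)

  # cohort example: S(60 months) = 0.95 * 7/8
  cohort <- resection_cohort()
  km <- kaplan_meier(cohort$follow_up_months, cohort$died)
  expect_equal(surv_at(km, 60), 19 / 20 * 7 / 8)
  expect_true(all(diff(km$surv) <= 1e-12))
  expect_error(kaplan_meier(numeric(0), logical(0)), "no follow-up")
  expect_error(kaplan_meier(c(1, -2), c(TRUE, TRUE)), "positive")
})
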