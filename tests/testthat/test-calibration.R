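# Frame-wise DLT calibration: exactness on noise-free correspondences,
# degeneracy detection, outlier rejection and trial-level reporting.

test_that("DLT recovers the projection matrix exactly from noise-free points", {
  cams <- oracle_cameras(3, seed = 11)
  X <- oracle_points(25, seed = 12)
  for (P in cams) {
    uv <- project_points(P, X)[, c("u", "v")]
    Pe <- estimate_dlt(X, uv)
    # up to scale and sign: both are unit-norm with positive depths
    expect_lt(max(abs(Pe - P / sqrt(sum(P^2)))), 1e-9)
    expect_lt(max(reprojection_errors(Pe, X, uv)), 1e-8)
  }
})

test_that("DLT is exact over many random seeded camera/point draws", {
  worst <- 0
  for (s in 1:100) {
    P <- oracle_cameras(1, seed = s)[[1]]
    X <- oracle_points(10, seed = s + 1000)
    uv <- project_points(P, X)[, c("u", "v")]
    Pe <- estimate_dlt(X, uv)
    worst <- max(worst, max(reprojection_errors(Pe, X, uv)))
  }
  expect_lt(worst, 1e-8)
})

test_that("coplanar correspondences raise a degeneracy error", {
  P <- oracle_cameras(1, seed = 2)[[1]]
  X <- oracle_points(12, seed = 3)
  X[, 3] <- -10                      # all points on one plane
  uv <- project_points(P, X)[, c("u", "v")]
  expect_error(estimate_dlt(X, uv), "degenerate")
})

test_that("fewer than six correspondences are refused", {
  P <- oracle_cameras(1, seed = 2)[[1]]
  X <- oracle_points(5, seed = 3)
  uv <- project_points(P, X)[, c("u", "v")]
  expect_error(estimate_dlt(X, uv), "at least 6")
})

test_that("reprojection errors are zero for exact points and infinite behind the camera", {
  P <- oracle_cameras(1, seed = 4)[[1]]
  X <- oracle_points(8, seed = 5)
  uv <- project_points(P, X)[, c("u", "v")]
  expect_lt(max(reprojection_errors(P, X, uv)), 1e-9)
  # reflect a point through the camera centre: negative depth
  centre <- -solve(P[, 1:3], P[, 4])
  Xb <- rbind(X, 2 * centre - X[1, ])
  uvb <- rbind(uv, uv[1, ])
  expect_true(is.infinite(reprojection_errors(P, Xb, uvb)[9]))
})

test_that("outlier rejection removes exactly the displaced correspondence", {
  P <- oracle_cameras(1, seed = 6)[[1]]
  X <- oracle_points(21, seed = 7)
  uv <- project_points(P, X)[, c("u", "v")]
  uv[13, ] <- uv[13, ] + c(100, 0)
  res <- reject_outliers(X, uv)
  expect_identical(res$rejected, 13L)
  expect_lt(res$mean_error, 1e-8)
  expect_lt(max(abs(res$P - P / sqrt(sum(P^2)))), 1e-8)
})

test_that("rejection never goes below the minimum point count", {
  P <- oracle_cameras(1, seed = 8)[[1]]
  X <- oracle_points(7, seed = 9)
  uv <- project_points(P, X)[, c("u", "v")]
  uv[1, ] <- uv[1, ] + 80
  uv[2, ] <- uv[2, ] + c(0, 60)
  res <- reject_outliers(X, uv, min_points = 6)
  expect_gte(length(res$inliers), 6)
  expect_lte(length(res$rejected), 1)
})

test_that("exact correspondences produce no rejections", {
  P <- oracle_cameras(1, seed = 10)[[1]]
  X <- oracle_points(15, seed = 11)
  uv <- project_points(P, X)[, c("u", "v")]
  res <- reject_outliers(X, uv)
  expect_length(res$rejected, 0)
})

test_that("every accepted removal lowers the mean error by the required fraction", {
  P <- oracle_cameras(1, seed = 10)[[1]]
  X <- oracle_points(15, seed = 11)
  uv <- project_points(P, X)[, c("u", "v")] +
    matrix(stats::rnorm(30, sd = 0.3), 15, 2)
  res <- reject_outliers(X, uv, improvement = 0.05)
  # replay the retained set: adding back any rejected point must raise the
  # mean error enough that its removal met the 5% criterion at some stage
  full <- reprojection_errors(estimate_dlt(X, uv), X, uv)
  kept_err <- reprojection_errors(res$P, X[res$inliers, ], uv[res$inliers, ])
  expect_lte(mean(kept_err), mean(full))
  expect_gte(length(res$inliers), 6)
})

test_that("nearest-point selection keeps the k identified points closest to the skier", {
  refs <- data.frame(ref_id = c(1:5, NA), cx = c(0, 10, 20, 30, 40, 1),
                     cy = 0)
  sel <- select_nearest(refs, c(21, 0), k = 3)
  expect_setequal(sel$ref_id, c(2L, 3L, 4L))
  expect_equal(nrow(select_nearest(refs, NULL, k = 3)), 5)   # no centroid
  expect_equal(nrow(select_nearest(refs, c(0, 0), k = 10)), 5)
})

test_that("trial calibration on a clean scene matches the true matrices", {
  b <- clean_bundle()
  refs <- do.call(rbind, lapply(unique(b$boxes$camera_id), function(cid)
    cbind(camera_id = cid,
          associate_refpoints(b$boxes[b$boxes$camera_id == cid, ],
                              b$identifications[b$identifications$camera_id == cid, ]))))
  cal <- calibrate_trial(refs, b$surveyed, b$skier_bbox)
  expect_true(all(cal$report$status %in% c("calibrated", "excluded")))
  ok <- cal$report[cal$report$status == "calibrated", ]
  expect_gt(nrow(ok), 0)
  expect_lt(max(ok$mean_error), 1e-8)
  expect_equal(sum(ok$n_rejected), 0)
  # calibrated matrices agree with ground truth up to scale/sign
  for (i in sample(nrow(ok), 5)) {
    cid <- ok$camera_id[i]; f <- ok$frame[i]
    Pe <- cal$matrices[[cid]][[f]]
    Pt <- b$ground_truth$P_true[[cid]][[f]]
    Pt <- Pt / sqrt(sum(Pt^2))
    expect_lt(min(max(abs(Pe - Pt)), max(abs(Pe + Pt))), 1e-7)
  }
})

test_that("frames with too few identified points are excluded, not fitted", {
  b <- clean_bundle()
  cid <- "cam01"
  refs <- cbind(camera_id = cid,
                associate_refpoints(b$boxes[b$boxes$camera_id == cid, ],
                                    b$identifications[b$identifications$camera_id == cid, ]))
  # starve one frame below the floor
  f0 <- refs$frame[1]
  in_f0 <- which(refs$frame == f0)
  starved <- refs[-in_f0[-(1:5)], ]
  cal <- calibrate_trial(starved, b$surveyed, b$skier_bbox)
  row <- cal$report[cal$report$camera_id == cid & cal$report$frame == f0, ]
  expect_identical(row$status, "excluded")
  expect_null(cal$matrices[[cid]][[f0]])
})
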