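# Triangulation, exhaustive camera-subset selection and zero-phase
# Butterworth smoothing.

test_that("triangulation is exact for noise-free multi-view observations", {
  cams <- oracle_cameras(8, seed = 20)
  X <- oracle_points(50, seed = 21)
  for (nv in c(2, 4, 8)) {
    Ps <- cams[seq_len(nv)]
    for (i in seq_len(nrow(X))) {
      uv <- t(vapply(Ps, function(P) project_points(P, X[i, , drop = FALSE])[1, 1:2],
                     numeric(2)))
      Xe <- triangulate(Ps, uv)
      expect_lt(max(abs(Xe - X[i, ])), 1e-6)
    }
  }
})

test_that("triangulation refuses a single view and flags near-parallel rays", {
  cams <- oracle_cameras(2, seed = 22)
  expect_error(triangulate(cams[1], matrix(c(1, 1), 1, 2)), "insufficient views")
  # two co-located cameras give (near-)parallel rays
  P <- cams[[1]]
  uv <- project_points(P, matrix(c(50, 0, -10), 1, 3))[1, 1:2]
  X <- triangulate(list(P, P), rbind(uv, uv))
  expect_true(isTRUE(attr(X, "unstable")) || attr(X, "condition") > 1e-8)
})

test_that("pixel noise degrades triangulation gracefully", {
  cams <- oracle_cameras(4, seed = 23)
  X <- oracle_points(100, seed = 24)
  set.seed(25)
  errs <- vapply(seq_len(nrow(X)), function(i) {
    uv <- t(vapply(cams, function(P) project_points(P, X[i, , drop = FALSE])[1, 1:2],
                   numeric(2)))
    uv <- uv + matrix(rnorm(8), 4, 2)
    sqrt(sum((triangulate(cams, uv) - X[i, ])^2))
  }, numeric(1))
  expect_lt(sqrt(mean(errs^2)), 0.1)    # 1 px noise -> centimetre-level 3D error
})

test_that("subset enumeration covers every subset of size at least two", {
  cams <- paste0("c", 1:4)
  combos <- subset_combinations(cams)
  expect_length(combos, 11)             # C(4,2)+C(4,3)+C(4,4)
  expect_true(all(lengths(combos) >= 2))
  expect_equal(length(unique(vapply(combos, paste, "", collapse = "+"))), 11)
  expect_length(subset_combinations(paste0("c", 1:3)), 4)
  expect_error(subset_combinations(paste0("c", 1:9)), "8 cameras")
})

test_that("exhaustive selection excludes a camera with biased detections", {
  b <- clean_bundle()
  kp <- b$keypoints
  bias <- kp$camera_id == "cam03"
  kp$u[bias] <- kp$u[bias] + 20
  ch <- select_subset(kp, b$ground_truth$P_true)
  expect_s3_class(ch, "subset_choice")
  expect_false("cam03" %in% ch$cameras)
  expect_equal(nrow(ch$evaluated), 11)
  # on unbiased data the full set wins (ties go to the larger subset)
  ch0 <- select_subset(b$keypoints, b$ground_truth$P_true)
  expect_setequal(ch0$cameras, names(b$ground_truth$P_true))
  expect_lt(ch0$mean_error, 1e-8)
})

test_that("trial reconstruction records the number of contributing views", {
  b <- clean_bundle()
  poses <- reconstruct_trial(b$keypoints, b$ground_truth$P_true)
  expect_true(all(poses$n_views >= 2))
  expect_true(all(poses$n_views <= length(b$ground_truth$P_true)))
  # dropping one camera's detections reduces the view counts accordingly
  kp2 <- b$keypoints[b$keypoints$camera_id != "cam01", ]
  poses2 <- reconstruct_trial(kp2, b$ground_truth$P_true)
  expect_true(all(poses2$n_views <= 3))
})

test_that("the zero-phase filter passes constants and attenuates per the analytic response", {
  const <- rep(3.7, 80)
  expect_lt(max(abs(butter_filtfilt(const, 4, 10 / 12.5) - 3.7)), 1e-9)
  # the bilinear-transform Butterworth has squared magnitude
  # 1 / (1 + (tan(pi f / fs) / tan(pi fc / fs))^(2n)); two passes square it
  t <- seq(0, 4, by = 1 / 25)
  for (f in c(2, 8)) {
    x <- sin(2 * pi * f * t)
    y <- butter_filtfilt(x, 4, 10 / 12.5)
    core <- seq(20, length(t) - 20)
    gain <- sqrt(sum(y[core]^2) / sum(x[core]^2))
    ratio <- tan(pi * f / 25) / tan(pi * 10 / 25)
    expect_equal(gain, 1 / (1 + ratio^8), tolerance = 0.01)
  }
})

test_that("the filter is zero-phase: a symmetric pulse keeps its peak location", {
  x <- exp(-((1:101) - 51)^2 / 18)
  y <- butter_filtfilt(x, 4, 0.4)
  expect_equal(which.max(y), 51)
})

test_that("smoothing reduces noise while preserving the underlying trajectory", {
  fr <- 1:100
  truth <- 5 + 0.2 * fr + 2 * sin(2 * pi * fr / 50)
  set.seed(30)
  poses <- data.frame(frame = fr, keypoint = "nose",
                      x = truth + rnorm(100, sd = 0.05),
                      y = 0, z = 0, n_views = 2L)
  sm <- smooth_trajectories(poses, cutoff = 5, sample_rate = 25)
  rms_raw <- sqrt(mean((poses$x - truth)^2))
  rms_sm <- sqrt(mean((sm$x - truth)^2))
  # a 5 Hz low-pass keeps ~0.4 of the white-noise band, so the residual
  # amplitude should shrink towards sqrt(0.4) ~ 0.63 of the raw level
  expect_lt(rms_sm, 0.7 * rms_raw)
  expect_equal(sm$frame, poses$frame)
  expect_equal(sm$y, poses$y)
})

test_that("short gaps are bridged and long gaps split the filtered spans", {
  fr <- setdiff(1:60, c(20:22, 40:50))      # 3-frame gap and 11-frame gap
  poses <- data.frame(frame = fr, keypoint = "nose",
                      x = sin(2 * pi * fr / 30), y = 0, z = 0, n_views = 2L)
  sm <- smooth_trajectories(poses, cutoff = 8, sample_rate = 25, max_gap = 5)
  expect_identical(sm$frame, poses$frame)    # gaps stay gaps
  expect_false(anyNA(sm$x))
  # a constant trajectory survives gap handling exactly
  pc <- data.frame(frame = fr, keypoint = "nose", x = 2, y = 2, z = 2,
                   n_views = 2L)
  smc <- smooth_trajectories(pc, cutoff = 8, sample_rate = 25, max_gap = 5)
  expect_lt(max(abs(smc$x - 2)), 1e-9)
})

test_that("smoothing rejects a cutoff at or above Nyquist", {
  poses <- data.frame(frame = 1:10, keypoint = "nose", x = 1, y = 1, z = 1,
                      n_views = 2L)
  expect_error(smooth_trajectories(poses, cutoff = 13, sample_rate = 25),
               "Nyquist")
})
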