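# Evaluation metrics: segment-length variation, PCK/mAP/MPJPE, run-level
# statistics and unit conversions.

toy_poses <- function(lens) {
  # one segment (left_hip -> left_knee) with prescribed per-frame lengths
  do.call(rbind, lapply(seq_along(lens), function(f)
    data.frame(frame = f, keypoint = c("left_hip", "left_knee"),
               x = c(0, 0), y = c(0, 0), z = c(0, -lens[f]))))
}

test_that("segment lengths and SDs match hand calculation", {
  rep <- segment_lengths(toy_poses(c(0.30, 0.32, 0.34)))
  row <- rep$per_segment[rep$per_segment$segment == "thigh_L", ]
  expect_equal(row$n_frames, 3L)
  expect_equal(row$mean_m, 0.32)
  expect_equal(row$sd_m, 0.02)         # sample SD of 0.30, 0.32, 0.34
  expect_equal(sort(rep$lengths$length_m[rep$lengths$segment == "thigh_L"]),
               c(0.30, 0.32, 0.34))
  # other segments have no reconstructed endpoints
  expect_true(all(is.na(rep$per_segment$sd_m[rep$per_segment$segment != "thigh_L"])))
})

test_that("frames missing one endpoint are excluded from a segment's lengths", {
  poses <- toy_poses(c(0.30, 0.30, 0.30))
  poses <- poses[!(poses$frame == 2 & poses$keypoint == "left_knee"), ]
  rep <- segment_lengths(poses)
  expect_equal(rep$per_segment$n_frames[rep$per_segment$segment == "thigh_L"], 2L)
})

test_that("identical prediction and truth give perfect 2D metrics", {
  b <- clean_bundle()
  kp <- b$keypoints
  m <- metrics_2d(kp, kp)
  expect_equal(m$pck, 1)
  expect_equal(m$map, 1)
  expect_equal(m$mpjpe_px, 0)
  expect_equal(m$n_matched, nrow(kp))
})

test_that("PCK counts displaced keypoints against the box-fraction radius", {
  truth <- data.frame(camera_id = "a", frame = 1, keypoint = letters[1:4],
                      u = c(0, 100, 0, 100), v = c(0, 0, 200, 200))
  bbox <- data.frame(camera_id = "a", frame = 1, x_min = 0, y_min = 0,
                     x_max = 100, y_max = 200)
  pred <- truth
  pred$u <- pred$u + c(0, 0, 9, 11)     # radius = 0.05 * 200 = 10 px
  m <- metrics_2d(pred, truth, bbox = bbox)
  expect_equal(m$pck, 0.75)
  expect_equal(m$mpjpe_px, mean(c(0, 0, 9, 11)))
})

test_that("OKS mAP follows the closed-form keypoint similarity", {
  truth <- data.frame(camera_id = "a", frame = 1, keypoint = "nose",
                      u = 50, v = 50)
  bbox <- data.frame(camera_id = "a", frame = 1, x_min = 0, y_min = 0,
                     x_max = 100, y_max = 100)
  sig <- c(nose = 0.1)
  d <- 20
  pred <- transform(truth, u = u + d)
  oks <- exp(-d^2 / (2 * 100 * 100 * (2 * 0.1)^2))   # = exp(-0.5) ~ 0.6065
  m <- metrics_2d(pred, truth, bbox = bbox, oks_sigmas = sig)
  thr <- seq(0.50, 0.95, by = 0.05)
  expect_equal(m$map, mean(oks >= thr))       # 0.50, 0.55, 0.60 pass -> 0.3
  expect_equal(m$map, 0.3)
})

test_that("uniformly half-displaced keypoints give PCK one half", {
  truth <- data.frame(camera_id = "a", frame = rep(1:10, each = 2),
                      keypoint = rep(c("p", "q"), 10),
                      u = rep(c(0, 100), 10), v = 0)
  bbox <- data.frame(camera_id = "a", frame = 1:10, x_min = 0, y_min = 0,
                     x_max = 100, y_max = 100)
  pred <- truth
  half <- pred$keypoint == "q"
  pred$u[half] <- pred$u[half] + 50
  m <- metrics_2d(pred, truth, bbox = bbox)
  expect_equal(m$pck, 0.5)
  expect_equal(m$per_keypoint$pck[m$per_keypoint$keypoint == "p"], 1)
  expect_equal(m$per_keypoint$pck[m$per_keypoint$keypoint == "q"], 0)
})

test_that("disjoint prediction and truth raise an informative error", {
  a <- data.frame(camera_id = "a", frame = 1, keypoint = "p", u = 0, v = 0)
  b <- data.frame(camera_id = "b", frame = 1, keypoint = "p", u = 0, v = 0)
  expect_error(metrics_2d(a, b), "no matched")
})

test_that("run-level summary reproduces the closed-form t interval", {
  set.seed(40)
  v <- rnorm(12, mean = 5)
  values <- rbind(data.frame(run = 1:12, method = "A", value = v),
                  data.frame(run = 1:12, method = "B", value = v + 1))
  rc <- run_level_comparison(values)
  a <- rc$summary[rc$summary$method == "A", ]
  expect_equal(a$mean, mean(v))
  expect_equal(a$ci_halfwidth, qt(0.975, 11) * sd(v) / sqrt(12))
  # quadrupling the run count halves the CI halfwidth (same spread)
  v4 <- rep(v, 4)
  values4 <- rbind(data.frame(run = 1:48, method = "A", value = v4),
                   data.frame(run = 1:48, method = "B", value = v4 + 1))
  a4 <- run_level_comparison(values4)$summary
  ratio <- a4$ci_halfwidth[1] / a$ci_halfwidth
  # sample SD of the 4x-replicated data is sqrt(4 SS / 47) vs sqrt(SS / 11)
  expect_equal(ratio,
               (qt(0.975, 47) / qt(0.975, 11)) * sqrt(4 * 11 / 47) / 2,
               tolerance = 1e-10)
})

test_that("the paired Wilcoxon test matches its exact small-sample p-value", {
  # differences 0.1 .. 1.0 are distinct (equal differences would tie and
  # force the normal approximation) and share one sign: exact p = 2 / 2^10
  values <- rbind(data.frame(run = 1:10, method = "A", value = 1:10),
                  data.frame(run = 1:10, method = "B",
                             value = (1:10) + (1:10) / 10))
  rc <- run_level_comparison(values)
  expect_equal(rc$tests$p_value, 2 / 1024)
  expect_equal(rc$tests$n_nonzero, 10L)
  # identical methods: all differences zero, p = 1
  same <- rbind(data.frame(run = 1:10, method = "A", value = 1:10),
                data.frame(run = 1:10, method = "B", value = 1:10))
  expect_equal(run_level_comparison(same)$tests$p_value, 1)
})

test_that("unpaired or single-run inputs are rejected", {
  bad <- rbind(data.frame(run = 1:3, method = "A", value = 1),
               data.frame(run = 1:2, method = "B", value = 1))
  expect_error(run_level_comparison(bad), "unpaired")
  one <- rbind(data.frame(run = 1, method = "A", value = 1),
               data.frame(run = 1, method = "B", value = 2))
  expect_error(run_level_comparison(one), "2 runs")
})

test_that("pixel-to-world conversion matches the similar-triangles arithmetic", {
  expect_equal(pixel_to_world(4.1, 1.5, 1080), 4.1 * 1.5 / 1080 * 100)
  expect_equal(pixel_to_world(0), 0)
  expect_equal(pixel_to_world(1080, 1.5, 1080), 150)
  expect_error(pixel_to_world(-1), "err")
  expect_error(pixel_to_world(1, 0), "> 0")
})

test_that("reference-point agreement reports distances and outliers", {
  auto <- data.frame(camera_id = "a", frame = 1:4, ref_id = 1L,
                     cx = c(0, 0, 0, 0), cy = 0)
  manual <- auto
  manual$cx <- c(3, 4, 0, 60)
  ag <- refpoint_agreement(auto, manual, outlier_px = 50)
  expect_equal(ag$mean_px, mean(c(3, 4, 0, 60)))
  expect_equal(nrow(ag$outliers), 1)
  expect_equal(ag$outliers$frame, 4L)
  expect_equal(ag$n_matched, 4L)
})
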