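# Evaluation metrics: 3D reconstruction consistency via anatomical
# segment-length variation, 2D keypoint accuracy (PCK, OKS-based mAP, MPJPE),
# run-level statistics (t-based confidence intervals, paired Wilcoxon
# signed-rank tests), reference-point agreement with manual annotation, and
# the pixel-to-world scale conversions used in reporting.

#' Segment-length report of a reconstructed pose sequence
#'
#' Because true anatomical segment lengths are constant, the standard
#' deviation of each reconstructed segment's length across frames measures 3D
#' reconstruction consistency independently of annotation error. A frame
#' contributes only when both segment endpoints were reconstructed. SDs use
#' the sample (n-1) formula; the overall value is the arithmetic mean of the
#' per-segment SDs.
#'
#' @param poses data.frame (frame, keypoint, x, y, z).
#' @param skeleton a [skeleton_model()].
#' @return list of class `segment_report`: `per_segment` data.frame (segment,
#'   n_frames, mean_m, sd_m), `lengths` (long data.frame of per-frame
#'   lengths), and `overall_sd_m`.
#' @export
segment_lengths <- function(poses, skeleton = skeleton_model()) {
  segs <- skeleton$segments
  keyp <- paste(poses$frame, poses$keypoint, sep = "\r")
  rows <- stats::setNames(seq_len(nrow(poses)), keyp)
  frames <- sort(unique(poses$frame))
  per <- vector("list", nrow(segs))
  lens_long <- vector("list", nrow(segs))
  for (i in seq_len(nrow(segs))) {
    ia <- rows[paste(frames, segs$from[i], sep = "\r")]
    ib <- rows[paste(frames, segs$to[i], sep = "\r")]
    ok <- !is.na(ia) & !is.na(ib)
    L <- sqrt((poses$x[ia[ok]] - poses$x[ib[ok]])^2 +
                (poses$y[ia[ok]] - poses$y[ib[ok]])^2 +
                (poses$z[ia[ok]] - poses$z[ib[ok]])^2)
    lens_long[[i]] <- data.frame(segment = rep(segs$segment[i], sum(ok)),
                                 frame = frames[ok], length_m = L)
    per[[i]] <- data.frame(
      segment = segs$segment[i], n_frames = sum(ok),
      mean_m = if (sum(ok)) mean(L) else NA_real_,
      sd_m = if (sum(ok) >= 2) stats::sd(L) else NA_real_)
  }
  per <- do.call(rbind, per)
  structure(list(per_segment = per,
                 lengths = do.call(rbind, lens_long),
                 overall_sd_m = mean(per$sd_m, na.rm = FALSE)),
            class = "segment_report")
}

#' @export
print.segment_report <- function(x, ...) {
  df <- x$per_segment
  df$sd_cm <- 100 * df$sd_m
  print(df[, c("segment", "n_frames", "mean_m", "sd_cm")], row.names = FALSE)
  cat(sprintf("overall segment-length SD: %.2f cm\n", 100 * x$overall_sd_m))
  invisible(x)
}

# Per-keypoint OKS fall-off constants: standard person-keypoint sigmas for the
# anatomical points; sport-specific endpoints (skis, poles) and other
# extremities reuse the ankle value.
default_oks_sigmas <- function(keypoints) {
  base <- c(
    nose = 0.026, left_eye = 0.025, right_eye = 0.025,
    left_ear = 0.035, right_ear = 0.035,
    left_shoulder = 0.079, right_shoulder = 0.079,
    left_elbow = 0.072, right_elbow = 0.072,
    left_wrist = 0.062, right_wrist = 0.062,
    left_hip = 0.107, right_hip = 0.107,
    left_knee = 0.087, right_knee = 0.087,
    left_ankle = 0.089, right_ankle = 0.089,
    head = 0.035, neck = 0.079, pelvis = 0.107)
  s <- base[keypoints]
  s[is.na(s)] <- 0.089
  stats::setNames(s, keypoints)
}

#' 2D keypoint metrics: PCK, OKS-based mAP, MPJPE
#'
#' Predictions and ground truth are matched by (camera_id, frame, keypoint);
#' each camera-frame is one instance whose reference scale is its ground-truth
#' bounding box. PCK counts keypoints within `pck_fraction` of the larger box
#' side; MPJPE is the mean Euclidean pixel error over matched keypoints; mAP
#' averages, over OKS thresholds 0.50 to 0.95 in steps of 0.05, the fraction
#' of instances whose object-keypoint-similarity reaches the threshold.
#'
#' @param pred predicted keypoints (camera_id, frame, keypoint, u, v).
#' @param truth ground-truth keypoints, same columns.
#' @param bbox per-instance reference boxes (camera_id, frame, x_min, y_min,
#'   x_max, y_max); defaults to the ground-truth keypoint extent per instance.
#' @param pck_fraction PCK radius as a fraction of max(box width, height).
#' @param oks_sigmas named per-keypoint sigma vector; defaults per
#'   `default_oks_sigmas()`.
#' @return list of class `metrics_2d`: `pck`, `map`, `mpjpe_px`,
#'   `per_keypoint` (data.frame keypoint, n, pck, mpjpe_px), `n_matched`.
#' @export
metrics_2d <- function(pred, truth, bbox = NULL, pck_fraction = 0.05,
                       oks_sigmas = NULL) {
  key <- function(d) paste(d$camera_id, d$frame, d$keypoint, sep = "\r")
  m <- match(key(pred), key(truth))
  ok <- !is.na(m)
  if (!any(ok)) stop("no matched keypoint instances between pred and truth")
  p <- pred[ok, , drop = FALSE]
  t2 <- truth[m[ok], , drop = FALSE]
  dist <- sqrt((p$u - t2$u)^2 + (p$v - t2$v)^2)

  inst <- paste(p$camera_id, p$frame, sep = "\r")
  if (is.null(bbox)) {
    tin <- paste(truth$camera_id, truth$frame, sep = "\r")
    bb <- do.call(rbind, lapply(split(seq_len(nrow(truth)), tin), function(i)
      data.frame(x_min = min(truth$u[i]), y_min = min(truth$v[i]),
                 x_max = max(truth$u[i]), y_max = max(truth$v[i]))))
    bb$inst <- names(split(seq_len(nrow(truth)), tin))
  } else {
    bb <- bbox
    bb$inst <- paste(bb$camera_id, bb$frame, sep = "\r")
  }
  bi <- match(inst, bb$inst)
  bw <- bb$x_max[bi] - bb$x_min[bi]
  bh <- bb$y_max[bi] - bb$y_min[bi]
  scale_px <- pmax(bw, bh)
  area <- pmax(bw * bh, .Machine$double.eps)

  pck_hit <- dist <= pck_fraction * scale_px
  if (is.null(oks_sigmas)) oks_sigmas <- default_oks_sigmas(unique(p$keypoint))
  sig <- oks_sigmas[p$keypoint]
  sig[is.na(sig)] <- 0.089
  ks <- exp(-dist^2 / (2 * area * (2 * sig)^2))
  oks_inst <- vapply(split(ks, inst), mean, numeric(1))
  thr <- seq(0.50, 0.95, by = 0.05)
  ap <- vapply(thr, function(T) mean(oks_inst >= T), numeric(1))

  perkp <- do.call(rbind, lapply(split(seq_along(dist), p$keypoint), function(i)
    data.frame(keypoint = p$keypoint[i[1]], n = length(i),
               pck = mean(pck_hit[i]), mpjpe_px = mean(dist[i]))))
  rownames(perkp) <- NULL
  structure(list(pck = mean(pck_hit), map = mean(ap), mpjpe_px = mean(dist),
                 per_keypoint = perkp, n_matched = length(dist)),
            class = "metrics_2d")
}

#' @export
print.metrics_2d <- function(x, ...) {
  cat(sprintf("2D keypoint metrics over %d matches: PCK %.3f, mAP %.3f, MPJPE %.2f px\n",
              x$n_matched, x$pck, x$map, x$mpjpe_px))
  invisible(x)
}

#' Run-level comparison of reconstruction methods
#'
#' Summarizes a per-run, per-method metric (e.g. overall segment-length SD or
#' mean segment length) by its run-wise mean and t-based 95% confidence
#' interval per method, and compares method pairs with the paired Wilcoxon
#' signed-rank test on run-matched values. Zero differences are discarded
#' before ranking (standard convention); when every difference is zero the
#' p-value is 1.
#'
#' @param values data.frame with columns `run`, `method`, `value`; every
#'   method must cover the same runs (paired design).
#' @param conf confidence level (default 0.95).
#' @return list of class `run_comparison`: `summary` (method, n_runs, mean,
#'   ci_lo, ci_hi, ci_halfwidth) and `tests` (method_a, method_b, p_value,
#'   n_nonzero).
#' @export
run_level_comparison <- function(values, conf = 0.95) {
  stopifnot(all(c("run", "method", "value") %in% names(values)))
  methods <- sort(unique(values$method))
  runs <- sort(unique(values$run))
  wide <- matrix(NA_real_, length(runs), length(methods),
                 dimnames = list(runs, methods))
  wide[cbind(match(values$run, runs), match(values$method, methods))] <- values$value
  if (anyNA(wide)) stop("unpaired runs: every method must provide every run")
  if (length(runs) < 2) stop("need at least 2 runs")
  alpha <- 1 - conf
  summ <- do.call(rbind, lapply(methods, function(mth) {
    v <- wide[, mth]
    n <- length(v)
    hw <- stats::qt(1 - alpha / 2, n - 1) * stats::sd(v) / sqrt(n)
    data.frame(method = mth, n_runs = n, mean = mean(v),
               ci_lo = mean(v) - hw, ci_hi = mean(v) + hw, ci_halfwidth = hw)
  }))
  pairs <- utils::combn(methods, 2, simplify = FALSE)
  tests <- do.call(rbind, lapply(pairs, function(pr) {
    d <- wide[, pr[1]] - wide[, pr[2]]
    nz <- d[d != 0]
    p <- if (!length(nz)) 1 else
      suppressWarnings(stats::wilcox.test(nz, exact = length(nz) < 50)$p.value)
    data.frame(method_a = pr[1], method_b = pr[2], p_value = p,
               n_nonzero = length(nz))
  }))
  structure(list(summary = summ, tests = tests), class = "run_comparison")
}

#' @export
print.run_comparison <- function(x, ...) {
  print(x$summary, row.names = FALSE)
  print(x$tests, row.names = FALSE)
  invisible(x)
}

#' Convert a pixel error to real-world centimetres
#'
#' Uses the apparent size of a reference object (the athlete): an error of
#' `err` pixels corresponds to `err * object_height / object_height_px`
#' metres, returned in centimetres. E.g. 4.1 px at 1.5 m / 1080 px is about
#' 0.57 cm.
#'
#' @param err pixel error (>= 0).
#' @param object_height physical object height, metres (> 0).
#' @param object_height_px apparent object height, pixels (> 0).
#' @return error in centimetres.
#' @export
pixel_to_world <- function(err, object_height = 1.5, object_height_px = 1080) {
  if (object_height <= 0 || object_height_px <= 0)
    stop("object height and pixel height must be > 0")
  if (any(err < 0)) stop("err must be >= 0")
  err * object_height / object_height_px * 100
}

#' Agreement between automatic and manually annotated reference points
#'
#' Matches detections by (camera_id, frame, ref_id) and reports the mean
#' Euclidean pixel distance overall and per camera, plus the detections whose
#' deviation exceeds `outlier_px` (candidates for visual inspection).
#'
#' @param auto,manual data.frames with camera_id, frame, ref_id, cx, cy.
#' @param outlier_px outlier listing threshold, pixels (default 50).
#' @return list of class `refpoint_agreement`: `mean_px`, `per_camera`
#'   (camera_id, n, mean_px), `outliers` (matched rows above threshold),
#'   `n_matched`.
#' @export
refpoint_agreement <- function(auto, manual, outlier_px = 50) {
  key <- function(d) paste(d$camera_id, d$frame, d$ref_id, sep = "\r")
  m <- match(key(auto), key(manual))
  ok <- !is.na(m)
  if (!any(ok)) stop("no detections matched between automatic and manual sets")
  a <- auto[ok, , drop = FALSE]
  b <- manual[m[ok], , drop = FALSE]
  d <- sqrt((a$cx - b$cx)^2 + (a$cy - b$cy)^2)
  per <- do.call(rbind, lapply(split(seq_along(d), a$camera_id), function(i)
    data.frame(camera_id = a$camera_id[i[1]], n = length(i), mean_px = mean(d[i]))))
  rownames(per) <- NULL
  out <- a[d > outlier_px, c("camera_id", "frame", "ref_id"), drop = FALSE]
  out$distance_px <- d[d > outlier_px]
  structure(list(mean_px = mean(d), per_camera = per, outliers = out,
                 n_matched = length(d)),
            class = "refpoint_agreement")
}

#' @export
print.refpoint_agreement <- function(x, ...) {
  cat(sprintf("reference-point agreement: mean %.2f px over %d matches; %d outliers\n",
              x$mean_px, x$n_matched, nrow(x$outliers)))
  print(x$per_camera, row.names = FALSE)
  invisible(x)
}
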