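# End-to-end pipeline: synchronization -> reference-point association ->
# frame-wise calibration -> subset selection -> triangulation -> smoothing ->
# segment-length evaluation.

#' Run the full reconstruction pipeline on a trial bundle
#'
#' @param bundle a `trial_bundle` from [generate_scene()] (or assembled from
#'   files via the io helpers).
#' @param drop_tracks optional list of drop tracks from [render_drop_event()];
#'   when supplied, per-camera offsets are estimated from them and every
#'   detection stream is resampled onto the reference camera's timeline.
#'   When `NULL` the streams are assumed synchronized.
#' @param select_cameras `"all"` (use every calibrated camera), `"optimal"`
#'   (exhaustive subset search), or a character vector naming a fixed subset.
#' @param smooth logical: apply the zero-phase Butterworth low-pass.
#' @param cutoff,filter_order smoothing parameters (Hz / filter order).
#' @param k,min_points,improvement calibration parameters, see
#'   [calibrate_trial()].
#' @param overlap_threshold IoU discard threshold for cube detections.
#' @return list of class `pipeline_result`: `sync` (or NULL), `refs`
#'   (associated detections), `calibration` (matrices + report), `subset`,
#'   `poses` (possibly smoothed 3D keypoints), `segments` (segment report).
#' @export
run_pipeline <- function(bundle, drop_tracks = NULL,
                         select_cameras = "all", smooth = TRUE,
                         cutoff = 10, filter_order = 4,
                         k = 15, min_points = 6, improvement = 0.05,
                         overlap_threshold = 0.5) {
  boxes <- bundle$boxes
  idents <- bundle$identifications
  kps <- bundle$keypoints
  sbox <- bundle$skier_bbox
  fps <- bundle$config$frame_rate

  sync <- NULL
  if (!is.null(drop_tracks)) {
    events <- vapply(drop_tracks, fit_sync_event, numeric(1))
    sync <- compute_offsets(events)
    resample_cam <- function(d, ...) {
      pieces <- lapply(split(d, d$camera_id), function(dc) {
        off <- sync$offsets[[dc$camera_id[1]]]
        resample_stream(dc, off, ...)
      })
      out <- do.call(rbind, pieces)
      rownames(out) <- NULL
      out
    }
    boxes <- resample_cam(boxes)
    idents <- resample_cam(idents, id_cols = c("camera_id", "ref_id"),
                           value_cols = c("mx", "my"), conf_col = character(0))
    kps <- resample_cam(kps)
    if (!is.null(sbox))
      sbox <- resample_cam(sbox, id_cols = "camera_id",
                           value_cols = intersect(c("x_min", "y_min", "x_max",
                                                    "y_max", "cx", "cy"),
                                                  names(sbox)),
                           conf_col = character(0))
  }

  refs <- do.call(rbind, lapply(split(boxes, boxes$camera_id), function(b) {
    associate_refpoints(b, idents[idents$camera_id == b$camera_id[1], , drop = FALSE],
                        overlap_threshold = overlap_threshold)
  }))
  rownames(refs) <- NULL

  calib <- calibrate_trial(refs, bundle$surveyed, sbox,
                           k = k, min_points = min_points,
                           improvement = improvement)

  subset <- NULL
  cams <- if (identical(select_cameras, "optimal")) {
    subset <- select_subset(kps, calib$matrices)
    subset$cameras
  } else if (identical(select_cameras, "all")) {
    names(calib$matrices)
  } else select_cameras

  poses <- reconstruct_trial(kps, calib$matrices, cams)
  if (smooth && nrow(poses))
    poses <- smooth_trajectories(poses, cutoff = cutoff, sample_rate = fps,
                                 order = filter_order)
  segs <- if (nrow(poses)) segment_lengths(poses) else NULL

  structure(list(sync = sync, refs = refs, calibration = calib,
                 subset = subset, cameras = cams, poses = poses,
                 segments = segs),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  rep <- x$calibration$report
  cat(sprintf("pipeline_result: %d/%d camera-frames calibrated, cameras %s\n",
              sum(rep$status == "calibrated"), nrow(rep),
              paste(x$cameras, collapse = "+")))
  if (!is.null(x$segments))
    cat(sprintf("overall segment-length SD: %.2f cm\n",
                100 * x$segments$overall_sd_m))
  invisible(x)
}
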