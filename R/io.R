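# On-disk formats. All files are plain text and versioned:
#   surveyed points   CSV   ref_id,x,y,z (metres)
#   detection streams JSON-lines, header line {"schema":"ptzmocap/detections-v1"},
#                     then one record per camera-frame
#   drop tracks       JSON-lines, header {"schema":"ptzmocap/droptracks-v1"}
#   ground truth      JSON   {"schema":"ptzmocap/groundtruth-v1", ...}
#   calibration       JSON   {"schema":"ptzmocap/calibration-v1", ...}
#   trajectories      CSV (long form) or JSON
#   configuration     YAML, archived in resolved form next to outputs

DETECTIONS_SCHEMA <- "ptzmocap/detections-v1"
DROPTRACKS_SCHEMA <- "ptzmocap/droptracks-v1"
GROUNDTRUTH_SCHEMA <- "ptzmocap/groundtruth-v1"
CALIBRATION_SCHEMA <- "ptzmocap/calibration-v1"

#' Read a surveyed reference-point table
#'
#' @param path CSV file with header `ref_id,x,y,z` (coordinates in metres).
#' @return validated data.frame.
#' @export
read_surveyed_points <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("ref_id", "x", "y", "z")
  if (!identical(names(df)[seq_along(need)], need))
    stop("surveyed-point file must have header ref_id,x,y,z: ", path)
  for (cc in c("x", "y", "z")) {
    bad <- which(!is.finite(df[[cc]]))
    if (length(bad))
      stop(sprintf("malformed surveyed point at line %d (column %s)", bad[1] + 1, cc))
  }
  if (anyDuplicated(df$ref_id)) {
    d <- df$ref_id[duplicated(df$ref_id)][1]
    stop("duplicate ref_id in surveyed table: ", d)
  }
  df$ref_id <- as.integer(df$ref_id)
  df
}

#' Write a surveyed reference-point table
#' @param points data.frame with ref_id, x, y, z.
#' @param path output CSV path.
#' @export
write_surveyed_points <- function(points, path) {
  utils::write.csv(points[, c("ref_id", "x", "y", "z")], path, row.names = FALSE)
  invisible(path)
}

df_or_empty <- function(x, cols) {
  if (is.null(x) || !length(x)) {
    out <- as.data.frame(stats::setNames(rep(list(numeric(0)), length(cols)), cols))
    return(out)
  }
  as.data.frame(x)
}

#' Write detection streams as JSON-lines
#'
#' One record per camera-frame carrying that frame's reference boxes,
#' fiducial identifications, skier keypoints and skier bounding box. The
#' first line is a schema header.
#'
#' @param streams list with data.frames `boxes`, `identifications`,
#'   `keypoints`, and optionally `skier_bbox` (as in a `trial_bundle`).
#' @param path output path.
#' @export
write_detections <- function(streams, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(jsonlite::toJSON(list(schema = DETECTIONS_SCHEMA), auto_unbox = TRUE), con)
  keyframes <- unique(rbind(
    streams$boxes[c("camera_id", "frame")],
    streams$keypoints[c("camera_id", "frame")]))
  keyframes <- keyframes[order(keyframes$camera_id, keyframes$frame), ]
  pick <- function(d, cid, f) {
    out <- d[d$camera_id == cid & d$frame == f,
             setdiff(names(d), c("camera_id", "frame")), drop = FALSE]
    rownames(out) <- NULL  # non-default rownames would serialize as "_row"
    out
  }
  for (i in seq_len(nrow(keyframes))) {
    cid <- keyframes$camera_id[i]; f <- keyframes$frame[i]
    rec <- list(camera_id = cid, frame = f,
                boxes = pick(streams$boxes, cid, f),
                identifications = if (!is.null(streams$identifications) &&
                                        nrow(streams$identifications))
                  pick(streams$identifications, cid, f) else data.frame(),
                keypoints = pick(streams$keypoints, cid, f))
    if (!is.null(streams$skier_bbox) && nrow(streams$skier_bbox)) {
      sb <- pick(streams$skier_bbox, cid, f)
      if (nrow(sb)) rec$skier_bbox <- as.list(sb[1, ])
    }
    writeLines(jsonlite::toJSON(rec, dataframe = "columns", auto_unbox = TRUE,
                                digits = NA, na = "null"), con)
  }
  invisible(path)
}

#' Read detection streams written by [write_detections()]
#'
#' @param path JSON-lines path.
#' @return list with `boxes`, `identifications`, `keypoints`, `skier_bbox`.
#' @export
read_detections <- function(path) {
  lines <- readLines(path)
  if (!length(lines)) stop("empty detections file: ", path)
  hdr <- jsonlite::fromJSON(lines[1])
  if (!identical(hdr$schema, DETECTIONS_SCHEMA))
    stop("unknown detections schema: ", hdr$schema %||% "<missing>")
  boxes <- list(); idents <- list(); kps <- list(); sbox <- list()
  for (k in seq_along(lines[-1])) {
    rec <- jsonlite::fromJSON(lines[k + 1])
    for (fld in c("camera_id", "frame"))
      if (is.null(rec[[fld]]))
        stop(sprintf("detections record %d: missing required field '%s'", k, fld))
    att <- function(d) {
      d <- as.data.frame(d)
      if (!nrow(d)) return(NULL)
      cbind(data.frame(camera_id = rec$camera_id, frame = rec$frame), d)
    }
    boxes[[k]] <- att(rec$boxes)
    idents[[k]] <- att(rec$identifications)
    kps[[k]] <- att(rec$keypoints)
    if (!is.null(rec$skier_bbox)) sbox[[k]] <- att(as.data.frame(rec$skier_bbox))
  }
  comb <- function(l) {
    l <- Filter(Negate(is.null), l)
    if (!length(l)) return(data.frame())
    out <- do.call(rbind, l)
    rownames(out) <- NULL
    out
  }
  list(boxes = comb(boxes), identifications = comb(idents),
       keypoints = comb(kps), skier_bbox = comb(sbox))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write drop-cube synchronization tracks
#' @param tracks list of drop-track data.frames from [render_drop_event()].
#' @param path output JSON-lines path.
#' @export
write_drop_tracks <- function(tracks, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(jsonlite::toJSON(list(schema = DROPTRACKS_SCHEMA), auto_unbox = TRUE), con)
  for (tr in tracks) {
    writeLines(jsonlite::toJSON(list(camera_id = tr$camera_id[1],
                                     frame = tr$frame, y_px = tr$y_px),
                                auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}

#' Read drop-cube synchronization tracks
#' @param path JSON-lines path from [write_drop_tracks()].
#' @return named list of drop-track data.frames.
#' @export
read_drop_tracks <- function(path) {
  lines <- readLines(path)
  hdr <- jsonlite::fromJSON(lines[1])
  if (!identical(hdr$schema, DROPTRACKS_SCHEMA))
    stop("unknown drop-track schema: ", hdr$schema %||% "<missing>")
  tracks <- lapply(lines[-1], function(l) {
    rec <- jsonlite::fromJSON(l)
    data.frame(camera_id = rec$camera_id, frame = rec$frame, y_px = rec$y_px)
  })
  stats::setNames(tracks, vapply(tracks, function(t) t$camera_id[1], ""))
}

#' Write synthetic ground truth as JSON
#' @param gt the `ground_truth` element of a `trial_bundle`.
#' @param path output path.
#' @export
write_ground_truth <- function(gt, path) {
  obj <- list(schema = GROUNDTRUTH_SCHEMA,
              keypoints_3d = gt$keypoints_3d,
              centroid_3d = gt$centroid_3d,
              frame_offsets = as.list(gt$frame_offsets),
              segment_lengths = as.list(gt$segment_lengths))
  jsonlite::write_json(obj, path, dataframe = "columns", auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read synthetic ground truth
#' @param path JSON path from [write_ground_truth()].
#' @return list with keypoints_3d, centroid_3d, frame_offsets, segment_lengths.
#' @export
read_ground_truth <- function(path) {
  obj <- jsonlite::fromJSON(path)
  if (!identical(obj$schema, GROUNDTRUTH_SCHEMA))
    stop("unknown ground-truth schema: ", obj$schema %||% "<missing>")
  obj$keypoints_3d <- as.data.frame(obj$keypoints_3d)
  obj$centroid_3d <- as.data.frame(obj$centroid_3d)
  obj$frame_offsets <- unlist(obj$frame_offsets)
  obj$segment_lengths <- unlist(obj$segment_lengths)
  obj
}

#' Write calibration matrices and report as JSON
#' @param calib result of [calibrate_trial()].
#' @param path output path.
#' @export
write_calibration <- function(calib, path) {
  cams <- lapply(calib$matrices, function(mats) {
    frames <- which(!vapply(mats, is.null, logical(1)))
    list(frames = frames,
         matrices = lapply(frames, function(f) unclass(mats[[f]])))
  })
  jsonlite::write_json(list(schema = CALIBRATION_SCHEMA, cameras = cams,
                            report = calib$report),
                       path, dataframe = "columns", auto_unbox = TRUE,
                       digits = NA, matrix = "rowmajor", na = "null")
  invisible(path)
}

#' Read calibration matrices and report
#' @param path JSON path from [write_calibration()].
#' @return list with `matrices` and `report` as in [calibrate_trial()].
#' @export
read_calibration <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyMatrix = TRUE)
  if (!identical(obj$schema, CALIBRATION_SCHEMA))
    stop("unknown calibration schema: ", obj$schema %||% "<missing>")
  matrices <- lapply(obj$cameras, function(cc) {
    frames <- unlist(cc$frames)
    if (!length(frames)) return(list())
    mm <- cc$matrices
    # equal-shaped matrices simplify to an (n x 3 x 4) array, otherwise a list
    get_mat <- function(i) {
      if (is.array(mm) && length(dim(mm)) == 3) matrix(mm[i, , ], 3, 4)
      else matrix(as.numeric(mm[[i]]), 3, 4)
    }
    mats <- vector("list", max(frames))
    for (i in seq_along(frames)) mats[[frames[i]]] <- get_mat(i)
    mats
  })
  list(matrices = matrices, report = as.data.frame(obj$report))
}

#' Export reconstructed trajectories
#'
#' Long-form export: one row per frame and reconstructed keypoint with world
#' coordinates in metres and the number of contributing views. Missing
#' (gap) keypoints are simply absent rows.
#'
#' @param poses data.frame from [reconstruct_trial()].
#' @param path output path.
#' @param format "csv" or "json".
#' @export
export_trajectories <- function(poses, path, format = c("csv", "json")) {
  format <- match.arg(format)
  cols <- c("frame", "keypoint", "x", "y", "z", "n_views")
  if (format == "csv") utils::write.csv(poses[, cols], path, row.names = FALSE)
  else jsonlite::write_json(poses[, cols], path, dataframe = "columns",
                            auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Import trajectories written by [export_trajectories()]
#' @param path file path.
#' @param format "csv" or "json".
#' @return poses data.frame.
#' @export
import_trajectories <- function(path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (format == "csv") utils::read.csv(path, stringsAsFactors = FALSE)
  else as.data.frame(jsonlite::fromJSON(path))
}

#' Default pipeline configuration
#'
#' All stage parameters with their standard values: IoU overlap threshold 0.5,
#' 15 nearest reference points, 6-point calibration floor, 5% outlier-rejection
#' improvement threshold, 10 Hz fourth-order zero-phase low-pass at 25 Hz
#' capture, and a 0.05 PCK fraction.
#'
#' @param ... overrides of individual fields.
#' @return named list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    overlap_threshold = 0.5,
    nearest_k = 15,
    min_points = 6,
    improvement = 0.05,
    cutoff_hz = 10,
    filter_order = 4,
    frame_rate = 25,
    pck_fraction = 0.05,
    subset_size_cap = 8,
    select_cameras = "all",
    smooth = TRUE,
    sync_warn_threshold = 0.2,
    seed = 1L,
    scene = list()
  )
  ov <- list(...)
  bad <- setdiff(names(ov), names(cfg))
  if (length(bad)) stop("unknown configuration field(s): ", paste(bad, collapse = ", "))
  cfg[names(ov)] <- ov
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML (with full defaulting)
#' @param path YAML path, or NULL for pure defaults.
#' @return `pipeline_config` list.
#' @export
read_config <- function(path = NULL) {
  if (is.null(path)) return(pipeline_config())
  ov <- yaml::read_yaml(path)
  do.call(pipeline_config, ov)
}

#' Write the resolved configuration next to the outputs
#' @param config `pipeline_config` list.
#' @param path output YAML path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
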