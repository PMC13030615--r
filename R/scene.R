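# Synthetic ski-slope scene generator: surveyed fiducial-cube field, articulated
# skier descending the fall line, and 2-8 tracking pan-tilt-zoom cameras with
# known (ground-truth) projection matrices. Produces the same detection streams
# a real localization/identification front-end would: reference-cube bounding
# boxes, fiducial identifications, skier keypoints, and drop-cube sync tracks.

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Scene configuration
#'
#' Bundles every parameter of the synthetic capture: geometry of the sloped
#' corridor, number of surveyed reference cubes and cameras, frame rate and
#' trial length, observation noise and dropout rates, per-camera sub-frame
#' timing offsets, and slow reference-point drift.
#'
#' Camera `c`'s frame `i` (1-based) samples the scene at time
#' `(i - 1 - frame_offsets[c]) / frame_rate` seconds on the reference clock, so
#' a positive offset makes events appear at a later fractional frame index in
#' that camera's stream.
#'
#' @param n_cameras number of cameras (>= 2).
#' @param n_refpoints number of surveyed reference cubes lining the corridor.
#' @param corridor_extent along-slope, across-slope and vertical extent, metres.
#' @param slope_angle slope inclination, degrees.
#' @param frame_rate capture rate, Hz.
#' @param n_frames trial length, frames.
#' @param skier_speed descent speed along the slope, m/s.
#' @param pixel_noise_sd Gaussian noise on reference-cube image positions, px.
#' @param keypoint_noise_sd Gaussian noise on skier keypoint positions, px.
#' @param ref_dropout_prob probability a visible cube is not localized.
#' @param id_dropout_prob probability a localized cube gets no identification.
#' @param keypoint_dropout_prob probability a visible keypoint is missing.
#' @param frame_offsets per-camera timing offsets in fractional frames
#'   (recycled/zero-padded to `n_cameras`).
#' @param ref_drift maximum surveyed-point displacement, metres (0 = stable
#'   field; 0.16 emulates the largest drift seen over a capture day).
#' @param image_size image width and height, pixels.
#' @param target_height_px apparent skier height the zoom controller maintains,
#'   pixels; focal length scales linearly with skier distance to hold it.
#' @param aim_lag_frames tracking lag of the camera operator, frames.
#' @param turn_period period of the skier's turn cycle, seconds.
#' @param rng_seed integer seed fixing every stochastic draw.
#' @return object of class `scene_config` (a validated list).
#' @export
scene_config <- function(n_cameras = 4,
                         n_refpoints = 120,
                         corridor_extent = c(100, 30, 20),
                         slope_angle = 12,
                         frame_rate = 25,
                         n_frames = 100,
                         skier_speed = 15,
                         pixel_noise_sd = 0,
                         keypoint_noise_sd = 0,
                         ref_dropout_prob = 0,
                         id_dropout_prob = 0,
                         keypoint_dropout_prob = 0,
                         frame_offsets = NULL,
                         ref_drift = 0,
                         image_size = c(3840, 2160),
                         target_height_px = 400,
                         aim_lag_frames = 0,
                         turn_period = 2.0,
                         rng_seed = 1L) {
  if (n_cameras < 2) stop("configuration error: n_cameras must be >= 2")
  if (frame_rate <= 0) stop("configuration error: frame_rate must be > 0")
  probs <- c(ref_dropout_prob, id_dropout_prob, keypoint_dropout_prob)
  if (any(probs < 0 | probs > 1)) stop("configuration error: probabilities must lie in [0,1]")
  if (ref_drift < 0) stop("configuration error: ref_drift must be >= 0")
  if (length(corridor_extent) != 3 || any(corridor_extent <= 0))
    stop("configuration error: corridor_extent must be 3 positive lengths")
  if (is.null(frame_offsets)) frame_offsets <- rep(0, n_cameras)
  frame_offsets <- rep_len(frame_offsets, n_cameras)
  structure(list(
    n_cameras = as.integer(n_cameras), n_refpoints = as.integer(n_refpoints),
    corridor_extent = corridor_extent, slope_angle = slope_angle,
    frame_rate = frame_rate, n_frames = as.integer(n_frames),
    skier_speed = skier_speed,
    pixel_noise_sd = pixel_noise_sd, keypoint_noise_sd = keypoint_noise_sd,
    ref_dropout_prob = ref_dropout_prob, id_dropout_prob = id_dropout_prob,
    keypoint_dropout_prob = keypoint_dropout_prob,
    frame_offsets = frame_offsets, ref_drift = ref_drift,
    image_size = image_size, target_height_px = target_height_px,
    aim_lag_frames = aim_lag_frames, turn_period = turn_period,
    rng_seed = as.integer(rng_seed)
  ), class = "scene_config")
}

camera_ids <- function(n) sprintf("cam%02d", seq_len(n))

# Slope surface height (z, metres) at along-slope coordinate x.
slope_surface <- function(x, slope_angle) -x * tan(slope_angle * pi / 180)

# Continuous skier root path: constant-speed descent with sinusoidal lateral
# turns about the fall line. Returns a closure t -> list(pos, tangent).
skier_path <- function(config, pelvis_height = 0.90,
                       turn_amplitude = NULL, turn_wavelength = 40) {
  # defaults give a minimum turn radius of ~13 m at 15 m/s (~1.6 g lateral),
  # typical of dynamic carving; tighter defaults would be physically implausible
  ey <- config$corridor_extent[2]
  A <- if (is.null(turn_amplitude)) min(ey / 6, 3) else turn_amplitude
  v <- config$skier_speed
  th <- config$slope_angle * pi / 180
  vx <- v * cos(th)
  function(t) {
    x <- vx * t
    k <- 2 * pi / turn_wavelength
    y <- A * sin(k * x)
    z <- slope_surface(x, config$slope_angle) + pelvis_height
    tangent <- c(vx, A * k * cos(k * x) * vx, -vx * tan(th))
    list(pos = c(x, y, z), tangent = tangent)
  }
}

# Surveyed cube field: poles of height 0.5-1.5 m lining the corridor around
# the descent line. Drawn under the scene seed so the field is reproducible.
make_refpoint_field <- function(config) {
  n <- config$n_refpoints
  ex <- config$corridor_extent[1]
  ey <- config$corridor_extent[2]
  x <- runif(n, -5, ex + 5)
  y <- runif(n, -ey / 2, ey / 2)
  z <- slope_surface(x, config$slope_angle) + runif(n, 0.5, 1.5)
  data.frame(ref_id = seq_len(n), x = x, y = y, z = z)
}

# Fixed camera placements: alternating sides of the corridor, elevated,
# spread along the descent.
camera_positions <- function(config) {
  n <- config$n_cameras
  ex <- config$corridor_extent[1]
  ey <- config$corridor_extent[2]
  xs <- seq(0.15, 0.85, length.out = n) * ex
  side <- rep(c(1, -1), length.out = n)
  ys <- side * (ey / 2 + 15)
  zs <- slope_surface(xs, config$slope_angle) + 6
  ids <- camera_ids(n)
  lapply(seq_len(n), function(i) list(camera_id = ids[i], position = c(xs[i], ys[i], zs[i])))
}

# Projection matrix of camera cam aimed at `target` with zoom holding the
# skier's apparent height at config$target_height_px.
ptz_matrix <- function(cam, target, config, skier_height = 1.5) {
  dist <- sqrt(sum((target - cam$position)^2))
  f <- config$target_height_px * dist / skier_height
  pp <- config$image_size / 2
  R <- look_at_rotation(cam$position, target)
  camera_matrix(f, pp, R, cam$position)
}

in_image <- function(uv, image_size, margin = 0) {
  uv[, 1] >= -margin & uv[, 1] <= image_size[1] + margin &
    uv[, 2] >= -margin & uv[, 2] <= image_size[2] + margin
}

#' Generate a complete synthetic trial
#'
#' Builds the surveyed cube field, the camera rig and the skier motion, then
#' renders every detection stream the pipeline consumes, each camera sampling
#' on its own (possibly fractionally offset) frame grid. All stochastic
#' effects -- pixel noise, localization/identification dropout, surveyed-point
#' drift -- derive from `config$rng_seed`, so identical configs yield
#' bit-identical bundles.
#'
#' @param config a [scene_config()].
#' @return list of class `trial_bundle` with elements:
#'   \describe{
#'     \item{config}{the generating configuration}
#'     \item{surveyed}{data.frame ref_id,x,y,z -- the (possibly drifted) table
#'       handed to calibration}
#'     \item{boxes}{reference-cube localizations: camera_id, frame, box corners,
#'       centroid cx/cy, confidence}
#'     \item{identifications}{fiducial decodes: camera_id, frame, ref_id, mx, my}
#'     \item{keypoints}{skier keypoint stream: camera_id, frame, keypoint, u, v,
#'       confidence}
#'     \item{skier_bbox}{per camera-frame skier bounding box and centroid}
#'     \item{ground_truth}{noise-free references: 3D keypoints on the reference
#'       timeline, true projection matrices per camera-frame, true surveyed
#'       table, noise-free cube projections with visibility, true offsets and
#'       segment lengths}
#'   }
#' @export
generate_scene <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  with_seed(config$rng_seed, {
    skel <- skeleton_model()
    path <- skier_path(config)
    refs_true <- make_refpoint_field(config)
    refs_used <- if (config$ref_drift > 0)
      perturb_refpoints(refs_true, config$ref_drift, seed = config$rng_seed + 101L)
    else refs_true
    cams <- camera_positions(config)
    fps <- config$frame_rate
    nF <- config$n_frames
    imsz <- config$image_size
    ids <- camera_ids(config$n_cameras)

    # ground truth on the reference timeline (offset 0)
    t_ref <- (seq_len(nF) - 1) / fps
    kp3d <- do.call(rbind, lapply(seq_len(nF), function(i) {
      M <- skier_pose(t_ref[i], skel, path, config$turn_period)
      data.frame(frame = i, keypoint = rownames(M),
                 x = M[, 1], y = M[, 2], z = M[, 3], row.names = NULL)
    }))
    centroid3d <- t(vapply(t_ref, function(t) path(t)$pos, numeric(3)))

    P_true <- list(); kp2d_true <- list()
    boxes <- list(); idents <- list(); kps <- list(); bbox <- list(); refproj <- list()
    refM <- as.matrix(refs_true[, c("x", "y", "z")])
    cube_half_m <- 0.045

    for (ci in seq_len(config$n_cameras)) {
      cam <- cams[[ci]]
      delta <- config$frame_offsets[ci]
      P_cam <- vector("list", nF)
      for (i in seq_len(nF)) {
        t <- (i - 1 - delta) / fps
        t_aim <- t - config$aim_lag_frames / fps
        target <- path(t_aim)$pos
        P <- ptz_matrix(cam, target, config)
        P_cam[[i]] <- P

        # --- reference cubes ---
        pr <- project_points(P, refM)
        vis <- pr[, "depth"] > 0 & in_image(pr, imsz)
        vidx <- which(vis)
        if (length(vidx)) {
          dist <- sqrt(rowSums((refM[vidx, , drop = FALSE] -
                                  matrix(cam$position, length(vidx), 3, byrow = TRUE))^2))
          f_px <- ptz_focal(cam, target, config)
          half <- f_px * cube_half_m / dist
          keep <- runif(length(vidx)) >= config$ref_dropout_prob
          kidx <- vidx[keep]
          refproj[[length(refproj) + 1]] <- data.frame(
            camera_id = cam$camera_id, frame = i, ref_id = refs_true$ref_id[vidx],
            u = pr[vidx, "u"], v = pr[vidx, "v"], localized = keep)
          if (length(kidx)) {
            nk <- length(kidx)
            ncx <- pr[kidx, "u"] + rnorm(nk, 0, config$pixel_noise_sd)
            ncy <- pr[kidx, "v"] + rnorm(nk, 0, config$pixel_noise_sd)
            hk <- half[keep]
            boxes[[length(boxes) + 1]] <- data.frame(
              camera_id = cam$camera_id, frame = i,
              x_min = ncx - hk, y_min = ncy - hk, x_max = ncx + hk, y_max = ncy + hk,
              cx = ncx, cy = ncy, confidence = runif(nk, 0.8, 1),
              true_ref_id = refs_true$ref_id[kidx])
            has_id <- runif(nk) >= config$id_dropout_prob
            if (any(has_id)) {
              jj <- which(has_id)
              idents[[length(idents) + 1]] <- data.frame(
                camera_id = cam$camera_id, frame = i,
                ref_id = refs_true$ref_id[kidx[jj]],
                mx = pr[kidx[jj], "u"] + rnorm(length(jj), 0, config$pixel_noise_sd),
                my = pr[kidx[jj], "v"] + rnorm(length(jj), 0, config$pixel_noise_sd))
            }
          }
        }

        # --- skier keypoints ---
        M3 <- skier_pose(t, skel, path, config$turn_period)
        pk <- project_points(P, M3)
        kvis <- pk[, "depth"] > 0 & in_image(pk, imsz)
        kp2d_true[[length(kp2d_true) + 1]] <- data.frame(
          camera_id = cam$camera_id, frame = i, keypoint = rownames(M3),
          u = pk[, "u"], v = pk[, "v"], visible = kvis, row.names = NULL)
        keepk <- kvis & runif(nrow(pk)) >= config$keypoint_dropout_prob
        if (any(keepk)) {
          nk <- sum(keepk)
          kps[[length(kps) + 1]] <- data.frame(
            camera_id = cam$camera_id, frame = i, keypoint = rownames(M3)[keepk],
            u = pk[keepk, "u"] + rnorm(nk, 0, config$keypoint_noise_sd),
            v = pk[keepk, "v"] + rnorm(nk, 0, config$keypoint_noise_sd),
            confidence = runif(nk, 0.85, 1), row.names = NULL)
        }
        if (any(kvis)) {
          bbox[[length(bbox) + 1]] <- data.frame(
            camera_id = cam$camera_id, frame = i,
            x_min = min(pk[kvis, "u"]), y_min = min(pk[kvis, "v"]),
            x_max = max(pk[kvis, "u"]), y_max = max(pk[kvis, "v"]),
            cx = (min(pk[kvis, "u"]) + max(pk[kvis, "u"])) / 2,
            cy = (min(pk[kvis, "v"]) + max(pk[kvis, "v"])) / 2)
        }
      }
      P_true[[ids[ci]]] <- P_cam
    }

    bind <- function(lst, proto) if (length(lst)) do.call(rbind, lst) else proto
    structure(list(
      config = config,
      surveyed = refs_used,
      boxes = bind(boxes, data.frame()),
      identifications = bind(idents, data.frame()),
      keypoints = bind(kps, data.frame()),
      skier_bbox = bind(bbox, data.frame()),
      ground_truth = list(
        skeleton = skel,
        keypoints_3d = kp3d,
        centroid_3d = data.frame(frame = seq_len(nF), x = centroid3d[, 1],
                                 y = centroid3d[, 2], z = centroid3d[, 3]),
        keypoints_2d = do.call(rbind, kp2d_true),
        ref_projections = do.call(rbind, refproj),
        surveyed_true = refs_true,
        P_true = P_true,
        frame_offsets = stats::setNames(config$frame_offsets, ids),
        segment_lengths = stats::setNames(skel$segments$length_m, skel$segments$segment)
      )
    ), class = "trial_bundle")
  })
}

# focal length the zoom controller would use for this aim target
ptz_focal <- function(cam, target, config, skier_height = 1.5) {
  config$target_height_px * sqrt(sum((target - cam$position)^2)) / skier_height
}

#' Render a synchronization drop event
#'
#' Simulates the calibration-cube drop used to synchronize cameras: the cube
#' free-falls under gravity from `drop_height`, hits the damper, and rebounds
#' with the given restitution. Each camera, aimed level at the drop site,
#' records the cube's vertical pixel coordinate on its own offset frame grid.
#'
#' @param config a [scene_config()]; `frame_offsets`, `frame_rate` and
#'   `pixel_noise_sd` are used.
#' @param drop_height release height above the damper, metres (> 0).
#' @param restitution rebound speed ratio in [0, 1); 0 suppresses the bounce.
#' @param release_time seconds of stationary hold before release.
#' @param noise_sd pixel noise on the track; defaults to `config$pixel_noise_sd`.
#' @return list of `drop_track` data.frames (camera_id, frame, y_px), with
#'   attribute `truth`: per-camera true event frame index and the impact time.
#' @export
render_drop_event <- function(config, drop_height = 1.8, restitution = 0.6,
                              release_time = 0.3, noise_sd = NULL) {
  stopifnot(inherits(config, "scene_config"))
  if (drop_height <= 0) stop("drop_height must be > 0")
  if (restitution < 0 || restitution >= 1) stop("restitution must be in [0, 1)")
  if (is.null(noise_sd)) noise_sd <- config$pixel_noise_sd
  g <- 9.81
  fps <- config$frame_rate
  ex <- config$corridor_extent[1]
  base <- c(ex / 2, 0, slope_surface(ex / 2, config$slope_angle) + 0.5)
  t_fall <- sqrt(2 * drop_height / g)
  t_imp <- release_time + t_fall
  v_reb <- restitution * g * t_fall
  bounce_dur <- 2 * v_reb / g
  n_track <- ceiling((t_imp + max(0.9 * bounce_dur, 2 / fps)) * fps)

  cube_z <- function(t) {
    z <- numeric(length(t))
    pre <- t < release_time
    fall <- t >= release_time & t < t_imp
    post <- t >= t_imp
    z[pre] <- base[3] + drop_height
    z[fall] <- base[3] + drop_height - g / 2 * (t[fall] - release_time)^2
    tau <- t[post] - t_imp
    zb <- base[3] + v_reb * tau - g / 2 * tau^2
    z[post] <- pmax(zb, base[3])
    z
  }

  cams <- camera_positions(config)
  ids <- camera_ids(config$n_cameras)
  with_seed(config$rng_seed + 7L, {
    tracks <- lapply(seq_len(config$n_cameras), function(ci) {
      cam <- cams[[ci]]
      # level the camera with the drop midpoint: optical axis horizontal, so the
      # vertical pixel coordinate is an exact affine image of cube height
      cam$position[3] <- base[3] + drop_height / 2
      target <- c(base[1], base[2], base[3] + drop_height / 2)
      P <- ptz_matrix(cam, target, config)
      delta <- config$frame_offsets[ci]
      frames <- seq_len(n_track)
      t <- (frames - 1 - delta) / fps
      X <- cbind(base[1], base[2], cube_z(t))
      pr <- project_points(P, X)
      df <- data.frame(camera_id = cam$camera_id, frame = frames,
                       y_px = pr[, "v"] + rnorm(n_track, 0, noise_sd))
      class(df) <- c("drop_track", class(df))
      df
    })
    names(tracks) <- ids
    attr(tracks, "truth") <- list(
      impact_time = t_imp,
      event_frame = stats::setNames(t_imp * fps + 1 + config$frame_offsets, ids))
    tracks
  })
}

#' Apply slow positional drift to surveyed reference points
#'
#' Emulates reference poles shifting between surveys (sun/heat-induced tilt):
#' each point is displaced by an independent random vector of magnitude at most
#' `drift` metres (uniform in the ball). IDs are unchanged.
#'
#' @param points data.frame with columns ref_id, x, y, z.
#' @param drift maximum displacement, metres (>= 0).
#' @param seed integer seed for the displacement draws.
#' @param ref_ids optional subset of ref_ids to perturb (default: all).
#' @return data.frame of the same shape with displaced coordinates.
#' @export
perturb_refpoints <- function(points, drift, seed = 1L, ref_ids = NULL) {
  if (drift < 0) stop("drift must be >= 0")
  if (drift == 0) return(points)
  sel <- if (is.null(ref_ids)) rep(TRUE, nrow(points)) else points$ref_id %in% ref_ids
  n <- sum(sel)
  with_seed(seed, {
    dir <- matrix(rnorm(3 * n), ncol = 3)
    dir <- dir / sqrt(rowSums(dir^2))
    mag <- drift * runif(n)^(1 / 3)
    points[sel, c("x", "y", "z")] <- points[sel, c("x", "y", "z")] + dir * mag
  })
  points
}
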