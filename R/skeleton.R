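# 26-point whole-body keypoint schema (HALPE26 ordering) extended with six
# skier-specific endpoints: ski tips, ski tails and pole tips for both sides.

.halpe26_names <- c(
  "nose", "left_eye", "right_eye", "left_ear", "right_ear",
  "left_shoulder", "right_shoulder", "left_elbow", "right_elbow",
  "left_wrist", "right_wrist", "left_hip", "right_hip",
  "left_knee", "right_knee", "left_ankle", "right_ankle",
  "head", "neck", "pelvis",
  "left_big_toe", "right_big_toe", "left_small_toe", "right_small_toe",
  "left_heel", "right_heel"
)

.ski_extra_names <- c(
  "left_ski_tip", "right_ski_tip", "left_ski_tail", "right_ski_tail",
  "left_pole_tip", "right_pole_tip"
)

#' Skier skeleton model
#'
#' Defines the keypoint schema (26 anatomical points in HALPE26 order plus
#' configurable skier-specific points) and the eight anatomical segments whose
#' lengths are used as the 3D reconstruction consistency metric: left/right
#' upper arm (shoulder-elbow), forearm (elbow-wrist), thigh (hip-knee) and
#' shank (knee-ankle). Segment lengths are fixed body parameters in metres.
#'
#' @param extra_keypoints character vector of sport-specific keypoint names
#'   appended to the anatomical schema.
#' @param segment_lengths named numeric vector (metres) overriding the default
#'   limb lengths: `upper_arm`, `forearm`, `thigh`, `shank` (applied to both
#'   sides), plus trunk geometry `trunk`, `shoulder_width`, `hip_width`.
#' @return object of class `skeleton_model` with elements `keypoints`,
#'   `segments` (data.frame: segment, from, to, length_m) and `params`.
#' @export
skeleton_model <- function(extra_keypoints = .ski_extra_names,
                           segment_lengths = NULL) {
  params <- c(upper_arm = 0.28, forearm = 0.25, thigh = 0.45, shank = 0.43,
              trunk = 0.50, shoulder_width = 0.36, hip_width = 0.30)
  if (!is.null(segment_lengths)) {
    bad <- setdiff(names(segment_lengths), names(params))
    if (length(bad)) stop("unknown segment parameter(s): ", paste(bad, collapse = ", "))
    params[names(segment_lengths)] <- segment_lengths
  }
  segs <- data.frame(
    segment = c("upper_arm_L", "upper_arm_R", "forearm_L", "forearm_R",
                "thigh_L", "thigh_R", "shank_L", "shank_R"),
    from = c("left_shoulder", "right_shoulder", "left_elbow", "right_elbow",
             "left_hip", "right_hip", "left_knee", "right_knee"),
    to = c("left_elbow", "right_elbow", "left_wrist", "right_wrist",
           "left_knee", "right_knee", "left_ankle", "right_ankle"),
    length_m = unname(params[c("upper_arm", "upper_arm", "forearm", "forearm",
                               "thigh", "thigh", "shank", "shank")]),
    stringsAsFactors = FALSE
  )
  kp <- c(.halpe26_names, extra_keypoints)
  if (anyDuplicated(kp)) stop("duplicate keypoint names in schema")
  stopifnot(all(segs$from %in% kp), all(segs$to %in% kp))
  structure(list(keypoints = kp, segments = segs, params = params),
            class = "skeleton_model")
}

#' @export
print.skeleton_model <- function(x, ...) {
  cat("skeleton_model:", length(x$keypoints), "keypoints,",
      nrow(x$segments), "tracked segments\n")
  invisible(x)
}

# Articulated skier pose at continuous time t (seconds).
#
# The root follows the descent path; limbs are posed by rotating fixed-length
# direction vectors, so every tracked segment length is constant to machine
# precision across time. `path` is a function t -> list(pos, tangent).
# Returns a named matrix (n_keypoints x 3) in world metres.
skier_pose <- function(t, skeleton, path, turn_period = 2.0) {
  pp <- path(t)
  fwd <- unit3(pp$tangent)
  right <- unit3(cross3(fwd, c(0, 0, 1)))
  up <- cross3(right, fwd)
  prm <- skeleton$params
  w <- 2 * pi * t / turn_period

  pelvis <- pp$pos
  # trunk leans forward; lean oscillates slightly with the turn cycle
  lean <- 0.30 + 0.08 * sin(w)
  d_trunk <- up * cos(lean) + fwd * sin(lean)
  neck_base <- pelvis + prm["trunk"] * d_trunk
  out <- matrix(NA_real_, nrow = length(skeleton$keypoints), ncol = 3,
                dimnames = list(skeleton$keypoints, c("x", "y", "z")))
  set <- function(name, v) out[name, ] <<- v

  set("pelvis", pelvis)
  set("neck", neck_base + 0.05 * d_trunk)
  set("head", neck_base + 0.20 * d_trunk)
  set("nose", neck_base + 0.18 * d_trunk + 0.08 * fwd)
  set("left_eye",  neck_base + 0.20 * d_trunk + 0.06 * fwd + 0.03 * (-right))
  set("right_eye", neck_base + 0.20 * d_trunk + 0.06 * fwd + 0.03 * right)
  set("left_ear",  neck_base + 0.19 * d_trunk + 0.07 * (-right))
  set("right_ear", neck_base + 0.19 * d_trunk + 0.07 * right)

  for (side in c("left", "right")) {
    sgn <- if (side == "left") -1 else 1       # left = -right axis (y across)
    lat <- sgn * right
    phase <- if (side == "left") 0 else pi

    hip <- pelvis + (prm["hip_width"] / 2) * lat
    set(paste0(side, "_hip"), hip)
    # leg flexion: thigh pitched forward, shank pitched back, both fixed length
    a_th <- 0.55 + 0.12 * sin(w + phase)
    a_sh <- 0.25 + 0.10 * sin(w + phase)
    d_th <- -up * cos(a_th) + fwd * sin(a_th)
    knee <- hip + prm["thigh"] * d_th
    set(paste0(side, "_knee"), knee)
    d_sh <- -up * cos(a_sh) - fwd * sin(a_sh)
    ankle <- knee + prm["shank"] * d_sh
    set(paste0(side, "_ankle"), ankle)

    set(paste0(side, "_big_toe"),   ankle + 0.18 * fwd - 0.05 * up)
    set(paste0(side, "_small_toe"), ankle + 0.17 * fwd + 0.04 * lat - 0.05 * up)
    set(paste0(side, "_heel"),      ankle - 0.07 * fwd - 0.05 * up)
    if (paste0(side, "_ski_tip") %in% skeleton$keypoints) {
      set(paste0(side, "_ski_tip"),  ankle + 0.85 * fwd - 0.06 * up)
      set(paste0(side, "_ski_tail"), ankle - 0.65 * fwd - 0.06 * up)
    }

    shoulder <- neck_base + (prm["shoulder_width"] / 2) * lat
    set(paste0(side, "_shoulder"), shoulder)
    a_arm <- 0.15 * sin(w + phase)
    d_ua <- unit3(-0.80 * up + 0.45 * lat + (0.30 + a_arm) * fwd)
    elbow <- shoulder + prm["upper_arm"] * d_ua
    set(paste0(side, "_elbow"), elbow)
    d_fa <- unit3(-0.40 * up + 0.85 * fwd + 0.15 * lat)
    wrist <- elbow + prm["forearm"] * d_fa
    set(paste0(side, "_wrist"), wrist)
    if (paste0(side, "_pole_tip") %in% skeleton$keypoints) {
      set(paste0(side, "_pole_tip"),
          wrist + 1.15 * unit3(-0.90 * up - 0.35 * fwd + 0.15 * lat))
    }
  }
  out
}
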