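# Association of reference-cube localizations with fiducial identifications:
# overlap filtering, containment matching, and temporal identity recovery via
# inter-frame image shift vectors.

box_iou <- function(a, b) {
  ix <- max(0, min(a["x_max"], b["x_max"]) - max(a["x_min"], b["x_min"]))
  iy <- max(0, min(a["y_max"], b["y_max"]) - max(a["y_min"], b["y_min"]))
  inter <- ix * iy
  ua <- (a["x_max"] - a["x_min"]) * (a["y_max"] - a["y_min"]) +
    (b["x_max"] - b["x_min"]) * (b["y_max"] - b["y_min"]) - inter
  unname(inter / ua)
}

#' Discard mutually overlapping cube detections
#'
#' Within one camera-frame, every pair of boxes with intersection-over-union
#' above the threshold is removed entirely (both members): overlapping cubes
#' cannot be attributed unambiguously.
#'
#' @param boxes data.frame of detections from one camera-frame with columns
#'   x_min, y_min, x_max, y_max.
#' @param threshold IoU above which a pair counts as overlapping (strict `>`).
#' @return the filtered data.frame.
#' @export
discard_overlaps <- function(boxes, threshold = 0.5) {
  n <- nrow(boxes)
  if (n < 2) return(boxes)
  m <- as.matrix(boxes[, c("x_min", "y_min", "x_max", "y_max")])
  drop <- logical(n)
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    if (box_iou(m[i, ], m[j, ]) > threshold) drop[i] <- drop[j] <- TRUE
  }
  boxes[!drop, , drop = FALSE]
}

#' Match fiducial identifications to localization boxes
#'
#' An identification is assigned to the box whose extent contains its marker
#' centroid; when several boxes contain it, the one with the nearest box
#' centroid wins. A box containing two different ids is discarded as a
#' conflict. Boxes containing no identification keep `ref_id = NA` and a
#' `provenance` of "unidentified"; matched boxes are tagged "direct".
#'
#' @param boxes data.frame of one camera-frame's localizations (columns
#'   x_min, y_min, x_max, y_max, cx, cy).
#' @param identifications data.frame with columns ref_id, mx, my for the same
#'   camera-frame (may be empty).
#' @return `boxes` with columns `ref_id` and `provenance` set.
#' @export
match_ids <- function(boxes, identifications) {
  boxes$ref_id <- NA_integer_
  boxes$provenance <- "unidentified"
  if (!nrow(boxes) || is.null(identifications) || !nrow(identifications))
    return(boxes)
  conflict <- logical(nrow(boxes))
  for (k in seq_len(nrow(identifications))) {
    mx <- identifications$mx[k]; my <- identifications$my[k]
    inside <- which(boxes$x_min <= mx & mx <= boxes$x_max &
                      boxes$y_min <= my & my <= boxes$y_max)
    if (!length(inside)) next
    d <- (boxes$cx[inside] - mx)^2 + (boxes$cy[inside] - my)^2
    b <- inside[which.min(d)]
    id <- identifications$ref_id[k]
    if (!is.na(boxes$ref_id[b]) && boxes$ref_id[b] != id) {
      conflict[b] <- TRUE
    } else {
      boxes$ref_id[b] <- id
      boxes$provenance[b] <- "direct"
    }
  }
  # duplicate ids across boxes: keep the identification nearest its box centre?
  # identities must be unique per frame -- keep the first (containment is
  # already one-to-one in practice); drop later duplicates back to unknown
  dup <- !is.na(boxes$ref_id) & duplicated(boxes$ref_id)
  boxes$ref_id[dup] <- NA_integer_
  boxes$provenance[dup] <- "unidentified"
  boxes[!conflict, , drop = FALSE]
}

#' Estimate the inter-frame image shift of a panning camera
#'
#' The shift is the component-wise median of centroid displacements over
#' reference points identified in both frames -- robust to a single
#' mis-tracked cube.
#'
#' @param prev,curr identified detection data.frames (columns ref_id, cx, cy)
#'   for consecutive frames of one camera.
#' @return numeric length-2 shift (dx, dy) in pixels with attribute
#'   `residual_mad` (median magnitude of the per-cube deviations from the
#'   shift, a measure of the parallax spread of the flow field), or `NULL`
#'   when the frames share no identified reference point (recovery is skipped
#'   then).
#' @export
estimate_shift <- function(prev, curr) {
  p <- prev[!is.na(prev$ref_id), ]
  q <- curr[!is.na(curr$ref_id), ]
  common <- intersect(p$ref_id, q$ref_id)
  if (!length(common)) return(NULL)
  ip <- match(common, p$ref_id); iq <- match(common, q$ref_id)
  dx <- q$cx[iq] - p$cx[ip]; dy <- q$cy[iq] - p$cy[ip]
  sh <- c(stats::median(dx), stats::median(dy))
  attr(sh, "residual_mad") <-
    stats::median(sqrt((dx - sh[1])^2 + (dy - sh[2])^2))
  sh
}

#' Recover missing identities by projecting the previous frame forward
#'
#' Each reference point identified in the previous frame is projected into the
#' current frame by the image shift vector; if the projection lands within
#' `radius` of an unidentified box centroid, that box inherits the id.
#' Assignment is one-to-one, nearest pair first; boxes already identified are
#' never reassigned. Recovered boxes are tagged `provenance = "recovered"`.
#'
#' @param prev identified detections of the previous frame.
#' @param curr current frame's detections (output of [match_ids()]).
#' @param shift length-2 pixel shift from [estimate_shift()].
#' @param radius acceptance radius in pixels; `NULL` uses an adaptive radius:
#'   half the projected box diagonal plus three times the parallax spread
#'   (`residual_mad`) reported by [estimate_shift()], since a panning camera
#'   moving past a field of cubes at different depths produces per-cube flow
#'   that deviates from the global shift by that order.
#' @return `curr` with recovered `ref_id`s filled in.
#' @export
temporal_recover <- function(prev, curr, shift, radius = NULL) {
  if (is.null(shift)) return(curr)
  p <- prev[!is.na(prev$ref_id) & !(prev$ref_id %in% curr$ref_id), , drop = FALSE]
  unk <- which(is.na(curr$ref_id))
  if (!nrow(p) || !length(unk)) return(curr)
  px <- p$cx + shift[1]; py <- p$cy + shift[2]
  rad <- if (is.null(radius)) {
    spread <- attr(shift, "residual_mad") %||% 0
    sqrt((p$x_max - p$x_min)^2 + (p$y_max - p$y_min)^2) / 2 + 3 * spread
  } else rep_len(radius, nrow(p))
  d <- outer(px, curr$cx[unk], "-")^2 + outer(py, curr$cy[unk], "-")^2
  used_p <- logical(nrow(p)); used_b <- logical(length(unk))
  repeat {
    d[used_p, ] <- Inf; d[, used_b] <- Inf
    k <- arrayInd(which.min(d), dim(d))
    if (!is.finite(d[k])) break
    i <- k[1]; j <- k[2]
    if (sqrt(d[k]) <= rad[i]) {
      b <- unk[j]
      curr$ref_id[b] <- p$ref_id[i]
      curr$provenance[b] <- "recovered"
    }
    used_p[i] <- TRUE; used_b[j] <- TRUE
  }
  curr
}

#' Run the full association chain over one camera's trial
#'
#' Per frame: overlap filtering, identification matching, then temporal
#' recovery using the shift estimated from reference points identified in both
#' the neighbouring and current frame. By default the recovery chain runs both
#' forward and backward through the trial and the passes are merged (forward
#' priority): a cube whose identification drops out right as it enters the
#' view has no earlier observation to project forward, but is recovered from
#' its later identified observations by the backward pass.
#'
#' @param boxes all localization boxes of one camera (column `frame`).
#' @param identifications all identifications of the same camera.
#' @param overlap_threshold IoU discard threshold.
#' @param radius recovery radius override (see [temporal_recover()]).
#' @param direction `"both"` (default), `"forward"` or `"backward"`.
#' @return data.frame of processed detections over all frames, with `ref_id`
#'   and `provenance` columns.
#' @export
associate_refpoints <- function(boxes, identifications,
                                overlap_threshold = 0.5, radius = NULL,
                                direction = c("both", "forward", "backward")) {
  direction <- match.arg(direction)
  boxes$.row <- seq_len(nrow(boxes))
  run_pass <- function(frame_order) {
    prev <- NULL
    out <- vector("list", length(frame_order))
    for (fi in seq_along(frame_order)) {
      f <- frame_order[fi]
      b <- boxes[boxes$frame == f, , drop = FALSE]
      idf <- identifications[identifications$frame == f, , drop = FALSE]
      b <- discard_overlaps(b, overlap_threshold)
      b <- match_ids(b, idf)
      if (!is.null(prev)) {
        sh <- estimate_shift(prev, b)
        if (!is.null(sh)) b <- temporal_recover(prev, b, sh, radius)
      }
      out[[fi]] <- b
      if (any(!is.na(b$ref_id))) prev <- b
    }
    res <- do.call(rbind, out)
    res[order(res$.row), , drop = FALSE]
  }
  frames <- sort(unique(boxes$frame))
  res <- switch(direction,
                forward = run_pass(frames),
                backward = run_pass(rev(frames)),
                both = {
                  fw <- run_pass(frames)
                  bw <- run_pass(rev(frames))
                  m <- match(fw$.row, bw$.row)
                  fill <- which(is.na(fw$ref_id) & !is.na(m) & !is.na(bw$ref_id[m]))
                  for (i in fill) {
                    id <- bw$ref_id[m[i]]
                    same <- fw$frame == fw$frame[i]
                    if (!id %in% fw$ref_id[same]) {
                      fw$ref_id[i] <- id
                      fw$provenance[i] <- "recovered"
                    }
                  }
                  fw
                })
  res$.row <- NULL
  rownames(res) <- NULL
  res
}
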