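# Sub-frame camera synchronization from drop-cube trajectories: the free-fall
# and first-bounce phases of the vertical pixel track are each fit with a
# quadratic; their intersection defines the synchronization event at
# fractional-frame precision.

#' Segment a drop track into free-fall and bounce phases
#'
#' Uses the track's curvature/velocity structure: the impact is bracketed by
#' the sample of largest vertical coordinate (image y grows downward); the
#' free-fall window is the contiguous run of descending samples ending just
#' before it, the bounce window the rebound samples just after it. The sample
#' nearest the impact is excluded from both windows since its phase membership
#' is ambiguous at sub-frame level.
#'
#' @param track data.frame with columns `frame` (strictly increasing) and
#'   `y_px`.
#' @param v_threshold minimum per-frame descent speed (px/frame) for a sample
#'   to count as falling; filters the stationary pre-release hold and noise.
#' @return list with `fall` and `bounce` integer index vectors into `track`.
#' @export
segment_phases <- function(track, v_threshold = 1.0) {
  stopifnot(all(c("frame", "y_px") %in% names(track)))
  if (is.unsorted(track$frame, strictly = TRUE))
    stop("frame indices must be strictly increasing")
  n <- nrow(track)
  if (n < 8) stop("no event detected: track too short")
  y <- track$y_px
  v <- diff(y)                      # v[i] = y[i+1] - y[i]
  imax <- which.max(y)

  # free fall: contiguous descending run ending at imax - 1
  a <- imax - 1
  while (a > 1 && v[a - 1] > v_threshold) a <- a - 1
  fall <- if (imax - 1 >= a) seq(a, imax - 1) else integer(0)

  # bounce: rebound after impact, up to the approach to the second impact
  b_end <- imax
  i <- imax + 1
  while (i <= n) {
    if (y[i] >= y[imax] - v_threshold && i > imax + 1) break
    b_end <- i
    i <- i + 1
  }
  bounce <- if (b_end >= imax + 1) seq(imax + 1, b_end) else integer(0)

  if (length(fall) < 3 || length(bounce) < 3)
    stop("no event detected: could not find fall-then-bounce structure")
  if (mean(diff(diff(y[fall]))) <= 0)
    stop("no event detected: free-fall window lacks downward acceleration")
  if (min(diff(y[bounce])) >= 0)
    stop("no event detected: no rebound after impact")
  list(fall = fall, bounce = bounce)
}

fit_quadratic <- function(frames, y) {
  f0 <- mean(frames)
  x <- frames - f0
  co <- stats::lm.fit(cbind(1, x, x^2), y)$coefficients
  # return coefficients in the original frame coordinate: a + b f + c f^2
  a <- co[1] - co[2] * f0 + co[3] * f0^2
  b <- co[2] - 2 * co[3] * f0
  c(a = unname(a), b = unname(b), c = unname(co[3]))
}

#' Fit the synchronization event time of one drop track
#'
#' Least-squares quadratics are fit to the free-fall and bounce windows; the
#' event is the intersection root lying between the two windows (when both
#' roots fall inside the gap, the one nearer its midpoint).
#'
#' @inheritParams segment_phases
#' @param phases optional precomputed result of [segment_phases()].
#' @return event time in fractional frame units of this camera's stream.
#' @export
fit_sync_event <- function(track, phases = NULL, v_threshold = 1.0) {
  if (is.null(phases)) phases <- segment_phases(track, v_threshold)
  qf <- fit_quadratic(track$frame[phases$fall], track$y_px[phases$fall])
  qb <- fit_quadratic(track$frame[phases$bounce], track$y_px[phases$bounce])
  lo <- track$frame[max(phases$fall)]
  hi <- track$frame[min(phases$bounce)]
  dc <- qf - qb                      # (a, b, c) of the difference polynomial
  roots <- if (abs(dc["c"]) < 1e-12 * max(abs(dc), 1)) {
    if (abs(dc["b"]) < .Machine$double.eps) numeric(0) else -dc["a"] / dc["b"]
  } else {
    disc <- dc["b"]^2 - 4 * dc["c"] * dc["a"]
    if (disc < 0) numeric(0)
    else (-dc["b"] + c(-1, 1) * sqrt(disc)) / (2 * dc["c"])
  }
  inside <- roots[roots >= lo & roots <= hi]
  if (!length(inside)) stop("no event detected: quadratics do not intersect between phases")
  mid <- (lo + hi) / 2
  unname(inside[which.min(abs(inside - mid))])
}

#' Derive inter-camera offsets from per-camera event times
#'
#' @param events named numeric vector of event times (fractional frames), one
#'   per camera; names are camera ids.
#' @return object of class `sync_result`: list with `reference` (the
#'   lexicographically smallest camera id), `events`, and `offsets` (event
#'   time minus the reference camera's event time; 0 for the reference).
#' @export
compute_offsets <- function(events) {
  if (length(events) < 2) stop("need events from at least 2 cameras")
  if (is.null(names(events)) || any(!nzchar(names(events))))
    stop("events must be named by camera id")
  if (any(!is.finite(events))) stop("event times must be finite")
  ref <- sort(names(events))[1]
  structure(list(reference = ref, events = events,
                 offsets = events - events[[ref]]),
            class = "sync_result")
}

#' @export
print.sync_result <- function(x, ...) {
  cat("sync_result: reference", x$reference, "\n")
  print(round(x$offsets, 4))
  invisible(x)
}

#' Average offsets over repeated synchronization events
#'
#' Field protocol records the drop twice per session; offsets are averaged,
#' and a repetition discrepancy above `warn_threshold` frames is reported as
#' a warning.
#'
#' @param sync_results list of `sync_result` objects over the same cameras.
#' @param warn_threshold maximum tolerated offset discrepancy, frames.
#' @return a `sync_result` with averaged offsets.
#' @export
average_sync <- function(sync_results, warn_threshold = 0.2) {
  stopifnot(length(sync_results) >= 1)
  offs <- do.call(rbind, lapply(sync_results, function(s) s$offsets[order(names(s$offsets))]))
  rng <- apply(offs, 2, function(o) diff(range(o)))
  if (any(rng > warn_threshold))
    warning(sprintf("synchronization repetitions disagree by up to %.3f frames for: %s",
                    max(rng), paste(colnames(offs)[rng > warn_threshold], collapse = ", ")))
  out <- sync_results[[1]]
  out$offsets <- colMeans(offs)[names(out$offsets)]
  out$events <- NULL
  out
}

#' Resample a detection stream onto the reference timeline
#'
#' Evaluates the stream at fractional frame positions `frame + offset` by
#' linear interpolation between adjacent frames. An interpolated point is
#' produced only when both neighbouring frames carry the same identity
#' (reference-point id or keypoint label); its confidence is the minimum of
#' the neighbours'. An integer offset needs only the single source frame.
#'
#' @param detections data.frame containing `frame`, the identity columns, and
#'   numeric value columns to interpolate.
#' @param offset fractional frame offset of this camera relative to the
#'   reference camera (see [compute_offsets()]).
#' @param id_cols character: columns identifying a track within the stream.
#'   Sub-frame resampling is only meaningful along tracks, so for a
#'   fractional offset the stream must carry a per-detection identity
#'   (an associated `ref_id`, a tracker-assigned `true_ref_id`, or a
#'   `keypoint` label).
#' @param value_cols character: numeric columns to interpolate.
#' @param conf_col optional confidence column (combined with `min`).
#' @return data.frame on the reference frame grid with the same columns.
#' @export
resample_stream <- function(detections, offset,
                            id_cols = intersect(c("camera_id", "ref_id",
                                                  "true_ref_id", "keypoint"),
                                                names(detections)),
                            value_cols = intersect(c("x_min", "y_min", "x_max", "y_max",
                                                     "cx", "cy", "u", "v"),
                                                   names(detections)),
                            conf_col = intersect("confidence", names(detections))) {
  if (!nrow(detections)) return(detections)
  if (abs(offset) >= diff(range(detections$frame)) + 1)
    stop("offset exceeds stream length")
  if (offset == round(offset)) {
    out <- detections
    out$frame <- out$frame - as.integer(round(offset))
    return(out)
  }
  key <- do.call(paste, c(detections[id_cols], sep = "\r"))
  pieces <- lapply(split(seq_len(nrow(detections)), key), function(idx) {
    d <- detections[idx, , drop = FALSE]
    d <- d[order(d$frame), , drop = FALSE]
    lookup <- match(seq(min(d$frame), max(d$frame)), d$frame)
    lo <- ceiling(min(d$frame) - offset)
    hi <- floor(max(d$frame) - offset)
    if (lo > hi) return(NULL)  # seq(lo, hi) would count downwards
    frames_out <- seq(lo, hi)
    q <- frames_out + offset
    i0 <- floor(q); frac <- q - i0
    r0 <- lookup[i0 - min(d$frame) + 1]
    r1 <- lookup[i0 + 1 - min(d$frame) + 1]
    ok <- !is.na(r0) & !is.na(r1)
    if (!any(ok)) return(NULL)
    out <- d[r0[ok], , drop = FALSE]
    for (vc in value_cols)
      out[[vc]] <- (1 - frac[ok]) * d[[vc]][r0[ok]] + frac[ok] * d[[vc]][r1[ok]]
    for (cc in conf_col)
      out[[cc]] <- pmin(d[[cc]][r0[ok]], d[[cc]][r1[ok]])
    out$frame <- frames_out[ok]
    out
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out[order(out$frame), , drop = FALSE]
}

#' Worst-case positional error of a half-frame synchronization offset
#'
#' For an athlete moving at `speed`, an offset of half a frame displaces the
#' reconstructed position by `speed / (2 * frame_rate)` metres -- e.g. 0.30 m
#' at 15 m/s and 25 Hz, which is why sub-frame synchronization is required.
#'
#' @param speed athlete speed, m/s (>= 0).
#' @param frame_rate capture rate, Hz (> 0).
#' @return displacement bound in metres.
#' @export
displacement_bound <- function(speed, frame_rate) {
  if (frame_rate <= 0) stop("frame_rate must be > 0")
  if (speed < 0) stop("speed must be >= 0")
  speed / (2 * frame_rate)
}
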