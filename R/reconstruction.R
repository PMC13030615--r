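# Multi-view 3D reconstruction: SVD triangulation of each keypoint from all
# calibrated views observing it, exhaustive selection of the camera subset
# minimizing mean reprojection error (held fixed over the trial), and
# zero-phase Butterworth smoothing of the resulting trajectories.

#' Triangulate one 3D point from two or more views
#'
#' Builds the homogeneous system with rows `u (p3) - p1` and `v (p3) - p2`
#' per view and takes the right singular vector of the smallest singular value
#' as the homogeneous world point.
#'
#' @param Ps list of 3x4 projection matrices.
#' @param uv matrix (n_views x 2) of observed pixel positions, same order.
#' @return length-3 world point, metres, with attribute `condition` (ratio of
#'   the two smallest singular values); an attribute `unstable = TRUE` flags
#'   near-parallel ray geometry.
#' @export
triangulate <- function(Ps, uv) {
  if (length(Ps) < 2) stop("insufficient views: triangulation needs >= 2")
  uv <- matrix(uv, ncol = 2)
  stopifnot(nrow(uv) == length(Ps))
  A <- matrix(0, 2 * length(Ps), 4)
  for (i in seq_along(Ps)) {
    P <- Ps[[i]]
    A[2 * i - 1, ] <- uv[i, 1] * P[3, ] - P[1, ]
    A[2 * i, ] <- uv[i, 2] * P[3, ] - P[2, ]
  }
  sv <- svd(A, nu = 0, nv = 4)
  Xh <- sv$v[, 4]
  X <- Xh[1:3] / Xh[4]
  cond <- sv$d[4] / max(sv$d[3], .Machine$double.xmin)
  attr(X, "condition") <- cond
  if (sv$d[3] / sv$d[1] < 1e-10) attr(X, "unstable") <- TRUE
  X
}

subset_combinations <- function(cameras) {
  n <- length(cameras)
  if (n > 8) stop("exhaustive subset search is limited to 8 cameras")
  out <- list()
  for (k in seq(2, n)) {
    cmb <- utils::combn(cameras, k, simplify = FALSE)
    out <- c(out, cmb)
  }
  out
}

# triangulate every keypoint of every frame using the given cameras; returns
# the pose data.frame plus the mean reprojection error into contributing views
reconstruct_with <- function(keypoints, matrices, cameras, min_views = 2) {
  sel <- keypoints$camera_id %in% cameras
  if (!any(sel)) return(list(poses = data.frame(), mean_error = NA_real_))
  cam <- keypoints$camera_id[sel]
  frm <- keypoints$frame[sel]
  kpn <- keypoints$keypoint[sel]
  u <- keypoints$u[sel]; v <- keypoints$v[sel]
  rows <- split(seq_along(cam), paste(frm, kpn, sep = "\r"))
  nG <- length(rows)
  rf <- integer(nG); rk <- character(nG); rn <- integer(nG)
  rx <- ry <- rz <- numeric(nG)
  err_sum <- 0; err_n <- 0L
  pi <- 0L
  for (idx in rows) {
    f <- frm[idx[1]]
    Ps <- vector("list", length(idx))
    ok <- logical(length(idx))
    for (j in seq_along(idx)) {
      m <- matrices[[cam[idx[j]]]]
      if (length(m) >= f && !is.null(m[[f]])) {
        Ps[[j]] <- m[[f]]; ok[j] <- TRUE
      }
    }
    if (sum(ok) < min_views) next
    Ps <- Ps[ok]; ii <- idx[ok]
    X <- triangulate(Ps, cbind(u[ii], v[ii]))
    Xh <- c(X, 1)
    for (j in seq_along(Ps)) {
      ph <- Ps[[j]] %*% Xh
      err_sum <- err_sum + sqrt((ph[1] / ph[3] - u[ii[j]])^2 +
                                  (ph[2] / ph[3] - v[ii[j]])^2)
      err_n <- err_n + 1L
    }
    pi <- pi + 1L
    rf[pi] <- f; rk[pi] <- kpn[idx[1]]; rn[pi] <- length(ii)
    rx[pi] <- X[1]; ry[pi] <- X[2]; rz[pi] <- X[3]
  }
  if (pi == 0L) return(list(poses = data.frame(), mean_error = NA_real_))
  out <- data.frame(frame = rf[1:pi], keypoint = rk[1:pi],
                    x = rx[1:pi], y = ry[1:pi], z = rz[1:pi],
                    n_views = rn[1:pi])
  out <- out[order(out$frame, out$keypoint), , drop = FALSE]
  rownames(out) <- NULL
  list(poses = out, mean_error = err_sum / err_n)
}

#' Choose the camera subset minimizing mean reprojection error
#'
#' Every subset of size >= 2 of the candidate cameras is evaluated by
#' triangulating all keypoints over all frames and reprojecting into the
#' subset's own views; the subset with the lowest mean reprojection error is
#' used for the whole trial. Ties go to the larger subset, then to the
#' lexicographically smallest.
#'
#' @param keypoints synchronized keypoint stream (camera_id, frame, keypoint,
#'   u, v).
#' @param matrices per-camera per-frame projection matrices
#'   (`calibrate_trial()$matrices`).
#' @param cameras candidate camera ids (default: all in `matrices`).
#' @param tol relative tolerance within which two subsets count as tied.
#' @return list of class `subset_choice`: `cameras`, `mean_error`, and the
#'   full `evaluated` table (subset, size, mean_error).
#' @export
select_subset <- function(keypoints, matrices, cameras = names(matrices),
                          tol = 1e-9) {
  cameras <- sort(cameras)
  if (length(cameras) < 2) stop("need at least 2 candidate cameras")
  combos <- subset_combinations(cameras)
  ev <- data.frame(subset = vapply(combos, paste, "", collapse = "+"),
                   size = lengths(combos),
                   mean_error = NA_real_)
  for (i in seq_along(combos)) {
    ev$mean_error[i] <- reconstruct_with(keypoints, matrices, combos[[i]])$mean_error
  }
  if (all(is.na(ev$mean_error)))
    stop("no camera subset yields >= 2 views for any keypoint")
  best_err <- min(ev$mean_error, na.rm = TRUE)
  tied <- which(!is.na(ev$mean_error) &
                  ev$mean_error <= best_err + tol * max(best_err, 1))
  tied <- tied[order(-ev$size[tied], ev$subset[tied])]
  pick <- tied[1]
  structure(list(cameras = combos[[pick]], mean_error = ev$mean_error[pick],
                 evaluated = ev),
            class = "subset_choice")
}

#' @export
print.subset_choice <- function(x, ...) {
  cat("subset_choice:", paste(x$cameras, collapse = "+"),
      sprintf("(mean reprojection error %.3f px; %d subsets evaluated)\n",
              x$mean_error, nrow(x$evaluated)))
  invisible(x)
}

#' Reconstruct the 3D pose sequence of a trial
#'
#' Triangulates every keypoint observed in at least `min_views` calibrated
#' views of the chosen camera subset, frame by frame. Keypoints with fewer
#' views are missing for that frame (gaps are recorded, not fatal).
#'
#' @inheritParams select_subset
#' @param cameras the fixed camera subset used for the whole trial.
#' @param min_views minimum contributing views (default 2).
#' @return data.frame (frame, keypoint, x, y, z, n_views), metres.
#' @export
reconstruct_trial <- function(keypoints, matrices, cameras = names(matrices),
                              min_views = 2) {
  reconstruct_with(keypoints, matrices, cameras, min_views)$poses
}

# direct-form II transposed IIR filter with explicit initial state
df2t_filter <- function(b, a, x, zi) {
  nz <- length(b) - 1
  z <- zi
  y <- numeric(length(x))
  for (i in seq_along(x)) {
    yi <- b[1] * x[i] + z[1]
    if (nz > 1) for (k in seq_len(nz - 1))
      z[k] <- b[k + 1] * x[i] + z[k + 1] - a[k + 1] * yi
    z[nz] <- b[nz + 1] * x[i] - a[nz + 1] * yi
    y[i] <- yi
  }
  y
}

# steady-state initial filter state for a unit-amplitude constant input,
# so a constant signal passes through with no start-up transient
lfilter_zi <- function(b, a) {
  n <- length(a)
  A <- rbind(-a[-1], cbind(diag(n - 2), 0))
  B <- b[-1] - a[-1] * b[1]
  solve(diag(n - 1) - t(A), B)
}

#' Zero-phase Butterworth low-pass filter
#'
#' Forward-backward filtering with odd-reflection end padding and
#' steady-state initial conditions at both ends, so constant signals pass
#' through unchanged and there is no start-up transient. The two passes
#' cancel the phase response; the squared magnitude response is applied
#' twice.
#'
#' @param x numeric signal.
#' @param order filter order of each pass.
#' @param wc_norm cut-off frequency normalized to the Nyquist frequency
#'   (in (0, 1)).
#' @return the filtered signal, same length as `x`.
#' @export
butter_filtfilt <- function(x, order, wc_norm) {
  bf <- signal::butter(order, wc_norm, type = "low")
  b <- bf$b; a <- bf$a
  padlen <- min(3 * (length(a) - 1), length(x) - 1)
  if (padlen < 1) return(x)
  zi <- lfilter_zi(b, a)
  pre <- 2 * x[1] - x[seq(padlen + 1, 2)]
  post <- 2 * x[length(x)] - x[seq(length(x) - 1, length(x) - padlen)]
  ext <- c(pre, x, post)
  fwd <- df2t_filter(b, a, ext, zi * ext[1])
  rv <- rev(fwd)
  bwd <- rev(df2t_filter(b, a, rv, zi * rv[1]))
  bwd[seq(padlen + 1, padlen + length(x))]
}

#' Smooth reconstructed trajectories
#'
#' Applies a zero-phase (forward-backward) low-pass Butterworth filter per
#' keypoint and coordinate. Interior gaps up to `max_gap` frames are linearly
#' interpolated before filtering and re-masked afterwards; longer gaps split
#' the trajectory into independently filtered spans.
#'
#' @param poses data.frame from [reconstruct_trial()].
#' @param cutoff low-pass cut-off frequency, Hz (default 10).
#' @param sample_rate frame rate, Hz (default 25).
#' @param order filter order (default 4).
#' @param max_gap longest interior gap (frames) bridged by interpolation.
#' @return `poses` with smoothed coordinates.
#' @export
smooth_trajectories <- function(poses, cutoff = 10, sample_rate = 25,
                                order = 4, max_gap = 5) {
  if (cutoff >= sample_rate / 2) stop("cutoff must be below the Nyquist frequency")
  if (!nrow(poses)) return(poses)
  wc <- cutoff / (sample_rate / 2)
  out <- poses
  for (kp in unique(poses$keypoint)) {
    idx <- which(poses$keypoint == kp)
    d <- poses[idx, ]
    fr <- seq(min(d$frame), max(d$frame))
    pos <- match(fr, d$frame)
    # split into spans separated by gaps longer than max_gap
    present <- !is.na(pos)
    gap_run <- rle(present)
    ends <- cumsum(gap_run$lengths)
    starts <- ends - gap_run$lengths + 1
    breakpts <- which(!gap_run$values & gap_run$lengths > max_gap)
    span_id <- integer(length(fr))
    cur <- 1L
    for (r in seq_along(gap_run$lengths)) {
      if (r %in% breakpts) cur <- cur + 1L
      span_id[starts[r]:ends[r]] <- cur
    }
    for (sp in unique(span_id[present])) {
      sel <- span_id == sp
      fr_sp <- fr[sel]; pos_sp <- pos[sel]
      obs <- which(!is.na(pos_sp))
      if (length(obs) < 2) next
      for (coord in c("x", "y", "z")) {
        v <- d[[coord]][pos_sp]
        vi <- stats::approx(fr_sp[obs], v[obs], xout = fr_sp, rule = 2)$y
        vs <- butter_filtfilt(vi, order, wc)
        out[[coord]][idx[pos_sp[obs]]] <- vs[obs]
      }
    }
  }
  out
}
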