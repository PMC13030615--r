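# Frame-wise camera calibration by the Direct Linear Transformation: the
# 3x4 projection matrix is the SVD null-space solution of the homogeneous
# system built from >= 6 world-to-image correspondences, with Hartley-style
# isotropic normalization for conditioning, iterative rejection of
# correspondences with large reprojection error, and restriction to the
# reference points nearest the skier.

normalize_2d <- function(x) {
  ctr <- colMeans(x)
  d <- sqrt(rowSums(sweep(x, 2, ctr)^2))
  s <- sqrt(2) / max(mean(d), .Machine$double.eps)
  T <- matrix(c(s, 0, -s * ctr[1], 0, s, -s * ctr[2], 0, 0, 1), 3, 3, byrow = TRUE)
  list(T = T, x = sweep(x, 2, ctr) * s)
}

normalize_3d <- function(X) {
  ctr <- colMeans(X)
  d <- sqrt(rowSums(sweep(X, 2, ctr)^2))
  s <- sqrt(3) / max(mean(d), .Machine$double.eps)
  U <- diag(c(s, s, s, 1))
  U[1:3, 4] <- -s * ctr
  list(U = U, X = sweep(X, 2, ctr) * s)
}

#' Estimate a projection matrix by DLT
#'
#' Solves the homogeneous system with two rows per correspondence,
#' `u (p3 . X) - p1 . X = 0` and `v (p3 . X) - p2 . X = 0`, for the 12 entries
#' of P as the right singular vector of the smallest singular value. Points
#' are isotropically normalized before solving and the solution denormalized.
#' The result is scaled to unit Frobenius norm with the sign chosen so the
#' calibration points have positive projective depth.
#'
#' @param world n x 3 matrix of surveyed positions, metres.
#' @param image n x 2 matrix of observed pixel positions.
#' @return 3x4 projection matrix.
#' @export
estimate_dlt <- function(world, image) {
  world <- as.matrix(world); image <- as.matrix(image)
  n <- nrow(world)
  if (n < 6) stop("insufficient correspondences: DLT needs at least 6 points")
  stopifnot(nrow(image) == n, ncol(world) == 3, ncol(image) == 2)
  n2 <- normalize_2d(image)
  n3 <- normalize_3d(world)
  Xh <- cbind(n3$X, 1)
  A <- matrix(0, 2 * n, 12)
  A[seq(1, 2 * n, 2), 1:4] <- -Xh
  A[seq(1, 2 * n, 2), 9:12] <- n2$x[, 1] * Xh
  A[seq(2, 2 * n, 2), 5:8] <- -Xh
  A[seq(2, 2 * n, 2), 9:12] <- n2$x[, 2] * Xh
  sv <- svd(A, nu = 0, nv = 12)
  if (sv$d[11] / sv$d[1] < 1e-8)
    stop("degenerate configuration: correspondences are (near-)coplanar")
  Pn <- matrix(sv$v[, 12], 3, 4, byrow = TRUE)
  P <- solve(n2$T) %*% Pn %*% n3$U
  P <- P / sqrt(sum(P^2))
  depths <- cbind(world, 1) %*% P[3, ]
  if (stats::median(sign(depths)) < 0) P <- -P
  structure(P, class = c("projection_matrix", class(P)))
}

#' Per-correspondence reprojection errors
#'
#' Euclidean pixel distance between each observed image point and the
#' dehomogenized projection of its world point. Points with non-positive
#' projective depth (behind the camera) get an infinite error.
#'
#' @param P 3x4 projection matrix.
#' @param world n x 3 world points, metres.
#' @param image n x 2 observed pixels.
#' @return numeric vector of pixel errors.
#' @export
reprojection_errors <- function(P, world, image) {
  pr <- project_points(P, as.matrix(world))
  err <- sqrt((pr[, "u"] - image[, 1])^2 + (pr[, "v"] - image[, 2])^2)
  err[pr[, "depth"] <= 0] <- Inf
  unname(err)
}

#' Iterative rejection of outlying correspondences
#'
#' Fits the DLT, then repeatedly removes the correspondence with the largest
#' reprojection error, keeping a removal only while it lowers the mean
#' reprojection error of the remaining set by at least `improvement` (relative)
#' and at least `min_points` correspondences remain.
#'
#' @param world,image correspondence matrices as in [estimate_dlt()].
#' @param min_points floor on the retained set size (default 6).
#' @param improvement minimum relative decrease of the mean reprojection error
#'   for a removal to be accepted (default 0.05). Because the criterion is
#'   relative it is scale-free, so rejection stops outright once the mean
#'   error falls below 1e-6 px: at that level remaining differences are
#'   floating-point noise, not outliers.
#' @return list: `P` (final matrix), `inliers` (integer indices kept),
#'   `rejected` (indices removed), `mean_error` (pixels, final set).
#' @export
reject_outliers <- function(world, image, min_points = 6, improvement = 0.05) {
  world <- as.matrix(world); image <- as.matrix(image)
  keep <- seq_len(nrow(world))
  P <- estimate_dlt(world, image)
  err <- reprojection_errors(P, world, image)
  mean_err <- mean(err)
  while (length(keep) > min_points && (!is.finite(mean_err) || mean_err > 1e-6)) {
    worst <- keep[which.max(err[keep])]
    trial <- setdiff(keep, worst)
    Pt <- tryCatch(estimate_dlt(world[trial, , drop = FALSE], image[trial, , drop = FALSE]),
                   error = function(e) NULL)
    if (is.null(Pt)) break
    errt <- reprojection_errors(Pt, world[trial, , drop = FALSE], image[trial, , drop = FALSE])
    if (!is.finite(mean_err) || mean(errt) <= (1 - improvement) * mean_err) {
      keep <- trial; P <- Pt
      full_err <- rep(Inf, nrow(world))
      full_err[trial] <- errt
      err <- full_err
      mean_err <- mean(errt)
    } else break
  }
  list(P = P, inliers = keep, rejected = setdiff(seq_len(nrow(world)), keep),
       mean_error = mean_err)
}

#' Select the reference points nearest the skier
#'
#' Calibration accuracy matters most near the athlete, so only the `k`
#' identified reference points with the smallest image distance to the skier
#' bounding-box centroid are used per frame. All are returned when fewer than
#' `k` are available, or when no centroid is known for the frame.
#'
#' @param refs identified detections of one camera-frame (columns cx, cy,
#'   non-NA ref_id).
#' @param skier_centroid length-2 pixel position, or NULL when unavailable.
#' @param k number of points to keep (default 15).
#' @return the selected rows of `refs`.
#' @export
select_nearest <- function(refs, skier_centroid, k = 15) {
  refs <- refs[!is.na(refs$ref_id), , drop = FALSE]
  if (is.null(skier_centroid) || anyNA(skier_centroid)) return(refs)
  if (nrow(refs) <= k) return(refs)
  d <- (refs$cx - skier_centroid[1])^2 + (refs$cy - skier_centroid[2])^2
  refs[order(d)[seq_len(k)], , drop = FALSE]
}

#' Frame-wise calibration of a whole trial
#'
#' For every camera and frame: keep the identified reference detections, pick
#' the `k` nearest the skier, join them to the surveyed table, and run the
#' DLT with iterative outlier rejection. Frames retaining fewer than
#' `min_points` valid reference points are excluded.
#'
#' @param refs processed reference detections (from [associate_refpoints()] or
#'   resampled equivalents), all cameras.
#' @param surveyed surveyed-point table (ref_id, x, y, z).
#' @param skier_bbox per camera-frame skier centroid (columns camera_id,
#'   frame, cx, cy); optional.
#' @param k nearest-point count (default 15).
#' @param min_points exclusion floor (default 6).
#' @param improvement outlier-rejection stopping threshold (default 0.05).
#' @return list: `matrices[[camera_id]][[frame]]` (3x4 matrix or NULL) and
#'   `report` data.frame (camera_id, frame, status, n_used, n_rejected,
#'   mean_error, rejected_ref_ids as comma string).
#' @export
calibrate_trial <- function(refs, surveyed, skier_bbox = NULL,
                            k = 15, min_points = 6, improvement = 0.05) {
  cams <- sort(unique(refs$camera_id))
  frames <- seq(min(refs$frame), max(refs$frame))
  matrices <- list()
  rep_rows <- list()
  for (cid in cams) {
    rc <- refs[refs$camera_id == cid & !is.na(refs$ref_id), , drop = FALSE]
    mats <- vector("list", max(frames))
    for (f in frames) {
      rf <- rc[rc$frame == f, , drop = FALSE]
      ctr <- NULL
      if (!is.null(skier_bbox)) {
        sb <- skier_bbox[skier_bbox$camera_id == cid & skier_bbox$frame == f, , drop = FALSE]
        if (nrow(sb)) ctr <- c(sb$cx[1], sb$cy[1])
      }
      sel <- select_nearest(rf, ctr, k)
      m <- match(sel$ref_id, surveyed$ref_id)
      sel <- sel[!is.na(m), , drop = FALSE]
      m <- m[!is.na(m)]
      if (nrow(sel) < min_points) {
        rep_rows[[length(rep_rows) + 1]] <- data.frame(
          camera_id = cid, frame = f, status = "excluded",
          n_used = nrow(sel), n_rejected = 0L, mean_error = NA_real_,
          rejected_ref_ids = "")
        next
      }
      world <- as.matrix(surveyed[m, c("x", "y", "z")])
      image <- cbind(sel$cx, sel$cy)
      res <- tryCatch(
        reject_outliers(world, image, min_points, improvement),
        error = function(e) NULL)
      if (is.null(res)) {
        rep_rows[[length(rep_rows) + 1]] <- data.frame(
          camera_id = cid, frame = f, status = "excluded",
          n_used = nrow(sel), n_rejected = 0L, mean_error = NA_real_,
          rejected_ref_ids = "")
        next
      }
      mats[[f]] <- res$P
      rep_rows[[length(rep_rows) + 1]] <- data.frame(
        camera_id = cid, frame = f, status = "calibrated",
        n_used = length(res$inliers), n_rejected = length(res$rejected),
        mean_error = res$mean_error,
        rejected_ref_ids = paste(sel$ref_id[res$rejected], collapse = ","))
    }
    matrices[[cid]] <- mats
  }
  report <- do.call(rbind, rep_rows)
  rownames(report) <- NULL
  list(matrices = matrices, report = report)
}
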