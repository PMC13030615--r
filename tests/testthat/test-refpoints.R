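# Reference-point association: overlap filtering, containment matching,
# shift estimation and temporal identity recovery.

mkbox <- function(frame, cx, cy, half = 10, ref = NULL) {
  b <- data.frame(frame = frame, cx = cx, cy = cy,
                  x_min = cx - half, y_min = cy - half,
                  x_max = cx + half, y_max = cy + half)
  if (!is.null(ref)) { b$ref_id <- ref; b$provenance <- "direct" }
  b
}

test_that("box IoU matches hand-computed values", {
  a <- c(x_min = 0, y_min = 0, x_max = 3, y_max = 1)
  b <- c(x_min = 1, y_min = 0, x_max = 4, y_max = 1)
  expect_equal(box_iou(a, b), 0.5)          # inter 2, union 4
  expect_equal(box_iou(a, a), 1)
  expect_equal(box_iou(a, a + c(10, 0, 10, 0)), 0)
})

test_that("overlap filtering removes both members of a pair, strictly above threshold", {
  boxes <- rbind(mkbox(1, 100, 100), mkbox(1, 103, 100), mkbox(1, 300, 300))
  kept <- discard_overlaps(boxes, 0.5)
  expect_equal(nrow(kept), 1)
  expect_equal(kept$cx, 300)
  # IoU exactly at the threshold is kept (strict >)
  edge <- data.frame(x_min = c(0, 1), y_min = 0, x_max = c(3, 4), y_max = 1,
                     cx = c(1.5, 2.5), cy = 0.5, frame = 1)
  expect_equal(nrow(discard_overlaps(edge, 0.5)), 2)
  expect_equal(nrow(discard_overlaps(edge, 0.49)), 0)
})

test_that("identifications attach by containment with nearest-centroid tie-break", {
  boxes <- rbind(mkbox(1, 100, 100), mkbox(1, 112, 100), mkbox(1, 300, 300))
  ids <- data.frame(ref_id = 7L, mx = 104, my = 100)  # inside both left boxes
  out <- match_ids(boxes, ids)
  expect_equal(out$ref_id, c(7L, NA, NA))
  expect_equal(out$provenance, c("direct", "unidentified", "unidentified"))
})

test_that("a box containing two different ids is discarded as a conflict", {
  boxes <- rbind(mkbox(1, 100, 100), mkbox(1, 300, 300))
  ids <- data.frame(ref_id = c(1L, 2L), mx = c(98, 102), my = c(100, 100))
  out <- match_ids(boxes, ids)
  expect_equal(nrow(out), 1)
  expect_equal(out$cx, 300)
})

test_that("duplicate ids across boxes keep only the first assignment", {
  boxes <- rbind(mkbox(1, 100, 100), mkbox(1, 300, 300))
  ids <- data.frame(ref_id = c(4L, 4L), mx = c(100, 300), my = c(100, 300))
  out <- match_ids(boxes, ids)
  expect_equal(out$ref_id, c(4L, NA))
})

test_that("shift estimation is exact for a translation and robust to one outlier", {
  prev <- mkbox(1, c(10, 50, 90, 130), c(20, 60, 40, 80), ref = 1:4)
  curr <- prev
  curr$cx <- prev$cx + 7; curr$cy <- prev$cy - 3
  sh <- estimate_shift(prev, curr)
  expect_equal(as.numeric(sh), c(7, -3))
  expect_equal(attr(sh, "residual_mad"), 0)
  curr$cx[2] <- curr$cx[2] + 500  # one mis-tracked cube
  sh2 <- estimate_shift(prev, curr)
  expect_equal(as.numeric(sh2), c(7, -3))
  expect_null(estimate_shift(prev, mkbox(1, 1, 1, ref = 99L)))
})

test_that("temporal recovery fills in an unidentified box near the projection", {
  prev <- mkbox(1, c(100, 200), c(100, 100), ref = c(1L, 2L))
  curr <- rbind(mkbox(2, 105, 100, ref = 1L),
                mkbox(2, 205, 100, ref = NA_integer_))
  curr$provenance[2] <- "unidentified"
  out <- temporal_recover(prev, curr, structure(c(5, 0), residual_mad = 0))
  expect_equal(out$ref_id, c(1L, 2L))
  expect_equal(out$provenance, c("direct", "recovered"))
})

test_that("recovery respects the radius and never reassigns identified boxes", {
  prev <- mkbox(1, 100, 100, ref = 3L)
  far <- mkbox(2, 400, 100)
  far$ref_id <- NA_integer_; far$provenance <- "unidentified"
  out <- temporal_recover(prev, far, structure(c(0, 0), residual_mad = 0),
                          radius = 20)
  expect_true(is.na(out$ref_id))
  # an already-identified box keeps its id even if the projection lands on it
  ided <- mkbox(2, 100, 100, ref = 9L)
  out2 <- temporal_recover(prev, ided, structure(c(0, 0), residual_mad = 0))
  expect_equal(out2$ref_id, 9L)
})

test_that("recovery assignment is one-to-one, nearest pair first", {
  prev <- mkbox(1, c(100, 130), c(100, 100), ref = c(1L, 2L))
  curr <- mkbox(2, c(102, 131), c(100, 100))
  curr$ref_id <- NA_integer_; curr$provenance <- "unidentified"
  out <- temporal_recover(prev, curr, structure(c(0, 0), residual_mad = 0),
                          radius = 50)
  expect_equal(out$ref_id, c(1L, 2L))
})

test_that("association on a clean scene reproduces the true identities", {
  b <- clean_bundle()
  cam <- b$boxes[b$boxes$camera_id == "cam01", ]
  ids <- b$identifications[b$identifications$camera_id == "cam01", ]
  out <- associate_refpoints(cam, ids)
  expect_true(all(!is.na(out$ref_id)))
  expect_true(all(out$ref_id == out$true_ref_id))
})

test_that("identity recovery under dropout exceeds 95 percent with few wrong ids", {
  cfg <- scene_config(n_cameras = 2, n_refpoints = 120, n_frames = 60,
                      id_dropout_prob = 0.3, pixel_noise_sd = 1, rng_seed = 5)
  b <- cached_scene("dropout", cfg)
  rates <- lapply(unique(b$boxes$camera_id), function(cid) {
    out <- associate_refpoints(b$boxes[b$boxes$camera_id == cid, ],
                               b$identifications[b$identifications$camera_id == cid, ])
    assigned <- !is.na(out$ref_id)
    c(rate = mean(assigned),
      wrong = mean(out$ref_id[assigned] != out$true_ref_id[assigned]))
  })
  for (r in rates) {
    expect_gte(r[["rate"]], 0.95)
    expect_lte(r[["wrong"]], 0.01)
  }
})

test_that("the backward pass recovers a cube unidentified on entry", {
  # id observed only at the later frame: forward-only cannot recover frame 1
  boxes <- rbind(mkbox(1, c(100, 200), c(50, 50)),
                 mkbox(2, c(110, 210), c(50, 50)))
  ids <- data.frame(frame = c(1L, 2L, 2L), ref_id = c(1L, 1L, 2L),
                    mx = c(100, 110, 210), my = 50)
  fw <- associate_refpoints(boxes, ids, direction = "forward", radius = 30)
  expect_true(is.na(fw$ref_id[fw$frame == 1 & fw$cx == 200]))
  both <- associate_refpoints(boxes, ids, radius = 30)
  expect_equal(both$ref_id[both$frame == 1 & both$cx == 200], 2L)
  expect_equal(both$provenance[both$frame == 1 & both$cx == 200], "recovered")
})
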