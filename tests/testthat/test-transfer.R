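test_that("project_bbox is exact for identity and pure translations", {
  box <- bbox_prompt(10, 30, 20, 60)
  idH <- diag(3)
  out <- project_bbox(box, idH, c(200, 200))
  expect_equal(unclass(out), unclass(box))

  tr <- diag(3); tr[1, 3] <- 10; tr[2, 3] <- 5
  out2 <- project_bbox(box, tr, c(200, 200))
  expect_equal(c(out2$x0, out2$x1, out2$y0, out2$y1), c(20, 30, 35, 65))
})

test_that("rotated boxes produce the envelope of their projected corners", {
  box <- bbox_prompt(10, 30, 20, 60)
  H <- maskwork:::build_transform(c(128, 128), angle = pi / 2)
  out <- project_bbox(box, H, c(128, 128))
  # oracle: map the envelope corners explicitly and take the integer cover
  corners <- rbind(c(9.5, 29.5), c(19.5, 29.5), c(19.5, 59.5), c(9.5, 59.5))
  pc <- apply_homography(H, corners)
  expect_equal(out$x0, floor(min(pc[, 1]) + 0.5))
  expect_equal(out$x1, ceiling(max(pc[, 1]) + 0.5))
  expect_equal(out$y0, floor(min(pc[, 2]) + 0.5))
  expect_equal(out$y1, ceiling(max(pc[, 2]) + 0.5))
})

test_that("boxes leaving the frame yield a drop signal, not an error", {
  box <- bbox_prompt(10, 10, 20, 20)
  far <- diag(3); far[1, 3] <- 500
  expect_null(project_bbox(box, far, c(100, 100)))
  # mostly outside: below the default 25% inside fraction
  edge <- diag(3); edge[1, 3] <- 88
  expect_null(project_bbox(box, edge, c(100, 100)))
  # more than a quarter inside: clipped, not dropped
  edge2 <- diag(3); edge2[1, 3] <- 85
  kept <- project_bbox(box, edge2, c(100, 100))
  expect_equal(kept$x1, 100)
})

test_that("projecting forward then backward contains the original box", {
  H <- maskwork:::build_transform(c(256, 256), dx = 7.3, dy = -4.1,
                                  angle = 0.2, projective = c(1e-5, -1e-5))
  box <- bbox_prompt(40, 60, 90, 120)
  there <- project_bbox(box, H, c(400, 400))
  back <- project_bbox(there, solve(H), c(400, 400))
  expect_lte(back$x0, box$x0); expect_gte(back$x1, box$x1)
  expect_lte(back$y0, box$y0); expect_gte(back$y1, box$y1)
})

test_that("self-registration recovers the identity", {
  sc <- generate_scene(scene_params(image_shape = c(256, 256),
                                    n_instances = 10), seed = 21)
  est <- estimate_homography(sc$image, sc$image)
  expect_lt(est$mean_reprojection_error, 0.5)
  corners <- rbind(c(0, 0), c(255, 0), c(255, 255), c(0, 255))
  expect_lt(max(abs(apply_homography(est$H, corners) - corners)), 0.5)
})

test_that("a known synthetic warp is recovered to sub-pixel corner error", {
  sc <- make_scene_pair(seed = 31, shape = c(256, 256), n = 12)
  est <- estimate_homography(sc$image, sc$paired_image)
  corners <- rbind(c(0, 0), c(255, 0), c(255, 255), c(0, 255))
  err <- sqrt(rowSums((apply_homography(est$H, corners) -
                         apply_homography(sc$true_homography_to_pair, corners))^2))
  expect_lt(max(err), 1)
  expect_gte(est$inlier_count, 4)
})

test_that("featureless images fail at the detection stage", {
  flat <- matrix(0.5, 128, 128)
  err <- tryCatch(estimate_homography(flat, flat), error = identity)
  expect_s3_class(err, "maskwork_detection_error")
  expect_match(conditionMessage(err), "detection")
})

test_that("identity transfer with an oracle segmenter reproduces the source", {
  sc <- generate_scene(scene_params(image_shape = c(192, 192),
                                    n_instances = 8), seed = 13)
  seg <- oracle_segmenter(scene_gt_provider(list(sc)))
  img_b <- sc$image
  attr(img_b, "image_id") <- sc$gt$image_id
  report <- transfer_masks(sc$gt, sc$image, img_b, seg,
                           params = list(homography = diag(3)))
  expect_equal(nrow(report$dropped), 0)
  expect_identical(report$transferred$instances, sc$gt$instances)
  expect_identical(report$transferred$instance_ids, sc$gt$instance_ids)
})

test_that("instance ids map bijectively onto transferred plus dropped", {
  sc <- make_scene_pair(seed = 17, shape = c(192, 192), n = 8, dx = 60, dy = 40,
                        angle = 0)
  seg <- oracle_segmenter(scene_gt_provider(list(sc)))
  report <- transfer_masks(sc$gt, sc$image, sc$paired_image, seg,
                           params = list(homography = sc$true_homography_to_pair))
  got <- sort(c(report$transferred$instance_ids, report$dropped$instance_id))
  expect_equal(got, sort(sc$gt$instance_ids))
})

test_that("empty sources and empty segmentations are reported cleanly", {
  sc <- generate_scene(scene_params(image_shape = c(128, 128),
                                    n_instances = 4), seed = 5)
  seg <- oracle_segmenter(scene_gt_provider(list(sc)))
  empty <- mask_set(image_shape = c(128, 128), image_id = "none")
  rep0 <- transfer_masks(empty, sc$image, sc$image, seg,
                         params = list(homography = diag(3)))
  expect_equal(n_instances(rep0$transferred), 0)
  expect_equal(nrow(rep0$dropped), 0)

  always_empty <- function(image, points = NULL, box = NULL) blank(128, 128)
  rep1 <- transfer_masks(sc$gt, sc$image, sc$image, always_empty,
                         params = list(homography = diag(3)))
  expect_equal(n_instances(rep1$transferred), 0)
  expect_equal(nrow(rep1$dropped), 4)
  expect_match(rep1$dropped$reason, "empty")
})

test_that("transfer scoring judges quality on the target image only", {
  sc <- generate_scene(scene_params(image_shape = c(160, 160),
                                    n_instances = 4), seed = 19)
  ref <- sc$gt
  # half-good fixture: two exact copies, two badly eroded ones
  bad <- lapply(ref$instances[3:4], function(m) {
    idx <- which(m)
    out <- blank(160, 160); out[idx[seq_len(ceiling(length(idx) / 3))]] <- TRUE
    out
  })
  report <- structure(list(
    transferred = mask_set(c(ref$instances[1:2], bad),
                           image_shape = c(160, 160)),
    dropped = data.frame(instance_id = integer(0), reason = character(0)),
    homography = diag(3)), class = "transfer_report")
  out <- score_transfer(report, ref, 0.8)
  pr <- precision_recall(out)
  expect_equal(pr$recall, 0.5)

  all_dropped <- structure(list(
    transferred = mask_set(image_shape = c(160, 160)),
    dropped = data.frame(instance_id = ref$instance_ids, reason = "x"),
    homography = diag(3)), class = "transfer_report")
  out2 <- score_transfer(all_dropped, ref, 0.8)
  expect_equal(out2$fn, 4)
  expect_equal(precision_recall(out2)$recall, 0)
})
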