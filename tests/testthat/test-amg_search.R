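test_that("grid expansion covers the Cartesian product in stable order", {
  expect_equal(nrow(expand_amg_grid(amg_grid_spec())), 729)

  single <- amg_grid_spec(points_per_side = 32, pred_iou_thresh = 0.8,
                          stability_score_thresh = 0.95,
                          stability_score_offset = 1, crop_n_layers = 0,
                          crop_n_points_downscale_factor = 1)
  expect_equal(nrow(expand_amg_grid(single)), 1)

  small <- amg_grid_spec(points_per_side = c(16, 32), pred_iou_thresh = c(0.7, 0.8, 0.9),
                         stability_score_thresh = 0.95,
                         stability_score_offset = 1, crop_n_layers = 0,
                         crop_n_points_downscale_factor = 1)
  g <- expand_amg_grid(small)
  expect_equal(nrow(g), 6)
  # lexicographic in canonical field order: first field varies slowest
  expect_equal(g$points_per_side, rep(c(16, 32), each = 3))
  expect_equal(g$pred_iou_thresh, rep(c(0.7, 0.8, 0.9), 2))
  expect_equal(g$config_id, 1:6)

  spec <- amg_grid_spec(points_per_side = c(8, 16, 24),
                        stability_score_offset = c(1, 1.3))
  expect_equal(nrow(expand_amg_grid(spec)), 3 * 1 * 3 * 3 * 2 * 3 * 3)

  expect_error(amg_grid_spec(points_per_side = numeric(0)), "nonempty")
  expect_error(amg_grid_spec(pred_iou_thresh = 1.2), "0, 1")
})

test_that("grid specs load from YAML and JSON", {
  spec <- amg_grid_spec(points_per_side = c(16, 32))
  ypath <- tempfile(fileext = ".yaml"); jpath <- tempfile(fileext = ".json")
  on.exit(unlink(c(ypath, jpath)))
  yaml::write_yaml(unclass(spec), ypath)
  jsonlite::write_json(unclass(spec), jpath)
  expect_equal(expand_amg_grid(read_grid_spec(ypath)),
               expand_amg_grid(spec))
  expect_equal(expand_amg_grid(read_grid_spec(jpath)),
               expand_amg_grid(spec))
  yaml::write_yaml(list(points_per_side = 32), ypath)
  expect_error(read_grid_spec(ypath), "misses")
})

small_scenes <- function(n_images = 2, n_instances = 5, seed = 40,
                         shape = c(96, 96)) {
  lapply(seq_len(n_images), function(k) {
    sc <- generate_scene(scene_params(image_shape = shape,
                                      n_instances = n_instances,
                                      instance_radius_range = c(6, 10)),
                         seed = seed + k)
    list(image = sc$image, gt = sc$gt)
  })
}

echo_backend <- function(provider) {
  function(image, config, seed = NULL) provider(attr(image, "image_id"))$instances
}

test_that("point-prompt evaluation scores every instance once", {
  scenes <- small_scenes(2, 4)
  provider <- scene_gt_provider(lapply(scenes, `[[`, "gt"))
  ev <- evaluate_point_prompts(oracle_segmenter(provider), scenes)
  expect_equal(ev$n_prompts, 8)
  expect_equal(nrow(ev$scores), 8)
  expect_equal(ev$scores$gds, rep(1, 8))
  expect_equal(nrow(ev$failures), 0)
})

test_that("imperfect segmenters score below 1 and failures are recorded", {
  scenes <- small_scenes(1, 5)
  provider <- scene_gt_provider(lapply(scenes, `[[`, "gt"))
  oracle <- oracle_segmenter(provider)
  eroding <- function(image, points = NULL, box = NULL) {
    m <- oracle(image, points = points, box = box)
    EBImage::erode(m * 1, EBImage::makeBrush(3, "box")) > 0
  }
  ev <- evaluate_point_prompts(eroding, scenes)
  expect_lt(ev$mean_gds, 1)
  expect_gt(ev$mean_gds, 0)

  flaky <- local({
    calls <- 0
    function(image, points = NULL, box = NULL) {
      calls <<- calls + 1
      if (calls == 2) stop("backend crash")
      oracle(image, points = points, box = box)
    }
  })
  ev2 <- evaluate_point_prompts(flaky, scenes)
  expect_equal(nrow(ev2$failures), 1)
  expect_equal(nrow(ev2$scores), 4)
  expect_match(ev2$failures$error, "crash")
})

test_that("the harness adds no bias: a ground-truth echo backend scores F2 = 1", {
  scenes <- small_scenes(2, 4)
  provider <- scene_gt_provider(lapply(scenes, `[[`, "gt"))
  backend <- echo_backend(provider)
  for (cfg in list(list(points_per_side = 32), list(points_per_side = 128,
                                                    crop_n_layers = 2))) {
    res <- evaluate_config(backend, scenes, cfg)
    expect_equal(res$per_image_f, rep(1, 2))
  }
})

test_that("spurious proposals depress precision exactly as the closed form predicts", {
  scenes <- small_scenes(1, 5)
  provider <- scene_gt_provider(lapply(scenes, `[[`, "gt"))
  k <- 3
  backend <- mock_proposal_backend(provider, quality = 1, spurious_rate = k,
                                   seed = 9)
  res <- evaluate_config(backend, scenes, list(points_per_side = 32))
  n <- 5
  p <- n / (n + k)
  expect_equal(res$mean_f, 5 * p / (4 * p + 1), tolerance = 1e-12)

  nothing <- function(image, config, seed = NULL) list()
  expect_equal(evaluate_config(nothing, scenes, list())$mean_f, 0)
})

test_that("grid search ranks a planted optimum first and is deterministic", {
  scenes <- small_scenes(2, 5)
  provider <- scene_gt_provider(lapply(scenes, `[[`, "gt"))
  spec <- amg_grid_spec(points_per_side = c(16, 32, 64),
                        pred_iou_thresh = c(0.72, 0.88),
                        stability_score_thresh = 0.95,
                        stability_score_offset = 1, crop_n_layers = 0,
                        crop_n_points_downscale_factor = 1)
  quality_fun <- function(cfg) {
    c("16" = 0.55, "32" = 0.95, "64" = 0.75)[as.character(cfg$points_per_side)]
  }
  backend <- mock_proposal_backend(provider, quality = quality_fun, seed = 4)
  res <- run_grid_search(backend, scenes, spec, seed = 11)
  expect_equal(nrow(res$entries) + nrow(res$failures), nrow(res$grid))
  expect_equal(res$ranking$points_per_side[1], 32)
  expect_equal(sort(res$ranking$config_id), sort(res$entries$config_id))

  res2 <- run_grid_search(backend, scenes, spec, seed = 11)
  expect_identical(res$ranking$mean_f, res2$ranking$mean_f)
})

test_that("grid-search ranking tracks expected scores across a quality gradient", {
  scenes <- small_scenes(2, 5)
  provider <- scene_gt_provider(lapply(scenes, `[[`, "gt"))
  spec <- amg_grid_spec(points_per_side = c(8, 16, 32, 64, 128),
                        pred_iou_thresh = 0.8, stability_score_thresh = 0.95,
                        stability_score_offset = 1, crop_n_layers = 0,
                        crop_n_points_downscale_factor = 1)
  # spurious count falls as points_per_side grows -> expected F2 rises
  spurious_fun <- function(cfg) {
    c("8" = 8, "16" = 5, "32" = 3, "64" = 1, "128" = 0)[
      as.character(cfg$points_per_side)]
  }
  backend <- mock_proposal_backend(provider, quality = 1,
                                   spurious_rate = spurious_fun, seed = 2)
  res <- run_grid_search(backend, scenes, spec, seed = 5)
  expected_order <- order(c(8, 16, 32, 64, 128), decreasing = TRUE)
  rho <- cor(match(res$ranking$points_per_side, c(8, 16, 32, 64, 128)),
             expected_order, method = "spearman")
  expect_gt(rho, 0.9)
})

test_that("backend failures are collected without stopping the search", {
  scenes <- small_scenes(1, 4)
  provider <- scene_gt_provider(lapply(scenes, `[[`, "gt"))
  spec <- amg_grid_spec(points_per_side = c(16, 32),
                        pred_iou_thresh = c(0.72, 0.88),
                        stability_score_thresh = 0.95,
                        stability_score_offset = 1, crop_n_layers = 0,
                        crop_n_points_downscale_factor = 1)
  failing <- function(image, config, seed = NULL) {
    if (config$points_per_side == 32 && config$pred_iou_thresh == 0.72) {
      stop("proposal generator crashed")
    }
    provider(attr(image, "image_id"))$instances
  }
  res <- run_grid_search(failing, scenes, spec)
  expect_equal(nrow(res$entries), 3)
  expect_equal(nrow(res$failures), 1)
  expect_match(res$failures$error, "crashed")
  expect_equal(res$failures$points_per_side, 32)

  all_fail <- function(image, config, seed = NULL) stop("nope")
  res2 <- run_grid_search(all_fail, scenes, spec)
  expect_equal(nrow(res2$ranking), 0)
  expect_equal(nrow(res2$failures), 4)
})
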