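# Independent brute-force oracles and tiny fixture builders. These stay
# deliberately naive — element loops and direct formula transcriptions — so
# they share no code path with the implementation they check.

blank <- function(h, w = h) matrix(FALSE, h, w)

# random blob mask: a few overlapping discs, possibly empty
random_blob_mask <- function(h, w = h, n_discs = sample(1:3, 1)) {
  m <- blank(h, w)
  for (k in seq_len(n_discs)) {
    cx <- runif(1, 0, w - 1); cy <- runif(1, 0, h - 1); r <- runif(1, 1, h / 4)
    for (row in seq_len(h)) {
      for (col in seq_len(w)) {
        if ((col - 1 - cx)^2 + (row - 1 - cy)^2 <= r^2) m[row, col] <- TRUE
      }
    }
  }
  m
}

# pixelwise IoU by explicit counting
iou_bruteforce <- function(a, b) {
  inter <- 0; uni <- 0
  for (i in seq_along(a)) {
    if (a[i] && b[i]) inter <- inter + 1
    if (a[i] || b[i]) uni <- uni + 1
  }
  if (uni == 0) 0 else inter / uni
}

# direct transcription of the two-class generalized Dice formula with
# inverse-square class weights; empty classes dropped
gds_bruteforce <- function(gt, pred) {
  num <- 0; den <- 0
  for (cls in 1:2) {
    g <- if (cls == 1) gt else !gt
    p <- if (cls == 1) pred else !pred
    ng <- sum(g)
    if (ng == 0) next
    w <- 1 / ng^2
    num <- num + w * sum(p * g)
    den <- den + w * (sum(p) + sum(g))
  }
  2 * num / den
}

# existential matching by full double loop
match_bruteforce <- function(gt_masks, pred_masks, thr = 0.8) {
  tp <- 0; fn <- 0
  pred_used <- rep(FALSE, length(pred_masks))
  for (g in gt_masks) {
    hit <- FALSE
    for (j in seq_along(pred_masks)) {
      v <- iou_bruteforce(g, pred_masks[[j]])
      if (v > thr) {
        hit <- TRUE
        pred_used[j] <- TRUE
      }
    }
    if (hit) tp <- tp + 1 else fn <- fn + 1
  }
  list(tp = tp, fn = fn, fp = sum(!pred_used))
}

# summed Euclidean distance from a point to all foreground pixel centers
median_objective <- function(mask, x, y) {
  idx <- which(mask, arr.ind = TRUE)
  sum(sqrt((idx[, 2] - 0.5 - x)^2 + (idx[, 1] - 0.5 - y)^2))
}

# exhaustive argmin of the geometric-median objective over foreground pixels,
# row-major tie-break
median_pixel_bruteforce <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  best <- NULL; best_val <- Inf
  for (k in seq_len(nrow(idx))) {
    v <- median_objective(mask, idx[k, 2] - 0.5, idx[k, 1] - 0.5)
    if (v < best_val - 1e-12) {
      best_val <- v
      best <- c(x = idx[k, 2] - 1L, y = idx[k, 1] - 1L)
    }
  }
  list(px = best, value = best_val)
}

# even-odd crossing-count point-in-polygon with boundary points inside
point_in_polygon_oracle <- function(px, py, xs, ys, eps = 1e-9) {
  n <- length(xs)
  crossings <- 0
  for (i in seq_len(n)) {
    j <- if (i == n) 1 else i + 1
    x1 <- xs[i]; y1 <- ys[i]; x2 <- xs[j]; y2 <- ys[j]
    # on-segment test (boundary counts as inside)
    dx <- x2 - x1; dy <- y2 - y1
    cross <- (px - x1) * dy - (py - y1) * dx
    if (abs(cross) < eps &&
        px >= min(x1, x2) - eps && px <= max(x1, x2) + eps &&
        py >= min(y1, y2) - eps && py <= max(y1, y2) + eps) {
      return(TRUE)
    }
    if ((y1 > py) != (y2 > py)) {
      x_int <- x1 + (py - y1) / (y2 - y1) * dx
      if (x_int > px) crossings <- crossings + 1
    }
  }
  crossings %% 2 == 1
}

rasterize_bruteforce <- function(vertices, shape) {
  m <- blank(shape[1], shape[2])
  for (row in seq_len(shape[1])) {
    for (col in seq_len(shape[2])) {
      m[row, col] <- point_in_polygon_oracle(col - 0.5, row - 0.5,
                                             vertices[, 1], vertices[, 2])
    }
  }
  m
}

# square mask helper: top-left pixel (x, y), side s
square_mask <- function(h, w, x, y, s) {
  m <- blank(h, w)
  m[(y + 1):(y + s), (x + 1):(x + s)] <- TRUE
  m
}

make_scene_pair <- function(seed = 7, shape = c(256, 256), n = 12,
                            dx = 18, dy = -11, angle = 5 * pi / 180) {
  sc <- generate_scene(scene_params(image_shape = shape, n_instances = n),
                       seed = seed)
  warp_scene(sc, list(dx = dx, dy = dy, angle = angle), seed = seed)
}
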