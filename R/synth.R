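#' Parameters for synthetic instance scenes
#'
#' Describes a scene of compact, round-ish textured object instances
#' (kernel-grid caricature) on a textured background — the fixture family
#' used to exercise metrics, matching, prompting, grid search and transfer
#' without any real dataset. Realism is not the goal; controllability and
#' determinism are.
#'
#' @param image_shape integer `c(height, width)`.
#' @param n_instances number of object instances to place.
#' @param instance_radius_range `c(min, max)` semi-major axis in px.
#' @param min_gap minimum gap in px between instance envelopes when
#'   `allow_overlap = FALSE`.
#' @param allow_overlap allow instances to overlap.
#' @return an object of class `scene_params`.
#' @export
scene_params <- function(image_shape = c(256, 256), n_instances = 25,
                         instance_radius_range = c(8, 16), min_gap = 2,
                         allow_overlap = FALSE) {
  stopifnot(length(image_shape) == 2, n_instances >= 0,
            length(instance_radius_range) == 2,
            instance_radius_range[1] > 0,
            instance_radius_range[1] <= instance_radius_range[2])
  structure(list(image_shape = as.integer(image_shape),
                 n_instances = as.integer(n_instances),
                 instance_radius_range = instance_radius_range,
                 min_gap = min_gap, allow_overlap = isTRUE(allow_overlap)),
            class = "scene_params")
}

# ellipse membership at pixel centers (pixel-center coordinates)
ellipse_mask <- function(shape, cx, cy, a, b, phi) {
  h <- shape[1]; w <- shape[2]
  m <- matrix(FALSE, h, w)
  r <- ceiling(max(a, b)) + 1L
  xs <- max(0L, floor(cx - r)):min(w - 1L, ceiling(cx + r))
  ys <- max(0L, floor(cy - r)):min(h - 1L, ceiling(cy + r))
  if (length(xs) == 0 || length(ys) == 0) return(m)
  g <- expand.grid(x = xs, y = ys)
  dx <- g$x - cx; dy <- g$y - cy
  u <- (dx * cos(phi) + dy * sin(phi)) / a
  v <- (-dx * sin(phi) + dy * cos(phi)) / b
  m[cbind(g$y + 1L, g$x + 1L)] <- (u^2 + v^2) <= 1
  m
}

#' Generate a deterministic synthetic instance scene
#'
#' Places `n_instances` textured elliptical blobs on a textured background
#' and records an exact per-instance ground-truth mask for each. The output
#' is a pure function of `(params, seed)`: the same call twice yields
#' bit-identical scenes.
#'
#' @param params a [scene_params()].
#' @param seed integer seed.
#' @return an object of class `synthetic_scene`: list with `image`
#'   (`h x w x 3` array in \[0, 1\] carrying an `image_id` attribute), `gt`
#'   (a [mask_set()]), `seed`, `params`, and — after [warp_scene()] —
#'   `true_homography_to_pair`, `paired_image`, `paired_gt`.
#' @export
generate_scene <- function(params, seed = 1L) {
  stopifnot(inherits(params, "scene_params"))
  h <- params$image_shape[1]; w <- params$image_shape[2]
  rmin <- params$instance_radius_range[1]; rmax <- params$instance_radius_range[2]
  with_local_seed(derive_seed(seed, "scene"), {
    # background: low-frequency field plus fine speckle (gives the corner
    # detector something to bite on)
    base <- matrix(stats::runif(h * w), h, w)
    low <- EBImage::gblur(base, 5)
    low <- (low - min(low)) / (max(low) - min(low) + 1e-12)
    speck <- matrix(stats::runif(h * w), h, w)
    gray <- 0.30 + 0.22 * low + 0.14 * speck
    tint <- stats::runif(3, -0.03, 0.03)
    image <- array(0, dim = c(h, w, 3))
    for (ch in 1:3) image[, , ch] <- pmin(pmax(gray + tint[ch], 0), 1)
    # placement by rejection sampling on instance envelopes
    placed <- matrix(numeric(0), ncol = 5)  # cx, cy, a, b, phi
    attempts <- 0L
    while (nrow(placed) < params$n_instances) {
      attempts <- attempts + 1L
      if (attempts > 10000L) {
        stop("could not place ", params$n_instances,
             " instances under min_gap in 10000 attempts")
      }
      a <- stats::runif(1, rmin, rmax)
      b <- stats::runif(1, 0.7 * a, a)
      phi <- stats::runif(1, 0, pi)
      margin <- a + 1
      if (w - 1 - 2 * margin <= 0 || h - 1 - 2 * margin <= 0) {
        stop("instances of this radius do not fit the frame")
      }
      cx <- stats::runif(1, margin, w - 1 - margin)
      cy <- stats::runif(1, margin, h - 1 - margin)
      if (!params$allow_overlap && nrow(placed) > 0) {
        dd <- sqrt((placed[, 1] - cx)^2 + (placed[, 2] - cy)^2)
        if (any(dd < placed[, 3] + a + params$min_gap)) next
      }
      placed <- rbind(placed, c(cx, cy, a, b, phi))
    }
    instances <- vector("list", params$n_instances)
    for (i in seq_len(params$n_instances)) {
      p <- placed[i, ]
      m <- ellipse_mask(c(h, w), p[1], p[2], p[3], p[4], p[5])
      instances[[i]] <- m
      idx <- which(m, arr.ind = TRUE)
      dx <- (idx[, 2] - 1) - p[1]; dy <- (idx[, 1] - 1) - p[2]
      u <- (dx * cos(p[5]) + dy * sin(p[5])) / p[3]
      v <- (-dx * sin(p[5]) + dy * cos(p[5])) / p[4]
      shade <- 1 - 0.45 * (u^2 + v^2)
      grain <- stats::runif(nrow(idx), -0.06, 0.06)
      col <- stats::runif(3, 0.45, 0.9)
      for (ch in 1:3) {
        image[, , ch][idx] <- pmin(pmax(col[ch] * shade + grain, 0), 1)
      }
    }
    image_id <- sprintf("scene-%d", as.integer(seed))
    attr(image, "image_id") <- image_id
    structure(
      list(image = image,
           gt = mask_set(instances, image_shape = c(h, w), image_id = image_id),
           seed = as.integer(seed), params = params,
           true_homography_to_pair = NULL, paired_image = NULL,
           paired_gt = NULL),
      class = "synthetic_scene"
    )
  })
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf("<synthetic_scene> '%s' %dx%d, %d instances%s\n",
              x$gt$image_id, x$params$image_shape[1], x$params$image_shape[2],
              n_instances(x$gt),
              if (!is.null(x$paired_image)) " (paired)" else ""))
  invisible(x)
}

# H0 for a translation / rotation-about-center / mild projective transform,
# in pixel-center coordinates.
build_transform <- function(shape, dx = 0, dy = 0, angle = 0,
                            projective = c(0, 0)) {
  cx <- (shape[2] - 1) / 2; cy <- (shape[1] - 1) / 2
  rot <- rbind(c(cos(angle), -sin(angle), 0),
               c(sin(angle), cos(angle), 0), c(0, 0, 1))
  t_in <- rbind(c(1, 0, -cx), c(0, 1, -cy), c(0, 0, 1))
  t_out <- rbind(c(1, 0, cx + dx), c(0, 1, cy + dy), c(0, 0, 1))
  persp <- rbind(c(1, 0, 0), c(0, 1, 0), c(projective[1], projective[2], 1))
  H <- persp %*% t_out %*% rot %*% t_in
  H / H[3, 3]
}

#' Render the overlapping pair of a scene under a known transform
#'
#' Warps the scene with an exact homography `H0` (translation, rotation
#' about the frame center, optional mild projective component), producing
#' the second image of an overlapping pair together with the warped
#' ground truth and the true transform — the fixture for registration and
#' transfer tests. The image is resampled bilinearly; ground-truth labels
#' are warped nearest-neighbor to stay binary (the source of at most ~1 px
#' boundary jitter under rotation). Instances warped fully out of frame are
#' dropped from the paired ground truth.
#'
#' @param scene a [generate_scene()] result.
#' @param transform_params list with any of `dx`, `dy` (px), `angle`
#'   (radians, about the frame center), `projective` (length-2 numeric,
#'   mild perspective terms).
#' @param noise_sd standard deviation of additive Gaussian pixel noise on
#'   the rendered pair (0 = noise-free).
#' @param seed integer seed for the noise.
#' @param min_visible minimum fraction of source pixels that must remain in
#'   frame; below it the transform is rejected with an error.
#' @return the scene with `true_homography_to_pair`, `paired_image` and
#'   `paired_gt` populated.
#' @export
warp_scene <- function(scene, transform_params = list(), noise_sd = 0,
                       seed = 1L, min_visible = 0.25) {
  stopifnot(inherits(scene, "synthetic_scene"))
  shape <- scene$params$image_shape
  h <- shape[1]; w <- shape[2]
  H <- do.call(build_transform, c(list(shape = shape), transform_params))
  # visibility check on a coarse grid of source pixels
  g <- expand.grid(x = seq(0, w - 1, by = 4), y = seq(0, h - 1, by = 4))
  pg <- apply_homography(H, as.matrix(g))
  vis <- mean(pg[, 1] >= 0 & pg[, 1] <= w - 1 & pg[, 2] >= 0 & pg[, 2] <= h - 1)
  if (vis == 0) stop("transform pushes all content out of frame")
  if (vis < min_visible) {
    stop(sprintf("only %.0f%% of the frame stays visible (min %.0f%%)",
                 100 * vis, 100 * min_visible))
  }
  hinv <- solve(H)
  tg <- expand.grid(x = 0:(w - 1), y = 0:(h - 1))
  src <- apply_homography(hinv, as.matrix(tg))
  inb <- src[, 1] >= -0.5 & src[, 1] <= w - 0.5 &
    src[, 2] >= -0.5 & src[, 2] <= h - 0.5
  paired <- array(0, dim = c(h, w, 3))
  fill <- 0.42
  for (ch in 1:3) {
    vals <- bilinear_sample(scene$image[, , ch], src[, 1], src[, 2])
    vals[!inb] <- fill
    paired[, , ch][cbind(tg$y + 1L, tg$x + 1L)] <- vals
  }
  if (noise_sd > 0) {
    with_local_seed(derive_seed(seed, "warp-noise"), {
      paired <- paired + array(stats::rnorm(length(paired), 0, noise_sd),
                               dim = dim(paired))
    })
  }
  paired <- pmin(pmax(paired, 0), 1)
  # nearest-neighbor label warp
  rx <- round(src[, 1]); ry <- round(src[, 2])
  okl <- rx >= 0 & rx <= w - 1 & ry >= 0 & ry <= h - 1
  warped <- list(); kept_ids <- integer(0)
  for (i in seq_along(scene$gt$instances)) {
    m <- scene$gt$instances[[i]]
    vals <- rep(FALSE, nrow(tg))
    vals[okl] <- m[cbind(ry[okl] + 1L, rx[okl] + 1L)]
    wm <- matrix(FALSE, h, w)
    wm[cbind(tg$y + 1L, tg$x + 1L)] <- vals
    if (any(wm)) {
      warped <- c(warped, list(wm))
      kept_ids <- c(kept_ids, scene$gt$instance_ids[i])
    }
  }
  pair_id <- paste0(scene$gt$image_id, "-pair")
  attr(paired, "image_id") <- pair_id
  scene$true_homography_to_pair <- H
  scene$paired_image <- paired
  scene$paired_gt <- mask_set(warped, image_shape = c(h, w), image_id = pair_id,
                              instance_ids = if (length(kept_ids)) kept_ids else NULL)
  scene
}

#' Ground-truth provider over a set of scenes
#'
#' Builds the lookup closure (`image_id -> mask_set`) that the mock
#' backends use to find the ground truth of the image they were handed.
#' Both the primary and the paired ground truth of each scene are
#' registered.
#'
#' @param scenes list of `synthetic_scene` objects (or of [mask_set()]s).
#' @return `function(image_id) -> mask_set`.
#' @export
scene_gt_provider <- function(scenes) {
  tab <- list()
  for (s in scenes) {
    if (inherits(s, "synthetic_scene")) {
      tab[[s$gt$image_id]] <- s$gt
      if (!is.null(s$paired_gt)) tab[[s$paired_gt$image_id]] <- s$paired_gt
    } else if (inherits(s, "mask_set")) {
      tab[[s$image_id]] <- s
    } else {
      stop("scenes must be synthetic_scene or mask_set objects")
    }
  }
  function(image_id) {
    gt <- tab[[image_id %||% ""]]
    if (is.null(gt)) stop("no ground truth registered for image '", image_id, "'")
    gt
  }
}
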