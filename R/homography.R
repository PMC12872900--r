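# Keypoint-based projective registration of overlapping images.
#
# Pipeline: Harris corner detection with subpixel refinement ->
# orientation-normalized intensity-patch descriptors (orientation from the
# intensity centroid, as in rotation-aware binary descriptors) ->
# ratio-test + cross-check matching -> RANSAC with a normalized-DLT
# homography fit, refined on the consensus set.
#
# All geometry lives in pixel-center coordinates: continuous (x, y) with
# integer positions at pixel centers, x = column - 1, y = row - 1.

harris_response <- function(gray, sigma = 1.5, k = 0.04) {
  kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE)
  ix <- EBImage::filter2(gray, t(kx))
  iy <- EBImage::filter2(gray, kx)
  a <- EBImage::gblur(ix * ix, sigma)
  b <- EBImage::gblur(iy * iy, sigma)
  cc <- EBImage::gblur(ix * iy, sigma)
  (a * b - cc * cc) - k * (a + b)^2
}

shift_mat <- function(m, dr, dc, fill = -Inf) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(fill, h, w)
  rs <- max(1, 1 + dr):min(h, h + dr)
  cs <- max(1, 1 + dc):min(w, w + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

# Harris corners: local maxima of the response, strongest first, with
# quadratic subpixel refinement. Returns data frame (x, y, response).
detect_keypoints <- function(gray, max_keypoints = 1500, sigma = 1.5,
                             border = 16L) {
  resp <- harris_response(gray, sigma)
  h <- nrow(resp); w <- ncol(resp)
  resp[c(seq_len(border), (h - border + 1):h), ] <- -Inf
  resp[, c(seq_len(border), (w - border + 1):w)] <- -Inf
  nb <- list(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1),
             c(0, 1), c(1, -1), c(1, 0), c(1, 1))
  is_max <- resp > 0
  for (d in nb) is_max <- is_max & (resp >= shift_mat(resp, d[1], d[2]))
  idx <- which(is_max, arr.ind = TRUE)
  if (nrow(idx) == 0) {
    return(data.frame(x = numeric(0), y = numeric(0), response = numeric(0)))
  }
  vals <- resp[idx]
  keep <- vals > 1e-9 * max(vals)
  idx <- idx[keep, , drop = FALSE]; vals <- vals[keep]
  ord <- order(-vals)
  if (length(ord) > max_keypoints) ord <- ord[seq_len(max_keypoints)]
  idx <- idx[ord, , drop = FALSE]; vals <- vals[ord]
  # subpixel peak: 1-d quadratic fit along each axis
  r <- idx[, 1]; c <- idx[, 2]
  dcx <- (resp[cbind(r, c - 1)] - resp[cbind(r, c + 1)]) /
    (2 * (resp[cbind(r, c - 1)] - 2 * vals + resp[cbind(r, c + 1)]))
  dcy <- (resp[cbind(r - 1, c)] - resp[cbind(r + 1, c)]) /
    (2 * (resp[cbind(r - 1, c)] - 2 * vals + resp[cbind(r + 1, c)]))
  dcx[!is.finite(dcx)] <- 0; dcy[!is.finite(dcy)] <- 0
  dcx <- pmin(pmax(dcx, -0.5), 0.5); dcy <- pmin(pmax(dcy, -0.5), 0.5)
  data.frame(x = c - 1 + dcx, y = r - 1 + dcy, response = vals)
}

# Orientation-normalized, intensity-normalized patch descriptors.
# patch_n^2 samples on a rotated grid; rows are unit-normalized.
describe_keypoints <- function(gray, kps, patch_n = 12L, spacing = 1.4) {
  n <- nrow(kps)
  if (n == 0) return(matrix(numeric(0), 0, patch_n^2))
  # orientation from the intensity centroid of a disc around the keypoint
  rad <- 7L
  off <- expand.grid(dx = -rad:rad, dy = -rad:rad)
  off <- off[off$dx^2 + off$dy^2 <= rad^2, ]
  ivals <- matrix(bilinear_sample(gray,
                                  rep(kps$x, each = nrow(off)) + off$dx,
                                  rep(kps$y, each = nrow(off)) + off$dy),
                  nrow = nrow(off))
  m10 <- colSums(ivals * off$dx); m01 <- colSums(ivals * off$dy)
  ang <- atan2(m01, m10)
  ca <- cos(ang); sa <- sin(ang)
  g <- (seq_len(patch_n) - (patch_n + 1) / 2) * spacing
  grid <- expand.grid(u = g, v = g)
  # rotate the sampling grid by each keypoint's orientation
  px <- outer(ca, grid$u) - outer(sa, grid$v) + kps$x  # n x patch_n^2
  py <- outer(sa, grid$u) + outer(ca, grid$v) + kps$y
  d <- matrix(bilinear_sample(gray, as.vector(px), as.vector(py)), nrow = n)
  d <- d - rowMeans(d)
  nrm <- sqrt(rowSums(d^2))
  nrm[nrm < 1e-12] <- 1
  d / nrm
}

# Lowe ratio test + mutual cross-check on unit-norm descriptors.
# Returns matrix of index pairs (ia, ib).
match_descriptors <- function(da, db, ratio = 0.75) {
  if (nrow(da) == 0 || nrow(db) == 0) return(cbind(ia = integer(0), ib = integer(0)))
  sim <- da %*% t(db)           # unit rows: dist^2 = 2 - 2 * sim
  best_b <- max.col(sim, ties.method = "first")
  s1 <- sim[cbind(seq_len(nrow(sim)), best_b)]
  sim2 <- sim
  sim2[cbind(seq_len(nrow(sim)), best_b)] <- -Inf
  s2 <- apply(sim2, 1, max)
  pass_ratio <- (2 - 2 * s1) < ratio^2 * (2 - 2 * s2)
  best_a <- max.col(t(sim), ties.method = "first")
  mutual <- best_a[best_b] == seq_len(nrow(sim))
  keep <- which(pass_ratio & mutual)
  cbind(ia = keep, ib = best_b[keep])
}

#' Apply a homography to points
#'
#' @param H 3x3 projective matrix.
#' @param pts `n x 2` matrix of (x, y) coordinates.
#' @return `n x 2` matrix of mapped coordinates.
#' @export
apply_homography <- function(H, pts) {
  pts <- matrix(pts, ncol = 2)
  ph <- cbind(pts, 1) %*% t(H)
  ph[, 1:2, drop = FALSE] / ph[, 3]
}

# Normalized direct linear transform from >= 4 correspondences.
homography_dlt <- function(pa, pb) {
  norm_t <- function(p) {
    mu <- colMeans(p)
    s <- sqrt(2) / mean(sqrt(rowSums(sweep(p, 2, mu)^2)) + 1e-12)
    rbind(c(s, 0, -s * mu[1]), c(0, s, -s * mu[2]), c(0, 0, 1))
  }
  ta <- norm_t(pa); tb <- norm_t(pb)
  a <- apply_homography(ta, pa); b <- apply_homography(tb, pb)
  n <- nrow(a)
  m <- matrix(0, 2 * n, 9)
  for (i in seq_len(n)) {
    x <- a[i, 1]; y <- a[i, 2]; u <- b[i, 1]; v <- b[i, 2]
    m[2 * i - 1, ] <- c(-x, -y, -1, 0, 0, 0, u * x, u * y, u)
    m[2 * i, ] <- c(0, 0, 0, -x, -y, -1, v * x, v * y, v)
  }
  sv <- svd(m, nu = 0, nv = 9)
  hn <- matrix(sv$v[, 9], 3, 3, byrow = TRUE)
  H <- solve(tb) %*% hn %*% ta
  if (abs(H[3, 3]) < 1e-12 || !all(is.finite(H))) return(NULL)
  H / H[3, 3]
}

ransac_homography <- function(pa, pb, n_iter = 1000, thresh = 3) {
  n <- nrow(pa)
  best_inl <- rep(FALSE, n)
  for (it in seq_len(n_iter)) {
    s <- sample.int(n, 4)
    # degenerate sample: near-coincident or collinear triples
    d <- stats::dist(pa[s, ])
    if (min(d) < 2) next
    H <- homography_dlt(pa[s, , drop = FALSE], pb[s, , drop = FALSE])
    if (is.null(H)) next
    err2 <- rowSums((apply_homography(H, pa) - pb)^2)
    inl <- err2 < thresh^2
    if (sum(inl) > sum(best_inl)) best_inl <- inl
  }
  if (sum(best_inl) < 4) return(NULL)
  # refit on the consensus set, twice (inliers can grow after the LS fit)
  for (pass in 1:2) {
    H <- homography_dlt(pa[best_inl, , drop = FALSE], pb[best_inl, , drop = FALSE])
    if (is.null(H)) return(NULL)
    err2 <- rowSums((apply_homography(H, pa) - pb)^2)
    best_inl <- err2 < thresh^2
    if (sum(best_inl) < 4) return(NULL)
  }
  list(H = H, inliers = best_inl,
       mean_error = mean(sqrt(err2[best_inl])))
}

#' Estimate the homography between two overlapping images
#'
#' Detects corners on both images, matches orientation-normalized patch
#' descriptors (ratio test + cross-check), and fits a projective homography
#' mapping image-A pixel coordinates to image-B robustly with RANSAC
#' followed by a least-squares refit on the consensus set. Failures name the
#' stage that broke down (detection / matching / estimation).
#'
#' @param image_a,image_b grayscale matrices or RGB arrays.
#' @param params optional list overriding the defaults: `max_keypoints`
#'   (1500), `sigma` (1.5, corner-scale in px), `ratio` (0.75, Lowe ratio),
#'   `ransac_thresh` (3 px reprojection), `ransac_iter` (1000), `seed` (42),
#'   `min_keypoints` (25).
#' @return an object of class `homography_estimate`: list with the 3x3
#'   matrix `H` (normalized so `H[3,3] = 1`), `inlier_count`,
#'   `mean_reprojection_error` (px, over inliers), `n_keypoints` and
#'   `n_matches`.
#' @export
estimate_homography <- function(image_a, image_b, params = list()) {
  p <- utils::modifyList(
    list(max_keypoints = 1500, sigma = 1.5, ratio = 0.75,
         ransac_thresh = 3, ransac_iter = 1000, seed = 42L,
         min_keypoints = 25), params)
  ga <- as_gray(image_a); gb <- as_gray(image_b)
  ka <- detect_keypoints(ga, p$max_keypoints, p$sigma)
  kb <- detect_keypoints(gb, p$max_keypoints, p$sigma)
  if (nrow(ka) < p$min_keypoints || nrow(kb) < p$min_keypoints) {
    stop_stage("detection", sprintf(
      "too few keypoints (%d / %d, need %d); images may lack texture",
      nrow(ka), nrow(kb), p$min_keypoints))
  }
  da <- describe_keypoints(ga, ka)
  db <- describe_keypoints(gb, kb)
  mm <- match_descriptors(da, db, p$ratio)
  if (nrow(mm) < 4) {
    stop_stage("matching", sprintf("only %d descriptor matches (need >= 4)", nrow(mm)))
  }
  pa <- as.matrix(ka[mm[, "ia"], c("x", "y")])
  pb <- as.matrix(kb[mm[, "ib"], c("x", "y")])
  fit <- with_local_seed(p$seed,
                         ransac_homography(pa, pb, p$ransac_iter, p$ransac_thresh))
  if (is.null(fit) || abs(det(fit$H)) < 1e-12) {
    stop_stage("estimation", "RANSAC found no valid homography (degenerate geometry?)")
  }
  structure(
    list(H = fit$H, inlier_count = sum(fit$inliers),
         mean_reprojection_error = fit$mean_error,
         n_keypoints = c(a = nrow(ka), b = nrow(kb)), n_matches = nrow(mm)),
    class = "homography_estimate"
  )
}

#' @export
print.homography_estimate <- function(x, ...) {
  cat(sprintf(
    "<homography_estimate> inliers=%d/%d matches, mean reproj err=%.3f px\n",
    x$inlier_count, x$n_matches, x$mean_reprojection_error))
  invisible(x)
}
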