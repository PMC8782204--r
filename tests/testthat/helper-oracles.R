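# Shared fixtures and independent oracles used across test files.

# A small volume containing Gaussian blobs at the given mm centers
# (1 mm isotropic grid unless an affine is supplied).
blob_volume <- function(centers_mm, shape = c(48, 48, 48), affine = diag(4),
                        peak = 1000, fwhm = 2, background = 0) {
  vol <- seeg_volume(array(background, dim = shape), affine)
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  idx <- as.matrix(expand.grid(seq_len(shape[1]) - 1, seq_len(shape[2]) - 1,
                               seq_len(shape[3]) - 1))
  mm <- voxel_to_mm(vol, idx)
  dat <- array(background, dim = shape)
  for (i in seq_len(nrow(centers_mm))) {
    r2 <- rowSums(sweep(mm, 2, centers_mm[i, ])^2)
    dat <- dat + array(peak * exp(-r2 / (2 * sigma^2)), dim = shape)
  }
  seeg_volume(dat, affine)
}

# A point cloud built directly from coordinates (bypassing thresholding).
make_cloud <- function(coords, intensities = rep(1000, nrow(coords)),
                       affine = diag(4), threshold = 500) {
  structure(list(coords = coords, intensities = intensities,
                 affine = affine, threshold = threshold,
                 voxel_size = sqrt(colSums(affine[1:3, 1:3]^2))),
            class = "seeg_pointcloud")
}

# Noiseless points along a 3D line: anchor + t * direction (+ jitter).
line_points <- function(n, anchor, direction, spacing = 1, jitter = 0,
                        seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  direction <- direction / sqrt(sum(direction^2))
  t <- (seq_len(n) - 1) * spacing
  pts <- outer(t, direction) + matrix(anchor, n, 3, byrow = TRUE)
  if (jitter > 0) pts <- pts + matrix(rnorm(3 * n, 0, jitter), n, 3)
  pts
}

# Oracle: assign each point to the nearest true generating line.
nearest_line_assignment <- function(pts, anchors, directions) {
  d <- vapply(seq_along(anchors), function(i) {
    dir <- directions[[i]] / sqrt(sum(directions[[i]]^2))
    rel <- sweep(pts, 2, anchors[[i]])
    proj <- as.numeric(rel %*% dir)
    sqrt(pmax(rowSums(rel^2) - proj^2, 0))
  }, numeric(nrow(pts)))
  max.col(-d, ties.method = "first")
}

# Oracle: AUC by explicit all-pairs concordance count, ties = 1/2.
auc_bruteforce <- function(scores, labels) {
  labels <- as.logical(labels)
  pos <- scores[labels]; neg <- scores[!labels]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# Oracle: brute-force brightest interpolated point near a start (fine grid
# argmax within a ball). For a trilinear field the maximum sits on a voxel
# center, so this locates blobs only to voxel precision.
argmax_near <- function(volume, center_vox, radius_vox = 2, step = 0.05) {
  off <- seq(-radius_vox, radius_vox, by = step)
  grid <- as.matrix(expand.grid(off, off, off))
  grid <- grid[rowSums(grid^2) <= radius_vox^2, ]
  cand <- sweep(grid, 2, center_vox, "+")
  cand[which.max(interp_intensity(volume, cand)), ]
}

# Oracle: brute-force brightest point of the *generating* analytic Gaussian
# profile (sum over blob centers), evaluated on a fine grid near a guess.
# Sub-voxel-exact, independent of the rendering/interpolation path.
argmax_analytic <- function(centers_mm, guess_mm, fwhm = 2, radius = 2,
                            step = 0.02) {
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  off <- seq(-radius, radius, by = step)
  grid <- sweep(as.matrix(expand.grid(off, off, off)), 2, guess_mm, "+")
  val <- numeric(nrow(grid))
  for (i in seq_len(nrow(centers_mm)))
    val <- val + exp(-rowSums(sweep(grid, 2, centers_mm[i, ])^2) /
                       (2 * sigma^2))
  grid[which.max(val), ]
}

# Agreement of two labelings up to label permutation (greedy best match).
relabel_agreement <- function(a, b) {
  tab <- table(a, b)
  matched <- 0
  while (length(tab) && max(tab) > 0) {
    m <- which(tab == max(tab), arr.ind = TRUE)[1, ]
    matched <- matched + tab[m[1], m[2]]
    tab[m[1], ] <- -1; tab[, m[2]] <- -1
  }
  matched / length(a)
}

# Event matching by temporal overlap, for precision/recall of the detector.
overlap_counts <- function(detected, truth) {
  n_det_hit <- if (nrow(detected)) sum(vapply(seq_len(nrow(detected)),
    function(i) any(pmin(detected[i, 2], truth[, 2]) -
                    pmax(detected[i, 1], truth[, 1]) > 0), logical(1))) else 0
  n_tr_hit <- if (nrow(truth)) sum(vapply(seq_len(nrow(truth)),
    function(i) nrow(detected) > 0 &&
      any(pmin(detected[, 2], truth[i, 2]) -
          pmax(detected[, 1], truth[i, 1]) > 0), logical(1))) else 0
  c(n_detected = nrow(detected), n_truth = nrow(truth),
    det_hit = n_det_hit, truth_hit = n_tr_hit)
}

# Envelope object constructed directly, for threshold/detector unit tests.
make_envelope <- function(values, fs) {
  structure(list(values = values, fs = fs,
                 channel_names = paste0("ch", seq_len(nrow(values))),
                 channel_median = apply(values, 1, stats::median),
                 global_median = stats::median(values)),
            class = "seeg_envelope")
}
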