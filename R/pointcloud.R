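#' Extract bright (electrode) voxels from a skull-stripped volume
#'
#' In a skull-stripped, CT-like volume the metallic electrode voxels are far
#' brighter than brain tissue, so the electrode point cloud is obtained by
#' plain intensity thresholding. The volume is assumed already skull-stripped
#' (a documented contract: extracranial bone would survive any intensity
#' threshold).
#'
#' @param volume A [seeg_volume].
#' @param rule Threshold rule. The default `"relative:0.5"` takes half of
#'   the robust intensity maximum (99.9th percentile of nonzero voxels): in
#'   a skull-stripped CT the brightest voxels are metal, so half of that is
#'   far above any tissue value - a cutoff that is invariant to intensity
#'   scale and voxel size and nearly immune to background noise tails.
#'   Alternatives: `"percentile:<p>"` (keep the top fraction of nonzero
#'   voxels), `"otsu"` (Otsu's method over nonzero voxels; suited to clearly
#'   bimodal intensity histograms - blob profiles that taper continuously
#'   into the background can defeat it), or `"absolute:<v>"` for a fixed
#'   cutoff. A plain number is taken as absolute.
#' @return A `seeg_pointcloud`: 0-based voxel coordinates (`coords`, N x 3),
#'   their `intensities` (all strictly above the resolved `threshold`), and
#'   the source `affine`. Raises `seeg_empty_cloud` if nothing survives.
#' @export
extract_bright_voxels <- function(volume, rule = "relative:0.5") {
  stopifnot(inherits(volume, "seeg_volume"))
  thr <- resolve_threshold(volume$data, rule)
  keep <- which(volume$data > thr)
  if (length(keep) == 0L)
    stop_seeg("empty_cloud",
              "no voxel above threshold ", signif(thr, 6),
              " (rule '", rule, "'); lower the threshold")
  coords <- arrayInd(keep, volume$shape) - 1L
  seeg_log("threshold rule '", rule, "' resolved to ", signif(thr, 6),
           "; ", length(keep), " voxels extracted")
  structure(list(coords = coords, intensities = volume$data[keep],
                 affine = volume$affine, threshold = thr,
                 voxel_size = voxel_size(volume)),
            class = "seeg_pointcloud")
}

resolve_threshold <- function(data, rule) {
  if (is.numeric(rule)) return(rule)
  if (identical(rule, "otsu")) {
    nz <- data[data > 0]
    if (length(nz) < 2L)
      stop_seeg("empty_cloud", "volume has no positive voxels to threshold")
    rng <- range(nz)
    if (diff(rng) == 0)
      stop_seeg("empty_cloud", "volume intensity is constant; cannot threshold")
    # EBImage's Otsu works on [0,1]-scaled data
    scaled <- (nz - rng[1]) / diff(rng)
    dim(scaled) <- c(length(scaled), 1)
    rng[1] + EBImage::otsu(scaled, range = c(0, 1), levels = 256) * diff(rng)
  } else if (grepl("^relative:", rule)) {
    f <- as.numeric(sub("^relative:", "", rule))
    if (!is.finite(f) || f <= 0 || f >= 1)
      stop_seeg("bad_threshold_rule", "relative fraction must be in (0, 1)")
    nz <- data[data > 0]
    if (!length(nz))
      stop_seeg("empty_cloud", "volume has no positive voxels to threshold")
    # robust max: 99.99th percentile - essentially the metal peak, but
    # isolated hot voxels cannot set it
    f * stats::quantile(nz, 0.9999, names = FALSE)
  } else if (grepl("^percentile:", rule)) {
    p <- as.numeric(sub("^percentile:", "", rule))
    if (!is.finite(p) || p <= 0 || p >= 100)
      stop_seeg("bad_threshold_rule", "percentile must be in (0, 100)")
    nz <- data[data > 0]
    stats::quantile(nz, p / 100, names = FALSE)
  } else if (grepl("^absolute:", rule)) {
    v <- as.numeric(sub("^absolute:", "", rule))
    if (!is.finite(v)) stop_seeg("bad_threshold_rule", "bad absolute threshold")
    v
  } else stop_seeg("bad_threshold_rule", "unknown threshold rule: ", rule)
}

#' @export
print.seeg_pointcloud <- function(x, ...) {
  cat("<seeg_pointcloud> ", nrow(x$coords), " voxels above ",
      signif(x$threshold, 6), "\n", sep = "")
  invisible(x)
}

# mm coordinates of cloud points (N x 3)
cloud_mm <- function(cloud, idx = seq_len(nrow(cloud$coords))) {
  t(cloud$affine %*% rbind(t(cloud$coords[idx, , drop = FALSE]), 1))[, 1:3,
                                                                     drop = FALSE]
}
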