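#' Assign electrode voxels to shafts with a Hough-initialized Gaussian mixture
#'
#' Fits a full-covariance Gaussian mixture with one component per detected
#' Hough line, initialized from the Hough result rather than at random: the
#' starting responsibilities assign each point to its nearest detected line,
#' which puts the component means at the Hough inlier centroids and makes the
#' starting covariances elongated along the Hough directions. EM then refines
#' the soft assignment over the whole cloud. A light conjugate prior
#' regularizes the covariances so exactly collinear (noiseless) clusters do
#' not collapse. The fit is deterministic given its inputs; `seed` is kept in
#' the signature for interface stability.
#'
#' Each resulting cluster's axis is refit with a trimmed total-least-squares
#' regression (see [fit_shaft_axis]).
#'
#' @param cloud A `seeg_pointcloud`.
#' @param lines Non-empty list of `seeg_hough_line` from [hough_lines_3d].
#' @param seed Unused RNG seed (the fit is deterministic); kept for interface
#'   stability.
#' @param min_members Minimum points a component may hold before the fit is
#'   declared degenerate (`seeg_degenerate_cluster`).
#' @return A list of `seeg_electrode_cluster` objects: `label`,
#'   `member_indices` (rows of the cloud; the clusters partition it),
#'   `centroid` (voxel coords), and `axis` (list with `point`, `direction`,
#'   `rms`, in voxel coords).
#' @export
cluster_electrodes <- function(cloud, lines, seed = 1L, min_members = 4L) {
  stopifnot(inherits(cloud, "seeg_pointcloud"))
  if (length(lines) < 1L)
    stop_seeg("no_lines", "need at least one Hough line to cluster")
  pts <- cloud$coords
  k <- length(lines)
  # hard nearest-line assignment as the one-hot starting responsibilities
  dmat <- vapply(lines, function(l) point_line_dist(pts, l$anchor, l$direction),
                 numeric(nrow(pts)))
  hard <- max.col(-dmat, ties.method = "first")
  assign_final <- hard
  if (k > 1L && nrow(pts) > k * 3L) {
    z <- matrix(0, nrow(pts), k)
    z[cbind(seq_len(nrow(pts)), hard)] <- 1
    fit <- tryCatch(
      mclust::me(data = pts, modelName = "VVV", z = z,
                 prior = mclust::priorControl()),
      error = function(e) NULL)
    if (!is.null(fit) && is.finite(fit$loglik) && !anyNA(fit$z))
      assign_final <- max.col(fit$z, ties.method = "first")
  }
  counts <- tabulate(assign_final, nbins = k)
  if (any(counts < min_members))
    stop_seeg("degenerate_cluster",
              "mixture component(s) ", paste(which(counts < min_members),
                                             collapse = ", "),
              " collapsed below ", min_members, " members")
  lapply(seq_len(k), function(g) {
    idx <- which(assign_final == g)
    ax <- fit_shaft_axis_points(pts[idx, , drop = FALSE])
    structure(list(label = paste0("E", g), member_indices = idx,
                   centroid = colMeans(pts[idx, , drop = FALSE]), axis = ax),
              class = "seeg_electrode_cluster")
  })
}

#' Total-least-squares shaft axis of an electrode cluster
#'
#' Fits the line minimizing perpendicular (not coordinate-wise) distances:
#' the leading principal axis through the member centroid. This choice is
#' rotation-invariant, unlike per-coordinate-pair ordinary regression. A
#' single trim pass discards points farther than 3 voxels from the first fit
#' (stray supra-threshold noise voxels) and refits, provided enough points
#' survive.
#'
#' @param cluster A `seeg_electrode_cluster`.
#' @param cloud The `seeg_pointcloud` the cluster indexes into.
#' @return List with `point` (on the line), `direction` (unit,
#'   sign-normalized), and `rms` perpendicular residual, in voxel coords.
#' @export
fit_shaft_axis <- function(cluster, cloud) {
  fit_shaft_axis_points(cloud$coords[cluster$member_indices, , drop = FALSE])
}

fit_shaft_axis_points <- function(pts, trim_radii = c(3, 2)) {
  if (nrow(pts) < 2L || nrow(unique(pts)) < 2L)
    stop_seeg("degenerate_axis",
              "need at least two distinct points to fit a shaft axis")
  fit <- principal_line(pts)
  for (r in trim_radii) {
    keep <- point_line_dist(pts, fit$point, fit$direction) <= r
    if (sum(keep) >= max(4L, 0.5 * nrow(pts)) && !all(keep))
      fit <- principal_line(pts[keep, , drop = FALSE])
  }
  fit
}
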