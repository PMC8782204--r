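#' Deep (head) end of an electrode shaft
#'
#' Projects the cluster's member voxels onto its axis; the two extreme
#' projections are the shaft endpoints. The head is the endpoint nearer the
#' volume's center of intensity mass (falling back to the geometric center of
#' the grid if the volume is empty), following the anatomical fact that the
#' deepest contact lies closest to the center of the brain. An exact tie is
#' broken toward the endpoint whose nearest voxel has the lower flattened
#' index. A single-point cluster returns its own centroid.
#'
#' @param cluster A `seeg_electrode_cluster`.
#' @param axis Axis list (`point`, `direction`) in voxel coords; defaults to
#'   the cluster's own fitted axis.
#' @param volume The source [seeg_volume].
#' @param cloud The `seeg_pointcloud` the cluster indexes into.
#' @return 0-based (possibly fractional) voxel coordinates of the head point.
#' @export
find_head_point <- function(cluster, axis = cluster$axis, volume, cloud) {
  pts <- cloud$coords[cluster$member_indices, , drop = FALSE]
  if (nrow(pts) == 1L) return(as.numeric(pts[1, ]))
  pts <- shaft_core_points(pts, axis)
  if (nrow(pts) == 1L) return(as.numeric(pts[1, ]))
  proj <- as.numeric(sweep(pts, 2, axis$point) %*% axis$direction)
  ends <- rbind(axis$point + min(proj) * axis$direction,
                axis$point + max(proj) * axis$direction)
  ctr <- intensity_center(volume)
  d <- sqrt(rowSums(sweep(ends, 2, ctr)^2))
  if (abs(d[1] - d[2]) < 1e-9) {
    flat <- function(p) {
      v <- pmin(pmax(round(p), 0), volume$shape - 1)
      v[1] + volume$shape[1] * (v[2] + volume$shape[2] * v[3])
    }
    return(ends[which.min(c(flat(ends[1, ]), flat(ends[2, ]))), ])
  }
  ends[which.min(d), ]
}

# Core of a shaft's member voxels: points near the axis (<= 3 voxels
# perpendicular) restricted to the largest contiguous run of axis
# projections (runs split at gaps > 3 voxels). Stray supra-threshold noise
# voxels - off the shaft, or near the axis line but beyond the shaft ends -
# are excluded so they cannot define endpoints or bounding boxes.
shaft_core_points <- function(pts, axis) {
  if (nrow(pts) <= 2L) return(pts)
  near <- point_line_dist(pts, axis$point, axis$direction) <= 3
  if (sum(near) >= 2L) pts <- pts[near, , drop = FALSE]
  proj <- as.numeric(sweep(pts, 2, axis$point) %*% axis$direction)
  ord <- order(proj)
  gaps <- diff(proj[ord])
  run_id <- cumsum(c(1, gaps > 3))
  best <- which.max(tabulate(run_id))
  pts[ord[run_id == best], , drop = FALSE]
}

# 0/1 array marking voxels within `radius` voxels of the cluster axis and
# within the shaft core's projection span dilated by one pitch. Computed
# only inside the tube's bounding box for speed.
axis_tube_mask <- function(volume, axis, core_pts, pitch_mm, radius = 2.5) {
  mask <- array(0, volume$shape)
  proj <- as.numeric(sweep(core_pts, 2, axis$point) %*% axis$direction)
  pitch_vox <- pitch_mm / min(voxel_size(volume))
  lo_p <- min(proj) - pitch_vox
  hi_p <- max(proj) + pitch_vox
  ends <- rbind(axis$point + lo_p * axis$direction,
                axis$point + hi_p * axis$direction)
  lo <- pmax(floor(apply(ends, 2, min) - radius), 0)
  hi <- pmin(ceiling(apply(ends, 2, max) + radius), volume$shape - 1)
  idx <- as.matrix(expand.grid(lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]))
  rel <- sweep(idx, 2, axis$point)
  p <- as.numeric(rel %*% axis$direction)
  perp2 <- rowSums(rel^2) - p^2
  inside <- perp2 <= radius^2 & p >= lo_p & p <= hi_p
  mask[idx[inside, , drop = FALSE] + 1] <- 1
  mask
}

# Intensity-weighted centroid of the volume, 0-based voxel coords; geometric
# grid center when there is no mass.
intensity_center <- function(volume) {
  tot <- sum(volume$data)
  if (tot <= 0) return((volume$shape - 1) / 2)
  d <- volume$shape
  w1 <- apply(volume$data, 1, sum); w2 <- apply(volume$data, 2, sum)
  w3 <- apply(volume$data, 3, sum)
  c(sum((seq_len(d[1]) - 1) * w1), sum((seq_len(d[2]) - 1) * w2),
    sum((seq_len(d[3]) - 1) * w3)) / tot
}

#' Center-of-mass convergence to the local brightest spot
#'
#' From a starting point, repeatedly replaces the current position with the
#' intensity-weighted centroid of the surrounding cube (`cube_mm` edge,
#' matched to the physical contact size), sampling intensities by trilinear
#' interpolation on a 0.25 mm grid. Voxels belonging to the electrode's own
#' cluster get double weight, which keeps the walk on the shaft when a
#' neighboring structure is nearby. Iteration stops when the displacement
#' falls below `tol_voxel` voxels or after `max_iter` steps; if the iterate
#' enters a two-point cycle (two comparable bright spots), the candidate with
#' the higher interpolated intensity is returned.
#'
#' @param volume A [seeg_volume].
#' @param start 0-based voxel coordinates of the starting point.
#' @param cube_mm Cube edge length in mm.
#' @param cluster_mask Optional logical/0-1 array (volume shape): voxels of
#'   the electrode's cluster, given double weight. The doubling is applied
#'   through the trilinearly interpolated membership fraction so it varies
#'   smoothly with sub-voxel position.
#' @param max_iter Iteration cap.
#' @param tol_voxel Convergence displacement threshold, voxels.
#' @return 0-based fractional voxel coordinates of the converged point.
#' @export
center_of_mass_converge <- function(volume, start, cube_mm = 2.0,
                                    cluster_mask = NULL, max_iter = 10L,
                                    tol_voxel = 0.05) {
  stopifnot(inherits(volume, "seeg_volume"))
  mask_vol <- if (is.null(cluster_mask)) NULL else
    seeg_volume(array(as.numeric(cluster_mask), volume$shape), volume$affine)
  p_mm <- as.numeric(voxel_to_mm(volume, start))
  off <- seq(-cube_mm / 2, cube_mm / 2, by = 0.25)
  grid <- as.matrix(expand.grid(x = off, y = off, z = off))
  prev <- NULL
  for (it in seq_len(max_iter)) {
    pos_mm <- sweep(grid, 2, p_mm, "+")
    vox <- mm_to_voxel(volume, pos_mm)
    w <- interp_intensity(volume, vox)
    if (!is.null(mask_vol)) {
      # doubling via the interpolated cluster-membership fraction: the same
      # in-cluster weighting, but smooth in the sub-voxel position, so the
      # discrete member set cannot bias the centroid
      w <- w * (1 + interp_intensity(mask_vol, vox))
    }
    tot <- sum(w)
    if (tot <= 0)
      stop_seeg("no_mass", "center-of-mass cube has zero total intensity")
    new_mm <- colSums(pos_mm * w) / tot
    step_vox <- sqrt(sum(((new_mm - p_mm) / voxel_size(volume))^2))
    if (!is.null(prev) &&
        sqrt(sum(((new_mm - prev) / voxel_size(volume))^2)) < tol_voxel &&
        step_vox >= tol_voxel) {
      # 2-cycle between two bright spots: keep the brighter candidate
      cand <- rbind(new_mm, p_mm)
      ints <- interp_intensity(volume, mm_to_voxel(volume, cand))
      p_mm <- cand[which.max(ints), ]
      break
    }
    prev <- p_mm
    p_mm <- new_mm
    if (step_vox < tol_voxel) break
  }
  as.numeric(mm_to_voxel(volume, p_mm))
}

#' Segment the contacts of one electrode
#'
#' Implements fixed-pitch stepping with center-of-mass refinement: the first
#' contact is converged from the shaft's head (deepest) point; each further
#' contact starts one pitch along the shaft axis away from the brain center
#' and is converged in turn. Stepping terminates when (a) `max_contacts` have
#' been found, (b) the stepped point leaves the cluster's bounding box
#' dilated by one pitch, (c) the converged intensity drops below the
#' extraction threshold (off the end of the shaft), or (d) the converged
#' point fails to advance along the axis by at least half a pitch (stalled on
#' the previous contact), which also guarantees strictly monotone contact
#' projections.
#'
#' @param volume A [seeg_volume].
#' @param cluster A `seeg_electrode_cluster`.
#' @param cloud The `seeg_pointcloud` (provides the extraction threshold and
#'   member coordinates).
#' @param pitch_mm Contact pitch (mm).
#' @param max_contacts Cap on contacts per electrode.
#' @param cube_mm Center-of-mass cube edge (mm).
#' @param com_max_iter,com_tol_voxel Convergence controls, see
#'   [center_of_mass_converge].
#' @return A `seeg_contact_set`: `electrode_label`, `contacts` (n x 3 matrix
#'   of mm coordinates, head/deepest first), `pitch_used`.
#' @export
segment_contacts <- function(volume, cluster, cloud, pitch_mm = 3.5,
                             max_contacts = 16L, cube_mm = 2.0,
                             com_max_iter = 10L, com_tol_voxel = 0.05) {
  threshold <- cloud$threshold
  pts <- cloud$coords[cluster$member_indices, , drop = FALSE]
  axis <- cluster$axis
  head_vox <- find_head_point(cluster, axis, volume, cloud)
  head_mm <- as.numeric(voxel_to_mm(volume, head_vox))
  # stepping direction: along the shaft from the head endpoint toward the
  # opposite (superficial) endpoint, in mm space
  core <- shaft_core_points(pts, axis)
  core_mm <- t(volume$affine %*% rbind(t(core), 1))[, 1:3, drop = FALSE]
  A <- volume$affine[1:3, 1:3]
  dir_mm <- as.numeric(A %*% axis$direction)
  dir_mm <- dir_mm / sqrt(sum(dir_mm^2))
  proj_core <- as.numeric(sweep(core_mm, 2, head_mm) %*% dir_mm)
  if (max(proj_core) < -min(proj_core)) dir_mm <- -dir_mm
  # in-cluster double weighting, realized as a smooth tube around the fitted
  # shaft axis (radius 2.5 voxels, spanning the shaft core +- one pitch):
  # rotationally symmetric about the axis, so the doubling confines the
  # center-of-mass walk to this electrode without biasing it sideways
  mask <- axis_tube_mask(volume, cluster$axis, core, pitch_mm)
  box_lo <- apply(core_mm, 2, min) - pitch_mm
  box_hi <- apply(core_mm, 2, max) + pitch_mm
  contacts <- NULL
  # first contact: converge from the head point; if that lands below the
  # extraction threshold (head defined by an off-shaft voxel), advance along
  # the shaft up to two pitches before giving up
  for (j in 0:2) {
    start_mm <- head_mm + j * pitch_mm * dir_mm
    cur_vox <- tryCatch(
      center_of_mass_converge(volume, as.numeric(mm_to_voxel(volume, start_mm)),
                              cube_mm, mask, com_max_iter, com_tol_voxel),
      seeg_no_mass = function(e) NULL)
    if (!is.null(cur_vox) && interp_intensity(volume, cur_vox) >= threshold) {
      contacts <- rbind(contacts, as.numeric(voxel_to_mm(volume, cur_vox)))
      break
    }
  }
  while (!is.null(contacts) && nrow(contacts) < max_contacts) {
    step_mm <- contacts[nrow(contacts), ] + pitch_mm * dir_mm
    if (any(step_mm < box_lo) || any(step_mm > box_hi)) break
    nxt <- tryCatch(
      center_of_mass_converge(volume, as.numeric(mm_to_voxel(volume, step_mm)),
                              cube_mm, mask, com_max_iter, com_tol_voxel),
      seeg_no_mass = function(e) NULL)
    if (is.null(nxt)) break
    if (interp_intensity(volume, nxt) < threshold) break
    nxt_mm <- as.numeric(voxel_to_mm(volume, nxt))
    advance <- sum((nxt_mm - contacts[nrow(contacts), ]) * dir_mm)
    if (advance < 0.5 * pitch_mm) break
    contacts <- rbind(contacts, nxt_mm)
  }
  if (is.null(contacts) || nrow(contacts) == 0L)
    stop_seeg("no_contacts", "no contact found for cluster ", cluster$label)
  rownames(contacts) <- NULL
  structure(list(electrode_label = cluster$label, contacts = contacts,
                 pitch_used = pitch_mm),
            class = "seeg_contact_set")
}

#' @export
print.seeg_contact_set <- function(x, ...) {
  cat("<seeg_contact_set> ", x$electrode_label, ": ", nrow(x$contacts),
      " contacts, pitch ", x$pitch_used, " mm\n", sep = "")
  invisible(x)
}

#' Geometric quality control of segmented contacts
#'
#' Two indirect accuracy metrics that need no manual gold standard, both
#' exploiting the rigid geometry of depth electrodes: (1) the axis-contact
#' distance, the perpendicular distance of each contact to a total-least-
#' squares line re-regressed through that electrode's final contact
#' coordinates (contacts on a straight shaft should be collinear), and
#' (2) the adjacent-contact distance error, the deviation of each
#' consecutive-contact Euclidean distance from the manufactured pitch.
#' Single-contact electrodes contribute an axis distance of 0 by convention
#' and no pair metric.
#'
#' @param contact_sets A `seeg_contact_set` or list of them.
#' @return A `seeg_geometry_qc` list with data frames `contacts`
#'   (`electrode`, `contact_index`, `axis_distance_mm`) and `pairs`
#'   (`electrode`, `pair_index`, `distance_mm`, `error_mm`).
#' @export
geometry_qc <- function(contact_sets) {
  if (inherits(contact_sets, "seeg_contact_set"))
    contact_sets <- list(contact_sets)
  cdf <- NULL; pdf_ <- NULL
  for (cs in contact_sets) {
    n <- nrow(cs$contacts)
    if (n >= 2L) {
      fit <- principal_line(cs$contacts)
      ad <- point_line_dist(cs$contacts, fit$point, fit$direction)
      dist_ <- sqrt(rowSums(diff(cs$contacts)^2))
      pdf_ <- rbind(pdf_, data.frame(electrode = cs$electrode_label,
                                     pair_index = seq_len(n - 1L),
                                     distance_mm = dist_,
                                     error_mm = dist_ - cs$pitch_used))
    } else ad <- 0
    cdf <- rbind(cdf, data.frame(electrode = cs$electrode_label,
                                 contact_index = seq_len(n),
                                 axis_distance_mm = ad))
  }
  structure(list(contacts = cdf,
                 pairs = if (is.null(pdf_))
                   data.frame(electrode = character(), pair_index = integer(),
                              distance_mm = numeric(), error_mm = numeric())
                 else pdf_),
            class = "seeg_geometry_qc")
}

#' @export
print.seeg_geometry_qc <- function(x, ...) {
  cat("<seeg_geometry_qc> ", nrow(x$contacts), " contacts, ",
      nrow(x$pairs), " adjacent pairs\n", sep = "")
  if (nrow(x$contacts))
    cat("  axis-contact distance: median ",
        signif(stats::median(x$contacts$axis_distance_mm), 3), " mm, max ",
        signif(max(x$contacts$axis_distance_mm), 3), " mm\n", sep = "")
  if (nrow(x$pairs))
    cat("  adjacent distance: mean ", signif(mean(x$pairs$distance_mm), 4),
        " mm (error sd ", signif(stats::sd(x$pairs$error_mm), 3), ")\n",
        sep = "")
  invisible(x)
}
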