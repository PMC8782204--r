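#' 3D Hough transform for line detection in a voxel point cloud
#'
#' Detects line-shaped structures (electrode shafts) by voting over a
#' discretized space of 3D line parameters: a direction from a subdivided
#' icosahedron (antipode-deduplicated, so ~321 directions at granularity 3,
#' angular spacing under 5 degrees) crossed with the line's anchor point,
#' expressed in the 2D plane orthogonal to the direction and binned on a
#' regular grid. Lines are extracted iteratively: take the globally
#' best-voted cell, claim every point within `inlier_radius` of that line,
#' remove the claimed points, and repeat until the next peak falls below
#' `min_votes`.
#'
#' The direction of each returned line is refined to the principal axis of
#' its inliers and sign-normalized so its largest-magnitude component is
#' positive; the anchor is the inlier centroid.
#'
#' @param cloud A `seeg_pointcloud` from [extract_bright_voxels].
#' @param direction_granularity Icosphere subdivision level (3 gives 321
#'   unique directions).
#' @param distance_bin Anchor grid resolution in voxels.
#' @param min_votes Minimum accumulator votes to accept a line. Default
#'   `NA` resolves to `max(10, 0.25 * votes of the first peak)`, so the
#'   number of electrodes need not be known in advance.
#' @param inlier_radius Point-to-line distance (voxels) below which a point
#'   is claimed by a detected line.
#' @param max_lines Optional hard cap on the number of lines (e.g. a known
#'   electrode count); `NA` for vote-based stopping only.
#' @return A list of `seeg_hough_line` objects, in descending vote order:
#'   each has `direction` (unit 3-vector), `anchor` (point on the line,
#'   voxel coordinates), `votes`, and `inliers` (row indices into the cloud).
#'   Empty list if no cell reaches `min_votes`.
#' @export
hough_lines_3d <- function(cloud, direction_granularity = 3L,
                           distance_bin = 1.0, min_votes = NA,
                           inlier_radius = 2.0, max_lines = NA) {
  stopifnot(inherits(cloud, "seeg_pointcloud"))
  pts <- cloud$coords
  if (nrow(pts) == 0L) stop_seeg("empty_cloud", "point cloud is empty")
  dirs <- icosphere_directions(direction_granularity)
  # per-direction orthonormal basis of the anchor plane
  bases <- lapply(seq_len(nrow(dirs)), function(i) plane_basis(dirs[i, ]))
  remaining <- seq_len(nrow(pts))
  lines <- list()
  repeat {
    if (length(remaining) == 0L) break
    if (!is.na(max_lines) && length(lines) >= max_lines) break
    peak <- hough_best_cell(pts[remaining, , drop = FALSE], dirs, bases,
                            distance_bin)
    if (is.null(peak)) break
    d <- dirs[peak$dir_idx, ]
    # anchor: centroid of the points in the winning cell
    anchor <- colMeans(pts[remaining[peak$members], , drop = FALSE])
    inl <- remaining[point_line_dist(pts[remaining, , drop = FALSE],
                                     anchor, d) <= inlier_radius]
    # refine with the principal axis of the inliers
    if (length(inl) >= 2L) {
      fit <- principal_line(pts[inl, , drop = FALSE])
      d <- fit$direction
      anchor <- fit$point
      inl <- remaining[point_line_dist(pts[remaining, , drop = FALSE],
                                       anchor, d) <= inlier_radius]
    }
    votes <- peak$votes
    if (is.na(min_votes)) min_votes <- max(10, 0.25 * votes)
    if (votes < min_votes) break
    lines[[length(lines) + 1L]] <-
      structure(list(direction = sign_normalize(d), anchor = anchor,
                     votes = votes, inliers = inl),
                class = "seeg_hough_line")
    remaining <- setdiff(remaining, inl)
    if (length(remaining) < min_votes) break
  }
  lines
}

# Global best accumulator cell over all directions; members are row indices
# into pts of the points voting in that cell.
hough_best_cell <- function(pts, dirs, bases, distance_bin) {
  best <- NULL
  for (i in seq_len(nrow(dirs))) {
    uv <- pts %*% bases[[i]]                      # N x 2 plane coordinates
    iu <- floor(uv[, 1] / distance_bin); iv <- floor(uv[, 2] / distance_bin)
    iu <- iu - min(iu); iv <- iv - min(iv)
    key <- as.integer(iu * (max(iv) + 1) + iv + 1)
    tab <- tabulate(key)
    v <- max(tab)
    if (is.null(best) || v > best$votes) {
      members <- which(key == which.max(tab))
      best <- list(dir_idx = i, votes = as.integer(v), members = members)
    }
  }
  if (is.null(best) || best$votes < 2L) NULL else best
}

# Unit directions from a subdivided icosahedron, one per antipodal pair.
icosphere_directions <- function(level = 3L) {
  phi <- (1 + sqrt(5)) / 2
  verts <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  faces <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  norm1 <- function(m) m / sqrt(rowSums(m^2))
  verts <- norm1(verts)
  for (s in seq_len(level)) {
    edge_mid <- new.env()
    midpoint <- function(a, b) {
      k <- paste(min(a, b), max(a, b))
      if (!is.null(edge_mid[[k]])) return(edge_mid[[k]])
      verts <<- rbind(verts, (verts[a, ] + verts[b, ]) /
                        sqrt(sum((verts[a, ] + verts[b, ])^2)))
      edge_mid[[k]] <- nrow(verts)
      nrow(verts)
    }
    newf <- matrix(0L, 0, 3)
    for (f in seq_len(nrow(faces))) {
      a <- faces[f, 1]; b <- faces[f, 2]; c <- faces[f, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c); ca <- midpoint(c, a)
      newf <- rbind(newf, c(a, ab, ca), c(b, bc, ab), c(c, ca, bc),
                    c(ab, bc, ca))
    }
    faces <- newf
  }
  verts <- norm1(verts)
  # antipode dedup: keep the representative with positive leading component
  keep <- apply(verts, 1, function(v) {
    lead <- v[which.max(abs(v))]
    lead > 0 || (lead == 0 && v[1] >= 0)
  })
  unique(round(verts[keep, , drop = FALSE], 10))
}

# Orthonormal basis (3 x 2) of the plane orthogonal to unit vector d.
plane_basis <- function(d) {
  ref <- if (abs(d[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- ref - sum(ref * d) * d
  u <- u / sqrt(sum(u^2))
  v <- c(d[2] * u[3] - d[3] * u[2],
         d[3] * u[1] - d[1] * u[3],
         d[1] * u[2] - d[2] * u[1])
  cbind(u, v)
}

# Perpendicular distances from points (N x 3) to the line (anchor, direction).
point_line_dist <- function(pts, anchor, d) {
  rel <- sweep(pts, 2, anchor)
  proj <- as.numeric(rel %*% d)
  sqrt(pmax(rowSums(rel^2) - proj^2, 0))
}

# Total-least-squares line: centroid + leading principal axis.
principal_line <- function(pts) {
  ctr <- colMeans(pts)
  rel <- sweep(pts, 2, ctr)
  sv <- svd(rel, nu = 0, nv = 3)
  d <- sv$v[, 1]
  rss <- max(sum(rel^2) - sum((rel %*% d)^2), 0)
  list(point = ctr, direction = sign_normalize(d),
       rms = sqrt(rss / nrow(pts)))
}

sign_normalize <- function(d) {
  d <- d / sqrt(sum(d^2))
  lead <- d[which.max(abs(d))]
  if (lead < 0) -d else d
}
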