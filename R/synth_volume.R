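#' Specification of synthetic depth electrodes
#'
#' Describes the implant geometry emulated by [synth_volume]: straight (or
#' slightly bent) shafts of bright ellipsoidal contact blobs over a dim
#' brain-like background. Defaults mirror common clinical depth electrodes:
#' 8-16 contacts per shaft, 2 mm contact diameter, 3.5 mm center-to-center
#' pitch.
#'
#' @param n_electrodes Number of shafts to place (>= 0).
#' @param contacts_range Integer range `c(min, max)` of contacts per shaft.
#' @param pitch_mm Center-to-center contact spacing in mm.
#' @param contact_diameter_mm Contact diameter in mm; the rendered blob's
#'   Gaussian profile has this FWHM.
#' @param bend_amplitude_mm Maximum perpendicular deviation of a bent shaft
#'   from the straight chord (0 = straight).
#' @param peak_intensity Blob peak intensity (arbitrary CT-like units).
#' @param background_ratio Brain background level as a fraction of blob peak.
#' @param noise_ratio Additive Gaussian noise SD as a fraction of blob peak.
#' @return A list of class `electrode_spec`.
#' @export
electrode_spec <- function(n_electrodes = 8L,
                           contacts_range = c(8L, 16L),
                           pitch_mm = 3.5,
                           contact_diameter_mm = 2.0,
                           bend_amplitude_mm = 0,
                           peak_intensity = 1000,
                           background_ratio = 0.1,
                           noise_ratio = 0.1) {
  if (n_electrodes < 0) stop_seeg("bad_spec", "n_electrodes must be >= 0")
  if (pitch_mm <= contact_diameter_mm / 2)
    stop_seeg("bad_spec", "pitch must exceed half the contact diameter")
  structure(list(n_electrodes = as.integer(n_electrodes),
                 contacts_range = as.integer(contacts_range),
                 pitch_mm = pitch_mm,
                 contact_diameter_mm = contact_diameter_mm,
                 bend_amplitude_mm = bend_amplitude_mm,
                 peak_intensity = peak_intensity,
                 background_ratio = background_ratio,
                 noise_ratio = noise_ratio),
            class = "electrode_spec")
}

# Run expr with an isolated, seeded RNG stream; the caller's RNG state is
# untouched, so generators are pure functions of (spec, seed).
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Synthetic skull-stripped CT volume with electrode ground truth
#'
#' Renders a dim ellipsoidal "brain" (with additive Gaussian noise, zero
#' outside the brain as after skull-stripping) and plants `n_electrodes`
#' shafts of Gaussian-profile contact blobs. Shafts run from a random entry
#' point on the brain surface toward the brain interior; the deepest contact
#' (the head) lies nearest the brain center. Shafts are rejected and resampled
#' until every pair of contacts on different shafts is at least twice the
#' contact diameter apart; placement failure after bounded retries raises
#' `seeg_placement_failed`.
#'
#' @param spec An [electrode_spec].
#' @param shape Volume dimensions in voxels (length 3); the default gives a
#'   96 mm field of view.
#' @param affine 4x4 voxel-to-mm affine. The default 0.7 mm isotropic grid
#'   matches typical thin-slice post-implant CT resolution.
#' @param seed Integer seed; the generator is deterministic given
#'   `(spec, shape, affine, seed)`.
#' @return A list with elements `volume` (a [seeg_volume]) and `truth`, a list
#'   of class `seeg_truth` with per-electrode mm contact coordinates
#'   (head first), unit directions (head toward tail), and the blob peak /
#'   threshold-relevant intensities.
#' @examples
#' sv <- synth_volume(electrode_spec(n_electrodes = 2), shape = c(64, 64, 64),
#'                    seed = 1)
#' sv$truth$contacts[[1]][1:2, ]
#' @export
synth_volume <- function(spec, shape = c(137L, 137L, 137L),
                         affine = diag(c(0.7, 0.7, 0.7, 1)), seed = 1L) {
  stopifnot(inherits(spec, "electrode_spec"))
  shape <- as.integer(shape)
  vol0 <- seeg_volume(array(0, dim = shape), affine)
  with_seed(seed, {
    vs <- voxel_size(vol0)
    # brain ellipsoid in mm, centered in the grid
    corner_mm <- voxel_to_mm(vol0, rbind(c(0, 0, 0), shape - 1))
    center <- colMeans(corner_mm)
    semi <- abs(corner_mm[2, ] - corner_mm[1, ]) / 2 * 0.88
    placed <- list()
    dirs <- list()
    all_pts <- NULL
    min_sep <- 2 * spec$contact_diameter_mm
    margin <- 2 * max(vs)
    lo <- pmin(corner_mm[1, ], corner_mm[2, ]) + margin
    hi <- pmax(corner_mm[1, ], corner_mm[2, ]) - margin
    n_try <- 0L
    while (length(placed) < spec$n_electrodes) {
      n_try <- n_try + 1L
      if (n_try > 400L * max(1L, spec$n_electrodes))
        stop_seeg("placement_failed",
                  "could not place ", spec$n_electrodes, " electrodes with ",
                  min_sep, " mm separation in this volume")
      n_range <- spec$contacts_range[1]:spec$contacts_range[2]
      n_c <- n_range[sample.int(length(n_range), 1)]
      len <- (n_c - 1) * spec$pitch_mm
      # entry point on the ellipsoid surface, shaft aimed near the center
      u <- rnorm(3); u <- u / sqrt(sum(u^2))
      entry <- center + semi * u
      target <- center + runif(3, -8, 8)
      dir_in <- target - entry
      dir_in <- dir_in / sqrt(sum(dir_in^2))
      # chord length from the entry point through the brain along dir_in
      qa <- sum((dir_in / semi)^2)
      qb <- 2 * sum((entry - center) * dir_in / semi^2)
      qc <- sum(((entry - center) / semi)^2) - 1
      disc <- qb^2 - 4 * qa * qc
      if (disc <= 0) next
      chord <- (-qb + sqrt(disc)) / (2 * qa)
      tail_depth <- runif(1, 2, 6)    # most superficial contact, mm from entry
      if (tail_depth + len > 0.94 * chord) next
      head_pt <- entry + dir_in * (tail_depth + len)   # deepest contact
      dir_out <- -dir_in               # head (deep) toward tail (superficial)
      s <- (seq_len(n_c) - 1) * spec$pitch_mm
      pts <- t(vapply(s, function(si) head_pt + dir_out * si, numeric(3)))
      if (spec$bend_amplitude_mm > 0 && n_c > 2) {
        # perpendicular sinusoidal deviation, max at mid-shaft
        ref <- if (abs(dir_out[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
        v <- ref - sum(ref * dir_out) * dir_out
        v <- v / sqrt(sum(v^2))
        L <- s[n_c]
        dev <- spec$bend_amplitude_mm * sin(pi * s / L)
        pts <- pts + outer(dev, v)
      }
      if (any(pts < matrix(lo, n_c, 3, byrow = TRUE)) ||
          any(pts > matrix(hi, n_c, 3, byrow = TRUE))) next
      # keep all contacts inside the brain ellipsoid
      if (any(colSums((t(pts) - center)^2 / semi^2) > 0.96)) next
      if (!is.null(all_pts)) {
        d2 <- outer(rowSums(pts^2), rowSums(all_pts^2), "+") -
          2 * pts %*% t(all_pts)
        if (min(d2) < min_sep^2) next
      }
      placed[[length(placed) + 1L]] <- pts
      dirs[[length(dirs) + 1L]] <- dir_out
      all_pts <- rbind(all_pts, pts)
    }
    # render: background ellipsoid + noise inside the brain, then blobs
    idx <- as.matrix(expand.grid(i = seq_len(shape[1]) - 1,
                                 j = seq_len(shape[2]) - 1,
                                 k = seq_len(shape[3]) - 1))
    mm <- voxel_to_mm(vol0, idx)
    r2 <- colSums((t(mm) - center)^2 / semi^2)
    brain <- r2 <= 1
    bg <- spec$background_ratio * spec$peak_intensity
    dat <- numeric(nrow(idx))
    dat[brain] <- bg * (1 - 0.3 * r2[brain]) +
      rnorm(sum(brain), 0, spec$noise_ratio * spec$peak_intensity)
    dat <- pmax(dat, 0)
    dim(dat) <- shape
    sigma <- spec$contact_diameter_mm / (2 * sqrt(2 * log(2)))  # FWHM -> sd
    if (!is.null(all_pts)) {
      ainv <- solve(affine)
      half <- ceiling(4 * sigma / vs)
      for (p in seq_len(nrow(all_pts))) {
        cvox <- (ainv %*% c(all_pts[p, ], 1))[1:3]
        w <- lapply(1:3, function(a)
          max(0, floor(cvox[a] - half[a])):min(shape[a] - 1,
                                               ceiling(cvox[a] + half[a])))
        loc <- as.matrix(expand.grid(w[[1]], w[[2]], w[[3]]))
        lmm <- t(affine %*% rbind(t(loc), 1))[, 1:3, drop = FALSE]
        g <- exp(-rowSums((lmm - matrix(all_pts[p, ], nrow(loc), 3,
                                        byrow = TRUE))^2) / (2 * sigma^2))
        dat[loc + 1] <- dat[loc + 1] + spec$peak_intensity * g
      }
    }
    truth <- structure(list(contacts = placed, directions = dirs,
                            pitch_mm = spec$pitch_mm,
                            peak_intensity = spec$peak_intensity,
                            brain_center_mm = center),
                       class = "seeg_truth")
    list(volume = seeg_volume(dat, affine), truth = truth)
  })
}
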