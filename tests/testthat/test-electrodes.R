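test_that("thresholding extracts exactly the supra-threshold voxels", {
  dat <- array(0, dim = c(20, 20, 20))
  set.seed(4)
  idx <- cbind(sample(0:19, 10), sample(0:19, 10), sample(0:19, 10))
  idx <- unique(idx)
  dat[idx + 1] <- 1000
  vol <- seeg_volume(dat)
  cloud <- extract_bright_voxels(vol, "absolute:500")
  # oracle: exhaustive scan
  truth <- arrayInd(which(dat > 500), dim(dat)) - 1L
  expect_equal(cloud$coords[order(cloud$coords[, 1], cloud$coords[, 2],
                                  cloud$coords[, 3]), ],
               truth[order(truth[, 1], truth[, 2], truth[, 3]), ],
               ignore_attr = TRUE)
  expect_true(all(cloud$intensities > cloud$threshold))
})

test_that("threshold boundary is strict and empty clouds raise named errors", {
  vol <- seeg_volume(array(100, dim = c(5, 5, 5)))
  expect_error(extract_bright_voxels(vol, "absolute:100"),
               class = "seeg_empty_cloud")
  expect_error(extract_bright_voxels(seeg_volume(array(0, dim = c(5, 5, 5)))),
               class = "seeg_empty_cloud")
  expect_error(extract_bright_voxels(vol, "nonsense"),
               class = "seeg_bad_threshold_rule")
})

test_that("Hough transform recovers a single collinear line's direction", {
  pts <- round(line_points(50, c(5, 20, 20), c(1, 0, 0)))
  cloud <- make_cloud(pts)
  lines <- hough_lines_3d(cloud)
  expect_length(lines, 1)
  # angle to the generating direction below the direction-bin half-width
  ang <- acos(min(1, abs(sum(lines[[1]]$direction * c(1, 0, 0))))) * 180 / pi
  expect_lt(ang, 2.5)
  expect_setequal(lines[[1]]$inliers, seq_len(50))
})

test_that("two parallel lines are separated with their generating inlier sets", {
  p1 <- round(line_points(100, c(5, 10, 10), c(1, 0, 0), spacing = 0.5))
  p2 <- round(line_points(100, c(5, 30, 10), c(1, 0, 0), spacing = 0.5))
  cloud <- make_cloud(rbind(p1, p2))
  lines <- hough_lines_3d(cloud)
  expect_length(lines, 2)
  sets <- lapply(lines, `[[`, "inliers")
  expect_true(setequal(sets[[1]], 1:100) && setequal(sets[[2]], 101:200) ||
              setequal(sets[[1]], 101:200) && setequal(sets[[2]], 1:100))
})

test_that("three non-parallel lines match truth under the best pairing", {
  dirs <- list(c(1, 0, 0), c(0.2, 1, 0.1), c(0.3, -0.2, 1))
  anchors <- list(c(4, 10, 12), c(20, 5, 30), c(10, 35, 5))
  pts <- do.call(rbind, lapply(1:3, function(i)
    line_points(60, anchors[[i]], dirs[[i]], spacing = 0.6)))
  cloud <- make_cloud(pts)
  lines <- hough_lines_3d(cloud)
  expect_length(lines, 3)
  # brute-force over all pairings of detected to truth lines
  perms <- list(1:3, c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2),
                c(3, 2, 1))
  best <- min(vapply(perms, function(p) {
    max(vapply(1:3, function(i) {
      d <- dirs[[p[i]]] / sqrt(sum(dirs[[p[i]]]^2))
      acos(min(1, abs(sum(lines[[i]]$direction * d)))) * 180 / pi
    }, numeric(1)))
  }, numeric(1)))
  expect_lt(best, 5)
})

test_that("clustering agrees 100% with the nearest-line oracle on separated lines", {
  p1 <- line_points(120, c(5, 10, 10), c(1, 0.1, 0), spacing = 0.4,
                    jitter = 0.3, seed = 10)
  p2 <- line_points(120, c(5, 30, 28), c(1, -0.05, 0.1), spacing = 0.4,
                    jitter = 0.3, seed = 11)
  cloud <- make_cloud(rbind(p1, p2))
  lines <- hough_lines_3d(cloud)
  expect_length(lines, 2)
  cls <- cluster_electrodes(cloud, lines)
  lab <- integer(240)
  for (g in seq_along(cls)) lab[cls[[g]]$member_indices] <- g
  oracle <- nearest_line_assignment(rbind(p1, p2),
                                    list(c(5, 10, 10), c(5, 30, 28)),
                                    list(c(1, 0.1, 0), c(1, -0.05, 0.1)))
  expect_equal(relabel_agreement(lab, oracle), 1.0)
  # partition invariant
  expect_setequal(unlist(lapply(cls, `[[`, "member_indices")), 1:240)
})

test_that("single line with one component assigns every point one label", {
  pts <- round(line_points(50, c(5, 20, 20), c(1, 0.2, 0.1)))
  cloud <- make_cloud(pts)
  lines <- hough_lines_3d(cloud)
  cls <- cluster_electrodes(cloud, lines)
  expect_length(cls, 1)
  expect_setequal(cls[[1]]$member_indices, 1:50)
})

test_that("clustering is deterministic across repeated runs", {
  p1 <- line_points(80, c(5, 12, 10), c(1, 0, 0.2), jitter = 0.4, seed = 20)
  p2 <- line_points(80, c(5, 30, 25), c(0.9, 0.3, 0), jitter = 0.4, seed = 21)
  cloud <- make_cloud(rbind(p1, p2))
  lines <- hough_lines_3d(cloud)
  a <- cluster_electrodes(cloud, lines, seed = 1)
  b <- cluster_electrodes(cloud, lines, seed = 1)
  expect_identical(lapply(a, `[[`, "member_indices"),
                   lapply(b, `[[`, "member_indices"))
})

test_that("shaft axis fit is a total-least-squares line", {
  pts <- line_points(30, c(2, 3, 4), c(1, 1, 0.5), spacing = 0.8)
  cl <- list(member_indices = 1:30)
  fit <- fit_shaft_axis(cl, make_cloud(pts))
  expect_equal(fit$rms, 0, tolerance = 1e-8)
  d <- c(1, 1, 0.5) / sqrt(sum(c(1, 1, 0.5)^2))
  expect_equal(abs(sum(fit$direction * d)), 1, tolerance = 1e-10)
  # jittered: within 1 degree of the oracle principal axis on the same sample
  ptsj <- line_points(200, c(2, 3, 4), c(1, 1, 0.5), spacing = 0.3,
                      jitter = 0.1, seed = 30)
  fitj <- fit_shaft_axis(list(member_indices = 1:200), make_cloud(ptsj))
  sv <- svd(sweep(ptsj, 2, colMeans(ptsj)))$v[, 1]
  expect_lt(acos(min(1, abs(sum(fitj$direction * sv)))) * 180 / pi, 1)
  # two distinct points define the line exactly
  fit2 <- fit_shaft_axis(list(member_indices = 1:2),
                         make_cloud(rbind(c(0, 0, 0), c(2, 2, 2))))
  expect_equal(fit2$rms, 0, tolerance = 1e-6)
  expect_error(fit_shaft_axis(list(member_indices = 1:3),
                              make_cloud(rbind(c(1, 1, 1), c(1, 1, 1),
                                               c(1, 1, 1)))),
               class = "seeg_degenerate_axis")
})

test_that("head point is the shaft end nearer the intensity center", {
  # shaft along x from x=10 (near center of mass) to x=40 (periphery)
  centers <- cbind(seq(10, 40, by = 3.5), 24, 24)
  vol <- blob_volume(centers, shape = c(48, 48, 48))
  cloud <- extract_bright_voxels(vol, "absolute:500")
  lines <- hough_lines_3d(cloud)
  cls <- cluster_electrodes(cloud, lines)
  hp <- find_head_point(cls[[1]], cls[[1]]$axis, vol, cloud)
  expect_lt(abs(hp[1] - 10), 1.5)   # the x=10 end, not x=40
  expect_lt(sqrt(sum((hp[2:3] - c(24, 24))^2)), 1.5)
})

test_that("center-of-mass convergence matches the brightest-point oracle", {
  ctr <- c(20.37, 19.62, 20.21)
  vol <- blob_volume(matrix(ctr, 1), shape = c(40, 40, 40))
  # start two voxels off-center
  res <- center_of_mass_converge(vol, ctr + c(2, 0, -1), cube_mm = 2)
  oracle <- argmax_analytic(matrix(ctr, 1), ctr + c(1, -1, 1))
  expect_lt(sqrt(sum((res - oracle)^2)), 0.2)
})

test_that("center-of-mass handles degenerate neighborhoods", {
  dat <- array(0, dim = c(20, 20, 20))
  dat[11, 11, 11] <- 500
  vol <- seeg_volume(dat)
  res <- center_of_mass_converge(vol, c(11, 10, 10))
  expect_equal(res, c(10, 10, 10), tolerance = 1e-6)
  # uniform region: the geometric center is a fixed point
  vol2 <- seeg_volume(array(10, dim = c(20, 20, 20)))
  expect_equal(center_of_mass_converge(vol2, c(9.5, 9.5, 9.5)),
               c(9.5, 9.5, 9.5), tolerance = 1e-9)
  expect_error(center_of_mass_converge(vol, c(2, 2, 2)),
               class = "seeg_no_mass")
})

test_that("an eight-blob shaft segments into eight accurate contacts", {
  d <- c(1, 0.3, 0.15); d <- d / sqrt(sum(d^2))
  centers <- matrix(8, 8, 3) + outer((0:7) * 3.5, d)
  vol <- blob_volume(centers, shape = c(48, 48, 48), background = 50)
  cloud <- extract_bright_voxels(vol, "absolute:500")
  lines <- hough_lines_3d(cloud)
  cls <- cluster_electrodes(cloud, lines)
  cs <- segment_contacts(vol, cls[[1]], cloud)
  expect_equal(nrow(cs$contacts), 8)
  rec <- match_contacts(cs, centers, tol_mm = 1.75)
  expect_equal(rec$n_matched, 8)
  expect_lt(max(rec$errors_mm), 0.5)
  # monotone projection invariant
  proj <- cs$contacts %*% d
  expect_true(all(diff(proj) > 0) || all(diff(proj) < 0))
})

test_that("a single isolated blob yields exactly one contact at its center", {
  ctr <- c(20, 20, 20)
  vol <- blob_volume(matrix(ctr, 1), shape = c(40, 40, 40))
  cloud <- extract_bright_voxels(vol, "absolute:500")
  cl <- structure(list(label = "E1",
                       member_indices = seq_len(nrow(cloud$coords)),
                       centroid = colMeans(cloud$coords),
                       axis = list(point = ctr, direction = c(1, 0, 0),
                                   rms = 0)),
                  class = "seeg_electrode_cluster")
  cs <- segment_contacts(vol, cl, cloud)
  expect_equal(nrow(cs$contacts), 1)
  expect_lt(sqrt(sum((cs$contacts[1, ] - ctr)^2)), 0.2)
})

test_that("geometry QC reproduces closed-form distances", {
  # perfectly collinear contacts at exact pitch
  ideal <- structure(list(electrode_label = "E1",
                          contacts = cbind(seq(0, 24.5, by = 3.5), 0, 0),
                          pitch_used = 3.5), class = "seeg_contact_set")
  qc <- geometry_qc(ideal)
  expect_equal(qc$contacts$axis_distance_mm, rep(0, 8), tolerance = 1e-10)
  expect_equal(qc$pairs$error_mm, rep(0, 7), tolerance = 1e-10)
  # one contact displaced 0.5 mm perpendicular to a long collinear set
  cc <- cbind(seq(0, 38.5, by = 3.5), 0, 0)
  cc[6, 2] <- 0.5
  disp <- structure(list(electrode_label = "E1", contacts = cc,
                         pitch_used = 3.5), class = "seeg_contact_set")
  qcd <- geometry_qc(disp)
  # slightly under 0.5: the displaced contact also pulls the fitted line
  expect_equal(qcd$contacts$axis_distance_mm[6], 0.5, tolerance = 0.1)
  # spacings 3.0 and 4.0 at pitch 3.5 give errors -0.5 and +0.5
  sp <- structure(list(electrode_label = "E1",
                       contacts = cbind(c(0, 3, 7), 0, 0), pitch_used = 3.5),
                  class = "seeg_contact_set")
  qcs <- geometry_qc(sp)
  expect_equal(qcs$pairs$error_mm, c(-0.5, 0.5))
  expect_equal(qcs$pairs$distance_mm, c(3, 4))
})
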