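test_that("bond-distance clustering splits and merges at the cutoff", {
  two_close <- rbind(c(0, 0, 0), c(1.4, 0, 0))
  two_far <- rbind(c(0, 0, 0), c(1.6, 0, 0))
  expect_equal(build_clusters(two_close, r_bond = 1.5)$n_clusters, 1)
  expect_equal(build_clusters(two_far, r_bond = 1.5)$n_clusters, 2)
  expect_equal(build_clusters(matrix(numeric(0), ncol = 3))$n_clusters, 0)
  expect_error(build_clusters(two_close, r_bond = 0.8), "r_bond > 1")
  # labels partition the particles
  set.seed(4)
  pts <- matrix(stats::runif(90, 0, 12), ncol = 3)
  cs <- build_clusters(pts)
  expect_length(cs$labels, nrow(pts))
  expect_equal(sum(cs$sizes), nrow(pts))
  expect_equal(length(unique(cs$labels)), cs$n_clusters)
})

test_that("clustering is invariant under global rotation", {
  sh <- shell_geometry(6, 11)
  cfg <- decorate(derived_connectivity(9, 1, 1, 6), sh, seed = 17)
  cs <- build_clusters(cfg)
  set.seed(5)
  for (rep in 1:3) {
    Q <- random_rotation()
    rot <- as_positions(cfg) %*% t(Q)
    cs2 <- build_clusters(rot)
    expect_equal(cs2$n_clusters, cs$n_clusters)
    expect_equal(sort(cs2$sizes), sort(cs$sizes))
  }
})

test_that("the generating-structure fixture yields exactly five clusters", {
  sh <- shell_geometry(6, 11)
  cfg <- decorate(derived_connectivity(9, 1, 1, 0), sh, seed = 7)
  cs <- build_clusters(cfg, r_bond = 1.5)
  expect_equal(cs$n_clusters, 5)
})

test_that("tube, loop and blob fixtures are classified with correct end counts", {
  sh <- shell_geometry(6, 11)
  # a single torus at a latitude circle -> closed tube with no free ends
  cl0 <- generate_centerline(derived_connectivity(9, 1, 1, 0), sh)
  torus <- cl0[[which(vapply(cl0, function(x) x$type == "closed", TRUE))[1]]]
  cfg_t <- decorate_curves(list(torus), shell = sh, seed = 8)
  res_t <- classify_cluster(cfg_t)
  expect_equal(res_t$class, "closed-tube")
  expect_equal(res_t$n_ends, 0L)
  # the polar sphere -> spherical
  pole <- cl0[[which(vapply(cl0, function(x) x$type == "sphere", TRUE))]]
  cfg_s <- decorate_curves(list(pole), shell = sh, seed = 9)
  expect_equal(classify_cluster(cfg_s)$class, "spherical")
  # the theta-rotation coil -> open tube, both ends near the same pole
  cfg_c <- decorate(derived_connectivity(9, 1, 1, 2), sh, seed = 10)
  res_c <- classify_cluster(cfg_c)
  expect_equal(res_c$class, "open-tube")
  expect_equal(res_c$n_ends, 2L)
  polar_angle <- acos(res_c$ends[, 3] / sqrt(rowSums(res_c$ends^2)))
  expect_true(all(polar_angle < pi / 3) || all(pi - polar_angle < pi / 3))
})

test_that("tube radius estimator matches the uniform-disk oracle", {
  # uniform (rsa) filled straight tube of radius 1.5: raw mean perpendicular
  # distance 2R/3, so the calibrated estimate reads R
  curve <- list(list(type = "tube", points = cbind(seq(-12, 12, 0.5), 0, 0)))
  cfg <- decorate_curves(curve, tube_radius = 1.5, target_density = 0.5,
                         method = "rsa", jitter = 0, seed = 11)
  est <- tube_radius(cfg)
  expect_equal(est$radius, 1.5, tolerance = 0.12)
  # particles exactly on the axis -> 0
  line <- cbind(seq(0, 10, 0.5), 0, 0)
  expect_equal(tube_radius(line, calibration = "none")$radius, 0,
               tolerance = 1e-9)
  # thin hollow tube at radius 1: the raw estimator reads the shell radius
  set.seed(12)
  tpos <- seq(0, 25, length.out = 220)
  ang <- stats::runif(220) * 2 * pi
  hollow <- cbind(tpos, cos(ang), sin(ang))
  expect_equal(tube_radius(hollow, calibration = "none")$radius, 1.0,
               tolerance = 0.08)
})

test_that("cluster spacing recovers the meridian chord and plain gaps", {
  sh <- shell_geometry(6, 11)
  topo <- cluster_topology(decorate(derived_connectivity(9, 1, 1, 0), sh,
                                    seed = 13))
  expect_equal(cluster_spacing(topo), 2 * 8.5 * sin(pi / 9), tolerance = 0.2)
  # two parallel straight tubes 6 sigma apart
  curves <- list(list(type = "tube", points = cbind(seq(-10, 10, 0.5), 0, 0)),
                 list(type = "tube", points = cbind(seq(-10, 10, 0.5), 6, 0)))
  t2 <- cluster_topology(decorate_curves(curves, seed = 14))
  expect_equal(cluster_spacing(t2), 6.0, tolerance = 0.15)
  # a single compact cluster has no defined spacing
  blob <- cluster_topology(decorate_curves(
    list(list(type = "sphere", points = matrix(c(0, 0, 0), 1))), seed = 15))
  expect_error(cluster_spacing(blob), "spacing")
})

test_that("free-end bookkeeping holds across a decorated menu", {
  sh <- shell_geometry(6, 11)
  for (m in c(0, 2, 6)) {
    ds <- derived_connectivity(9, 1, 1, m)
    topo <- cluster_topology(decorate(ds, sh, seed = 20 + m))
    s <- topo$summary
    expect_equal(sum(s$n_ends[s$class == "open-tube"]), ds$n_open_ends)
    expect_true(all(s$n_ends[s$class %in% c("closed-tube", "spherical")] == 0))
  }
})
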