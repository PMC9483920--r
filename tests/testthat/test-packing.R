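test_that("rotation quantum is 2*pi/(2k+l)", {
  expect_equal(rotation_angle(4, 1), 2 * pi / 9)
  expect_equal(rotation_angle(2, 2), pi / 3)
  expect_equal(rotation_angle(5, 0), pi / 5)
  expect_error(rotation_angle(3, 3), "l must be")
})

test_that("inner radius follows the touching-chord condition", {
  expect_equal(shell_inner_radius(6, 5, 5), 5 / (2 * sin(pi / 6)) - 2.5)  # = 2.5
  expect_equal(shell_inner_radius(6, 5, 5), 2.5)
  expect_equal(shell_inner_radius(4, 5), 5 / (2 * sin(pi / 4)) - 2.5)
  expect_equal(shell_inner_radius(9, 5, 6), 6 / (2 * sin(pi / 9)) - 2.5,
               tolerance = 1e-12)
  expect_equal(shell_inner_radius(9, 5, 6), 6.27, tolerance = 1e-2)
  expect_error(shell_inner_radius(3, 10, 2), "no valid shell")
})

test_that("packing selection reproduces the four studied shells", {
  cases <- list(list(sh = c(3, 8), n = 6), list(sh = c(5, 10), n = 8),
                list(sh = c(6, 11), n = 9), list(sh = c(7.5, 12.5), n = 11))
  for (cs in cases) {
    sel <- select_packing(shell_geometry(cs$sh[1], cs$sh[2]))
    expect_equal(sel$n, cs$n)
    expect_false(sel$tie)
    if (cs$n %% 2 == 1) {
      expect_length(sel$solutions, 1)
      expect_equal(sel$solutions[[1]]$k, (cs$n - 1) / 2)
      expect_equal(sel$solutions[[1]]$l, 1)
    } else {
      expect_length(sel$solutions, 2)
      expect_equal(sel$solutions[[1]]$k, cs$n / 2)
      expect_equal(sel$solutions[[1]]$l, 0)
      expect_equal(sel$solutions[[2]]$k, cs$n / 2 - 1)
      expect_equal(sel$solutions[[2]]$l, 2)
    }
    for (s in sel$solutions)
      expect_equal(s$spacing, 2 * s$R_c * sin(pi / s$n))
  }
})

test_that("the default preferred spacing lies inside the window that fits all shells", {
  # brute-force re-verification of the d* calibration over [5.0, 6.0]
  shells <- list(shell_geometry(3, 8), shell_geometry(5, 10),
                 shell_geometry(6, 11), shell_geometry(7.5, 12.5))
  want <- c(6, 8, 9, 11)
  ds <- seq(5.0, 6.0, by = 0.005)
  fits_all <- vapply(ds, function(d) {
    all(vapply(seq_along(shells),
               function(i) select_packing(shells[[i]], d_star = d)$n == want[i],
               TRUE))
  }, TRUE)
  expect_true(any(fits_all))
  window <- range(ds[fits_all])
  expect_gte(5.6, window[1])
  expect_lte(5.6, window[2])
})

test_that("an exact spacing tie is flagged with both candidates", {
  sh <- shell_geometry(6, 11)
  mid <- (2 * sh$R_c * sin(pi / 9) + 2 * sh$R_c * sin(pi / 10)) / 2
  sel <- select_packing(sh, d_star = mid)
  expect_true(sel$tie)
  expect_length(sel$alternatives, 2)
})

test_that("derived connectivity reproduces the published n = 9 and n = 11 menus", {
  # identity rotation: the generating structure, 4 tori + 1 polar sphere
  ds0 <- derived_connectivity(9, 1, 1, 0)
  expect_equal(ds0$n_components, 5)
  expect_equal(sort(vapply(ds0$components, `[[`, "", "type")),
               c("closed", "closed", "closed", "closed", "sphere"))
  # rotation 3*theta: one open tube over 3 positions + one closed over 6,
  # with the open path exactly 0-6-3 and the loop 1-8-7-2-4-5
  ds3 <- derived_connectivity(9, 1, 1, 6)
  expect_equal(ds3$n_components, 2)
  types <- vapply(ds3$components, `[[`, "", "type")
  open_c <- ds3$components[[which(types == "open")]]
  closed_c <- ds3$components[[which(types == "closed")]]
  expect_equal(open_c$positions, c(0, 6, 3))
  expect_setequal(closed_c$positions, c(1, 8, 7, 2, 4, 5))
  # rotations theta, 2*theta, 4*theta: a single open coil over all 9
  for (m in c(2, 4, 8)) {
    ds <- derived_connectivity(9, 1, 1, m)
    expect_equal(ds$n_components, 1)
    expect_equal(ds$components[[1]]$type, "open")
    expect_setequal(ds$components[[1]]$positions, 0:8)
  }
  # theta rotation: both ends at adjacent positions (same pole)
  ds1 <- derived_connectivity(9, 1, 1, 2)
  ends <- ds1$components[[1]]$ends
  gap <- min((ends[1] - ends[2]) %% 9, (ends[2] - ends[1]) %% 9)
  expect_equal(gap, 1)
  # n = 11: every pure rotation gives one open coil
  for (m in seq(2, 10, 2)) {
    ds <- derived_connectivity(11, 1, 1, m)
    expect_equal(ds$n_components, 1)
    expect_equal(ds$components[[1]]$type, "open")
  }
  # parity guards
  expect_error(derived_connectivity(9, 0, 0, 0), "odd n")
  expect_error(derived_connectivity(8, 1, 1, 0), "even n")
  expect_error(derived_connectivity(8, 0, 2, 2), "odd multiples")
  expect_error(derived_connectivity(8, 0, 0, 3), "even multiples")
  expect_error(derived_connectivity(9, 1, 1, 1), "even multiples")
})

test_that("trace agrees with the orbit-decomposition oracle for n <= 31", {
  for (n in 3:31) {
    cases <- connectivity_cases(n)
    for (i in seq_len(nrow(cases))) {
      ds <- derived_connectivity(n, cases$l_A[i], cases$l_B[i], cases$m[i])
      oracle <- connectivity_oracle(n, cases$l_A[i], cases$l_B[i], cases$m[i])
      expect_identical(comp_signature(ds$components),
                       comp_signature(oracle, from_oracle = TRUE),
                       info = sprintf("n=%d lA=%d lB=%d m=%d", n,
                                      cases$l_A[i], cases$l_B[i], cases$m[i]))
      # positions partition {0..n-1}
      allpos <- sort(as.numeric(unlist(lapply(ds$components, `[[`, "positions"))))
      expect_equal(allpos, as.numeric(0:(n - 1)))
      # open ends account for all caps
      n_open <- sum(vapply(ds$components, function(cc) cc$type == "open", TRUE))
      n_sph <- sum(vapply(ds$components, function(cc) cc$type == "sphere", TRUE))
      expect_equal(n_open + n_sph, (cases$l_A[i] + cases$l_B[i]) / 2)
    }
  }
})

test_that("prime n with one polar sphere always yields a single open coil", {
  for (n in c(5, 7, 11, 13, 17, 19, 23, 29, 31)) {
    for (mp in 1:((n - 1) / 2)) {
      ds <- derived_connectivity(n, 1, 1, 2 * mp)
      expect_equal(ds$n_components, 1)
      expect_equal(ds$components[[1]]$type, "open")
    }
  }
})

test_that("center-lines stay on the mid sphere, join continuously, and conserve length", {
  sh <- shell_geometry(6, 11)
  lens <- vapply(c(0, 2, 4, 6, 8), function(m) {
    cl <- generate_centerline(derived_connectivity(9, 1, 1, m), sh,
                              points_per_arc = 120)
    for (comp in cl) {
      r <- sqrt(rowSums(comp$points^2))
      expect_lt(max(abs(r - sh$R_c)), 1e-9)
      if (comp$type != "sphere") {
        steps <- sqrt(rowSums(diff(comp$points)^2))
        expect_lt(max(steps), 0.3)  # no gaps at the arc joints
      }
    }
    sum(vapply(cl, `[[`, 0, "length"))
  }, 0)
  # rotations are isometries: total arc length is invariant
  expect_equal(max(lens) - min(lens), 0, tolerance = 1e-9)
  # generating structure: k closed circles + l isolated polar points
  cl0 <- generate_centerline(derived_connectivity(9, 1, 1, 0), sh)
  expect_equal(sum(vapply(cl0, function(x) x$type == "sphere", TRUE)), 1)
  expect_equal(sum(vapply(cl0, function(x) x$type == "closed", TRUE)), 4)
  sphere_pt <- cl0[[which(vapply(cl0, function(x) x$type == "sphere", TRUE))]]$points
  expect_equal(abs(sphere_pt[1, 3]), sh$R_c, tolerance = 1e-9)  # at a pole
})

test_that("opposite rotations give mirror-image (opposite-handed) structures", {
  sh <- shell_geometry(6, 11)
  for (m in c(2, 4, 8)) {
    hp <- centerline_handedness(generate_centerline(derived_connectivity(9, 1, 1, m), sh))
    hm <- centerline_handedness(generate_centerline(derived_connectivity(9, 1, 1, -m), sh))
    expect_true(hp != 0)
    expect_equal(hm, -hp)
  }
  h0 <- centerline_handedness(generate_centerline(derived_connectivity(9, 1, 1, 0), sh))
  expect_equal(h0, 0)  # tori are planar
})

test_that("the structure menu covers the distinct derived structures", {
  menu <- structure_menu(shell_geometry(3, 8))
  expect_equal(menu$selection$n, 6)
  sigs <- vapply(menu$structures, function(ds)
    paste(sort(vapply(ds$components, `[[`, "", "type")), collapse = "|"), "")
  expect_true("closed|closed|closed" %in% sigs)          # three tori
  expect_true("closed|closed|sphere|sphere" %in% sigs)   # two tori + 2 spheres
  expect_true(any(grepl("open", sigs)))                  # coiled derivatives
  hyb <- vapply(menu$structures, `[[`, TRUE, "hybrid")
  expect_true(any(hyb))
})
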