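test_that("pair potential has the square-well-linear shape", {
  p <- salr_params()
  # hard core / well / ramp / cutoff values
  expect_identical(pair_potential(0.99, p), Inf)
  expect_equal(pair_potential(1.2, p), -1)
  expect_equal(pair_potential(1.5, p), 0.05 * (4 - 1.5))  # ramp top = 0.125
  expect_equal(pair_potential(4.0, p), 0)
  expect_equal(pair_potential(10, p), 0)
  # exactly -eps on [sigma, lam), exactly 0 beyond kappa
  r_well <- seq(1, 1.5 - 1e-9, length.out = 20)
  expect_true(all(pair_potential(r_well, p) == -1))
  expect_true(all(pair_potential(seq(4, 12, 0.5), p) == 0))
  # linear ramp with slope -zeta*eps/sigma, continuous at kappa
  r_ramp <- seq(1.6, 3.9, 0.1)
  u <- pair_potential(r_ramp, p)
  slopes <- diff(u) / diff(r_ramp)
  expect_equal(slopes, rep(-0.05, length(slopes)), tolerance = 1e-10)
  expect_lt(pair_potential(4 - 1e-9, p), 1e-8)
  expect_error(pair_potential(0, p), "positive")
  # invalid parameter ranges rejected
  expect_error(salr_params(lam = 0.9), "lam")
  expect_error(salr_params(lam = 5, kappa = 4), "lam")
})

test_that("hard-wall shell potential is inclusive at both radii", {
  sh <- shell_geometry(6, 11)
  expect_equal(external_potential(c(8, 0, 0), sh), 0)
  expect_identical(external_potential(c(5.9, 0, 0), sh), Inf)
  expect_equal(external_potential(c(0, 11, 0), sh), 0)     # on the outer wall
  expect_equal(external_potential(c(0, 0, 6), sh), 0)      # on the inner wall
  expect_identical(external_potential(c(0, 0, 11.0001), sh), Inf)
})

test_that("total energy sums pairs and walls", {
  p <- salr_params()
  sh <- shell_geometry(6, 11)
  expect_equal(total_energy(matrix(c(8, 0, 0), 1), p, sh), 0)
  two <- rbind(c(8, 0, 0), c(8 + 1.2, 0, 0))
  expect_equal(total_energy(two, p, sh), -1)
  three <- rbind(c(8, 0, 0), c(-8, 0, 0), c(0, 8, 0))  # all pairs beyond 4
  expect_equal(total_energy(three, p, sh), 0)
  expect_identical(total_energy(rbind(c(8, 0, 0), c(8.5, 0, 0)), p, sh), Inf)
  expect_identical(total_energy(rbind(c(3, 0, 0), c(8, 0, 0)), p, sh), Inf)
})

test_that("particle energy matches the ramp and supports trial positions", {
  p <- salr_params()
  cfg <- matrix(c(8, 0, 0), 1)
  expect_equal(particle_energy(cfg, c(8, 2, 0), p), 0.05 * (4 - 2))
  expect_identical(particle_energy(cfg, c(8.4, 0, 0), p), Inf)
  expect_equal(particle_energy(cfg, c(8, 0, 6), p), 0)  # beyond kappa
})

test_that("half-sum of particle energies reproduces the total energy", {
  p <- salr_params()
  sh <- shell_geometry(6, 11)
  set.seed(99)
  for (rep in 1:5) {
    # random non-overlapping in-shell configuration
    pos <- matrix(numeric(0), ncol = 3)
    while (nrow(pos) < 40) {
      r <- (stats::runif(1, 6^3, 11^3))^(1 / 3)
      v <- stats::rnorm(3); v <- v / sqrt(sum(v^2))
      cand <- r * v
      if (nrow(pos) == 0 || min(sqrt(rowSums(sweep(pos, 2, cand)^2))) >= 1)
        pos <- rbind(pos, cand)
    }
    tot <- total_energy(pos, p, sh)
    half <- sum(vapply(seq_len(nrow(pos)), function(i)
      particle_energy(pos, i, p, sh), 0)) / 2
    expect_equal(tot, half, tolerance = 1e-9 * nrow(pos))
  }
})

test_that("accessible volume follows the half-core padding convention", {
  expect_equal(accessible_volume(shell_geometry(6, 11)),
               (4 * pi / 3) * (11.5^3 - 5.5^3))        # ~ 5673.7
  expect_equal(accessible_volume(shell_geometry(5, 10)),
               (4 * pi / 3) * (10.5^3 - 4.5^3))        # ~ 4468.9
  # narrow inner spheres warn (repulsion reaches across the core)
  expect_warning(sh_small <- shell_geometry(0.5, 7), "R_inn < 1.5")
  expect_equal(accessible_volume(sh_small),
               (4 * pi / 3) * 7.5^3)                   # inner term vanishes
  expect_error(accessible_volume(suppressWarnings(shell_geometry(0.3, 7))),
               "R_inn")
  # monotone in both radii
  v0 <- accessible_volume(shell_geometry(6, 11))
  expect_gt(accessible_volume(shell_geometry(6, 11.1)), v0)
  expect_lt(accessible_volume(shell_geometry(6.1, 11)), v0)
})

test_that("number density uses the accessible volume", {
  sh <- shell_geometry(6, 11)
  expect_equal(number_density(0, sh), 0)
  expect_equal(number_density(5674, sh), 5674 / accessible_volume(sh))
  expect_equal(number_density(1000, shell_geometry(5, 10)),
               1000 / accessible_volume(shell_geometry(5, 10)), tolerance = 1e-12)
  expect_equal(number_density(1000, shell_geometry(5, 10)), 0.2238, tolerance = 1e-3)
})

test_that("configuration validation catches violations", {
  sh <- shell_geometry(6, 11)
  good <- configuration(rbind(c(8, 0, 0), c(0, 9, 0)), shell = sh)
  expect_true(validate_configuration(good))
  expect_error(validate_configuration(configuration(c(2, 0, 0), shell = sh)),
               "outside")
  expect_error(
    validate_configuration(configuration(rbind(c(8, 0, 0), c(8.5, 0, 0)),
                                         shell = sh)), "overlap")
})
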