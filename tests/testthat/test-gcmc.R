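sh_test <- shell_geometry(6, 11)
th_test <- thermo_state(0.35, -2.17)

test_that("runs are deterministic given the seed and empty schedules are no-ops", {
  sch <- run_schedule(1e4, 5e4, 1e3, traj_interval = 2.5e4, seed = 3)
  r1 <- run_gcmc(thermo = th_test, shell = sh_test, schedule = sch)
  r2 <- run_gcmc(thermo = th_test, shell = sh_test, schedule = sch)
  expect_identical(r1$observables, r2$observables)
  expect_identical(as_positions(r1$final), as_positions(r2$final))
  expect_identical(lapply(r1$trajectory, as_positions),
                   lapply(r2$trajectory, as_positions))
  r3 <- run_gcmc(thermo = th_test, shell = sh_test,
                 schedule = run_schedule(0, 0, 1e3, seed = 3))
  expect_equal(nrow(r3$observables), 0)
  expect_equal(nrow(r3$final), 0)
  expect_error(run_gcmc(thermo = list(T_star = -1, mu_star = 0, z = 1),
                        shell = sh_test), "positive")
})

test_that("ideal-gas filling matches the grand-canonical closed form", {
  # with pair interactions off, N is Poisson with mean z * V(shell region)
  sch <- run_schedule(2e5, 1e6, 2.5e3, seed = 5)
  run <- run_gcmc(thermo = th_test, shell = sh_test, schedule = sch,
                  ideal_gas = TRUE)
  expected <- th_test$z * shell_volume(sh_test)
  Ns <- run$observables$N
  se <- stats::sd(Ns) / sqrt(length(Ns) / 3)  # conservative n_eff
  expect_lt(abs(mean(Ns) - expected), 3 * se + 0.02 * expected)
  # all particles inside the shell
  expect_true(validate_configuration(run$final, sh_test))
  # chi-square goodness of fit against the Poisson law (mean from theory)
  tab <- table(factor(Ns, levels = 0:max(Ns)))
  pr <- stats::dpois(0:max(Ns), expected)
  # pool bins to expected counts >= 5
  obs <- as.numeric(tab); grp <- cumsum(pr * length(Ns))
  cut <- floor(grp / 5)
  o <- tapply(obs, cut, sum); e <- tapply(pr * length(Ns), cut, sum)
  keep <- e > 0
  stat <- sum((o[keep] - e[keep])^2 / e[keep])
  p <- stats::pchisq(stat, df = sum(keep) - 1, lower.tail = FALSE)
  expect_gt(p, 0.01)
})

test_that("incremental energies agree with full recomputation over long runs", {
  run <- run_gcmc(thermo = th_test, shell = sh_test,
                  schedule = run_schedule(0, 1e6, 1e5, seed = 8))
  N <- max(1, nrow(run$final))
  expect_lt(abs(run$U - run$U_recomputed), 1e-8 * N)
  expect_equal(run$U_recomputed,
               total_energy(run$final, salr_params(), sh_test),
               tolerance = 1e-9)
  # hard constraints hold after every accepted move (checked on the final
  # state; an overlap at any earlier step could not have been removed by
  # displacement moves alone without first being accepted)
  expect_true(validate_configuration(run$final, sh_test))
})

test_that("hard-sphere filling follows the low-density virial expansion", {
  # pure hard spheres (well depth 0): beta mu = ln(rho) + 2 B2 rho + ...
  B2 <- 2 * pi / 3
  L <- 12
  z <- 0.035
  th <- thermo_state(1.0, log(z))
  p_hs <- salr_params(zeta = 0, lam = 1.5, kappa = 4, epsilon = 0)
  run <- run_gcmc(params = p_hs, thermo = th, box_L = L, geometry = "box",
                  schedule = run_schedule(2e5, 1.2e6, 3e3, seed = 9))
  rho_pred <- z
  for (i in 1:50) rho_pred <- z * exp(-2 * B2 * rho_pred)
  expect_lt(rho_pred, 0.05)
  rho_sim <- mean(run$observables$N) / L^3
  expect_equal(rho_sim, rho_pred, tolerance = 0.05)
})

test_that("displacement-only dynamics conserve N and respect walls", {
  # start from a decorated structure, displacements only
  cfg <- decorate(derived_connectivity(9, 1, 1, 0), sh_test, seed = 2)
  run <- run_gcmc(thermo = th_test, shell = sh_test, init = cfg,
                  mix = move_mix(1.0),
                  schedule = run_schedule(0, 2e5, 1e4, seed = 11))
  expect_true(all(run$observables$N == nrow(cfg)))
  expect_true(validate_configuration(run$final, sh_test))
  # observable bookkeeping: rho* column equals number_density(N)
  expect_equal(run$observables$rho_star,
               number_density(run$observables$N, sh_test))
})

test_that("delta tuning only adapts during equilibration and stays in range", {
  run <- run_gcmc(thermo = th_test, shell = sh_test, tune_delta = TRUE,
                  schedule = run_schedule(2e5, 1e5, 1e4, seed = 13))
  expect_gte(run$delta, 0.05)
  expect_lte(run$delta, 2.0)
  acc <- run$acceptance
  rate <- acc[["disp_acc"]] / max(1, acc[["disp_try"]])
  expect_gt(rate, 0.15)  # production acceptance in a workable range
  expect_lt(rate, 0.8)
})
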