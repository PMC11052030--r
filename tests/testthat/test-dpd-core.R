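# DPD pair forces, neighbour search, integration and thermostatting.

test_that("conservative force follows the soft-repulsion law", {
  # hand evaluation: a = 100, rc = 0.5, r = 0.25 -> magnitude 100*(1-0.5) = 50
  f <- conservative_force(c(0.25, 0, 0), c(0, 0, 0), a_ij = 100, r_c = 0.5)
  expect_equal(f, c(50, 0, 0), tolerance = 1e-12)
  # zero at the cutoff boundary
  expect_equal(conservative_force(c(0.5, 0, 0), c(0, 0, 0), 100, 0.5),
               c(0, 0, 0))
  # antisymmetry for a generic offset
  set.seed(1)
  ri <- runif(3); rj <- ri + c(0.1, -0.2, 0.05)
  expect_equal(conservative_force(ri, rj, 80, 1),
               -conservative_force(rj, ri, 80, 1), tolerance = 1e-14)
  expect_error(conservative_force(ri, ri, 80, 1), "overlap")
})

test_that("dissipative and random forces use the DPD weights and FD sigma", {
  # sigma = sqrt(2 gamma kBT): gamma = 4.5, kBT = 1 -> sigma = 3
  expect_equal(fd_sigma(4.5, 1), 3)
  # v_ij = 0 kills the dissipative term
  fr <- dissipative_random_forces(c(0.2, 0, 0), c(0, 0, 0),
                                  c(1, 2, 3), c(1, 2, 3),
                                  gamma = 4.5, r_c = 0.5, eps = 1.3)
  expect_equal(fr$dissipative, c(0, 0, 0))
  # weights at near-contact tend to omega = 1: random magnitude sigma*eps/sqrt(dt)
  fr0 <- dissipative_random_forces(c(1e-9, 0, 0), c(0, 0, 0),
                                   c(0, 0, 0), c(0, 0, 0),
                                   gamma = 4.5, r_c = 0.5, dt = 0.004,
                                   eps = 1)
  expect_equal(sqrt(sum(fr0$random^2)), 3 / sqrt(0.004), tolerance = 1e-6)
  # dissipative term opposes the radial relative velocity
  fr2 <- dissipative_random_forces(c(0.2, 0, 0), c(0, 0, 0),
                                   c(1, 0, 0), c(0, 0, 0),
                                   gamma = 10, r_c = 0.4, eps = 0)
  expect_lt(fr2$dissipative[1], 0)
})

test_that("pair parameter tables enforce symmetry and the FD constraint", {
  pp <- pair_params()
  expect_equal(pp$a, t(pp$a))
  expect_equal(unname(pp$a["membrane", "actin"]), 100)
  expect_equal(unname(pp$gamma["membrane", "membrane"]), 45)
  expect_equal(unname(pp$rc["actin", "acp"]), 0.25)
  # holding vs membrane is the one soft entry
  expect_equal(unname(pp$a["membrane", "holding_pipette"]), 30)
  expect_silent(validate_pair_params(pp, sigma = sqrt(2 * pp$gamma * pp$kBT)))
  expect_error(validate_pair_params(pp, sigma = sqrt(2 * pp$gamma) + 0.1),
               "fluctuation")
})

test_that("neighbour list reproduces the brute-force pair set", {
  set.seed(7)
  for (case in list(list(n = 200, periodic = TRUE),
                    list(n = 150, periodic = FALSE))) {
    L <- 6
    sys <- particle_system(pos = matrix(runif(3 * case$n, 0, L), ncol = 3),
                           box = rep(L, 3), periodic = case$periodic)
    rmax <- 1.1
    nl <- build_neighbor_list(sys, rmax)
    # O(N^2) oracle with minimum image
    ref <- NULL
    for (i in 1:(case$n - 1)) {
      d <- sweep(sys$pos[(i + 1):case$n, , drop = FALSE], 2, sys$pos[i, ])
      if (case$periodic) d <- d - L * round(d / L)
      j <- which(rowSums(d^2) < rmax^2)
      if (length(j)) ref <- rbind(ref, cbind(i, i + j))
    }
    key <- function(m) sort(paste(pmin(m[, 1], m[, 2]), pmax(m[, 1], m[, 2])))
    expect_identical(key(nl), key(ref))
  }
  # empty system
  sys0 <- particle_system(pos = matrix(numeric(0), 0, 3), box = c(5, 5, 5))
  expect_equal(nrow(build_neighbor_list(sys0, 1)), 0)
  # two close particles -> exactly one pair
  sys2 <- particle_system(pos = rbind(c(1, 1, 1), c(1.3, 1, 1)),
                          box = c(5, 5, 5))
  expect_equal(nrow(build_neighbor_list(sys2, 1)), 1)
  # periodic box too small for the minimum image convention
  expect_error(build_neighbor_list(
    particle_system(pos = rbind(c(0, 0, 0)), box = c(1.5, 5, 5)), 1),
    "minimum image")
})

test_that("conservative pair force is the exact gradient of its energy", {
  fl <- dpd_fluid(L = 4, density = 3, seed = 5)
  expect_forces_match_fd(fl, pair_params(), integrator_config(), tol = 1e-6)
})

test_that("free streaming, momentum conservation and determinism hold", {
  # single free particle, no interactions: x(t+dt) = x + v dt
  pp <- pairs_off()
  sys <- particle_system(pos = rbind(c(2, 2, 2)), vel = rbind(c(0.3, -0.1, 0.2)),
                         box = c(10, 10, 10), periodic = FALSE)
  res <- run_dpd(sys, pp, integrator_config(dt = 0.01, rng_seed = 1), nsteps = 10)
  expect_equal(res$sys$pos[1, ], c(2, 2, 2) + 10 * 0.01 * c(0.3, -0.1, 0.2),
               tolerance = 1e-12)

  # interacting fluid: total momentum conserved to high precision
  fl <- dpd_fluid(L = 5, density = 3, seed = 2)
  r1 <- run_dpd(fl, pair_params(), integrator_config(rng_seed = 3),
                nsteps = 1000, sample_every = 100)
  expect_lt(max(abs(as.matrix(r1$obs[, c("px", "py", "pz")]))), 1e-8)

  # identical seed => bit-identical trajectory
  r2 <- run_dpd(fl, pair_params(), integrator_config(rng_seed = 3),
                nsteps = 1000, sample_every = 100)
  expect_identical(r1$sys$pos, r2$sys$pos)
  r3 <- run_dpd(fl, pair_params(), integrator_config(rng_seed = 4),
                nsteps = 1000)
  expect_false(identical(r1$sys$pos, r3$sys$pos))
})

test_that("kinetic temperature measures kBT per degree of freedom", {
  sys <- particle_system(pos = matrix(runif(300), 100, 3), box = c(5, 5, 5))
  expect_equal(compute_temperature(sys), 0)
  set.seed(11)
  n <- 10000
  sys2 <- particle_system(pos = matrix(runif(3 * n, 0, 10), n, 3),
                          vel = maxwell_velocities(n, kBT = 1),
                          box = c(10, 10, 10))
  expect_equal(compute_temperature(sys2), 1, tolerance = 0.02)
  sys2$vel <- 2 * sys2$vel
  expect_equal(compute_temperature(sys2),
               4 * compute_temperature(particle_system(
                 pos = sys2$pos, vel = sys2$vel / 2, box = sys2$box)),
               tolerance = 1e-12)
  sys2$frozen[] <- TRUE
  expect_error(compute_temperature(sys2), "frozen")
})

test_that("equilibrated DPD fluid holds the configured temperature", {
  fl <- dpd_fluid(L = 7, density = 3, seed = 4)
  res <- run_dpd(fl, pair_params(), integrator_config(rng_seed = 9),
                 nsteps = 3000, sample_every = 25)
  second_half <- res$obs$temperature[seq(nrow(res$obs) %/% 2, nrow(res$obs))]
  expect_equal(mean(second_half), 1, tolerance = 0.02)
})

test_that("frozen particles never move and keep zero velocity", {
  set.seed(3)
  n <- 60
  sys <- particle_system(pos = matrix(runif(3 * n, 0, 4), n, 3),
                         vel = maxwell_velocities(n),
                         frozen = rep(c(TRUE, FALSE), length.out = n),
                         box = c(4, 4, 4))
  res <- run_dpd(sys, pair_params(), integrator_config(rng_seed = 2),
                 nsteps = 300)
  frozen <- sys$frozen
  expect_equal(res$sys$pos[frozen, ], sys$pos[frozen, ])
  expect_true(all(res$sys$vel[frozen, ] == 0))
})
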