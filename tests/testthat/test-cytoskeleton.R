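# Filament network generation, harmonic/twist potentials and Bell kinetics.

test_that("network generation honours counts, chain sizes and clearance", {
  net <- generate_filament_network(
    Na = 180, n_acp = 60,
    region = list(kind = "box", box = c(5, 5, 5)), seed = 2)
  expect_equal(nrow(net$actin_pos), 180)
  expect_equal(nrow(net$acp_pos), 60)
  expect_true(all(lengths(net$filaments) >= 3 & lengths(net$filaments) <= 11))
  # backbone spacing = bond_r0 (straight seeds)
  d <- net$actin_pos[net$bonds[, 1], ] - net$actin_pos[net$bonds[, 2], ]
  d <- d - 5 * round(d / 5)
  expect_equal(sqrt(rowSums(d^2)), rep(0.25, nrow(net$bonds)),
               tolerance = 1e-9)
  # determinism
  net2 <- generate_filament_network(
    Na = 180, n_acp = 60,
    region = list(kind = "box", box = c(5, 5, 5)), seed = 2)
  expect_identical(net$actin_pos, net2$actin_pos)
  # sphere region keeps everything inside
  nets <- generate_filament_network(
    Na = 90, n_acp = 20,
    region = list(kind = "sphere", radius = 3, center = c(5, 5, 5)), seed = 4)
  expect_true(all(sqrt(rowSums(sweep(nets$actin_pos, 2, c(5, 5, 5))^2)) <= 3))
})

test_that("filament bond and angle potentials match their printed forms", {
  cp <- cyto_params()
  pp <- pairs_off()
  cfg <- integrator_config()
  # single bond stretched by delta: |F| = 2 k delta (U = k (r-r0)^2)
  delta <- 0.013
  s <- particle_system(pos = rbind(c(1, 1, 1), c(1 + 0.25 + delta, 1, 1)),
                       box = c(5, 5, 5), types = "actin", periodic = FALSE)
  b <- list(harm = list(ij = rbind(c(1, 2)), r0 = 0.25, k = cp$kbond))
  f <- system_forces(s, pp, cfg, b)
  expect_equal(f$forces[1, 1], 2 * cp$kbond * delta, tolerance = 1e-9)
  expect_equal(f$energies$harm, cp$kbond * delta^2, tolerance = 1e-12)
  # straight chain at theta0 = pi: zero angle force
  s3 <- particle_system(pos = rbind(c(0, 0, 0), c(0.25, 0, 0), c(0.5, 0, 0)),
                        box = c(5, 5, 5), types = "actin", periodic = FALSE)
  b3 <- list(angles = list(ijk = rbind(c(1, 2, 3)), theta0 = pi,
                           k = cp$kangle))
  expect_lt(max(abs(system_forces(s3, pp, cfg, b3)$forces)), 1e-9)
  # bent chain: forces equal the numerical gradient
  s3$pos[3, ] <- c(0.45, 0.12, -0.03)
  expect_forces_match_fd(s3, pp, cfg, b3, n_check = 3)
})

test_that("ACP twist dihedral has the cosine form with exact gradients", {
  set.seed(9)
  s <- particle_system(pos = matrix(rnorm(12), 4, 3), box = c(9, 9, 9),
                       types = "actin", periodic = FALSE)
  q <- rbind(1:4)
  th <- dihedral_angle(s$pos[1, ], s$pos[2, ], s$pos[3, ], s$pos[4, ])
  # at theta0 = current angle the energy is zero
  at0 <- acp_twist_energy(s, q, kb = 550, theta0 = th)
  expect_equal(at0$energy, 0, tolerance = 1e-10)
  expect_lt(max(abs(at0$forces)), 1e-6)
  # opposite angle: energy 2 kb (cosine extremum)
  api <- acp_twist_energy(s, q, kb = 550, theta0 = th + pi)
  expect_equal(api$energy, 2 * 550, tolerance = 1e-9)
  # generic theta0: gradient consistency
  b <- list(dihedrals = list(ijkl = q, theta0 = 0.7, k = 550))
  expect_forces_match_fd(s, pairs_off(), integrator_config(), b, n_check = 4)
})

test_that("Bell rates follow k0 exp(-sigma (l-l0)^2 / 2kBT)", {
  expect_equal(binding_rate(0.2, 0.2, k0 = 26e-4, sigma = 3.5e-4), 26e-4)
  # symmetry about l0
  expect_equal(binding_rate(0.3, 0.2, 26e-4, 3.5e-4),
               binding_rate(0.1, 0.2, 26e-4, 3.5e-4))
  # hand evaluation at l - l0 = 10
  expect_equal(binding_rate(10.2, 0.2, 26e-4, 3.5e-4),
               26e-4 * exp(-0.0175), tolerance = 1e-12)
})

test_that("stochastic binding matches its Bernoulli law and capacities", {
  cp <- cyto_params(kon0 = 0.5, koff0 = 0.5)  # fast kinetics for statistics
  # one ACP next to one filament particle at fixed distance l < don
  l <- 0.15
  base <- particle_system(pos = rbind(c(2, 2, 2), c(2 + l, 2, 2)),
                          types = c("acp", "actin"), box = c(4, 4, 4),
                          periodic = FALSE)
  dt <- 0.8
  kon <- binding_rate(l, cp$acp_l0, cp$kon0, cp$sigma_on[1])
  p_on <- 1 - exp(-kon * dt)
  n <- 4000
  hits <- 0
  for (k in seq_len(n)) {
    dyn <- stochastic_binding_step(base, cp, dyn = NULL, dt = dt, seed = k)
    hits <- hits + (nrow(dyn$ij) == 1)
  }
  se <- sqrt(p_on * (1 - p_on) / n)
  expect_lt(abs(hits / n - p_on), 3 * se)

  # beyond don no binding ever happens
  far <- particle_system(pos = rbind(c(2, 2, 2), c(2.26, 2, 2)),
                         types = c("acp", "actin"), box = c(4, 4, 4),
                         periodic = FALSE)
  for (k in 1:50)
    expect_equal(nrow(stochastic_binding_step(far, cp, NULL, dt = 5,
                                              seed = k)$ij), 0)

  # capacity: an ACP surrounded by three filament particles binds at most two
  tri <- particle_system(
    pos = rbind(c(2, 2, 2), c(2.1, 2, 2), c(1.9, 2, 2), c(2, 2.1, 2)),
    types = c("acp", "actin", "actin", "actin"), box = c(4, 4, 4),
    periodic = FALSE)
  cp_fast <- cyto_params(kon0 = 100)
  for (k in 1:25) {
    dyn <- stochastic_binding_step(tri, cp_fast, NULL, dt = 10, seed = k)
    expect_lte(nrow(dyn$ij), 2)
    expect_true(all(table(dyn$ij[, 2]) <= 1))
  }
})

test_that("repeated bind/unbind sweeps preserve the capacity invariants", {
  set.seed(5)
  n_a <- 8; n_f <- 20
  pos <- rbind(matrix(runif(3 * n_a, 1.8, 2.4), n_a, 3),
               matrix(runif(3 * n_f, 1.8, 2.4), n_f, 3))
  sys <- particle_system(pos = pos,
                         types = c(rep("acp", n_a), rep("actin", n_f)),
                         box = c(4, 4, 4), periodic = FALSE)
  cp <- cyto_params(kon0 = 5, koff0 = 5, doff = 0.05)  # high churn
  dyn <- NULL
  for (k in 1:40) {
    dyn <- stochastic_binding_step(sys, cp, dyn, dt = 0.5, seed = 100 + k)
    if (nrow(dyn$ij) > 0) {
      acp_counts <- table(dyn$ij[, 1])
      fil_counts <- table(dyn$ij[, 2])
      expect_true(all(acp_counts <= 2))
      expect_true(all(fil_counts <= 1))
    }
  }
})

test_that("saturation matching is deterministic and capacity-respecting", {
  sl <- tiny_slab()
  dyn <- sl$bonds$dyn
  expect_gt(nrow(dyn$ij), 0)
  expect_true(all(table(dyn$ij[dyn$kind == 0, 1]) <= 2))
  expect_true(all(table(dyn$ij[dyn$kind == 0, 2]) <= 1))
  sl2 <- build_network_slab(Na = 120, n_acp = 45, seed = 3, relax_steps = 500)
  expect_identical(sl$bonds$dyn$ij, sl2$bonds$dyn$ij)
})

test_that("assembled cells respect link capacities and relax near kBT", {
  mem <- build_membrane(radius = 3.5, level = 2, seed = 2)
  cell <- assemble_cell(mem, Na = 150, n_acp = 60, relax_steps = 1500,
                        seed = 2, percolation_fraction = 0)
  dyn <- cell$bonds$dyn
  acp0 <- dyn$ij[dyn$kind == 0, , drop = FALSE]
  if (nrow(acp0) > 0) {
    expect_true(all(table(acp0[, 1]) <= 2))
    expect_true(all(table(acp0[, 2]) <= 1))
  }
  # the membrane is directly thermostatted by its viscous bonds; the sparse
  # interior couples only through rare contacts and thermalises much more
  # slowly, so the temperature check targets the membrane particles
  vmem <- cell$sys$vel[cell$idx$membrane, ]
  expect_equal(sum(vmem^2) / (3 * nrow(vmem)), 1, tolerance = 0.15)
  # no membrane bond near its contour length after relaxation
  bl <- sqrt(rowSums((cell$sys$pos[cell$bonds$wlc$ij[, 1], ] -
                      cell$sys$pos[cell$bonds$wlc$ij[, 2], ])^2))
  expect_true(all(bl < cell$bonds$wlc$lmax))
  # zero ACPs -> no cross-links
  cell0 <- assemble_cell(build_membrane(radius = 3, level = 1, seed = 3),
                         Na = 24, n_acp = 0, relax_steps = 200, seed = 3,
                         percolation_fraction = 0)
  expect_equal(sum(cell0$bonds$dyn$kind == 0), 0)
})
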