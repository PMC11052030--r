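# Triangulated WLC membrane: mesh topology, elastic law, calibration,
# constraint forces and viscous-bond thermostat.

test_that("icosphere meshes are closed 2-manifolds with the expected counts", {
  m0 <- build_membrane_mesh(radius = 5, level = 0)
  expect_equal(nrow(m0$vertices), 12)
  expect_equal(nrow(m0$edges), 30)
  expect_equal(nrow(m0$faces), 20)
  for (lv in 0:2) {
    m <- build_membrane_mesh(radius = 2 + lv, level = lv)
    expect_equal(nrow(m$faces), 20 * 4^lv)
    expect_equal(nrow(m$vertices) - nrow(m$edges) + nrow(m$faces), 2)
    expect_silent(check_mesh(m))
    expect_gt(m$V0, 0)
    # vertices on the sphere
    r <- sqrt(rowSums(sweep(m$vertices, 2, colMeans(m$vertices))^2))
    expect_equal(r, rep(2 + lv, length(r)), tolerance = 1e-12)
  }
})

test_that("OFF meshes round-trip", {
  m <- build_membrane_mesh(radius = 3, level = 1)
  p <- tempfile(fileext = ".off")
  write_off(m, p)
  m2 <- read_off(p)
  expect_equal(m2$vertices, m$vertices, tolerance = 1e-14)
  expect_equal(mesh_geometry(m2)$volume, m$V0, tolerance = 1e-12)
})

test_that("shear modulus expression and calibration are mutually consistent", {
  # hand evaluation: kBT=1, p=1, lmax=2, x0=0.5, kp=0
  # -> (3/(4*1*2*0.5)) * (0.25*8 - 1/(4*0.25) + 0.25) = 0.75 * 1.25 = 0.9375
  expect_equal(shear_modulus(kBT = 1, p = 1, lmax = 2, x0 = 0.5, kp = 0),
               0.9375, tolerance = 1e-12)
  # doubling p halves the first (kp = 0) term
  expect_equal(shear_modulus(p = 2, kp = 0, lmax = 2, x0 = 0.5),
               0.9375 / 2, tolerance = 1e-12)
  # inverse calibration round trip across a mu0 grid
  for (mu0 in c(5, 50, 100, 300)) {
    cal <- calibrate_wlc(mu0, x0 = 0.45, l0 = 1.05, m = 2)
    expect_equal(shear_modulus(kBT = 1, p = cal$p, lmax = cal$lmax,
                               x0 = 0.45, kp = cal$kp, m = 2),
                 mu0, tolerance = 1e-8)
    # force balance: zero net bond force at l0
    par <- membrane_params(mu0 = mu0, x0 = 0.45, l0 = 1.05)
    expect_equal(wlc_pow_bond_force(1.05, par), 0, tolerance = 1e-10)
  }
  expect_error(shear_modulus(x0 = 1), "x0")
})

test_that("shear modulus is monotone in kp and in 1/p", {
  kps <- seq(0, 50, length.out = 6)
  mus <- vapply(kps, function(kp)
    shear_modulus(kBT = 1, p = 0.05, lmax = 2, x0 = 0.45, kp = kp),
    numeric(1))
  expect_true(all(diff(mus) > 0))
  ps <- seq(0.02, 0.2, length.out = 6)
  mus2 <- vapply(ps, function(p)
    shear_modulus(kBT = 1, p = p, lmax = 2, x0 = 0.45, kp = 3),
    numeric(1))
  expect_true(all(diff(mus2) < 0))
})

test_that("WLC attraction diverges toward the contour length", {
  par <- membrane_params(mu0 = 50, x0 = 0.45, l0 = 1)
  f_near <- wlc_pow_bond_force(par$lmax * 0.999, par)
  expect_lt(f_near, -1e3)
  expect_error(wlc_pow_bond_force(par$lmax, par), "contour")
})

test_that("every membrane force term is the gradient of its energy", {
  mem <- tiny_membrane(perturb = 0.02)
  cfg <- integrator_config()
  pp <- pairs_off()
  expect_forces_match_fd(mem$sys, pp, cfg, list(wlc = mem$bonds$wlc))
  expect_forces_match_fd(mem$sys, pp, cfg,
                         list(dihedrals = mem$bonds$dihedrals))
  expect_forces_match_fd(mem$sys, pp, cfg, membrane = mem$membrane)
  expect_forces_match_fd(mem$sys, pair_params(), cfg, mem$bonds,
                         membrane = mem$membrane)
})

test_that("constraint forces vanish on the reference mesh and restore it", {
  mem <- tiny_membrane(perturb = 0)
  f <- system_forces(mem$sys, pairs_off(), integrator_config(),
                     membrane = mem$membrane)
  expect_lt(max(abs(f$forces)), 1e-9)
  # uniform 1% inflation: the volume force points inward everywhere
  infl <- mem$sys
  ctr <- colMeans(infl$pos)
  infl$pos <- sweep(sweep(infl$pos, 2, ctr), 1, 1.01, "*")
  infl$pos <- sweep(infl$pos, 2, ctr, "+")
  mem_vol_only <- mem$membrane
  mem_vol_only$ka <- 0; mem_vol_only$kd <- 0
  fv <- system_forces(infl, pairs_off(), integrator_config(),
                      membrane = mem_vol_only)$forces
  radial <- rowSums(fv * sweep(infl$pos, 2, ctr))
  expect_true(all(radial < 0))
})

test_that("bending forces vanish at the spontaneous dihedral angle", {
  mem <- tiny_membrane(perturb = 0)
  f <- system_forces(mem$sys, pairs_off(), integrator_config(),
                     list(dihedrals = mem$bonds$dihedrals))
  expect_lt(max(abs(f$forces)), 1e-9)
  expect_equal(f$energies$dihedral, 0, tolerance = 1e-12)
})

test_that("a relaxed free membrane holds area, volume and temperature", {
  mem <- build_membrane(radius = 4, level = 2, seed = 1)
  cfg <- integrator_config(dt = 0.001, rng_seed = 5)
  res <- run_dpd(mem$sys, pair_params(), cfg, nsteps = 20000,
                 bonds = mem$bonds, membrane = mem$membrane,
                 sample_every = 200)
  geo <- mesh_geometry(mem$mesh, res$sys$pos)
  expect_equal(geo$area / mem$mesh$A0, 1, tolerance = 0.01)
  expect_equal(geo$volume / mem$mesh$V0, 1, tolerance = 0.01)
  tail_T <- tail(res$obs$temperature, 40)
  expect_equal(mean(tail_T), 1, tolerance = 0.02)
  # no bond approaches the contour length at default parameters
  bl <- sqrt(rowSums((res$sys$pos[mem$mesh$edges[, 1], ] -
                      res$sys$pos[mem$mesh$edges[, 2], ])^2))
  expect_true(all(bl < mem$bonds$wlc$lmax))
  # viscous bond forces conserve linear momentum
  expect_lt(max(abs(as.matrix(res$obs[, c("px", "py", "pz")]))), 1e-7)
})
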