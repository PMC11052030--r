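# Indentation geometry, Sneddon fitting, rigid bodies, microinjection parts.

test_that("Sneddon round trip is exact for the reference modulus", {
  # synthetic curve at E = 17.96 (kPa scale), alpha = 18 deg, nu = 0.5
  cur <- sneddon_curve(E = 17.96, alpha_deg = 18, nu = 0.5,
                       delta = seq(0, 1, by = 0.005))
  expect_equal(sneddon_fit(cur, window = c(0.4, 0.8)), 17.96,
               tolerance = 1e-10)
  expect_equal(sneddon_fit(cur, window = c(0.4, 0.8), method = "ls"),
               17.96, tolerance = 1e-8)
  # exact for any (E, alpha, nu) in valid ranges
  set.seed(5)
  for (k in 1:10) {
    E <- runif(1, 1, 300); al <- runif(1, 5, 60); nu <- runif(1, 0, 0.49)
    c2 <- sneddon_curve(E, al, nu)
    expect_equal(sneddon_fit(c2, c(0.3, 0.9), alpha_deg = al, nu = nu), E,
                 tolerance = 1e-9)
  }
  # linearity: doubling all forces doubles the fitted modulus
  cur2 <- cur; cur2$load <- 2 * cur2$load
  expect_equal(sneddon_fit(cur2, c(0.4, 0.8)), 2 * 17.96, tolerance = 1e-9)
  # window before contact: negative fit rejected
  bad <- cur; bad$load <- -bad$load
  expect_error(sneddon_fit(bad, c(0.4, 0.8)), "non-positive")
})

test_that("probe and pipette geometry builders are sane", {
  pr <- make_cone_probe(tip = c(0, 0, 1), half_angle_deg = 18, height = 3)
  expect_gt(pr$n, 100)
  # all particles lie on the cone surface: r = (z - tip_z) tan(alpha)
  r <- sqrt(pr$pos[, 1]^2 + pr$pos[, 2]^2)
  z <- pr$pos[, 3] - 1
  expect_equal(r, z * tan(18 * pi / 180), tolerance = 1e-9)
  pp <- make_pipette(mouth = c(0, 0, 0), axis = c(0, 1, 0),
                     inner_radius = 1.5, length = 4)
  rad <- sqrt(pp$pos[, 1]^2 + pp$pos[, 3]^2)
  # two concentric wall shells: bore radius and bore + layer gap
  expect_true(all(abs(rad - 1.5) < 1e-9 | abs(rad - 1.7) < 1e-9))
  expect_gt(sum(abs(rad - 1.5) < 1e-9), 0)
  expect_gt(sum(abs(rad - 1.7) < 1e-9), 0)
  expect_true(all(pp$pos[, 2] >= -1e-12 & pp$pos[, 2] <= 4 + 1e-12))
})

test_that("rigid bodies never deform during a driven run", {
  mem <- tiny_membrane(radius = 2.5, level = 1)
  sys <- mem$sys
  pr <- make_cone_probe(tip = c(mem$sys$box[1] / 2, mem$sys$box[2] / 2,
                                max(sys$pos[, 3]) + 0.5), height = 1.5)
  n0 <- nrow(sys$pos)
  sys <- cytomech:::.add_rigid(sys, pr$pos, "probe")
  pidx <- n0 + seq_len(pr$n)
  res <- run_dpd(sys, pair_params(), integrator_config(dt = 1e-3,
                                                       rng_seed = 2),
                 nsteps = 1500, bonds = mem$bonds, membrane = mem$membrane,
                 drivers = list(list(mode = "translate", idx = pidx,
                                     vel = c(0, 0, -0.3))))
  # probe moved exactly with its prescribed velocity, undeformed
  d0 <- dist(sys$pos[pidx[1:20], ])
  d1 <- dist(res$sys$pos[pidx[1:20], ])
  expect_equal(as.numeric(d1), as.numeric(d0), tolerance = 1e-12)
  expect_equal(res$sys$pos[pidx[1], 3] - sys$pos[pidx[1], 3],
               -0.3 * 1500 * 1e-3, tolerance = 1e-9)
})

test_that("indentation produces a contact point and a rising smoothed load", {
  mem <- tiny_membrane(radius = 2.5, level = 2, mu0 = 100)
  cur <- run_indentation(mem, speed = 0.1, max_depth = 1.4,
                         relax_steps = 600, substrate_gap = 0.3, seed = 4,
                         cfg = integrator_config(dt = 1e-3, rng_seed = 4),
                         sample_every = 40)
  expect_false(is.na(attr(cur, "contact_index")))
  # early approach (probe still clear of the cell) shows only noise
  pre <- cur$load[cur$displacement < 0.3]
  expect_lt(abs(mean(pre)), 1)
  # smoothed load is (weakly) increasing with depth after contact
  post <- cur[cur$displacement > attr(cur, "contact_displacement"), ]
  sm <- stats::filter(post$load, rep(1 / 7, 7), sides = 2)
  sm <- sm[!is.na(sm)]
  third <- length(sm) %/% 3
  expect_gt(mean(sm[(2 * third):length(sm)]), mean(sm[1:third]))
  # deterministic repeat
  cur2 <- run_indentation(mem, speed = 0.1, max_depth = 1.4,
                          relax_steps = 600, substrate_gap = 0.3, seed = 4,
                          cfg = integrator_config(dt = 1e-3, rng_seed = 4),
                          sample_every = 40)
  expect_identical(cur$load, cur2$load)
})

test_that("aspiration field acts only inside the capture region", {
  mem <- tiny_membrane(radius = 2.5, level = 1)
  sys <- mem$sys
  ctr <- colMeans(sys$pos)
  mouth <- ctr + c(0, -3, 0)
  F <- apply_aspiration_field(sys, mouth, axis = c(0, -1, 0),
                              magnitude = 0.5, radius = 1.2)
  nz <- rowSums(abs(F)) > 0
  expect_true(any(nz))
  # forces all point along -y with the set magnitude
  expect_true(all(F[nz, 2] == -0.5))
  expect_true(all(F[nz, c(1, 3)] == 0))
  # particles far from the axis are untouched
  d <- sweep(sys$pos, 2, mouth)
  radial <- sqrt(d[, 1]^2 + d[, 3]^2)
  expect_true(all(radial[nz] <= 1.2))
  # zero magnitude -> no force anywhere
  expect_true(all(apply_aspiration_field(sys, mouth, c(0, -1, 0), 0, 1.2) == 0))
})

test_that("microinjection halts at the rupture rule and reports it", {
  mem <- build_membrane(radius = 2.5, level = 3, seed = 11,
                        params = membrane_params(mu0 = 20, l0 = 1))
  cell <- list(sys = mem$sys, bonds = mem$bonds, membrane = mem$membrane,
               binding = NULL)
  cfg <- microinjection_config(holding_radius = 1.0, injection_radius = 0.45,
                               speed = 0.5, aspiration_magnitude = 0.5)
  res <- run_microinjection(cell, cfg, seed = 11,
                            cfg = integrator_config(dt = 1e-3,
                                                    rng_seed = 11),
                            stabilize_steps = 400, max_windows = 6)
  expect_s3_class(res, "microinjection_result")
  # halt-rule postcondition: reported bond exceeds twice its rest length
  expect_gte(res$rupture$length, 2 * res$rupture$l0)
  # the reference checkpoint differs from the final state
  expect_gt(max(abs(res$final[seq_len(nrow(res$reference)), ] -
                    res$reference)), 0.1)
  expect_gt(res$metrics$compression, 0)
})
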