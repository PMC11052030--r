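# MSD, GSER conversion, sinusoid fitting and the modulus pipelines.

make_frames <- function(pos_fun, T_, P = 3) {
  fr <- array(0, c(T_, P, 3))
  for (t in seq_len(T_)) for (p in seq_len(P)) fr[t, p, ] <- pos_fun(t, p)
  fr
}

test_that("MSD reproduces static, ballistic and diffusive laws", {
  # static particles -> msd identically zero
  fr <- make_frames(function(t, p) c(p, 0, 0), 50)
  msd <- compute_msd(fr, dt_frame = 0.1)
  expect_true(all(msd$msd == 0))
  # ballistic: msd(t) = v^2 t^2
  v <- c(0.3, -0.4, 1.2)
  frb <- make_frames(function(t, p) v * (t - 1) * 0.1, 60)
  msdb <- compute_msd(frb, dt_frame = 0.1)
  expect_equal(msdb$msd, sum(v^2) * msdb$t^2, tolerance = 1e-10)
  # 3-D random walk with per-axis step variance s2: msd(n) = 3 s2 n
  set.seed(4)
  s2 <- 0.04
  T_ <- 3000; P <- 40
  steps <- array(rnorm(T_ * P * 3, sd = sqrt(s2)), c(T_, P, 3))
  frw <- array(apply(steps, c(2, 3), cumsum), c(T_, P, 3))
  msdw <- compute_msd(frw, dt_frame = 1)
  expect_equal(msdw$msd / (3 * s2 * msdw$t), rep(1, nrow(msdw)),
               tolerance = 0.1)
})

test_that("log-log slope recovers pure and perturbed power laws", {
  t <- exp(seq(log(0.05), log(50), length.out = 60))
  for (expo in c(1, 0.85)) {
    msd <- data.frame(t = t, msd = 0.3 * t^expo)
    sl <- loglog_slope(msd)
    expect_equal(sl$chi, rep(expo, nrow(sl)), tolerance = 1e-8)
  }
  # msd = t (1 + 0.1 ln t): chi = 1 + 0.1 / (1 + 0.1 ln t)
  msd2 <- data.frame(t = t, msd = t * (1 + 0.1 * log(t)))
  sl2 <- loglog_slope(msd2, window = range(t))
  # the quadratic fit is an approximation here; check mid-window points only
  mid <- abs(log(sl2$t)) < 1
  truth <- 1 + 0.1 / (1 + 0.1 * log(sl2$t[mid]))
  expect_equal(sl2$chi[mid], truth, tolerance = 0.02)
  expect_error(loglog_slope(data.frame(t = 1:3, msd = 1:3)), "5 points")
})

test_that("GSER conversion matches closed forms", {
  t <- exp(seq(log(0.01), log(100), length.out = 80))
  a <- 0.5; kBT <- 1
  # diffusive msd = 6 D t (chi = 1): G' = 0, G'' = kBT s / (6 pi a D)
  D <- 0.2
  spec <- mason_moduli(data.frame(t = t, msd = 6 * D * t), a = a, kBT = kBT)
  expect_equal(spec$G_storage, rep(0, nrow(spec)), tolerance = 1e-8)
  expect_equal(spec$G_loss, kBT * spec$freq / (6 * pi * a * D),
               tolerance = 1e-6)
  expect_equal(spec$chi, rep(1, nrow(spec)), tolerance = 1e-8)
  # plateau msd (chi = 0): purely elastic, G'' = 0
  spec0 <- mason_moduli(data.frame(t = t, msd = rep(2.5, length(t))),
                        a = a, kBT = kBT)
  expect_equal(spec0$G_loss, rep(0, nrow(spec0)), tolerance = 1e-8)
  expect_equal(spec0$G_storage, rep(kBT / (pi * a * 2.5), nrow(spec0)),
               tolerance = 1e-6)
  # generic power law: |G*| = kBT/(pi a c t^x Gamma(1+x)) at every frequency
  x <- 0.85; cc <- 0.3
  specx <- mason_moduli(data.frame(t = t, msd = cc * t^x), a = a, kBT = kBT)
  expect_equal(specx$Gstar,
               kBT / (pi * a * cc * (1 / specx$freq)^x * gamma(1 + x)),
               tolerance = 1e-6)
  expect_equal(specx$G_loss / specx$G_storage,
               rep(tan(pi * x / 2), nrow(specx)), tolerance = 1e-6)
  # ballistic input is rejected (chi = 2 boundary handled, > 2 errors)
  expect_error(mason_moduli(data.frame(t = t, msd = t^2.6), a = a), "GSER")
})

test_that("power-law exponent fit is exact on power laws", {
  f <- exp(seq(log(0.1), log(10), length.out = 30))
  sp <- data.frame(freq = f, Gstar = 2 * f^0.75)
  expect_equal(as.numeric(powerlaw_exponent(sp)), 0.75, tolerance = 1e-9)
  sp$Gstar <- 0.7 * f^0.85
  expect_equal(as.numeric(powerlaw_exponent(sp)), 0.85, tolerance = 1e-9)
  # G = c f + d: analytic local slope at the window midpoint
  cc <- 2; dd <- 0.5
  spl <- data.frame(freq = f, Gstar = cc * f + dd)
  w <- c(1, 3)
  mid <- exp(mean(log(w)))
  e <- powerlaw_exponent(spl, window = w)
  expect_equal(as.numeric(e), cc * mid / (cc * mid + dd), tolerance = 0.01)
  expect_error(powerlaw_exponent(data.frame(freq = f, Gstar = -f)), "positive")
})

test_that("sinusoid fitting recovers amplitude and phase", {
  fs <- 0.5
  t <- seq(0, 10 / fs, length.out = 2000)
  rec <- data.frame(time = t, stress = 2 * sin(2 * pi * fs * t + 0.3) + 0.1)
  attr(rec, "fs") <- fs
  ft <- fit_sinusoid(rec)
  expect_equal(ft$amplitude, 2, tolerance = 1e-10)
  expect_equal(ft$phase, 0.3, tolerance = 1e-10)
  expect_equal(ft$offset, 0.1, tolerance = 1e-10)
  expect_false(ft$low_confidence)
  # with noise: amplitude within 1%
  set.seed(8)
  rec$stress <- rec$stress + rnorm(length(t), sd = 0.1)
  ftn <- fit_sinusoid(rec)
  expect_equal(ftn$amplitude, 2, tolerance = 0.01)
  expect_error(fit_sinusoid(rec[rec$time < 4, ], fs = fs),
               "3 retained cycles")
})

test_that("moduli follow from amplitude, phase and strain amplitude", {
  # phase 0: purely elastic; phase pi/2: purely viscous
  m0 <- moduli_from_stress(1, 0, gamma0 = 0.02, fs = 1)
  expect_equal(m0$G_loss, 0)
  expect_equal(m0$G_storage, 50)
  m90 <- moduli_from_stress(1, pi / 2, gamma0 = 0.02, fs = 1)
  expect_equal(m90$G_storage, 0, tolerance = 1e-12)
  # hand evaluation: |tau| = 1, gamma0 = 0.02, phi = pi/4
  m45 <- moduli_from_stress(1, pi / 4, gamma0 = 0.02, fs = 1)
  expect_equal(m45$G_storage, 50 * cos(pi / 4), tolerance = 1e-12)
  expect_equal(m45$G_loss, m45$G_storage, tolerance = 1e-12)
  expect_error(moduli_from_stress(1, 2, gamma0 = 0.02, fs = 1), "phase")
})

test_that("elastic and viscous toy systems bracket the phase response", {
  # elastic limit: chain of stiff harmonic bonds between the plates
  nz <- 11
  pos <- cbind(1, 1, seq(0, 2, length.out = nz))
  sys <- particle_system(pos = pos, box = c(2, 2, 3),
                         periodic = c(TRUE, TRUE, FALSE), types = "actin")
  # pre-tensioned springs (r0 below the built spacing) give the chain a
  # first-order transverse stiffness
  bonds <- list(harm = list(ij = cbind(1:(nz - 1), 2:nz),
                            r0 = rep(0.1, nz - 1), k = rep(2000, nz - 1)))
  pp <- pairs_off()
  rec <- suppressWarnings(run_oscillatory_shear(sys, bonds = bonds, pairs = pp,
                               cfg = integrator_config(dt = 2e-4,
                                                       rng_seed = 3),
                               fs = 2, gamma0 = 0.05, cycles = 10,
                               plate_fraction = 0.12))
  ft <- fit_sinusoid(rec)
  expect_lt(ft$phase, 0.2)          # nearly in phase (elastic)
  expect_gt(ft$amplitude, 0)

  # viscous limit: unbonded particles coupled to the plates by friction only
  set.seed(2)
  nfl <- 400
  posf <- cbind(runif(nfl, 0, 2), runif(nfl, 0, 2), runif(nfl, 0, 2.2))
  sysf <- particle_system(pos = posf, box = c(2, 2, 2.2),
                          periodic = c(TRUE, TRUE, FALSE), types = "solvent",
                          vel = maxwell_velocities(nfl))
  recf <- run_oscillatory_shear(sysf, pairs = pair_params(),
                                cfg = integrator_config(dt = 2e-3,
                                                        rng_seed = 4),
                                fs = 1, gamma0 = 0.3, cycles = 10,
                                plate_fraction = 0.1)
  ftf <- fit_sinusoid(recf)
  expect_gt(ftf$phase, pi / 4)      # strongly out of phase (viscous)
})

test_that("zero strain amplitude leaves only thermal stress noise", {
  sl <- tiny_slab()
  rec <- suppressWarnings(run_oscillatory_shear(sl$sys, bonds = sl$bonds,
                               binding = sl$binding,
                               cfg = integrator_config(dt = 2e-4,
                                                       rng_seed = 5),
                               fs = 2, gamma0 = 0, cycles = 4))
  expect_equal(attr(rec, "gamma0"), 0)
  expect_lt(abs(mean(rec$stress)), 3 * sd(rec$stress))
})
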