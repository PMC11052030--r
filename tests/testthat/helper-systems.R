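# Shared fixtures, built in code at test time.

# pair table with all non-bonded interactions switched off (bonded-term tests)
pairs_off <- function() {
  pp <- pair_params()
  pp$a[] <- 0; pp$gamma[] <- 0; pp$rc[] <- 0
  pp
}

# small free membrane, optionally perturbed off the built geometry
tiny_membrane <- function(radius = 3, level = 1, perturb = 0, seed = 1,
                          mu0 = 100) {
  mem <- build_membrane(radius = radius, level = level, seed = seed,
                        params = membrane_params(mu0 = mu0, l0 = 1))
  if (perturb > 0) {
    set.seed(seed)
    mem$sys$pos <- mem$sys$pos +
      matrix(rnorm(length(mem$sys$pos), sd = perturb), nrow(mem$sys$pos))
  }
  mem
}

# numerical gradient of the total deterministic energy
fd_forces <- function(sys, pairs, cfg, bonds = list(), membrane = NULL,
                      idx = seq_len(nrow(sys$pos)), h = 1e-6) {
  out <- matrix(NA_real_, nrow(sys$pos), 3)
  for (i in idx) for (d in 1:3) {
    sp <- sys; sp$pos[i, d] <- sp$pos[i, d] + h
    sm <- sys; sm$pos[i, d] <- sm$pos[i, d] - h
    out[i, d] <- -(system_forces(sp, pairs, cfg, bonds, membrane)$energies$total -
                   system_forces(sm, pairs, cfg, bonds, membrane)$energies$total) / (2 * h)
  }
  out
}

expect_forces_match_fd <- function(sys, pairs, cfg, bonds = list(),
                                   membrane = NULL, n_check = 5,
                                   tol = 1e-5, seed = 42) {
  set.seed(seed)
  idx <- sample(nrow(sys$pos), min(n_check, nrow(sys$pos)))
  f <- system_forces(sys, pairs, cfg, bonds, membrane)$forces
  nf <- fd_forces(sys, pairs, cfg, bonds, membrane, idx = idx)
  err <- max(abs(f[idx, ] - nf[idx, ]) / (1 + abs(nf[idx, ])))
  expect_lt(err, tol)
}

# tiny periodic cross-linked network slab (shared across rheology tests)
tiny_slab <- function(Na = 120, n_acp = 45, seed = 3)
  build_network_slab(Na = Na, n_acp = n_acp, seed = seed,
                     relax_steps = 500)
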