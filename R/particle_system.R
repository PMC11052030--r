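#' Construct a DPD particle system
#'
#' The single mutable simulation state: positions, velocities, species and
#' frozen flags of every particle, plus the box geometry.  Frozen particles
#' exert forces but are never integrated; their positions change only under
#' prescribed rigid-body motion.
#'
#' @param pos N x 3 matrix of positions (reduced length units).
#' @param vel N x 3 matrix of velocities; defaults to zero.
#' @param types character vector of species labels
#'   (\code{membrane}, \code{actin}, \code{acp}, \code{probe},
#'   \code{substrate}, \code{holding_pipette}, \code{injection_pipette},
#'   \code{solvent}).
#' @param frozen logical vector; default all \code{FALSE}.
#' @param box length-3 box edge lengths (origin at 0).
#' @param periodic length-3 logical, per-dimension periodic wrap.
#' @return an object of class \code{particle_system}.
#' @export
particle_system <- function(pos, vel = NULL, types = "solvent",
                            frozen = FALSE, box, periodic = c(TRUE, TRUE, TRUE)) {
  pos <- as.matrix(pos)
  stopifnot(ncol(pos) == 3, all(is.finite(pos)))
  n <- nrow(pos)
  if (is.null(vel)) vel <- matrix(0, n, 3)
  vel <- as.matrix(vel)
  types <- rep_len(types, n)
  frozen <- rep_len(frozen, n)
  if (any(frozen & rowSums(abs(vel)) > 0))
    vel[frozen, ] <- 0
  box <- as.numeric(box)
  periodic <- as.logical(rep_len(periodic, 3))
  for (d in 1:3) if (periodic[d]) pos[, d] <- pos[, d] %% box[d]
  structure(list(pos = pos, vel = vel, types = types, frozen = frozen,
                 box = box, periodic = periodic),
            class = "particle_system")
}

#' @export
print.particle_system <- function(x, ...) {
  cat("particle_system:", nrow(x$pos), "particles\n")
  print(table(x$types))
  cat("box:", paste(signif(x$box, 4), collapse = " x "),
      " periodic:", paste(substr(as.character(x$periodic), 1, 1), collapse = ""),
      "\n")
  cat("frozen:", sum(x$frozen), " mobile:", sum(!x$frozen), "\n")
  invisible(x)
}

#' Integrator configuration
#'
#' @param dt time step (reduced time); default 0.005.
#' @param kBT energy scale; default 1.
#' @param lambda velocity-prediction factor of the DPD-modified
#'   velocity-Verlet scheme; default 0.5.
#' @param rng_seed integer seed; mandatory for any stochastic run.
#' @return list of class \code{integrator_config}.
#' @export
integrator_config <- function(dt = 0.005, kBT = 1, lambda = 0.5,
                              rng_seed = 1L) {
  stopifnot(dt > 0, kBT > 0)
  structure(list(dt = dt, kBT = kBT, lambda = lambda,
                 rng_seed = as.integer(rng_seed)),
            class = "integrator_config")
}

#' Instantaneous kinetic temperature
#'
#' Mean kinetic energy per translational degree of freedom of the non-frozen
#' particles, in units of kBT (particle mass 1).
#'
#' @param sys a \code{particle_system}.
#' @return scalar temperature.
#' @export
compute_temperature <- function(sys) {
  free <- !sys$frozen
  if (!any(free)) stop("all particles are frozen; temperature undefined")
  v <- sys$vel[free, , drop = FALSE]
  sum(v^2) / (3 * nrow(v))
}

#' Draw Maxwell-Boltzmann velocities
#'
#' @param n number of particles.
#' @param kBT temperature (mass 1, so per-axis variance is kBT).
#' @param zero_momentum subtract the mean so total momentum is zero.
#' @return n x 3 matrix.
#' @export
maxwell_velocities <- function(n, kBT = 1, zero_momentum = TRUE) {
  v <- matrix(rnorm(3 * n, sd = sqrt(kBT)), n, 3)
  if (zero_momentum && n > 1) v <- sweep(v, 2, colMeans(v))
  v
}

#' Remove rigid-body drift from a velocity field
#'
#' Subtracts the centre-of-mass velocity and the rigid rotation implied by
#' the total angular momentum about the centre of mass.  DPD pair forces
#' are central, so both linear and angular momentum of an isolated body are
#' conserved; zeroing them at initialisation prevents a free membrane or
#' cell from translating/rotating coherently for the whole run, which
#' would contaminate tracer mean-square displacements.
#'
#' @param pos,vel n x 3 matrices (unit masses).
#' @return corrected velocity matrix.
#' @export
remove_rigid_drift <- function(pos, vel) {
  vel <- sweep(vel, 2, colMeans(vel))
  com <- colMeans(pos)
  r <- sweep(pos, 2, com)
  L <- c(sum(r[, 2] * vel[, 3] - r[, 3] * vel[, 2]),
         sum(r[, 3] * vel[, 1] - r[, 1] * vel[, 3]),
         sum(r[, 1] * vel[, 2] - r[, 2] * vel[, 1]))
  r2 <- rowSums(r^2)
  I <- diag(sum(r2), 3) - crossprod(r)   # inertia tensor, unit masses
  omega <- solve(I, L)
  vel - cbind(omega[2] * r[, 3] - omega[3] * r[, 2],
              omega[3] * r[, 1] - omega[1] * r[, 3],
              omega[1] * r[, 2] - omega[2] * r[, 1])
}

#' Neighbour pairs within a cutoff
#'
#' Cell-list search returning every unordered pair closer than \code{rmax}
#' (minimum-image convention in periodic dimensions) exactly once.
#'
#' @param sys a \code{particle_system}.
#' @param rmax search radius; must be at least the largest pair cutoff it
#'   will serve.
#' @return two-column integer matrix of particle indices (i < j).
#' @export
build_neighbor_list <- function(sys, rmax) {
  for (d in 1:3)
    if (sys$periodic[d] && sys$box[d] < 2 * rmax)
      stop("periodic box edge ", d, " shorter than 2*rmax: ",
           "minimum image convention violated")
  cpp_neighbor_pairs(sys$pos, sys$box, sys$periodic, rmax)
}

#' Conservative DPD pair force
#'
#' Soft repulsion a_ij (1 - r/r_c) along the unit vector from j to i for
#' r < r_c, zero beyond the cutoff.  The force on j is the exact negation.
#'
#' @param r_i,r_j positions (length-3; already minimum-imaged).
#' @param a_ij repulsion strength.
#' @param r_c cutoff radius.
#' @return length-3 force vector acting on particle i.
#' @export
conservative_force <- function(r_i, r_j, a_ij, r_c) {
  d <- r_i - r_j
  r <- sqrt(sum(d^2))
  if (r == 0) stop("overlapping particles: force direction undefined")
  if (r >= r_c) return(c(0, 0, 0))
  a_ij * (1 - r / r_c) * d / r
}

#' Dissipative and random DPD pair forces
#'
#' The dissipative term is \code{-gamma omega_D(r) (v_ij . rhat) rhat} with
#' \code{omega_D = (1 - r/r_c)^2}; the random term is
#' \code{sigma omega_R(r) eps/sqrt(dt) rhat} with \code{omega_R =
#' sqrt(omega_D)} and \code{sigma = sqrt(2 gamma kBT)}.  One standard-normal
#' deviate \code{eps} is shared by the pair, so the forces on i and j are
#' exact negations and momentum is conserved.
#'
#' @param r_i,r_j positions; \code{r_ij} must be below the cutoff.
#' @param v_i,v_j velocities.
#' @param gamma friction coefficient; \code{r_c} cutoff; \code{kBT} energy
#'   scale; \code{dt} time step.
#' @param eps optional fixed normal deviate (drawn if missing).
#' @return list with \code{dissipative} and \code{random} force vectors on i.
#' @export
dissipative_random_forces <- function(r_i, r_j, v_i, v_j, gamma, r_c,
                                      kBT = 1, dt = 0.005, eps = NULL) {
  d <- r_i - r_j
  r <- sqrt(sum(d^2))
  stopifnot(r > 0, r < r_c)
  rhat <- d / r
  w <- 1 - r / r_c
  if (is.null(eps)) eps <- rnorm(1)
  list(dissipative = -gamma * w^2 * sum((v_i - v_j) * rhat) * rhat,
       random = fd_sigma(gamma, kBT) * w * eps / sqrt(dt) * rhat)
}

# ------------------------------------------------------------------ world

# Assemble the list the compiled engine consumes.  `bonds` may carry wlc /
# harm / dyn / angles / dihedrals entries; the remaining arguments attach
# membrane surface constraints, Bell binding kinetics, prescribed drivers,
# the aspiration field, the rupture halt rule and force-measurement groups.
build_world <- function(sys, pairs, config, bonds = list(),
                        membrane = NULL, binding = NULL, drivers = NULL,
                        aspiration = NULL, rupture = NULL,
                        measure_group = NULL, bg_gamma = 0) {
  list(pos = sys$pos, vel = sys$vel, type = .type_code(sys$types),
       frozen = sys$frozen, box = sys$box, periodic = sys$periodic,
       pair_a = pairs$a, pair_gamma = pairs$gamma, pair_rc = pairs$rc,
       kBT = config$kBT, dt = config$dt, lambda = config$lambda,
       bonds = bonds, membrane = membrane, binding = binding,
       drivers = drivers, aspiration = aspiration, rupture = rupture,
       measure_group = measure_group, bg_gamma = bg_gamma)
}

#' Run a DPD simulation
#'
#' Integrates the system with the DPD-modified velocity-Verlet scheme
#' (velocity prediction factor \code{lambda}).  Frozen particles never move
#' except under prescribed drivers; periodic images are tracked so that
#' recorded trajectories are unwrapped.
#'
#' @param sys a \code{particle_system}.
#' @param pairs a \code{pair_params} table.
#' @param config an \code{integrator_config} (its \code{rng_seed} drives all
#'   stochastic forces and kinetics).
#' @param nsteps number of time steps.
#' @param bonds,membrane,binding,drivers,aspiration,rupture,measure_group
#'   optional engine attachments (bond tables, membrane surface constraints,
#'   Bell kinetics, prescribed motions, aspiration field, rupture halt rule,
#'   per-particle measurement group ids).
#' @param sample_every record observables/trajectory every this many steps
#'   (0 = never).
#' @param track integer indices of particles whose unwrapped trajectory is
#'   recorded.
#' @param log_bond_events keep a log of binding/unbinding events.
#' @param skin Verlet-list skin added to the largest cutoff; the list is
#'   rebuilt every \code{nl_every} steps, so the skin only needs to cover
#'   that much drift.  Small time steps warrant a thin skin (pair-list
#'   size grows with the cube of cutoff + skin).
#' @param nl_every steps between pair-list rebuilds; at small time steps
#'   particles drift far less than the skin between rebuilds, so a larger
#'   interval is safe and cheaper.
#' @param bg_gamma weak per-particle Langevin friction (with matching
#'   noise) applied to free particles as a numerical stabiliser for
#'   sparsely-coupled networks on multi-million-step runs; 0 disables it.
#'   Values far below every physical friction leave the measured
#'   mechanics unchanged on assay time scales.
#' @return list with the updated \code{sys}, observable data frame
#'   \code{obs} (time, temperature, momentum, driver displacement, dynamic
#'   bond count, per-group forces), unwrapped \code{frames} array
#'   (sample x tracked x 3), final dynamic bond table \code{dyn}, and
#'   \code{rupture} event (or NULL).
#' @export
run_dpd <- function(sys, pairs, config, nsteps, bonds = list(),
                    membrane = NULL, binding = NULL, drivers = NULL,
                    aspiration = NULL, rupture = NULL, measure_group = NULL,
                    sample_every = 0L, track = integer(0),
                    log_bond_events = FALSE, skin = 0.3, nl_every = 5L,
                    bg_gamma = 0) {
  world <- build_world(sys, pairs, config, bonds, membrane, binding,
                       drivers, aspiration, rupture, measure_group,
                       bg_gamma = bg_gamma)
  res <- cpp_run(world, as.integer(nsteps), config$rng_seed,
                 as.integer(sample_every), as.integer(track),
                 nl_every = as.integer(nl_every), skin = skin,
                 log_bond_events = log_bond_events)
  out_sys <- sys
  out_sys$pos <- res$pos
  out_sys$vel <- res$vel
  ngroups <- if (is.null(measure_group)) 0L else max(0L, measure_group)
  obs <- as.data.frame(res$obs)
  base_names <- c("time", "temperature", "px", "py", "pz",
                  "driver_disp", "n_dyn_bonds", "reserved")
  gnames <- if (ngroups > 0)
    as.vector(t(outer(seq_len(ngroups), c("fx", "fy", "fz"),
                      function(g, c) paste0("g", g, "_", c)))) else character(0)
  names(obs) <- c(base_names, gnames)
  obs <- obs[seq_len(res$nsample), , drop = FALSE]
  frames <- res$frames
  if (length(frames) > 0 && res$nsample < dim(frames)[1])
    frames <- frames[seq_len(res$nsample), , , drop = FALSE]
  rupture <- res$rupture
  if (is.null(rupture) || length(rupture) == 0) rupture <- NULL
  list(sys = out_sys, obs = obs, frames = frames, img = res$img,
       dyn = res$dyn, rupture = rupture, events = res$events,
       steps_done = res$steps_done)
}

#' Deterministic forces and energies of the current configuration
#'
#' Evaluates the conservative pair force plus every bonded and constraint
#' term (no dissipative or random contributions): the reference used by the
#' finite-difference consistency checks.
#'
#' @inheritParams run_dpd
#' @return list with an N x 3 \code{forces} matrix and a named
#'   \code{energies} list (per term and total).
#' @export
system_forces <- function(sys, pairs, config, bonds = list(),
                          membrane = NULL, aspiration = NULL) {
  world <- build_world(sys, pairs, config, bonds, membrane,
                       aspiration = aspiration)
  cpp_forces_energy(world)
}

#' Build an equilibrated homogeneous DPD fluid
#'
#' Random solvent particles at the requested number density in a fully
#' periodic cube, velocities drawn from the Maxwell-Boltzmann distribution.
#'
#' @param L cube edge length.
#' @param density number density (particles per unit volume); default 3.
#' @param kBT temperature.
#' @param seed RNG seed.
#' @return a \code{particle_system}.
#' @export
dpd_fluid <- function(L = 6, density = 3, kBT = 1, seed = 1) {
  set.seed(seed)
  n <- round(density * L^3)
  particle_system(pos = matrix(runif(3 * n, 0, L), n, 3),
                  vel = maxwell_velocities(n, kBT),
                  types = "solvent", box = rep(L, 3))
}
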