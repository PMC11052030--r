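#' Build a rigid conical indenter
#'
#' Particles on the surface of a downward-pointing cone with the given
#' half-angle from the indentation axis, arranged in rings at
#' \code{spacing}.  The probe is rigid: all its particles are frozen and
#' move only under the prescribed approach.
#'
#' @param tip length-3 position of the cone tip.
#' @param half_angle_deg cone half-angle from the axis, degrees; default 18.
#' @param height cone height along +z above the tip.
#' @param spacing surface particle spacing; default 0.18, comfortably
#'   below the probe-membrane interaction cutoff so the wall is gap-free.
#' @return list with \code{pos} (n x 3), \code{n}, and the geometry.
#' @export
make_cone_probe <- function(tip, half_angle_deg = 18, height = 3,
                            spacing = 0.18) {
  stopifnot(half_angle_deg > 0, half_angle_deg < 90)
  alpha <- half_angle_deg * pi / 180
  ds <- spacing
  slant <- height / cos(alpha)
  pts <- matrix(tip, 1, 3, byrow = TRUE)
  s <- ds
  while (s <= slant) {
    z <- s * cos(alpha)
    r <- s * sin(alpha)
    nring <- max(3L, ceiling(2 * pi * r / ds))
    th <- 2 * pi * seq_len(nring) / nring
    pts <- rbind(pts, cbind(tip[1] + r * cos(th), tip[2] + r * sin(th),
                            tip[3] + z))
    s <- s + ds
  }
  list(pos = pts, n = nrow(pts), half_angle_deg = half_angle_deg,
       height = height, spacing = spacing, tip = tip)
}

#' Build a rigid flat substrate
#'
#' @param center x/y centre; \code{z} plane height; square \code{extent};
#'   particle \code{spacing}.
#' @return list with \code{pos} and \code{n}.
#' @export
make_substrate <- function(center = c(0, 0), z = 0, extent = 12,
                           spacing = 0.3) {
  g <- seq(-extent / 2, extent / 2, by = spacing)
  pos <- cbind(rep(center[1] + g, each = length(g)),
               rep(center[2] + g, times = length(g)), z)
  list(pos = pos, n = nrow(pos))
}

#' Build a rigid hollow-cylinder micropipette
#'
#' Rings of particles forming an open tube along \code{axis}; used for both
#' the holding and the injection micropipette.
#'
#' @param mouth length-3 centre of the pipette mouth.
#' @param axis direction pointing from the mouth into the pipette body.
#' @param inner_radius bore radius; \code{length} tube length;
#'   \code{spacing} particle spacing.
#' @param closed fill the mouth with a particle disk (a blunt needle tip).
#'   At reduced scale the membrane mesh is coarse relative to the bore, so
#'   an open injection tube would swallow the membrane through its mouth
#'   instead of indenting it; the closed tip restores the full-scale
#'   poking mechanics.
#' @param layers,layer_gap number of concentric wall shells and their
#'   radial gap.  The DPD wall potentials are soft; a single particle layer
#'   is penetrable under the loads the assays apply, so walls are built
#'   with thickness like their glass counterparts.
#' @return list with \code{pos}, \code{n} and the geometry.
#' @export
make_pipette <- function(mouth, axis, inner_radius, length = 6,
                         spacing = 0.15, closed = FALSE, layers = 2,
                         layer_gap = 0.2) {
  u <- axis / sqrt(sum(axis^2))
  # orthonormal frame
  a <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- a - sum(a * u) * u; e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(u[2] * e1[3] - u[3] * e1[2], u[3] * e1[1] - u[1] * e1[3],
          u[1] * e1[2] - u[2] * e1[1])
  nring <- max(6L, ceiling(2 * pi * inner_radius / spacing))
  th <- 2 * pi * seq_len(nring) / nring
  ring <- outer(cos(th), e1) + outer(sin(th), e2)
  ss <- seq(0, length, by = spacing)
  pos <- NULL
  for (lay in seq_len(layers) - 1) {
    rl <- inner_radius + lay * layer_gap
    nringl <- max(6L, ceiling(2 * pi * rl / spacing))
    thl <- 2 * pi * seq_len(nringl) / nringl
    ringl <- outer(cos(thl), e1) + outer(sin(thl), e2)
    pos <- rbind(pos, do.call(rbind, lapply(ss, function(s)
      sweep(ringl * rl, 2, mouth + s * u, "+"))))
  }
  if (closed) {
    for (lay in seq_len(layers) - 1) {
      rr <- seq(0, inner_radius - spacing / 2, by = spacing)
      for (r1 in rr) {
        nr <- max(1L, ceiling(2 * pi * r1 / spacing))
        th1 <- 2 * pi * seq_len(nr) / nr
        disk <- outer(cos(th1), e1) + outer(sin(th1), e2)
        pos <- rbind(pos, sweep(disk * r1, 2, mouth - lay * layer_gap * u, "+"))
      }
    }
  }
  list(pos = pos, n = nrow(pos), mouth = mouth, axis = u,
       inner_radius = inner_radius, length = length, closed = closed)
}

#' Build a rigid cone-tipped injection needle
#'
#' A sharp conical tip (like the bevelled tip of a real injection
#' micropipette) opening into a cylindrical shaft.  The sharp tip wedges a
#' membrane face open with geometric amplification as it advances, so
#' puncture proceeds by progressive bond stretch -- a blunt tube of the same
#' radius pushed against a coarse triangulated membrane only invaginates
#' it.
#'
#' @param tip length-3 tip position.
#' @param axis direction from the tip into the needle body.
#' @param shaft_radius cylindrical shaft radius.
#' @param tip_half_angle_deg cone half-angle; default 25.
#' @param length total needle length; \code{spacing} particle spacing.
#' @return list with \code{pos}, \code{n}, and the geometry.
#' @export
make_injection_needle <- function(tip, axis, shaft_radius = 0.45,
                                  tip_half_angle_deg = 25, length = 6,
                                  spacing = 0.09) {
  u <- axis / sqrt(sum(axis^2))
  a <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- a - sum(a * u) * u; e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(u[2] * e1[3] - u[3] * e1[2], u[3] * e1[1] - u[1] * e1[3],
          u[1] * e1[2] - u[2] * e1[1])
  alpha <- tip_half_angle_deg * pi / 180
  cone_len <- shaft_radius / tan(alpha)
  pos <- matrix(tip, 1, 3, byrow = TRUE)
  zz <- seq(spacing, length, by = spacing * 0.9)
  for (z in zz) {
    r1 <- if (z < cone_len) z * tan(alpha) else shaft_radius
    nr <- max(3L, ceiling(2 * pi * r1 / spacing))
    th <- 2 * pi * seq_len(nr) / nr
    ring <- outer(cos(th), e1) + outer(sin(th), e2)
    pos <- rbind(pos, sweep(ring * r1, 2, tip + z * u, "+"))
    if (z >= cone_len) {   # second wall layer along the shaft
      r2 <- shaft_radius + 0.2
      nr2 <- max(3L, ceiling(2 * pi * r2 / spacing))
      th2 <- 2 * pi * seq_len(nr2) / nr2
      ring2 <- outer(cos(th2), e1) + outer(sin(th2), e2)
      pos <- rbind(pos, sweep(ring2 * r2, 2, tip + z * u, "+"))
    }
  }
  list(pos = pos, n = nrow(pos), tip = tip, axis = u,
       shaft_radius = shaft_radius, tip_half_angle_deg = tip_half_angle_deg,
       length = length)
}

# append a rigid block of particles to a system
.add_rigid <- function(sys, pos, species) {
  n0 <- nrow(sys$pos)
  n <- nrow(pos)
  particle_system(pos = rbind(sys$pos, pos),
                  vel = rbind(sys$vel, matrix(0, n, 3)),
                  types = c(sys$types, rep(species, n)),
                  frozen = c(sys$frozen, rep(TRUE, n)),
                  box = sys$box, periodic = sys$periodic)
}

#' Virtual conical indentation of a cell
#'
#' Places the cell on a fixed substrate, relaxes it, positions a rigid
#' conical probe above the apex, then advances the probe at constant speed.
#' The load is the axial force the cell exerts on the probe, averaged over
#' each sampling interval; the contact point is the first displacement at
#' which the smoothed load exceeds three standard deviations of the
#' pre-contact noise, sustained thereafter.
#'
#' @param cell a \code{membrane_system} or \code{cell_system}.
#' @param speed probe approach speed (reduced length/time); default 0.05.
#' @param max_depth probe travel beyond first touch estimate.
#' @param relax_steps pre-indentation relaxation steps.
#' @param probe geometry from \code{\link{make_cone_probe}} (built
#'   automatically when NULL).
#' @param substrate_gap initial gap between cell and substrate plane.
#' @param seed RNG seed; \code{pairs} pair table; \code{cfg} integrator.
#' @param sample_every sampling stride (steps).
#' @return object of class \code{force_indentation}: data frame with
#'   \code{displacement} (probe travel), \code{load}; attributes
#'   \code{contact_index}, \code{contact_displacement}, \code{speed},
#'   \code{probe_n}.
#' @export
run_indentation <- function(cell, speed = 0.05, max_depth = 2.5,
                            relax_steps = 2000, probe = NULL,
                            substrate_gap = 0.3, seed = 1,
                            pairs = pair_params(),
                            cfg = integrator_config(rng_seed = seed),
                            sample_every = 25L) {
  sys <- cell$sys
  bonds <- cell$bonds
  mem <- cell$membrane
  binding <- cell$binding
  center <- colMeans(sys$pos[sys$types == "membrane", , drop = FALSE])
  rad <- max(sys$pos[sys$types == "membrane", 3]) - center[3]

  zmin <- min(sys$pos[, 3])
  sub <- make_substrate(center = center[1:2], z = zmin - substrate_gap,
                        extent = 4 * rad)
  sys <- .add_rigid(sys, sub$pos, "substrate")

  # settle on the substrate
  eq <- run_dpd(sys, pairs, cfg, nsteps = relax_steps, bonds = bonds,
                membrane = mem, binding = binding,
                sample_every = max(1L, relax_steps %/% 10L))
  sys <- eq$sys

  # the coated slide adheres to the cell: anchor the membrane vertices in
  # the basal contact patch so the cell cannot recoil from the probe
  memv <- which(sys$types == "membrane")
  basal <- memv[sys$pos[memv, 3] <= min(sys$pos[memv, 3]) + 0.25]
  sys$frozen[basal] <- TRUE
  sys$vel[basal, ] <- 0

  apex_z <- max(sys$pos[sys$types == "membrane", 3])
  gap0 <- 0.6
  if (is.null(probe))
    probe <- make_cone_probe(tip = c(center[1], center[2], apex_z + gap0),
                             height = max_depth + 1.5)
  n0 <- nrow(sys$pos)
  sys <- .add_rigid(sys, probe$pos, "probe")
  pidx <- n0 + seq_len(probe$n)

  travel <- gap0 + max_depth
  nsteps <- ceiling(travel / (speed * cfg$dt))
  mg <- integer(nrow(sys$pos)); mg[pidx] <- 1L
  drivers <- list(list(mode = "translate", idx = pidx, vel = c(0, 0, -speed)))
  cfg2 <- integrator_config(dt = cfg$dt, kBT = cfg$kBT, lambda = cfg$lambda,
                            rng_seed = cfg$rng_seed + 1L)
  res <- run_dpd(sys, pairs, cfg2, nsteps = nsteps, bonds = bonds,
                 membrane = mem, binding = binding, drivers = drivers,
                 measure_group = mg, sample_every = sample_every)
  disp <- res$obs$time * speed
  load <- res$obs$g1_fz       # cell pushes the descending probe upward (+z)
  curve <- data.frame(displacement = disp, load = load)
  ci <- .contact_index(curve)
  structure(curve, class = c("force_indentation", "data.frame"),
            contact_index = ci,
            contact_displacement = if (is.na(ci)) NA_real_ else disp[ci],
            speed = speed, probe_n = probe$n, probe = probe,
            final_sys = res$sys)
}

# first sustained load above 3 x pre-contact noise SD, on a smoothed curve
.contact_index <- function(curve, baseline_frac = 0.2, k_smooth = 5) {
  sm <- stats::filter(curve$load, rep(1 / k_smooth, k_smooth), sides = 1)
  sm[is.na(sm)] <- curve$load[is.na(sm)]
  nb <- max(3L, floor(nrow(curve) * baseline_frac))
  thr <- mean(sm[1:nb]) + 3 * sd(sm[1:nb])
  above <- sm > thr
  # sustained: above threshold and stays above for most of the remainder
  for (i in which(above)) {
    rest <- above[i:min(length(above), i + 20L)]
    if (mean(rest) > 0.8) return(i)
  }
  NA_integer_
}

#' Sneddon fit of a force-indentation curve
#'
#' Conical-indenter contact model F = (2/pi) (E / (1 - nu^2)) tan(alpha)
#' delta^2, with delta measured from the contact point.  The default
#' two-point method uses the window endpoints (the large-slope portion of
#' the curve); \code{method = "ls"} least-squares fits F against delta^2
#' over the whole window.
#'
#' @param curve a \code{force_indentation} (or data frame with
#'   \code{displacement}, \code{load}).
#' @param window indentation-depth window (from contact), default
#'   c(0.4, 0.8) in the curve's length units.
#' @param alpha_deg cone half-angle, degrees; default 18.
#' @param nu Poisson ratio; default 0.5 (incompressible).
#' @param contact contact displacement; taken from the curve's attribute,
#'   else 0.
#' @param method \code{"two-point"} or \code{"ls"}.
#' @param smooth half-width (samples) of the moving average applied before
#'   the two-point fit; thermal contact noise on a coarse-grained cell is
#'   large, and the two endpoints alone would inherit it.
#' @return Young's modulus E (units of load / length^2); errors when the
#'   fit comes out non-positive.
#' @export
sneddon_fit <- function(curve, window = c(0.4, 0.8), alpha_deg = 18,
                        nu = 0.5, contact = NULL,
                        method = c("two-point", "ls"), smooth = 4L) {
  method <- match.arg(method)
  # the two-point method inherits the endpoints' noise directly, so it is
  # applied to a smoothed curve (the moving-average bias cancels in the
  # two-point difference); the through-origin LS variant averages over the
  # window by construction and stays exact on noise-free curves
  if (method == "two-point" && smooth > 0 && nrow(curve) > 2 * smooth + 1) {
    k <- 2L * as.integer(smooth) + 1L
    sm <- stats::filter(curve$load, rep(1 / k, k), sides = 2)
    curve$load <- ifelse(is.na(sm), curve$load, sm)
  }
  if (is.null(contact))
    contact <- attr(curve, "contact_displacement")
  if (is.null(contact) || is.na(contact)) contact <- 0
  delta <- curve$displacement - contact
  keep <- delta >= window[1] & delta <= window[2]
  if (sum(keep) < 2) stop("fit window outside the measured curve")
  C <- (2 / pi) * tan(alpha_deg * pi / 180) / (1 - nu^2)
  d <- delta[keep]; f <- curve$load[keep]
  E <- if (method == "two-point") {
    i1 <- which.min(d); i2 <- which.max(d)
    (f[i2] - f[i1]) / (C * (d[i2]^2 - d[i1]^2))
  } else {
    # the contact law has no intercept, so the fit goes through the
    # origin: far more noise-robust than estimating a free intercept
    sum(f * d^2) / (C * sum(d^4))
  }
  if (!is.finite(E) || E <= 0)
    stop("non-positive fitted modulus; window precedes contact?")
  E
}

#' Generate a synthetic Sneddon force-indentation curve
#'
#' @param E Young's modulus; \code{alpha_deg} cone half-angle; \code{nu}
#'   Poisson ratio; \code{delta} indentation depths.
#' @return \code{force_indentation} data frame with exact Sneddon loads.
#' @export
sneddon_curve <- function(E, alpha_deg = 18, nu = 0.5,
                          delta = seq(0, 1, by = 0.01)) {
  C <- (2 / pi) * tan(alpha_deg * pi / 180) / (1 - nu^2)
  structure(data.frame(displacement = delta, load = C * E * delta^2),
            class = c("force_indentation", "data.frame"),
            contact_displacement = 0, contact_index = 1L)
}

#' Indentation parameter sweep
#'
#' Repeats the virtual indentation over grids of the membrane shear
#' modulus, bending stiffness and maximum bond length, fitting a Sneddon
#' modulus for each run.  All runs share one seed so curves differ only
#' through the swept parameter.
#'
#' @param cell_factory function(mu0, kbending, x0) returning a fresh cell
#'   (a \code{membrane_system} or \code{cell_system}).
#' @param mu0_values sweep of WLC shear moduli; default c(5, 50, 100, 300).
#' @param kbending_values default 65.
#' @param x0_values equilibrium-to-contour ratios standing in for the
#'   lmax sweep at fixed l0 (lmax = l0/x0); default NULL (no sweep).
#' @param window Sneddon window; \code{...} passed to
#'   \code{\link{run_indentation}}.
#' @return data frame with one row per combination (parameters, fitted E)
#'   and the curves as attribute \code{"curves"}.
#' @export
parameter_sweep_indentation <- function(cell_factory,
                                        mu0_values = c(5, 50, 100, 300),
                                        kbending_values = 65,
                                        x0_values = NULL,
                                        window = c(0.4, 0.8), ...) {
  grid <- expand.grid(mu0 = mu0_values, kbending = kbending_values,
                      x0 = if (is.null(x0_values)) NA_real_ else x0_values)
  curves <- vector("list", nrow(grid))
  E <- numeric(nrow(grid))
  for (k in seq_len(nrow(grid))) {
    cell <- cell_factory(grid$mu0[k], grid$kbending[k], grid$x0[k])
    cur <- run_indentation(cell, ...)
    curves[[k]] <- cur
    E[k] <- sneddon_fit(cur, window = window)
  }
  grid$E <- E
  attr(grid, "curves") <- curves
  grid
}

#' @export
plot.force_indentation <- function(x, ...) {
  plot(x$displacement, x$load, type = "l",
       xlab = "probe displacement (reduced)", ylab = "load (reduced)", ...)
  cd <- attr(x, "contact_displacement")
  if (!is.null(cd) && !is.na(cd)) graphics::abline(v = cd, lty = 3)
  invisible(x)
}

# ------------------------------------------------------------ microinjection

#' Microinjection configuration
#'
#' @param holding_radius,injection_radius bore radii of the two pipettes.
#' @param speed injection pipette speed (reduced length/time).
#' @param speed_label_um_s nominal physical speed label (um/s), stored as
#'   metadata only.
#' @param aspiration_magnitude body-force magnitude of the aspiration
#'   field; calibrated so the aspirated tongue is about one bore radius.
#' @param rupture_factor halt when a membrane bond exceeds this multiple of
#'   its equilibrium length; default 2.
#' @return list of class \code{microinjection_config}.
#' @export
microinjection_config <- function(holding_radius = 1.6,
                                  injection_radius = 0.6,
                                  speed = 0.5, speed_label_um_s = NA,
                                  aspiration_magnitude = 0.6,
                                  rupture_factor = 2) {
  structure(list(holding_radius = holding_radius,
                 injection_radius = injection_radius, speed = speed,
                 speed_label_um_s = speed_label_um_s,
                 aspiration_magnitude = aspiration_magnitude,
                 rupture_factor = rupture_factor),
            class = "microinjection_config")
}

#' Apply the aspiration force field (one evaluation)
#'
#' The holding pipette's negative pressure is simplified into a constant
#' body force drawing membrane particles inside the capture region toward
#' and into the pipette mouth.
#'
#' @param sys a \code{particle_system}.
#' @param mouth,axis pipette mouth and inward axis.
#' @param magnitude force magnitude; \code{radius} capture radius;
#'   \code{smin,smax} axial extent of the capture region relative to the
#'   mouth.
#' @return N x 3 matrix of external forces (zero outside the region).
#' @export
apply_aspiration_field <- function(sys, mouth, axis, magnitude, radius,
                                   smin = -2, smax = 4) {
  u <- axis / sqrt(sum(axis^2))
  F <- matrix(0, nrow(sys$pos), 3)
  mem <- which(sys$types == "membrane" & !sys$frozen)
  d <- sweep(sys$pos[mem, , drop = FALSE], 2, mouth)
  s <- d %*% u
  radial <- sqrt(rowSums((d - outer(as.numeric(s), u))^2))
  sel <- s >= smin & s <= smax & radial <= radius
  F[mem[sel], ] <- matrix(u * magnitude, sum(sel), 3, byrow = TRUE)
  F
}

#' Virtual microinjection with rupture detection
#'
#' Stage 1 (aspiration): the cell is drawn against the fixed holding
#' pipette by the aspiration force field until the drawn-in tongue length
#' stabilises (variation below 1\% of the bore radius across consecutive
#' check windows).  The stabilised state is checkpointed as the strain
#' reference.  Stage 2 (injection): the injection pipette advances along
#' -y at constant speed; every step all membrane bond lengths are checked
#' and the run halts at the first bond exceeding
#' \code{rupture_factor * l0}.
#'
#' @param cell a \code{cell_system} (or \code{membrane_system}).
#' @param config a \code{microinjection_config}.
#' @param seed RNG seed; \code{pairs} pair table; \code{cfg} integrator.
#' @param max_travel abort if the pipette advances this far with no
#'   rupture.
#' @param stabilize_steps steps per aspiration check window;
#'   \code{max_windows} cap on windows.
#' @return list of class \code{microinjection_result}: \code{reference}
#'   (checkpointed positions), \code{final} (state at rupture),
#'   \code{rupture} event, cell indices, and summary metrics (cell y-extent
#'   before/at rupture, pipette penetration depth).
#' @export
run_microinjection <- function(cell, config = microinjection_config(),
                               seed = 1, pairs = pair_params(),
                               cfg = integrator_config(rng_seed = seed),
                               max_travel = NULL, stabilize_steps = 600L,
                               max_windows = 12L) {
  sys <- cell$sys
  bonds <- cell$bonds
  mem <- cell$membrane
  binding <- cell$binding
  midx <- which(sys$types == "membrane")
  center <- colMeans(sys$pos[midx, , drop = FALSE])
  rad <- max(sys$pos[midx, 2]) - center[2]

  # holding pipette on -y side, mouth facing the cell; axis -y into the body
  hold_mouth <- center + c(0, -(rad + 0.35), 0)
  hold <- make_pipette(hold_mouth, axis = c(0, -1, 0),
                       inner_radius = config$holding_radius)
  sys <- .add_rigid(sys, hold$pos, "holding_pipette")
  # the capture region reaches only a short way into the bore: once a
  # tongue plugs the mouth the negative pressure acts on that plug, not on
  # ever-deeper material (otherwise the whole cell is slowly extruded
  # through the holding pipette)
  asp <- list(point = hold_mouth, axis = c(0, -1, 0),
              magnitude = config$aspiration_magnitude,
              radius = config$holding_radius * 0.95,
              smin = -2, smax = 1)

  tongue <- function(s) {
    m <- which(s$types == "membrane")
    depth <- hold_mouth[2] - min(s$pos[m, 2])  # how far past the mouth
    max(0, depth)
  }
  # calibrate the field so the aspirated tongue is about one bore radius
  # deep (anchoring the cell), then run until the tongue length stabilises
  prev <- tongue(sys)
  target <- config$holding_radius
  for (wdw in seq_len(max_windows)) {
    cfg_w <- integrator_config(dt = cfg$dt, kBT = cfg$kBT,
                               lambda = cfg$lambda,
                               rng_seed = cfg$rng_seed + wdw)
    res <- run_dpd(sys, pairs, cfg_w, nsteps = stabilize_steps,
                   bonds = bonds, membrane = mem, binding = binding,
                   aspiration = asp, sample_every = stabilize_steps)
    bonds$dyn <- res$dyn
    sys <- res$sys
    cur <- tongue(sys)
    stretch <- max(.wlc_bond_lengths(sys, bonds)$len / bonds$wlc$l0)
    if (cur < 0.8 * target && stretch < 0.8 * config$rupture_factor &&
        asp$magnitude < 20 * config$aspiration_magnitude) {
      asp$magnitude <- asp$magnitude * 1.6   # too weak: no anchoring tongue
    } else if (stretch >= 0.9 * config$rupture_factor) {
      asp$magnitude <- asp$magnitude / 1.6   # about to tear the membrane
    } else if (abs(cur - prev) < 0.01 * config$holding_radius && wdw >= 3) {
      break
    }
    prev <- cur
  }
  config$aspiration_magnitude <- asp$magnitude  # record calibrated value
  # aspiration must not rupture: verify every membrane bond is intact
  bl <- .wlc_bond_lengths(sys, bonds)
  if (any(bl$len > config$rupture_factor * bl$l0))
    stop("aspiration field ruptured the membrane; reduce its magnitude")

  reference <- sys$pos                      # checkpointed state
  ref_extent <- diff(range(sys$pos[which(sys$types == "membrane"), 2]))

  # the holding pipette grips the captured membrane cap: anchor it for the
  # injection stage so the cell cannot escape the needle as a rigid body
  memv2 <- which(sys$types == "membrane")
  dcap <- sweep(sys$pos[memv2, , drop = FALSE], 2, hold_mouth)
  radial <- sqrt(dcap[, 1]^2 + dcap[, 3]^2)
  cap <- memv2[radial <= config$holding_radius & dcap[, 2] <= 0.6]
  sys$frozen[cap] <- TRUE
  sys$vel[cap, ] <- 0

  inj_mouth <- center + c(0, rad + 0.8, 0)
  inj <- make_injection_needle(inj_mouth, axis = c(0, 1, 0),
                               shaft_radius = config$injection_radius)
  n0 <- nrow(sys$pos)
  sys <- .add_rigid(sys, inj$pos, "injection_pipette")
  iidx <- n0 + seq_len(inj$n)
  if (is.null(max_travel)) max_travel <- 2.2 * rad
  nsteps <- ceiling(max_travel / (config$speed * cfg$dt))
  drivers <- list(list(mode = "translate", idx = iidx,
                       vel = c(0, -config$speed, 0)))
  cfg2 <- integrator_config(dt = cfg$dt, kBT = cfg$kBT, lambda = cfg$lambda,
                            rng_seed = cfg$rng_seed + 101L)
  res <- run_dpd(sys, pairs, cfg2, nsteps = nsteps, bonds = bonds,
                 membrane = mem, binding = binding, aspiration = asp,
                 drivers = drivers, rupture = list(factor = config$rupture_factor),
                 sample_every = 50L)
  if (is.null(res$rupture))
    stop("injection pipette crossed the cell with no rupture; ",
         "parameters inconsistent")
  fin <- res$sys
  fin_extent <- diff(range(fin$pos[which(fin$types == "membrane"), 2]))
  structure(list(
    reference = reference, final = fin$pos, sys = fin,
    rupture = res$rupture,
    idx = list(membrane = which(cell$sys$types == "membrane"),
               actin = which(cell$sys$types == "actin"),
               acp = which(cell$sys$types == "acp")),
    metrics = list(
      extent_before = ref_extent, extent_at_rupture = fin_extent,
      compression = 1 - fin_extent / ref_extent,
      penetration = config$speed * res$rupture$time),
    config = config, obs = res$obs), class = "microinjection_result")
}

.wlc_bond_lengths <- function(sys, bonds) {
  ij <- bonds$wlc$ij
  d <- sys$pos[ij[, 1], , drop = FALSE] - sys$pos[ij[, 2], , drop = FALSE]
  list(len = sqrt(rowSums(d^2)), l0 = bonds$wlc$l0)
}

#' @export
print.microinjection_result <- function(x, ...) {
  cat("microinjection_result: rupture at t =", signif(x$rupture$time, 4),
      " bond", x$rupture$bond,
      " length", signif(x$rupture$length, 4),
      "(", signif(x$rupture$length / x$rupture$l0, 3), "x l0 )\n")
  cat("cell y-extent:", signif(x$metrics$extent_before, 4), "->",
      signif(x$metrics$extent_at_rupture, 4),
      " compression:", signif(x$metrics$compression, 3), "\n")
  invisible(x)
}
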