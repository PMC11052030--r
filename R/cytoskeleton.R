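#' Cytoskeleton parameters
#'
#' Stiffness and kinetic constants of the cross-linked filament/ACP network
#' (reduced units).  Filament particles are connected by harmonic bonds
#' (U = kbond (r - r0)^2, no 1/2 factor) and straightened by harmonic
#' angles (U = kangle (theta - pi)^2); ACP-mediated junctions carry a
#' four-body cosine twist term U = kb (1 - cos(theta - theta0)).  Binding
#' and unbinding of ACP-filament and membrane-filament links follow the
#' Bell rate law k = k0 exp(-sigma (l - l0)^2 / (2 kBT)) converted to
#' per-interval probabilities P = 1 - exp(-k dt).
#'
#' @param kbond filament spring constant; default 8e4.
#' @param kangle filament bending stiffness; default 350.
#' @param kacp ACP spring constant; default 8e3 (also used for
#'   membrane-filament links).
#' @param kb ACP-filament bending (four-body twist) stiffness; default 550.
#' @param kt ACP-filament torsion constant from the shipped table; kept for
#'   completeness, the four-body term uses \code{kb}.
#' @param kon0,koff0 zero-strain binding/unbinding rates; default 26e-4.
#' @param sigma_on,sigma_off Bell switch strengths, one per link kind
#'   (ACP-filament, membrane-filament); defaults 3.5e-4 and 1e-4.
#' @param don,doff binding/unbinding distances; default 0.25.
#' @param acp_l0 equilibrium ACP spring length, the reference length in the
#'   binding rate for unbound candidates; default 0.2.
#' @param bond_r0 filament backbone bond length; default 0.25.
#' @param bind_every evaluate the stochastic binding step every this many
#'   integration steps; default 10.
#' @param kBT energy scale.
#' @return object of class \code{cyto_params}.
#' @export
cyto_params <- function(kbond = 8e4, kangle = 350, kacp = 8e3, kb = 550,
                        kt = 470, kon0 = 26e-4, koff0 = 26e-4,
                        sigma_on = c(3.5e-4, 1e-4),
                        sigma_off = c(3.5e-4, 1e-4),
                        don = 0.25, doff = 0.25, acp_l0 = 0.2,
                        bond_r0 = 0.25, bind_every = 10L, kBT = 1) {
  stopifnot(kbond >= 0, kangle >= 0, kacp >= 0, kb >= 0, don > 0, doff > 0)
  structure(list(kbond = kbond, kangle = kangle, kacp = kacp, kb = kb,
                 kt = kt, kon0 = kon0, koff0 = koff0,
                 sigma_on = rep_len(sigma_on, 2),
                 sigma_off = rep_len(sigma_off, 2),
                 don = don, doff = doff, acp_l0 = acp_l0,
                 bond_r0 = bond_r0, bind_every = as.integer(bind_every),
                 kBT = kBT),
            class = "cyto_params")
}

#' Bell-model binding/unbinding rate
#'
#' k(l) = k0 exp(-sigma (l - l0)^2 / (2 kBT)): the rate equals k0 when the
#' ligand-receptor distance is l0 and falls off symmetrically around it.
#'
#' @param l instantaneous distance; \code{l0} reference distance.
#' @param k0 zero-strain rate; \code{sigma} switch strength; \code{kBT}
#'   energy scale.
#' @return rate (same units as \code{k0}).
#' @export
binding_rate <- function(l, l0, k0, sigma, kBT = 1) {
  stopifnot(all(l >= 0))
  k0 * exp(-sigma * (l - l0)^2 / (2 * kBT))
}

#' Generate a random non-intersecting filament network
#'
#' Straight filament seeds with uniform random origin and orientation.
#' Each filament carries between \code{Naf[1]} and \code{Naf[2]} particles
#' at \code{bond_r0} spacing (so lengths span the configured filament
#' length range); filament sizes are drawn so the total particle count hits
#' \code{Na} exactly.  Non-intersection is enforced as a minimum clearance
#' between any two particles of different filaments.  \code{n_acp} free
#' ACPs are placed uniformly in the region.
#'
#' @param Na total number of filament (actin) particles; default 2698.
#' @param Naf admissible per-filament particle counts; default c(3, 11).
#' @param n_acp number of ACPs; default 1000.
#' @param region either \code{list(kind = "box", box = c(Lx, Ly, Lz),
#'   periodic = c(TRUE, TRUE, TRUE))} (chains may wrap only through
#'   periodic dimensions; otherwise they must fit inside) or
#'   \code{list(kind = "sphere", radius =, center =)}.
#' @param clearance minimum inter-filament particle distance; default one
#'   bond length.
#' @param bond_r0 backbone spacing; default 0.25.
#' @param seed RNG seed (same seed, same network).
#' @param max_retry placement attempts per filament before giving up.
#' @return object of class \code{cytoskeleton_network}: \code{actin_pos},
#'   \code{acp_pos}, \code{filaments} (list of row-index chains into
#'   \code{actin_pos}), \code{bonds} / \code{angles} local index tables.
#' @export
generate_filament_network <- function(Na = 2698, Naf = c(3, 11),
                                      n_acp = 1000, region, clearance = 0.25,
                                      bond_r0 = 0.25, seed = 1,
                                      max_retry = 2000) {
  set.seed(seed)
  if (region$kind == "box" && is.null(region$periodic))
    region$periodic <- c(TRUE, TRUE, TRUE)
  draw_point <- function(n) {
    if (region$kind == "box") {
      cbind(runif(n, 0, region$box[1]), runif(n, 0, region$box[2]),
            runif(n, 0, region$box[3]))
    } else {
      # uniform in sphere
      out <- matrix(0, n, 3)
      for (k in seq_len(n)) {
        repeat {
          p <- runif(3, -1, 1)
          if (sum(p^2) <= 1) break
        }
        out[k, ] <- region$center + region$radius * p
      }
      out
    }
  }
  inside <- function(pts) {
    if (region$kind == "box") {
      ok <- TRUE
      for (d in 1:3)
        if (!region$periodic[d])
          ok <- ok && all(pts[, d] >= 0 & pts[, d] <= region$box[d])
      ok
    } else {
      all(sqrt(rowSums(sweep(pts, 2, region$center)^2)) <= region$radius)
    }
  }
  wrap <- function(pts) {
    if (region$kind == "box")
      for (d in which(region$periodic))
        pts[, d] <- pts[, d] %% region$box[d]
    pts
  }
  mindist2 <- function(pts, ref) {
    # squared min distance from each new point to the reference cloud
    if (is.null(ref) || nrow(ref) == 0) return(Inf)
    m <- Inf
    for (k in seq_len(nrow(pts))) {
      d <- sweep(ref, 2, pts[k, ])
      if (region$kind == "box")
        for (dd in which(region$periodic)) {
          L <- region$box[dd]
          d[, dd] <- d[, dd] - L * round(d[, dd] / L)
        }
      m <- min(m, min(rowSums(d^2)))
    }
    m
  }

  actin <- NULL
  filaments <- list()
  total <- 0L
  while (total < Na) {
    r <- Na - total
    lo <- Naf[1]; hi <- min(Naf[2], r)
    if (hi < lo) stop("cannot reach Na exactly with the given Naf range")
    naf <- if (r <= Naf[2]) r else sample(lo:hi, 1)
    # never leave a remainder smaller than the minimum filament size
    while (r - naf > 0 && r - naf < Naf[1]) naf <- naf - 1L
    placed <- FALSE
    for (try in seq_len(max_retry)) {
      o <- draw_point(1)[1, ]
      u <- rnorm(3); u <- u / sqrt(sum(u^2))
      pts <- t(o + outer(u, 0:(naf - 1)) * bond_r0)
      if (!inside(pts)) next
      if (mindist2(pts, actin) < clearance^2) next
      pts <- wrap(pts)
      filaments[[length(filaments) + 1L]] <- total + seq_len(naf)
      actin <- rbind(actin, pts)
      total <- total + as.integer(naf)
      placed <- TRUE
      break
    }
    if (!placed)
      stop("filament placement failed after ", max_retry,
           " attempts; lower the density or enlarge the region")
  }
  acp <- wrap(draw_point(n_acp))

  bonds <- do.call(rbind, lapply(filaments, function(ch)
    cbind(ch[-length(ch)], ch[-1])))
  angles <- do.call(rbind, lapply(filaments, function(ch) {
    if (length(ch) < 3) return(NULL)
    cbind(ch[1:(length(ch) - 2)], ch[2:(length(ch) - 1)], ch[3:length(ch)])
  }))
  structure(list(actin_pos = actin, acp_pos = acp, filaments = filaments,
                 bonds = bonds, angles = angles, bond_r0 = bond_r0,
                 region = region, seed = seed),
            class = "cytoskeleton_network")
}

#' @export
print.cytoskeleton_network <- function(x, ...) {
  cat("cytoskeleton_network:", length(x$filaments), "filaments,",
      nrow(x$actin_pos), "filament particles,", nrow(x$acp_pos), "ACPs\n")
  cat("chain sizes:", paste(range(lengths(x$filaments)), collapse = "-"),
      " bond length:", x$bond_r0, "\n")
  invisible(x)
}

# Engine bond/binding attachments for a network whose actin particles start
# at index offset_a + 1 and ACPs at offset_c + 1 in the particle system.
network_attachments <- function(net, cp, offset_a = 0L, offset_c = 0L) {
  list(
    harm = list(ij = net$bonds + offset_a,
                r0 = rep(net$bond_r0, nrow(net$bonds)),
                k = rep(cp$kbond, nrow(net$bonds))),
    angles = if (!is.null(net$angles))
      list(ijk = net$angles + offset_a,
           theta0 = rep(pi, nrow(net$angles)),
           k = rep(cp$kangle, nrow(net$angles))) else NULL,
    binding = list(kon0 = cp$kon0, koff0 = cp$koff0,
                   sigma_on = cp$sigma_on, sigma_off = cp$sigma_off,
                   don = cp$don, doff = cp$doff, l0 = cp$acp_l0,
                   every = cp$bind_every, k = c(cp$kacp, cp$kacp)))
}

#' One stochastic Bell binding/unbinding sweep
#'
#' Evaluates, for the current configuration, the unbinding probability of
#' every existing dynamic bond at or beyond \code{doff} and the binding
#' probability of every eligible unbound (ACP, filament) or
#' (membrane, filament) pair closer than \code{don}, drawing a Bernoulli
#' outcome for each.  Capacity invariants (an ACP holds at most two
#' filament links, a filament particle at most one ACP link,
#' membrane-filament links are one-to-one) are preserved.
#'
#' @param sys a \code{particle_system} containing actin/acp (and possibly
#'   membrane) particles.
#' @param cp a \code{cyto_params}.
#' @param dyn current dynamic bond table (list with \code{ij}, \code{r0},
#'   \code{kind}) or \code{NULL}.
#' @param dt elapsed time covered by this sweep.
#' @param seed RNG seed.
#' @param pairs a \code{pair_params} (geometry only); default table.
#' @return updated dynamic bond table.
#' @export
stochastic_binding_step <- function(sys, cp, dyn = NULL, dt, seed,
                                    pairs = pair_params(kBT = cp$kBT)) {
  cfg <- integrator_config(kBT = cp$kBT, rng_seed = seed)
  bonds <- list(dyn = dyn)
  binding <- list(kon0 = cp$kon0, koff0 = cp$koff0, sigma_on = cp$sigma_on,
                  sigma_off = cp$sigma_off, don = cp$don, doff = cp$doff,
                  l0 = cp$acp_l0, every = cp$bind_every,
                  k = c(cp$kacp, cp$kacp))
  world <- build_world(sys, pairs, cfg, bonds, binding = binding)
  cpp_binding_sweep(world, dt, as.integer(seed))
}

#' ACP twist energy and forces
#'
#' Sum over junction dihedrals of kb [1 - cos(theta_j - theta0)], with
#' forces as the exact negative gradient.
#'
#' @param sys a \code{particle_system} (any species).
#' @param quads Q x 4 index matrix of dihedral quadruples.
#' @param kb stiffness; \code{theta0} rest angles (recycled).
#' @return list with scalar \code{energy} and N x 3 \code{forces}.
#' @export
acp_twist_energy <- function(sys, quads, kb, theta0 = 0) {
  cfg <- integrator_config()
  pairs0 <- pair_params()
  pairs0$a[] <- 0; pairs0$gamma[] <- 0; pairs0$rc[] <- 0
  bonds <- list(dihedrals = list(ijkl = quads,
                                 theta0 = rep_len(theta0, nrow(quads)),
                                 k = rep_len(kb, nrow(quads))))
  world <- build_world(sys, pairs0, cfg, bonds)
  res <- cpp_forces_energy(world)
  list(energy = res$energies$dihedral, forces = res$forces)
}

# Dihedral quadruples across ACP junctions: for each ACP holding two
# filament links (a-f1, a-f2), the quadruple is (n1, f1, f2, n2) with n1/n2
# chain neighbours of f1/f2; theta0 is the dihedral angle at formation.
.acp_junction_terms <- function(dyn, chains_neighbor, pos) {
  ij <- dyn$ij
  if (is.null(ij) || nrow(ij) == 0) return(NULL)
  acp_rows <- which(dyn$kind == 0)
  if (length(acp_rows) == 0) return(NULL)
  by_acp <- split(acp_rows, ij[acp_rows, 1])
  quads <- NULL; th0 <- NULL
  for (rows in by_acp) {
    if (length(rows) != 2) next
    f1 <- ij[rows[1], 2]; f2 <- ij[rows[2], 2]
    n1 <- chains_neighbor[[as.character(f1)]]
    n2 <- chains_neighbor[[as.character(f2)]]
    if (is.null(n1) || is.null(n2)) next
    q <- c(n1, f1, f2, n2)
    if (length(unique(q)) < 4) next
    quads <- rbind(quads, q)
    th0 <- c(th0, dihedral_angle(pos[q[1], ], pos[q[2], ], pos[q[3], ],
                                 pos[q[4], ]))
  }
  if (is.null(quads)) return(NULL)
  list(quads = unname(quads), theta0 = th0)
}

#' Assemble the full cell: membrane plus cytoskeleton
#'
#' Staged assembly: (1) generate filaments and free ACPs inside the
#' membrane, (2) cross-link the network to saturation (the long-time fixed
#' point of the stochastic binding rule, realised as capacity-respecting
#' greedy matching within \code{don}), (3) place the network inside the
#' membrane so membrane-filament links form by the same rule, (4) activate
#' the ACP twist dihedral constraints at their formation angles, then relax
#' the combined system with kinetics running.
#'
#' @param mem a \code{membrane_system} from \code{\link{build_membrane}}.
#' @param net optional pre-generated \code{cytoskeleton_network}; generated
#'   inside a sphere at 80\% of the membrane radius when \code{NULL}.
#' @param cp a \code{cyto_params}.
#' @param Na,n_acp network size when generating (reduced-scale callers pass
#'   smaller numbers; full scale is 2698 and 1000).
#' @param relax_steps integration steps of relaxation; default 2000.
#' @param dt relaxation time step; small because the stiff filament springs
#'   set the stable step.
#' @param seed RNG seed.
#' @param pairs pair-parameter table.
#' @param percolation_fraction warn if the largest connected network
#'   cluster holds less than this fraction of filament particles.
#' @return object of class \code{cell_system}: the combined \code{sys},
#'   engine attachments (\code{bonds}, \code{membrane}, \code{binding}),
#'   index bookkeeping, and the relaxation observables.
#' @export
assemble_cell <- function(mem, net = NULL, cp = cyto_params(),
                          Na = 2698, n_acp = 1000, relax_steps = 2000,
                          dt = 2e-4, seed = 1, pairs = pair_params(),
                          percolation_fraction = 0.5) {
  mesh <- mem$mesh
  center <- colMeans(mesh$vertices)
  radius <- mean(sqrt(rowSums(sweep(mesh$vertices, 2, center)^2)))
  if (is.null(net))
    net <- generate_filament_network(
      Na = Na, n_acp = n_acp,
      region = list(kind = "sphere", radius = 0.8 * radius, center = center),
      bond_r0 = cp$bond_r0, seed = seed)

  nmem <- nrow(mesh$vertices)
  nact <- nrow(net$actin_pos)
  nacp <- nrow(net$acp_pos)
  pos <- rbind(mem$sys$pos, net$actin_pos, net$acp_pos)
  set.seed(seed + 7L)
  vel <- maxwell_velocities(nmem + nact + nacp, cp$kBT)
  sys <- particle_system(pos = pos, vel = vel,
                         types = c(rep("membrane", nmem),
                                   rep("actin", nact), rep("acp", nacp)),
                         box = mem$sys$box, periodic = mem$sys$periodic)

  natt <- network_attachments(net, cp, offset_a = nmem,
                              offset_c = nmem + nact)
  bonds <- mem$bonds
  bonds$harm <- natt$harm
  bonds$angles <- natt$angles

  # stages 2-3: cross-link to saturation (ACP-filament and membrane-filament)
  cfg <- integrator_config(dt = dt, kBT = cp$kBT, rng_seed = seed)
  world <- build_world(sys, pairs, cfg, c(bonds, list(dyn = NULL)),
                       membrane = mem$membrane, binding = natt$binding)
  dyn <- cpp_bind_saturate(world, as.integer(seed))

  # stage 4: activate junction dihedrals at formation geometry
  nbr <- new.env(hash = TRUE)
  for (ch in net$filaments) {
    gch <- ch + nmem
    for (k in seq_along(gch)) {
      nb <- if (k == 1) gch[2] else gch[k - 1]
      nbr[[as.character(gch[k])]] <- nb
    }
  }
  jt <- .acp_junction_terms(dyn, nbr, sys$pos)
  if (!is.null(jt)) {
    add <- list(ijkl = jt$quads, theta0 = jt$theta0,
                k = rep(cp$kb, nrow(jt$quads)))
    bonds$dihedrals <- list(
      ijkl = rbind(bonds$dihedrals$ijkl, add$ijkl),
      theta0 = c(bonds$dihedrals$theta0, add$theta0),
      k = c(bonds$dihedrals$k, add$k))
  }
  bonds$dyn <- dyn

  frac <- .largest_cluster_fraction(nrow(sys$pos), nact, net$bonds, dyn, nmem)
  if (frac < percolation_fraction)
    warning(sprintf(
      "largest connected network cluster holds %.0f%% of filament particles",
      100 * frac))

  res <- run_dpd(sys, pairs, cfg, nsteps = relax_steps, bonds = bonds,
                 membrane = mem$membrane, binding = natt$binding,
                 sample_every = max(1L, relax_steps %/% 20L))
  bonds$dyn <- res$dyn
  structure(list(sys = res$sys, mesh = mesh, mparams = mem$params,
                 cparams = cp, bonds = bonds, membrane = mem$membrane,
                 binding = natt$binding, pairs = pairs,
                 idx = list(membrane = seq_len(nmem),
                            actin = nmem + seq_len(nact),
                            acp = nmem + nact + seq_len(nacp)),
                 net = net, relax_obs = res$obs, seed = seed),
            class = "cell_system")
}

#' @export
print.cell_system <- function(x, ...) {
  cat("cell_system:", nrow(x$sys$pos), "particles (",
      length(x$idx$membrane), "membrane,", length(x$idx$actin), "actin,",
      length(x$idx$acp), "ACP )\n")
  cat("dynamic links:", nrow(x$bonds$dyn$ij),
      " ( kind ACP-filament:", sum(x$bonds$dyn$kind == 0),
      ", membrane-filament:", sum(x$bonds$dyn$kind == 1), ")\n")
  if (nrow(x$relax_obs) > 0)
    cat("relaxed temperature:",
        signif(mean(tail(x$relax_obs$temperature, 5)), 4), "kBT\n")
  invisible(x)
}

# union-find over filament backbone + dynamic links (ACPs as nodes)
.largest_cluster_fraction <- function(N, nact, chain_bonds, dyn, offset_a) {
  parent <- seq_len(N)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  un <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[ri] <<- rj
  }
  for (b in seq_len(nrow(chain_bonds)))
    un(chain_bonds[b, 1] + offset_a, chain_bonds[b, 2] + offset_a)
  ij <- dyn$ij
  if (!is.null(ij) && nrow(ij) > 0)
    for (b in seq_len(nrow(ij))) un(ij[b, 1], ij[b, 2])
  act_ids <- offset_a + seq_len(nact)
  roots <- vapply(act_ids, find, integer(1))
  max(table(roots)) / nact
}
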