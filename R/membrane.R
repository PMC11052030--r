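#' Membrane material parameters
#'
#' The WLC+POW elastic law, bending stiffness and area/volume constraint
#' constants of the triangulated membrane.  The user-facing stiffness knob
#' is the WLC shear modulus \code{mu0}: given (\code{mu0}, \code{x0},
#' \code{l0}, \code{m}) the persistence length \code{p} and the POW
#' constant \code{kp} are calibrated jointly so that (i) the shear-modulus
#' expression returns \code{mu0} and (ii) the net bond force vanishes at the
#' equilibrium length \code{l0}.  Supplying \code{p} and \code{kp} directly
#' bypasses calibration.
#'
#' @param mu0 target WLC shear modulus (reduced units); default 100.
#' @param x0 equilibrium-to-contour length ratio \code{l0/lmax}; default
#'   0.45 so the 2 l0 rupture length lies below the contour length.
#' @param l0 representative equilibrium bond length (mesh mean is used when
#'   building a membrane).
#' @param m POW exponent; default 2.
#' @param kbending dihedral bending stiffness; default 65.
#' @param ka,kv global area/volume constraint constants; default 7.5e3.
#' @param kd local (per-face) area constant; default 300.
#' @param gamma_bond central (bond-direction) dissipative coefficient; the
#'   matching random coefficient is \code{sqrt(2 gamma_bond kBT)};
#'   default 45.
#' @param gamma_bond_t tangential dissipative coefficient acting on the
#'   non-radial part of the relative velocity (membrane viscosity); same
#'   fluctuation-dissipation pairing, default equal to \code{gamma_bond}.
#' @param kBT energy scale.
#' @param p,kp optional explicit persistence length and POW constant.
#' @param eq6_variant \code{"printed"} evaluates the shear-modulus formula
#'   exactly as printed; \code{"sqrt3"} uses the literature variant with
#'   sqrt(3) prefactors.
#' @param theta0 spontaneous dihedral angle; \code{NULL} means use the
#'   built mesh's own dihedrals (relaxed-sphere spontaneous curvature).
#' @return object of class \code{membrane_params}.
#' @export
membrane_params <- function(mu0 = 100, x0 = 0.45, l0 = 1, m = 2,
                            kbending = 65, ka = 7.5e3, kv = 7.5e3, kd = 300,
                            gamma_bond = 45, gamma_bond_t = gamma_bond,
                            kBT = 1, p = NULL, kp = NULL,
                            eq6_variant = c("printed", "sqrt3"),
                            theta0 = NULL) {
  eq6_variant <- match.arg(eq6_variant)
  stopifnot(x0 > 0, x0 < 1, m > 0, mu0 > 0)
  lmax <- l0 / x0
  if (is.null(p) || is.null(kp)) {
    cal <- calibrate_wlc(mu0, x0, l0, m, kBT, eq6_variant)
    p <- cal$p; kp <- cal$kp
  }
  structure(list(mu0 = mu0, x0 = x0, l0 = l0, lmax = lmax, m = m, p = p,
                 kp = kp, kbending = kbending, ka = ka, kv = kv, kd = kd,
                 gamma_bond = gamma_bond, gamma_bond_t = gamma_bond_t,
                 kBT = kBT,
                 eq6_variant = eq6_variant, theta0 = theta0),
            class = "membrane_params")
}

# helper terms of the shear-modulus expression
.wlc_Q <- function(x0) x0^2 / (1 - x0)^3 - 1 / (4 * (1 - x0)^2) + 1 / 4
.wlc_W <- function(x0) 1 / (4 * (1 - x0)^2) - 1 / 4 + x0

#' WLC shear modulus of a membrane bond
#'
#' Evaluates mu0 = 3 kBT / (4 p lmax x0) * (x0^2 (1-x0)^-3 -
#' 1/(4(1-x0)^2) + 1/4) + 3 kp (m+1) / (4 l0^(m+1)) (the \code{"printed"}
#' variant) or the literature form with sqrt(3) prefactors.
#'
#' @param params a \code{membrane_params} object, or missing if the named
#'   scalars below are given.
#' @param kBT,p,lmax,x0,kp,m scalar inputs (used when \code{params} is
#'   missing).
#' @param variant \code{"printed"} or \code{"sqrt3"}.
#' @return the shear modulus mu0.
#' @export
shear_modulus <- function(params, kBT = 1, p = 1, lmax = 2, x0 = 0.5,
                          kp = 0, m = 2, variant = "printed") {
  if (!missing(params) && inherits(params, "membrane_params")) {
    kBT <- params$kBT; p <- params$p; lmax <- params$lmax; x0 <- params$x0
    kp <- params$kp; m <- params$m; variant <- params$eq6_variant
  }
  if (x0 <= 0 || x0 >= 1) stop("x0 must lie strictly between 0 and 1")
  l0 <- x0 * lmax
  pre <- if (variant == "sqrt3") sqrt(3) else 3
  pre * kBT / (4 * p * lmax * x0) * .wlc_Q(x0) +
    pre * kp * (m + 1) / (4 * l0^(m + 1))
}

#' Calibrate (p, kp) from a target shear modulus
#'
#' Solves the two conditions jointly: the shear-modulus expression equals
#' \code{mu0}, and the WLC attraction balances the POW repulsion at
#' \code{l0} (zero net bond force at equilibrium).  Both are linear in
#' \code{1/p} once combined, so the solution is closed-form.
#'
#' @inheritParams shear_modulus
#' @param mu0 target modulus; \code{l0} equilibrium length.
#' @return list with \code{p}, \code{kp}, \code{lmax}.
#' @export
calibrate_wlc <- function(mu0, x0, l0, m = 2, kBT = 1, variant = "printed") {
  lmax <- l0 / x0
  pre <- if (variant == "sqrt3") sqrt(3) else 3
  # mu0 = pre*kBT/(4p) * [ Q/(lmax x0) + (m+1) W / l0 ]   (after substituting
  # the force balance kp = l0^m (kBT/p) W)
  p <- pre * kBT / (4 * mu0) * (.wlc_Q(x0) / (lmax * x0) +
                                (m + 1) * .wlc_W(x0) / l0)
  kp <- l0^m * (kBT / p) * .wlc_W(x0)
  list(p = p, kp = kp, lmax = lmax)
}

#' Scalar WLC+POW bond force
#'
#' Positive values are repulsive (push the bonded pair apart).  The
#' attractive WLC term is -(kBT/p) [1/(4(1-x)^2) - 1/4 + x] with
#' x = l/lmax; the repulsive POW term is +kp/l^m.
#'
#' @param l bond length, 0 < l < lmax.
#' @param params a \code{membrane_params}.
#' @param lmax,kp optional per-bond overrides.
#' @return scalar force along the bond.
#' @export
wlc_pow_bond_force <- function(l, params, lmax = params$lmax,
                               kp = params$kp) {
  if (any(l <= 0)) stop("bond length must be positive")
  if (any(l >= lmax))
    stop("bond length beyond contour length lmax; bond must rupture first")
  x <- l / lmax
  kp / l^params$m - (params$kBT / params$p) * .wlc_W_at(x)
}

.wlc_W_at <- function(x) 1 / (4 * (1 - x)^2) - 1 / 4 + x

#' Assemble a free membrane system
#'
#' Builds an icosphere mesh, attaches WLC+POW bonds per edge (per-edge
#' \code{lmax = l0/x0} and per-edge \code{kp} from the force balance, so
#' every edge is in equilibrium as built), cosine dihedral bending across
#' every edge, and the global/local area and volume constraints, inside a
#' large open (non-periodic) box.
#'
#' @param radius,level icosphere geometry (defaults: cell radius 8,
#'   subdivision level 3).
#' @param params a \code{membrane_params}; its \code{l0} is replaced by the
#'   built mesh's mean edge length before calibration.
#' @param kBT temperature used for the initial Maxwell-Boltzmann velocities.
#' @param box_pad padding added around the sphere to size the open box.
#' @param seed RNG seed for initial velocities.
#' @return list of class \code{membrane_system}: \code{sys}
#'   (a \code{particle_system}), \code{mesh}, \code{params}, and engine
#'   attachment lists \code{bonds} and \code{membrane}.
#' @export
build_membrane <- function(radius = 8, level = 3, params = NULL, kBT = 1,
                           box_pad = 6, seed = 1) {
  mesh <- build_membrane_mesh(radius, level,
                              center = rep(radius + box_pad, 3))
  l0bar <- mean(mesh$l0)
  if (is.null(params)) params <- membrane_params(l0 = l0bar, kBT = kBT)
  else if (abs(params$l0 - l0bar) > 1e-12)
    params <- membrane_params(mu0 = params$mu0, x0 = params$x0, l0 = l0bar,
                              m = params$m, kbending = params$kbending,
                              ka = params$ka, kv = params$kv, kd = params$kd,
                              gamma_bond = params$gamma_bond,
                              gamma_bond_t = params$gamma_bond_t,
                              kBT = params$kBT,
                              eq6_variant = params$eq6_variant,
                              theta0 = params$theta0)
  L <- 2 * (radius + box_pad)
  set.seed(seed)
  vel <- remove_rigid_drift(mesh$vertices,
                            maxwell_velocities(nrow(mesh$vertices), kBT))
  sys <- particle_system(pos = mesh$vertices, vel = vel,
                         types = "membrane", box = rep(L, 3),
                         periodic = c(FALSE, FALSE, FALSE))
  membrane_attachments(mesh, params, sys)
}

#' Engine attachments for a membrane mesh
#'
#' @param mesh a \code{membrane_mesh}.
#' @param params a \code{membrane_params}.
#' @param sys the \code{particle_system} holding the mesh vertices (vertex k
#'   of the mesh is particle \code{offset + k}).
#' @param offset index offset of the first mesh vertex in \code{sys}.
#' @return list with \code{sys}, \code{mesh}, \code{params}, \code{bonds},
#'   \code{membrane} ready for \code{\link{run_dpd}}.
#' @export
membrane_attachments <- function(mesh, params, sys, offset = 0L) {
  per_kp <- mesh$l0^params$m * (params$kBT / params$p) * .wlc_W(params$x0)
  th0 <- if (is.null(params$theta0)) mesh$dihedral0
         else rep(params$theta0, nrow(mesh$dihedrals))
  bonds <- list(
    wlc = list(ij = mesh$edges + offset, l0 = mesh$l0,
               lmax = mesh$l0 / params$x0, kp = per_kp,
               p = params$p, m = params$m, gamma = params$gamma_bond,
               gamma_t = params$gamma_bond_t),
    dihedrals = list(ijkl = mesh$dihedrals + offset, theta0 = th0,
                     k = rep(params$kbending, nrow(mesh$dihedrals))))
  membrane <- list(faces = mesh$faces + offset, face_a0 = mesh$face_a0,
                   A0 = mesh$A0, V0 = mesh$V0, ka = params$ka,
                   kv = params$kv, kd = params$kd)
  structure(list(sys = sys, mesh = mesh, params = params, bonds = bonds,
                 membrane = membrane, offset = offset),
            class = "membrane_system")
}
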